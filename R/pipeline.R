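#' Write / read a flat run configuration
#'
#' The configuration is a flat key=value text file covering paths and
#' thresholds of a full profiling run; \code{readRunConfig} restores it
#' with numeric fields coerced back, so a round trip reproduces the
#' configuration exactly.
#'
#' @param config named list of scalar values.
#' @param path file path.
#' @return \code{writeRunConfig}: \code{path}, invisibly;
#'   \code{readRunConfig}: named list.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k)
    paste0(k, "=", as.character(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && grepl("^-?[0-9.eE+-]+$", v)) num else v
  })
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

#' Default full-profile configuration
#'
#' @return named list of the documented defaults.
#' @export
defaultRunConfig <- function() {
  list(min_identity = 60, call_threshold = 97, min_clones = 1,
       chimera_window = 60, chimera_step = 10, chimera_margin = 2,
       chimera_support = 3, bootstrap_reps = 100, seed = 1,
       distance_model = "p")
}

#' Run the full profiling pipeline
#'
#' Wires the stages together: per-clone genotyping of every compartment
#' library, occurrence-table construction, optional comparison against an
#' expected table, a neighbor-joining tree of the reference library, and
#' a manifest recording per-stage counts and md5 checksums of every
#' artifact. Reruns with identical inputs and configuration reproduce
#' byte-identical primary outputs.
#'
#' @param samples named list of clone \code{DNAStringSet}s (compartment
#'   label -> clones), or a directory containing one FASTA per
#'   compartment (filename = label).
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param out_dir output directory (created if needed).
#' @param expected optional expected \linkS4class{OccurrenceTable}.
#' @param config named list as from \code{\link{defaultRunConfig}}.
#' @return invisible list with table, comparison, tree, manifest.
#' @export
runFullProfile <- function(samples, library, out_dir,
                           expected = NULL,
                           config = defaultRunConfig()) {
  if (is.character(samples) && length(samples) == 1) {
    if (!dir.exists(samples)) stop("sample directory not found: ", samples)
    files <- list.files(samples, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files in ", samples)
    nm <- tools::file_path_sans_ext(basename(files))
    samples <- setNames(lapply(files, readFasta), nm)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(defaultRunConfig(), config)
  manifest <- list(stages = list(), artifacts = list())

  tab <- profileSamples(samples, library, min_clones = cfg$min_clones,
                        call_threshold = cfg$call_threshold)
  n_clones <- vapply(samples, length, integer(1))
  manifest$stages$genotyping <- list(
    clones_read = sum(n_clones),
    clones_unassigned = sum(unassignedCounts(tab), na.rm = TRUE))
  writeOccurrenceTable(tab, file.path(out_dir, "occurrence_counts.tsv"))
  writeOccurrenceTable(tab, file.path(out_dir, "occurrence_presence.tsv"),
                       what = "presence")

  cmp <- NULL
  if (!is.null(expected)) {
    cmp <- compareToExpected(tab, expected)
    jsonlite::write_json(
      list(n_agree = cmp$n_agree, n_disagree = cmp$n_disagree,
           diffs = cmp$diffs),
      file.path(out_dir, "expected_diff.json"), auto_unbox = TRUE)
    manifest$stages$comparison <- list(n_disagree = cmp$n_disagree)
  }

  d <- seqDistances(refSeqs(library), model = cfg$distance_model)
  tr <- njTree(d)
  ape::write.tree(tr, file.path(out_dir, "library_nj.nwk"))
  manifest$stages$tree <- list(n_taxa = length(tr$tip.label))

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$artifacts <- as.list(tools::md5sum(files))
  names(manifest$artifacts) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(table = tab, comparison = cmp, tree = tr,
                 manifest = manifest))
}
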