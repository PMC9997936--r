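#' Path to a bundled data file
#' @noRd
extdata <- function(file) {
  system.file("extdata", file, package = "OphioITS", mustWork = TRUE)
}

#' Load the primer table
#'
#' Reads a TSV of primer definitions (columns \code{name}, \code{direction},
#' \code{sequence}, \code{pair_label}) together with the primer-pair table
#' that assigns forward/reverse pairings to amplification targets. The
#' bundled default reproduces the published set: the ITS5/ITS4 universal
#' primers, the Genotype #1 (Hsprp1-3) and AT-biased (HsATp1-3)
#' genotype-specific primers, the species-specific pairs Prp2/Prp5,
#' Pcp3/Pcp7, Php4/Php6 and Tsp1/Tsp3, and the M13F/M13R vector primers.
#'
#' @param path primer TSV; defaults to the bundled table.
#' @param pairs_path primer-pair TSV; defaults to the bundled table.
#' @return list with elements \code{primers} (data.frame: name, direction,
#'   sequence, pair_label) and \code{pairs} (data.frame: forward, reverse,
#'   label, target).
#' @examples
#' p <- loadPrimerTable()
#' subset(p$primers, name == "ITS5")
#' @export
loadPrimerTable <- function(path = extdata("primers.tsv"),
                            pairs_path = extdata("primer_pairs.tsv")) {
  pr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "direction", "sequence")
  if (!all(need %in% colnames(pr)))
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pr$name))
    stop("duplicate primer name(s): ",
         paste(unique(pr$name[duplicated(pr$name)]), collapse = ", "))
  bad <- !pr$direction %in% c("forward", "reverse")
  if (any(bad))
    stop("unknown direction token(s): ",
         paste(unique(pr$direction[bad]), collapse = ", "))
  pr$sequence <- toupper(pr$sequence)
  for (k in seq_len(nrow(pr))) {
    m <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")),
                 pr$sequence[k])
    if (m > 0)
      stop(sprintf("primer '%s' has non-IUPAC character at position %d",
                   pr$name[k], m))
  }
  pairs <- utils::read.delim(pairs_path, stringsAsFactors = FALSE)
  missing <- setdiff(c(pairs$forward, pairs$reverse), pr$name)
  if (length(missing))
    stop("pair table refers to unknown primers: ",
         paste(missing, collapse = ", "))
  fd <- pr$direction[match(pairs$forward, pr$name)]
  rd <- pr$direction[match(pairs$reverse, pr$name)]
  if (any(fd != "forward") || any(rd != "reverse"))
    stop("pair table mismatches primer directions")
  list(primers = pr, pairs = pairs)
}

#' Fetch one primer sequence by name
#' @param name primer name, e.g. "ITS5".
#' @param table result of \code{\link{loadPrimerTable}}.
#' @return character primer sequence.
#' @export
primerSeq <- function(name, table = loadPrimerTable()) {
  i <- match(name, table$primers$name)
  if (is.na(i)) stop("unknown primer: ", name)
  table$primers$sequence[i]
}

#' Load the accession registry
#'
#' The registry maps GenBank accessions to genotype labels (#1..#17,
#' species controls, the AB067719-type outgroup), compositional class
#' (GC-biased / AT-biased / outgroup / species-control) and AT-clade
#' cluster (A / B / GC / none).
#'
#' @param path registry TSV; defaults to the bundled table.
#' @return data.frame with columns accession, genotype_id, class, cluster,
#'   note.
#' @export
loadRegistry <- function(path = extdata("registry.tsv")) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "genotype_id", "class", "cluster")
  if (!all(need %in% colnames(reg)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(reg$accession))
    stop("duplicate accession(s) in registry")
  reg
}

#' Strip a GenBank version suffix
#' @noRd
stripVersion <- function(x) sub("\\.[0-9]+$", "", x)

#' Load a reference genotype library
#'
#' Combines a FASTA of accessioned ITS sequences with the registry to build
#' a \linkS4class{ReferenceLibrary}. FASTA record ids are matched to
#' registry accessions after stripping version suffixes. Records absent
#' from the registry are kept with class \code{"unregistered"} (with a
#' warning); registry accessions absent from the FASTA are reported in the
#' \code{"missing"} attribute, not silently dropped.
#'
#' @param fasta_path FASTA of reference sequences, record ids = accessions.
#' @param registry_path registry TSV (default: bundled).
#' @param segments optional named list of segment annotations
#'   (\link[IRanges]{IRanges} named among flank5/its1/r58s/its2/flank3),
#'   keyed by accession.
#' @return a \linkS4class{ReferenceLibrary}; attribute \code{"missing"}
#'   lists registry accessions without a sequence.
#' @export
loadReferenceLibrary <- function(fasta_path,
                                 registry_path = extdata("registry.tsv"),
                                 segments = NULL) {
  seqs <- readFasta(fasta_path)
  names(seqs) <- stripVersion(names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  reg <- loadRegistry(registry_path)
  idx <- match(names(seqs), reg$accession)
  if (anyNA(idx))
    warning("accession(s) not in registry, classified 'unregistered': ",
            paste(names(seqs)[is.na(idx)], collapse = ", "))
  info <- S4Vectors::DataFrame(
    genotype_id = ifelse(is.na(idx), names(seqs), reg$genotype_id[idx]),
    accession = names(seqs),
    class = ifelse(is.na(idx), "unregistered", reg$class[idx]),
    cluster = ifelse(is.na(idx), "none", reg$cluster[idx]),
    row.names = names(seqs))
  segl <- rep(list(NULL), length(seqs))
  names(segl) <- names(seqs)
  if (!is.null(segments)) {
    keep <- intersect(names(segments), names(seqs))
    segl[keep] <- segments[keep]
  }
  lib <- new("ReferenceLibrary", seqs = seqs, info = info, segments = segl)
  missing <- setdiff(reg$accession, names(seqs))
  if (length(missing))
    message("registry accession(s) without sequence: ",
            paste(missing, collapse = ", "))
  attr(lib, "missing") <- missing
  lib
}
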