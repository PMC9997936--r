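#' Profile compartment clone libraries into an occurrence table
#'
#' Genotypes every clone of every compartment library via
#' \code{\link{callGenotype}} and tabulates clone counts per taxon and
#' compartment. A taxon is present when at least \code{min_clones} of a
#' compartment's clones call to it; clones that fall below the call
#' threshold are tallied as unassigned. Empty samples yield an
#' all-\code{NA} (unassessed) column. Cells with a nonzero count below
#' \code{min_clones} are reported in the \code{"near_miss"} attribute.
#'
#' @param samples named list of clone sets (\code{DNAStringSet} each);
#'   names are the compartment labels.
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param min_clones presence threshold (default 1).
#' @param call_threshold identity threshold passed to
#'   \code{\link{callGenotype}}.
#' @param params alignment parameters.
#' @param check_chimera run per-clone chimera detection (slower; off by
#'   default since presence calls do not depend on it).
#' @return an \linkS4class{OccurrenceTable}.
#' @export
profileSamples <- function(samples, library, min_clones = 1,
                           call_threshold = 97, params = alignParams(),
                           check_chimera = FALSE) {
  stopifnot(is.list(samples), !is.null(names(samples)),
            !anyDuplicated(names(samples)))
  taxa <- unique(refInfo(library)$genotype_id)
  counts <- matrix(0, nrow = length(taxa), ncol = length(samples),
                   dimnames = list(taxa, names(samples)))
  unassigned <- setNames(numeric(length(samples)), names(samples))
  for (comp in names(samples)) {
    clones <- samples[[comp]]
    if (length(clones) == 0) {
      counts[, comp] <- NA_real_
      unassigned[comp] <- NA_real_
      next
    }
    for (k in seq_along(clones)) {
      call <- callGenotype(clones[k], library, call_threshold, params,
                           check_chimera = check_chimera)
      if (call$genotype == "unassigned")
        unassigned[comp] <- unassigned[comp] + 1
      else counts[call$genotype, comp] <- counts[call$genotype, comp] + 1
    }
  }
  out <- new("OccurrenceTable", counts = counts, unassigned = unassigned,
             minClones = min_clones)
  nm <- which(counts > 0 & counts < min_clones, arr.ind = TRUE)
  attr(out, "near_miss") <- data.frame(
    taxon = rownames(counts)[nm[, 1]],
    compartment = colnames(counts)[nm[, 2]],
    n_clones = counts[nm], stringsAsFactors = FALSE)
  out
}

#' Load the bundled expected occurrence table
#'
#' The bundled fixture transcribes the published compartment-by-genotype
#' presence/absence pattern (including the absence of Cluster-B genotypes
#' #4 and #15 from both ascospore columns, #13 only in semiejected and
#' #14 only in fully ejected ascospores).
#'
#' @param path TSV with a \code{taxon} column and one 0/1 column per
#'   compartment; defaults to the bundled fixture.
#' @return an \linkS4class{OccurrenceTable} (presence encoded as counts
#'   of 1).
#' @export
expectedOccurrence <- function(path = extdata("table2_expected.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$taxon
  storage.mode(m) <- "numeric"
  new("OccurrenceTable", counts = m,
      unassigned = setNames(numeric(ncol(m)), colnames(m)), minClones = 1)
}

#' Compare an observed occurrence table against an expected one
#'
#' Compares presence/absence cell by cell after checking that the row and
#' column label sets match. Cells where exactly one side is unassessed
#' (NA) count as disagreements and are listed.
#'
#' @param observed,expected \linkS4class{OccurrenceTable} objects with
#'   identical taxon/compartment label sets.
#' @return list with diffs (data.frame taxon, compartment, observed,
#'   expected), n_agree, n_disagree and identical (logical).
#' @export
compareToExpected <- function(observed, expected) {
  po <- presenceMatrix(observed); pe <- presenceMatrix(expected)
  if (!setequal(rownames(po), rownames(pe)) ||
      !setequal(colnames(po), colnames(pe))) {
    bad <- c(setdiff(rownames(po), rownames(pe)),
             setdiff(rownames(pe), rownames(po)),
             setdiff(colnames(po), colnames(pe)),
             setdiff(colnames(pe), colnames(po)))
    stop("label mismatch between tables: ", paste(bad, collapse = ", "))
  }
  pe <- pe[rownames(po), colnames(po), drop = FALSE]
  same <- (po == pe) | (is.na(po) & is.na(pe))
  same[is.na(same)] <- FALSE
  idx <- which(!same, arr.ind = TRUE)
  diffs <- data.frame(taxon = rownames(po)[idx[, 1]],
                      compartment = colnames(po)[idx[, 2]],
                      observed = po[idx], expected = pe[idx],
                      stringsAsFactors = FALSE)
  list(diffs = diffs, n_agree = sum(same),
       n_disagree = sum(!same), identical = all(same))
}

#' Write an occurrence table as TSV
#'
#' @param x an \linkS4class{OccurrenceTable}.
#' @param path output path.
#' @param what "counts" or "presence".
#' @return \code{path}, invisibly.
#' @export
writeOccurrenceTable <- function(x, path, what = c("counts", "presence")) {
  what <- match.arg(what)
  m <- if (what == "counts") occurrenceCounts(x)
       else ifelse(presenceMatrix(x), 1, 0)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
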