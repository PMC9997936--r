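#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch alignment under the given
#' \linkS4class{AlignmentParams}. Traceback tie-breaking is fixed
#' (substitution preferred over a gap in \code{a}, preferred over a gap in
#' \code{b}) so results are bit-reproducible.
#'
#' @param a,b sequences: character strings, \link[Biostrings]{DNAString} or
#'   single-element \code{DNAStringSet} objects.
#' @param params an \linkS4class{AlignmentParams}.
#' @param idA,idB optional identifiers carried into the result.
#' @return a \linkS4class{PairwiseAln}.
#' @examples
#' globalAlign("ACGT", "AGT")
#' @export
globalAlign <- function(a, b, params = alignParams(), idA = "a", idB = "b") {
  a <- asSeqChar(a); b <- asSeqChar(b)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  res <- .nw_align_cpp(a, b, params@match, params@mismatch, params@gapOpen,
                       params@gapExtend, params@terminalGaps == "free")
  new("PairwiseAln", alignedA = res$aligned_a, alignedB = res$aligned_b,
      idA = idA, idB = idB, score = res$score, params = params)
}

# coerce the accepted sequence representations to an uppercase string
asSeqChar <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1) stop("expected a single sequence")
    x <- as.character(x)
  } else if (methods::is(x, "DNAString") || methods::is(x, "XString")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1)
    stop("sequence must be a single character string or DNAString(Set)")
  toupper(x)
}

#' Exhaustive-enumeration alignment score (oracle)
#'
#' Best achievable global alignment score obtained by enumerating every
#' monotone alignment path, independently of the dynamic-programming
#' aligner. Exponential in sequence length; restricted to short inputs.
#'
#' @inheritParams globalAlign
#' @return numeric score.
#' @export
bruteForceScore <- function(a, b, params = alignParams()) {
  .nw_score_brute_cpp(asSeqChar(a), asSeqChar(b), params@match,
                      params@mismatch, params@gapOpen, params@gapExtend,
                      params@terminalGaps == "free")
}

# per-column view of an alignment: characters and 1-based sequence
# positions (NA at gap columns)
alnColumns <- function(aln) {
  a <- strsplit(aln@alignedA, "")[[1]]
  b <- strsplit(aln@alignedB, "")[[1]]
  apos <- ifelse(a == "-", NA_integer_, cumsum(a != "-"))
  bpos <- ifelse(b == "-", NA_integer_, cumsum(b != "-"))
  list(a = a, b = b, apos = apos, bpos = bpos)
}

#' Percent identity of an alignment
#'
#' 100 x identical columns / counted columns. Under
#' \code{"exclude_terminal_gaps"} (the default convention for GenBank-style
#' percent-homology figures) leading and trailing gap columns are not
#' counted; internal gap columns always count as non-identical. Ambiguity
#' codes match only themselves (no partial credit).
#'
#' @param aln a \linkS4class{PairwiseAln}.
#' @param convention "exclude_terminal_gaps" (default) or "all_columns".
#' @param cols optional integer vector restricting the computation to a
#'   subset of alignment columns (used for segment-wise identities).
#' @return percentage in [0, 100].
#' @export
percentIdentity <- function(aln,
                            convention = c("exclude_terminal_gaps",
                                           "all_columns"),
                            cols = NULL) {
  convention <- match.arg(convention)
  cc <- alnColumns(aln)
  keep <- if (is.null(cols)) seq_along(cc$a) else cols
  a <- cc$a[keep]; b <- cc$b[keep]
  if (convention == "exclude_terminal_gaps") {
    res <- which(a != "-" & b != "-")
    if (!length(res)) stop("no counted columns in alignment")
    span <- res[1]:res[length(res)]
    a <- a[span]; b <- b[span]
  }
  if (!length(a)) stop("no counted columns in alignment")
  100 * sum(a == b & a != "-") / length(a)
}

#' Project reference segment annotations onto a query
#'
#' Maps ITS segment boundaries (flank5, its1, r58s, its2, flank3) of an
#' annotated reference through a global alignment into query coordinates.
#' Boundaries falling in query gaps snap to the nearest query residue
#' inside the segment; segments entirely deleted or truncated from the
#' query are dropped from the result.
#'
#' @param reference a \linkS4class{ReferenceLibrary} of length one, or an
#'   index into \code{library}; must carry segment annotations.
#' @param query query sequence (string or DNAString(Set)).
#' @param params alignment parameters.
#' @param min_identity minimum full-sequence percent identity below which
#'   projection is refused (default 50).
#' @param min_overlap minimum number of residue-aligned columns; shorter
#'   overlaps (chance alignments of small fragments) are refused.
#' @return named \link[IRanges]{IRanges} in query coordinates.
#' @export
projectSegments <- function(reference, query, params = alignParams(),
                            min_identity = 50, min_overlap = 50) {
  stopifnot(methods::is(reference, "ReferenceLibrary"),
            length(reference) == 1)
  seg <- refSegments(reference)[[1]]
  if (is.null(seg)) stop("reference has no segment annotation")
  aln <- globalAlign(refSeqs(reference)[[1]], query, params,
                     idA = names(refSeqs(reference)), idB = "query")
  pid <- percentIdentity(aln)
  cc <- alnColumns(aln)
  overlap <- sum(cc$a != "-" & cc$b != "-")
  if (pid < min_identity || overlap < min_overlap)
    stop(sprintf(
      "no reliable projection: identity %.1f%% over %d aligned columns",
      pid, overlap))
  out_s <- integer(); out_e <- integer(); out_n <- character()
  for (k in seq_along(seg)) {
    cols <- which(!is.na(cc$apos) & cc$apos >= IRanges::start(seg)[k] &
                    cc$apos <= IRanges::end(seg)[k])
    qpos <- cc$bpos[cols]
    qpos <- qpos[!is.na(qpos)]
    if (!length(qpos)) next  # segment absent from the query
    out_s <- c(out_s, min(qpos)); out_e <- c(out_e, max(qpos))
    out_n <- c(out_n, names(seg)[k])
  }
  out <- IRanges::IRanges(start = out_s, end = out_e)
  names(out) <- out_n
  out
}

#' Segment-wise identity profile of a query against a reference
#'
#' Computes percent identity for the ITS1, 5.8S and ITS2 segments and for
#' the full in-scope ITS1-5.8S-ITS2 region (18S/28S flanks excluded). The
#' full-region value is computed on the concatenated region, not averaged
#' from the three parts. Identities use the exclude-terminal-gaps
#' convention, so partial-coverage queries are scored only where they
#' overlap a segment.
#'
#' @param query query sequence.
#' @param reference a \linkS4class{ReferenceLibrary} of length one with
#'   segment annotations.
#' @param params alignment parameters.
#' @return data.frame with columns query_id, reference_id, its1, r58s,
#'   its2, full (percentages, NA where the query does not cover a segment).
#' @export
segmentIdentityProfile <- function(query, reference,
                                   params = alignParams()) {
  stopifnot(methods::is(reference, "ReferenceLibrary"),
            length(reference) == 1)
  seg <- refSegments(reference)[[1]]
  if (is.null(seg)) stop("reference has no segment annotation")
  for (need in c("its1", "r58s", "its2"))
    if (!need %in% names(seg)) stop("reference annotation lacks ", need)
  qid <- if (methods::is(query, "DNAStringSet") && !is.null(names(query)))
    names(query)[1] else "query"
  aln <- globalAlign(refSeqs(reference)[[1]], query, params,
                     idA = names(refSeqs(reference)), idB = qid)
  cc <- alnColumns(aln)
  segIdent <- function(s, e) {
    cols <- which((!is.na(cc$apos) & cc$apos >= s & cc$apos <= e))
    if (!length(cols)) return(NA_real_)
    cols <- min(cols):max(cols)  # include insertion columns inside the span
    if (!any(cc$b[cols] != "-")) return(NA_real_)
    percentIdentity(aln, "exclude_terminal_gaps", cols = cols)
  }
  its1 <- segIdent(IRanges::start(seg["its1"]), IRanges::end(seg["its1"]))
  r58s <- segIdent(IRanges::start(seg["r58s"]), IRanges::end(seg["r58s"]))
  its2 <- segIdent(IRanges::start(seg["its2"]), IRanges::end(seg["its2"]))
  full <- segIdent(IRanges::start(seg["its1"]), IRanges::end(seg["its2"]))
  data.frame(query_id = qid, reference_id = names(refSeqs(reference)),
             its1 = its1, r58s = r58s, its2 = its2, full = full)
}

#' Table of segment identities for many queries
#'
#' Convenience wrapper running \code{\link{segmentIdentityProfile}} for
#' each query in a set, mirroring a similarity-table layout (rows =
#' queries; columns = ITS1, 5.8S, ITS2, full region).
#'
#' @param queries a \link[Biostrings]{DNAStringSet}.
#' @param reference annotated reference (length-one
#'   \linkS4class{ReferenceLibrary}).
#' @param params alignment parameters.
#' @return data.frame, one row per query.
#' @export
segmentIdentityTable <- function(queries, reference,
                                 params = alignParams()) {
  rows <- lapply(seq_along(queries), function(k)
    segmentIdentityProfile(queries[k], reference, params))
  do.call(rbind, rows)
}
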