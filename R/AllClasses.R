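#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges
NULL

IUPAC_CHARS <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Alignment scoring parameters
#'
#' Scoring scheme for global pairwise alignment with affine gaps. A gap of
#' length k costs \code{gapOpen + k * gapExtend}; both penalties are
#' non-positive. Terminal (leading/trailing) gap columns are free under the
#' default \code{"free"} policy, which is the natural choice for comparing a
#' partial ITS clone against a full-length reference.
#'
#' @slot match numeric, score for an identical column (> mismatch).
#' @slot mismatch numeric, score for a substitution column.
#' @slot gapOpen numeric <= 0, one-off cost of opening a gap.
#' @slot gapExtend numeric <= 0, per-base gap cost.
#' @slot terminalGaps either "free" or "penalized".
#' @exportClass AlignmentParams
setClass("AlignmentParams",
  representation(match = "numeric", mismatch = "numeric",
                 gapOpen = "numeric", gapExtend = "numeric",
                 terminalGaps = "character"),
  prototype(match = 1, mismatch = -1, gapOpen = -5, gapExtend = -1,
            terminalGaps = "free"))

setValidity("AlignmentParams", function(object) {
  msg <- character()
  if (object@gapOpen > 0) msg <- c(msg, "gapOpen must be <= 0")
  if (object@gapExtend > 0) msg <- c(msg, "gapExtend must be <= 0")
  if (object@match <= object@mismatch)
    msg <- c(msg, "match score must exceed mismatch score")
  if (!object@terminalGaps %in% c("free", "penalized"))
    msg <- c(msg, "terminalGaps must be 'free' or 'penalized'")
  if (length(msg)) msg else TRUE
})

#' Construct alignment parameters
#'
#' @param match,mismatch,gapOpen,gapExtend scoring values, see
#'   \linkS4class{AlignmentParams}.
#' @param terminalGaps "free" (default) or "penalized".
#' @return An \linkS4class{AlignmentParams} object.
#' @examples
#' alignParams()
#' alignParams(gapOpen = -10, terminalGaps = "penalized")
#' @export
alignParams <- function(match = 1, mismatch = -1, gapOpen = -5,
                        gapExtend = -1, terminalGaps = c("free", "penalized")) {
  new("AlignmentParams", match = match, mismatch = mismatch,
      gapOpen = gapOpen, gapExtend = gapExtend,
      terminalGaps = match.arg(terminalGaps))
}

#' Global pairwise alignment
#'
#' Result of an affine-gap Needleman-Wunsch alignment. The two gapped
#' strings have equal length, contain no gap/gap column, and recover the
#' input sequences when gaps are stripped.
#'
#' @slot alignedA,alignedB gapped sequence strings.
#' @slot idA,idB sequence identifiers.
#' @slot score numeric alignment score.
#' @slot params the \linkS4class{AlignmentParams} used.
#' @exportClass PairwiseAln
setClass("PairwiseAln",
  representation(alignedA = "character", alignedB = "character",
                 idA = "character", idB = "character",
                 score = "numeric", params = "AlignmentParams"))

setValidity("PairwiseAln", function(object) {
  a <- strsplit(object@alignedA, "")[[1]]
  b <- strsplit(object@alignedB, "")[[1]]
  msg <- character()
  if (length(a) != length(b)) msg <- c(msg, "aligned strings differ in length")
  if (any(a == "-" & b == "-")) msg <- c(msg, "gap/gap column present")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairwiseAln", function(object) {
  cat("PairwiseAln:", object@idA, "vs", object@idB,
      sprintf("(%d columns, score %.1f)\n", nchar(object@alignedA),
              object@score))
})

#' Reference genotype library
#'
#' Sequences plus per-entry metadata (genotype label, GenBank accession,
#' compositional class, phylogenetic cluster) and optional ITS segment
#' annotations. The compositional class records whether a genotype carries
#' the transition-driven shift towards A/T relative to Genotype #1
#' (H. sinensis); the cluster slot records membership of the two branches
#' of the AT-biased clade (A = #5, #6, #16, #17; B = #4, #15).
#'
#' @slot seqs a \link[Biostrings]{DNAStringSet}.
#' @slot info a \link[S4Vectors]{DataFrame} with columns \code{genotype_id},
#'   \code{accession}, \code{class}
#'   (GC-biased/AT-biased/outgroup/species-control/unregistered) and
#'   \code{cluster} (A/B/GC/none), one row per sequence.
#' @slot segments named list, per sequence either \code{NULL} or a named
#'   \link[IRanges]{IRanges} with elements among
#'   \code{flank5, its1, r58s, its2, flank3}.
#' @exportClass ReferenceLibrary
setClass("ReferenceLibrary",
  representation(seqs = "DNAStringSet", info = "DataFrame",
                 segments = "list"))

setValidity("ReferenceLibrary", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (nrow(object@info) != n) msg <- c(msg, "info rows must match sequences")
  need <- c("genotype_id", "accession", "class", "cluster")
  if (!all(need %in% colnames(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  if (length(object@segments) != n)
    msg <- c(msg, "segments list must match sequences")
  ok_class <- c("GC-biased", "AT-biased", "outgroup", "species-control",
                "unregistered")
  if (nrow(object@info) && !all(object@info$class %in% ok_class))
    msg <- c(msg, "invalid compositional class")
  if (nrow(object@info) && !all(object@info$cluster %in% c("A", "B", "GC", "none")))
    msg <- c(msg, "invalid cluster label")
  for (k in seq_len(n)) {
    seg <- object@segments[[k]]
    if (is.null(seg)) next
    if (!validSegmentAnnotation(seg, Biostrings::width(object@seqs)[k]))
      msg <- c(msg, sprintf("invalid segment annotation for '%s'",
                            names(object@seqs)[k]))
  }
  if (length(msg)) msg else TRUE
})

# segments must be named, ordered flank5 < its1 < r58s < its2 < flank3,
# non-overlapping and inside the sequence
validSegmentAnnotation <- function(seg, seqlen) {
  if (!methods::is(seg, "IRanges") || is.null(names(seg))) return(FALSE)
  order_ref <- c("flank5", "its1", "r58s", "its2", "flank3")
  if (!all(names(seg) %in% order_ref)) return(FALSE)
  if (anyDuplicated(names(seg))) return(FALSE)
  seg <- seg[order(match(names(seg), order_ref))]
  s <- IRanges::start(seg); e <- IRanges::end(seg)
  if (any(s > e) || any(s < 1) || any(e > seqlen)) return(FALSE)
  if (length(seg) > 1 && any(s[-1] <= e[-length(seg)])) return(FALSE)
  TRUE
}

setMethod("show", "ReferenceLibrary", function(object) {
  cat("ReferenceLibrary with", length(object@seqs), "sequences\n")
  tab <- table(object@info$class)
  cat(" classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  ann <- sum(!vapply(object@segments, is.null, logical(1)))
  cat(" segment-annotated:", ann, "\n")
})

#' @describeIn ReferenceLibrary number of reference sequences
#' @param x,i a ReferenceLibrary and an index
#' @export
setMethod("length", "ReferenceLibrary", function(x) length(x@seqs))

#' @describeIn ReferenceLibrary subset by index or sequence name
#' @export
setMethod("[", "ReferenceLibrary", function(x, i) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  new("ReferenceLibrary", seqs = x@seqs[i], info = x@info[i, , drop = FALSE],
      segments = x@segments[i])
})

#' Accessors for ReferenceLibrary
#'
#' \code{refSeqs} returns the \code{DNAStringSet}, \code{refInfo} the
#' metadata \code{DataFrame}, \code{refSegments} the per-sequence segment
#' annotations.
#' @param x a \linkS4class{ReferenceLibrary}.
#' @return see description.
#' @export
refSeqs <- function(x) x@seqs

#' @rdname refSeqs
#' @export
refInfo <- function(x) x@info

#' @rdname refSeqs
#' @export
refSegments <- function(x) x@segments

#' Two-parent chimera call
#'
#' Windowed parental-assignment result for one query against two candidate
#' parent sequences. Each query window is won by the parent with the higher
#' windowed identity when the margin reaches \code{minMargin}; breakpoints
#' are reported where sufficiently supported runs of opposite winners abut.
#'
#' @slot queryId,parentA,parentB identifiers.
#' @slot windows data.frame with columns start, end, idA, idB, winner.
#' @slot breakpoints data.frame with columns lo, hi (query coordinates).
#' @slot windowSize,step,minMargin,minSupport parameters used.
#' @exportClass ChimeraCall
setClass("ChimeraCall",
  representation(queryId = "character", parentA = "character",
                 parentB = "character", windows = "data.frame",
                 breakpoints = "data.frame", windowSize = "numeric",
                 step = "numeric", minMargin = "numeric",
                 minSupport = "numeric"))

setMethod("show", "ChimeraCall", function(object) {
  cat("ChimeraCall:", object@queryId, "vs parents", object@parentA, "/",
      object@parentB, "\n")
  cat(" windows:", nrow(object@windows), " breakpoints:",
      nrow(object@breakpoints), "\n")
  if (nrow(object@breakpoints))
    cat(" intervals:", paste(sprintf("[%d,%d]", object@breakpoints$lo,
                                     object@breakpoints$hi), collapse = " "),
        "\n")
})

#' @describeIn ChimeraCall number of supported breakpoints
#' @param x a ChimeraCall
#' @export
nBreakpoints <- function(x) nrow(x@breakpoints)

#' @rdname nBreakpoints
#' @export
breakpoints <- function(x) x@breakpoints

#' @rdname nBreakpoints
#' @export
chimeraWindows <- function(x) x@windows

#' Compartment occurrence table
#'
#' Clone counts per taxon (rows) and compartment (columns). A taxon is
#' present in a compartment when its clone count reaches \code{minClones};
#' an all-\code{NA} column marks an unassessed (empty) sample.
#'
#' @slot counts numeric matrix, taxa x compartments (NA = unassessed).
#' @slot unassigned numeric vector, clones per compartment that called to
#'   no taxon.
#' @slot minClones presence threshold.
#' @exportClass OccurrenceTable
setClass("OccurrenceTable",
  representation(counts = "matrix", unassigned = "numeric",
                 minClones = "numeric"))

setValidity("OccurrenceTable", function(object) {
  msg <- character()
  if (is.null(rownames(object@counts)) || is.null(colnames(object@counts)))
    msg <- c(msg, "counts must have row and column names")
  if (anyDuplicated(rownames(object@counts)) ||
      anyDuplicated(colnames(object@counts)))
    msg <- c(msg, "row/column labels must be unique")
  if (length(object@unassigned) != ncol(object@counts))
    msg <- c(msg, "unassigned must have one entry per compartment")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OccurrenceTable", function(object) {
  cat("OccurrenceTable:", nrow(object@counts), "taxa x",
      ncol(object@counts), "compartments (minClones =", object@minClones,
      ")\n")
  print(presenceMatrix(object))
})

#' Presence/absence view of an occurrence table
#'
#' @param x an \linkS4class{OccurrenceTable}.
#' @return logical matrix (NA for unassessed compartments).
#' @export
presenceMatrix <- function(x) {
  p <- x@counts >= x@minClones
  p[is.na(x@counts)] <- NA
  p
}

#' @rdname presenceMatrix
#' @export
occurrenceCounts <- function(x) x@counts

#' @rdname presenceMatrix
#' @export
unassignedCounts <- function(x) x@unassigned
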