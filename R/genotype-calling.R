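TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Mutation profile of a query against a reference
#'
#' Classifies every substitution column of the global alignment as a
#' transition (A<->G, C<->T) or transversion, counts internal indel
#' columns, and tallies the AT shift: transitions whose reference base is
#' G or C and whose query base is A or T. A high AT-shift fraction is the
#' signature of the AT-biased genotypes relative to Genotype #1.
#'
#' @param query query sequence.
#' @param reference length-one \linkS4class{ReferenceLibrary} or a plain
#'   sequence.
#' @param params alignment parameters.
#' @param min_identity projection threshold (error below it).
#' @return list with reference_id, n_columns (residue-aligned columns),
#'   n_transitions, n_transversions, n_indel_columns, at_shift,
#'   at_shift_fraction (NA when there are no transitions).
#' @export
mutationProfile <- function(query, reference, params = alignParams(),
                            min_identity = 50) {
  if (methods::is(reference, "ReferenceLibrary")) {
    stopifnot(length(reference) == 1)
    refseq <- as.character(refSeqs(reference)[[1]])
    rid <- names(refSeqs(reference))
  } else {
    refseq <- asSeqChar(reference); rid <- "reference"
  }
  aln <- globalAlign(refseq, query, params, idA = rid)
  if (percentIdentity(aln) < min_identity)
    stop(sprintf("alignment identity below %s%%; no reliable profile",
                 min_identity))
  cc <- alnColumns(aln)
  res <- which(cc$a != "-" & cc$b != "-")
  span <- res[1]:res[length(res)]
  a <- cc$a[span]; b <- cc$b[span]
  indel <- sum(a == "-" | b == "-")
  both <- a %in% names(TRANSITIONS) & b %in% names(TRANSITIONS)
  sub <- both & a != b
  ts <- sub & TRANSITIONS[a] == b
  tv <- sub & !ts
  at <- ts & a %in% c("G", "C") & b %in% c("A", "T")
  list(reference_id = rid, n_columns = sum(both),
       n_transitions = sum(ts), n_transversions = sum(tv),
       n_indel_columns = indel, at_shift = sum(at),
       at_shift_fraction = if (sum(ts)) sum(at) / sum(ts) else NA_real_)
}

#' Classify compositional bias from a mutation profile
#'
#' A query is AT-biased when it differs from the Genotype #1 reference by
#' at least \code{min_transitions} transitions of which a fraction of at
#' least \code{at_fraction_threshold} shift G/C to A/T; otherwise it is
#' GC-biased (near-#1 sequences fall here by construction). Alignments
#' spanning fewer than \code{min_columns} residue columns are
#' unclassified.
#'
#' @param profile result of \code{\link{mutationProfile}}.
#' @param min_transitions minimum transition count for an AT call
#'   (default 5).
#' @param at_fraction_threshold minimum AT-shift fraction (default 0.6).
#' @param min_columns minimum aligned residue columns (default 100).
#' @return "GC-biased", "AT-biased" or "unclassified".
#' @export
classifyBias <- function(profile, min_transitions = 5,
                         at_fraction_threshold = 0.6, min_columns = 100) {
  if (profile$n_columns < min_columns) return("unclassified")
  if (profile$n_transitions < min_transitions) return("GC-biased")
  if (profile$at_shift_fraction >= at_fraction_threshold) "AT-biased"
  else "GC-biased"
}

# numeric genotype rank for tie-breaking: "#4" -> 4, others -> Inf
genotypeRank <- function(id) {
  n <- suppressWarnings(as.numeric(sub("^#", "", id)))
  ifelse(grepl("^#[0-9]+$", id), n, Inf)
}

# full-region identity of a query against one library entry: segment-
# annotated entries are scored on the ITS1..ITS2 region, others on the
# whole alignment
libraryIdentity <- function(query, library, k, params) {
  if (!is.null(refSegments(library)[[k]])) {
    segmentIdentityProfile(query, library[k], params)$full
  } else {
    percentIdentity(globalAlign(refSeqs(library)[[k]], query, params))
  }
}

#' Call the genotype of a query sequence
#'
#' Assigns the query to the library reference with the highest full-region
#' identity (ties broken by lower genotype number, then lexicographic
#' accession). Queries whose best identity falls below
#' \code{call_threshold} are reported as \code{"unassigned"} with the best
#' candidate retained. The compositional class is derived from the
#' mutation profile against the Genotype #1 representative, and a chimera
#' flag is raised when windowed parental assignment against the two
#' default parents (Genotype #1 and the AB067719-type fungus) finds a
#' supported breakpoint.
#'
#' @param query query sequence.
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param call_threshold minimum identity for an assignment (default 97).
#' @param params alignment parameters.
#' @param check_chimera run chimera detection when both default parents
#'   are present (default TRUE).
#' @param chimera_parents optional character vector of two sequence names
#'   in \code{library} to use as parents.
#' @return list with query_id, genotype, best_reference, best_identity,
#'   runner_up_identity, class, chimera_flag.
#' @export
callGenotype <- function(query, library, call_threshold = 97,
                         params = alignParams(), check_chimera = TRUE,
                         chimera_parents = NULL) {
  stopifnot(methods::is(library, "ReferenceLibrary"), length(library) > 0)
  qid <- if (methods::is(query, "DNAStringSet") && !is.null(names(query)))
    names(query)[1] else "query"
  query <- asSeqChar(query)
  info <- refInfo(library)
  ident <- vapply(seq_len(length(library)), function(k)
    libraryIdentity(query, library, k, params), numeric(1))
  ident[is.na(ident)] <- -Inf  # e.g. no overlap with the scored region
  ord <- order(-ident, genotypeRank(info$genotype_id), info$accession)
  best <- ord[1]
  others <- which(info$genotype_id != info$genotype_id[best])
  runner <- if (length(others)) max(ident[others]) else NA_real_
  g1 <- which(info$genotype_id == "#1")
  cls <- "unclassified"
  if (length(g1)) {
    g1 <- g1[order(info$accession[g1] != "AB067721")][1]
    prof <- try(mutationProfile(query, library[g1], params), silent = TRUE)
    if (!inherits(prof, "try-error")) cls <- classifyBias(prof)
  }
  flag <- FALSE
  if (check_chimera) {
    if (is.null(chimera_parents)) {
      pa <- g1
      pb <- which(info$genotype_id == "AB067719-type")
      if (length(pa) && length(pb))
        chimera_parents <- c(names(refSeqs(library))[pa[1]],
                             names(refSeqs(library))[pb[1]])
    }
    if (!is.null(chimera_parents)) {
      cal <- try(detectChimera(query,
                               refSeqs(library)[[chimera_parents[1]]],
                               refSeqs(library)[[chimera_parents[2]]],
                               params = params,
                               query_id = qid,
                               parent_ids = chimera_parents),
                 silent = TRUE)
      if (!inherits(cal, "try-error")) flag <- nBreakpoints(cal) >= 1
    }
  }
  list(query_id = qid,
       genotype = if (ident[best] >= call_threshold)
         info$genotype_id[best] else "unassigned",
       best_reference = info$genotype_id[best],
       best_accession = info$accession[best],
       best_identity = ident[best], runner_up_identity = runner,
       class = cls, chimera_flag = flag)
}

#' Detect a two-parent chimera by windowed parental assignment
#'
#' Aligns the query to both candidate parents, computes percent identity
#' to each parent in sliding windows of query coordinates, and assigns
#' each window to the parent with the higher identity when the margin
#' reaches \code{min_margin} identity points (otherwise the window is a
#' tie). A breakpoint is reported wherever two runs of opposite winners,
#' each at least \code{min_support} windows long, abut; the breakpoint
#' interval spans the query region between the last window of one run and
#' the first window of the next.
#'
#' @param query query sequence.
#' @param parent_a,parent_b parent sequences (must differ from each
#'   other).
#' @param window,step window size and step in bp of query coordinates.
#' @param min_margin minimum identity-point margin for a window winner.
#' @param min_support minimum consecutive concordant windows flanking a
#'   breakpoint.
#' @param params alignment parameters.
#' @param query_id,parent_ids identifiers for the report.
#' @return a \linkS4class{ChimeraCall}.
#' @export
detectChimera <- function(query, parent_a, parent_b, window = 60,
                          step = 10, min_margin = 2, min_support = 3,
                          params = alignParams(), query_id = "query",
                          parent_ids = c("parentA", "parentB")) {
  query <- asSeqChar(query)
  parent_a <- asSeqChar(parent_a); parent_b <- asSeqChar(parent_b)
  pp <- globalAlign(parent_a, parent_b, params)
  if (percentIdentity(pp) >= 100)
    stop("parents indistinguishable: 100% identity")
  alnA <- globalAlign(query, parent_a, params)
  alnB <- globalAlign(query, parent_b, params)
  winIdent <- function(aln, w1, w2) {
    cc <- alnColumns(aln)  # a = query, b = parent
    cols <- which(!is.na(cc$apos) & cc$apos >= w1 & cc$apos <= w2)
    if (!length(cols)) return(NA_real_)
    cols <- min(cols):max(cols)
    100 * sum(cc$a[cols] == cc$b[cols] & cc$a[cols] != "-") / length(cols)
  }
  qlen <- nchar(query)
  starts <- seq(1, max(1, qlen - window + 1), by = step)
  wins <- data.frame(start = starts, end = pmin(starts + window - 1, qlen))
  wins$idA <- mapply(function(s, e) winIdent(alnA, s, e), wins$start, wins$end)
  wins$idB <- mapply(function(s, e) winIdent(alnB, s, e), wins$start, wins$end)
  d <- wins$idA - wins$idB
  wins$winner <- ifelse(is.na(d) | abs(d) < min_margin, "tie",
                        ifelse(d > 0, "A", "B"))
  # runs over non-tie windows
  nz <- which(wins$winner != "tie")
  bp <- data.frame(lo = integer(), hi = integer())
  if (length(nz)) {
    lab <- wins$winner[nz]
    r <- rle(lab)
    ends <- cumsum(r$lengths); startsr <- ends - r$lengths + 1L
    for (k in seq_len(length(r$lengths) - 1L)) {
      if (r$values[k] != r$values[k + 1L] &&
          r$lengths[k] >= min_support && r$lengths[k + 1L] >= min_support) {
        lastw <- nz[ends[k]]          # last window of the first run
        firstw <- nz[startsr[k + 1L]] # first window of the next run
        lo <- min(wins$end[lastw], wins$start[firstw])
        hi <- max(wins$end[lastw], wins$start[firstw])
        bp <- rbind(bp, data.frame(lo = lo, hi = hi))
      }
    }
  }
  new("ChimeraCall", queryId = query_id, parentA = parent_ids[1],
      parentB = parent_ids[2], windows = wins, breakpoints = bp,
      windowSize = window, step = step, minMargin = min_margin,
      minSupport = min_support)
}
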