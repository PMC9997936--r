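#' Layout of a synthetic ITS-like marker
#'
#' Describes the coordinate plan of the generator's base marker: segment
#' tiling (partial 18S flank, ITS1, 5.8S, ITS2, partial 28S flank),
#' planting positions for a forward primer at the 5' end and the reverse
#' complement of a reverse primer at the 3' end, and an EcoRI site planted
#' inside the 5.8S gene, mirroring the locus arrangement of the real
#' Genotype #1 marker.
#'
#' @param total total length in bp.
#' @param flank5,its1,r58s,its2,flank3 segment intervals as
#'   \code{c(start, end)}; must tile \code{1:total} in order.
#' @param fwd_start forward-primer planting start (within flank5).
#' @param rev_end reverse-primer planting end (within flank3; the site is
#'   the reverse complement of the reverse primer).
#' @param ecori_start EcoRI site (GAATTC) planting start.
#' @param gc base composition (GC fraction) of the random background.
#' @return a list of class "MarkerLayout".
#' @export
markerLayout <- function(total = 650,
                         flank5 = c(1, 40), its1 = c(41, 270),
                         r58s = c(271, 430), its2 = c(431, 620),
                         flank3 = c(621, 650),
                         fwd_start = 1, rev_end = 650,
                         ecori_start = 294, gc = 0.5) {
  segs <- rbind(flank5, its1, r58s, its2, flank3)
  if (segs[1, 1] != 1 || segs[5, 2] != total ||
      any(segs[-1, 1] != segs[-5, 2] + 1))
    stop("segments must tile 1:total in order")
  if (ecori_start < r58s[1] || ecori_start + 5 > its2[2])
    stop("EcoRI site must lie in the 5.8S/ITS2 region")
  structure(list(total = total, flank5 = flank5, its1 = its1,
                 r58s = r58s, its2 = its2, flank3 = flank3,
                 fwd_start = fwd_start, rev_end = rev_end,
                 ecori_start = ecori_start, gc = gc),
            class = "MarkerLayout")
}

# segment annotation (IRanges) of a layout
layoutSegments <- function(layout) {
  ir <- IRanges::IRanges(
    start = c(layout$flank5[1], layout$its1[1], layout$r58s[1],
              layout$its2[1], layout$flank3[1]),
    end = c(layout$flank5[2], layout$its1[2], layout$r58s[2],
            layout$its2[2], layout$flank3[2]))
  names(ir) <- c("flank5", "its1", "r58s", "its2", "flank3")
  ir
}

# positions that the generator never mutates: primer plantings + EcoRI
layoutProtected <- function(layout, fwd_len, rev_len) {
  c(seq(layout$fwd_start, layout$fwd_start + fwd_len - 1),
    seq(layout$rev_end - rev_len + 1, layout$rev_end),
    seq(layout$ecori_start, layout$ecori_start + 5))
}

#' Generate a random marker sequence with planted features
#'
#' Draws a random background at the layout's base composition, then plants
#' the forward primer, the reverse complement of the reverse primer, and a
#' single GAATTC site at the layout positions. Unintended GAATTC
#' occurrences arising by chance are scrubbed (one base changed outside
#' protected positions) so the planted site is unique. Deterministic for a
#' fixed seed.
#'
#' @param seed integer RNG seed.
#' @param layout a \code{\link{markerLayout}}.
#' @param forward,reverse primer sequences to plant (defaults: the
#'   bundled ITS5 and ITS4 universal primers).
#' @return list with seq (character), segments (named IRanges), protected
#'   (integer positions).
#' @export
randomMarker <- function(seed, layout = markerLayout(),
                         forward = primerSeq("ITS5"),
                         reverse = primerSeq("ITS4")) {
  fwd_len <- nchar(forward); rev_len <- nchar(reverse)
  prot <- layoutProtected(layout, fwd_len, rev_len)
  if (anyDuplicated(prot)) stop("layout plantings overlap")
  set.seed(seed)
  p <- c(A = (1 - layout$gc) / 2, C = layout$gc / 2, G = layout$gc / 2,
         T = (1 - layout$gc) / 2)
  x <- sample(names(p), layout$total, replace = TRUE, prob = p)
  x[seq(layout$fwd_start, length.out = fwd_len)] <-
    strsplit(toupper(forward), "")[[1]]
  x[seq(layout$rev_end - rev_len + 1, layout$rev_end)] <-
    strsplit(revComp(toupper(reverse)), "")[[1]]
  x[seq(layout$ecori_start, length.out = 6)] <-
    c("G", "A", "A", "T", "T", "C")
  # scrub chance GAATTC occurrences so the planted site is unique
  repeat {
    sites <- findRecognitionSites(paste(x, collapse = ""))
    extra <- setdiff(sites, layout$ecori_start)
    if (!length(extra)) break
    for (s in extra) {
      cand <- setdiff(seq(s, s + 5), prot)
      if (!length(cand)) stop("cannot scrub GAATTC inside protected region")
      i <- cand[1]
      x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    }
  }
  list(seq = paste(x, collapse = ""), segments = layoutSegments(layout),
       protected = prot)
}

#' Plant transitions and transversions into a sequence
#'
#' Applies exactly the requested numbers of substitutions at distinct,
#' unprotected positions and records every edit. A fraction
#' \code{at_bias} of the transitions is drawn from G/C positions and
#' shifted to A/T (G->A, C->T), emulating the transition-dominated AT
#' shift of the biased genotypes; the remaining transitions are drawn from
#' A/T positions (A->G, T->C) so the recorded AT-shift count is exact.
#'
#' @param seq input sequence (character).
#' @param n_transitions,n_transversions counts to plant.
#' @param at_bias fraction of transitions that shift G/C to A/T.
#' @param seed integer RNG seed.
#' @param protected integer positions that must not be touched.
#' @return list with seq (mutant) and truth (data.frame pos, from, to,
#'   type, at_shift).
#' @export
mutateSeq <- function(seq, n_transitions = 0, n_transversions = 0,
                      at_bias = 0, seed = 1, protected = integer()) {
  x <- strsplit(asSeqChar(seq), "")[[1]]
  set.seed(seed)
  free <- setdiff(seq_along(x), protected)
  n_at <- round(at_bias * n_transitions)
  n_other <- n_transitions - n_at
  gc_pos <- free[x[free] %in% c("G", "C")]
  at_pos <- free[x[free] %in% c("A", "T")]
  if (length(gc_pos) < n_at || length(at_pos) < n_other)
    stop("not enough mutable positions for the requested transitions")
  p_at <- sort(sample(gc_pos, n_at))
  at_pos <- setdiff(at_pos, p_at)
  p_other <- sort(sample(at_pos, n_other))
  used <- c(p_at, p_other)
  tv_pool <- setdiff(free, used)
  if (length(tv_pool) < n_transversions)
    stop("not enough mutable positions for the requested transversions")
  p_tv <- sort(sample(tv_pool, n_transversions))
  truth <- data.frame(pos = integer(), from = character(),
                      to = character(), type = character(),
                      at_shift = logical(), stringsAsFactors = FALSE)
  edit <- function(pos, to, type, at_shift) {
    truth <<- rbind(truth, data.frame(pos = pos, from = x[pos], to = to,
                                      type = type, at_shift = at_shift,
                                      stringsAsFactors = FALSE))
    x[pos] <<- to
  }
  for (pos in p_at) edit(pos, unname(TRANSITIONS[x[pos]]), "transition", TRUE)
  for (pos in p_other) edit(pos, unname(TRANSITIONS[x[pos]]), "transition",
                            FALSE)
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  for (pos in p_tv)
    edit(pos, sample(tv_map[[x[pos]]], 1), "transversion", FALSE)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(seq = paste(x, collapse = ""), truth = truth)
}

#' Build a two-parent chimera with known breakpoints
#'
#' Concatenates alternating parental blocks, starting with
#' \code{parent_a}: positions 1..b1 from a, b1+1..b2 from b, and so on.
#' Parents must have equal length (generator parents do, since all
#' generator mutations are substitutions).
#'
#' @param parent_a,parent_b parent sequences of equal length.
#' @param breakpoints strictly increasing positions inside the sequence.
#' @return list with seq and truth (breakpoints).
#' @export
makeChimera <- function(parent_a, parent_b, breakpoints = integer()) {
  a <- strsplit(asSeqChar(parent_a), "")[[1]]
  b <- strsplit(asSeqChar(parent_b), "")[[1]]
  if (length(a) != length(b)) stop("parents must have equal length")
  if (length(breakpoints)) {
    if (any(diff(breakpoints) <= 0))
      stop("breakpoints must be strictly increasing")
    if (any(breakpoints < 1 | breakpoints >= length(a)))
      stop("breakpoints must lie inside the sequence")
  }
  bounds <- c(0, breakpoints, length(a))
  x <- character(length(a))
  for (k in seq_len(length(bounds) - 1)) {
    idx <- (bounds[k] + 1):bounds[k + 1]
    x[idx] <- if (k %% 2 == 1) a[idx] else b[idx]
  }
  list(seq = paste(x, collapse = ""), truth = list(breakpoints = breakpoints))
}

#' Simulate a clone library from a genotype composition
#'
#' Emits clones by copying each source sequence with independent uniform
#' substitution errors at the stated per-base rate, emulating the
#' PCR/cloning error process of a cloning-based amplicon library.
#' Deterministic for a fixed seed.
#'
#' @param composition named integer vector, taxon -> clone count (taxa
#'   must name entries of \code{sources}).
#' @param sources named \code{DNAStringSet} or named character vector of
#'   source sequences.
#' @param per_base_error substitution probability per base, in [0, 0.05].
#' @param seed integer RNG seed.
#' @return list with clones (\code{DNAStringSet}, names clone_0001, ...)
#'   and truth (data.frame clone, source).
#' @export
simulateCloneLibrary <- function(composition, sources, per_base_error = 0,
                                 seed = 1) {
  if (per_base_error < 0 || per_base_error > 0.05)
    stop("per_base_error must be in [0, 0.05]")
  if (is.character(sources)) sources <- Biostrings::DNAStringSet(sources)
  if (length(composition) && is.null(names(composition)))
    stop("composition must be named")
  missing <- setdiff(names(composition), names(sources))
  if (length(missing))
    stop("composition names not in sources: ", paste(missing, collapse = ", "))
  set.seed(seed)
  out <- character(); src <- character()
  bases <- c("A", "C", "G", "T")
  for (taxon in names(composition)) {
    n <- composition[[taxon]]
    if (n < 0) stop("negative clone count for ", taxon)
    tmpl <- strsplit(as.character(sources[[taxon]]), "")[[1]]
    for (i in seq_len(n)) {
      x <- tmpl
      if (per_base_error > 0) {
        hit <- which(stats::runif(length(x)) < per_base_error)
        for (h in hit) x[h] <- sample(setdiff(bases, x[h]), 1)
      }
      out <- c(out, paste(x, collapse = ""))
      src <- c(src, taxon)
    }
  }
  clones <- Biostrings::DNAStringSet(out)
  names(clones) <- sprintf("clone_%04d", seq_along(out))
  list(clones = clones,
       truth = data.frame(clone = names(clones), source = src,
                          stringsAsFactors = FALSE))
}

#' Build a synthetic reference genotype family
#'
#' Generates a family of marker variants with the structure of the real
#' genotype panel: a Genotype #1-like base marker; a near-#1 GC-biased
#' variant (#2); an AT-biased lineage that loses the EcoRI site through
#' the diagnostic GAATTC->GAATTT transition and splits into two clusters
#' (A: #5, #6, #16, #17; B: #4, #15) via shared cluster mutations plus
#' private ones; a strongly diverged outgroup (AB067719-type); two
#' reciprocal chimeras (#13: ITS1 from #1, remainder from the outgroup;
#' #14: the converse) with the breakpoint at the ITS1/5.8S boundary; and
#' a distant species control (S.hepiali-like).
#'
#' @param seed integer RNG seed.
#' @param layout a \code{\link{markerLayout}}.
#' @param outgroup_divergence substitutions separating the outgroup from
#'   the base marker, as a fraction of length (default 0.10).
#' @return list with library (a \linkS4class{ReferenceLibrary} whose
#'   sequence names are the genotype labels), parents (names of the two
#'   chimera parents), truth (per-taxon mutation/breakpoint records) and
#'   layout.
#' @export
buildReferenceFamily <- function(seed = 1, layout = markerLayout(),
                                 outgroup_divergence = 0.10) {
  base <- randomMarker(seed, layout)
  prot <- base$protected
  n_out <- round(outgroup_divergence * layout$total)
  truth <- list()
  seqs <- list()
  seqs[["#1"]] <- base$seq

  g719 <- mutateSeq(base$seq, n_transitions = ceiling(n_out / 2),
                    n_transversions = floor(n_out / 2), at_bias = 0.5,
                    seed = seed + 101, protected = prot)
  seqs[["AB067719-type"]] <- g719$seq; truth[["AB067719-type"]] <- g719$truth

  # AT lineage: shared root transitions + the diagnostic EcoRI loss
  atroot <- mutateSeq(base$seq, n_transitions = 24, at_bias = 1,
                      seed = seed + 102, protected = prot)
  x <- strsplit(atroot$seq, "")[[1]]
  x[layout$ecori_start + 5] <- "T"  # GAATTC -> GAATTT
  atroot$seq <- paste(x, collapse = "")
  aroot <- mutateSeq(atroot$seq, n_transitions = 10, at_bias = 1,
                     seed = seed + 103, protected = prot)
  broot <- mutateSeq(atroot$seq, n_transitions = 10, at_bias = 1,
                     seed = seed + 104, protected = prot)
  leafs <- list(`#5` = aroot, `#6` = aroot, `#16` = aroot, `#17` = aroot,
                `#4` = broot, `#15` = broot)
  for (k in seq_along(leafs)) {
    id <- names(leafs)[k]
    m <- mutateSeq(leafs[[k]]$seq, n_transitions = 6, at_bias = 1,
                   seed = seed + 110 + k, protected = prot)
    seqs[[id]] <- m$seq; truth[[id]] <- m$truth
  }

  g2 <- mutateSeq(base$seq, n_transitions = 4, at_bias = 0.5,
                  seed = seed + 105, protected = prot)
  seqs[["#2"]] <- g2$seq; truth[["#2"]] <- g2$truth

  bp <- layout$its1[2]  # ITS1 / 5.8S boundary
  c13 <- makeChimera(base$seq, seqs[["AB067719-type"]], bp)
  c14 <- makeChimera(seqs[["AB067719-type"]], base$seq, bp)
  seqs[["#13"]] <- c13$seq; truth[["#13"]] <- c13$truth
  seqs[["#14"]] <- c14$seq; truth[["#14"]] <- c14$truth

  n_sp <- round(0.2 * layout$total)
  shep <- mutateSeq(base$seq, n_transitions = ceiling(n_sp / 2),
                    n_transversions = floor(n_sp / 2), at_bias = 0.5,
                    seed = seed + 106, protected = prot)
  seqs[["S.hepiali"]] <- shep$seq; truth[["S.hepiali"]] <- shep$truth

  ids <- c("#1", "#2", "#4", "#5", "#6", "#13", "#14", "#15", "#16",
           "#17", "S.hepiali", "AB067719-type")
  sset <- Biostrings::DNAStringSet(unlist(seqs[ids]))
  names(sset) <- ids
  cls <- c(`#1` = "GC-biased", `#2` = "GC-biased", `#4` = "AT-biased",
           `#5` = "AT-biased", `#6` = "AT-biased", `#13` = "GC-biased",
           `#14` = "GC-biased", `#15` = "AT-biased", `#16` = "AT-biased",
           `#17` = "AT-biased", S.hepiali = "species-control",
           `AB067719-type` = "outgroup")
  clu <- c(`#1` = "GC", `#2` = "GC", `#4` = "B", `#5` = "A", `#6` = "A",
           `#13` = "GC", `#14` = "GC", `#15` = "B", `#16` = "A",
           `#17` = "A", S.hepiali = "none", `AB067719-type` = "none")
  info <- S4Vectors::DataFrame(
    genotype_id = ids, accession = paste0("SYN_", sub("#", "G", ids)),
    class = unname(cls[ids]), cluster = unname(clu[ids]),
    row.names = ids)
  segs <- rep(list(layoutSegments(layout)), length(ids))
  names(segs) <- ids
  lib <- new("ReferenceLibrary", seqs = sset, info = info, segments = segs)
  list(library = lib, parents = c("#1", "AB067719-type"), truth = truth,
       layout = layout)
}

#' Simulate the five-compartment study design
#'
#' Builds the synthetic genotype family and samples one clone library per
#' compartment (immature stroma, mature stroma, stromal fertile portion,
#' fully ejected and semiejected ascospores), with compositions realizing
#' the published presence/absence pattern: Cluster-B genotypes (#4, #15)
#' confined to stroma/SFP, the recombinant #13 only in semiejected and
#' #14 only in fully ejected ascospores, and a lower S.hepiali clone
#' count in fully ejected than in semiejected ascospores. Thirty clones
#' per compartment, matching the study's colony-picking depth.
#'
#' @param seed integer RNG seed.
#' @param per_base_error clone substitution error rate.
#' @param layout a \code{\link{markerLayout}}.
#' @return list with samples (named list of clone \code{DNAStringSet}),
#'   library, parents, expected (an \linkS4class{OccurrenceTable}),
#'   truth (per-compartment clone truth tables).
#' @export
buildTable2Scenario <- function(seed = 1, per_base_error = 0,
                                layout = markerLayout()) {
  fam <- buildReferenceFamily(seed, layout)
  comps <- list(
    stroma_immature = c(`#1` = 3, `#2` = 3, `#4` = 3, `#5` = 3, `#6` = 3,
                        `#15` = 3, `#16` = 3, `#17` = 3, S.hepiali = 3,
                        `AB067719-type` = 3),
    stroma_mature = c(`#1` = 4, `#2` = 4, `#4` = 4, `#5` = 4, `#6` = 4,
                      `#15` = 4, S.hepiali = 3, `AB067719-type` = 3),
    SFP = c(`#1` = 5, `#4` = 5, `#5` = 4, `#6` = 4, `#15` = 4,
            S.hepiali = 4, `AB067719-type` = 4),
    ascospores_fully_ejected = c(`#1` = 6, `#5` = 6, `#6` = 5, `#14` = 5,
                                 `#16` = 4, S.hepiali = 2,
                                 `AB067719-type` = 2),
    ascospores_semiejected = c(`#1` = 7, `#5` = 6, `#13` = 5,
                               S.hepiali = 8, `AB067719-type` = 4))
  samples <- list(); truth <- list()
  for (k in seq_along(comps)) {
    sim <- simulateCloneLibrary(comps[[k]], refSeqs(fam$library),
                                per_base_error, seed = seed + 200 + k)
    samples[[names(comps)[k]]] <- sim$clones
    truth[[names(comps)[k]]] <- sim$truth
  }
  list(samples = samples, library = fam$library, parents = fam$parents,
       expected = expectedOccurrence(), truth = truth)
}
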