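#' Pairwise distance matrix from unaligned sequences
#'
#' Aligns every pair globally and computes either the p-distance
#' (1 - identity fraction under the exclude-terminal-gaps convention,
#' internal gap columns counted as differences) or the Kimura
#' two-parameter distance from the transition (P) and transversion (Q)
#' proportions over residue-aligned columns:
#' \deqn{d = -\frac{1}{2}\ln\big((1-2P-Q)\sqrt{1-2Q}\big).}
#' Saturated pairs for which the K2P logarithm is undefined are flagged
#' and fall back to the p-distance rather than being dropped.
#'
#' @param seqs named \link[Biostrings]{DNAStringSet} (or named character
#'   vector), at least 3 sequences.
#' @param model "p" (p-distance) or "K2P".
#' @param params alignment parameters.
#' @return a symmetric numeric matrix with zero diagonal; attribute
#'   \code{"saturated"} is a character matrix listing flagged pairs (zero
#'   rows when none).
#' @export
seqDistances <- function(seqs, model = c("p", "K2P"),
                         params = alignParams()) {
  model <- match.arg(model)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  if (n < 3) stop("need at least 3 sequences")
  if (is.null(names(seqs))) stop("sequences must be named")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  sat <- matrix(character(0), ncol = 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    aln <- globalAlign(seqs[[i]], seqs[[j]], params)
    dij <- pairDistance(aln, model)
    if (isTRUE(attr(dij, "saturated"))) {
      sat <- rbind(sat, c(names(seqs)[i], names(seqs)[j]))
      warning(sprintf("K2P undefined for pair %s/%s; using p-distance",
                      names(seqs)[i], names(seqs)[j]))
    }
    d[i, j] <- d[j, i] <- as.numeric(dij)
  }
  attr(d, "saturated") <- sat
  d
}

# distance for one alignment; attr "saturated" flags a K2P fallback
pairDistance <- function(aln, model) {
  p_dist <- 1 - percentIdentity(aln, "exclude_terminal_gaps") / 100
  if (model == "p") return(p_dist)
  cc <- alnColumns(aln)
  res <- which(cc$a != "-" & cc$b != "-")
  span <- res[1]:res[length(res)]
  a <- cc$a[span]; b <- cc$b[span]
  both <- a %in% names(TRANSITIONS) & b %in% names(TRANSITIONS)
  a <- a[both]; b <- b[both]
  L <- length(a)
  if (!L) return(structure(p_dist, saturated = TRUE))
  ts <- sum(a != b & TRANSITIONS[a] == b)
  tv <- sum(a != b) - ts
  P <- ts / L; Q <- tv / L
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(structure(p_dist, saturated = TRUE))
  -0.5 * log(w1 * sqrt(w2))
}

#' Kimura two-parameter distance from P and Q proportions
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return numeric distance (NaN when undefined).
#' @examples
#' k2pDistance(0.2, 0)  # -0.5 * log(0.6)
#' @export
k2pDistance <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

#' Neighbor-joining tree
#'
#' Standard neighbor-joining on a distance matrix (via
#' \code{\link[ape]{nj}}); negative branch lengths, which NJ can produce
#' on non-additive inputs, are clamped to zero. The topology is what the
#' downstream cluster extraction consumes.
#'
#' @param d symmetric distance matrix with labels (e.g. from
#'   \code{\link{seqDistances}}).
#' @return an \code{\link[ape]{ape}} \code{phylo} object.
#' @export
njTree <- function(d) {
  if (is.matrix(d) && nrow(d) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# master alignment: per-sequence base at every reference position
# (insertions relative to the reference are dropped, deletions are '-')
masterAlignment <- function(seqs, reference, params = alignParams()) {
  refseq <- asSeqChar(reference)
  L <- nchar(refseq)
  mat <- matrix("-", nrow = length(seqs), ncol = L,
                dimnames = list(names(seqs), NULL))
  for (k in seq_along(seqs)) {
    aln <- globalAlign(refseq, seqs[[k]], params)
    cc <- alnColumns(aln)
    keep <- !is.na(cc$apos) & !is.na(cc$bpos)
    mat[k, cc$apos[keep]] <- cc$b[keep]
  }
  mat
}

# p- or K2P distances between rows of a character matrix (master
# alignment columns), pairwise deletion of '-' columns for K2P; for "p"
# the denominator is the shared covered span, gap columns counting as
# differences, mirroring pairDistance
matDistances <- function(mat, model = c("p", "K2P")) {
  model <- match.arg(model)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  cov <- apply(mat != "-", 1, function(x) {
    w <- which(x); if (length(w)) c(w[1], w[length(w)]) else c(NA, NA)
  })
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lo <- max(cov[1, i], cov[1, j]); hi <- min(cov[2, i], cov[2, j])
    if (is.na(lo) || lo > hi) { d[i, j] <- d[j, i] <- NA; next }
    a <- mat[i, lo:hi]; b <- mat[j, lo:hi]
    if (model == "p") {
      dij <- mean(a != b | a == "-")
    } else {
      both <- a %in% names(TRANSITIONS) & b %in% names(TRANSITIONS)
      aa <- a[both]; bb <- b[both]
      L <- length(aa)
      ts <- sum(aa != bb & TRANSITIONS[aa] == bb)
      tv <- sum(aa != bb) - ts
      w1 <- 1 - 2 * ts / L - tv / L; w2 <- 1 - 2 * tv / L
      dij <- if (L == 0 || w1 <= 0 || w2 <= 0) mean(a != b | a == "-")
             else -0.5 * log(w1 * sqrt(w2))
    }
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds a master alignment by aligning every sequence to a designated
#' reference (column resampling semantics without a full multiple
#' alignment), infers the NJ tree, and attaches percent bootstrap support
#' for each internal bipartition from \code{reps} column-resampled
#' replicates. Reproducible for a fixed seed.
#'
#' @param seqs named \code{DNAStringSet}.
#' @param reference name of the master-alignment reference within
#'   \code{seqs} (default: the first sequence), typically the Genotype #1
#'   representative.
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param model distance model, "p" or "K2P".
#' @param params alignment parameters.
#' @return a \code{phylo} tree whose \code{node.label} holds percent
#'   support (root label empty).
#' @export
bootstrapTree <- function(seqs, reference = names(seqs)[1], reps = 500,
                          seed = 1, model = c("p", "K2P"),
                          params = alignParams()) {
  model <- match.arg(model)
  if (reps < 1) stop("reps must be >= 1")
  if (is.character(seqs) && is.null(dim(seqs)))
    seqs <- Biostrings::DNAStringSet(seqs)
  mat <- masterAlignment(seqs, seqs[[reference]], params)
  tr <- njTree(matDistances(mat, model))
  set.seed(seed)
  reptrees <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    reptrees[[r]] <- njTree(matDistances(mat[, cols, drop = FALSE], model))
  }
  counts <- ape::prop.clades(tr, reptrees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tr$node.label <- as.character(round(100 * counts / reps))
  tr$node.label[1] <- ""  # root pseudo-node carries no support
  tr
}

#' Extract GC / AT-cluster memberships from a tree
#'
#' Roots the tree at the outgroup and locates the maximal clade that
#' contains every AT-biased seed and no GC-biased seed (the AT clade).
#' Its two basal subclades are labelled A and B according to which one
#' holds the designated Cluster-A seed; all remaining ingroup tips are
#' labelled GC. When the seeds are not monophyletic under the rooting,
#' the affected labels are "unplaced" and a warning is raised rather than
#' guessing.
#'
#' @param tree a \code{phylo} object.
#' @param outgroup_ids tip labels of the outgroup (non-empty).
#' @param at_seed_ids tip labels known to be AT-biased.
#' @param gc_seed_ids tip labels known to be GC-biased.
#' @param clusterA_seed tip label anchoring Cluster-A (default: first AT
#'   seed).
#' @return named character vector over all tips with values in
#'   \code{GC, A, B, outgroup, unplaced}.
#' @export
extractClusters <- function(tree, outgroup_ids, at_seed_ids, gc_seed_ids,
                            clusterA_seed = at_seed_ids[1]) {
  tips <- tree$tip.label
  if (!length(outgroup_ids)) stop("outgroup must be non-empty")
  missing <- setdiff(c(outgroup_ids, at_seed_ids, gc_seed_ids), tips)
  if (length(missing))
    stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
  out <- setNames(rep("GC", length(tips)), tips)
  out[outgroup_ids] <- "outgroup"
  ingroup <- setdiff(tips, outgroup_ids)
  # tip sets of every internal node
  parts <- ape::prop.part(rooted)
  labels <- attr(parts, "labels")
  cladesets <- lapply(parts, function(p) labels[p])
  ok <- vapply(cladesets, function(s)
    all(at_seed_ids %in% s) && !any(gc_seed_ids %in% s) &&
      !any(outgroup_ids %in% s), logical(1))
  if (!any(ok)) {
    warning("AT seeds not monophyletic under this rooting; labels unplaced")
    out[c(at_seed_ids, setdiff(ingroup, gc_seed_ids))] <- "unplaced"
    out[gc_seed_ids] <- "GC"
    return(out)
  }
  at_clade <- cladesets[ok][[which.max(lengths(cladesets[ok]))]]
  # basal split of the AT clade
  nodeOf <- function(set) {
    cand <- which(vapply(cladesets, function(s)
      length(s) == length(set) && all(set %in% s), logical(1)))
    cand[1]
  }
  node <- nodeOf(at_clade) + ape::Ntip(rooted)
  kids <- rooted$edge[rooted$edge[, 1] == node, 2]
  subsets <- lapply(kids, function(k) {
    if (k <= ape::Ntip(rooted)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label
  })
  hasA <- vapply(subsets, function(s) clusterA_seed %in% s, logical(1))
  if (sum(hasA) != 1) {
    warning("Cluster-A seed does not identify a unique basal subclade")
    out[at_clade] <- "unplaced"
    return(out)
  }
  for (k in seq_along(subsets))
    out[subsets[[k]]] <- if (hasA[k]) "A" else "B"
  out
}
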