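test_that("distances satisfy metric basics and known values", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ATGTACGTAC")
  d <- seqDistances(seqs, model = "p")
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.1)  # 1 difference / 10

  d4 <- seqDistances(c(x = "ACGT", y = "ATGT", z = "ACGA"), model = "p")
  expect_equal(d4["x", "y"], 0.25)
})

test_that("K2P distance matches its closed form", {
  # P = 0.2 transitions, Q = 0: d = -0.5 ln(0.6)
  expect_equal(k2pDistance(0.2, 0), -0.5 * log(0.6))
  # anchored pair differing by 4 transitions over 20 sites (P = 0.2)
  a <- "CCGGAAAAAAAAAAAACCGG"
  b <- "CCGGGGAAGAAAAGAACCGG"  # A->G at 4 internal positions
  d <- seqDistances(c(a = a, b = b, c = a), model = "K2P")
  expect_equal(d["a", "b"], k2pDistance(4 / 20, 0), tolerance = 1e-12)
})

test_that("saturated K2P pairs fall back to p-distance with a warning", {
  # transition-saturated pair: P = 0.6 makes 1 - 2P - Q negative
  a <- paste0("CCGG", strrep("A", 12), "CCGG")
  b <- paste0("CCGG", strrep("G", 12), "CCGG")
  ch <- paste0("CCGG", strrep("G", 6), strrep("A", 6), "CCGG")  # halfway
  expect_warning(
    d <- seqDistances(c(a = a, b = b, c = ch), model = "K2P",
                      params = alignParams(terminalGaps = "penalized")),
    "p-distance")
  expect_equal(d["a", "b"], 0.6)
  expect_equal(nrow(attr(d, "saturated")), 1)
})

test_that("distances agree with an independent implementation on
           ungapped variants", {
  mk <- randomMarker(77)
  seqs <- c(ref = mk$seq,
            v1 = mutateSeq(mk$seq, 15, 5, at_bias = 0.5, seed = 78)$seq,
            v2 = mutateSeq(mk$seq, 8, 12, at_bias = 0.5, seed = 79)$seq)
  bin <- ape::as.DNAbin(t(sapply(seqs, function(x)
    strsplit(tolower(x), "")[[1]])))
  for (model in c("p", "K2P")) {
    mine <- seqDistances(seqs, model = model)
    ref <- as.matrix(ape::dist.dna(bin,
                                   model = if (model == "p") "raw" else "K80"))
    expect_equal(mine[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("NJ recovers additive four-taxon structure", {
  # additive matrix with ((a,b),(c,d)) structure
  d <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 2,
                8, 8, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(d)
  ab <- ape::getMRCA(ape::root(tr, "d"), c("a", "b"))
  tips_ab <- ape::extract.clade(ape::root(tr, "d"), ab)$tip.label
  expect_setequal(tips_ab, c("a", "b"))
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("identical sequences become sibling tips", {
  seqs <- c(a = "ACGTACGTACGTACGTACGT", b = "ACGTACGTACGTACGTACGT",
            c = "TTTTACGTACGTACGTAAAA", d = "TTTTACGTACGTCCGTAAAA")
  tr <- njTree(seqDistances(seqs))
  rooted <- ape::root(tr, "d")
  sib <- ape::extract.clade(rooted, ape::getMRCA(rooted, c("a", "b")))
  expect_setequal(sib$tip.label, c("a", "b"))
})

test_that("NJ exactly recovers random additive topologies", {
  set.seed(81)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- stats::runif(length(tr0$edge.length), 0.5, 2)
    d <- ape::cophenetic.phylo(tr0)
    tr <- njTree(d[tr0$tip.label, tr0$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr)), 0,
                 ignore_attr = TRUE, info = paste("case", k))
  }
})

test_that("bootstrap support is high for well-separated clades and
           reproducible", {
  mk <- randomMarker(82)
  prot <- mk$protected
  # two clades separated by 40 diagnostic transitions
  cladeA <- mutateSeq(mk$seq, n_transitions = 40, at_bias = 1, seed = 83,
                      protected = prot)
  a1 <- mutateSeq(cladeA$seq, 3, at_bias = 1, seed = 84, protected = prot)
  a2 <- mutateSeq(cladeA$seq, 3, at_bias = 1, seed = 85, protected = prot)
  b1 <- mutateSeq(mk$seq, 3, at_bias = 1, seed = 86, protected = prot)
  b2 <- mutateSeq(mk$seq, 3, at_bias = 1, seed = 87, protected = prot)
  seqs <- Biostrings::DNAStringSet(c(ref = mk$seq, a1 = a1$seq, a2 = a2$seq,
                                     b1 = b1$seq, b2 = b2$seq))
  tr <- bootstrapTree(seqs, reference = "ref", reps = 100, seed = 88)
  rooted <- ape::root(tr, "ref", resolve.root = TRUE)
  node <- ape::getMRCA(rooted, c("a1", "a2"))
  expect_setequal(ape::extract.clade(rooted, node)$tip.label, c("a1", "a2"))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup >= 95, na.rm = TRUE))
  tr2 <- bootstrapTree(seqs, reference = "ref", reps = 100, seed = 88)
  expect_identical(tr$node.label, tr2$node.label)
  expect_error(bootstrapTree(seqs, reps = 0), "reps")
})

test_that("cluster extraction reproduces the planted family structure", {
  fam <- buildReferenceFamily(89)
  d <- seqDistances(refSeqs(fam$library), model = "p")
  tr <- njTree(d)
  cl <- extractClusters(tr,
                        outgroup_ids = "AB067719-type",
                        at_seed_ids = c("#5", "#4", "#6", "#15", "#16", "#17"),
                        gc_seed_ids = c("#1", "#2", "#13", "#14", "S.hepiali"),
                        clusterA_seed = "#5")
  expect_equal(unname(cl[c("#5", "#6", "#16", "#17")]), rep("A", 4))
  expect_equal(unname(cl[c("#4", "#15")]), rep("B", 2))
  expect_equal(unname(cl[c("#1", "#2")]), rep("GC", 2))
  expect_equal(unname(cl["AB067719-type"]), "outgroup")

  expect_error(extractClusters(tr, "missing_tip", "#5", "#1"),
               "not in tree")
  expect_error(extractClusters(tr, character(0), "#5", "#1"), "outgroup")
})

test_that("non-monophyletic seeds yield unplaced labels, not guesses", {
  fam <- buildReferenceFamily(90)
  tr <- njTree(seqDistances(refSeqs(fam$library), model = "p"))
  # deliberately contradictory seeds: one AT seed inside the GC set
  expect_warning(
    cl <- extractClusters(tr, "AB067719-type",
                          at_seed_ids = c("#5", "#1"),
                          gc_seed_ids = c("#2", "#13")),
    "unplaced")
  expect_true(any(cl == "unplaced"))
})
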