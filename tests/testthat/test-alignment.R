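test_that("identical sequences align without gaps at full score", {
  aln <- globalAlign("ACGT", "ACGT")
  expect_equal(aln@alignedA, "ACGT")
  expect_equal(aln@alignedB, "ACGT")
  expect_equal(aln@score, 4)
})

test_that("empty input is rejected", {
  expect_error(globalAlign("", "ACGT"), "empty")
})

test_that("gap placement follows the scoring scheme and the oracle", {
  # with penalized terminal gaps the single gap lands opposite the C,
  # keeping the three matches
  p <- alignParams(terminalGaps = "penalized")
  aln <- globalAlign("ACGT", "AGT", p)
  expect_equal(aln@alignedB, "A-GT")
  expect_equal(aln@score, bruteForceScore("ACGT", "AGT", p))
  # with free terminal gaps a leading overhang is cheaper than an
  # internal gap
  f <- alignParams()
  alnf <- globalAlign("ACGT", "AGT", f)
  expect_equal(alnf@score, bruteForceScore("ACGT", "AGT", f))
})

test_that("the EcoRI-site pair aligns ungapped with one mismatch", {
  aln <- globalAlign("GAATTC", "GAATTT")
  expect_equal(aln@alignedA, "GAATTC")
  expect_equal(aln@alignedB, "GAATTT")
  cc <- strsplit(aln@alignedA, "")[[1]] == strsplit(aln@alignedB, "")[[1]]
  expect_equal(sum(cc), 5)
})

test_that("DP score equals the exhaustive enumeration oracle", {
  set.seed(11)
  for (k in 1:60) {
    a <- randomDna(sample(1:8, 1))
    b <- randomDna(sample(1:8, 1))
    for (pol in c("free", "penalized")) {
      p <- alignParams(terminalGaps = pol)
      expect_equal(globalAlign(a, b, p)@score, bruteForceScore(a, b, p),
                   info = sprintf("%s vs %s (%s)", a, b, pol))
    }
  }
})

test_that("DP score matches an independent aligner on random pairs", {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  set.seed(5)
  for (k in 1:25) {
    a <- randomDna(sample(10:60, 1))
    b <- randomDna(sample(10:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = m, gapOpening = 5, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    mine <- globalAlign(a, b, alignParams(terminalGaps = "penalized"))@score
    expect_equal(mine, ref, info = paste(a, b))
  }
})

test_that("alignment is deterministic and recovers its inputs", {
  set.seed(3)
  for (k in 1:20) {
    a <- randomDna(sample(5:40, 1)); b <- randomDna(sample(5:40, 1))
    x <- globalAlign(a, b); y <- globalAlign(a, b)
    expect_identical(x@alignedA, y@alignedA)
    expect_identical(x@alignedB, y@alignedB)
    expect_equal(gsub("-", "", x@alignedA), a)
    expect_equal(gsub("-", "", x@alignedB), b)
    cols_a <- strsplit(x@alignedA, "")[[1]]
    cols_b <- strsplit(x@alignedB, "")[[1]]
    expect_false(any(cols_a == "-" & cols_b == "-"))
  }
})

test_that("percent identity follows the stated conventions", {
  expect_equal(percentIdentity(globalAlign(strrep("ACGTT", 4),
                                           strrep("ACGTT", 4))), 100)
  # hand-counted 17/20 matching positions of the two AT-genotype primers
  aln <- globalAlign("GGGGCTCGAGGGTTAAGATA", "GGGGCTTAAGGGTTAAGGTA")
  expect_equal(percentIdentity(aln), 85)
  # terminal gaps excluded by default, counted under all_columns
  aln2 <- globalAlign("AAACGCGCGC", "CGCGCGC")
  expect_equal(percentIdentity(aln2, "exclude_terminal_gaps"), 100)
  expect_lt(percentIdentity(aln2, "all_columns"), 100)
})

test_that("percent identity is reflexive and symmetric", {
  mk <- randomMarker(9)
  for (k in 1:10) {
    a <- mk$seq
    b <- mutateSeq(a, n_transitions = 10, n_transversions = 5,
                   at_bias = 0.5, seed = k)$seq
    if (k %% 2 == 0)  # drop a short block to exercise gapped alignments
      b <- paste0(substr(b, 1, 99), substr(b, 108, nchar(b)))
    expect_equal(percentIdentity(globalAlign(a, a)), 100)
    expect_equal(percentIdentity(globalAlign(a, b)),
                 percentIdentity(globalAlign(b, a)))
  }
})

test_that("segment projection maps boundaries through the alignment", {
  fam <- buildReferenceFamily(21)
  ref <- fam$library["#1"]
  refseq <- as.character(refSeqs(ref)[[1]])
  seg <- refSegments(ref)[[1]]

  # identity projection
  pr <- projectSegments(ref, refseq)
  expect_identical(as.data.frame(pr), as.data.frame(seg))

  # 10 bp deleted inside ITS1: ITS1 shrinks by 10, later segments keep
  # their lengths
  s <- IRanges::start(seg["its1"]) + 50
  del <- paste0(substr(refseq, 1, s - 1), substr(refseq, s + 10, nchar(refseq)))
  pr2 <- projectSegments(ref, del)
  expect_equal(IRanges::width(pr2["its1"]), IRanges::width(seg["its1"]) - 10)
  expect_equal(IRanges::width(pr2["r58s"]), IRanges::width(seg["r58s"]))
  expect_equal(IRanges::width(pr2["its2"]), IRanges::width(seg["its2"]))

  # 5' flank removed: flank5 absent, ITS1 starts at 1
  trunc <- substr(refseq, IRanges::start(seg["its1"]), nchar(refseq))
  pr3 <- projectSegments(ref, trunc)
  expect_false("flank5" %in% names(pr3))
  expect_equal(IRanges::start(pr3["its1"]), 1)

  # unalignable fragments are refused
  expect_error(projectSegments(ref, randomDna(30, 4)), "no reliable")
})

test_that("segment identity profile isolates the recombinant structure", {
  fam <- buildReferenceFamily(22)
  ref1 <- fam$library["#1"]
  s <- as.character(refSeqs(fam$library))

  self <- segmentIdentityProfile(s[["#1"]], ref1)
  expect_equal(unlist(self[, c("its1", "r58s", "its2", "full")]),
               c(its1 = 100, r58s = 100, its2 = 100, full = 100))

  # chimera with ITS1 from parent A (#1): its1 = 100, its2 < 100
  ch <- makeChimera(s[["#1"]], s[["AB067719-type"]],
                    fam$layout$its1[2])$seq
  prof <- segmentIdentityProfile(ch, ref1)
  expect_equal(prof$its1, 100)
  expect_lt(prof$its2, 100)
})

test_that("full-region identity is bounded by segment identities on
           gap-free cases", {
  fam <- buildReferenceFamily(23)
  ref1 <- fam$library["#1"]
  s <- as.character(refSeqs(fam$library))
  for (id in c("#2", "#4", "#5", "#13", "#14")) {
    prof <- segmentIdentityProfile(s[[id]], ref1)
    segs <- unlist(prof[, c("its1", "r58s", "its2")])
    expect_gte(prof$full, min(segs) - 1e-9)
    expect_lte(prof$full, max(segs) + 1e-9)
  }
})
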