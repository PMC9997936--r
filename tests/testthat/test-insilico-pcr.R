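test_that("reverse complement handles IUPAC codes and is an involution", {
  expect_equal(revComp("GAATTC"), "GAATTC")  # palindrome
  expect_equal(revComp("ACGTN"), "NACGT")
  expect_equal(revComp("RYSWKM"), "KMWSRY")
  set.seed(2)
  for (k in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T", "N", "R", "Y"),
                      sample(5:40, 1), replace = TRUE), collapse = "")
    expect_equal(revComp(revComp(x)), x)
  }
})

test_that("an exact substring yields a single perfect plus-strand site", {
  tmpl <- paste0(randomDna(50, 31), "GATTACAGATTACAGATT", randomDna(50))
  sites <- scanPrimer(tmpl, "GATTACAGATTACAGATT", min_identity = 90)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$strand, "+")
  expect_equal(sites$start, 51)
  expect_equal(sites$identity, 100)
  expect_equal(sites$n_mismatch, 0)
})

test_that("minus-strand sites are found via the reverse complement", {
  primer <- "ACCGTTGGACCGTTGGACGT"
  tmpl <- paste0(randomDna(40, 32), revComp(primer), randomDna(40))
  sites <- scanPrimer(tmpl, primer, min_identity = 95)
  expect_equal(sites$strand, "-")
  expect_equal(sites$start, 41)
  expect_equal(sites$identity, 100)
})

test_that("mismatch positions are in primer coordinates with 3' flag", {
  primer <- "AAAACCCCGGGGTTTTACGT"
  site <- primer
  substr(site, 19, 19) <- "C"  # mismatch 2 bases from the 3' end
  tmpl <- paste0(randomDna(30, 33), site, randomDna(30))
  hit <- scanPrimer(tmpl, primer, min_identity = 90)
  hit <- hit[hit$strand == "+", ]
  expect_equal(hit$mismatch_positions, "19")
  expect_true(hit$three_prime_mismatch)
  # same site planted as reverse complement: primer coordinates preserved
  tmplrc <- paste0(randomDna(30, 34), revComp(site), randomDna(30))
  hitrc <- scanPrimer(tmplrc, primer, min_identity = 90)
  hitrc <- hitrc[hitrc$strand == "-", ]
  expect_equal(hitrc$mismatch_positions, "19")
  expect_true(hitrc$three_prime_mismatch)
})

test_that("sites below the identity threshold are not reported", {
  primer <- "AAAACCCCGGGGTTTTACGT"
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  site <- strsplit(primer, "")[[1]]
  for (i in c(3, 9, 17)) site[i] <- flip[site[i]]  # 17/20 = 85%
  tmpl <- paste0(randomDna(25, 35), paste(site, collapse = ""),
                 randomDna(25))
  expect_equal(nrow(scanPrimer(tmpl, primer, min_identity = 90)), 0)
  hits <- scanPrimer(tmpl, primer, min_identity = 80)
  expect_equal(hits$identity[1], 85)
})

test_that("scanning is mirror-symmetric under reverse complement", {
  set.seed(36)
  tmpl <- randomDna(200)
  primer <- substr(tmpl, 81, 100)
  fwd <- scanPrimer(tmpl, primer, min_identity = 70)
  rev <- scanPrimer(revComp(tmpl), revComp(primer), min_identity = 70)
  # sites map to mirrored coordinates, strand labels preserved
  expect_equal(nrow(fwd), nrow(rev))
  key <- function(df, L) sort(paste(df$strand, L - df$end + 1))
  expect_equal(key(fwd, 200), sort(paste(rev$strand, rev$start)))
})

test_that("best-site identity decreases as planted mismatches accumulate", {
  primer <- "ACACGTGTACACGTGTACAC"
  set.seed(37)
  prev <- 101
  site <- primer
  for (nmm in 0:4) {
    if (nmm > 0) {
      i <- 4 * nmm
      substr(site, i, i) <- setdiff(c("A", "C", "G", "T"),
                                    substr(site, i, i))[1]
    }
    tmpl <- paste0(randomDna(30), site, randomDna(30))
    best <- scanPrimer(tmpl, primer, min_identity = 50)$identity[1]
    expect_lte(best, prev)
    prev <- best
  }
})

test_that("amplicons are predicted from facing site pairs", {
  fwd <- "GGAAGTAAAAGTCGTAACAAGG"  # ITS5
  rev <- "TCCTCCGCTTATTGATATGC"    # ITS4
  mid <- randomDna(650 - nchar(fwd) - nchar(rev), 38)
  tmpl <- paste0(fwd, mid, revComp(rev))
  amp <- predictAmplicons(tmpl, fwd, rev, min_identity = 90)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 650)
  expect_equal(amp$fwd_start, 1)
  expect_equal(amp$rev_end, 650)
  expect_equal(amp$sequence, tmpl)

  # no reverse site -> no amplicon
  amp2 <- predictAmplicons(paste0(fwd, mid), fwd, rev, min_identity = 90)
  expect_equal(nrow(amp2), 0)

  # two forward sites -> two amplicons, best combined identity first
  fwd2 <- fwd; substr(fwd2, 5, 5) <- "C"
  tmpl3 <- paste0(fwd2, randomDna(50, 39), fwd, mid, revComp(rev))
  amp3 <- predictAmplicons(tmpl3, fwd, rev, min_identity = 80)
  expect_equal(nrow(amp3), 2)
  expect_true(all(diff(amp3$fwd_identity + amp3$rev_identity) <= 0))
})

test_that("amplicon length equals the planted inter-primer distance", {
  fwd <- primerSeq("ITS5"); rev <- primerSeq("ITS4")
  for (seed in 1:25) {
    set.seed(seed)
    gap <- sample(100:500, 1)
    tmpl <- paste0(randomDna(10), fwd, randomDna(gap), revComp(rev),
                   randomDna(10))
    amp <- predictAmplicons(tmpl, fwd, rev, min_identity = 95)
    expect_equal(amp$length[1], nchar(fwd) + gap + nchar(rev))
  }
})

test_that("specificity matrix reports best identity per primer/reference", {
  fam <- buildReferenceFamily(40)
  pt <- loadPrimerTable()
  pr <- pt$primers[pt$primers$name %in% c("ITS5", "ITS4"), ]
  m <- specificityMatrix(pr, fam$library)
  # the universal primers are planted verbatim in every generated marker
  expect_true(all(m == 100))
  # a primer against its own sequence is a perfect site
  self <- specificityMatrix(
    pr, Biostrings::DNAStringSet(c(ITS5 = primerSeq("ITS5"))))
  expect_equal(self["ITS5", "ITS5"], 100)
})
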