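test_that("marker generation is deterministic and plants its features", {
  m1 <- randomMarker(101)
  m2 <- randomMarker(101)
  expect_identical(m1$seq, m2$seq)
  expect_false(identical(randomMarker(102)$seq, m1$seq))

  lay <- markerLayout()
  # planted forward primer found at 100% at its planting position
  hit <- scanPrimer(m1$seq, primerSeq("ITS5"), min_identity = 100)
  hit <- hit[hit$strand == "+", ]
  expect_true(any(hit$start == lay$fwd_start & hit$identity == 100))
  # reverse primer planted as reverse complement at the 3' end
  rhit <- scanPrimer(m1$seq, primerSeq("ITS4"), min_identity = 100)
  expect_true(any(rhit$strand == "-" & rhit$end == lay$rev_end))
  # exactly the planted EcoRI site
  expect_equal(findRecognitionSites(m1$seq), lay$ecori_start)
})

test_that("layout validation rejects inconsistent plans", {
  expect_error(markerLayout(its1 = c(41, 269)), "tile")
  expect_error(markerLayout(ecori_start = 50), "5.8S")
})

test_that("mutateSeq applies exactly the requested edits", {
  mk <- randomMarker(103)
  m0 <- mutateSeq(mk$seq, 0, 0, seed = 104)
  expect_identical(m0$seq, mk$seq)
  expect_equal(nrow(m0$truth), 0)

  m <- mutateSeq(mk$seq, n_transitions = 20, n_transversions = 7,
                 at_bias = 1, seed = 105, protected = mk$protected)
  expect_equal(sum(m$truth$type == "transition"), 20)
  expect_equal(sum(m$truth$type == "transversion"), 7)
  expect_equal(sum(m$truth$at_shift), 20)
  expect_false(any(m$truth$pos %in% mk$protected))
  expect_false(anyDuplicated(m$truth$pos) > 0)
  # truth describes real edits
  x <- strsplit(mk$seq, "")[[1]]; y <- strsplit(m$seq, "")[[1]]
  expect_equal(which(x != y), m$truth$pos)
  expect_equal(y[m$truth$pos], m$truth$to)

  expect_error(mutateSeq("ACGT", n_transitions = 10), "not enough")
})

test_that("chimera construction alternates parental blocks", {
  a <- strrep("A", 600); b <- strrep("C", 600)
  expect_equal(makeChimera(a, b)$seq, a)
  ch <- makeChimera(a, b, 300)$seq
  expect_equal(substr(ch, 1, 300), strrep("A", 300))
  expect_equal(substr(ch, 301, 600), strrep("C", 300))
  ch2 <- makeChimera(a, b, c(200, 400))$seq
  expect_equal(ch2, paste0(strrep("A", 200), strrep("C", 200),
                           strrep("A", 200)))
  expect_error(makeChimera(a, b, c(300, 300)), "increasing")
  expect_error(makeChimera(a, substr(b, 1, 599), 300), "equal length")
})

test_that("a double-breakpoint chimera is recovered by detection", {
  fam <- buildReferenceFamily(106)
  s <- as.character(refSeqs(fam$library))
  ch <- makeChimera(s[["#1"]], s[["AB067719-type"]], c(200, 430))
  call <- detectChimera(ch$seq, s[["#1"]], s[["AB067719-type"]])
  expect_equal(nBreakpoints(call), 2)
})

test_that("clone libraries are deterministic with recorded truth", {
  fam <- buildReferenceFamily(107)
  lib <- simulateCloneLibrary(c(`#1` = 5, `#5` = 3), refSeqs(fam$library),
                              per_base_error = 0.01, seed = 108)
  lib2 <- simulateCloneLibrary(c(`#1` = 5, `#5` = 3), refSeqs(fam$library),
                               per_base_error = 0.01, seed = 108)
  expect_identical(as.character(lib$clones), as.character(lib2$clones))
  expect_equal(lib$truth$source, rep(c("#1", "#5"), c(5, 3)))

  # error 0: clones are exact copies
  lib0 <- simulateCloneLibrary(c(`#1` = 3), refSeqs(fam$library), 0, 109)
  expect_true(all(as.character(lib0$clones) ==
                    as.character(refSeqs(fam$library)[["#1"]])))

  # empty composition -> empty sample
  lib_empty <- simulateCloneLibrary(setNames(integer(0), character(0)),
                                    refSeqs(fam$library), 0, 110)
  expect_length(lib_empty$clones, 0)
  expect_error(simulateCloneLibrary(c(`#1` = 1), refSeqs(fam$library),
                                    per_base_error = 0.2), "per_base_error")
})

test_that("the synthetic family realizes its design constraints", {
  fam <- buildReferenceFamily(111)
  lib <- fam$library
  s <- as.character(refSeqs(lib))
  info <- refInfo(lib)
  expect_equal(length(lib), 12)
  # AT-biased members lost the EcoRI site, GC-biased kept it
  lay <- fam$layout
  for (id in info$genotype_id[info$class == "AT-biased"])
    expect_false(lay$ecori_start %in% findRecognitionSites(s[[id]]))
  for (id in c("#1", "#2"))
    expect_true(lay$ecori_start %in% findRecognitionSites(s[[id]]))
  # chimeras: #13 carries #1's ITS1 and the outgroup's ITS2; #14 converse
  p13 <- segmentIdentityProfile(s[["#13"]], lib["#1"])
  expect_equal(p13$its1, 100)
  expect_lt(p13$its2, 100)
  p14 <- segmentIdentityProfile(s[["#14"]], lib["#1"])
  expect_lt(p14$its1, 100)
  expect_equal(p14$its2, 100)
  # distinct genotypes stay below the call threshold of each other
  for (pair in list(c("#4", "#5"), c("#5", "#17"), c("#1", "#2"))) {
    pid <- percentIdentity(globalAlign(s[[pair[1]]], s[[pair[2]]]))
    expect_lt(pid, 100)
  }
})

test_that("scenario samples are deterministic and follow the design", {
  sc <- buildTable2Scenario(seed = 112)
  sc2 <- buildTable2Scenario(seed = 112)
  expect_identical(lapply(sc$samples, as.character),
                   lapply(sc2$samples, as.character))
  expect_equal(names(sc$samples),
               c("stroma_immature", "stroma_mature", "SFP",
                 "ascospores_fully_ejected", "ascospores_semiejected"))
  expect_true(all(vapply(sc$samples, length, integer(1)) == 30))
  # recombinants confined to their ascospore type
  expect_true("#13" %in% sc$truth$ascospores_semiejected$source)
  expect_false("#13" %in% sc$truth$ascospores_fully_ejected$source)
  expect_true("#14" %in% sc$truth$ascospores_fully_ejected$source)
  # S. hepiali less abundant in fully ejected than semiejected ascospores
  n_full <- sum(sc$truth$ascospores_fully_ejected$source == "S.hepiali")
  n_semi <- sum(sc$truth$ascospores_semiejected$source == "S.hepiali")
  expect_lt(n_full, n_semi)
  # Cluster-B genotypes absent from both ascospore columns
  for (comp in c("ascospores_fully_ejected", "ascospores_semiejected"))
    expect_length(intersect(c("#4", "#15"), sc$truth[[comp]]$source), 0)
})
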