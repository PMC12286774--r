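test_that("regeneration with the same seed is byte-identical on disk", {
  b1 <- smallBundle(seed = 99L, nLibraries = 6L)
  b2 <- smallBundle(seed = 99L, nLibraries = 6L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeBundle(b1, d1)
  writeBundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  b3 <- smallBundle(seed = 100L, nLibraries = 6L)
  expect_false(identical(b1$counts, b3$counts))
})

test_that("the manifest accounts for every contig exactly once", {
  b <- smallBundle(seed = 12L, nLibraries = 5L)
  expect_setequal(b$truth$contig_id, contigIds(b$contigs))
  expect_equal(anyDuplicated(b$truth$contig_id), 0L)
  nSeg <- sum(b$truth$entity_type == "segmented_virus_segment")
  expect_equal(nSeg, 2L + 3L + 2L + 4L + 3L)   # sum of planted segments
  expect_equal(sum(b$truth$entity_type == "unsegmented_virus"), 2L)
  expect_equal(sum(b$truth$entity_type == "host"), 30L)
  expect_equal(rownames(b$counts), contigIds(b$contigs))
})

test_that("segment rates are exactly proportional to scales when noise is off", {
  v <- virusSpec("v1", 3L, segmentScales = c(0.3, 0.1, 1.0),
                 prevalence = 1.0)
  b <- simulateBundle(simulationSpec(list(v), nLibraries = 40L,
                                     hostContigs = 2L, noiseCv = 0,
                                     rngSeed = 5L))
  cnt <- b$counts[paste0("v1::seg", c("01", "02", "03")), ]
  # Poisson counts around proportional rates: compare totals, which
  # concentrate tightly around the scale ratios
  tot <- rowSums(cnt)
  expect_equal(unname(tot[2] / tot[1]), 0.1 / 0.3, tolerance = 0.05)
  expect_equal(unname(tot[3] / tot[1]), 1.0 / 0.3, tolerance = 0.05)
  # shared presence pattern: a segment is only ever positive where the
  # virus load is positive
  expect_true(all(colSums(cnt > 0) %in% c(0L, 1L, 2L, 3L)))
})

test_that("full dropout silences every segment", {
  v <- virusSpec("v1", 2L, prevalence = 1.0)
  b <- simulateBundle(simulationSpec(list(v), nLibraries = 10L,
                                     hostContigs = 1L, dropoutProb = 1,
                                     rngSeed = 6L))
  expect_true(all(b$counts[startsWith(rownames(b$counts), "v1::"), ] == 0))
})

test_that("per-library loads follow the specified lognormal (KS at alpha 0.01)", {
  v <- virusSpec("v1", 2L, prevalence = 1.0)
  spec <- simulationSpec(list(v), nLibraries = 250L, hostContigs = 1L,
                         noiseCv = 0, loadMeanlog = log(3000),
                         loadSdlog = 1.2, rngSeed = 7L)
  b <- simulateBundle(spec)
  # recover the anchor's library loads from its counts (scale 0.3);
  # Poisson error is negligible relative to the lognormal spread
  loads <- b$counts["v1::seg01", ] / 0.3
  ks <- suppressWarnings(
    stats::ks.test(log(loads[loads > 0]), "pnorm", log(3000), 1.2))
  expect_gt(ks$p.value, 0.01)
})

test_that("two independent viruses separate in correlation at 50 libraries", {
  vs <- list(virusSpec("vA", 2L, prevalence = 0.5),
             virusSpec("vB", 2L, prevalence = 0.5))
  b <- simulateBundle(simulationSpec(vs, nLibraries = 50L,
                                     hostContigs = 5L, noiseCv = 0.05,
                                     rngSeed = 8L))
  lens <- contigLengths(b$contigs)
  ab <- computeTpm(b$counts, lens)
  res <- buildCorrelationMatrix(ab, c("vA::seg01", "vB::seg01"))
  same <- res[res$anchor_id == "vA::seg01" & res$member_id == "vA::seg02", ]
  cross <- res[res$anchor_id == "vA::seg01" &
                 startsWith(res$member_id, "vB::"), ]
  expect_gt(same$rho, 0.95)
  expect_true(all(cross$rho < 0.8))
})

test_that("planted terminal motifs appear in the sequences as specified", {
  v <- virusSpec("v1", 3L, motif = "AGATCGGAAGAGC", rcMotif = TRUE)
  b <- simulateBundle(simulationSpec(list(v), nLibraries = 4L,
                                     hostContigs = 1L, rngSeed = 9L))
  for (s in sprintf("v1::seg%02d", 1:3)) {
    sq <- as.character(contigSequences(b$contigs)[[s]])
    expect_equal(substring(sq, 1, 13), "AGATCGGAAGAGC")
    expect_equal(substring(sq, nchar(sq) - 12), rcOracle("AGATCGGAAGAGC"))
  }
})

test_that("an infeasible prevalence warns instead of failing", {
  v <- virusSpec("v1", 2L, prevalence = 0.01)
  expect_warning(simulationSpec(list(v), nLibraries = 10L),
                 "fewer than one library")
})
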