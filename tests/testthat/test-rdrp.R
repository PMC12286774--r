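mkContigs <- function(ids, lens, cov) {
  set.seed(1)
  seqs <- vapply(lens, function(L) codingSeq(L %/% 3), character(1))
  names(seqs) <- ids
  ContigSet(Biostrings::DNAStringSet(seqs), library = "L1", coverage = cov)
}

test_that("candidacy needs both a viral-protein and an RdRP hit within cutoffs", {
  contigs <- mkContigs(c("c1", "c2", "c3"), c(900, 900, 900), c(60, 60, 60))
  nr <- annotationHits(c("c1", "c3"), "vp", 40, 300L, 1L, 300L,
                       evalue = c(1e-5, 1e-3), bitscore = 100,
                       category = "viral_protein")
  rdrp <- annotationHits(c("c1", "c2", "c3"), "rd", 45, 300L, 1L, 300L,
                         evalue = c(1e-6, 1e-3, 1e-20), bitscore = 200,
                         category = "rdrp")
  cands <- flagRdrpContigs(contigs, nr, rdrp, segConfig())
  ids <- vapply(cands, function(x) x@contigId, character(1))
  # c1: both hits pass; c2: no nr hit; c3: nr hit above 1e-4
  expect_equal(ids, "c1")
})

test_that("best RdRP hit tie-breaks by bitscore then subject id", {
  contigs <- mkContigs("c1", 900, 60)
  nr <- annotationHits("c1", "vp", 40, 300L, 1L, 300L, 1e-9, 100,
                       category = "viral_protein")
  rdrp <- rbind(
    annotationHits("c1", "rdA", 45, 300L, 1L, 300L, 1e-10, 200, "rdrp"),
    annotationHits("c1", "rdB", 45, 300L, 10L, 310L, 1e-10, 210, "rdrp"))
  cand <- flagRdrpContigs(contigs, nr, rdrp, segConfig())[[1]]
  expect_equal(cand@bestRdrpHit$subject_id, "rdB")
  expect_equal(cand@rdrpRegion, c(10L, 310L))
})

test_that("chimera rule follows the interval-overlap oracle", {
  contigs <- mkContigs("c1", 2000, 80)
  nr <- annotationHits("c1", "vp", 40, 300L, 200L, 1500L, 1e-9, 100,
                       category = "viral_protein")
  rdrp <- annotationHits("c1", "rd", 45, 300L, 200L, 1500L, 1e-9, 200,
                         category = "rdrp")
  cand <- flagRdrpContigs(contigs, nr, rdrp, segConfig())[[1]]

  cases <- list(
    list(qs = 1600L, qe = 1990L, chim = TRUE),   # fully outside
    list(qs = 300L,  qe = 1400L, chim = FALSE),  # inside the RdRP region
    list(qs = 1450L, qe = 1549L, chim = FALSE),  # 100 nt, half overlapping
    list(qs = 1460L, qe = 1659L, chim = TRUE))   # 200 nt, 20% overlap
  for (cs in cases) {
    nt <- annotationHits("c1", "ntdb", 95, 500L, cs$qs, cs$qe, 1e-20, 400,
                         category = "nonviral_nt")
    got <- flagChimeras(cand, nt, segConfig())
    # oracle: hit length >= 100 and overlap with the RdRP region < 50%
    hitLen <- cs$qe - cs$qs + 1
    expOut <- hitLen >= 100 && overlapLen(cs$qs, cs$qe, 200, 1500) / hitLen < 0.5
    expect_equal(expOut, cs$chim)
    expect_equal("chimeric" %in% failReasons(got), cs$chim,
                 info = sprintf("hit %d-%d", cs$qs, cs$qe))
  }
  # no nonviral hits leaves the candidate unchanged
  expect_true(passes(flagChimeras(cand, emptyAnnotationTable("nonviral_nt"),
                                  segConfig())))
})

test_that("anchor filters: coverage >= 50 passes, 599 nt fails length, missing coverage fails", {
  contigs <- mkContigs(c("a", "b", "c"), c(1433, 599, 900),
                       c(50, 80, NA))
  nr <- annotationHits(c("a", "b", "c"), "vp", 40, 300L, 1L, 300L, 1e-9,
                       100, category = "viral_protein")
  rdrp <- annotationHits(c("a", "b", "c"), "rd", 45, 300L, 1L, 300L, 1e-9,
                         200, category = "rdrp")
  cands <- screenRdrp(contigs, nr, rdrp, config = segConfig())
  byId <- setNames(cands, vapply(cands, function(x) x@contigId, character(1)))
  expect_true(passes(byId$a))                       # boundary: exactly 50
  expect_equal(failReasons(byId$b), "length")       # 599 < 600
  expect_equal(failReasons(byId$c), "coverage")     # missing coverage
})

test_that("raising the coverage threshold never adds a passing anchor", {
  run <- cachedSmallRun()
  b <- run$bundle
  nr <- rbind(b$annotations$viral, b$annotations$cellular)
  passing <- function(covMin) {
    cfg <- segConfig(rdrpCoverageMin = covMin)
    ids <- vapply(Filter(passes,
                         screenRdrp(b$contigs, nr, b$annotations$rdrp,
                                    b$annotations$nonviral, cfg)),
                  function(x) x@contigId, character(1))
    ids
  }
  prev <- passing(0)
  for (covMin in c(10, 50, 200, 1e5)) {
    cur <- passing(covMin)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("passing anchors on synthetic data equal the manifest's qualifying RdRP contigs", {
  run <- cachedSmallRun()
  b <- run$bundle
  got <- sort(vapply(run$run$anchors, function(x) x@contigId, character(1)))
  cov <- contigCoverage(b$contigs)
  lens <- contigLengths(b$contigs)
  rdrpIds <- unique(b$annotations$rdrp$query_id)
  want <- sort(Filter(function(id)
    !is.na(cov[id]) && cov[id] >= 50 && lens[id] >= 600, rdrpIds))
  expect_equal(got, want)
})
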