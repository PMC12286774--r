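test_that("spearmanRho handles the canonical cases", {
  x <- c(3, 7, 1, 9)
  expect_equal(spearmanRho(x, x), 1)
  expect_equal(spearmanRho(sort(x), rev(sort(x))), -1)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearmanRho(c(2, 2, 2), c(1, 5, 3))))
  expect_error(spearmanRho(1:3, 1:4), "equal length")
})

test_that("spearmanRho is invariant under strictly monotone transforms", {
  set.seed(10)
  for (i in 1:20) {
    x <- rlnorm(15)
    y <- rlnorm(15)
    r <- spearmanRho(x, y)
    expect_equal(spearmanRho(log1p(x), y), r, tolerance = 1e-12)
    expect_equal(spearmanRho(x, sqrt(y)), r, tolerance = 1e-12)
  }
})

test_that("anchor-vs-all correlation has the right shape and treats zeros honestly", {
  m <- rbind(
    anch1 = c(10, 20, 30, 0, 5),
    anch2 = c(1, 2, 1, 8, 1),
    segA  = c(22, 41, 65, 0, 11),
    dead  = c(0, 0, 0, 0, 0))
  colnames(m) <- paste0("L", 1:5)
  ab <- AbundanceMatrix(m * 1.0)
  res <- buildCorrelationMatrix(ab, c("anch1", "anch2"))
  expect_equal(nrow(res), 2L * 3L)
  expect_equal(unique(res$n_libraries), 5L)
  dead <- res[res$member_id == "dead", ]
  expect_true(all(is.na(dead$rho)))
  segRow <- res[res$anchor_id == "anch1" & res$member_id == "segA", ]
  expect_equal(segRow$rho, 1)          # same rank order
  expect_equal(segRow$n_joint_nonzero, 4L)
  expect_error(buildCorrelationMatrix(ab, "ghost"), "ghost")
})

test_that("cluster membership respects the threshold boundary in both modes", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6),
             exact = c(1, 2, 3, 4, 6, 5),   # rho vs a < 1 but high
             low = c(6, 1, 5, 2, 4, 3))
  colnames(m) <- paste0("L", 1:6)
  ab <- AbundanceMatrix(m * 1.0)
  res <- buildCorrelationMatrix(ab, "a")
  rhoExact <- res$rho[res$member_id == "exact"]
  cfgIn <- segConfig(corrThreshold = rhoExact)
  cfgEx <- segConfig(corrThreshold = rhoExact, inclusiveThreshold = FALSE)
  memIn <- formClusters(res, ab, config = cfgIn)[[1]]@members$memberId
  memEx <- formClusters(res, ab, config = cfgEx)[[1]]@members$memberId
  expect_true("exact" %in% memIn)   # inclusive keeps rho == threshold
  expect_false("exact" %in% memEx)  # exclusive drops it
  expect_false("low" %in% memIn)
})

test_that("raising the correlation threshold never adds members", {
  run <- cachedSmallRun()$run
  sizes <- function(th) {
    cls <- formClusters(run$correlations, run$abundance,
                        config = segConfig(corrThreshold = th))
    vapply(cls, function(cl) nrow(cl@members), integer(1))
  }
  prev <- sizes(0.05)
  for (th in c(0.3, 0.6, 0.8, 0.95, 1)) {
    cur <- sizes(th)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("same-virus segments correlate above 0.8 and independent viruses below, for >=95% of pairs", {
  run <- cachedBenchmarkRun()
  b <- cachedBenchmark()
  truth <- b$truth
  virusOf <- setNames(truth$virus_id, truth$contig_id)
  typeOf <- setNames(truth$entity_type, truth$contig_id)
  cor <- run$correlations
  seg <- cor[typeOf[cor$member_id] %in% "segmented_virus_segment", ]
  same <- seg[virusOf[seg$anchor_id] == virusOf[seg$member_id], ]
  diff <- seg[virusOf[seg$anchor_id] != virusOf[seg$member_id], ]
  expect_gte(mean(same$rho >= 0.8, na.rm = TRUE), 0.95)
  expect_gte(mean(diff$rho < 0.8, na.rm = TRUE), 0.95)
})

test_that("a planted proportional profile with small noise lands near rho 1", {
  set.seed(11)
  load <- rlnorm(50, log(1000), 1)
  anchor <- rpois(50, load * 0.5)
  seg <- rpois(50, load * 2 * rlnorm(50, 0, 0.05))
  m <- rbind(anchor = anchor, seg = seg)
  colnames(m) <- paste0("L", 1:50)
  res <- buildCorrelationMatrix(AbundanceMatrix(m * 1.0), "anchor")
  expect_gt(res$rho[res$member_id == "seg"], 0.95)
})

test_that("threshold sweep is deterministic and hits its degenerate corners", {
  run <- cachedSmallRun()
  b <- run$bundle
  cand <- run$run$candidates
  ab <- run$run$abundance
  sw1 <- sweepThresholds(ab, cand, b$truth, covGrid = c(0, 50),
                         rhoGrid = c(0.8, 2))
  sw2 <- sweepThresholds(ab, cand, b$truth, covGrid = c(0, 50),
                         rhoGrid = c(0.8, 2))
  expect_identical(sw1, sw2)
  # a threshold above all finite rho leaves only anchors: completeness
  # equals the anchor share of true segments, FDR 0
  top <- sw1[sw1$rho == 2 & sw1$cov == 50, ]
  expect_equal(top$fdr, 0)
  nSeg <- sum(b$truth$entity_type == "segmented_virus_segment")
  expect_equal(top$completeness, 5 / nSeg)
  expect_error(sweepThresholds(ab, cand, b$truth, numeric(), 0.8),
               "non-empty")
})
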