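# A comfortable TPM profile: positive in 5 libraries, max well above 200.
.hi <- c(800, 500, 900, 300, 400)
.libs <- paste0("L", 1:5)

test_that("member filters remove on one primary reason each", {
  set.seed(20)
  w <- makeQcWorld(
    tpm = list(anch = .hi, cellm = .hi, shorty = .hi,
               faint = c(50, 100, 199.9, 0, 3), lowcov = .hi, good = .hi),
    lengths = c(anch = 1200, cellm = 1200, shorty = 599, faint = 1200,
                lowcov = 1200, good = 1200),
    coverage = c(anch = 80, cellm = 30, shorty = 30, faint = 30,
                 lowcov = 9.99, good = 10),   # member boundary: 10 passes
    cellularIds = "cellm", cellularIdent = 45)
  cl <- makeCluster("anch", c("cellm", "shorty", "faint", "lowcov", "good"))
  out <- filterMembers(cl, w$abund, w$annotations, w$contigs, segConfig())
  rm <- setNames(out@removedMembers$reason, out@removedMembers$memberId)
  expect_equal(rm[["cellm"]], "cellular_member")
  expect_equal(rm[["shorty"]], "short")
  expect_equal(rm[["faint"]], "low_tpm")      # 199.9 < 200 boundary
  expect_equal(rm[["lowcov"]], "low_coverage")
  expect_setequal(out@members$memberId, c("anch", "good"))
  # conservation: retained + removed = original
  expect_equal(nrow(out@members) + nrow(out@removedMembers),
               nrow(cl@members))
})

test_that("a weakly cellular-looking viral protein is kept", {
  set.seed(21)
  w <- makeQcWorld(
    tpm = list(anch = .hi, dual = .hi),
    lengths = c(anch = 1200, dual = 1200),
    coverage = c(anch = 80, dual = 40),
    cellularIds = "dual", cellularIdent = 45)
  # give the member a stronger viral-protein hit than its cellular one
  viral <- annotationHits("dual", "viralhit", 55, 300L, 1L, 300L,
                          1e-30, 500, category = "viral_protein")
  ann <- rbind(w$annotations, viral)
  cl <- makeCluster("anch", "dual")
  out <- filterMembers(cl, w$abund, ann, w$contigs, segConfig())
  expect_true("dual" %in% out@members$memberId)
})

test_that("each cluster rule fires alone on its minimal cluster", {
  set.seed(22)
  w <- makeQcWorld(
    tpm = list(anch = .hi, mate = .hi, rdrp2 = .hi,
               cell1 = .hi, cell2 = .hi,
               faintAnchor = c(0, 10, 30, 150, 0)),
    lengths = c(anch = 1500, mate = 1200, rdrp2 = 1400, cell1 = 1200,
                cell2 = 1200, faintAnchor = 1500),
    coverage = c(anch = 80, mate = 30, rdrp2 = 70, cell1 = 30,
                 cell2 = 30, faintAnchor = 80),
    cellularIds = c("cell1", "cell2"), cellularIdent = 60)
  cfg <- segConfig()
  qc <- function(cl) {
    cl <- filterMembers(cl, w$abund, w$annotations, w$contigs, cfg)
    applyClusterRules(cl, w$abund, w$contigs, cfg)
  }

  lone <- qc(makeCluster("anch", character(), isRdrp = TRUE))
  expect_equal(qcFlags(lone), "rdrp_only")
  expect_equal(clusterStatus(lone), "removed")

  multi <- qc(makeCluster("anch", c("rdrp2", "mate"),
                          isRdrp = c(TRUE, TRUE, FALSE)))
  expect_equal(qcFlags(multi), "multi_rdrp")

  cellular <- qc(makeCluster("anch", c("cell1", "cell2", "mate")))
  expect_equal(qcFlags(cellular), "cellular")  # 2 of 3 members cellular

  lowab <- qc(makeCluster("faintAnchor", "mate"))
  expect_equal(qcFlags(lowab), "low_abundance")  # anchor max TPM 150 < 200

  lowprev <- qc(makeCluster("anch", "mate", prevalence = 2L))
  expect_equal(qcFlags(lowprev), "low_prevalence")

  clean <- qc(makeCluster("anch", "mate", prevalence = 3L))
  expect_equal(qcFlags(clean), character(0))
  expect_equal(clusterStatus(clean), "retained")
})

test_that("finalize sorts retained clusters and flags shared members", {
  a <- makeCluster("a1", c("m1", "shared"))
  b <- makeCluster("b1", c("m2", "shared"))
  removed <- makeCluster("c1", "m3")
  removed@qcFlags <- "low_prevalence"
  removed@status <- "removed"
  fin <- finalizeClusters(list(b, removed, a))
  expect_equal(vapply(fin, anchorId, character(1)), c("a1", "b1"))
  expect_equal(fin[[1]]@ambiguousMembers, "shared")
  expect_equal(fin[[2]]@ambiguousMembers, "shared")
  expect_equal(length(finalizeClusters(list(removed))), 0L)
})

test_that("the benchmark satellite rides its helper cluster as a retained member", {
  run <- cachedBenchmarkRun()
  b <- cachedBenchmark()
  satId <- b$truth$contig_id[b$truth$entity_type == "satellite"]
  helper <- b$truth$virus_id[b$truth$entity_type == "satellite"]
  inCluster <- vapply(run$retained, function(cl)
    satId %in% cl@members$memberId, logical(1))
  anchors <- vapply(run$retained, anchorId, character(1))
  expect_true(any(inCluster))
  expect_true(startsWith(anchors[which(inCluster)[1]], helper))
})
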