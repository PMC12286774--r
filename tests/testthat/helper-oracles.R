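# Independent oracles and shared fixtures for the test suite.

# Brute-force Spearman for tie-free vectors: 1 - 6*sum(d^2)/(n(n^2-1))
bruteSpearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exhaustive mid-rank Spearman: mid-ranks by pairwise counting, then the
# Pearson formula written out longhand.
midrankSpearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i)
      1 + sum(v < v[i]) + sum(v == v[i] & seq_along(v) != i) / 2,
      numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) NA_real_ else num / den
}

# Simple interval-overlap oracle used against the chimera rule.
overlapLen <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1) + 1)

# Plain-R reverse complement, independent of Biostrings.
rcOracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# A random stop-free coding stretch (frame +1 after `pad` nt).
codingSeq <- function(nCodon, pad = 0) {
  gc <- Biostrings::GENETIC_CODE
  nonstop <- names(gc)[gc != "*"]
  paste0(paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
               collapse = ""),
         paste(sample(nonstop, nCodon, replace = TRUE), collapse = ""))
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

# Heavy fixtures are built once per test run and shared.
.fixtures <- new.env(parent = emptyenv())

cachedBenchmark <- function() {
  if (is.null(.fixtures$bench)) .fixtures$bench <- defaultBenchmark()
  .fixtures$bench
}

cachedBenchmarkRun <- function() {
  if (is.null(.fixtures$benchRun))
    .fixtures$benchRun <- runBundle(cachedBenchmark())
  .fixtures$benchRun
}

# A small bundle (fast): 5 segmented + 2 unsegmented viruses, 30 host
# contigs, 30 libraries.
smallBundle <- function(seed = 7L, nLibraries = 30L, ...) {
  viruses <- c(
    lapply(1:5, function(i)
      virusSpec(sprintf("virus%02d", i), c(2L, 3L, 2L, 4L, 3L)[i],
                prevalence = 0.6)),
    lapply(1:2, function(i)
      virusSpec(sprintf("unseg%02d", i), 1L, prevalence = 0.5)))
  simulateBundle(simulationSpec(viruses, nLibraries = nLibraries,
                                hostContigs = 30L, rngSeed = seed, ...))
}

cachedSmallRun <- function() {
  if (is.null(.fixtures$smallRun)) {
    b <- smallBundle()
    .fixtures$smallBundle <- b
    .fixtures$smallRun <- runBundle(b)
  }
  list(bundle = .fixtures$smallBundle, run = .fixtures$smallRun)
}

# Minimal hand-built cluster for QC rule tests. `tpm` is a named list of
# per-library TPM profiles; all ids must appear in it.
makeQcWorld <- function(tpm, lengths, coverage, cellularIds = character(),
                        cellularIdent = 60) {
  m <- do.call(rbind, tpm)
  colnames(m) <- paste0("L", seq_len(ncol(m)))
  abund <- AbundanceMatrix(m)
  seqs <- vapply(names(lengths), function(id) codingSeq(lengths[[id]] %/% 3),
                 character(1))
  contigs <- ContigSet(Biostrings::DNAStringSet(seqs), library = "L1",
                       coverage = coverage[names(lengths)])
  ann <- if (length(cellularIds)) {
    annotationHits(cellularIds, "cellhit", pident = cellularIdent,
                   length = 200L, qstart = 1L, qend = 200L,
                   evalue = 1e-20, bitscore = 300,
                   category = "cellular_protein")
  } else emptyAnnotationTable("cellular_protein")
  list(abund = abund, contigs = contigs, annotations = ann)
}

makeCluster <- function(anchor, memberIds, rho = 0.9, isRdrp = NULL,
                        prevalence = 5L) {
  ids <- c(anchor, memberIds)
  if (is.null(isRdrp)) isRdrp <- c(TRUE, rep(FALSE, length(memberIds)))
  new("SegmentCluster",
      clusterId = paste0("cl_", anchor), anchorId = anchor,
      rdrpIds = ids[isRdrp],
      members = data.frame(memberId = ids,
                           rho = c(1, rep_len(rho, length(memberIds))),
                           isRdrp = isRdrp, stringsAsFactors = FALSE),
      removedMembers = data.frame(memberId = character(),
                                  reason = character(),
                                  stringsAsFactors = FALSE),
      prevalence = as.integer(prevalence), qcFlags = character(),
      status = "retained", ambiguousMembers = character(),
      terminalSupport = NA_character_)
}
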