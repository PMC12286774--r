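#' @include AllClasses.R
NULL

#' Spearman rank correlation with mid-rank ties
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks
#' (tied values — including tied zeros, which are common in sparse
#' abundance profiles — receive their average rank). Returns `NA` when
#' either vector is constant: an undefined correlation is never treated
#' as perfect co-occurrence.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Rho in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 2L)
    stop("need at least two paired observations")
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx * dx)
  sy <- sum(dy * dy)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sx * sy)
}

## rank each row of a matrix (mid-ranks), plus centered ranks and their
## sums of squares, shared by all anchor comparisons
.rankRows <- function(m) {
  r <- t(apply(m, 1L, rank))
  ctr <- r - rowMeans(r)
  list(ctr = ctr, ss = rowSums(ctr * ctr))
}

#' Correlate every anchor with every other contig
#'
#' For each RdRP anchor, computes the Spearman correlation between the
#' anchor's TPM profile and every other contig's profile across ALL
#' libraries — zeros included, since joint absence is genuine
#' co-occurrence signal. `n_joint_nonzero` (libraries where both
#' profiles are positive) is recorded for diagnostics. Contigs with a
#' constant profile (e.g. all-zero) get `rho = NA`.
#'
#' @param abund An [AbundanceMatrix-class].
#' @param anchors Character vector of anchor contig ids, or a list of
#'   [RdrpCandidate-class] objects.
#' @return data.frame with columns `anchor_id`, `member_id`, `rho`,
#'   `n_libraries`, `n_joint_nonzero`; one row per (anchor, other
#'   contig) pair.
#' @export
buildCorrelationMatrix <- function(abund, anchors) {
  if (is.list(anchors))
    anchors <- vapply(anchors, function(a) a@contigId, character(1))
  m <- tpmMatrix(abund)
  missing <- setdiff(anchors, rownames(m))
  if (length(missing))
    stop("anchor(s) missing from abundance matrix: ",
         paste(head(missing, 3), collapse = ", "))
  rk <- .rankRows(m)
  nLib <- ncol(m)
  out <- vector("list", length(anchors))
  for (i in seq_along(anchors)) {
    a <- anchors[i]
    others <- setdiff(rownames(m), a)
    num <- as.vector(rk$ctr[others, , drop = FALSE] %*% rk$ctr[a, ])
    den <- sqrt(rk$ss[others] * rk$ss[a])
    rho <- ifelse(den > 0, num / den, NA_real_)
    jointNz <- as.vector((m[others, , drop = FALSE] > 0) %*% (m[a, ] > 0))
    out[[i]] <- data.frame(
      anchor_id = a, member_id = others, rho = unname(rho),
      n_libraries = nLib, n_joint_nonzero = as.integer(jointNz),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group correlated contigs into anchor clusters
#'
#' One cluster per anchor: every contig whose rho with the anchor
#' reaches `corrThreshold` (inclusive by default; exclusive available
#' via `inclusiveThreshold = FALSE`) joins. Undefined rho never joins.
#' A contig may appear in multiple clusters — disambiguation is
#' deferred to quality control. Members that are themselves RdRP
#' anchors are tracked in `rdrpIds` (feeding the multi-RdRP rule).
#' Prevalence is the number of libraries where the anchor has TPM > 0.
#'
#' @param corResults Output of [buildCorrelationMatrix()].
#' @param abund The [AbundanceMatrix-class] (for anchor prevalence).
#' @param rdrpIds Character vector of all RdRP contig ids in the run.
#' @param config A [RunConfig-class].
#' @return List of [SegmentCluster-class], ordered by anchor id.
#' @export
formClusters <- function(corResults, abund, rdrpIds = character(),
                         config = segConfig()) {
  m <- tpmMatrix(abund)
  anchors <- sort(unique(corResults$anchor_id))
  lapply(anchors, function(a) {
    sub <- corResults[corResults$anchor_id == a & !is.na(corResults$rho), ,
                      drop = FALSE]
    hit <- if (config@inclusiveThreshold)
      sub$rho >= config@corrThreshold
    else sub$rho > config@corrThreshold
    sub <- sub[hit, , drop = FALSE]
    sub <- sub[order(sub$member_id), , drop = FALSE]
    members <- data.frame(
      memberId = c(a, sub$member_id),
      rho = c(1, sub$rho),
      isRdrp = c(TRUE, sub$member_id %in% rdrpIds),
      stringsAsFactors = FALSE)
    new("SegmentCluster",
        clusterId = paste0("cl_", a),
        anchorId = a,
        rdrpIds = members$memberId[members$isRdrp],
        members = members,
        removedMembers = data.frame(memberId = character(),
                                    reason = character(),
                                    stringsAsFactors = FALSE),
        prevalence = as.integer(sum(m[a, ] > 0)),
        qcFlags = character(),
        status = "retained",
        ambiguousMembers = character(),
        terminalSupport = NA_character_)
  })
}

#' Score clusters against a ground-truth manifest
#'
#' A member assignment is each (anchor, non-anchor member) pair across
#' the clusters; it is false when the member's true virus differs from
#' the anchor's (host and noise contigs are always false; a satellite
#' carries its helper virus's id, so joining the helper's cluster is
#' correct). Completeness is the fraction of planted segmented-virus
#' segments found in their own virus's cluster.
#'
#' @param clusters List of [SegmentCluster-class].
#' @param truth Ground-truth data.frame (see [simulateBundle()]), with
#'   columns `contig_id`, `entity_type`, `virus_id`, `segment_index`.
#' @return List: `fdr`, `completeness`, `n_assignments`, `n_false`,
#'   `n_true_segments`, `n_recovered`.
#' @export
evaluateClusters <- function(clusters, truth) {
  virusOf <- stats::setNames(truth$virus_id, truth$contig_id)
  typeOf <- stats::setNames(truth$entity_type, truth$contig_id)
  nAssign <- 0L
  nFalse <- 0L
  segIds <- truth$contig_id[truth$entity_type == "segmented_virus_segment"]
  recovered <- character()
  for (cl in clusters) {
    av <- virusOf[cl@anchorId]
    mem <- setdiff(cl@members$memberId, cl@anchorId)
    nAssign <- nAssign + length(mem)
    mv <- virusOf[mem]
    mt <- typeOf[mem]
    bad <- is.na(mv) | mv == "" | mv != av |
      mt %in% c("host", "noise")
    nFalse <- nFalse + sum(bad)
    ok <- cl@members$memberId[
      virusOf[cl@members$memberId] == av &
        typeOf[cl@members$memberId] == "segmented_virus_segment"]
    recovered <- union(recovered, ok[!is.na(ok)])
  }
  list(fdr = if (nAssign > 0) nFalse / nAssign else 0,
       completeness = if (length(segIds) > 0)
         length(intersect(recovered, segIds)) / length(segIds) else NA,
       n_assignments = nAssign,
       n_false = nFalse,
       n_true_segments = length(segIds),
       n_recovered = length(intersect(recovered, segIds)))
}

#' Sweep coverage and correlation thresholds against ground truth
#'
#' Re-forms clusters over a grid of (anchor coverage threshold, rho
#' threshold) combinations and scores each grid point against the
#' manifest: the false discovery rate over member assignments and the
#' completeness of planted segments. Anchors failing any non-coverage
#' screen are excluded throughout; the coverage screen is re-applied per
#' grid point. Deterministic given inputs.
#'
#' @param abund An [AbundanceMatrix-class].
#' @param candidates List of [RdrpCandidate-class] from the anchor
#'   screen (coverage verdicts are ignored here and re-derived per grid
#'   point).
#' @param truth Ground-truth data.frame.
#' @param covGrid Numeric vector of anchor coverage thresholds.
#' @param rhoGrid Numeric vector of correlation thresholds.
#' @param config A [RunConfig-class] (non-swept settings).
#' @return data.frame with columns `cov`, `rho`, `fdr`, `completeness`,
#'   `n_anchors`, `n_assignments`.
#' @export
sweepThresholds <- function(abund, candidates, truth, covGrid, rhoGrid,
                            config = segConfig()) {
  if (length(covGrid) == 0L || length(rhoGrid) == 0L)
    stop("threshold grids must be non-empty")
  nonCov <- vapply(candidates, function(cd)
    length(setdiff(cd@failReasons, "coverage")) == 0L, logical(1))
  candidates <- candidates[nonCov]
  ids <- vapply(candidates, function(cd) cd@contigId, character(1))
  covs <- vapply(candidates, function(cd) cd@coverage, numeric(1))
  ids <- ids[ids %in% rownames(tpmMatrix(abund))]
  covs <- covs[match(ids, vapply(candidates, function(cd) cd@contigId,
                                 character(1)))]
  corAll <- if (length(ids)) buildCorrelationMatrix(abund, ids) else NULL
  grid <- expand.grid(cov = sort(covGrid), rho = sort(rhoGrid),
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cv <- grid$cov[i]
    keep <- !is.na(covs) & covs >= cv
    anchorIds <- ids[keep]
    if (length(anchorIds) == 0L || is.null(corAll)) {
      ev <- list(fdr = 0, completeness = 0, n_assignments = 0L)
    } else {
      cfg <- config
      cfg@corrThreshold <- grid$rho[i]
      cls <- formClusters(
        corAll[corAll$anchor_id %in% anchorIds, , drop = FALSE],
        abund, rdrpIds = ids, config = cfg)
      ev <- evaluateClusters(cls, truth)
    }
    data.frame(cov = cv, rho = grid$rho[i], fdr = ev$fdr,
               completeness = ev$completeness,
               n_anchors = length(anchorIds),
               n_assignments = ev$n_assignments)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
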