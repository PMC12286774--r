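#' @include AllClasses.R
NULL

#' Per-member quality filters within a cluster
#'
#' Removes non-anchor members that are implausible as genome segments,
#' each with exactly one primary reason (checked in this order):
#' \describe{
#'   \item{cellular_member}{best cellular-protein hit above
#'     `cellularIdentityMax` percent amino-acid identity (default 30)
#'     whose bitscore also exceeds every viral-protein hit for that
#'     contig — a viral protein with weak cellular similarity is kept.}
#'   \item{short}{length below `minContigLen` (default 600 nt).}
#'   \item{low_tpm}{maximum TPM across libraries below `tpmMin`
#'     (default 200).}
#'   \item{low_coverage}{assembler coverage below `segmentCoverageMin`
#'     (default 10; exactly 10 is kept) or missing.}
#' }
#'
#' @param cluster A [SegmentCluster-class] from [formClusters()].
#' @param abund An [AbundanceMatrix-class].
#' @param annotations Annotation table holding `cellular_protein` (and
#'   optionally `viral_protein`) rows.
#' @param contigs A [ContigSet-class] (lengths and coverage).
#' @param config A [RunConfig-class].
#' @return The cluster with failing members moved from `members` to
#'   `removedMembers`.
#' @export
filterMembers <- function(cluster, abund, annotations, contigs,
                          config = segConfig()) {
  m <- tpmMatrix(abund)
  lens <- contigLengths(contigs)
  covs <- contigCoverage(contigs)
  cell <- annotations[annotations$category == "cellular_protein", ,
                      drop = FALSE]
  viral <- annotations[annotations$category == "viral_protein", ,
                       drop = FALSE]
  mem <- cluster@members
  keep <- rep(TRUE, nrow(mem))
  reasons <- character(nrow(mem))
  for (i in seq_len(nrow(mem))) {
    id <- mem$memberId[i]
    if (id == cluster@anchorId) next
    ch <- cell[cell$query_id == id, , drop = FALSE]
    bestCell <- if (nrow(ch)) max(ch$bitscore) else -Inf
    bestCellIdent <- if (nrow(ch)) ch$pident[which.max(ch$bitscore)] else NA
    vh <- viral[viral$query_id == id, , drop = FALSE]
    bestViral <- if (nrow(vh)) max(vh$bitscore) else -Inf
    reason <- if (nrow(ch) && bestCellIdent > config@cellularIdentityMax &&
                    bestCell > bestViral) {
      "cellular_member"
    } else if (!is.na(lens[id]) && lens[id] < config@minContigLen) {
      "short"
    } else if (id %in% rownames(m) && max(m[id, ]) < config@tpmMin) {
      "low_tpm"
    } else if (is.na(covs[id]) || covs[id] < config@segmentCoverageMin) {
      "low_coverage"
    } else {
      ""
    }
    if (nzchar(reason)) {
      keep[i] <- FALSE
      reasons[i] <- reason
    }
  }
  cluster@removedMembers <- rbind(
    cluster@removedMembers,
    data.frame(memberId = mem$memberId[!keep], reason = reasons[!keep],
               stringsAsFactors = FALSE))
  cluster@members <- mem[keep, , drop = FALSE]
  cluster@rdrpIds <- cluster@members$memberId[cluster@members$isRdrp]
  cluster
}

#' Cluster-level removal rules
#'
#' Applies the five cluster-removal rules and sets `qcFlags`/`status`:
#' \describe{
#'   \item{rdrp_only}{no non-RdRP member survived member filtering — a
#'     lone RdRP is not evidence of segmentation.}
#'   \item{multi_rdrp}{more RdRP contigs than `maxRdrpPerCluster`
#'     (default 1): the cluster mixes more than one virus.}
#'   \item{cellular}{more than half of the cluster's original non-anchor
#'     members were removed as cellular genes — the cluster primarily
#'     comprises non-viral sequence.}
#'   \item{low_abundance}{the anchor itself fails the abundance screen
#'     (coverage below `rdrpCoverageMin` or maximum TPM below `tpmMin`)
#'     — re-checked here because dereplication pooling can change the
#'     anchor's profile after the initial screen.}
#'   \item{low_prevalence}{the anchor is detected in fewer than
#'     `minPrevalence` libraries (default 3): too little data for the
#'     correlation to be trustworthy.}
#' }
#'
#' @param cluster A [SegmentCluster-class] after [filterMembers()].
#' @param abund An [AbundanceMatrix-class] (anchor TPM).
#' @param contigs Optional [ContigSet-class] (anchor coverage); when
#'   `NULL` the coverage part of `low_abundance` is skipped.
#' @param config A [RunConfig-class].
#' @return The cluster with `qcFlags` set and `status` updated
#'   (`"removed"` iff any flag is set).
#' @export
applyClusterRules <- function(cluster, abund, contigs = NULL,
                              config = segConfig()) {
  flags <- character()
  mem <- cluster@members
  nonAnchor <- setdiff(mem$memberId, cluster@anchorId)
  if (length(nonAnchor) == 0L ||
        all(mem$isRdrp[mem$memberId %in% nonAnchor]))
    flags <- c(flags, "rdrp_only")
  if (sum(mem$isRdrp) > config@maxRdrpPerCluster)
    flags <- c(flags, "multi_rdrp")
  origNonAnchor <- length(nonAnchor) +
    sum(cluster@removedMembers$memberId != cluster@anchorId)
  nCellular <- sum(cluster@removedMembers$reason == "cellular_member")
  if (origNonAnchor > 0L && nCellular / origNonAnchor > 0.5)
    flags <- c(flags, "cellular")
  m <- tpmMatrix(abund)
  anchorLow <- cluster@anchorId %in% rownames(m) &&
    max(m[cluster@anchorId, ]) < config@tpmMin
  if (!is.null(contigs)) {
    cov <- contigCoverage(contigs)[cluster@anchorId]
    if (is.na(cov) || cov < config@rdrpCoverageMin) anchorLow <- TRUE
  }
  if (anchorLow) flags <- c(flags, "low_abundance")
  if (cluster@prevalence < config@minPrevalence)
    flags <- c(flags, "low_prevalence")
  cluster@qcFlags <- flags
  cluster@status <- if (length(flags)) "removed" else "retained"
  cluster
}

#' Quality-control report for a cluster
#'
#' @param cluster A [SegmentCluster-class] after [applyClusterRules()].
#' @return List with `cluster_id`, a named logical `rule_verdicts`
#'   vector over the five rules (`TRUE` = rule fired), and the
#'   `removed_members` data.frame with per-member reasons.
#' @export
qcReport <- function(cluster) {
  rules <- c("cellular", "rdrp_only", "multi_rdrp",
             "low_abundance", "low_prevalence")
  list(cluster_id = cluster@clusterId,
       rule_verdicts = stats::setNames(rules %in% cluster@qcFlags, rules),
       removed_members = cluster@removedMembers)
}

#' Finalize clusters: retain, order, flag ambiguity
#'
#' Keeps clusters whose status is `"retained"`, sorts them by anchor id
#' for deterministic output, and flags (without removing) members that
#' are retained in more than one cluster.
#'
#' @param clusters List of [SegmentCluster-class] after
#'   [applyClusterRules()].
#' @return List of retained [SegmentCluster-class] objects.
#' @export
finalizeClusters <- function(clusters) {
  retained <- Filter(function(cl) cl@status == "retained", clusters)
  retained <- retained[order(vapply(retained, anchorId, character(1)))]
  if (length(retained) > 1L) {
    all <- unlist(lapply(retained, function(cl) cl@members$memberId))
    dup <- unique(all[duplicated(all)])
    retained <- lapply(retained, function(cl) {
      cl@ambiguousMembers <- intersect(cl@members$memberId, dup)
      cl
    })
  }
  retained
}

#' Run member filters and cluster rules over a cluster list
#'
#' @param clusters List of [SegmentCluster-class] from [formClusters()].
#' @param abund An [AbundanceMatrix-class].
#' @param annotations Annotation table (cellular/viral protein rows).
#' @param contigs A [ContigSet-class].
#' @param config A [RunConfig-class].
#' @return List of all clusters with QC applied (retained and removed);
#'   pass through [finalizeClusters()] for the retained set.
#' @export
qcClusters <- function(clusters, abund, annotations, contigs,
                       config = segConfig()) {
  lapply(clusters, function(cl) {
    cl <- filterMembers(cl, abund, annotations, contigs, config)
    applyClusterRules(cl, abund, contigs, config)
  })
}
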