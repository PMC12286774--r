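#' @include AllClasses.R rdrp.R abundance.R cooccurrence.R qc.R motifs.R
NULL

#' Run the full segment-discovery pipeline
#'
#' Chains every stage: RdRP anchor screening (candidacy by homology,
#' chimera flagging, coverage/length/ORF filters), abundance matrix
#' construction (length + coding filter, k-mer dereplication with count
#' pooling, TPM), anchor-versus-all Spearman correlation, cluster
#' formation, quality control, and terminal-motif verification.
#' Verification attaches evidence only; it never removes a cluster.
#'
#' @param contigs A [ContigSet-class] covering all libraries.
#' @param counts Contigs-by-libraries count matrix (e.g. from
#'   [readCountTable()]). Row names must match contig ids. If the
#'   matrix already holds TPM values set `countsAreTpm = TRUE` to skip
#'   renormalization (recorded in the manifest).
#' @param annotations List with annotation data.frames `viral`,
#'   `cellular`, `rdrp`, `nonviral` (see [readAnnotationTable()]).
#' @param config A [RunConfig-class].
#' @param countsAreTpm Counts are already TPM; dereplication pooling is
#'   still applied, then columns are renormalized.
#' @param outDir Optional directory: writes `clusters.tsv` (+ config
#'   sidecar) and `run_manifest.json`.
#' @return List with `candidates` (all [RdrpCandidate-class]),
#'   `anchors` (passing anchors), `abundance`
#'   ([AbundanceMatrix-class]), `correlations`, `clusters` (all, with
#'   QC), `retained` (finalized retained clusters, motif-verified),
#'   `motifs` (combined motif table), `derep`, and `manifest`.
#' @export
runAll <- function(contigs, counts, annotations,
                   config = segConfig(), countsAreTpm = FALSE,
                   outDir = NULL) {
  stopifnot(is(contigs, "ContigSet"), is.matrix(counts))
  nrHits <- rbind(annotations$viral, annotations$cellular)
  candidates <- screenRdrp(contigs, nrHits, annotations$rdrp,
                           annotations$nonviral, config)
  anchors <- Filter(passes, candidates)
  if (!config@removeChimeric) {
    chimOnly <- Filter(function(cd)
      identical(cd@failReasons, "chimeric"), candidates)
    anchors <- c(anchors, chimOnly)
  }

  kept <- filterContigs(contigs, config)
  derep <- dereplicate(kept, identity = config@derepIdentity,
                       k = config@derepK)
  counts <- counts[intersect(rownames(counts), contigIds(kept)), ,
                   drop = FALSE]
  abund <- assembleMatrix(counts, contigLengths(kept), derep)
  if (countsAreTpm) {
    ## keep the caller's scale: renormalize pooled columns back to 1e6
    m <- tpmMatrix(abund)
    abund <- AbundanceMatrix(m, lengths = contigLengths(kept))
  }

  anchorIds <- vapply(anchors, function(a) a@contigId, character(1))
  anchorIds <- intersect(anchorIds, rownames(tpmMatrix(abund)))
  rdrpIds <- unique(annotations$rdrp$query_id)
  if (length(anchorIds) == 0L) {
    correlations <- NULL
    clusters <- list()
    retained <- list()
  } else {
    correlations <- buildCorrelationMatrix(abund, anchorIds)
    clusters <- formClusters(correlations, abund, rdrpIds = rdrpIds,
                             config = config)
    clusters <- qcClusters(clusters, abund, nrHits, contigs, config)
    retained <- finalizeClusters(clusters)
  }

  motifs <- list()
  retained <- lapply(retained, function(cl) {
    hits <- findClusterMotifs(cl, contigs, config)
    if (nrow(hits)) motifs[[cl@clusterId]] <<- hits
    verifyCluster(cl, hits, minFraction = config@motifMinFraction,
                  minSupportLen = config@motifMinSupportLen)
  })
  motifTable <- if (length(motifs)) do.call(rbind, unname(motifs))
  else NULL

  manifest <- list(
    tool = "virseg",
    version = as.character(utils::packageVersion("virseg")),
    seed = config@rngSeed,
    config = configAsList(config),
    counts_were_tpm = countsAreTpm,
    n_contigs_in = length(contigs),
    n_contigs_after_filter = length(kept),
    n_representatives = length(derep$representatives),
    n_candidates = length(candidates),
    n_anchors = length(anchorIds),
    n_clusters = length(clusters),
    n_retained = length(retained),
    retained_note = if (length(retained) == 0L)
      "no segmented viruses retained" else NULL)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeClusterReport(c(retained,
                         Filter(function(cl) cl@status == "removed",
                                clusters)),
                       file.path(outDir, "clusters.tsv"),
                       abund = abund, config = config)
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(candidates = candidates, anchors = anchors, abundance = abund,
       correlations = correlations, clusters = clusters,
       retained = retained, motifs = motifTable, derep = derep,
       manifest = manifest)
}

#' Run the pipeline on a simulated or on-disk bundle
#'
#' @param bundle A [simulateBundle()] result or a directory written by
#'   [writeBundle()].
#' @param config A [RunConfig-class].
#' @param outDir Optional output directory (see [runAll()]).
#' @return As [runAll()], plus `truth` and `evaluation`
#'   (see [evaluateClusters()]) when ground truth is available.
#' @export
runBundle <- function(bundle, config = segConfig(), outDir = NULL) {
  if (is.character(bundle)) bundle <- readBundle(bundle)
  res <- runAll(bundle$contigs, bundle$counts, bundle$annotations,
                config = config, outDir = outDir)
  if (!is.null(bundle$truth)) {
    res$truth <- bundle$truth
    res$evaluation <- evaluateClusters(res$retained, bundle$truth)
  }
  res
}
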