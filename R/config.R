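#' @include AllClasses.R
NULL

#' Build a run configuration
#'
#' Returns a [RunConfig-class] pinned by default to the published
#' operating point of the co-occurrence pipeline; any field can be
#' overridden. Thresholds are validated on construction so an invalid
#' setting (e.g. a correlation threshold outside (0, 1]) fails before
#' any compute.
#'
#' @param corrThreshold Spearman correlation required for a contig to
#'   join an anchor's cluster. Default 0.8.
#' @param inclusiveThreshold If `TRUE` (default) a contig joins at
#'   `rho >= corrThreshold`; if `FALSE` strictly greater is required.
#' @param rdrpCoverageMin Minimum assembler coverage for an RdRP anchor.
#'   Default 50.
#' @param segmentCoverageMin Minimum assembler coverage for non-anchor
#'   cluster members. Default 10.
#' @param minContigLen Minimum contig length in nt. Default 600.
#' @param tpmMin Minimum (maximum-across-libraries) TPM for a cluster
#'   member. Default 200.
#' @param minPrevalence Minimum number of libraries in which the anchor
#'   must be detected (TPM > 0). Default 3.
#' @param cellularIdentityMax Amino-acid percent identity to cellular
#'   proteins above which a member is treated as a cellular gene.
#'   Default 30.
#' @param maxRdrpPerCluster Maximum RdRP contigs a retained cluster may
#'   contain. Default 1.
#' @param evalueNr,evalueRdrp,evalueNt E-value cutoffs for the protein
#'   reference, RdRP database and virus-free nucleotide searches
#'   (defaults 1e-4, 1e-5, 1e-10).
#' @param derepIdentity K-mer containment threshold for dereplication.
#'   Default 0.8.
#' @param derepK K-mer size used by the containment surrogate. Default 10.
#' @param minOrfAa Minimum ORF length in amino acids. Default 30.
#' @param chimeraMinLen Minimum length (nt) of a virus-free nucleotide
#'   hit outside the RdRP region for a contig to be called chimeric.
#'   Default 100.
#' @param chimeraMaxOverlap A hit overlapping the RdRP region by at
#'   least this fraction of its own length is not counted as outside it.
#'   Default 0.5.
#' @param removeChimeric Remove chimeric anchors (`TRUE`, default) or
#'   only record the flagged regions.
#' @param terminalWindow Length (nt) of the 5'/3' windows searched for
#'   conserved terminal motifs. Default 50.
#' @param motifKmin,motifKmax Motif length range searched (defaults
#'   6 and 15).
#' @param motifMinFraction Fraction of a cluster's segments that must
#'   share a motif. Default 0.8.
#' @param motifMinSupportLen Minimum motif length counted as
#'   homology-independent support. Default 8.
#' @param motifMaxMismatch Substitutions tolerated when matching a motif
#'   within a terminal window (0 = exact, default).
#' @param rngSeed Seed recorded in reports for reproducibility.
#' @return A validated [RunConfig-class] object.
#' @examples
#' cfg <- segConfig(corrThreshold = 0.9)
#' cfg@corrThreshold
#' @export
segConfig <- function(corrThreshold = 0.8,
                      inclusiveThreshold = TRUE,
                      rdrpCoverageMin = 50,
                      segmentCoverageMin = 10,
                      minContigLen = 600L,
                      tpmMin = 200,
                      minPrevalence = 3L,
                      cellularIdentityMax = 30,
                      maxRdrpPerCluster = 1L,
                      evalueNr = 1e-4,
                      evalueRdrp = 1e-5,
                      evalueNt = 1e-10,
                      derepIdentity = 0.8,
                      derepK = 10L,
                      minOrfAa = 30L,
                      chimeraMinLen = 100L,
                      chimeraMaxOverlap = 0.5,
                      removeChimeric = TRUE,
                      terminalWindow = 50L,
                      motifKmin = 6L,
                      motifKmax = 15L,
                      motifMinFraction = 0.8,
                      motifMinSupportLen = 8L,
                      motifMaxMismatch = 0L,
                      rngSeed = 1L) {
  new("RunConfig",
      corrThreshold = as.numeric(corrThreshold),
      inclusiveThreshold = isTRUE(inclusiveThreshold),
      rdrpCoverageMin = as.numeric(rdrpCoverageMin),
      segmentCoverageMin = as.numeric(segmentCoverageMin),
      minContigLen = as.integer(minContigLen),
      tpmMin = as.numeric(tpmMin),
      minPrevalence = as.integer(minPrevalence),
      cellularIdentityMax = as.numeric(cellularIdentityMax),
      maxRdrpPerCluster = as.integer(maxRdrpPerCluster),
      evalueNr = as.numeric(evalueNr),
      evalueRdrp = as.numeric(evalueRdrp),
      evalueNt = as.numeric(evalueNt),
      derepIdentity = as.numeric(derepIdentity),
      derepK = as.integer(derepK),
      minOrfAa = as.integer(minOrfAa),
      chimeraMinLen = as.integer(chimeraMinLen),
      chimeraMaxOverlap = as.numeric(chimeraMaxOverlap),
      removeChimeric = isTRUE(removeChimeric),
      terminalWindow = as.integer(terminalWindow),
      motifKmin = as.integer(motifKmin),
      motifKmax = as.integer(motifKmax),
      motifMinFraction = as.numeric(motifMinFraction),
      motifMinSupportLen = as.integer(motifMinSupportLen),
      motifMaxMismatch = as.integer(motifMaxMismatch),
      rngSeed = as.integer(rngSeed))
}

#' Serialize a RunConfig to a plain list
#'
#' Used to echo the full configuration into JSON sidecars and run
#' manifests so every result is parameter-attributable.
#'
#' @param config A [RunConfig-class].
#' @return A named list of all configuration fields.
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "RunConfig"))
  nms <- slotNames("RunConfig")
  stats::setNames(lapply(nms, function(s) slot(config, s)), nms)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig (co-occurrence segment discovery)\n")
  cat(sprintf("  rho >= %g (%s), RdRP cov >= %g, segment cov >= %g\n",
              object@corrThreshold,
              if (object@inclusiveThreshold) "inclusive" else "exclusive",
              object@rdrpCoverageMin, object@segmentCoverageMin))
  cat(sprintf("  length >= %d nt, TPM >= %g, prevalence >= %d libraries\n",
              object@minContigLen, object@tpmMin, object@minPrevalence))
  cat(sprintf("  e-values: nr %g, rdrp %g, nt %g; derep %g (k=%d); ORF >= %d aa\n",
              object@evalueNr, object@evalueRdrp, object@evalueNt,
              object@derepIdentity, object@derepK, object@minOrfAa))
})
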