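#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet width
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Contig container for multi-library assemblies
#'
#' A `ContigSet` holds assembled contigs from one or more sequencing
#' libraries: the nucleotide sequences, the library each contig was
#' assembled in, and the assembler's own coverage estimate (the megahit
#' `multi=` or SPAdes `_cov_` value) when available. Contig ids are
#' namespaced as `"<library>::<original id>"` so they are unique across
#' an entire multi-library run.
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by contig id.
#' @slot library Character vector, one library id per contig.
#' @slot coverage Numeric vector of assembler coverage values; `NA` when
#'   the assembler header carried no coverage token and no coverage table
#'   was supplied (missing coverage is distinct from zero coverage).
#'
#' @seealso [readContigs()], [filterContigs()]
#' @export
setClass("ContigSet",
  representation(
    sequences = "DNAStringSet",
    library   = "character",
    coverage  = "numeric"
  )
)

setValidity("ContigSet", function(object) {
  n <- length(object@sequences)
  ids <- names(object@sequences)
  msg <- character()
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all contigs must be named")
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate contig id: ",
                         ids[duplicated(ids)][1L]))
  if (length(object@library) != n)
    msg <- c(msg, "library must have one entry per contig")
  if (length(object@coverage) != n)
    msg <- c(msg, "coverage must have one entry per contig")
  if (any(object@coverage < 0, na.rm = TRUE))
    msg <- c(msg, "coverage must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a ContigSet
#'
#' @param sequences A [Biostrings::DNAStringSet] (or character vector)
#'   named by contig id.
#' @param library Library id(s); recycled to the number of contigs.
#' @param coverage Assembler coverage per contig (`NA` = unknown).
#' @return A [ContigSet-class] object.
#' @examples
#' cs <- ContigSet(c(c1 = "ACGTACGT"), library = "L1", coverage = 12.5)
#' contigLengths(cs)
#' @export
ContigSet <- function(sequences, library = "lib1",
                      coverage = rep(NA_real_, length(sequences))) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(sequences)
  n <- length(sequences)
  new("ContigSet",
      sequences = sequences,
      library   = rep_len(as.character(library), n),
      coverage  = rep_len(as.numeric(coverage), n))
}

#' Abundance matrix of contigs by libraries (TPM)
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' contigs-by-libraries TPM matrix that the co-occurrence step correlates.
#' Rows are (dereplicated) contigs, columns are libraries, the single
#' assay `"tpm"` holds transcripts-per-million values. Absent
#' contig/library combinations are encoded as 0, never `NA`: joint
#' absence across libraries is genuine co-occurrence signal.
#'
#' @seealso [computeTpm()], [assembleMatrix()], [tpmMatrix()]
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    return("must carry a 'tpm' assay")
  m <- assay(object, "tpm")
  if (anyNA(m)) return("TPM values must not be missing (absence is 0)")
  if (any(m < 0)) return("TPM values must be non-negative")
  TRUE
})

#' Construct an AbundanceMatrix from a TPM matrix
#'
#' @param tpm Numeric matrix (contigs x libraries) with dimnames.
#' @param lengths Optional named vector of contig lengths (nt), stored in
#'   `rowData`.
#' @return An [AbundanceMatrix-class].
#' @export
AbundanceMatrix <- function(tpm, lengths = NULL) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  rd <- if (!is.null(lengths)) {
    DataFrame(length_nt = as.integer(lengths[rownames(tpm)]),
              row.names = rownames(tpm))
  } else {
    DataFrame(row.names = rownames(tpm))
  }
  new("AbundanceMatrix",
      SummarizedExperiment(assays = list(tpm = tpm), rowData = rd))
}

#' Run configuration: every threshold of the pipeline
#'
#' One object carries every tunable of the discovery pipeline, pinned by
#' default to the published operating point: correlation threshold 0.8,
#' RdRP anchor coverage 50 (10 for other segments), minimum contig length
#' 600 nt, TPM threshold 200, anchor prevalence in at least 3 libraries,
#' 30% amino-acid identity ceiling for cellular genes, homology-search
#' e-value cutoffs 1e-4 (protein reference), 1e-5 (RdRP database) and
#' 1e-10 (virus-free nucleotide database), dereplication identity 0.8 and
#' a 30-aa minimum ORF.
#'
#' @seealso [segConfig()]
#' @export
setClass("RunConfig",
  representation(
    corrThreshold      = "numeric",
    inclusiveThreshold = "logical",
    rdrpCoverageMin    = "numeric",
    segmentCoverageMin = "numeric",
    minContigLen       = "integer",
    tpmMin             = "numeric",
    minPrevalence      = "integer",
    cellularIdentityMax = "numeric",
    maxRdrpPerCluster  = "integer",
    evalueNr           = "numeric",
    evalueRdrp         = "numeric",
    evalueNt           = "numeric",
    derepIdentity      = "numeric",
    derepK             = "integer",
    minOrfAa           = "integer",
    chimeraMinLen      = "integer",
    chimeraMaxOverlap  = "numeric",
    removeChimeric     = "logical",
    terminalWindow     = "integer",
    motifKmin          = "integer",
    motifKmax          = "integer",
    motifMinFraction   = "numeric",
    motifMinSupportLen = "integer",
    motifMaxMismatch   = "integer",
    rngSeed            = "integer"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) m else character()
  msg <- c(msg,
    chk(object@corrThreshold > 0 && object@corrThreshold <= 1,
        "corrThreshold must be in (0, 1]"),
    chk(object@rdrpCoverageMin >= 0, "rdrpCoverageMin must be >= 0"),
    chk(object@segmentCoverageMin >= 0, "segmentCoverageMin must be >= 0"),
    chk(object@minContigLen >= 1L, "minContigLen must be >= 1"),
    chk(object@tpmMin >= 0, "tpmMin must be >= 0"),
    chk(object@minPrevalence >= 1L, "minPrevalence must be >= 1"),
    chk(object@cellularIdentityMax >= 0 && object@cellularIdentityMax <= 100,
        "cellularIdentityMax must be in [0, 100]"),
    chk(object@maxRdrpPerCluster >= 1L, "maxRdrpPerCluster must be >= 1"),
    chk(all(c(object@evalueNr, object@evalueRdrp, object@evalueNt) >= 0),
        "e-value cutoffs must be >= 0"),
    chk(object@derepIdentity > 0 && object@derepIdentity <= 1,
        "derepIdentity must be in (0, 1]"),
    chk(object@minOrfAa >= 1L, "minOrfAa must be >= 1"),
    chk(object@motifKmin >= 1L && object@motifKmax >= object@motifKmin,
        "motif k range must satisfy 1 <= kmin <= kmax"),
    chk(object@motifMinFraction > 0 && object@motifMinFraction <= 1,
        "motifMinFraction must be in (0, 1]"),
    chk(object@terminalWindow >= object@motifKmax,
        "terminalWindow must be >= motifKmax"))
  if (length(msg)) msg else TRUE
})

#' An RdRP anchor candidate and its screening verdict
#'
#' Produced by [flagRdrpContigs()] and refined by [flagChimeras()] and
#' [applyAnchorFilters()]. Candidates that fail a screen are retained
#' with their `failReasons` rather than dropped, so the screen is
#' auditable; `passes()` is `TRUE` iff `failReasons` is empty.
#'
#' @slot contigId,libraryId Contig identity.
#' @slot lengthNt Contig length (nt).
#' @slot coverage Assembler coverage (`NA` = missing).
#' @slot bestRdrpHit One-row data.frame: the lowest-e-value RdRP hit
#'   (ties broken by higher bitscore, then subject id).
#' @slot rdrpRegion Integer `(qstart, qend)` of that hit on the contig.
#' @slot nonviralRegions Two-column integer matrix of virus-free
#'   nucleotide hit regions flagged as potential chimera joints.
#' @slot orfs data.frame of ORF calls (see [scanOrfs()]).
#' @slot failReasons Subset of
#'   `c("evalue", "coverage", "orf", "chimeric", "length")`.
#' @export
setClass("RdrpCandidate",
  representation(
    contigId        = "character",
    libraryId       = "character",
    lengthNt        = "integer",
    coverage        = "numeric",
    bestRdrpHit     = "data.frame",
    rdrpRegion      = "integer",
    nonviralRegions = "matrix",
    orfs            = "data.frame",
    failReasons     = "character"
  )
)

#' One RdRP-anchored co-occurrence cluster
#'
#' A cluster is one RdRP anchor contig plus every contig whose TPM
#' profile across libraries correlates with the anchor at or above the
#' run's Spearman threshold. Quality control attaches removal flags;
#' `status` is `"removed"` iff any flag is set. Terminal-motif
#' verification attaches evidence but never removes a cluster.
#'
#' @slot clusterId Cluster identifier (derived from the anchor id).
#' @slot anchorId The anchor RdRP contig id.
#' @slot rdrpIds All RdRP contigs in the cluster (anchor included).
#' @slot members data.frame with columns `memberId`, `rho`, `isRdrp`
#'   (the anchor appears with `rho = 1`).
#' @slot removedMembers data.frame `memberId`, `reason` filled by QC
#'   (reasons: `short`, `low_tpm`, `low_coverage`, `cellular_member`).
#' @slot prevalence Number of libraries where the anchor has TPM > 0.
#' @slot qcFlags Subset of `c("cellular", "rdrp_only", "multi_rdrp",
#'   "low_abundance", "low_prevalence")`.
#' @slot status `"retained"` or `"removed"`.
#' @slot ambiguousMembers Members retained in more than one cluster.
#' @slot terminalSupport `"homology_independent_support"`,
#'   `"no_terminal_support"`, or `NA` before verification.
#' @export
setClass("SegmentCluster",
  representation(
    clusterId        = "character",
    anchorId         = "character",
    rdrpIds          = "character",
    members          = "data.frame",
    removedMembers   = "data.frame",
    prevalence       = "integer",
    qcFlags          = "character",
    status           = "character",
    ambiguousMembers = "character",
    terminalSupport  = "character"
  )
)

setValidity("SegmentCluster", function(object) {
  msg <- character()
  if (!object@status %in% c("retained", "removed"))
    msg <- c(msg, "status must be 'retained' or 'removed'")
  if ((length(object@qcFlags) > 0L) != (object@status == "removed"))
    msg <- c(msg, "status must be 'removed' iff qcFlags is non-empty")
  if (!object@anchorId %in% object@members$memberId)
    msg <- c(msg, "anchor must be among members")
  if (length(msg)) msg else TRUE
})
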