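#' @include AllClasses.R orf.R
NULL

.noRegions <- function() {
  matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

#' Flag RdRP anchor candidates from annotation tables
#'
#' A contig becomes an anchor candidate iff it carries a viral-protein
#' hit from the protein-reference search at `evalue <= evalueNr` (1e-4
#' by default) AND an RdRP-database hit at `evalue <= evalueRdrp` (1e-5
#' by default). The best RdRP hit (lowest e-value; ties broken by higher
#' bitscore, then lexicographic subject id) defines the RdRP region used
#' downstream for chimera detection. Contigs with no qualifying hits are
#' simply not candidates.
#'
#' @param contigs A [ContigSet-class].
#' @param nrHits Annotation table from the protein-reference search;
#'   rows with `category == "viral_protein"` are considered.
#' @param rdrpHits Annotation table from the RdRP-database search
#'   (`category == "rdrp"`).
#' @param config A [RunConfig-class].
#' @return List of [RdrpCandidate-class], one per qualifying contig, in
#'   contig-id order.
#' @export
flagRdrpContigs <- function(contigs, nrHits, rdrpHits,
                            config = segConfig()) {
  viral <- nrHits[nrHits$category == "viral_protein" &
                    nrHits$evalue <= config@evalueNr, , drop = FALSE]
  rdrp <- rdrpHits[rdrpHits$category == "rdrp" &
                     rdrpHits$evalue <= config@evalueRdrp, , drop = FALSE]
  ids <- sort(intersect(intersect(unique(viral$query_id),
                                  unique(rdrp$query_id)),
                        contigIds(contigs)))
  lens <- contigLengths(contigs)
  covs <- contigCoverage(contigs)
  libs <- contigLibrary(contigs)
  lapply(ids, function(id) {
    h <- rdrp[rdrp$query_id == id, , drop = FALSE]
    h <- h[order(h$evalue, -h$bitscore, h$subject_id), , drop = FALSE]
    best <- h[1L, , drop = FALSE]
    new("RdrpCandidate",
        contigId = id,
        libraryId = unname(libs[id]),
        lengthNt = unname(lens[id]),
        coverage = unname(covs[id]),
        bestRdrpHit = best,
        rdrpRegion = c(best$qstart, best$qend),
        nonviralRegions = .noRegions(),
        orfs = .emptyOrfTable(),
        failReasons = character())
  })
}

#' Flag chimeric anchor candidates
#'
#' A candidate is chimeric when a virus-free nucleotide hit of at least
#' `chimeraMinLen` nt (default 100) lies on the contig essentially
#' outside the RdRP region (overlap with the RdRP region below
#' `chimeraMaxOverlap` of the hit's own length, default 50%) — the
#' signature of an assembly artifact joining viral and non-viral
#' sequence. Flagged regions are recorded on the candidate so callers
#' can trim instead of discarding.
#'
#' @param candidate An [RdrpCandidate-class].
#' @param ntHits Annotation table from the virus-free nucleotide search
#'   (`category == "nonviral_nt"`); hits at `evalue <= evalueNt` are
#'   considered.
#' @param config A [RunConfig-class].
#' @return The candidate, with `failReasons` gaining `"chimeric"` and
#'   `nonviralRegions` filled when the rule fires.
#' @export
flagChimeras <- function(candidate, ntHits, config = segConfig()) {
  h <- ntHits[ntHits$category == "nonviral_nt" &
                ntHits$query_id == candidate@contigId &
                ntHits$evalue <= config@evalueNt, , drop = FALSE]
  if (nrow(h) == 0L) return(candidate)
  rs <- candidate@rdrpRegion[1L]
  re <- candidate@rdrpRegion[2L]
  hitLen <- h$qend - h$qstart + 1L
  overlap <- pmax(0L, pmin(h$qend, re) - pmax(h$qstart, rs) + 1L)
  outside <- hitLen >= config@chimeraMinLen &
    (overlap / hitLen) < config@chimeraMaxOverlap
  if (any(outside)) {
    reg <- cbind(start = h$qstart[outside], end = h$qend[outside])
    candidate@nonviralRegions <- reg[order(reg[, 1L], reg[, 2L]), ,
                                     drop = FALSE]
    candidate@failReasons <- union(candidate@failReasons, "chimeric")
  }
  candidate
}

#' Apply anchor-level length, coverage and ORF filters
#'
#' The anchor thresholds guard against fragmented assemblies of
#' unsegmented genomes masquerading as segments: assembler coverage must
#' reach `rdrpCoverageMin` (default 50; exactly 50 passes), length must
#' reach `minContigLen` (default 600 nt), and the contig must encode at
#' least one ORF of `minOrfAa` (default 30 aa). Missing coverage fails
#' the coverage filter: the anchor coverage screen is mandatory.
#'
#' @param candidate An [RdrpCandidate-class].
#' @param contigs The [ContigSet-class] (for the ORF scan).
#' @param config A [RunConfig-class].
#' @return The candidate with any of `"coverage"`, `"length"`, `"orf"`
#'   added to its `failReasons`, and its `orfs` slot filled.
#' @export
applyAnchorFilters <- function(candidate, contigs, config = segConfig()) {
  if (is.na(candidate@coverage) ||
        candidate@coverage < config@rdrpCoverageMin)
    candidate@failReasons <- union(candidate@failReasons, "coverage")
  if (candidate@lengthNt < config@minContigLen)
    candidate@failReasons <- union(candidate@failReasons, "length")
  seq <- contigs@sequences[[candidate@contigId]]
  candidate@orfs <- scanOrfs(as.character(seq),
                             minOrfAa = config@minOrfAa,
                             contigId = candidate@contigId)
  if (nrow(candidate@orfs) == 0L)
    candidate@failReasons <- union(candidate@failReasons, "orf")
  candidate
}

#' Full anchor screen: candidacy, chimeras, anchor filters
#'
#' Chains [flagRdrpContigs()], [flagChimeras()] and
#' [applyAnchorFilters()]. All candidates are returned with their fail
#' reasons; `onlyPassing = TRUE` restricts to clean anchors.
#'
#' @param contigs A [ContigSet-class].
#' @param nrHits,rdrpHits,ntHits Annotation tables (see
#'   [readAnnotationTable()]).
#' @param config A [RunConfig-class].
#' @param onlyPassing Return only candidates with empty `failReasons`.
#' @return List of [RdrpCandidate-class].
#' @export
screenRdrp <- function(contigs, nrHits, rdrpHits,
                       ntHits = emptyAnnotationTable("nonviral_nt"),
                       config = segConfig(), onlyPassing = FALSE) {
  cands <- flagRdrpContigs(contigs, nrHits, rdrpHits, config)
  cands <- lapply(cands, flagChimeras, ntHits = ntHits, config = config)
  cands <- lapply(cands, applyAnchorFilters, contigs = contigs,
                  config = config)
  if (onlyPassing) cands <- Filter(passes, cands)
  cands
}
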