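#' @include AllClasses.R io.R orf.R
NULL

.NONSTOP_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

## a random contig that always encodes an ORF (a long stop-free stretch
## in frame +1), optionally carrying a terminal motif at the 5' end and
## its reverse complement at the 3' end
.simSequence <- function(lengthNt, motif = NULL, rcMotif = FALSE) {
  pad1 <- 20L
  nCodon <- (lengthNt - pad1 - 23L) %/% 3L
  body <- paste0(
    paste(sample(c("A", "C", "G", "T"), pad1, replace = TRUE),
          collapse = ""),
    paste(sample(.NONSTOP_CODONS, nCodon, replace = TRUE),
          collapse = ""),
    "TAA")
  rest <- lengthNt - nchar(body)
  seq <- paste0(body,
                paste(sample(c("A", "C", "G", "T"), rest, replace = TRUE),
                      collapse = ""))
  if (!is.null(motif) && nzchar(motif)) {
    k <- nchar(motif)
    substring(seq, 1L, k) <- motif
    if (rcMotif) {
      rc <- .revcompChar(motif)
      substring(seq, lengthNt - k + 1L, lengthNt) <- rc
    }
  }
  seq
}

#' Describe one planted virus
#'
#' @param virusId Virus identifier.
#' @param nSegments Number of genome segments (1 = unsegmented).
#' @param segmentLengths Lengths (nt) per segment; default: segment 1
#'   (the RdRP segment) 2100 nt, others log-spaced 900-2400 nt.
#' @param segmentScales Per-segment abundance scale factors relative to
#'   the virus's per-library load. Defaults span one order of magnitude
#'   (0.1x to 1x around the RdRP's 0.3), the multipartite signature:
#'   segment abundances differ strongly but proportionally.
#' @param prevalence Probability the virus is present in a library.
#' @param motif Optional terminal motif (6-15 nt) planted at the 5' end
#'   of every segment.
#' @param rcMotif Also plant the motif's reverse complement at the 3'
#'   end of every segment.
#' @return A list consumed by [simulationSpec()].
#' @export
virusSpec <- function(virusId, nSegments, segmentLengths = NULL,
                      segmentScales = NULL, prevalence = 0.6,
                      motif = NULL, rcMotif = FALSE) {
  if (is.null(segmentLengths)) {
    segmentLengths <- if (nSegments == 1L) 2100L else
      as.integer(round(c(2100, exp(seq(log(900), log(2400),
                                       length.out = nSegments - 1L)))))
  }
  if (is.null(segmentScales)) {
    segmentScales <- if (nSegments == 1L) 0.3 else
      c(0.3, exp(seq(log(0.1), log(1.0),
                     length.out = nSegments - 1L)))
  }
  stopifnot(length(segmentLengths) == nSegments,
            length(segmentScales) == nSegments,
            all(segmentScales > 0))
  list(virusId = virusId, nSegments = as.integer(nSegments),
       segmentLengths = as.integer(segmentLengths),
       segmentScales = as.numeric(segmentScales),
       prevalence = prevalence,
       motif = if (is.null(motif)) "" else toupper(motif),
       rcMotif = isTRUE(rcMotif))
}

#' Build a simulation specification
#'
#' The generator emulates the statistical structure the co-occurrence
#' method relies on: within a library, all segments of one virus share a
#' single lognormal load factor, so their TPM profiles across libraries
#' are proportional (up to multiplicative noise and Poisson counting);
#' per-segment scale offsets span an order of magnitude (multipartite
#' behavior); independent unsegmented viruses, host background contigs,
#' co-varying host confounder groups, an optional satellite RNA riding a
#' helper virus's load, and optional low-coverage decoy RdRP contigs
#' tied to host profiles are all included so that every filter of the
#' pipeline is exercised.
#'
#' @param viruses List of [virusSpec()] entries (segmented and
#'   unsegmented).
#' @param nLibraries Number of sequencing libraries.
#' @param hostContigs Number of independent host/cellular background
#'   contigs.
#' @param confounderGroups Number of host contig groups (of
#'   `confounderSize`) sharing a per-library load — non-viral co-varying
#'   profiles.
#' @param confounderSize Contigs per confounder group.
#' @param noiseCv Coefficient of variation of the multiplicative
#'   lognormal noise on segment abundances (default 0.1).
#' @param dropoutProb Probability a present segment's count is zeroed
#'   (assembly/mapping dropout; default 0 — Poisson counting already
#'   produces stochastic zeros at low load).
#' @param loadMeanlog,loadSdlog Parameters of the per-virus per-library
#'   lognormal load (defaults `log(3000)` and 1.2: loads span about two
#'   orders of magnitude across libraries).
#' @param satellites Number of satellite RNAs, each tied to the load of
#'   one segmented helper virus (701 nt, its own scale).
#' @param decoys Number of low-coverage decoy RdRP contigs whose
#'   abundance tracks a host confounder contig; their assembler
#'   coverages are evenly spread over `decoyCoverage`.
#' @param decoyCoverage Range (min, max) of decoy coverages.
#' @param coverageFactor Assembler coverage is simulated as (count in
#'   the contig's best library / length) times this constant, so the
#'   coverage and TPM filters are exercised independently.
#' @param hostMeanlog,hostSdlog Lognormal parameters of host contig
#'   counts.
#' @param rngSeed Seed; the same spec regenerates byte-identical output.
#' @return A list consumed by [simulateBundle()].
#' @export
simulationSpec <- function(viruses, nLibraries = 100L,
                           hostContigs = 200L, confounderGroups = 2L,
                           confounderSize = 3L, noiseCv = 0.1,
                           dropoutProb = 0, loadMeanlog = log(3000),
                           loadSdlog = 1.2, satellites = 0L,
                           decoys = 0L, decoyCoverage = c(5, 45),
                           coverageFactor = 150,
                           hostMeanlog = log(500), hostSdlog = 1,
                           rngSeed = 1L) {
  stopifnot(length(viruses) >= 1L, nLibraries >= 2L)
  for (v in viruses) {
    if (v$prevalence * nLibraries < 1)
      warning("virus ", v$virusId,
              " is expected in fewer than one library")
  }
  list(viruses = viruses, nLibraries = as.integer(nLibraries),
       hostContigs = as.integer(hostContigs),
       confounderGroups = as.integer(confounderGroups),
       confounderSize = as.integer(confounderSize),
       noiseCv = noiseCv, dropoutProb = dropoutProb,
       loadMeanlog = loadMeanlog, loadSdlog = loadSdlog,
       satellites = as.integer(satellites),
       decoys = as.integer(decoys),
       decoyCoverage = decoyCoverage,
       coverageFactor = coverageFactor,
       hostMeanlog = hostMeanlog, hostSdlog = hostSdlog,
       rngSeed = as.integer(rngSeed))
}

.lnNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a multi-library metatranscriptome bundle
#'
#' Generates contig sequences (every contig encodes an ORF so the
#' coding-potential filter passes on construction quality, not luck),
#' a contigs-by-libraries count table, assembler coverages, annotation
#' tables for the three homology searches (RdRP hits for segment 1 of
#' every virus and every decoy, viral-protein hits for viral segments,
#' cellular-protein hits at 40-90% identity for host contigs), and a
#' ground-truth manifest mapping each contig to its planted entity.
#'
#' @param spec A [simulationSpec()].
#' @return List with elements `contigs` ([ContigSet-class]), `counts`
#'   (matrix), `annotations` (list `viral`, `cellular`, `rdrp`,
#'   `nonviral` of annotation data.frames), `truth` (data.frame
#'   `contig_id`, `entity_type`, `virus_id`, `segment_index`,
#'   `planted_motif`), and `spec`.
#' @export
simulateBundle <- function(spec) {
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(spec$rngSeed)
  nLib <- spec$nLibraries
  libs <- sprintf("S%03d", seq_len(nLib))
  seqs <- character()
  covOverride <- numeric()
  counts <- list()
  truth <- list()
  ann <- list(viral = list(), cellular = list(), rdrp = list(),
              nonviral = list())
  addTruth <- function(id, type, virus = "", segIdx = NA_integer_,
                       motif = "") {
    truth[[length(truth) + 1L]] <<- data.frame(
      contig_id = id, entity_type = type, virus_id = virus,
      segment_index = segIdx, planted_motif = motif,
      stringsAsFactors = FALSE)
  }
  segTotals <- list()

  ## segmented and unsegmented viruses
  helperLoads <- list()
  for (v in spec$viruses) {
    present <- stats::runif(nLib) < v$prevalence
    load <- ifelse(present,
                   stats::rlnorm(nLib, spec$loadMeanlog, spec$loadSdlog),
                   0)
    helperLoads[[v$virusId]] <- load
    type <- if (v$nSegments > 1L) "segmented_virus_segment"
    else "unsegmented_virus"
    for (s in seq_len(v$nSegments)) {
      id <- sprintf("%s::seg%02d", v$virusId, s)
      L <- v$segmentLengths[s]
      motif <- if (nzchar(v$motif)) v$motif else NULL
      seqs[id] <- .simSequence(L, motif = motif, rcMotif = v$rcMotif)
      rate <- load * v$segmentScales[s] * .lnNoise(nLib, spec$noiseCv)
      if (spec$dropoutProb > 0)
        rate[stats::runif(nLib) < spec$dropoutProb] <- 0
      counts[[id]] <- stats::rpois(nLib, rate)
      addTruth(id, type, v$virusId, s, v$motif)
      if (s == 1L) {
        ann$rdrp[[id]] <- annotationHits(
          id, paste0("RdRP_ref_", v$virusId), pident = 45, length = L,
          qstart = 30L, qend = as.integer(L * 0.9),
          evalue = 10^stats::runif(1, -50, -10), bitscore = 300,
          category = "rdrp")
      }
      ## most viral segments also have protein-reference support
      if (s == 1L || stats::runif(1) < 0.7) {
        ann$viral[[id]] <- annotationHits(
          id, paste0("viral_ref_", v$virusId, "_", s), pident = 40,
          length = L, qstart = 25L, qend = as.integer(L * 0.85),
          evalue = 10^stats::runif(1, -40, -8), bitscore = 200,
          category = "viral_protein")
      }
    }
  }

  ## satellite RNAs riding a helper virus's load
  segViruses <- Filter(function(v) v$nSegments > 1L, spec$viruses)
  if (spec$satellites > 0L && length(segViruses)) {
    for (i in seq_len(spec$satellites)) {
      helper <- segViruses[[1L + (i - 1L) %% length(segViruses)]]
      id <- sprintf("satellite%02d::seg01", i)
      seqs[id] <- .simSequence(701L)
      rate <- helperLoads[[helper$virusId]] * 0.5 *
        .lnNoise(nLib, spec$noiseCv)
      counts[[id]] <- stats::rpois(nLib, rate)
      addTruth(id, "satellite", helper$virusId, 1L)
    }
  }

  ## host background, including co-varying confounder groups
  nConf <- spec$confounderGroups * spec$confounderSize
  confLoads <- lapply(seq_len(spec$confounderGroups), function(g)
    stats::rlnorm(nLib, spec$hostMeanlog, spec$hostSdlog))
  firstConfIds <- character(spec$confounderGroups)
  for (h in seq_len(spec$hostContigs)) {
    id <- sprintf("host%04d::c1", h)
    L <- sample(800:2200, 1L)
    seqs[id] <- .simSequence(L)
    if (h <= nConf) {
      g <- 1L + (h - 1L) %/% spec$confounderSize
      if ((h - 1L) %% spec$confounderSize == 0L) firstConfIds[g] <- id
      rate <- confLoads[[g]] * .lnNoise(nLib, spec$noiseCv)
    } else {
      rate <- stats::rlnorm(nLib, spec$hostMeanlog, spec$hostSdlog)
    }
    counts[[id]] <- stats::rpois(nLib, rate)
    addTruth(id, "host")
    ann$cellular[[id]] <- annotationHits(
      id, paste0("cell_ref_", h), pident = stats::runif(1, 40, 90),
      length = L, qstart = 15L, qend = as.integer(L * 0.8),
      evalue = 10^stats::runif(1, -30, -6), bitscore = 250,
      category = "cellular_protein")
  }

  ## low-coverage decoy "RdRP" contigs tracking a host confounder
  if (spec$decoys > 0L) {
    decoyCov <- seq(spec$decoyCoverage[1], spec$decoyCoverage[2],
                    length.out = spec$decoys)
    for (d in seq_len(spec$decoys)) {
      id <- sprintf("decoy%02d::seg01", d)
      L <- 900L
      seqs[id] <- .simSequence(L)
      g <- 1L + (d - 1L) %% spec$confounderGroups
      rate <- confLoads[[g]] * 0.8 * .lnNoise(nLib, spec$noiseCv)
      counts[[id]] <- stats::rpois(nLib, rate)
      covOverride[id] <- decoyCov[d]
      addTruth(id, "noise")
      ann$rdrp[[id]] <- annotationHits(
        id, paste0("RdRP_ref_decoy", d), pident = 38, length = L,
        qstart = 40L, qend = 800L,
        evalue = 10^stats::runif(1, -30, -10), bitscore = 150,
        category = "rdrp")
      ann$viral[[id]] <- annotationHits(
        id, paste0("viral_ref_decoy", d), pident = 35, length = L,
        qstart = 40L, qend = 800L,
        evalue = 10^stats::runif(1, -20, -8), bitscore = 120,
        category = "viral_protein")
    }
  }

  ids <- names(seqs)
  countMat <- do.call(rbind, counts)
  rownames(countMat) <- names(counts)
  colnames(countMat) <- libs
  storage.mode(countMat) <- "double"
  lens <- nchar(seqs)
  coverage <- apply(countMat, 1L, max) / lens * spec$coverageFactor
  coverage[names(covOverride)] <- covOverride
  contigs <- ContigSet(DNAStringSet(seqs),
                       library = sub("::.*$", "", ids),
                       coverage = unname(coverage[ids]))
  truthDf <- do.call(rbind, truth)
  rownames(truthDf) <- NULL
  annTabs <- lapply(ann, function(x)
    if (length(x)) do.call(rbind, unname(x))
    else emptyAnnotationTable())
  annTabs$cellular$category <- if (nrow(annTabs$cellular))
    "cellular_protein" else character()
  annTabs$rdrp$category <- if (nrow(annTabs$rdrp)) "rdrp" else character()
  annTabs$nonviral <- emptyAnnotationTable("nonviral_nt")
  list(contigs = contigs, counts = countMat, annotations = annTabs,
       truth = truthDf, spec = spec)
}

#' The default desk-scale benchmark bundle
#'
#' A fixed-seed bundle with 100 libraries; 20 segmented viruses with
#' segment counts cycling through 2, 2, 3, 3, 3, 4, 5, 8 (70 planted
#' segments in total); 10 unsegmented viruses; one satellite RNA tied to
#' a helper virus; and 200 host contigs including two co-varying
#' confounder triplets. Eight viruses carry planted terminal motifs
#' (half of them reverse-complementary across the termini). Multiplicative
#' noise CV is 0.1. Expected outcome at default thresholds: all 20
#' segmented viruses recovered with every segment and no cross-virus
#' contamination.
#'
#' @param seed RNG seed for the bundle.
#' @param decoys Optional number of low-coverage decoy anchors (for
#'   threshold sweeps).
#' @return A bundle as returned by [simulateBundle()].
#' @export
defaultBenchmark <- function(seed = 20240601L, decoys = 0L) {
  segCounts <- rep(c(2L, 2L, 3L, 3L, 3L, 4L, 5L, 8L), 3L)[1:20]
  motifs <- c("AGATCGGAAGAGC", "TGCATGGACGTTAC", "CCGTAAGGTC",
              "ATTCGCGGATTA", "GGTACCTTAGCA", "CAGTTGACCGGT",
              "TTGGCACGATCC", "ACGCGTTAAGGC")
  viruses <- lapply(seq_len(20L), function(i) {
    virusSpec(sprintf("virus%02d", i), segCounts[i],
              prevalence = 0.6,
              motif = if (i <= 8L) motifs[i] else NULL,
              rcMotif = i %in% c(2L, 4L, 6L, 8L))
  })
  unseg <- lapply(seq_len(10L), function(i)
    virusSpec(sprintf("unseg%02d", i), 1L, prevalence = 0.5))
  simulateBundle(simulationSpec(
    viruses = c(viruses, unseg), nLibraries = 100L, hostContigs = 200L,
    confounderGroups = 2L, confounderSize = 3L, noiseCv = 0.1,
    dropoutProb = 0, satellites = 1L, decoys = decoys,
    rngSeed = as.integer(seed)))
}

#' Write a simulated bundle to a directory
#'
#' Emits `contigs.fasta` (coverage in megahit-style `multi=` tokens),
#' `counts.tsv`, `coverage.tsv`, the four annotation tables
#' (`annotation_<category>.tsv`), `truth.json` and `spec.json`.
#' Regenerating and rewriting with the same spec is byte-identical.
#'
#' @param bundle A [simulateBundle()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeContigs(bundle$contigs, file.path(dir, "contigs.fasta"))
  writeCountTable(bundle$counts, file.path(dir, "counts.tsv"))
  writeCoverageTable(contigCoverage(bundle$contigs),
                     file.path(dir, "coverage.tsv"))
  for (nm in names(bundle$annotations))
    writeAnnotationTable(bundle$annotations[[nm]],
                         file.path(dir, paste0("annotation_", nm, ".tsv")))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  jsonlite::write_json(bundle$spec[setdiff(names(bundle$spec), "viruses")],
                       file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' @param dir Directory written by [writeBundle()].
#' @return List with `contigs`, `counts`, `annotations`, `truth`.
#' @export
readBundle <- function(dir) {
  contigs <- readContigs(file.path(dir, "contigs.fasta"),
                         coverageTablePath = file.path(dir, "coverage.tsv"))
  counts <- readCountTable(file.path(dir, "counts.tsv"))
  cats <- c(viral = "viral_protein", cellular = "cellular_protein",
            rdrp = "rdrp", nonviral = "nonviral_nt")
  annotations <- lapply(names(cats), function(nm)
    readAnnotationTable(file.path(dir, paste0("annotation_", nm, ".tsv")),
                        category = cats[[nm]]))
  names(annotations) <- names(cats)
  truthRaw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                  simplifyVector = TRUE)
  truth <- as.data.frame(truthRaw, stringsAsFactors = FALSE)
  truth$segment_index <- as.integer(truth$segment_index)
  list(contigs = contigs, counts = counts, annotations = annotations,
       truth = truth)
}
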