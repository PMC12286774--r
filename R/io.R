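#' @include AllClasses.R
NULL

## Header-dialect coverage parsing is total: any FASTA header yields a
## contig (coverage possibly missing), never an error.
.parseHeaderCoverage <- function(header) {
  m <- regmatches(header, regexpr("\\bmulti=[0-9.eE+-]+", header))
  if (length(m) == 1L && nzchar(m)) {
    v <- suppressWarnings(as.numeric(sub("multi=", "", m)))
    if (!is.na(v)) return(v)
  }
  id <- strsplit(header, "[ \t]")[[1]][1]
  m <- regmatches(id, regexpr("_cov_[0-9.eE+-]+", id))
  if (length(m) == 1L && nzchar(m)) {
    v <- suppressWarnings(as.numeric(sub("_cov_", "", m)))
    if (!is.na(v)) return(v)
  }
  NA_real_
}

#' Read assembled contigs from FASTA
#'
#' Parses a per-library contig FASTA. Assembler coverage is recovered
#' from megahit-style headers (token `multi=X`), SPAdes-style ids
#' (token `_cov_X`), or an optional two-column coverage table
#' (`contig_id <tab> coverage`), in that precedence; coverage that
#' cannot be resolved is recorded as missing (`NA`), never as 0.
#' Contig ids are namespaced as `"<library>::<id>"` to guarantee global
#' uniqueness across libraries; ids that already contain `"::"` are
#' taken as pre-namespaced and their library prefix is used.
#'
#' @param fastaPath Path to a FASTA file of assembled contigs.
#' @param coverageTablePath Optional TSV fallback (`contig_id`,
#'   `coverage`), keyed by the original (un-namespaced) contig id.
#' @param libraryId Library of origin; required unless ids are already
#'   namespaced.
#' @return A [ContigSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">k141_5 flag=1 multi=63.0 len=8", "ACGTACGT"), fa)
#' cs <- readContigs(fa, libraryId = "L1")
#' contigCoverage(cs)
#' @export
readContigs <- function(fastaPath, coverageTablePath = NULL,
                        libraryId = NULL) {
  if (!file.exists(fastaPath))
    stop("FASTA file not found: ", fastaPath)
  seqs <- readDNAStringSet(fastaPath)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "[ \t]"), `[`, character(1), 1L)
  if (any(width(seqs) == 0L))
    stop("empty sequence for record '", ids[width(seqs) == 0L][1L], "'")
  if (anyDuplicated(ids))
    stop("duplicate contig id in ", fastaPath, ": '",
         ids[duplicated(ids)][1L], "'")
  coverage <- vapply(headers, .parseHeaderCoverage, numeric(1),
                     USE.NAMES = FALSE)
  if (!is.null(coverageTablePath)) {
    tab <- readCoverageTable(coverageTablePath)
    miss <- is.na(coverage) & ids %in% names(tab)
    coverage[miss] <- tab[ids[miss]]
  }
  pre <- grepl("::", ids, fixed = TRUE)
  if (is.null(libraryId)) {
    lib <- ifelse(pre, sub("::.*$", "", ids), "lib1")
    full <- ifelse(pre, ids, paste0(lib, "::", ids))
  } else {
    lib <- ifelse(pre, sub("::.*$", "", ids), libraryId)
    full <- ifelse(pre, ids, paste0(libraryId, "::", ids))
  }
  names(seqs) <- full
  ContigSet(seqs, library = lib, coverage = coverage)
}

#' Write contigs to FASTA
#'
#' Headers carry the namespaced contig id plus a megahit-style
#' `multi=` token when coverage is known, so [readContigs()] on the
#' output reproduces the object (round-trip).
#'
#' @param contigs A [ContigSet-class].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
writeContigs <- function(contigs, path) {
  seqs <- contigs@sequences
  cov <- contigs@coverage
  hdr <- ifelse(is.na(cov), names(seqs),
                paste0(names(seqs), " multi=",
                       format(cov, digits = 15, scientific = FALSE,
                              trim = TRUE)))
  out <- seqs
  names(out) <- hdr
  writeXStringSet(out, path, width = 80L)
  invisible(path)
}

#' Read a two-column coverage table
#'
#' @param path TSV with columns `contig_id` and `coverage` (no header).
#' @return Named numeric vector of coverage values.
#' @export
readCoverageTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig_id", "coverage"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$coverage, tab$contig_id)
}

#' Write a coverage table
#'
#' @param coverage Named numeric vector (`NA` entries are omitted).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeCoverageTable <- function(coverage, path) {
  keep <- !is.na(coverage)
  utils::write.table(
    data.frame(contig_id = names(coverage)[keep],
               coverage = format(coverage[keep], digits = 15,
                                 scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.annotationCols <- c("query_id", "subject_id", "pident", "length",
                     "mismatch", "gapopen", "qstart", "qend",
                     "sstart", "send", "evalue", "bitscore")

#' Read a BLAST/DIAMOND tabular annotation table
#'
#' Parses the 12-column `outfmt 6` dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Query
#' coordinates are canonicalized so `qstart <= qend`; a hit reported on
#' the reverse strand keeps `strand = "-"`. The `category` column
#' records which search the table came from.
#'
#' @param path Tabular file (no header). An empty file yields an empty
#'   table.
#' @param category One of `"rdrp"`, `"viral_protein"`,
#'   `"cellular_protein"`, `"nonviral_nt"`.
#' @return data.frame with the 12 standard columns plus `strand` and
#'   `category`.
#' @export
readAnnotationTable <- function(path,
    category = c("rdrp", "viral_protein", "cellular_protein",
                 "nonviral_nt")) {
  category <- match.arg(category)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(emptyAnnotationTable(category))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns at line ",
         which(nf != 12L)[1L], " of ", path, " (found ",
         nf[nf != 12L][1L], ")")
  mat <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = mat[, 1], subject_id = mat[, 2],
    pident = as.numeric(mat[, 3]), length = as.integer(mat[, 4]),
    mismatch = as.integer(mat[, 5]), gapopen = as.integer(mat[, 6]),
    qstart = as.integer(mat[, 7]), qend = as.integer(mat[, 8]),
    sstart = as.integer(mat[, 9]), send = as.integer(mat[, 10]),
    evalue = as.numeric(mat[, 11]), bitscore = as.numeric(mat[, 12]),
    stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) stop("negative e-value in ", path)
  rev <- hits$qstart > hits$qend
  tmp <- hits$qstart[rev]
  hits$qstart[rev] <- hits$qend[rev]
  hits$qend[rev] <- tmp
  hits$strand <- ifelse(rev, "-", "+")
  hits$category <- category
  hits
}

#' An empty annotation table with the standard columns
#'
#' @param category Subject category for the (empty) table.
#' @return Zero-row annotation data.frame.
#' @export
emptyAnnotationTable <- function(category = "viral_protein") {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), length = integer(),
             mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(),
             strand = character(), category = character(),
             stringsAsFactors = FALSE)
}

#' Build annotation rows in memory
#'
#' Convenience constructor matching [readAnnotationTable()] output, for
#' simulators and tests.
#'
#' @param query_id,subject_id,pident,length,qstart,qend,evalue,bitscore
#'   Hit fields (recycled to a common length).
#' @param category Subject category of the search.
#' @return Annotation data.frame.
#' @export
annotationHits <- function(query_id, subject_id, pident, length,
                           qstart, qend, evalue, bitscore,
                           category = "viral_protein") {
  n <- max(lengths(list(query_id, subject_id, pident, length,
                        qstart, qend, evalue, bitscore)))
  data.frame(
    query_id = rep_len(query_id, n),
    subject_id = rep_len(subject_id, n),
    pident = rep_len(as.numeric(pident), n),
    length = rep_len(as.integer(length), n),
    mismatch = 0L, gapopen = 0L,
    qstart = rep_len(as.integer(qstart), n),
    qend = rep_len(as.integer(qend), n),
    sstart = 1L,
    send = rep_len(as.integer(length), n),
    evalue = rep_len(as.numeric(evalue), n),
    bitscore = rep_len(as.numeric(bitscore), n),
    strand = "+",
    category = rep_len(category, n),
    stringsAsFactors = FALSE)
}

#' Write an annotation table in BLAST tabular format
#'
#' Reverse-strand hits are written with `qstart > qend` so reading the
#' file back reproduces the canonicalized coordinates and strand flag.
#'
#' @param hits Annotation data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAnnotationTable <- function(hits, path) {
  if (nrow(hits) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  qs <- ifelse(hits$strand == "-", hits$qend, hits$qstart)
  qe <- ifelse(hits$strand == "-", hits$qstart, hits$qend)
  out <- data.frame(hits$query_id, hits$subject_id,
                    format(hits$pident, digits = 15, trim = TRUE),
                    hits$length, hits$mismatch, hits$gapopen, qs, qe,
                    hits$sstart, hits$send,
                    format(hits$evalue, digits = 15, trim = TRUE),
                    format(hits$bitscore, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contigs-by-libraries count (or TPM) table
#'
#' @param path TSV with a header row of library ids and contig ids in
#'   the first column.
#' @return Numeric matrix, contigs in rows, libraries in columns.
#' @export
readCountTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative count in ", path)
  m
}

#' Write a contigs-by-libraries matrix as TSV
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCountTable <- function(mat, path) {
  df <- data.frame(contig_id = rownames(mat),
                   apply(mat, 2, function(x)
                     format(x, digits = 15, scientific = FALSE,
                            trim = TRUE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("contig_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the final cluster report
#'
#' One TSV row per cluster member (`cluster_id`, `member_id`, `is_rdrp`,
#' `rho`, `max_tpm`, `ambiguous`, `qc_flags`, `status`) plus a JSON
#' sidecar (`<path>.config.json`) echoing the full [RunConfig-class].
#' Output is deterministic: identical inputs and configuration produce
#' byte-identical files.
#'
#' @param clusters List of [SegmentCluster-class] objects.
#' @param path Output TSV path.
#' @param abund Optional [AbundanceMatrix-class] used for the
#'   `max_tpm` column.
#' @param config Optional [RunConfig-class] echoed to the sidecar.
#' @return Invisibly, `path`.
#' @export
writeClusterReport <- function(clusters, path, abund = NULL,
                               config = NULL) {
  header <- paste(c("cluster_id", "member_id", "is_rdrp", "rho",
                    "max_tpm", "ambiguous", "qc_flags", "status"),
                  collapse = "\t")
  rows <- character()
  ord <- order(vapply(clusters, function(cl) cl@clusterId, character(1)))
  for (cl in clusters[ord]) {
    mem <- cl@members[order(cl@members$memberId), , drop = FALSE]
    maxTpm <- if (!is.null(abund)) {
      m <- tpmMatrix(abund)
      vapply(mem$memberId, function(id)
        if (id %in% rownames(m)) max(m[id, ]) else NA_real_, numeric(1))
    } else rep(NA_real_, nrow(mem))
    rows <- c(rows, sprintf(
      "%s\t%s\t%d\t%s\t%s\t%d\t%s\t%s",
      cl@clusterId, mem$memberId, as.integer(mem$isRdrp),
      sprintf("%.6f", mem$rho),
      ifelse(is.na(maxTpm), "NA", sprintf("%.4f", maxTpm)),
      as.integer(mem$memberId %in% cl@ambiguousMembers),
      if (length(cl@qcFlags)) paste(sort(cl@qcFlags), collapse = ",")
      else ".",
      cl@status))
  }
  writeLines(c(header, rows), path)
  if (!is.null(config)) {
    jsonlite::write_json(configAsList(config),
                         paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
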