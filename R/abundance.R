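#' @include AllClasses.R orf.R
NULL

#' Length and coding-potential filter for contigs
#'
#' Keeps contigs of at least `minContigLen` nt (default 600, the
#' published minimum segment length) that encode at least one ORF of
#' `minOrfAa` amino acids (default 30) — short or non-coding contigs add
#' correlation noise without being plausible genome segments.
#'
#' @param contigs A [ContigSet-class].
#' @param config A [RunConfig-class].
#' @return The filtered [ContigSet-class].
#' @export
filterContigs <- function(contigs, config = segConfig()) {
  if (length(contigs) == 0L) return(contigs)
  lens <- contigLengths(contigs)
  keep <- lens >= config@minContigLen
  idx <- which(keep)
  hasOrfV <- vapply(idx, function(i)
    hasOrf(as.character(contigs@sequences[[i]]),
           minOrfAa = config@minOrfAa), logical(1))
  contigs[idx[hasOrfV]]
}

.kmerSet <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  unique(substring(seq, seq_len(L - k + 1L), k:L))
}

#' Greedy dereplication by k-mer containment
#'
#' Collapses near-identical contigs (typically the same virus segment
#' assembled independently in several libraries) to one representative
#' before cross-library quantification. Contigs are visited longest
#' first (length ties broken lexicographically by id); a contig joins an
#' existing representative when the fraction of its distinct k-mers
#' (default k = 10) found in the representative — on either strand —
#' reaches `identity` (default 0.8, matching the published clustering
#' threshold); otherwise it founds a new representative. When several
#' representatives qualify, the best containment wins (ties to the
#' earliest-founded). Deterministic, and idempotent on its own
#' representatives.
#'
#' @param contigs A [ContigSet-class].
#' @param identity Containment threshold in (0, 1].
#' @param k K-mer size.
#' @return List with `map` (named list: representative id -> character
#'   vector of replaced member ids), `representatives` (character
#'   vector), and `identity`.
#' @export
dereplicate <- function(contigs, identity = 0.8, k = 10L) {
  n <- length(contigs)
  if (n == 0L)
    return(list(map = list(), representatives = character(),
                identity = identity))
  ids <- contigIds(contigs)
  lens <- unname(contigLengths(contigs))
  ord <- order(-lens, ids)
  repIds <- character()
  repSets <- list()
  map <- list()
  for (i in ord) {
    id <- ids[i]
    seq <- as.character(contigs@sequences[[i]])
    fwd <- .kmerSet(seq, k)
    rev <- .kmerSet(.revcompChar(seq), k)
    best <- 0
    bestRep <- NA_integer_
    for (j in seq_along(repSets)) {
      nf <- sum(fwd %in% repSets[[j]])
      nr <- sum(rev %in% repSets[[j]])
      cont <- max(if (length(fwd)) nf / length(fwd) else 0,
                  if (length(rev)) nr / length(rev) else 0)
      if (cont > best) {
        best <- cont
        bestRep <- j
      }
    }
    if (!is.na(bestRep) && best >= identity) {
      map[[repIds[bestRep]]] <- c(map[[repIds[bestRep]]], id)
    } else {
      repIds <- c(repIds, id)
      repSets[[length(repSets) + 1L]] <- fwd
      map[[id]] <- character()
    }
  }
  list(map = map[repIds], representatives = repIds, identity = identity)
}

#' TPM normalization of a count table
#'
#' Per library: each contig's count is divided by its length in
#' kilobases to give a rate, and rates are rescaled to sum to one
#' million. Columns of the result sum to 1e6 (relative tolerance 1e-6)
#' except all-zero libraries, which stay all-zero. TPM is
#' scale-invariant per library: multiplying a library's counts by any
#' positive constant leaves its TPM column unchanged.
#'
#' @param counts Numeric matrix (contigs x libraries), non-negative;
#'   fractional counts (multi-mapping-aware quantifiers) are allowed.
#' @param lengths Named vector of contig lengths in nt covering every
#'   row of `counts`.
#' @return An [AbundanceMatrix-class].
#' @examples
#' counts <- matrix(c(100, 100), 2, 1,
#'                  dimnames = list(c("a", "b"), "L1"))
#' tpmMatrix(computeTpm(counts, c(a = 1000, b = 2000)))
#' @export
computeTpm <- function(counts, lengths) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("no length for contig(s): ", paste(head(miss, 3), collapse = ", "))
  kb <- lengths[rownames(counts)] / 1000
  rate <- counts / kb
  totals <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(totals > 0, totals, 1), "/") * 1e6
  tpm[, totals == 0] <- 0
  AbundanceMatrix(tpm, lengths = lengths[rownames(counts)])
}

#' Pool member counts into their dereplication representative
#'
#' Counts of replaced members are summed into their representative's
#' row before TPM normalization, so a segment assembled independently in
#' many libraries contributes one row with a full cross-library profile
#' (without pooling, cross-library correlation would be undefined).
#'
#' @param counts Numeric matrix (contigs x libraries).
#' @param derep Result of [dereplicate()].
#' @return Count matrix restricted to representatives, members pooled.
#' @export
poolCounts <- function(counts, derep) {
  reps <- derep$representatives
  reps <- reps[reps %in% rownames(counts)]
  pooled <- counts[reps, , drop = FALSE]
  for (r in reps) {
    mem <- intersect(derep$map[[r]], rownames(counts))
    if (length(mem))
      pooled[r, ] <- pooled[r, ] +
        colSums(counts[mem, , drop = FALSE])
  }
  pooled
}

#' Assemble the final contigs-by-libraries abundance matrix
#'
#' Applies dereplication pooling and TPM normalization in one step.
#' Rows are representatives only; columns are all libraries of the
#' count table; contig/library combinations without signal are 0.
#'
#' @param counts Numeric count matrix (all contigs x all libraries).
#' @param lengths Named contig lengths (nt).
#' @param derep Optional [dereplicate()] result; `NULL` skips pooling.
#' @return An [AbundanceMatrix-class].
#' @export
assembleMatrix <- function(counts, lengths, derep = NULL) {
  if (anyDuplicated(rownames(counts)))
    stop("duplicate contig row id in count table")
  if (!is.null(derep)) counts <- poolCounts(counts, derep)
  computeTpm(counts, lengths)
}
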