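#' @include AllClasses.R orf.R
NULL

#' Extract terminal windows of a cluster's segments
#'
#' Segmented viruses often share highly conserved — sometimes
#' reverse-complementary — sequences at their genome termini. This
#' returns, per member, the first `windowNt` nt (`head`), the last
#' `windowNt` nt (`tail`), and the reverse complement of the tail
#' (`tailRc`, used for the cross-terminus reverse-complement search).
#' Contigs shorter than the window contribute their whole sequence.
#'
#' @param memberIds Character vector of contig ids, or a
#'   [SegmentCluster-class] (its retained members are used).
#' @param contigs A [ContigSet-class] holding all member sequences.
#' @param windowNt Window length in nt (default 50).
#' @return Named list (one entry per member, in id order) of lists with
#'   `head`, `tail`, `tailRc` character strings.
#' @export
extractTermini <- function(memberIds, contigs, windowNt = 50L) {
  if (is(memberIds, "SegmentCluster"))
    memberIds <- memberIds@members$memberId
  memberIds <- sort(memberIds)
  missing <- setdiff(memberIds, contigIds(contigs))
  if (length(missing))
    stop("no sequence for member(s): ",
         paste(head(missing, 3), collapse = ", "))
  out <- lapply(memberIds, function(id) {
    s <- as.character(contigs@sequences[[id]])
    L <- nchar(s)
    w <- min(windowNt, L)
    tail <- substring(s, L - w + 1L, L)
    list(head = substring(s, 1L, w), tail = tail,
         tailRc = .revcompChar(tail))
  })
  stats::setNames(out, memberIds)
}

.windowKmers <- function(s, k) .kmerSet(s, k)

.matchesWindow <- function(motif, window, maxMismatch) {
  k <- nchar(motif)
  if (maxMismatch == 0L)
    return(grepl(motif, window, fixed = TRUE))
  L <- nchar(window)
  if (L < k) return(FALSE)
  mv <- strsplit(motif, "")[[1]]
  for (p in seq_len(L - k + 1L)) {
    wv <- strsplit(substring(window, p, p + k - 1L), "")[[1]]
    if (sum(mv != wv) <= maxMismatch) return(TRUE)
  }
  FALSE
}

#' Find conserved terminal motifs across a cluster's segments
#'
#' Exhaustive ungapped k-mer enumeration over the terminal windows: for
#' each k in `kRange`, every k-mer observed in any 5' window (resp. 3'
#' window) is scored by the fraction of segments whose window contains
#' it; the `cross_rc` search scores k-mers present in a segment's 5'
#' window whose reverse complement occurs in the same segment's 3'
#' window (the reverse-complementary terminus signature). Motifs
#' reaching `minFraction` are reported, pruned to maximal motifs (a
#' motif that is a substring of an equally- or better-supported longer
#' reported motif at the same terminus is dropped), and sorted by
#' fraction (desc), length (desc), then lexicographically. The result
#' does not depend on segment input order.
#'
#' @param termini Output of [extractTermini()] (>= 2 segments).
#' @param kRange Integer vector of motif lengths to scan (default 6:15).
#' @param minFraction Minimum supporting fraction (default 0.8,
#'   tolerating one ragged assembly end in a five-segment cluster).
#' @param maxMismatch Substitutions tolerated when matching (default 0,
#'   exact).
#' @return data.frame with columns `motif`, `terminus` (`five_prime`,
#'   `three_prime`, `cross_rc`), `segments_with_motif`,
#'   `segments_total`, `fraction`, and a list column `positions` of
#'   named 0-based offsets from the respective terminus. Zero rows
#'   (with a warning) for clusters of fewer than two segments.
#' @export
findConservedMotifs <- function(termini, kRange = 6:15,
                                minFraction = 0.8, maxMismatch = 0L) {
  empty <- data.frame(motif = character(), terminus = character(),
                      segments_with_motif = integer(),
                      segments_total = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  empty$positions <- list()
  if (length(termini) < 2L) {
    warning("motif search needs at least two segments")
    return(empty)
  }
  segIds <- sort(names(termini))
  termini <- termini[segIds]
  nSeg <- length(segIds)
  rows <- list()
  for (k in sort(kRange)) {
    heads <- vapply(termini, `[[`, character(1), "head")
    tails <- vapply(termini, `[[`, character(1), "tail")
    candHead <- sort(unique(unlist(lapply(heads, .windowKmers, k = k))))
    candTail <- sort(unique(unlist(lapply(tails, .windowKmers, k = k))))
    scan <- function(cands, windows, terminus) {
      for (motif in cands) {
        hit <- vapply(windows, .matchesWindow, logical(1),
                      motif = motif, maxMismatch = maxMismatch)
        frac <- sum(hit) / nSeg
        if (frac >= minFraction) {
          pos <- vapply(windows[hit], function(w) {
            p <- regexpr(motif, w, fixed = TRUE)[1]
            if (p < 0) NA_integer_ else {
              if (terminus == "three_prime")
                nchar(w) - (p + k - 1L)   # offset from the 3' end
              else p - 1L
            }
          }, integer(1))
          rows[[length(rows) + 1L]] <<- data.frame(
            motif = motif, terminus = terminus,
            segments_with_motif = sum(hit), segments_total = nSeg,
            fraction = frac, positions = I(list(pos)),
            stringsAsFactors = FALSE)
        }
      }
    }
    scan(candHead, heads, "five_prime")
    scan(candTail, tails, "three_prime")
    ## cross_rc: motif in the 5' window, reverse complement in the 3'
    rcHead <- if (length(candHead))
      as.character(reverseComplement(DNAStringSet(candHead)))
    else character()
    for (ci in seq_along(candHead)) {
      motif <- candHead[ci]
      rc <- rcHead[ci]
      hit <- vapply(seq_len(nSeg), function(i)
        .matchesWindow(motif, heads[i], maxMismatch) &&
          .matchesWindow(rc, tails[i], maxMismatch), logical(1))
      frac <- sum(hit) / nSeg
      if (frac >= minFraction) {
        pos <- vapply(which(hit), function(i) {
          regexpr(motif, heads[i], fixed = TRUE)[1] - 1L
        }, integer(1))
        names(pos) <- segIds[hit]
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motif, terminus = "cross_rc",
          segments_with_motif = sum(hit), segments_total = nSeg,
          fraction = frac, positions = I(list(pos)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  ## keep maximal motifs: drop substrings of an at-least-as-supported
  ## longer reported motif at the same terminus
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    longer <- which(res$terminus == res$terminus[i] &
                      nchar(res$motif) > nchar(res$motif[i]) &
                      res$fraction >= res$fraction[i])
    if (any(vapply(longer, function(j)
      grepl(res$motif[i], res$motif[j], fixed = TRUE), logical(1))))
      keep[i] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(-res$fraction, -nchar(res$motif), res$motif,
                   res$terminus), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Terminal-motif verdict for a cluster
#'
#' A cluster gains homology-independent support when any conserved
#' terminal motif reaches `minFraction` support and is at least
#' `minSupportLen` nt long (default 8 — shorter shared k-mers arise too
#' easily by chance). Verification attaches evidence to the cluster
#' report; it never deletes a cluster.
#'
#' @param cluster A [SegmentCluster-class].
#' @param motifHits Output of [findConservedMotifs()] for the cluster.
#' @param minFraction,minSupportLen Support thresholds.
#' @return The cluster with `terminalSupport` set to
#'   `"homology_independent_support"` or `"no_terminal_support"`.
#' @export
verifyCluster <- function(cluster, motifHits, minFraction = 0.8,
                          minSupportLen = 8L) {
  supported <- nrow(motifHits) > 0L &&
    any(motifHits$fraction >= minFraction &
          nchar(motifHits$motif) >= minSupportLen)
  cluster@terminalSupport <- if (supported)
    "homology_independent_support" else "no_terminal_support"
  cluster
}

#' Motif search for a cluster in one call
#'
#' @param cluster A [SegmentCluster-class].
#' @param contigs A [ContigSet-class].
#' @param config A [RunConfig-class] (window, k range, fraction,
#'   mismatch tolerance).
#' @return As [findConservedMotifs()], with a `cluster_id` column.
#' @export
findClusterMotifs <- function(cluster, contigs, config = segConfig()) {
  term <- extractTermini(cluster, contigs,
                         windowNt = config@terminalWindow)
  hits <- if (length(term) < 2L) {
    suppressWarnings(findConservedMotifs(term))
  } else {
    findConservedMotifs(term,
                        kRange = config@motifKmin:config@motifKmax,
                        minFraction = config@motifMinFraction,
                        maxMismatch = config@motifMaxMismatch)
  }
  if (nrow(hits)) hits <- cbind(cluster_id = cluster@clusterId, hits)
  hits
}
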