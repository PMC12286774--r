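#' @include AllClasses.R
NULL

.revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

.emptyOrfTable <- function() {
  data.frame(contig_id = character(), start = integer(),
             end = integer(), strand = character(),
             length_aa = integer(), stringsAsFactors = FALSE)
}

## translate one frame; codons touching N (or any ambiguity) become "X",
## which never terminates an ORF
.frameAA <- function(seq, offset) {
  L <- nchar(seq)
  nCodon <- (L - offset) %/% 3L
  if (nCodon < 1L) return(character())
  starts <- offset + 1L + 3L * (seq_len(nCodon) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

.orfsOneStrand <- function(seq, minOrfAa) {
  out <- list()
  for (offset in 0:2) {
    aa <- .frameAA(seq, offset)
    if (!length(aa)) next
    isStop <- aa == "*"
    ## maximal stop-to-stop runs of coding codons
    r <- rle(isStop)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    keep <- !r$values & r$lengths >= minOrfAa
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = offset + 1L + 3L * (startIdx[keep] - 1L),
      end = offset + 3L * endIdx[keep],
      length_aa = r$lengths[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Six-frame open reading frame scan
#'
#' Finds maximal stop-to-stop ORFs in all six frames: a run of coding
#' codons bounded by stop codons (or the sequence ends) counts as an ORF
#' when it spans at least `minOrfAa` codons, with no start-codon
#' requirement (ORFfinder's "any sense codon" mode). Codons containing
#' `N` translate to `X` and never terminate an ORF. Reverse-strand ORFs
#' are reported with 1-based inclusive coordinates on the forward
#' sequence and `strand = "-"`.
#'
#' @param sequence Nucleotide string (or length-1 `DNAStringSet`) over
#'   `A`, `C`, `G`, `T`, `N`.
#' @param minOrfAa Minimum ORF length in amino acids (default 30,
#'   ORFfinder's `-ml 30`).
#' @param contigId Id recorded in the output.
#' @return data.frame with columns `contig_id`, `start`, `end`,
#'   `strand`, `length_aa`; zero rows when no ORF qualifies. The span
#'   satisfies `end - start + 1 == 3 * length_aa` (the bounding stop
#'   codons are excluded).
#' @examples
#' scanOrfs(paste(rep("ATG", 40), collapse = ""), minOrfAa = 30)
#' @export
scanOrfs <- function(sequence, minOrfAa = 30L, contigId = "contig") {
  if (is(sequence, "DNAStringSet")) sequence <- as.character(sequence[[1]])
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  fwd <- .orfsOneStrand(sequence, minOrfAa)
  rev <- .orfsOneStrand(.revcompChar(sequence), minOrfAa)
  res <- list()
  if (!is.null(fwd)) {
    fwd$strand <- "+"
    res$fwd <- fwd
  }
  if (!is.null(rev)) {
    ## map coordinates from the reverse complement back to the forward
    ## sequence
    tmp <- rev
    tmp$strand <- "-"
    s <- L - rev$end + 1L
    e <- L - rev$start + 1L
    tmp$start <- s
    tmp$end <- e
    res$rev <- tmp
  }
  if (!length(res)) return(.emptyOrfTable())
  orfs <- do.call(rbind, res)
  orfs <- data.frame(contig_id = contigId, orfs[c("start", "end")],
                     strand = orfs$strand, length_aa = orfs$length_aa,
                     stringsAsFactors = FALSE)
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Does a contig encode at least one qualifying ORF?
#'
#' @param sequence Nucleotide string.
#' @param minOrfAa Minimum ORF length (aa).
#' @return Logical scalar.
#' @export
hasOrf <- function(sequence, minOrfAa = 30L) {
  nrow(scanOrfs(sequence, minOrfAa = minOrfAa)) > 0L
}
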