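mkTermContigs <- function(seqs) {
  ContigSet(Biostrings::DNAStringSet(seqs))
}

test_that("terminal windows, short contigs, and tail reverse complement", {
  set.seed(30)
  long <- randSeq(1000)
  short <- randSeq(30)
  cs <- mkTermContigs(c(a = long, b = short))
  term <- extractTermini(c("a", "b"), cs, windowNt = 50)
  expect_equal(term[["a"]]$head, substring(long, 1, 50))
  expect_equal(term[["a"]]$tail, substring(long, 951, 1000))
  expect_equal(term[["a"]]$tailRc,
               rcOracle(substring(long, 951, 1000)))
  expect_equal(term[["b"]]$head, short)  # whole sequence
  expect_equal(term[["b"]]$tail, short)
  expect_error(extractTermini("ghost", cs), "ghost")
})

test_that("reverse complement is an involution", {
  set.seed(31)
  for (i in 1:20) {
    s <- randSeq(sample(10:80, 1))
    expect_equal(rcOracle(rcOracle(s)), s)
  }
})

test_that("planted head motifs are recovered at fraction 1.0 with full length", {
  set.seed(32)
  for (k in c(8, 11, 13, 15)) {
    motif <- randSeq(k)
    seqs <- setNames(
      vapply(1:3, function(i) paste0(motif, randSeq(600)), character(1)),
      paste0("s", 1:3))
    cs <- mkTermContigs(seqs)
    term <- extractTermini(contigIds(cs), cs, windowNt = 50)
    hits <- findConservedMotifs(term, kRange = 6:15, minFraction = 1)
    five <- hits[hits$terminus == "five_prime", ]
    # the planted motif (or a superstring of it) is reported maximal
    expect_true(any(vapply(five$motif, function(m)
      grepl(motif, m, fixed = TRUE) || grepl(m, motif, fixed = TRUE),
      logical(1))))
    expect_true(any(five$fraction == 1 & nchar(five$motif) >= k))
  }
})

test_that("reverse-complementary termini produce a cross_rc hit", {
  set.seed(33)
  motif <- "AGATCGGAAGAGC"
  seqs <- setNames(vapply(1:3, function(i)
    paste0(motif, randSeq(500), rcOracle(motif)), character(1)),
    paste0("s", 1:3))
  term <- extractTermini(paste0("s", 1:3), mkTermContigs(seqs), 50)
  hits <- findConservedMotifs(term, kRange = 6:15, minFraction = 1)
  cross <- hits[hits$terminus == "cross_rc", ]
  expect_true(motif %in% cross$motif)
  expect_equal(cross$fraction[cross$motif == motif], 1)
})

test_that("the result is independent of segment input order", {
  set.seed(34)
  motif <- randSeq(10)
  seqs <- setNames(vapply(1:4, function(i)
    paste0(motif, randSeq(300)), character(1)), paste0("s", 1:4))
  cs <- mkTermContigs(seqs)
  t1 <- extractTermini(paste0("s", 1:4), cs, 50)
  t2 <- extractTermini(paste0("s", c(3, 1, 4, 2)), cs, 50)
  expect_identical(findConservedMotifs(t1, minFraction = 0.8),
                   findConservedMotifs(t2, minFraction = 0.8))
})

test_that("random independent termini produce no shared long motif", {
  set.seed(35)
  seqs <- setNames(vapply(1:3, function(i) randSeq(400), character(1)),
                   paste0("s", 1:3))
  term <- extractTermini(paste0("s", 1:3), mkTermContigs(seqs), 50)
  hits <- findConservedMotifs(term, kRange = 10:10, minFraction = 1)
  expect_equal(nrow(hits), 0L)
})

test_that("single-substitution tolerance rescues a ragged copy when enabled", {
  set.seed(36)
  motif <- "GGATCCTTAAGG"
  mutated <- paste0(substring(motif, 1, 5), "A", substring(motif, 7))
  seqs <- setNames(c(paste0(motif, randSeq(300)),
                     paste0(motif, randSeq(300)),
                     paste0(mutated, randSeq(300))), paste0("s", 1:3))
  term <- extractTermini(paste0("s", 1:3), mkTermContigs(seqs), 50)
  exact <- findConservedMotifs(term, kRange = 12:12, minFraction = 1)
  loose <- findConservedMotifs(term, kRange = 12:12, minFraction = 1,
                               maxMismatch = 1L)
  expect_false(motif %in% exact$motif)
  expect_true(motif %in% loose$motif)
})

test_that("the verification verdict follows fraction and length floors", {
  cl <- makeCluster("a", c("b", "c"))
  strong <- data.frame(motif = "AGATCGGAAGAGC", terminus = "five_prime",
                       segments_with_motif = 3L, segments_total = 3L,
                       fraction = 1.0, stringsAsFactors = FALSE)
  weakFrac <- transform(strong, fraction = 0.6)
  shortM <- transform(strong, motif = "AGATCGG")
  expect_equal(verifyCluster(cl, strong)@terminalSupport,
               "homology_independent_support")
  expect_equal(verifyCluster(cl, weakFrac)@terminalSupport,
               "no_terminal_support")
  expect_equal(verifyCluster(cl, shortM)@terminalSupport,
               "no_terminal_support")
  none <- verifyCluster(cl, strong[0, ])
  expect_equal(none@terminalSupport, "no_terminal_support")
})
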