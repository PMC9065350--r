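test_that("local_align handles identity and no-alignment cases", {
  x <- strrep("ACGTACGTACGT", 10)   # 120 bp
  a <- local_align(x, x)
  expect_equal(a$score, 120)
  expect_equal(c(a$a_start, a$a_end, a$b_start, a$b_end), c(1, 120, 1, 120))
  expect_equal(a$identity_pct, 100)

  expect_null(local_align(strrep("A", 100), strrep("C", 100)))
  expect_error(local_align("", "ACGT"), "nonempty")
})

test_that("N bases never count as matches", {
  a <- local_align("ACGTNNACGT", "ACGTNNACGT")
  # best alignment avoids paying for the NN mismatches: one 4-bp block
  expect_equal(a$score, 4)
  a2 <- local_align("ACGTACGTAANAACGTACGT", "ACGTACGTAANAACGTACGT")
  expect_lt(a2$identity_pct, 100)
})

test_that("local_align matches the independent DP oracle on block cases", {
  set.seed(101)
  x <- random_dna_str(200); y <- random_dna_str(200)
  z <- random_dna_str(300)
  # guard the junctions so neither shared block extends by a chance match
  substr(z, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(y, 1, 1))[1]
  substr(z, 300, 300) <- setdiff(c("A", "C", "G", "T"), substr(x, 200, 200))[1]
  a <- paste0(x, y)
  b <- paste0(x, z, y)
  aln <- local_align(a, b)
  expect_equal(aln$score, oracle_align_score(a, b))
  # the best single local alignment is one of the shared blocks, and the
  # tie between X and Y is broken toward the smaller start on A
  expect_equal(aln$a_start, 1)
  expect_equal(aln$b_start, 1)
  expect_equal(aln$score, 200)
})

test_that("local_align equals the oracle score on random short pairs", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(40:300, 1)
    core <- random_dna_str(n)
    a <- paste0(random_dna_str(sample(0:60, 1)), core,
                random_dna_str(sample(0:60, 1)))
    # partner shares the core with a few substitutions
    mut <- strsplit(core, "")[[1]]
    k <- sample(0:5, 1)
    if (k > 0) {
      pos <- sample(n, k)
      mut[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    b <- paste0(random_dna_str(sample(0:60, 1)), paste(mut, collapse = ""),
                random_dna_str(sample(0:60, 1)))
    aln <- local_align(a, b)
    sc <- if (is.null(aln)) 0 else aln$score
    expect_equal(sc, max(0, oracle_align_score(a, b)))
  }
})

test_that("find_hsps reports one full-length HSP for identical sequences", {
  set.seed(7)
  x <- random_dna_str(500)
  h <- find_hsps(x, x)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$qstart, h$qend, h$sstart, h$send), c(1L, 500L, 1L, 500L))
  expect_equal(h$strand, "plus")
  expect_equal(h$identity_pct, 100)
})

test_that("find_hsps splits around an inserted block into two HSPs", {
  set.seed(13)
  x <- random_dna_str(300); y <- random_dna_str(300)
  z <- random_dna_str(300)
  q <- paste0(x, y); s <- paste0(x, z, y)
  h <- find_hsps(q, s, qid = "q", sid = "s")
  hp <- h[h$strand == "plus", ]
  expect_equal(nrow(hp), 2L)
  # the two query intervals partition the query (masking allows no overlap)
  o <- order(hp$qstart)
  expect_equal(hp$qstart[o[1]], 1L)
  expect_equal(hp$qend[o[2]], 600L)
  expect_equal(hp$qstart[o[2]], hp$qend[o[1]] + 1L)
  # subject gap between the two intervals has the inserted block's length
  expect_equal(hp$sstart[o[2]] - hp$send[o[1]] - 1L, 300L)
})

test_that("find_hsps maps minus-strand hits back to plus coordinates", {
  set.seed(17)
  x <- random_dna_str(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  h <- find_hsps(x, rc)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "minus")
  expect_equal(c(h$qstart, h$qend, h$sstart, h$send), c(1L, 300L, 1L, 300L))
})

test_that("HSP existence is symmetric and scores transpose", {
  set.seed(23)
  for (i in 1:5) {
    a <- paste0(random_dna_str(100), random_dna_str(150))
    core <- random_dna_str(120)
    b <- paste0(random_dna_str(40), core, random_dna_str(40))
    a2 <- paste0(substr(a, 1, 80), core)
    hab <- find_hsps(a2, b)
    hba <- find_hsps(b, a2)
    expect_equal(nrow(hab) > 0, nrow(hba) > 0)
    if (nrow(hab) > 0) {
      expect_equal(sort(hab$score), sort(hba$score))
      expect_equal(hab$qstart[order(hab$score)],
                   hba$sstart[order(hba$score)])
    }
  }
})

test_that("reported HSP query intervals never overlap (masking soundness)", {
  set.seed(29)
  blocks <- replicate(4, random_dna_str(150))
  q <- paste(blocks, collapse = "")
  s <- paste(c(blocks[1], random_dna_str(200), blocks[2],
               random_dna_str(150), blocks[3], blocks[4]), collapse = "")
  h <- find_hsps(q, s)
  for (st in unique(h$strand)) {
    hh <- h[h$strand == st, ]
    if (nrow(hh) < 2) next
    o <- order(hh$qstart)
    expect_true(all(hh$qstart[o][-1] > hh$qend[o][-nrow(hh)]))
  }
})

test_that("minus-strand HSPs are the plus-strand HSPs of the revcomp subject", {
  set.seed(31)
  q <- random_dna_str(400)
  s <- paste0(random_dna_str(50),
              as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(substr(q, 101, 350)))),
              random_dna_str(50))
  h <- find_hsps(q, s)
  minus <- h[h$strand == "minus", ]
  src <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h2 <- find_hsps(q, src)
  plus2 <- h2[h2$strand == "plus", ]
  expect_equal(nrow(minus), nrow(plus2))
  slen <- nchar(s)
  expect_equal(sort(minus$qstart), sort(plus2$qstart))
  expect_equal(sort(slen - minus$send + 1L), sort(plus2$sstart))
})

test_that("all_vs_all covers every ordered pair and respects thresholds", {
  set.seed(37)
  x <- random_dna_str(400)
  tx <- c(t1 = x, t2 = x, t3 = x)
  h <- all_vs_all(tx)
  expect_equal(nrow(h), 6L)
  expect_true(all(h$qstart == 1L & h$qend == 400L))
  expect_error(all_vs_all(tx[1]), "at least 2")

  # unrelated sequences yield nothing above the thresholds
  tx2 <- c(a = random_dna_str(400), b = random_dna_str(400),
           c = random_dna_str(400))
  expect_equal(nrow(all_vs_all(tx2)), 0L)
})
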