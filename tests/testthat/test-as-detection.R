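mk_hsp <- function(qs, qe, ss, se, strand = "plus", qid = "t1", sid = "t2") {
  data.frame(qid = qid, sid = sid, identity_pct = 100,
             aln_len = qe - qs + 1L, mismatch = 0L, gapopen = 0L,
             qstart = as.integer(qs), qend = as.integer(qe),
             sstart = as.integer(ss), send = as.integer(se),
             strand = strand, score = qe - qs + 1,
             stringsAsFactors = FALSE)
}

test_that("a textbook exon-skipping configuration is classified", {
  h1 <- mk_hsp(1, 500, 1, 500)
  h2 <- mk_hsp(501, 1000, 801, 1300)
  ev <- classify_pair(h1, h2, qlen = 1000, slen = 1300)
  expect_equal(ev$continuous_role, "query")
  expect_equal(c(ev$gap_start, ev$gap_end, ev$gap_len), c(501, 801 - 1, 300))
  expect_equal(c(ev$flank5, ev$flank3), c(500, 500))
  expect_equal(ev$overlap_continuous, 0)
  expect_equal(ev$coverage_continuous, 1.0)
  # agrees with the literal criterion checker
  bf <- bf_classify_pair(h1, h2, 1000, 1300)
  expect_equal(ev, bf)
})

test_that("gap length and flank thresholds are applied at the boundary", {
  h1 <- mk_hsp(1, 500, 1, 500)
  # gap of exactly 100 fails "longer than 100 bp"
  expect_null(classify_pair(h1, mk_hsp(501, 1000, 601, 1100), 1000, 1100))
  # gap of 101 passes
  ev <- classify_pair(h1, mk_hsp(501, 1000, 602, 1101), 1000, 1101)
  expect_equal(ev$gap_len, 101)
  # flank of 99 fails "at least 100 bp away", 100 passes
  expect_null(classify_pair(mk_hsp(1, 99, 1, 99),
                            mk_hsp(100, 1000, 300, 1200), 1000, 1200))
  ev <- classify_pair(mk_hsp(1, 100, 1, 100),
                      mk_hsp(101, 1000, 301, 1200), 1000, 1200)
  expect_equal(ev$flank5, 100)
})

test_that("continuous-side overlap must be smaller than 5 bp", {
  h1 <- mk_hsp(1, 500, 1, 500)
  # overlap 5 on the query side: rejected
  expect_null(classify_pair(h1, mk_hsp(496, 1000, 801, 1305), 1000, 1305))
  # overlap 4: accepted
  ev <- classify_pair(h1, mk_hsp(497, 1000, 801, 1304), 1000, 1304)
  expect_equal(ev$overlap_continuous, 4)
  # a positive gap on the continuous side is rejected under defaults
  expect_null(classify_pair(h1, mk_hsp(502, 1000, 801, 1299), 1000, 1299))
  expect_false(is.null(classify_pair(h1, mk_hsp(502, 1000, 801, 1299),
                                     1000, 1299,
                                     as_params(max_gap_continuous = 1))))
})

test_that("strand disagreement and degenerate pairs yield no event", {
  h1 <- mk_hsp(1, 500, 1, 500)
  h2 <- mk_hsp(501, 1000, 801, 1300, strand = "minus")
  expect_null(classify_pair(h1, h2, 1000, 1300))
  expect_null(classify_pair(h1, h1, 1000, 1300))
  expect_error(classify_pair(h1, mk_hsp(1, 10, 1, 10, sid = "other"),
                             1000, 1300), "different")
})

test_that("minus-strand pairs are classified with plus-strand gap coords", {
  # subject is the reverse complement layout: the event geometry holds
  # after mapping subject positions through slen - pos + 1
  slen <- 1300
  h1 <- mk_hsp(1, 500, slen - 500 + 1, slen, strand = "minus")
  h2 <- mk_hsp(501, 1000, slen - 1300 + 1, slen - 801 + 1, strand = "minus")
  ev <- classify_pair(h1, h2, 1000, slen)
  expect_equal(ev$continuous_role, "query")
  expect_equal(ev$gap_len, 300)
  expect_equal(c(ev$gap_start, ev$gap_end), c(501, 800))
  expect_equal(ev, bf_classify_pair(h1, h2, 1000, slen))
})

test_that("subject-continuous configurations are detected", {
  # roles flipped: subject continuous, gap on the query
  h1 <- mk_hsp(1, 500, 1, 500)
  h2 <- mk_hsp(801, 1300, 501, 1000)
  ev <- classify_pair(h1, h2, qlen = 1300, slen = 1000)
  expect_equal(ev$continuous_role, "subject")
  expect_equal(c(ev$gap_start, ev$gap_end, ev$gap_len), c(501, 800, 300))
  expect_equal(ev, bf_classify_pair(h1, h2, 1300, 1000))
})

test_that("low continuous coverage is rejected", {
  # continuous query of length 1250 covered only 1000/1250 = 0.8
  h1 <- mk_hsp(1, 500, 1, 500)
  h2 <- mk_hsp(501, 1000, 801, 1300)
  expect_null(classify_pair(h1, h2, 1250, 1300))
  expect_false(is.null(classify_pair(
    h1, h2, 1250, 1300, as_params(min_continuous_coverage = 0.8))))
})

test_that("detect_events groups, deduplicates reciprocals, sorts", {
  h <- rbind(mk_hsp(1, 500, 1, 500), mk_hsp(501, 1000, 801, 1300),
             # transposed orientation of the same pair
             mk_hsp(1, 500, 1, 500, qid = "t2", sid = "t1"),
             mk_hsp(801, 1300, 501, 1000, qid = "t2", sid = "t1"))
  lens <- c(t1 = 1000, t2 = 1300)
  ev <- detect_events(h, lens)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gap_len, 300)
  expect_equal(ev, bf_detect_events(h, lens))

  expect_equal(nrow(detect_events(h[0, ], lens)), 0L)
  expect_equal(nrow(detect_events(h[1, , drop = FALSE], lens)), 0L)
  expect_error(detect_events(h, c(t1 = 1000)), "t2")
})

test_that("strict two-HSP mode ignores groups with extra HSPs", {
  h <- rbind(mk_hsp(1, 500, 1, 500), mk_hsp(501, 1000, 801, 1300),
             mk_hsp(10, 60, 700, 750))
  lens <- c(t1 = 1000, t2 = 1300)
  expect_equal(nrow(detect_events(h, lens)), 1L)
  expect_equal(nrow(detect_events(h, lens,
                                  as_params(require_exactly_two_hsps = TRUE))),
               0L)
})

test_that("detector agrees with the brute-force checker on random configs", {
  configs <- random_hsp_configs(800, seed = 4242)
  p <- as_params()
  mism <- 0L
  for (cf in configs) {
    ours <- detect_events(cf$hsps, c(q = cf$qlen, s = cf$slen), p)
    bf <- bf_detect_events(cf$hsps, c(q = cf$qlen, s = cf$slen), p)
    same <- nrow(ours) == nrow(bf) &&
      (nrow(ours) == 0 || isTRUE(all.equal(ours, bf, check.attributes = FALSE)))
    if (!same) mism <- mism + 1L
  }
  expect_equal(mism, 0L)
})

test_that("raising thresholds never increases the number of events", {
  configs <- random_hsp_configs(300, seed = 777)
  count_with <- function(p) {
    sum(vapply(configs, function(cf)
      nrow(detect_events(cf$hsps, c(q = cf$qlen, s = cf$slen), p)), 0L))
  }
  base <- count_with(as_params())
  expect_gt(base, 0)  # the generator produces some qualifying geometries
  expect_lte(count_with(as_params(min_as_gap = 120)), base)
  expect_lte(count_with(as_params(min_end_distance = 130)), base)
  expect_lte(count_with(as_params(min_as_gap = 200,
                                  min_end_distance = 200)), base)
})

test_that("transposing all HSPs yields the same canonical event set", {
  configs <- random_hsp_configs(200, seed = 999)
  for (cf in configs) {
    t_hsps <- cf$hsps
    t_hsps$qid <- cf$hsps$sid; t_hsps$sid <- cf$hsps$qid
    t_hsps$qstart <- cf$hsps$sstart; t_hsps$qend <- cf$hsps$send
    t_hsps$sstart <- cf$hsps$qstart; t_hsps$send <- cf$hsps$qend
    lens <- c(q = cf$qlen, s = cf$slen)
    a <- detect_events(cf$hsps, lens)
    b <- detect_events(t_hsps, lens)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0) {
      gapped_a <- ifelse(a$continuous_role == "query", a$sid, a$qid)
      gapped_b <- ifelse(b$continuous_role == "query", b$sid, b$qid)
      expect_equal(paste(gapped_a, a$gap_start, a$gap_end),
                   paste(gapped_b, b$gap_start, b$gap_end))
    }
  }
})
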