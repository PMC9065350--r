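# Independent oracles used across tests.
#
# bf_classify_pair / bf_detect_events re-check the four AS criteria by a
# literal, position-set-based enumeration, written independently of the
# package's detector. oracle_align_score provides an independent optimal
# local-alignment score via Biostrings' Smith-Waterman under the same
# scoring scheme (gap of length k costs open + k*ext).

bf_classify_pair <- function(h1, h2, qlen, slen, p = as_params()) {
  if (h1$strand != h2$strand) return(NULL)                 # criterion 1
  minus <- h1$strand == "minus"
  s_iv <- function(h) {
    if (minus) c(slen - h$send + 1, slen - h$sstart + 1)
    else c(h$sstart, h$send)
  }
  q_iv <- function(h) c(h$qstart, h$qend)
  for (role in c("query", "subject")) {
    if (role == "query") {
      cont <- list(q_iv(h1), q_iv(h2)); cont_len <- qlen
      gpd <- list(s_iv(h1), s_iv(h2)); gpd_len <- slen
    } else {
      cont <- list(s_iv(h1), s_iv(h2)); cont_len <- slen
      gpd <- list(q_iv(h1), q_iv(h2)); gpd_len <- qlen
    }
    # order the two HSPs along the continuous sequence (tie: gapped start)
    if (cont[[1]][1] > cont[[2]][1] ||
        (cont[[1]][1] == cont[[2]][1] && gpd[[1]][1] > gpd[[2]][1])) {
      cont <- rev(cont); gpd <- rev(gpd)
    }
    cont_pos <- unique(c(seq(cont[[1]][1], cont[[1]][2]),
                         seq(cont[[2]][1], cont[[2]][2])))
    overlap_pos <- intersect(seq(cont[[1]][1], cont[[1]][2]),
                             seq(cont[[2]][1], cont[[2]][2]))
    d_cont <- cont[[2]][1] - cont[[1]][2] - 1
    # criterion 2: continuous side abuts/overlaps a little; gapped side
    # leaves an ordered, disjoint gap of >= 1 bp
    if (d_cont > p$max_gap_continuous) next
    if (length(overlap_pos) > p$max_overlap_continuous) next
    gap_pos <- seq_len(gpd_len)
    gap_pos <- gap_pos[gap_pos > gpd[[1]][2] & gap_pos < gpd[[2]][1]]
    if (length(gap_pos) < 1) next
    if (gpd[[2]][1] <= gpd[[1]][2]) next
    # criterion 3
    coverage <- length(cont_pos) / cont_len
    if (coverage < p$min_continuous_coverage) next
    # criterion 4
    gap <- range(gap_pos)
    if (length(gap_pos) < p$min_as_gap) next
    if (gap[1] - 1 < p$min_end_distance) next
    if (gpd_len - gap[2] < p$min_end_distance) next
    # report on the plus strand of the gapped sequence
    if (minus && role == "query") {
      gap <- c(slen - gap[2] + 1, slen - gap[1] + 1)
    }
    return(data.frame(qid = h1$qid, sid = h1$sid, continuous_role = role,
                      gap_start = gap[1], gap_end = gap[2],
                      gap_len = length(gap_pos),
                      flank5 = gap[1] - 1, flank3 = gpd_len - gap[2],
                      overlap_continuous = length(overlap_pos),
                      coverage_continuous = coverage,
                      stringsAsFactors = FALSE))
  }
  NULL
}

bf_detect_events <- function(hsps, lengths, p = as_params()) {
  out <- list()
  if (nrow(hsps) > 0) {
    keys <- paste(hsps$qid, hsps$sid)
    for (key in unique(keys)) {
      idx <- which(keys == key)
      if (length(idx) < 2) next
      if (p$require_exactly_two_hsps && length(idx) != 2) next
      qlen <- lengths[[hsps$qid[idx[1]]]]
      slen <- lengths[[hsps$sid[idx[1]]]]
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a >= b) next
        ev <- bf_classify_pair(hsps[idx[a], ], hsps[idx[b], ],
                               qlen, slen, p)
        if (!is.null(ev)) out[[length(out) + 1]] <- ev
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(qid = character(), sid = character(),
                      continuous_role = character(), gap_start = integer(),
                      gap_end = integer(), gap_len = integer(),
                      flank5 = integer(), flank3 = integer(),
                      overlap_continuous = integer(),
                      coverage_continuous = numeric(),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  gapped <- ifelse(ev$continuous_role == "query", ev$sid, ev$qid)
  key <- paste(pmin(ev$qid, ev$sid), pmax(ev$qid, ev$sid), gapped,
               ev$gap_start, ev$gap_end)
  ev <- ev[!duplicated(key), , drop = FALSE]
  ev <- ev[order(ev$qid, ev$sid, ev$gap_start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# random two-HSP configurations; a mix of AS-like geometries jittered
# across the decision thresholds and fully random interval pairs
random_hsp_configs <- function(n, seed) {
  set.seed(seed)
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    strand <- sample(c("plus", "minus"), 1)
    if (i %% 2 == 0) {
      # AS-like: split query at a, insert a gap on the subject
      f1 <- sample(60:160, 1); f2 <- sample(60:160, 1)
      gap <- sample(70:140, 1)
      d <- sample(-7:3, 1)                      # continuous-side overlap/gap
      qlen <- f1 + f2
      slen <- f1 + gap + f2
      h1 <- list(qstart = 1L, qend = f1, sstart = 1L, send = f1)
      h2 <- list(qstart = f1 + 1L + d, qend = qlen,
                 sstart = f1 + gap + 1L, send = slen)
      if (h2$qstart < 1) h2$qstart <- 1L
    } else {
      qlen <- sample(300:900, 1); slen <- sample(300:900, 1)
      iv <- function(len) sort(sample.int(len, 2))
      a <- iv(qlen); b <- iv(slen); c2 <- iv(qlen); d2 <- iv(slen)
      h1 <- list(qstart = a[1], qend = a[2], sstart = b[1], send = b[2])
      h2 <- list(qstart = c2[1], qend = c2[2], sstart = d2[1], send = d2[2])
    }
    mk <- function(h, id) {
      data.frame(qid = "q", sid = "s", identity_pct = 100,
                 aln_len = h$qend - h$qstart + 1L, mismatch = 0L,
                 gapopen = 0L, qstart = h$qstart, qend = h$qend,
                 sstart = h$sstart, send = h$send, strand = strand,
                 score = h$qend - h$qstart + 1,
                 stringsAsFactors = FALSE)
    }
    configs[[i]] <- list(hsps = rbind(mk(h1), mk(h2)),
                         qlen = qlen, slen = slen)
  }
  configs
}

# Vectorized variant of random_hsp_configs for large-scale oracle
# comparisons: returns one pooled HSP data frame (two HSPs per
# configuration, distinct ids per configuration) plus the lengths
# vector. Even-numbered configurations are AS-like geometries jittered
# across the thresholds, odd-numbered ones fully random interval pairs.
pooled_hsp_configs <- function(n, seed) {
  set.seed(seed)
  qid <- sprintf("q%05d", seq_len(n))
  sid <- sprintf("s%05d", seq_len(n))
  strand <- sample(c("plus", "minus"), n, replace = TRUE)
  as_like <- seq_len(n) %% 2 == 0
  f1 <- sample(60:160, n, replace = TRUE)
  f2 <- sample(60:160, n, replace = TRUE)
  gap <- sample(70:140, n, replace = TRUE)
  d <- sample(-7:3, n, replace = TRUE)
  qlen <- ifelse(as_like, f1 + f2, sample(300:900, n, replace = TRUE))
  slen <- ifelse(as_like, f1 + gap + f2, sample(300:900, n, replace = TRUE))
  q1s <- rep(1L, n); q1e <- f1; s1s <- rep(1L, n); s1e <- f1
  q2s <- pmax(f1 + 1L + d, 1L); q2e <- qlen
  s2s <- f1 + gap + 1L; s2e <- slen
  ri <- function(len) {
    a <- ceiling(runif(n) * len); b <- ceiling(runif(n) * len)
    list(lo = pmin(a, b), hi = pmax(a, b))
  }
  A <- ri(qlen); B <- ri(slen); C <- ri(qlen); D <- ri(slen)
  k <- which(!as_like)
  q1s[k] <- A$lo[k]; q1e[k] <- A$hi[k]
  s1s[k] <- B$lo[k]; s1e[k] <- B$hi[k]
  q2s[k] <- C$lo[k]; q2e[k] <- C$hi[k]
  s2s[k] <- D$lo[k]; s2e[k] <- D$hi[k]
  ord <- c(seq_len(n) * 2L - 1L, seq_len(n) * 2L)   # interleave h1/h2
  qs <- c(q1s, q2s); qe <- c(q1e, q2e)
  ss <- c(s1s, s2s); se <- c(s1e, s2e)
  pick <- c(seq_len(n), seq_len(n))
  hsps <- data.frame(qid = qid[pick], sid = sid[pick], identity_pct = 100,
                     aln_len = qe - qs + 1L, mismatch = 0L, gapopen = 0L,
                     qstart = as.integer(qs), qend = as.integer(qe),
                     sstart = as.integer(ss), send = as.integer(se),
                     strand = strand[pick], score = qe - qs + 1,
                     stringsAsFactors = FALSE)
  hsps <- hsps[order(ord), , drop = FALSE]
  rownames(hsps) <- NULL
  list(hsps = hsps,
       lengths = setNames(c(qlen, slen), c(qid, sid)))
}

# independent optimal local alignment score (same scheme: gap of length
# k costs open + k * ext) via Biostrings
oracle_align_score <- function(a, b, params = align_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match_score, mismatch = params$mismatch_score,
    baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend,
    scoreOnly = TRUE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
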