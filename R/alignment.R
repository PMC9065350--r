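#' Alignment parameter set
#'
#' Scoring and reporting parameters for the internal local aligner that
#' emulates a high-identity nucleotide BLAST search. A gap of length k
#' costs `gap_open + k * gap_extend`.
#'
#' @param match_score Score for a match (positive). N never matches.
#' @param mismatch_score Score for a mismatch (negative).
#' @param gap_open Gap opening penalty (negative).
#' @param gap_extend Per-base gap extension penalty (negative).
#' @param min_hsp_score Minimum score for a reported HSP.
#' @param min_hsp_len Minimum alignment length (columns) for a reported
#'   HSP.
#' @param min_identity_pct Minimum percent identity for a reported HSP.
#' @param max_hsps_per_pair Maximum number of HSPs reported per ordered
#'   sequence pair and strand search.
#' @param search_minus_strand Also search the reverse complement of the
#'   subject.
#' @param max_gap_per_hsp Longest gap run (bp) allowed inside a single
#'   HSP; an optimal local alignment containing a longer gap is split at
#'   that gap into separate HSPs. This mirrors the behavior of heuristic
#'   aligners, whose X-drop termination prevents one HSP from bridging a
#'   long indel, and is what makes a skipped exon appear as two HSPs
#'   rather than one gapped alignment.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match_score = 1L, mismatch_score = -2L,
                         gap_open = -5L, gap_extend = -2L,
                         min_hsp_score = 50, min_hsp_len = 50L,
                         min_identity_pct = 90, max_hsps_per_pair = 10L,
                         search_minus_strand = TRUE,
                         max_gap_per_hsp = 50L) {
  stopifnot(match_score > 0, mismatch_score < 0, gap_open < 0,
            gap_extend < 0, min_hsp_score > 0, min_hsp_len > 0,
            min_identity_pct > 0, min_identity_pct <= 100,
            max_hsps_per_pair >= 1, max_gap_per_hsp >= 1)
  structure(list(match_score = as.integer(match_score),
                 mismatch_score = as.integer(mismatch_score),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_hsp_score = min_hsp_score,
                 min_hsp_len = as.integer(min_hsp_len),
                 min_identity_pct = min_identity_pct,
                 max_hsps_per_pair = as.integer(max_hsps_per_pair),
                 search_minus_strand = isTRUE(search_minus_strand),
                 max_gap_per_hsp = as.integer(max_gap_per_hsp)),
            class = "align_params")
}

#' Optimal local alignment of two sequences
#'
#' Exact affine-gap Smith-Waterman. Returns the maximal-score local
#' alignment; ties are broken by the smallest start on `seq_a`, then the
#' smallest start on `seq_b`, then the smallest end. N bases never count
#' as matches.
#'
#' @param seq_a,seq_b Nucleotide strings (nonempty).
#' @param params An [align_params()] object (only the scoring fields are
#'   used).
#' @return `NULL` if no alignment scores above 0, else a list with
#'   `score`, `a_start`, `a_end`, `b_start`, `b_end`, `aln_len`
#'   (columns), `n_match`, `identity_pct`, and `ops` (per-column codes:
#'   0 match, 1 mismatch, 2 gap in B, 3 gap in A).
#' @export
local_align <- function(seq_a, seq_b, params = align_params()) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stop("sequences must be nonempty")
  r <- .sw_align(seq_a, seq_b, params$match_score, params$mismatch_score,
                 params$gap_open, params$gap_extend)
  if (r$score <= 0) return(NULL)
  n_match <- sum(r$ops == 0)
  list(score = r$score,
       a_start = r$a_start, a_end = r$a_end,
       b_start = r$b_start, b_end = r$b_end,
       aln_len = length(r$ops), n_match = n_match,
       identity_pct = 100 * n_match / length(r$ops),
       ops = r$ops)
}

# Split one optimal alignment into HSP pieces at gap runs longer than
# max_gap. Pieces always begin and end on aligned (match/mismatch)
# columns because the Gotoh recurrence never places opposite gap runs
# adjacently. Returns a list of piece records with recomputed scores.
split_alignment <- function(aln, max_gap, params) {
  ops <- aln$ops
  r <- rle(ops)
  cut <- r$values >= 2 & r$lengths > max_gap
  # assign each run to a piece, bumping the index after every cut run
  pid <- integer(length(r$values)); cur <- 1L
  for (k in seq_along(r$values)) {
    if (cut[k]) { pid[k] <- NA_integer_; cur <- cur + 1L }
    else pid[k] <- cur
  }
  piece_id <- rep.int(pid, r$lengths)
  a_adv <- cumsum(ops != 3)   # columns advancing on A
  b_adv <- cumsum(ops != 2)   # columns advancing on B
  pieces <- list()
  for (p in unique(piece_id[!is.na(piece_id)])) {
    idx <- which(piece_id == p)
    po <- ops[idx]
    i0 <- idx[1]; i1 <- idx[length(idx)]
    a_before <- if (i0 == 1) 0L else a_adv[i0 - 1]
    b_before <- if (i0 == 1) 0L else b_adv[i0 - 1]
    n_match <- sum(po == 0); n_mis <- sum(po == 1)
    pr <- rle(po); gap_runs <- pr$lengths[pr$values >= 2]
    score <- n_match * params$match_score + n_mis * params$mismatch_score +
      length(gap_runs) * params$gap_open +
      sum(gap_runs) * params$gap_extend
    pieces[[length(pieces) + 1]] <- list(
      a_start = aln$a_start + a_before,
      a_end = aln$a_start - 1L + a_adv[i1],
      b_start = aln$b_start + b_before,
      b_end = aln$b_start - 1L + b_adv[i1],
      score = score, aln_len = length(po), n_match = n_match,
      n_mismatch = n_mis, gapopen = length(gap_runs),
      identity_pct = 100 * n_match / length(po))
  }
  pieces
}

# iterative HSP extraction on one subject orientation; returns a list of
# piece records with query coordinates on the full query and subject
# coordinates on the oriented subject
find_hsps_strand <- function(qseq, sseq, params) {
  qlen <- nchar(qseq)
  segments <- list(list(lo = 1L, hi = qlen, aln = NULL, done = FALSE))
  hsps <- list()
  repeat {
    if (length(hsps) >= params$max_hsps_per_pair) break
    # (re)compute best alignment for segments lacking one
    for (k in seq_along(segments)) {
      seg <- segments[[k]]
      if (seg$done || !is.null(seg$aln)) next
      if (seg$hi - seg$lo + 1 < params$min_hsp_len) {
        segments[[k]]$done <- TRUE; next
      }
      aln <- local_align(substr(qseq, seg$lo, seg$hi), sseq, params)
      if (is.null(aln) || aln$score < params$min_hsp_score) {
        segments[[k]]$done <- TRUE
      } else {
        aln$a_start <- aln$a_start + seg$lo - 1L
        aln$a_end <- aln$a_end + seg$lo - 1L
        segments[[k]]$aln <- aln
      }
    }
    live <- which(!vapply(segments, `[[`, TRUE, "done"))
    if (length(live) == 0) break
    # best segment by score, ties by smallest query then subject start
    scores <- vapply(segments[live], function(s) s$aln$score, 0)
    astarts <- vapply(segments[live], function(s) s$aln$a_start, 0)
    bstarts <- vapply(segments[live], function(s) s$aln$b_start, 0)
    o <- order(-scores, astarts, bstarts)[1]
    k <- live[o]
    aln <- segments[[k]]$aln
    pieces <- split_alignment(aln, params$max_gap_per_hsp, params)
    pass <- Filter(function(p) {
      p$score >= params$min_hsp_score && p$aln_len >= params$min_hsp_len &&
        p$identity_pct >= params$min_identity_pct
    }, pieces)
    if (length(pass) == 0) break
    room <- params$max_hsps_per_pair - length(hsps)
    hsps <- c(hsps, pass[seq_len(min(room, length(pass)))])
    # mask the consumed query interval of the full alignment
    seg <- segments[[k]]
    segments[[k]] <- list(lo = seg$lo, hi = aln$a_start - 1L, aln = NULL,
                          done = FALSE)
    segments[[length(segments) + 1]] <- list(lo = aln$a_end + 1L,
                                             hi = seg$hi, aln = NULL,
                                             done = FALSE)
  }
  hsps
}

#' Find HSPs between a query and a subject sequence
#'
#' Emulates a high-identity pairwise BLAST search: iteratively extracts
#' the best remaining local alignment, reports it as one or more HSPs
#' (splitting at gap runs longer than `max_gap_per_hsp`), masks the
#' consumed query interval, and repeats. When `search_minus_strand` is
#' set, the procedure is repeated against the reverse complement of the
#' subject and those HSPs are reported with `strand = "minus"` and
#' subject coordinates mapped back to the plus strand (`sstart <=
#' send`).
#'
#' @param query,subject Nucleotide strings (or length-1 `DNAStringSet`).
#' @param params An [align_params()] object.
#' @param qid,sid Ids recorded in the output (defaults: names of the
#'   inputs if present, else "query"/"subject").
#' @return An HSP data frame (possibly 0-row) sorted by descending
#'   score, with columns `qid, sid, identity_pct, aln_len, mismatch,
#'   gapopen, qstart, qend, sstart, send, strand, score`.
#' @export
find_hsps <- function(query, subject, params = align_params(),
                      qid = NULL, sid = NULL) {
  if (is.null(qid)) qid <- if (!is.null(names(query))) names(query)[1] else "query"
  if (is.null(sid)) sid <- if (!is.null(names(subject))) names(subject)[1] else "subject"
  qseq <- toupper(as.character(query)[1])
  sseq <- toupper(as.character(subject)[1])
  slen <- nchar(sseq)

  piece_row <- function(p, strand) {
    if (strand == "plus") { ss <- p$b_start; se <- p$b_end }
    else { ss <- slen - p$b_end + 1L; se <- slen - p$b_start + 1L }
    data.frame(qid = qid, sid = sid, identity_pct = p$identity_pct,
               aln_len = p$aln_len, mismatch = p$n_mismatch,
               gapopen = p$gapopen, qstart = p$a_start, qend = p$a_end,
               sstart = ss, send = se, strand = strand, score = p$score,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(find_hsps_strand(qseq, sseq, params), piece_row, "plus")
  if (params$search_minus_strand) {
    rc <- reverse_complement(sseq)
    rows <- c(rows, lapply(find_hsps_strand(qseq, rc, params),
                           piece_row, "minus"))
  }
  if (length(rows) == 0) return(empty_hsp_df())
  df <- do.call(rbind, rows)
  df[order(-df$score, df$qstart, df$sstart), , drop = FALSE]
}

#' All-vs-all HSP search over a transcript collection
#'
#' Runs [find_hsps()] for every ordered pair of distinct transcripts.
#'
#' @param transcripts A `DNAStringSet` or named character vector with at
#'   least 2 elements.
#' @param params An [align_params()] object.
#' @return Combined HSP data frame.
#' @export
all_vs_all <- function(transcripts, params = align_params()) {
  seqs <- as_transcripts(transcripts)
  if (length(seqs) < 2) stop("need at least 2 transcripts")
  ids <- names(seqs)
  out <- list()
  for (q in ids) for (s in ids) {
    if (q == s) next
    out[[length(out) + 1]] <- find_hsps(seqs[[q]], seqs[[s]], params,
                                        qid = q, sid = s)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcript lengths from a collection
#' @param transcripts A `DNAStringSet` or named character vector.
#' @return Named integer vector of lengths.
#' @export
transcript_lengths <- function(transcripts) {
  seqs <- as_transcripts(transcripts)
  setNames(nchar(seqs), names(seqs))
}
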