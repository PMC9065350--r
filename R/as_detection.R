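#' Alternative-splicing detection parameters
#'
#' Thresholds for classifying a two-HSP alignment configuration as a
#' candidate alternative-splicing event. Defaults encode the published
#' criteria: the continuous sequence may show only a small overlap
#' between its two HSPs (smaller than 5 bp, i.e. at most 4), the AS gap
#' must be longer than 100 bp (at least 101) and lie at least 100 bp
#' from either end of the gapped sequence, and the continuous sequence
#' must be almost completely covered by the two HSPs (the quantification
#' of "almost completely", 0.95, is this package's choice).
#'
#' @param max_overlap_continuous Maximum overlap (bp) of the two HSP
#'   intervals on the continuous sequence.
#' @param max_gap_continuous Maximum gap (bp) allowed between the two
#'   HSP intervals on the continuous sequence (0 = they must abut or
#'   overlap).
#' @param min_as_gap Minimum AS gap length (bp).
#' @param min_end_distance Minimum distance (bp) from the gap to either
#'   end of the gapped sequence.
#' @param min_continuous_coverage Minimum fraction of the continuous
#'   sequence covered by the union of the two HSP intervals.
#' @param require_exactly_two_hsps If `TRUE`, only (query, subject)
#'   groups with exactly two HSPs are considered, the literal reading of
#'   "two HSPs exist in the same alignment"; by default all HSP pairs
#'   within a group are tested.
#' @return A list of class `as_params`.
#' @export
as_params <- function(max_overlap_continuous = 4L,
                      max_gap_continuous = 0L,
                      min_as_gap = 101L,
                      min_end_distance = 100L,
                      min_continuous_coverage = 0.95,
                      require_exactly_two_hsps = FALSE) {
  stopifnot(max_overlap_continuous >= 0, max_gap_continuous >= 0,
            min_as_gap >= 0, min_end_distance >= 0,
            min_continuous_coverage > 0, min_continuous_coverage <= 1)
  structure(list(max_overlap_continuous = as.integer(max_overlap_continuous),
                 max_gap_continuous = as.integer(max_gap_continuous),
                 min_as_gap = as.integer(min_as_gap),
                 min_end_distance = as.integer(min_end_distance),
                 min_continuous_coverage = min_continuous_coverage,
                 require_exactly_two_hsps = isTRUE(require_exactly_two_hsps)),
            class = "as_params")
}

# evaluate one role assignment; cont/gap intervals are 2-column matrices
# [hsp, c(start,end)] in a uniform (plus-mapped) coordinate space
.eval_role <- function(cont, gapped, cont_len, gapped_len, params) {
  o <- order(cont[, 1], gapped[, 1])
  cont <- cont[o, , drop = FALSE]; gapped <- gapped[o, , drop = FALSE]
  d_cont <- cont[2, 1] - cont[1, 2] - 1L
  if (d_cont > params$max_gap_continuous) return(NULL)
  overlap <- max(0L, -d_cont)
  if (overlap > params$max_overlap_continuous) return(NULL)
  # gapped intervals must be disjoint and in the same relative order
  if (gapped[2, 1] <= gapped[1, 2] + 1L) return(NULL)
  gap <- c(gapped[1, 2] + 1L, gapped[2, 1] - 1L)
  gap_len <- gap[2] - gap[1] + 1L
  inter <- max(0L, min(cont[1, 2], cont[2, 2]) -
                 max(cont[1, 1], cont[2, 1]) + 1L)
  covered <- (cont[1, 2] - cont[1, 1] + 1L) +
    (cont[2, 2] - cont[2, 1] + 1L) - inter
  coverage <- covered / cont_len
  if (coverage < params$min_continuous_coverage) return(NULL)
  flank5 <- gap[1] - 1L
  flank3 <- gapped_len - gap[2]
  if (gap_len < params$min_as_gap || flank5 < params$min_end_distance ||
      flank3 < params$min_end_distance) return(NULL)
  list(gap = gap, gap_len = gap_len, flank5 = flank5, flank3 = flank3,
       overlap = overlap, coverage = coverage)
}

#' Classify a pair of HSPs as a candidate AS event
#'
#' Applies the four published criteria to one HSP pair: (1) both HSPs on
#' the same strand; (2) one sequence continuous (overlap < 5 bp or
#' abutting) while the HSP intervals on the other sequence leave a gap —
#' the AS gap; (3) the continuous sequence almost completely covered by
#' the two HSPs; (4) the AS gap longer than 100 bp and at least 100 bp
#' from both ends of the gapped sequence. Both role assignments are
#' evaluated; if both qualify the query-continuous reading is reported.
#' For minus-strand pairs subject coordinates are mapped through
#' `slen - pos + 1` so ordering is uniform; reported gap coordinates are
#' on the plus strand of the gapped sequence.
#'
#' @param hsp1,hsp2 Single HSP records (one-row data frames or lists)
#'   sharing `qid` and `sid`.
#' @param qlen,slen Full lengths of the query and subject transcripts.
#' @param params An [as_params()] object.
#' @return A one-row event data frame, or `NULL` if the pair does not
#'   qualify.
#' @export
classify_pair <- function(hsp1, hsp2, qlen, slen, params = as_params()) {
  if (hsp1$qid != hsp2$qid || hsp1$sid != hsp2$sid)
    stop("HSPs belong to different sequence pairs: (", hsp1$qid, ",",
         hsp1$sid, ") vs (", hsp2$qid, ",", hsp2$sid, ")")
  if (hsp1$strand != hsp2$strand) return(NULL)            # criterion 1
  minus <- hsp1$strand == "minus"
  q <- rbind(c(hsp1$qstart, hsp1$qend), c(hsp2$qstart, hsp2$qend))
  if (minus) {
    s <- rbind(c(slen - hsp1$send + 1L, slen - hsp1$sstart + 1L),
               c(slen - hsp2$send + 1L, slen - hsp2$sstart + 1L))
  } else {
    s <- rbind(c(hsp1$sstart, hsp1$send), c(hsp2$sstart, hsp2$send))
  }
  if (all(q[1, ] == q[2, ]) && all(s[1, ] == s[2, ])) return(NULL)

  build <- function(res, role) {
    gap <- res$gap
    # the query is never strand-mapped, so only a subject-side gap from a
    # minus-strand pair needs mapping back to plus coordinates
    if (role == "query" && minus) {
      # gap is on the subject in mapped space; map back to plus strand
      gap <- c(slen - res$gap[2] + 1L, slen - res$gap[1] + 1L)
      gapped_len <- slen
      res$flank5 <- gap[1] - 1L
      res$flank3 <- gapped_len - gap[2]
    }
    data.frame(qid = hsp1$qid, sid = hsp1$sid, continuous_role = role,
               gap_start = gap[1], gap_end = gap[2], gap_len = res$gap_len,
               flank5 = res$flank5, flank3 = res$flank3,
               overlap_continuous = res$overlap,
               coverage_continuous = res$coverage,
               stringsAsFactors = FALSE)
  }
  res <- .eval_role(q, s, qlen, slen, params)
  if (!is.null(res)) return(build(res, "query"))
  res <- .eval_role(s, q, slen, qlen, params)
  if (!is.null(res)) return(build(res, "subject"))
  NULL
}

#' Detect AS events from a collection of HSPs
#'
#' Groups HSPs by ordered (qid, sid) pair, tests HSP pairs within each
#' group with [classify_pair()], and deduplicates events reported from
#' both orientations of the same transcript pair by a canonical key
#' (lexicographically smaller id first, plus the gap interval on the
#' gapped sequence).
#'
#' @param hsps HSP data frame ([find_hsps()], [all_vs_all()] or
#'   [read_blast_tabular()] output).
#' @param lengths Named vector of transcript lengths covering every id
#'   in `hsps` (see [transcript_lengths()]).
#' @param params An [as_params()] object.
#' @return Event data frame sorted by (qid, sid, gap_start); 0-row when
#'   nothing qualifies.
#' @export
detect_events <- function(hsps, lengths, params = as_params()) {
  empty <- data.frame(qid = character(), sid = character(),
                      continuous_role = character(), gap_start = integer(),
                      gap_end = integer(), gap_len = integer(),
                      flank5 = integer(), flank3 = integer(),
                      overlap_continuous = integer(),
                      coverage_continuous = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(hsps) || nrow(hsps) == 0) return(empty)
  need <- unique(c(hsps$qid, hsps$sid))
  missing <- setdiff(need, names(lengths))
  if (length(missing) > 0)
    stop("no length provided for transcript(s): ",
         paste(missing, collapse = ", "))
  groups <- split(seq_len(nrow(hsps)), paste0(hsps$qid, "\r", hsps$sid))
  out <- list()
  for (idx in groups) {
    if (length(idx) < 2) next
    if (params$require_exactly_two_hsps && length(idx) != 2) next
    qlen <- lengths[[hsps$qid[idx[1]]]]
    slen <- lengths[[hsps$sid[idx[1]]]]
    prs <- combn(idx, 2)
    for (k in seq_len(ncol(prs))) {
      ev <- classify_pair(hsps[prs[1, k], ], hsps[prs[2, k], ],
                          qlen, slen, params)
      if (!is.null(ev)) out[[length(out) + 1]] <- ev
    }
  }
  if (length(out) == 0) return(empty)
  ev <- do.call(rbind, out)
  gapped_id <- ifelse(ev$continuous_role == "query", ev$sid, ev$qid)
  key <- paste(pmin(ev$qid, ev$sid), pmax(ev$qid, ev$sid), gapped_id,
               ev$gap_start, ev$gap_end, sep = "\r")
  ev <- ev[!duplicated(key), , drop = FALSE]
  ev <- ev[order(ev$qid, ev$sid, ev$gap_start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
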