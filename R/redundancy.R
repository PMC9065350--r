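#' Redundancy clustering parameters
#'
#' Thresholds replicating the CD-HIT parameterization used for
#' transcript redundancy removal: `-c 0.95 -G 0 -aL 0.00 -aS 0.99`,
#' i.e. local-alignment identity at least 0.95, at least 99% of the
#' shorter sequence aligned, and no constraint on coverage of the longer
#' sequence.
#'
#' @param identity_threshold Minimum local-alignment identity
#'   (identical columns / alignment columns) for a member to join a
#'   cluster (CD-HIT `-c`).
#' @param coverage_shorter Minimum aligned fraction of the shorter
#'   sequence (CD-HIT `-aS`).
#' @param coverage_longer Minimum aligned fraction of the longer
#'   sequence (CD-HIT `-aL`); 0 disables the constraint.
#' @param best_fit If `TRUE`, a transcript joins the qualifying cluster
#'   with the highest identity instead of the first-founded one.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.95,
                           coverage_shorter = 0.99,
                           coverage_longer = 0.0,
                           best_fit = FALSE) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 1,
            coverage_shorter >= 0, coverage_shorter <= 1,
            coverage_longer >= 0, coverage_longer <= 1)
  structure(list(identity_threshold = identity_threshold,
                 coverage_shorter = coverage_shorter,
                 coverage_longer = coverage_longer,
                 best_fit = isTRUE(best_fit)),
            class = "cluster_params")
}

#' Identity and coverage between two transcripts
#'
#' Computes the best local alignment between the two sequences and
#' returns alignment-column identity together with the aligned span as
#' a fraction of each sequence (the quantities CD-HIT's `-c`, `-aS` and
#' `-aL` thresholds act on, under its local `-G 0` mode).
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param aln_params An [align_params()] object (scoring fields only).
#' @return List with `identity`, `coverage_shorter`, `coverage_longer`
#'   (all fractions; all 0 when no positive-scoring alignment exists).
#' @export
pair_identity_coverage <- function(seq_a, seq_b,
                                   aln_params = align_params()) {
  aln <- local_align(seq_a, seq_b, aln_params)
  if (is.null(aln))
    return(list(identity = 0, coverage_shorter = 0, coverage_longer = 0))
  la <- nchar(seq_a); lb <- nchar(seq_b)
  span_a <- (aln$a_end - aln$a_start + 1) / la
  span_b <- (aln$b_end - aln$b_start + 1) / lb
  if (la <= lb) {
    cs <- span_a; cl <- span_b
  } else {
    cs <- span_b; cl <- span_a
  }
  list(identity = aln$n_match / aln$aln_len,
       coverage_shorter = cs, coverage_longer = cl)
}

#' Greedy redundancy clustering of transcripts
#'
#' CD-HIT-style greedy clustering: transcripts are sorted by descending
#' length (ties by ascending id); the first unassigned transcript founds
#' a cluster and becomes its representative; each subsequent transcript
#' joins the first existing cluster whose representative it matches at
#' the identity/coverage thresholds, otherwise founds its own. Input
#' order never affects the result because of the canonical sort.
#'
#' @param transcripts A `DNAStringSet` or named character vector
#'   (nonempty).
#' @param params A [cluster_params()] object.
#' @param aln_params An [align_params()] object for the pairwise
#'   alignments.
#' @return A list with `members` (data frame: cluster_id,
#'   representative, member, identity, coverage_shorter; one row per
#'   transcript, representatives included with identity and coverage 1)
#'   and `representatives` (named character vector, the non-redundant
#'   set in cluster order).
#' @export
cluster_greedy <- function(transcripts, params = cluster_params(),
                           aln_params = align_params()) {
  seqs <- as_transcripts(transcripts)
  if (length(seqs) == 0) stop("no transcripts to cluster")
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  reps <- character(0)
  rows <- list()
  for (i in ord) {
    id <- ids[i]
    hit <- 0L; hit_iden <- NA_real_; hit_cov <- NA_real_
    for (k in seq_along(reps)) {
      pc <- pair_identity_coverage(seqs[[reps[k]]], seqs[[id]], aln_params)
      ok <- pc$identity >= params$identity_threshold &&
        pc$coverage_shorter >= params$coverage_shorter &&
        pc$coverage_longer >= params$coverage_longer
      if (ok) {
        if (!params$best_fit) {
          hit <- k; hit_iden <- pc$identity; hit_cov <- pc$coverage_shorter
          break
        }
        if (hit == 0L || pc$identity > hit_iden) {
          hit <- k; hit_iden <- pc$identity; hit_cov <- pc$coverage_shorter
        }
      }
    }
    if (hit == 0L) {
      reps <- c(reps, id)
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = length(reps), representative = id, member = id,
        identity = 1, coverage_shorter = 1, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = hit, representative = reps[hit], member = id,
        identity = hit_iden, coverage_shorter = hit_cov,
        stringsAsFactors = FALSE)
    }
  }
  members <- do.call(rbind, rows)
  members <- members[order(members$cluster_id, members$member), ,
                     drop = FALSE]
  rownames(members) <- NULL
  list(members = members, representatives = seqs[reps])
}
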