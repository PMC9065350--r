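#' Filter reads by length and accuracy
#'
#' Excludes read fragments shorter than `min_len` bp or with accuracy
#' below `min_accuracy` (both thresholds read strictly on the exclusion
#' side: a 50 bp read at accuracy 0.75 is kept). Reads without an
#' accuracy value pass the accuracy filter.
#'
#' @param reads Data frame with columns `id`, `length`, and optionally
#'   `accuracy` (NA allowed, treated as passing).
#' @param min_len Minimum length in bp.
#' @param min_accuracy Minimum accuracy fraction.
#' @return List with `kept` and `removed` data frames; the partition
#'   preserves input order.
#' @export
filter_reads <- function(reads, min_len = 50, min_accuracy = 0.75) {
  if (any(reads$length < 0)) stop("negative read length")
  if (!is.null(reads$accuracy) &&
      any(!is.na(reads$accuracy) &
            (reads$accuracy < 0 | reads$accuracy > 1)))
    stop("accuracy must be in [0, 1]")
  acc_ok <- if (is.null(reads$accuracy)) TRUE
            else is.na(reads$accuracy) | reads$accuracy >= min_accuracy
  keep <- reads$length >= min_len & acc_ok
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Length statistics for a read or transcript set
#'
#' Computes count, total bases, truncated mean length, N50, minimum and
#' maximum. N50 is the largest length L in the set such that reads of
#' length >= L together contain at least half of all bases (sort
#' descending, accumulate, first length at which the running sum reaches
#' half the total). The mean is truncated (floor), the convention
#' implied by published per-library summaries.
#'
#' @param lengths Nonempty numeric vector of lengths (bp).
#' @return List with `n`, `total_bases`, `mean_len`, `n50`, `min_len`,
#'   `max_len`.
#' @export
length_stats <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list")
  if (any(lengths < 0)) stop("negative length")
  total <- sum(as.numeric(lengths))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= total / 2)[1]]
  list(n = length(lengths), total_bases = total,
       mean_len = floor(total / length(lengths)), n50 = n50,
       min_len = min(lengths), max_len = max(lengths))
}

#' Per-library sequencing-run summary
#'
#' Derives the summary statistics a per-library run table prints from
#' its raw totals: the truncated mean subread length
#' `floor(total_bases / n_subreads)` per library, and grand totals of
#' subreads and polymerase reads across libraries. A run table with the
#' expected columns ships with the package (see
#' `system.file("extdata", "pacbio_run_stats.tsv", package = "isokit")`).
#'
#' @param stats Data frame with columns `library`, `polymerase_reads`,
#'   `total_subread_bases`, `subread_count`.
#' @return List with `per_library` (the input plus a `mean_subread_len`
#'   column), `total_subreads`, and `total_polymerase_reads`.
#' @export
run_summary <- function(stats) {
  need <- c("library", "polymerase_reads", "total_subread_bases",
            "subread_count")
  missing <- setdiff(need, names(stats))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  stats$mean_subread_len <- floor(stats$total_subread_bases /
                                    stats$subread_count)
  list(per_library = stats,
       total_subreads = sum(stats$subread_count),
       total_polymerase_reads = sum(stats$polymerase_reads))
}
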