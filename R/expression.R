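#' Convert a fragment count matrix to FPKM
#'
#' FPKM (fragments per kilobase of transcript per million mapped
#' fragments) normalizes counts for transcript length and sequencing
#' depth: `FPKM[i,j] = counts[i,j] * 1e9 / (column_total[j] *
#' length[i])`, where the column total is the number of mapped fragments
#' in that sample's count column.
#'
#' @param counts Nonnegative numeric matrix, transcripts x samples, with
#'   row (transcript) and column (sample) names.
#' @param lengths Transcript lengths in bp: either a named vector
#'   covering all row names, or an unnamed vector aligned with the rows.
#' @return FPKM matrix with the same dimnames.
#' @examples
#' m <- matrix(c(100, 0, 200, 50), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' fpkm(m, c(t1 = 1000, t2 = 500))
#' @export
fpkm <- function(counts, lengths) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row and column names")
  if (any(counts < 0)) stop("negative counts")
  if (!is.null(names(lengths))) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing) > 0)
      stop("no length for transcript(s): ", paste(missing, collapse = ", "))
    lengths <- lengths[rownames(counts)]
  } else if (length(lengths) != nrow(counts)) {
    stop("lengths must be named or match the number of rows")
  }
  if (any(lengths < 1)) stop("transcript lengths must be >= 1")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("zero column total for sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(sweep(counts, 2, totals, "/"), 1, as.numeric(lengths), "/") * 1e9
}

#' Pairwise Pearson correlation between samples
#'
#' Pearson r between the sample columns of an expression matrix,
#' optionally after a `log10(x + pseudocount)` transform (the default,
#' matching how replicate-correlation heatmaps are usually drawn for
#' FPKM). Columns with zero variance yield NA correlations rather than
#' 0.
#'
#' @param mat Numeric matrix, transcripts x samples.
#' @param log_transform Apply `log10(x + pseudocount)` first.
#' @param pseudocount Added before the log transform.
#' @return Symmetric sample x sample matrix of Pearson r with unit
#'   diagonal (NA where undefined).
#' @export
sample_correlation <- function(mat, log_transform = TRUE, pseudocount = 1) {
  if (ncol(mat) < 2 || nrow(mat) < 2)
    stop("need at least 2 samples and 2 transcripts")
  m <- if (log_transform) log10(mat + pseudocount) else mat
  suppressWarnings(cor(m, method = "pearson"))
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Within each (gene, tissue), `dCt = mean(ct_target) -
#' mean(ct_reference)` over replicates (reference = the housekeeping
#' gene's Ct measured alongside the target). Then `ddCt = dCt_tissue -
#' dCt_calibrator` and relative expression `= 2^(-ddCt)`, so the
#' calibrator tissue maps to exactly 1 for every gene.
#'
#' @param ct Data frame with columns `gene`, `tissue`, `ct_target`,
#'   `ct_reference` (one row per replicate).
#' @param calibrator Name of the calibrator tissue; must be present for
#'   every gene.
#' @return Data frame with columns `gene`, `tissue`, `d_ct`, `dd_ct`,
#'   `rel_expr`, sorted by (gene, tissue).
#' @export
ddct <- function(ct, calibrator) {
  need <- c("gene", "tissue", "ct_target", "ct_reference")
  missing <- setdiff(need, names(ct))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(ct$ct_target)) || any(is.na(ct$ct_reference)))
    stop("missing Ct value(s)")
  if (any(ct$ct_target <= 0) || any(ct$ct_reference <= 0))
    stop("Ct values must be positive")
  agg <- aggregate(cbind(ct_target, ct_reference) ~ gene + tissue,
                   data = ct, FUN = mean)
  agg$d_ct <- agg$ct_target - agg$ct_reference
  cal <- agg[agg$tissue == calibrator, c("gene", "d_ct")]
  missing_cal <- setdiff(unique(agg$gene), cal$gene)
  if (length(missing_cal) > 0)
    stop("calibrator tissue '", calibrator, "' missing for gene(s): ",
         paste(missing_cal, collapse = ", "))
  names(cal)[2] <- "d_ct_cal"
  out <- merge(agg, cal, by = "gene")
  out$dd_ct <- out$d_ct - out$d_ct_cal
  out$rel_expr <- 2^(-out$dd_ct)
  out <- out[order(out$gene, out$tissue),
             c("gene", "tissue", "d_ct", "dd_ct", "rel_expr")]
  rownames(out) <- NULL
  out
}

#' Pivot a long qPCR Ct table into target/reference form
#'
#' Takes measurements of target genes and a housekeeping reference gene
#' recorded as separate rows (columns `gene`, `tissue`, `replicate`,
#' `ct`) and pairs each target replicate with the reference Ct of the
#' same tissue and replicate.
#'
#' @param ct_long Long-format data frame with columns `gene`, `tissue`,
#'   `replicate`, `ct`.
#' @param reference_gene Name of the housekeeping gene.
#' @return Data frame with columns `gene`, `tissue`, `replicate`,
#'   `ct_target`, `ct_reference`, suitable for [ddct()].
#' @export
prepare_ct <- function(ct_long, reference_gene) {
  need <- c("gene", "tissue", "replicate", "ct")
  missing <- setdiff(need, names(ct_long))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  ref <- ct_long[ct_long$gene == reference_gene, ]
  if (nrow(ref) == 0)
    stop("reference gene '", reference_gene, "' not found")
  tgt <- ct_long[ct_long$gene != reference_gene, ]
  names(ref)[names(ref) == "ct"] <- "ct_reference"
  names(tgt)[names(tgt) == "ct"] <- "ct_target"
  out <- merge(tgt, ref[, c("tissue", "replicate", "ct_reference")],
               by = c("tissue", "replicate"))
  if (any(is.na(out$ct_reference)))
    stop("missing reference Ct for some tissue/replicate")
  out[order(out$gene, out$tissue, out$replicate),
      c("gene", "tissue", "replicate", "ct_target", "ct_reference")]
}
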