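#' Read transcripts from a FASTA file
#'
#' Parses a (multi-line) FASTA file into a [Biostrings::DNAStringSet].
#' The record id is the header token up to the first whitespace; sequences
#' are uppercased. Only A, C, G, T and N are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 some description", "acgtACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  seqs <- as_transcripts(setNames(as.character(x), names(x)))
  Biostrings::DNAStringSet(seqs)
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(transcripts, path, width = 70L) {
  seqs <- as_transcripts(transcripts)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = as.integer(width))
  invisible(path)
}

#' Read pairwise alignments in 12-column BLAST tabular format
#'
#' Reads the standard `outfmt 6` layout (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). Comment
#' lines starting with `#` are skipped. When a data line has
#' `sstart > send` the subject interval is swapped and the HSP is marked
#' as minus strand, so stored coordinates always satisfy
#' `sstart <= send`.
#'
#' @param path Path to a tab-separated alignment file.
#' @return A data frame of HSPs with columns `qid, sid, identity_pct,
#'   aln_len, mismatch, gapopen, qstart, qend, sstart, send, strand,
#'   score`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_hsp_df())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 12)) {
    bad <- which(ncols != 12)[1]
    stop("line ", lineno[bad], ": expected 12 tab-separated columns, found ",
         ncols[bad])
  }
  mat <- do.call(rbind, parts)
  num <- function(col, name, integer = FALSE) {
    v <- suppressWarnings(as.numeric(mat[, col]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      stop("line ", lineno[bad], ": non-numeric ", name, ": ",
           mat[bad, col])
    }
    if (integer) as.integer(v) else v
  }
  sstart_raw <- num(9, "sstart", TRUE)
  send_raw <- num(10, "send", TRUE)
  minus <- sstart_raw > send_raw
  df <- data.frame(
    qid = mat[, 1], sid = mat[, 2],
    identity_pct = num(3, "pident"),
    aln_len = num(4, "length", TRUE),
    mismatch = num(5, "mismatch", TRUE),
    gapopen = num(6, "gapopen", TRUE),
    qstart = num(7, "qstart", TRUE), qend = num(8, "qend", TRUE),
    sstart = ifelse(minus, send_raw, sstart_raw),
    send = ifelse(minus, sstart_raw, send_raw),
    strand = ifelse(minus, "minus", "plus"),
    score = num(12, "bitscore"),
    stringsAsFactors = FALSE
  )
  if (any(df$qstart > df$qend)) {
    bad <- which(df$qstart > df$qend)[1]
    stop("line ", lineno[bad], ": qstart > qend")
  }
  if (any(df$identity_pct < 0 | df$identity_pct > 100)) {
    bad <- which(df$identity_pct < 0 | df$identity_pct > 100)[1]
    stop("line ", lineno[bad], ": identity out of [0,100]")
  }
  df
}

empty_hsp_df <- function() {
  data.frame(qid = character(), sid = character(),
             identity_pct = numeric(), aln_len = integer(),
             mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             strand = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Write HSPs as 12-column BLAST tabular
#'
#' Minus-strand HSPs are serialized with `sstart > send`, the BLAST
#' convention, so `read_blast_tabular()` round-trips orientation. The
#' e-value column is written as 0 (the internal aligner computes no
#' e-value statistics).
#'
#' @param hsps HSP data frame as produced by [find_hsps()] or
#'   [read_blast_tabular()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hsps_tsv <- function(hsps, path) {
  minus <- hsps$strand == "minus"
  out <- data.frame(
    hsps$qid, hsps$sid, sprintf("%.3f", hsps$identity_pct), hsps$aln_len,
    if (is.null(hsps$mismatch)) 0L else hsps$mismatch,
    if (is.null(hsps$gapopen)) 0L else hsps$gapopen,
    hsps$qstart, hsps$qend,
    ifelse(minus, hsps$send, hsps$sstart),
    ifelse(minus, hsps$sstart, hsps$send),
    0, hsps$score, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write detected AS events to TSV
#'
#' Columns: qid, sid, continuous_role, gap_start, gap_end, gap_len,
#' flank5, flank3, overlap_continuous, coverage_continuous. Rows are
#' sorted by (qid, sid, gap_start).
#'
#' @param events Event data frame from [detect_events()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("qid", "sid", "continuous_role", "gap_start", "gap_end",
            "gap_len", "flank5", "flank3", "overlap_continuous",
            "coverage_continuous")
  ev <- events[, cols, drop = FALSE]
  if (nrow(ev) > 0)
    ev <- ev[order(ev$qid, ev$sid, ev$gap_start), , drop = FALSE]
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events TSV written by [write_events_tsv()]
#' @param path Input path.
#' @return Event data frame.
#' @export
read_events_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write redundancy clusters to TSV
#'
#' Columns: cluster_id, representative, member, identity,
#' coverage_shorter; one row per member (representatives included with
#' identity and coverage 1). Rows sorted by (cluster_id, member).
#'
#' @param clusters Cluster list from [cluster_greedy()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- clusters$members
  df <- df[order(df$cluster_id, df$member), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a transcript-by-sample numeric matrix to TSV
#'
#' First column `transcript_id`, remaining columns one per sample. Rows
#' are written sorted by transcript id so output is deterministic.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have row (transcript) and column (sample) names")
  m <- m[order(rownames(m)), , drop = FALSE]
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript-by-sample matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Numeric matrix with transcript ids as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
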