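#' Generate a random multi-exon gene model
#'
#' Draws exon and intron sequences uniformly over {A,C,G,T} using R's
#' default Mersenne-Twister generator seeded with `seed`; the caller's
#' RNG state is untouched and regeneration with the same arguments is
#' byte-identical. Lengths are drawn uniformly from the given inclusive
#' ranges.
#'
#' @param n_exons Number of exons (>= 2).
#' @param exon_len_range,intron_len_range Length-2 vectors `c(lo, hi)`
#'   of positive inclusive bounds in bp.
#' @param seed Integer seed.
#' @return A list of class `gene_model` with `exon_seqs`, `intron_seqs`
#'   (length `n_exons - 1`), and `seed`.
#' @export
make_gene <- function(n_exons, exon_len_range, intron_len_range, seed) {
  if (n_exons < 2) stop("a gene model needs at least 2 exons")
  check_range <- function(r, what) {
    if (length(r) != 2 || any(r < 1) || r[1] > r[2])
      stop("invalid ", what, " length range")
  }
  check_range(exon_len_range, "exon")
  check_range(intron_len_range, "intron")
  with_seed(seed, {
    draw_lens <- function(r, k)   # safe for degenerate ranges (lo == hi)
      r[1] + sample.int(r[2] - r[1] + 1L, k, replace = TRUE) - 1L
    exon_lens <- draw_lens(exon_len_range, n_exons)
    intron_lens <- draw_lens(intron_len_range, n_exons - 1)
    structure(list(exon_seqs = vapply(exon_lens, random_dna, ""),
                   intron_seqs = vapply(intron_lens, random_dna, ""),
                   seed = as.integer(seed)),
              class = "gene_model")
  })
}

#' Build an isoform pair with known AS ground truth
#'
#' From a gene model, constructs two mature isoforms differing by one
#' alternative-splicing event, plus a truth record locating the implied
#' AS gap.
#'
#' For `exon_skipping`, isoform A is all exons concatenated and isoform
#' B omits the target (internal) exon; the gap is the target exon's
#' interval within A. For `intron_retention`, isoform A is all exons
#' and isoform B retains the target intron; the gap is the intron's
#' interval within B. `detectable` reflects the detector thresholds:
#' gap length >= `min_as_gap` and both flanks >= `min_end_distance` on
#' the gapped isoform.
#'
#' @param gene A [make_gene()] model.
#' @param event_type `"exon_skipping"` or `"intron_retention"`.
#' @param target_index Index of the skipped exon (must be internal:
#'   2 .. n_exons-1) or of the retained intron (1 .. n_exons-1).
#' @param min_as_gap,min_end_distance Detectability thresholds (defaults
#'   match [as_params()]).
#' @param mutation_rate Optional per-base substitution rate applied to
#'   the shorter isoform, to stress alignment robustness; 0 (default)
#'   keeps shared blocks mutation-free so HSP boundaries are exact.
#' @return List with `transcripts` (named character vector of the two
#'   isoforms, A first) and `truth` (one-row data frame: isoform_a,
#'   isoform_b, event_type, gapped_isoform, gap_len, gap_start,
#'   gap_end, detectable).
#' @export
make_isoform_pair <- function(gene, event_type = c("exon_skipping",
                                                   "intron_retention"),
                              target_index,
                              min_as_gap = 101L, min_end_distance = 100L,
                              mutation_rate = 0) {
  event_type <- match.arg(event_type)
  n <- length(gene$exon_seqs)
  exon_lens <- nchar(gene$exon_seqs)
  iso_a <- paste(gene$exon_seqs, collapse = "")
  base <- paste0("gene", gene$seed)
  if (event_type == "exon_skipping") {
    if (target_index < 2 || target_index > n - 1)
      stop("can only skip an internal exon (index 2..", n - 1, ")")
    iso_b <- paste(gene$exon_seqs[-target_index], collapse = "")
    gap_start <- sum(exon_lens[seq_len(target_index - 1)]) + 1L
    gap_len <- exon_lens[target_index]
    gapped_iso <- "a"
    gapped_len <- nchar(iso_a)
    id_b <- paste0(base, "_skip", target_index)
  } else {
    if (target_index < 1 || target_index > n - 1)
      stop("intron index must be in 1..", n - 1)
    parts <- gene$exon_seqs[1]
    for (k in seq(2, n)) {
      if (k - 1 == target_index) parts <- c(parts, gene$intron_seqs[k - 1])
      parts <- c(parts, gene$exon_seqs[k])
    }
    iso_b <- paste(parts, collapse = "")
    gap_start <- sum(exon_lens[seq_len(target_index)]) + 1L
    gap_len <- nchar(gene$intron_seqs[target_index])
    gapped_iso <- "b"
    gapped_len <- nchar(iso_b)
    id_b <- paste0(base, "_ir", target_index)
  }
  gap_end <- gap_start + gap_len - 1L
  id_a <- paste0(base, "_full")
  detectable <- gap_len >= min_as_gap &&
    (gap_start - 1L) >= min_end_distance &&
    (gapped_len - gap_end) >= min_end_distance
  if (mutation_rate > 0) {
    iso_b <- with_seed(gene$seed + 1L, mutate_seq(iso_b, mutation_rate))
  }
  list(transcripts = setNames(c(iso_a, iso_b), c(id_a, id_b)),
       truth = data.frame(isoform_a = id_a, isoform_b = id_b,
                          event_type = event_type,
                          gapped_isoform = gapped_iso,
                          gap_len = gap_len, gap_start = gap_start,
                          gap_end = gap_end, detectable = detectable,
                          stringsAsFactors = FALSE))
}

# substitute bases at the given per-base rate (always to a different base)
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a fragment count matrix
#'
#' Draws per-transcript mean expression log-uniformly over
#' `mean_range`, then counts per sample from a negative binomial with
#' that mean and the given dispersion (variance `mu + dispersion *
#' mu^2`); `dispersion = 0` is the deterministic limit where every
#' count equals its rounded mean. Transcript lengths are drawn
#' uniformly from `length_range`.
#'
#' @param n_transcripts,n_samples Positive dimensions.
#' @param seed Integer seed (caller RNG state is preserved).
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @param mean_range,length_range Length-2 positive ranges.
#' @return List with `counts` (matrix, transcripts x samples) and
#'   `lengths` (named integer vector).
#' @export
simulate_counts <- function(n_transcripts, n_samples, seed,
                            dispersion = 0.1, mean_range = c(5, 500),
                            length_range = c(500L, 3000L)) {
  stopifnot(n_transcripts >= 1, n_samples >= 1, dispersion >= 0,
            all(mean_range > 0), all(length_range >= 1))
  with_seed(seed, {
    ids <- sprintf("t%03d", seq_len(n_transcripts))
    samples <- sprintf("s%02d", seq_len(n_samples))
    mu <- exp(runif(n_transcripts, log(mean_range[1]), log(mean_range[2])))
    counts <- if (dispersion == 0) {
      matrix(rep(round(mu), n_samples), ncol = n_samples)
    } else {
      matrix(rnbinom(n_transcripts * n_samples, mu = rep(mu, n_samples),
                     size = 1 / dispersion),
             ncol = n_samples)
    }
    dimnames(counts) <- list(ids, samples)
    lengths <- setNames(length_range[1] +
                          sample.int(length_range[2] - length_range[1] + 1L,
                                     n_transcripts, replace = TRUE) - 1L,
                        ids)
    list(counts = counts, lengths = lengths)
  })
}

# Could a local alignment extend across a block junction?
# a and b are the two continuations past the junction (element-wise
# comparison, no gaps). A prefix with positive running score makes the
# extended alignment strictly better; a prefix with zero score makes it
# tie, and the smallest-start tie-break can then still prefer the
# extended one — so both are rejected.
.walk_extends <- function(a, b, match = 1, mismatch = -2) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(FALSE)
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  any(cumsum(ifelse(av == bv, match, mismatch)) >= 0)
}

.rev_str <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# TRUE iff neither flanking HSP of the excision C = pre+post of
# G = pre+gap+post can be extended across its true boundary: the
# prefix HSP extends by comparing gap vs post, the suffix HSP by
# comparing reversed gap vs reversed pre.
.junctions_forced <- function(gap_seq, pre, post) {
  !.walk_extends(gap_seq, post) &&
    !.walk_extends(.rev_str(gap_seq), .rev_str(pre))
}

#' Simulate a batch of isoform pairs with ground truth
#'
#' Convenience wrapper generating `n_genes` gene models (seeds `seed`,
#' `seed + 1`, ...), one isoform pair each, pooling transcripts and
#' truth records. Exon skipping always targets exon 2 of a 3-exon gene;
#' intron retention targets intron 1.
#'
#' The gap segment (skipped exon or retained intron) is redrawn by
#' seeded rejection sampling until a score-walk check certifies that no
#' local alignment can extend a shared-block HSP across a true block
#' boundary (chance homology at a junction would otherwise shift HSP
#' ends by a few bases). This makes HSP boundaries — and therefore
#' detected gap coordinates — exactly equal to the truth record for
#' mutation-free pairs.
#'
#' @param n_genes Number of gene models.
#' @param event_type Passed to [make_isoform_pair()].
#' @param seed Base seed.
#' @param exon_len_range,intron_len_range Passed to [make_gene()].
#' @param mutation_rate Passed to [make_isoform_pair()].
#' @return List with `transcripts` (named character vector) and `truth`
#'   (data frame, one row per pair).
#' @export
simulate_isoforms <- function(n_genes, event_type = "exon_skipping",
                              seed = 1L,
                              exon_len_range = c(200L, 400L),
                              intron_len_range = c(150L, 350L),
                              mutation_rate = 0) {
  stopifnot(n_genes >= 1)
  transcripts <- character(0)
  truth <- list()
  for (g in seq_len(n_genes)) {
    gene <- make_gene(3, exon_len_range, intron_len_range,
                      seed = seed + g - 1L)
    target <- if (event_type == "exon_skipping") 2L else 1L
    for (attempt in seq_len(100L)) {
      pair <- make_isoform_pair(gene, event_type, target)
      tr <- pair$truth
      gseq <- pair$transcripts[[if (tr$gapped_isoform == "a") 1L else 2L]]
      gap_seq <- substr(gseq, tr$gap_start, tr$gap_end)
      pre <- substr(gseq, 1L, tr$gap_start - 1L)
      post <- substr(gseq, tr$gap_end + 1L, nchar(gseq))
      if (.junctions_forced(gap_seq, pre, post)) break
      redrawn <- with_seed(gene$seed + 100003L * attempt, {
        if (event_type == "exon_skipping") {
          random_dna(nchar(gene$exon_seqs[target]))
        } else {
          random_dna(nchar(gene$intron_seqs[target]))
        }
      })
      if (event_type == "exon_skipping") {
        gene$exon_seqs[target] <- redrawn
      } else {
        gene$intron_seqs[target] <- redrawn
      }
    }
    if (mutation_rate > 0) {
      pair <- make_isoform_pair(gene, event_type, target,
                                mutation_rate = mutation_rate)
    }
    transcripts <- c(transcripts, pair$transcripts)
    truth[[g]] <- pair$truth
  }
  list(transcripts = transcripts, truth = do.call(rbind, truth))
}
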