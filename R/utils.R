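# internal helpers shared across modules

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards. All stochastic generators in the package route
# through this so results are reproducible and side-effect free.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# uniform random DNA string (uses current RNG state; callers seed it)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# coerce a transcript collection (DNAStringSet or named character vector)
# to a named uppercase character vector, validating ids
as_transcripts <- function(x) {
  if (methods::is(x, "XStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x)) {
    seqs <- x
  } else {
    stop("transcripts must be a DNAStringSet or a named character vector")
  }
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop("every transcript must have a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(grepl("\\s", ids)))
    stop("transcript ids must not contain whitespace")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for transcript(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nchar(bad) > 0)) {
    letters_found <- sort(unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
    stop("non-ACGTN character(s) in sequences: ",
         paste(letters_found, collapse = ", "))
  }
  seqs
}
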