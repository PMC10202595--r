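# Shared fixture builders (all fixtures are generated in code).

# one individual, one population; noise off unless asked for
clean_config <- function(seed, n_loci = 50L, depth = 25L, het_rate = 0.2,
                         ...) {
  sim_config(
    seed = seed,
    n_populations = 1L, n_individuals_per_pop = 1L,
    n_loci = n_loci, het_rate = het_rate, divergence = 0,
    mda_sigma = 0, dropout_prob = 0,
    contamination_frac = 0, pcr_dup_rate = 0, seq_error_rate = 0,
    reads_per_sample = n_loci * depth,
    ...
  )
}

# strip the inline barcode from simulated read-1 sequences
trim_barcode <- function(reads, config) {
  substr(reads$seq1, config$barcode_length + 1L, config$read_length)
}

# the read-1 window of every truth haplotype (what the assembler can see)
truth_windows <- function(truth, individual = NULL) {
  h <- truth$haplotypes
  if (!is.null(individual)) {
    h <- h[h$individual_id == individual, , drop = FALSE]
  }
  win <- truth$config$read_length - truth$config$barcode_length
  h$window <- substr(h$seq, 1L, win)
  h
}

# a quality string of uniform Phred score `q`
qual_string <- function(q, len) {
  strrep(intToUtf8(q + 33L), len)
}

# minimal hand-built read table
toy_reads <- function(seq1, seq2 = NULL, q = 37L) {
  n <- length(seq1)
  seq2 <- seq2 %||% vapply(seq1, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  tibble::tibble(
    read_id = sprintf("toy_%03d", seq_len(n)),
    seq1 = seq1,
    qual1 = vapply(seq1, function(s) qual_string(q, nchar(s)), character(1L),
      USE.NAMES = FALSE
    ),
    seq2 = seq2,
    qual2 = vapply(seq2, function(s) qual_string(q, nchar(s)), character(1L),
      USE.NAMES = FALSE
    ),
    insert = rep(400L, n)
  )
}

`%||%` <- rlang::`%||%`
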