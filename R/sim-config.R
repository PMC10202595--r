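#' Configuration for the SAG-RAD read simulator
#'
#' Collects every parameter of the synthetic experiment: population design,
#' library geometry, amplification-bias model and sequencing noise. The
#' defaults follow the single-digest RAD protocol the package emulates:
#' 7-bp inline barcodes, an SbfI cut-site remnant at the start of read 1,
#' 150-bp paired-end reads, and insert sizes centred on 400 bp with size
#' selection to 300-600 bp.
#'
#' Each individual is a diploid genome of `n_loci` RAD loci. Each locus
#' haplotype begins with the 6-bp SbfI remnant `TGCAGG` (SbfI recognises
#' CCTGCAGG and cleaves after the A, so the barcode-adjacent read-through is
#' TGCAGG). Individuals can be sequenced several times: `n_replicates`
#' single-cell (MDA-amplified) libraries and `n_bulk_replicates` bulk
#' libraries per individual. Bulk libraries are simulated without
#' amplification bias (`mda_sigma` and `dropout_prob` forced to zero), as if
#' prepared from many clonal cells.
#'
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param n_populations Number of diverged demes.
#' @param n_individuals_per_pop Diploid individuals per deme.
#' @param n_replicates Single-cell (MDA) libraries per individual.
#' @param n_bulk_replicates Bulk libraries per individual (no MDA bias).
#' @param n_loci Number of RAD loci per genome.
#' @param locus_length Haplotype length in bp; must cover the longest
#'   insert minus the barcode so read 2 never runs off the locus.
#' @param het_rate Fraction of loci heterozygous per individual.
#' @param divergence Per-site substitution probability between a population
#'   and the ancestral sequence.
#' @param mda_sigma Lognormal shape (sdlog) of the per-locus amplification
#'   factor; 0 means perfectly uniform amplification.
#' @param dropout_prob Probability that one allele of a heterozygous locus
#'   receives zero amplification (allelic dropout).
#' @param contamination_frac Fraction of read pairs drawn from a
#'   contaminant genome lacking the cut-site remnant.
#' @param pcr_dup_rate Fraction of read pairs that are exact PCR copies of
#'   another pair (same sequences and insert length).
#' @param reads_per_sample Read pairs emitted per library.
#' @param read_length Read length in bp (both mates).
#' @param insert_mean,insert_min,insert_max Insert-size model: a normal
#'   centred on `insert_mean` with sd chosen so that at least 99% of its
#'   mass lies in `[insert_min, insert_max]`, then clipped to that range.
#' @param barcode_length Inline barcode length in bp.
#' @param seq_error_rate Per-base substitution error probability.
#' @param cutsite_remnant Cut-site remnant expected at the start of every
#'   target read 1 after barcode removal.
#' @return A list of class `sagrad_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_loci = 50, reads_per_sample = 500)
#' cfg$n_loci
sim_config <- function(seed,
                       n_populations = 3L,
                       n_individuals_per_pop = 4L,
                       n_replicates = 1L,
                       n_bulk_replicates = 0L,
                       n_loci = 200L,
                       locus_length = 600L,
                       het_rate = 0.05,
                       divergence = 0.02,
                       mda_sigma = 1,
                       dropout_prob = 0.2,
                       contamination_frac = 0.05,
                       pcr_dup_rate = 0.1,
                       reads_per_sample = 5000L,
                       read_length = 150L,
                       insert_mean = 400L,
                       insert_min = 300L,
                       insert_max = 600L,
                       barcode_length = 7L,
                       seq_error_rate = 0.001,
                       cutsite_remnant = "TGCAGG") {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer.",
      class = "sagrad_config_error"
    )
  }
  cfg <- list(
    seed = as.integer(seed),
    n_populations = as.integer(n_populations),
    n_individuals_per_pop = as.integer(n_individuals_per_pop),
    n_replicates = as.integer(n_replicates),
    n_bulk_replicates = as.integer(n_bulk_replicates),
    n_loci = as.integer(n_loci),
    locus_length = as.integer(locus_length),
    het_rate = het_rate,
    divergence = divergence,
    mda_sigma = mda_sigma,
    dropout_prob = dropout_prob,
    contamination_frac = contamination_frac,
    pcr_dup_rate = pcr_dup_rate,
    reads_per_sample = as.integer(reads_per_sample),
    read_length = as.integer(read_length),
    insert_mean = as.integer(insert_mean),
    insert_min = as.integer(insert_min),
    insert_max = as.integer(insert_max),
    barcode_length = as.integer(barcode_length),
    seq_error_rate = seq_error_rate,
    cutsite_remnant = toupper(cutsite_remnant)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sagrad_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) abort(msg, class = "sagrad_config_error")
  fracs <- c(
    "het_rate", "divergence", "dropout_prob", "contamination_frac",
    "pcr_dup_rate", "seq_error_rate"
  )
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      bad(sprintf("`%s` must be a single number in [0, 1] (got %s).", f, format(v)))
    }
  }
  counts <- c(
    "n_populations", "n_individuals_per_pop", "n_replicates",
    "n_loci", "locus_length", "reads_per_sample", "read_length",
    "insert_mean", "insert_min", "insert_max", "barcode_length"
  )
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1L) {
      bad(sprintf("`%s` must be a positive count.", f))
    }
  }
  if (cfg$n_bulk_replicates < 0L) bad("`n_bulk_replicates` must be >= 0.")
  if (cfg$n_replicates + cfg$n_bulk_replicates < 1L) {
    bad("At least one replicate (single-cell or bulk) per individual is required.")
  }
  if (cfg$mda_sigma < 0) bad("`mda_sigma` must be >= 0.")
  if (cfg$insert_min > cfg$insert_mean || cfg$insert_mean > cfg$insert_max) {
    bad("Insert sizes must satisfy insert_min <= insert_mean <= insert_max.")
  }
  if (cfg$insert_min < cfg$read_length) {
    bad("`insert_min` must be >= `read_length` so mates do not read through each other.")
  }
  if (cfg$locus_length < cfg$read_length) {
    bad("`locus_length` must be >= `read_length`.")
  }
  if (cfg$locus_length < cfg$insert_max - cfg$barcode_length) {
    bad("`locus_length` must be >= insert_max - barcode_length so read 2 stays on the locus.")
  }
  if (cfg$barcode_length >= cfg$read_length) {
    bad("`barcode_length` must be smaller than `read_length`.")
  }
  if (nchar(cfg$cutsite_remnant) + cfg$barcode_length >= cfg$read_length) {
    bad("Cut-site remnant plus barcode must fit inside read 1.")
  }
  invisible(cfg)
}

#' @export
print.sagrad_config <- function(x, ...) {
  n_samples <- x$n_populations * x$n_individuals_per_pop *
    (x$n_replicates + x$n_bulk_replicates)
  cat(sprintf(
    paste0(
      "<sagrad_config> %d population(s) x %d individual(s), %d loci, ",
      "%d librar%s (%d single-cell + %d bulk per individual)\n"
    ),
    x$n_populations, x$n_individuals_per_pop, x$n_loci,
    n_samples, if (n_samples == 1L) "y" else "ies",
    x$n_replicates, x$n_bulk_replicates
  ))
  cat(sprintf(
    "  reads/sample %d, read length %d, insert %d [%d-%d], barcode %d bp\n",
    x$reads_per_sample, x$read_length, x$insert_mean, x$insert_min,
    x$insert_max, x$barcode_length
  ))
  cat(sprintf(
    "  het %.3g, divergence %.3g, mda_sigma %.3g, dropout %.3g, contam %.3g, dup %.3g, err %.3g, seed %d\n",
    x$het_rate, x$divergence, x$mda_sigma, x$dropout_prob,
    x$contamination_frac, x$pcr_dup_rate, x$seq_error_rate, x$seed
  ))
  invisible(x)
}

#' Generate a deterministic set of inline barcodes
#'
#' Greedily selects barcodes with pairwise Hamming distance at least
#' `min_dist` from a fixed pseudo-random enumeration of all sequences of
#' the given length, so one-mismatch barcode rescue is always unambiguous.
#' The enumeration is deterministic and independent of the RNG state.
#'
#' @param n Number of barcodes required.
#' @param length Barcode length in bp.
#' @param min_dist Minimum pairwise Hamming distance.
#' @return Character vector of `n` barcodes.
#' @export
#' @examples
#' generate_barcodes(4)
generate_barcodes <- function(n, length = 7L, min_dist = 3L) {
  total <- 4^length
  # odd multiplier modulo a power of two is a bijection: a fixed scramble
  mult <- 2654435761 %% total
  picked <- character(0L)
  i <- 0
  while (length(picked) < n && i < total) {
    code <- (i * mult) %% total
    digs <- integer(length)
    for (p in seq_len(length)) {
      digs[p] <- code %% 4
      code <- code %/% 4
    }
    bc <- paste(DNA_BASES[digs + 1L], collapse = "")
    if (length(picked) == 0L ||
      all(str_hamming(rep(bc, length(picked)), picked) >= min_dist)) {
      picked <- c(picked, bc)
    }
    i <- i + 1
  }
  if (length(picked) < n) {
    abort(sprintf(
      "Cannot construct %d barcodes of length %d with pairwise distance >= %d.",
      n, length, min_dist
    ), class = "sagrad_config_error")
  }
  picked
}
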