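#' Simulate a structured diploid population of RAD loci
#'
#' Draws ancestral locus sequences (the fixed cut-site remnant followed by
#' uniform random bases), derives one sequence per population by per-site
#' substitution at probability `divergence`, and gives every individual a
#' diploid genotype: at a fraction `het_rate` of loci the two alleles differ
#' by exactly one substitution. Heterozygous substitutions are placed inside
#' the read-1 window (after the remnant) so downstream assembly can observe
#' both alleles; divergence substitutions may fall anywhere after the
#' remnant. A contaminant genome without cut-site remnants is simulated
#' alongside.
#'
#' The result is the ground truth of the experiment: it records every
#' haplotype, the library layout (samples, barcodes, populations) and, after
#' [apply_mda_bias()], the per-allele amplification weights and dropout
#' events that downstream recovery tests compare against.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sagrad_truth` with elements `config`, `samples`
#'   (one row per library: `sample_id`, `individual_id`, `population`,
#'   `protocol`, `barcode`), `individuals`, `haplotypes` (one row per
#'   individual x locus x allele: `individual_id`, `population`, `locus`,
#'   `allele`, `het`, `seq`), `contaminant_genome`, and `weights` (`NULL`
#'   until [apply_mda_bias()] is called).
#' @seealso [apply_mda_bias()], [generate_reads()]
#' @export
#' @examples
#' truth <- simulate_population(sim_config(
#'   seed = 1, n_populations = 2,
#'   n_individuals_per_pop = 2, n_loci = 20, reads_per_sample = 200
#' ))
#' truth$samples
simulate_population <- function(config) {
  if (!inherits(config, "sagrad_config")) {
    abort("`config` must be a `sagrad_config` (see `sim_config()`).",
      class = "sagrad_config_error"
    )
  }
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    remnant <- config$cutsite_remnant
    rlen <- nchar(remnant)
    ancestral <- paste0(remnant, random_dna(config$n_loci, config$locus_length - rlen))

    pop_ids <- sprintf("P%d", seq_len(config$n_populations))
    pop_seqs <- lapply(pop_ids, function(p) {
      mutate_seqs(ancestral, config$divergence, first_mutable = rlen + 1L)
    })
    names(pop_seqs) <- pop_ids

    individuals <- tidyr::expand_grid(
      population = pop_ids,
      ind = seq_len(config$n_individuals_per_pop)
    ) |>
      mutate(individual_id = sprintf("%s_I%d", .data$population, .data$ind)) |>
      select("individual_id", "population")

    # heterozygous substitution must land in the read-1 window so the
    # assembler (which sees read 1 only) can recover both alleles
    het_lo <- rlen + 1L
    het_hi <- config$read_length - config$barcode_length
    haplotypes <- purrr::pmap(individuals, function(individual_id, population) {
      base_seq <- pop_seqs[[population]]
      het <- runif(config$n_loci) < config$het_rate
      allele2 <- base_seq
      for (l in which(het)) {
        pos <- sample(het_lo:het_hi, 1L)
        allele2[l] <- point_mutation(allele2[l], pos)
      }
      tibble(
        individual_id = individual_id,
        population = population,
        locus = rep(seq_len(config$n_loci), 2L),
        allele = rep(c(1L, 2L), each = config$n_loci),
        het = rep(het, 2L),
        seq = c(base_seq, allele2)
      )
    }) |>
      list_rbind() |>
      arrange(.data$individual_id, .data$locus, .data$allele)

    n_reps <- config$n_replicates + config$n_bulk_replicates
    samples <- individuals |>
      tidyr::expand_grid(rep = seq_len(n_reps)) |>
      mutate(
        protocol = ifelse(.data$rep <= config$n_replicates, "sag", "bulk"),
        sample_id = ifelse(
          .data$protocol == "sag",
          sprintf("%s_R%d", .data$individual_id, .data$rep),
          sprintf("%s_B%d", .data$individual_id, .data$rep - config$n_replicates)
        )
      ) |>
      select("sample_id", "individual_id", "population", "protocol")
    samples$barcode <- generate_barcodes(nrow(samples), config$barcode_length)

    contaminant_genome <- random_dna(1L, 20000L)

    structure(
      list(
        config = config,
        samples = samples,
        individuals = individuals,
        haplotypes = haplotypes,
        contaminant_genome = contaminant_genome,
        weights = NULL
      ),
      class = "sagrad_truth"
    )
  })
}

#' @export
print.sagrad_truth <- function(x, ...) {
  cat(sprintf(
    "<sagrad_truth> %d individuals in %d population(s), %d loci, %d libraries%s\n",
    nrow(x$individuals), x$config$n_populations, x$config$n_loci,
    nrow(x$samples),
    if (is.null(x$weights)) " (weights not yet drawn)" else ""
  ))
  invisible(x)
}

#' Draw per-locus amplification weights and allelic dropout
#'
#' Models the coverage bias of multiple displacement amplification: for
#' every single-cell library and locus, an amplification factor is drawn
#' lognormal(0, `mda_sigma`) and shared by both alleles; at heterozygous
#' loci one allele (chosen at random) is independently zeroed with
#' probability `dropout_prob`. Bulk libraries always get uniform weights
#' (factor 1) and no dropout, regardless of the configured `mda_sigma`.
#'
#' @param truth A `sagrad_truth` from [simulate_population()].
#' @return The truth object with `weights` populated: one row per sample x
#'   locus x allele with columns `weight` and `dropout`.
#' @export
apply_mda_bias <- function(truth) {
  stopifnot(inherits(truth, "sagrad_truth"))
  cfg <- truth$config
  withr::with_seed(cfg$seed + 1L, {
    loci <- truth$haplotypes |>
      filter(.data$allele == 1L) |>
      select("individual_id", "locus", "het")
    per_locus <- truth$samples |>
      select("sample_id", "individual_id", "protocol") |>
      left_join(loci, by = "individual_id", relationship = "many-to-many")
    n <- nrow(per_locus)
    sigma <- ifelse(per_locus$protocol == "bulk", 0, cfg$mda_sigma)
    factor <- exp(rnorm(n) * sigma)
    d_prob <- ifelse(per_locus$protocol == "bulk", 0, cfg$dropout_prob)
    drops <- per_locus$het & (runif(n) < d_prob)
    dropped_allele <- ifelse(drops, sample(c(1L, 2L), n, replace = TRUE), NA_integer_)

    weights <- per_locus |>
      mutate(factor = factor, dropped_allele = dropped_allele) |>
      tidyr::expand_grid(allele = c(1L, 2L)) |>
      mutate(
        dropout = !is.na(.data$dropped_allele) & .data$allele == .data$dropped_allele,
        weight = ifelse(.data$dropout, 0, .data$factor)
      ) |>
      select(
        "sample_id", "individual_id", "protocol", "locus", "allele",
        "het", "weight", "dropout"
      ) |>
      arrange(.data$sample_id, .data$locus, .data$allele)

    truth$weights <- weights
    truth
  })
}

# normal sd putting >= 99% of the mass inside [lo, hi] around `mean`
insert_sd <- function(mean, lo, hi) {
  min(mean - lo, hi - mean) / qnorm(0.995)
}

#' Generate paired-end reads for every library
#'
#' Emits exactly `reads_per_sample` read pairs per library. Target pairs
#' pick a (locus, allele) proportional to the amplification weights; read 1
#' is the inline barcode followed by the start of the haplotype (cut-site
#' remnant first), read 2 is the reverse complement of the fragment end at
#' the drawn insert length. Contaminant pairs are drawn from the
#' contaminant genome (no remnant) at `contamination_frac`; sequencing
#' errors are injected per base at `seq_error_rate` (quality Q37 for
#' correct bases, Q12 at error positions); finally `pcr_dup_rate` of pairs
#' are exact copies of another pair of the same library.
#'
#' @param truth A `sagrad_truth` with weights populated.
#' @return A tibble of read pairs with truth annotation: `read_id`,
#'   `sample_id`, `seq1`, `qual1`, `seq2`, `qual2`, `insert`, `locus`,
#'   `allele`, `is_contaminant`, `is_duplicate`.
#' @export
generate_reads <- function(truth) {
  stopifnot(inherits(truth, "sagrad_truth"))
  if (is.null(truth$weights)) {
    abort("Weights not populated; call `apply_mda_bias()` first.",
      class = "sagrad_truth_error"
    )
  }
  cfg <- truth$config
  withr::with_seed(cfg$seed + 2L, {
    purrr::pmap(truth$samples, function(sample_id, barcode, ...) {
      generate_sample_reads(truth, sample_id, barcode)
    }) |>
      list_rbind()
  })
}

generate_sample_reads <- function(truth, sample_id, barcode) {
  cfg <- truth$config
  rl <- cfg$read_length
  bl <- cfg$barcode_length

  wts <- truth$weights |>
    filter(.data$sample_id == !!sample_id) |>
    inner_join(
      truth$haplotypes |> select("individual_id", "locus", "allele", "seq"),
      by = c("individual_id", "locus", "allele")
    ) |>
    arrange(.data$locus, .data$allele)
  if (sum(wts$weight) <= 0) {
    abort(
      sprintf("Sample %s has an all-zero amplification weight vector.", sample_id),
      class = "sagrad_degenerate_sample"
    )
  }

  n_pairs <- cfg$reads_per_sample
  n_dup <- rbinom(1L, n_pairs, cfg$pcr_dup_rate)
  n_orig <- n_pairs - n_dup
  is_contam <- runif(n_orig) < cfg$contamination_frac
  n_con <- sum(is_contam)
  n_tgt <- n_orig - n_con

  inserts <- as.integer(round(rnorm(
    n_orig, cfg$insert_mean,
    insert_sd(cfg$insert_mean, cfg$insert_min, cfg$insert_max)
  )))
  inserts <- pmin(pmax(inserts, cfg$insert_min), cfg$insert_max)

  hap <- character(n_orig)
  locus <- rep(NA_integer_, n_orig)
  allele <- rep(NA_integer_, n_orig)
  if (n_tgt > 0L) {
    pick <- sample.int(nrow(wts), n_tgt, replace = TRUE, prob = wts$weight)
    hap[!is_contam] <- wts$seq[pick]
    locus[!is_contam] <- wts$locus[pick]
    allele[!is_contam] <- wts$allele[pick]
  }
  if (n_con > 0L) {
    glen <- nchar(truth$contaminant_genome)
    start <- sample.int(glen - cfg$insert_max, n_con, replace = TRUE)
    hap[is_contam] <- substr(
      rep(truth$contaminant_genome, n_con),
      start, start + cfg$insert_max
    )
  }

  frag <- paste0(barcode, substr(hap, 1L, inserts - bl))
  seq1 <- substr(frag, 1L, rl)
  seq2 <- revcomp(substr(frag, inserts - rl + 1L, inserts))

  e1 <- add_seq_errors(seq1, cfg$seq_error_rate)
  e2 <- add_seq_errors(seq2, cfg$seq_error_rate)

  out <- tibble(
    sample_id = sample_id,
    seq1 = e1$seq, qual1 = e1$qual,
    seq2 = e2$seq, qual2 = e2$qual,
    insert = inserts,
    locus = locus, allele = allele,
    is_contaminant = is_contam,
    is_duplicate = FALSE
  )
  if (n_dup > 0L) {
    dup <- out[sample.int(n_orig, n_dup, replace = TRUE), ]
    dup$is_duplicate <- TRUE
    out <- bind_rows(out, dup)
  }
  out$read_id <- sprintf("%s_%06d", sample_id, seq_len(nrow(out)))
  select(
    out, "read_id", "sample_id", "seq1", "qual1", "seq2", "qual2",
    "insert", "locus", "allele", "is_contaminant", "is_duplicate"
  )
}

# substitution errors at `rate` per base; qualities Q37 ('F'), errors Q12 ('-')
add_seq_errors <- function(seqs, rate, q_hi = "F", q_lo = "-") {
  n <- length(seqs)
  if (n == 0L) {
    return(list(seq = seqs, qual = character()))
  }
  len <- nchar(seqs[1L])
  quals <- rep(strrep(q_hi, len), n)
  if (rate > 0) {
    nerr <- rbinom(n, len, rate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(len, nerr[i])
      s <- seqs[i]
      q <- quals[i]
      for (p in pos) {
        s <- point_mutation(s, p)
        substr(q, p, p) <- q_lo
      }
      seqs[i] <- s
      quals[i] <- q
    }
  }
  list(seq = seqs, qual = quals)
}

#' Simulate a complete SAG-RAD experiment
#'
#' Convenience wrapper chaining [simulate_population()], [apply_mda_bias()]
#' and [generate_reads()].
#'
#' @param config A [sim_config()].
#' @return A list with elements `truth` (weights populated) and `reads`.
#' @export
#' @examples
#' sim <- simulate_rad(sim_config(
#'   seed = 1, n_populations = 1, n_individuals_per_pop = 1,
#'   n_loci = 20, reads_per_sample = 200
#' ))
#' nrow(sim$reads)
simulate_rad <- function(config) {
  truth <- simulate_population(config) |> apply_mda_bias()
  list(truth = truth, reads = generate_reads(truth))
}
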