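# Per-sample quality-control metrics: locus counts and sample dropout,
# replicate sharing, Lorenz/Gini coverage uniformity, depth distributions,
# bulk concordance, heterozygosity and the allelic-dropout rate.

#' Count a sample's retained loci
#'
#' @param loci Locus tibble with a `retained` column (see [filter_loci()]);
#'   a table without the column counts all rows.
#' @return Integer count.
#' @export
loci_per_sample <- function(loci) {
  if ("retained" %in% names(loci)) sum(loci$retained) else nrow(loci)
}

#' Flag samples with too few loci for downstream analysis
#'
#' Samples with fewer than `min_loci` loci are excluded ("fewer than" is
#' strict: a sample at exactly `min_loci` is retained).
#'
#' @param reports Tibble with columns `sample` and `n_loci`.
#' @param min_loci Minimum locus count.
#' @return `reports` with a logical `retained` column; excluded samples are
#'   reported via a message.
#' @export
sample_dropout <- function(reports, min_loci = 10000L) {
  reports$retained <- reports$n_loci >= min_loci
  dropped <- reports$sample[!reports$retained]
  if (length(dropped) > 0L) {
    inform(sprintf(
      "Excluding %d sample(s) with fewer than %d loci: %s",
      length(dropped), min_loci, paste(dropped, collapse = ", ")
    ))
  }
  reports
}

#' Tabulate locus sharing among replicates
#'
#' For a group of replicate samples matched against one common catalog,
#' counts how many catalog loci are recovered by exactly k replicates, and
#' by each exact replicate subset.
#'
#' @param matches A list of `sagrad_matches` (one per replicate) or a
#'   single tibble combining them. All match sets must come from the same
#'   catalog (checked via the stored catalog hash when available).
#' @return List of class `sagrad_sharing`: `by_k` (tibble `k`, `n_loci`
#'   for k = 1..group size) and `by_subset` (tibble `samples`, `n_loci`).
#' @export
sharing_table <- function(matches) {
  if (is.data.frame(matches)) {
    combined <- matches
  } else {
    hashes <- unique(unlist(lapply(matches, attr, "catalog_hash")))
    if (length(hashes) > 1L) {
      abort("Replicates were matched against different catalogs.",
        class = "sagrad_input_error"
      )
    }
    combined <- list_rbind(lapply(matches, as_tibble))
  }
  group_size <- n_distinct(combined$sample)
  per_locus <- combined |>
    filter(.data$status == "matched") |>
    distinct(.data$catalog_id, .data$sample) |>
    group_by(.data$catalog_id) |>
    summarise(
      k = n(),
      samples = paste(sort(unique(.data$sample)), collapse = "+")
    )
  by_k <- tibble(k = seq_len(group_size)) |>
    left_join(count(per_locus, .data$k, name = "n_loci"), by = "k") |>
    mutate(n_loci = tidyr::replace_na(.data$n_loci, 0L))
  by_subset <- count(per_locus, .data$samples, name = "n_loci") |>
    arrange(desc(.data$n_loci))
  structure(list(by_k = by_k, by_subset = by_subset), class = "sagrad_sharing")
}

#' @export
print.sagrad_sharing <- function(x, ...) {
  cat("<sagrad_sharing> loci recovered by exactly k replicates:\n")
  print(x$by_k)
  invisible(x)
}

#' Lorenz curve of per-locus coverage
#'
#' Loci are sorted by ascending depth; the curve gives the cumulative
#' fraction of total reads covering a given cumulative fraction of loci.
#' The diagonal corresponds to perfectly uniform coverage.
#'
#' @param depths Non-negative per-locus total depths, not all zero.
#' @return Tibble with `frac_loci` and `frac_reads`, starting at (0, 0)
#'   and ending at (1, 1).
#' @export
#' @examples
#' lorenz(c(1, 2, 3, 4))
lorenz <- function(depths) {
  check_depths(depths)
  d <- sort(depths)
  n <- length(d)
  tibble(
    frac_loci = c(0, seq_len(n) / n),
    frac_reads = c(0, cumsum(d) / sum(d))
  )
}

#' Gini coefficient of per-locus coverage
#'
#' One minus twice the trapezoidal area under the Lorenz curve: 0 for
#' perfectly uniform coverage, approaching 1 as reads concentrate on few
#' loci (maximum (L-1)/L when a single locus holds all reads).
#'
#' @inheritParams lorenz
#' @return Gini coefficient in `[0, 1)`.
#' @export
#' @examples
#' gini(c(1, 2, 3, 4))
gini <- function(depths) {
  lc <- lorenz(depths)
  area <- sum(diff(lc$frac_loci) * (head(lc$frac_reads, -1) + lc$frac_reads[-1]) / 2)
  1 - 2 * area
}

check_depths <- function(depths) {
  if (length(depths) == 0L) {
    abort("At least one locus depth is required.", class = "sagrad_input_error")
  }
  if (any(depths < 0)) {
    abort("Depths must be non-negative.", class = "sagrad_input_error")
  }
  if (sum(depths) == 0) {
    abort("All depths are zero: coverage uniformity is undefined.",
      class = "sagrad_degenerate_input"
    )
  }
  invisible(depths)
}

#' Median and log-binned histogram of locus depths
#'
#' Bins are decade-spaced from 1 upwards with ten sub-bins per decade
#' (breaks at 10^(0, 0.1, 0.2, ...)), extended to cover the deepest locus.
#'
#' @param depths Positive per-locus depths.
#' @return List with `median` and `histogram` (tibble `bin_lo`, `bin_hi`,
#'   `n`).
#' @export
depth_summary <- function(depths) {
  if (length(depths) == 0L || any(depths <= 0)) {
    abort("Depths must be positive.", class = "sagrad_input_error")
  }
  top <- max(1, ceiling(log10(max(depths)) * 10) / 10)
  breaks <- 10^seq(0, top, by = 0.1)
  breaks[1] <- breaks[1] - 1e-9 # include depth exactly 1
  cuts <- cut(depths, breaks = breaks, right = TRUE)
  counts <- tabulate(cuts, nbins = length(breaks) - 1L)
  list(
    median = median(depths),
    histogram = tibble(
      bin_lo = head(breaks, -1L),
      bin_hi = breaks[-1L],
      n = counts
    )
  )
}

#' Count loci with a unique catalog match
#'
#' The concordance of a single-cell sample with a bulk catalog: the number
#' of its loci that match exactly one catalog locus within the match
#' distance. Ambiguous multi-matches are excluded.
#'
#' @param matches A `sagrad_matches` tibble.
#' @return Integer count.
#' @export
concordance <- function(matches) {
  sum(matches$status == "matched")
}

#' Proportion of heterozygous loci
#'
#' Heterozygous loci are loci with more than one allele.
#'
#' @param loci Locus tibble with an `n_alleles` column; when a `retained`
#'   column is present only retained loci are considered.
#' @return Fraction in `[0, 1]`.
#' @export
heterozygosity <- function(loci) {
  if ("retained" %in% names(loci)) loci <- loci[loci$retained, , drop = FALSE]
  if (nrow(loci) == 0L) {
    abort("Heterozygosity is undefined for zero loci.",
      class = "sagrad_degenerate_input"
    )
  }
  mean(loci$n_alleles >= 2L)
}

#' Allelic-dropout rate against a bulk catalog
#'
#' The number of matched loci that are homozygous in the sample (one
#' allele) while their catalog locus is diploid (two or more alleles in
#' the bulk catalog), relative to the total number of matched loci. With
#' `denominator = "diploid"` the rate is normalised to matched
#' diploid-catalog loci only.
#'
#' @param matches A `sagrad_matches` tibble (sample matched against a
#'   bulk catalog).
#' @param denominator Either `"all"` (default; all matched loci) or
#'   `"diploid"` (matched loci whose catalog locus is diploid).
#' @return Fraction in `[0, 1]`.
#' @export
ado_rate <- function(matches, denominator = c("all", "diploid")) {
  denominator <- match.arg(denominator)
  m <- matches[matches$status == "matched", , drop = FALSE]
  if (nrow(m) == 0L) {
    abort("Allelic-dropout rate is undefined with zero matched loci.",
      class = "sagrad_degenerate_input"
    )
  }
  num <- sum(m$n_alleles == 1L & m$catalog_n_alleles >= 2L)
  den <- if (denominator == "all") nrow(m) else sum(m$catalog_n_alleles >= 2L)
  if (den == 0L) {
    return(0)
  }
  num / den
}

#' Per-sample quality-control report
#'
#' Combines the per-sample metrics into one row per sample: retained locus
#' count, Gini coefficient and Lorenz points of the retained-locus depths,
#' median depth, heterozygosity, and -- when matches against a bulk catalog
#' are supplied -- the matched-locus count and allelic-dropout rate.
#'
#' @param assemblies Named list of `sagrad_assembly` objects (names are
#'   sample ids).
#' @param bulk_matches Optional named list of `sagrad_matches`, each sample
#'   matched against the bulk catalog.
#' @param min_loci Sample-dropout threshold passed to [sample_dropout()].
#' @return Tibble of class `sagrad_qc` with one row per sample, including
#'   a `lorenz` list column for plotting.
#' @export
qc_report <- function(assemblies, bulk_matches = NULL, min_loci = 10000L) {
  rows <- purrr::imap(assemblies, function(a, sid) {
    kept <- a$loci[a$loci$retained, , drop = FALSE]
    depths <- kept$total_depth
    has <- nrow(kept) > 0L && sum(depths) > 0
    bm <- if (!is.null(bulk_matches)) bulk_matches[[sid]] else NULL
    tibble(
      sample = sid,
      n_loci = nrow(kept),
      gini = if (has) gini(depths) else NA_real_,
      depth_median = if (has) median(depths) else NA_real_,
      depth_mean = if (has) mean(depths) else NA_real_,
      prop_heterozygous = if (nrow(kept) > 0L) heterozygosity(kept) else NA_real_,
      n_matched_bulk = if (!is.null(bm)) concordance(bm) else NA_integer_,
      ado_rate = if (!is.null(bm) && concordance(bm) > 0L) ado_rate(bm) else NA_real_,
      lorenz = list(if (has) lorenz(depths) else NULL)
    )
  })
  out <- sample_dropout(list_rbind(rows), min_loci)
  structure(out, class = c("sagrad_qc", class(out)))
}
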