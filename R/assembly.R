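# De-novo RAD locus assembly in the style of the stacks/catalog/matching
# workflow: exact-identity read stacks (minimum depth m), transitive
# Hamming merging of stacks into loci (distance M), absorption of
# below-threshold secondary reads, coverage-based locus filters, catalog
# construction across samples (distance n) and sample-to-catalog matching.

#' Remove PCR duplicates by read sequence and insert length
#'
#' Among read pairs of one sample sharing an identical read-1 sequence and
#' an identical insert length, only the first encountered pair is kept:
#' same sequence at a different insert length is an independent molecule.
#'
#' @param reads Tibble with `seq1` and `insert`; when a `sample` column is
#'   present deduplication is per sample.
#' @return List with `reads` (deduplicated) and `removed`, a per-sample
#'   tibble of duplicate counts.
#' @export
dedup_pcr <- function(reads) {
  if (!"insert" %in% names(reads) || anyNA(reads$insert)) {
    abort("Insert lengths are required for PCR deduplication.",
      class = "sagrad_format_error"
    )
  }
  grp <- if ("sample" %in% names(reads)) reads$sample else rep("all", nrow(reads))
  key <- paste(grp, reads$seq1, reads$insert, sep = "\r")
  dup <- duplicated(key)
  removed <- tibble(sample = grp[dup]) |>
    count(.data$sample, name = "n_removed")
  list(reads = reads[!dup, , drop = FALSE], removed = removed)
}

#' Group identical reads into stacks
#'
#' Exact-identity grouping of barcode-trimmed read-1 sequences. Groups
#' reaching depth `m` become primary stacks (putative alleles); the
#' remaining reads are secondary and may later be absorbed into loci.
#'
#' @param seqs Character vector of equal-length read-1 sequences.
#' @param m Minimum stack depth.
#' @return List with `stacks` (tibble `seq`, `depth`, ordered by depth then
#'   sequence) and `secondary` (tibble `seq`, `depth` below threshold).
#' @export
#' @examples
#' build_stacks(c(rep("ACGT", 3), "ACGA"), m = 3)
build_stacks <- function(seqs, m = 3L) {
  if (length(seqs) > 0L && length(unique(nchar(seqs))) != 1L) {
    abort("All reads must have equal length.", class = "sagrad_length_error")
  }
  counts <- tibble(seq = seqs) |>
    count(.data$seq, name = "depth") |>
    arrange(desc(.data$depth), .data$seq)
  list(
    stacks = filter(counts, .data$depth >= m),
    secondary = filter(counts, .data$depth < m)
  )
}

# 0-based positions at which the allele sequences differ (any column with
# variation necessarily differs from the first allele)
snp_positions <- function(alleles) {
  if (length(alleles) < 2L) {
    return(integer())
  }
  r1 <- charToRaw(alleles[1L])
  diffpos <- rep(FALSE, length(r1))
  for (a in alleles[-1L]) {
    diffpos <- diffpos | (charToRaw(a) != r1)
  }
  which(diffpos) - 1L
}

#' Merge stacks into putative loci
#'
#' Stacks connected by pairwise Hamming distance at most `M` (transitively
#' closed) form one locus. The member stacks become the locus alleles; the
#' consensus is the deepest allele (ties broken lexicographically).
#'
#' @param stacks Tibble with `seq` and `depth` from [build_stacks()].
#' @param M Maximum distance between stacks merged into one locus.
#' @return Tibble of loci: `locus_id`, `consensus`, `n_stacks`, `n_alleles`,
#'   `alleles` (list column of tibbles `seq`, `depth`), `snp_positions`
#'   (list column, 0-based), `total_depth`.
#' @export
merge_stacks <- function(stacks, M = 2L) {
  if (nrow(stacks) == 0L) {
    return(tibble(
      locus_id = integer(), consensus = character(), n_stacks = integer(),
      n_alleles = integer(), alleles = list(), snp_positions = list(),
      total_depth = integer()
    ))
  }
  memb <- seq_components(nrow(stacks), hamming_edges(stacks$seq, M))
  ord <- order(memb, -stacks$depth, stacks$seq)
  memb_o <- memb[ord]
  seqs <- stacks$seq[ord]
  deps <- stacks$depth[ord]
  idx <- unname(split(seq_along(memb_o), memb_o))
  out <- tibble(
    consensus = vapply(idx, function(i) seqs[i[1L]], character(1L)),
    n_stacks = lengths(idx),
    n_alleles = lengths(idx),
    alleles = lapply(idx, function(i) {
      new_tibble(list(seq = seqs[i], depth = deps[i]), nrow = length(i))
    }),
    snp_positions = lapply(idx, function(i) snp_positions(seqs[i])),
    total_depth = vapply(idx, function(i) sum(deps[i]), integer(1L))
  )
  out <- out[order(-out$total_depth, out$consensus), ]
  mutate(out, locus_id = row_number(), .before = 1L)
}

#' Absorb secondary reads into assembled loci
#'
#' Each secondary read is assigned to the unique nearest allele within
#' `max_dist` substitutions; reads tied between two alleles or farther than
#' `max_dist` from every allele are dropped. Allele and locus depths are
#' incremented by the absorbed read counts.
#'
#' @param loci Locus tibble from [merge_stacks()].
#' @param secondary Tibble `seq`, `depth` from [build_stacks()].
#' @param max_dist Maximum absorption distance.
#' @return List with `loci` (depths updated), `n_absorbed` and `n_dropped`
#'   (read counts).
#' @export
absorb_secondary <- function(loci, secondary, max_dist = 4L) {
  if (nrow(loci) == 0L || nrow(secondary) == 0L) {
    return(list(loci = loci, n_absorbed = 0L, n_dropped = sum(secondary$depth)))
  }
  allele_tbl <- loci |>
    select("locus_id", "alleles") |>
    tidyr::unnest("alleles")
  nn <- nearest_neighbors(secondary$seq, allele_tbl$seq, max_dist)
  if (nrow(nn) == 0L) {
    return(list(loci = loci, n_absorbed = 0L, n_dropped = sum(secondary$depth)))
  }
  hit <- nn |>
    group_by(.data$query) |>
    summarise(
      dmin = min(.data$dist),
      n_best = sum(.data$dist == min(.data$dist)),
      ref = .data$ref[which.min(.data$dist)]
    ) |>
    filter(.data$n_best == 1L)
  absorbed <- sum(secondary$depth[hit$query])
  if (nrow(hit) > 0L) {
    add <- tibble(ref = hit$ref, extra = secondary$depth[hit$query]) |>
      count(.data$ref, wt = .data$extra, name = "extra")
    allele_tbl$extra <- 0L
    allele_tbl$extra[add$ref] <- add$extra
    allele_tbl$depth <- allele_tbl$depth + allele_tbl$extra
    new_alleles <- lapply(
      split(seq_len(nrow(allele_tbl)), allele_tbl$locus_id),
      function(ix) tibble(seq = allele_tbl$seq[ix], depth = allele_tbl$depth[ix])
    )
    loci$alleles <- unname(
      new_alleles[match(as.character(loci$locus_id), names(new_alleles))]
    )
    loci$total_depth <- vapply(
      loci$alleles, function(a) as.integer(sum(a$depth)), integer(1L)
    )
  }
  list(
    loci = loci,
    n_absorbed = absorbed,
    n_dropped = sum(secondary$depth) - absorbed
  )
}

#' Flag confounded and extreme-coverage loci
#'
#' A locus is confounded when it was merged from more than `max_stacks`
#' allele-forming stacks (more variants than plausible for a diploid), and
#' has extreme coverage when its total depth exceeds mean + 3 sd of the
#' per-locus total depth of the sample, with mean and sd computed over all
#' loci before any removal. Retained loci carry neither flag.
#'
#' @param loci Locus tibble (depths final).
#' @param max_stacks Maximum allele-forming stacks for a well-behaved
#'   diploid locus.
#' @param sd_mult Multiplier on the depth standard deviation.
#' @return List with `loci` (columns `confounded`, `extreme_coverage`,
#'   `retained` added) and `accounting` (tibble of per-category counts).
#' @export
filter_loci <- function(loci, max_stacks = 3L, sd_mult = 3) {
  if (nrow(loci) == 0L) {
    loci$confounded <- logical()
    loci$extreme_coverage <- logical()
    loci$retained <- logical()
    return(list(loci = loci, accounting = tibble(
      category = c("retained", "confounded", "extreme_coverage"),
      n = c(0L, 0L, 0L)
    )))
  }
  confounded <- loci$n_stacks > max_stacks
  if (nrow(loci) < 2L) {
    warn("Fewer than 2 loci: depth standard deviation undefined, extreme-coverage filter skipped.")
    extreme <- rep(FALSE, nrow(loci))
  } else {
    thr <- mean(loci$total_depth) + sd_mult * sd(loci$total_depth)
    extreme <- loci$total_depth > thr
  }
  loci$confounded <- confounded
  loci$extreme_coverage <- extreme
  loci$retained <- !confounded & !extreme
  accounting <- tibble(
    category = c("retained", "confounded", "extreme_coverage"),
    n = c(sum(loci$retained), sum(confounded), sum(extreme))
  )
  list(loci = loci, accounting = accounting)
}

#' Assemble one sample from barcode-trimmed reads
#'
#' Chains [build_stacks()], [merge_stacks()], [absorb_secondary()] and
#' [filter_loci()] and keeps the read-accounting needed for conservation
#' checks: reads in = reads in stacks + absorbed + dropped secondary.
#'
#' @param seqs Character vector of barcode-trimmed read-1 sequences.
#' @param m Minimum stack depth.
#' @param M Maximum within-sample merge distance.
#' @param secondary_max_dist Maximum secondary-read absorption distance.
#' @param max_stacks,sd_mult Locus-filter parameters (see [filter_loci()]).
#' @return List of class `sagrad_assembly`: `loci` (with status flags),
#'   `accounting` (locus filter counts) and `reads` (named read counts).
#' @export
assemble_sample <- function(seqs, m = 3L, M = 2L, secondary_max_dist = 4L,
                            max_stacks = 3L, sd_mult = 3) {
  st <- build_stacks(seqs, m)
  loci <- merge_stacks(st$stacks, M)
  ab <- absorb_secondary(loci, st$secondary, secondary_max_dist)
  fl <- filter_loci(ab$loci, max_stacks, sd_mult)
  structure(
    list(
      loci = fl$loci,
      accounting = fl$accounting,
      reads = c(
        n_reads = length(seqs),
        n_in_stacks = sum(st$stacks$depth),
        n_secondary = sum(st$secondary$depth),
        n_absorbed = ab$n_absorbed,
        n_secondary_dropped = ab$n_dropped
      )
    ),
    class = "sagrad_assembly"
  )
}

#' @export
print.sagrad_assembly <- function(x, ...) {
  cat(sprintf(
    "<sagrad_assembly> %d loci (%d retained), %d reads (%d in stacks, %d secondary absorbed)\n",
    nrow(x$loci), sum(x$loci$retained), x$reads[["n_reads"]],
    x$reads[["n_in_stacks"]], x$reads[["n_absorbed"]]
  ))
  invisible(x)
}

#' Build a cross-sample catalog of loci
#'
#' Sample loci whose consensus sequences are within Hamming distance `n`
#' of each other (transitively closed) merge into one catalog locus. The
#' catalog allele set is the union of the member alleles; a catalog locus
#' with two or more alleles is "diploid" in the sense used by the
#' allelic-dropout rate.
#'
#' @param sample_loci Tibble with columns `sample`, `locus_id`, `consensus`
#'   and `alleles` (list column), typically the retained loci of several
#'   samples bound together.
#' @param n Maximum merge distance between sample consensus sequences.
#' @return Tibble of class `sagrad_catalog`: `catalog_id`, `consensus`,
#'   `n_alleles`, `alleles` (list of character vectors), `n_samples`,
#'   `members` (list of `sample`/`locus_id` tibbles). The merge distance is
#'   kept in attribute `n`.
#' @export
build_catalog <- function(sample_loci, n = 2L) {
  if (nrow(sample_loci) == 0L) {
    abort("Cannot build a catalog from zero loci.", class = "sagrad_input_error")
  }
  if (length(unique(nchar(sample_loci$consensus))) != 1L) {
    abort("Sample loci have inconsistent consensus lengths.",
      class = "sagrad_length_error"
    )
  }
  ucons <- sort(unique(sample_loci$consensus))
  memb <- seq_components(length(ucons), hamming_edges(ucons, n))
  cons_of <- memb[match(sample_loci$consensus, ucons)]
  idx <- unname(split(seq_len(nrow(sample_loci)), cons_of))
  allele_seqs <- function(a) if (is.data.frame(a)) a$seq else a
  rows <- lapply(idx, function(ix) {
    tb <- table(sample_loci$consensus[ix])
    top <- names(tb)[tb == max(tb)]
    alleles <- sort(unique(unlist(lapply(sample_loci$alleles[ix], allele_seqs))))
    list(
      consensus = sort(top)[1L],
      n_alleles = length(alleles),
      alleles = alleles,
      n_samples = length(unique(sample_loci$sample[ix])),
      members = new_tibble(
        list(
          sample = sample_loci$sample[ix],
          locus_id = sample_loci$locus_id[ix]
        ),
        nrow = length(ix)
      )
    )
  })
  cat_tbl <- tibble(
    consensus = vapply(rows, function(r) r$consensus, character(1L)),
    n_alleles = vapply(rows, function(r) r$n_alleles, integer(1L)),
    alleles = lapply(rows, function(r) r$alleles),
    n_samples = vapply(rows, function(r) r$n_samples, integer(1L)),
    members = lapply(rows, function(r) r$members)
  )
  cat_tbl <- cat_tbl[order(cat_tbl$consensus), ]
  cat_tbl <- mutate(cat_tbl, catalog_id = row_number(), .before = 1L)
  structure(cat_tbl, class = c("sagrad_catalog", class(cat_tbl)), n = n)
}

#' Match one sample's loci against a catalog
#'
#' A sample locus matches the catalog locus whose consensus is nearest in
#' Hamming distance, provided the minimum is at most `n` and unique; ties
#' are recorded as `ambiguous` and no-candidate loci as `unmatched`,
#' neither of which counts as matched.
#'
#' @param sample_loci One sample's locus tibble (columns `locus_id`,
#'   `consensus`, `n_alleles`, `alleles`).
#' @param catalog A `sagrad_catalog`.
#' @param n Maximum match distance; defaults to the catalog merge distance.
#' @param sample Optional sample name stored in the result.
#' @return Tibble of class `sagrad_matches`: `sample`, `locus_id`,
#'   `status` (matched/ambiguous/unmatched), `catalog_id`, `distance`,
#'   `n_alleles`, `alleles`, `catalog_n_alleles`, `shared_alleles` (how
#'   many of the sample's alleles occur verbatim in the catalog allele
#'   set). Attribute `catalog_hash` identifies the catalog matched against.
#' @export
match_to_catalog <- function(sample_loci, catalog, n = NULL, sample = NULL) {
  n <- n %||% attr(catalog, "n") %||% 2L
  sample <- sample %||% (if ("sample" %in% names(sample_loci) &&
    nrow(sample_loci) > 0L) {
    sample_loci$sample[1L]
  } else {
    "sample"
  })
  out <- tibble(
    sample = sample,
    locus_id = sample_loci$locus_id,
    status = "unmatched",
    catalog_id = NA_integer_,
    distance = NA_integer_,
    n_alleles = sample_loci$n_alleles,
    alleles = lapply(sample_loci$alleles, function(a) {
      if (is.data.frame(a)) a$seq else a
    }),
    catalog_n_alleles = NA_integer_,
    shared_alleles = NA_integer_
  )
  if (nrow(sample_loci) > 0L) {
    nn <- nearest_neighbors(sample_loci$consensus, catalog$consensus, n)
    if (nrow(nn) > 0L) {
      hit <- nn |>
        group_by(.data$query) |>
        summarise(
          dmin = min(.data$dist),
          n_best = sum(.data$dist == min(.data$dist)),
          ref = .data$ref[which.min(.data$dist)]
        )
      amb <- hit$query[hit$n_best > 1L]
      out$status[amb] <- "ambiguous"
      uni <- hit[hit$n_best == 1L, ]
      out$status[uni$query] <- "matched"
      out$catalog_id[uni$query] <- catalog$catalog_id[uni$ref]
      out$distance[uni$query] <- uni$dmin
      out$catalog_n_alleles[uni$query] <- catalog$n_alleles[uni$ref]
      out$shared_alleles[uni$query] <- mapply(
        function(a, r) sum(a %in% catalog$alleles[[r]]),
        out$alleles[uni$query], uni$ref
      )
    }
  }
  structure(out,
    class = c("sagrad_matches", class(out)),
    catalog_hash = rlang::hash(catalog$consensus)
  )
}
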