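# De-novo assembly: PCR deduplication, stacks, Hamming merging (checked
# against a brute-force oracle), secondary-read absorption, locus filters,
# catalog construction and matching.

test_that("PCR deduplication keys on read sequence plus insert length", {
  rd <- tibble::tibble(
    sample = "s1",
    seq1 = c("ACGT", "ACGT", "ACGT", "TTTT"),
    insert = c(400L, 400L, 410L, 400L)
  )
  dd <- dedup_pcr(rd)
  # byte-identical pair at the same insert collapses; a different insert
  # is an independent molecule
  expect_identical(nrow(dd$reads), 3L)
  expect_identical(dd$removed$n_removed, 1L)
  expect_true(all(c("ACGT", "TTTT") %in% dd$reads$seq1))
  expect_identical(sum(dd$reads$seq1 == "ACGT" & dd$reads$insert == 400L), 1L)

  rd$insert[2] <- NA
  expect_error(dedup_pcr(rd), class = "sagrad_format_error")

  # on simulated data the removed count equals the multiset-repeat count
  # computed independently in base R
  cfg <- clean_config(seed = 30, n_loci = 100, depth = 40)
  cfg$pcr_dup_rate <- 0.2
  sim <- simulate_rad(cfg)
  reads <- dplyr::mutate(sim$reads, sample = sample_id)
  dd <- dedup_pcr(reads)
  oracle_removed <- sum(duplicated(paste(reads$sample, reads$seq1, reads$insert)))
  expect_identical(nrow(reads) - nrow(dd$reads), oracle_removed)
  # every labelled PCR duplicate is covered by the removal
  expect_gte(oracle_removed, sum(reads$is_duplicate))
})

test_that("stacks are exact-identity groups thresholded at depth m", {
  st <- build_stacks(rep("ACGT", 10), m = 3)
  expect_identical(st$stacks$depth, 10L)
  expect_identical(nrow(st$secondary), 0L)

  st <- build_stacks(rep("ACGT", 2), m = 3)
  expect_identical(nrow(st$stacks), 0L)
  expect_identical(st$secondary$depth, 2L)

  st <- build_stacks(c(rep("AAAA", 3), rep("CCCC", 2)), m = 3)
  expect_identical(st$stacks$seq, "AAAA")
  expect_identical(st$secondary$seq, "CCCC")

  expect_error(build_stacks(c("AA", "AAA")), class = "sagrad_length_error")
})

test_that("stack merging follows transitive Hamming closure with deterministic consensus", {
  mk <- function(seqs, depths) tibble::tibble(seq = seqs, depth = depths)
  base <- strrep("A", 20)
  mut <- function(s, pos, to = "C") {
    for (i in seq_along(pos)) substr(s, pos[i], pos[i]) <- to[min(i, length(to))]
    s
  }

  # distance 1: one locus with two alleles, consensus = deepest stack
  loci <- merge_stacks(mk(c(base, mut(base, 5)), c(10L, 4L)), M = 2)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_alleles, 2L)
  expect_identical(loci$consensus, base)
  expect_identical(loci$total_depth, 14L)
  expect_identical(loci$snp_positions[[1]], 4L) # 0-based

  # distance 3: two separate loci
  loci <- merge_stacks(mk(c(base, mut(base, c(5, 6, 7))), c(10L, 4L)), M = 2)
  expect_identical(nrow(loci), 2L)

  # transitive closure: A-B 2, B-C 2, A-C 4 merge into one locus
  a <- base
  b <- mut(base, c(5, 6))
  c3 <- mut(base, c(5, 6, 9, 10))
  loci <- merge_stacks(mk(c(a, b, c3), c(5L, 5L, 5L)), M = 2)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_alleles, 3L)
  # consensus tie at equal depth: lexicographically smallest allele
  expect_identical(loci$consensus, min(c(a, b, c3)))
})

test_that("merging and catalog construction agree exactly with the brute-force oracle", {
  withr::with_seed(31, {
    for (i in 1:30) {
      seqs <- random_related_seqs(sample(5:50, 1))
      depths <- sample.int(20, length(seqs), replace = TRUE)
      loci <- merge_stacks(tibble::tibble(seq = seqs, depth = depths), M = 2)
      memb_impl <- integer(length(seqs))
      for (r in seq_len(nrow(loci))) {
        memb_impl[match(loci$alleles[[r]]$seq, seqs)] <- r
      }
      expect_identical(
        canonical_partition(memb_impl),
        canonical_partition(oracle_components(seqs, 2))
      )
    }
  })
})

test_that("secondary reads are absorbed only at a unique nearest allele", {
  base <- strrep("A", 20)
  mut <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- "C"
    s
  }
  stacks <- tibble::tibble(seq = c(base, mut(base, c(1, 2))), depth = c(5L, 5L))
  loci <- merge_stacks(stacks, M = 2)
  expect_identical(nrow(loci), 1L)

  # identical to an allele: depth + 1
  ab <- absorb_secondary(loci, tibble::tibble(seq = base, depth = 1L))
  expect_identical(ab$n_absorbed, 1L)
  expect_identical(ab$loci$total_depth, 11L)
  expect_identical(
    ab$loci$alleles[[1]]$depth[ab$loci$alleles[[1]]$seq == base], 6L
  )

  # equidistant from the two alleles (distance 1 each): dropped
  tie <- mut(base, 1)
  ab <- absorb_secondary(loci, tibble::tibble(seq = tie, depth = 2L))
  expect_identical(ab$n_absorbed, 0L)
  expect_identical(ab$n_dropped, 2L)

  # beyond max_dist from everything: dropped
  far <- mut(base, c(5, 6, 7, 8, 9))
  ab <- absorb_secondary(loci, tibble::tibble(seq = far, depth = 1L))
  expect_identical(ab$n_dropped, 1L)
})

test_that("locus filters reproduce hand-computed thresholds and stack limits", {
  mk_loci <- function(depths, stacks = 2L) {
    ns <- rep(stacks, length(depths))
    tibble::tibble(
      locus_id = seq_along(depths),
      consensus = strrep("A", 10),
      n_stacks = ns,
      n_alleles = ns,
      total_depth = as.integer(depths)
    )
  }

  # {10,10,10,10,1000}: threshold = mean + 3 sd > 1000, nothing extreme
  fl <- filter_loci(mk_loci(c(10, 10, 10, 10, 1000)))
  expect_identical(sum(fl$loci$extreme_coverage), 0L)
  expect_identical(sum(fl$loci$retained), 5L)

  # 99 loci at depth 10 plus one at 500: mean 14.9, threshold ~ 163,
  # exactly the deep locus removed
  depths <- c(rep(10, 99), 500)
  fl <- filter_loci(mk_loci(depths))
  expect_identical(which(fl$loci$extreme_coverage), 100L)
  expect_identical(sum(fl$loci$retained), 99L)
  expect_identical(
    fl$accounting$n[fl$accounting$category == "extreme_coverage"], 1L
  )

  # more than three stacks: confounded
  fl <- filter_loci(dplyr::bind_rows(mk_loci(c(10, 12)), mk_loci(15, stacks = 4L)))
  expect_identical(sum(fl$loci$confounded), 1L)
  expect_true(fl$loci$confounded[fl$loci$n_stacks == 4L])

  # a single locus: sd undefined, extreme filter skipped with a warning
  expect_warning(fl <- filter_loci(mk_loci(10)), "standard deviation")
  expect_identical(sum(fl$loci$extreme_coverage), 0L)
})

test_that("catalog merging and matching honour the distance n", {
  base <- strrep("G", 20)
  mut <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- "T"
    s
  }
  mk <- function(sample, consensus, alleles = list(consensus)) {
    tibble::tibble(
      sample = sample, locus_id = 1L, consensus = consensus,
      n_alleles = lengths(alleles), alleles = lapply(
        alleles,
        function(a) tibble::tibble(seq = a, depth = 5L)
      )
    )
  }

  # identical consensus from two clonal samples: one catalog locus
  cat1 <- build_catalog(dplyr::bind_rows(mk("a", base), mk("b", base)), n = 2)
  expect_identical(nrow(cat1), 1L)
  expect_identical(cat1$n_samples, 2L)

  # distance 2 merges; the allele set is the union
  cat2 <- build_catalog(
    dplyr::bind_rows(mk("a", base), mk("b", mut(base, c(3, 4)))),
    n = 2
  )
  expect_identical(nrow(cat2), 1L)
  expect_identical(cat2$n_alleles, 2L)

  # distance 3 stays separate
  cat3 <- build_catalog(
    dplyr::bind_rows(mk("a", base), mk("b", mut(base, c(3, 4, 5)))),
    n = 2
  )
  expect_identical(nrow(cat3), 2L)

  expect_error(
    build_catalog(dplyr::bind_rows(
      mk("a", base),
      mk("b", strrep("G", 19))
    )),
    class = "sagrad_length_error"
  )

  # matching: exact, within-distance, and ambiguous ties
  catalog <- build_catalog(dplyr::bind_rows(
    mk("a", base),
    mk("b", mut(base, c(1, 2, 3, 4))) # distance 4 away: separate locus
  ), n = 2)
  qry <- mk("q", base)
  m <- match_to_catalog(qry, catalog, sample = "q")
  expect_identical(m$status, "matched")
  expect_identical(m$distance, 0L)

  m2 <- match_to_catalog(mk("q", mut(base, 8)), catalog)
  expect_identical(m2$status, "matched")
  expect_identical(m2$distance, 1L)

  # equidistant (2 and 2) between the two catalog loci: ambiguous
  m3 <- match_to_catalog(mk("q", mut(base, c(1, 2))), catalog)
  expect_identical(m3$status, "ambiguous")
  expect_true(is.na(m3$catalog_id))

  # distance 3 from everything: unmatched
  m4 <- match_to_catalog(mk("q", mut(base, c(8, 9, 10))), catalog)
  expect_identical(m4$status, "unmatched")
})

test_that("ideal simulated libraries are recovered nearly losslessly", {
  cfg <- clean_config(seed = 32, n_loci = 100, depth = 25, het_rate = 0.2)
  sim <- simulate_rad(cfg)
  a <- assemble_sample(trim_barcode(sim$reads, cfg))

  # conservation of reads through the assembler
  rc <- a$reads
  expect_identical(
    rc[["n_reads"]],
    rc[["n_in_stacks"]] + rc[["n_absorbed"]] + rc[["n_secondary_dropped"]]
  )

  # nearly every truth locus is assembled and retained
  expect_gte(sum(a$loci$retained), ceiling(0.99 * cfg$n_loci))
  expect_gte(mean(a$loci$total_depth[a$loci$retained]), 20)

  # every assembled heterozygous locus carries exactly the two truth alleles
  tw <- truth_windows(sim$truth)
  truth_alleles <- split(tw$window, tw$locus)
  het_loci <- a$loci[a$loci$retained & a$loci$n_alleles == 2L, ]
  for (i in seq_len(nrow(het_loci))) {
    got <- sort(het_loci$alleles[[i]]$seq)
    hit <- which(vapply(
      truth_alleles,
      function(x) identical(sort(unique(x)), got), logical(1)
    ))
    expect_length(hit, 1L)
  }
})
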