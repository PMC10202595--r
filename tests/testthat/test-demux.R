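# Demultiplexing: barcode assignment and rescue, the filter cascade,
# contaminant screening and bin conservation.

test_that("sample sheets are validated", {
  expect_error(sample_sheet(character(), character()), class = "sagrad_sheet_error")
  expect_error(
    sample_sheet(c("a", "b"), c("AAAAAAA", "AAAAAAA")),
    class = "sagrad_sheet_error"
  )
  expect_warning(
    sample_sheet(c("a", "b"), c("AAAAAAA", "AAAAACC")),
    "distance"
  )
  expect_silent(sh <- sample_sheet(c("a", "b"), c("AAAAAAA", "CCCCCCC")))
  expect_identical(sh$barcode, c("AAAAAAA", "CCCCCCC"))
})

test_that("barcode assignment rescues one mismatch and trims on success", {
  sheet <- sample_sheet(c("s1", "s2", "s3"), c("AAAAAAA", "CCCCCCC", "GGGGGGG"))
  tail <- strrep("T", 143)

  # exact match: assigned and trimmed
  rd <- toy_reads(paste0("AAAAAAA", tail))
  out <- assign_barcodes(rd, sheet)
  expect_identical(out$sample, "s1")
  expect_identical(out$seq1, tail)
  expect_identical(nchar(out$qual1), 143L)

  # exhaustive single-mutant check: every 1-mismatch variant of every
  # barcode is rescued to the right sample (pairwise distance 7 here)
  for (b in seq_len(3)) {
    bc <- sheet$barcode[b]
    for (pos in 1:7) {
      for (base in setdiff(c("A", "C", "G", "T"), substr(bc, pos, pos))) {
        mut <- bc
        substr(mut, pos, pos) <- base
        out <- assign_barcodes(toy_reads(paste0(mut, tail)), sheet)
        expect_identical(out$sample, sheet$sample_id[b])
      }
    }
  }

  # no barcode within one mismatch
  out <- assign_barcodes(toy_reads(paste0("AACCGGT", tail)), sheet)
  expect_identical(out$discard_reason, "no_barcode")
  expect_true(is.na(out$sample))

  # equidistant between two barcodes: ambiguous
  sheet2 <- suppressWarnings(sample_sheet(c("x", "y"), c("AAAAAAA", "AAAAACC")))
  out <- assign_barcodes(toy_reads(paste0("AAAAAAC", tail)), sheet2)
  expect_identical(out$discard_reason, "ambiguous_barcode")

  expect_error(
    assign_barcodes(rd, sheet[0, ]),
    class = "sagrad_sheet_error"
  )
})

test_that("cut-site check demands the exact remnant", {
  tail <- strrep("A", 137)
  expect_true(check_cutsite(toy_reads(paste0("TGCAGG", tail))))
  expect_false(check_cutsite(toy_reads(paste0("TGCAGC", tail))))
  # all simulator target reads pass once the barcode is trimmed
  cfg <- clean_config(seed = 20, n_loci = 20, depth = 10)
  sim <- simulate_rad(cfg)
  trimmed <- toy_reads(trim_barcode(sim$reads, cfg))
  expect_true(all(check_cutsite(trimmed)))
})

test_that("uncalled-base filter discards reads with N in either mate", {
  seqs <- c(
    strrep("A", 20), strrep("C", 20),
    paste0(strrep("A", 10), "N", strrep("A", 9)), # N in read 1
    strrep("G", 20), strrep("T", 20),
    strrep("A", 20), strrep("C", 20), strrep("G", 20),
    strrep("T", 20), strrep("A", 20)
  )
  rd <- toy_reads(seqs)
  substr(rd$seq2[5], 3, 3) <- "N" # N in read 2
  substr(rd$seq2[8], 20, 20) <- "N"
  pass <- filter_uncalled(rd)
  expect_identical(sum(!pass), 3L)
  expect_identical(which(!pass), c(3L, 5L, 8L))
})

test_that("sliding-window quality filter matches hand-computed window means", {
  # all Q37: passes
  rd <- toy_reads(strrep("A", 150))
  expect_true(filter_quality(rd))

  # 30 consecutive Q2 bases: window (23 bp) fully inside has mean 2 < 10
  q <- paste0(strrep("F", 60), strrep("#", 30), strrep("F", 60))
  rd_bad <- rd
  rd_bad$qual1 <- q
  expect_false(filter_quality(rd_bad))
  # same failure on the second mate (both mates are filtered)
  rd_bad2 <- rd
  rd_bad2$qual2 <- q
  expect_false(filter_quality(rd_bad2))

  # a single Q2 among Q37: worst window mean (22*37 + 2)/23 = 35.5 >= 10
  q1 <- paste0(strrep("F", 75), "#", strrep("F", 74))
  rd_ok <- rd
  rd_ok$qual1 <- q1
  expect_true(filter_quality(rd_ok))

  expect_error(
    filter_quality(toy_reads(strrep("A", 5)) |>
      dplyr::mutate(qual1 = "ab\ncd")),
    class = "sagrad_format_error"
  )
})

test_that("adapter filter agrees with a brute-force sliding comparison", {
  adapter <- "AGATCGGAAGAGC"
  tail <- function(n) strrep("T", n)

  # exact adapter at the 3' end: fail
  rd <- toy_reads(paste0(tail(137), adapter))
  expect_false(filter_adapter(rd, adapter))
  # two substitutions mid-read: fail
  mut <- adapter
  substr(mut, 2, 2) <- "C"
  substr(mut, 9, 9) <- "T"
  rd2 <- toy_reads(paste0(tail(50), mut, tail(87)))
  expect_false(filter_adapter(rd2, adapter))
  # three substitutions: pass
  substr(mut, 12, 12) <- "A"
  rd3 <- toy_reads(paste0(tail(50), mut, tail(87)))
  expect_true(filter_adapter(rd3, adapter))

  # randomised agreement with the brute-force oracle (both mates)
  withr::with_seed(21, {
    for (i in 1:40) {
      s1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
      if (i %% 2 == 0) { # implant a mutated adapter at a random offset
        a <- adapter
        for (p in sample.int(nchar(a), sample(0:3, 1))) {
          substr(a, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        off <- sample.int(60 - nchar(a) + 1, 1)
        substr(s1, off, off + nchar(a) - 1) <- a
      }
      rd <- toy_reads(s1)
      want <- !(oracle_adapter_hit(rd$seq1, adapter, 2) ||
        oracle_adapter_hit(rd$seq2, adapter, 2))
      expect_identical(filter_adapter(rd, adapter), want)
    }
  })
})

test_that("k-mer screen flags contaminants and spares target reads", {
  withr::with_seed(22, {
    ref <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
    # read copied verbatim from the reference: contaminant
    rd <- toy_reads(c(substr(ref, 101, 250), substr(ref, 5001, 5150)))
    scr <- screen_contaminants(rd, ref)
    expect_identical(nrow(scr$contaminant), 2L)
    # random unrelated read: kept (k-mer collisions are vanishingly rare)
    rnd <- toy_reads(paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""))
    expect_identical(nrow(screen_contaminants(rnd, ref)$kept), 1L)
  })
  expect_error(
    screen_contaminants(toy_reads(strrep("A", 20)), strrep("C", 100), k = 31),
    class = "sagrad_config_error"
  )

  # flagged fraction agrees with the simulator's truth labels
  cfg <- sim_config(
    seed = 23, n_populations = 1, n_individuals_per_pop = 1,
    n_loci = 50, het_rate = 0, divergence = 0, mda_sigma = 0, dropout_prob = 0,
    contamination_frac = 0.05, pcr_dup_rate = 0, seq_error_rate = 0,
    reads_per_sample = 4000
  )
  sim <- simulate_rad(cfg)
  scr <- screen_contaminants(sim$reads, sim$truth$contaminant_genome)
  expect_identical(scr$flag, sim$reads$is_contaminant)
})

test_that("demultiplexing bins every read exactly once, with hand-checked counts", {
  sheet <- sample_sheet(c("s1", "s2"), c("AAAAAAA", "CCCCCCC"))
  good <- function(bc) paste0(bc, "TGCAGG", strrep("A", 137))
  reads <- toy_reads(c(
    good("AAAAAAA"), good("AAAAAAA"), good("AAAAAAA"), # s1
    good("CCCCCCC"), good("CCCCCCC"), good("CCCCCCC"), # s2
    good("GGTTGGT"), good("TTGGTTG"), # no barcode
    paste0("AAAAAAA", "TTTTTT", strrep("A", 137)), # no cut site
    good("AAAAAAA") # uncalled base (N injected below)
  ))
  substr(reads$seq1[10], 20, 20) <- "N"
  dm <- demultiplex(reads, sheet)
  counts <- setNames(dm$accounting$n, dm$accounting$category)
  expect_identical(counts[["assigned"]], 6L)
  expect_identical(counts[["no_barcode"]], 2L)
  expect_identical(counts[["no_cutsite"]], 1L)
  expect_identical(counts[["uncalled_base"]], 1L)
  expect_identical(sum(dm$accounting$n), nrow(reads))
  expect_identical(table(dm$reads$sample)[["s1"]], 3L)

  # discard reason and assignment are mutually exclusive
  expect_true(all(is.na(dm$reads$sample) != is.na(dm$reads$discard_reason)))

  # empty input: zero-count table, no bins
  dm0 <- demultiplex(reads[0, ], sheet)
  expect_identical(sum(dm0$accounting$n), 0L)
})

test_that("demultiplexing simulated libraries recovers the truth assignment", {
  cfg <- sim_config(
    seed = 24, n_populations = 2, n_individuals_per_pop = 2,
    n_loci = 30, het_rate = 0.1, divergence = 0.01, mda_sigma = 0.5,
    dropout_prob = 0.1, contamination_frac = 0.05, pcr_dup_rate = 0.1,
    seq_error_rate = 0, reads_per_sample = 1000
  )
  sim <- simulate_rad(cfg)
  sheet <- sample_sheet(sim$truth$samples$sample_id, sim$truth$samples$barcode)
  dm <- demultiplex(sim$reads, sheet,
    contaminant_ref = sim$truth$contaminant_genome
  )
  # conservation: every pair lands in exactly one bin
  expect_identical(sum(dm$accounting$n), nrow(sim$reads))
  # all non-contaminant reads are assigned to their true sample
  assigned <- dm$reads[!is.na(dm$reads$sample), ]
  expect_true(all(assigned$sample == assigned$sample_id))
  expect_true(all(!assigned$is_contaminant))
  non_contam <- sum(!sim$reads$is_contaminant)
  expect_identical(sum(!is.na(dm$reads$sample)), non_contam)

  # idempotence: re-demultiplexing one sample's reads (with their original
  # untrimmed sequences) yields the same trimmed sequences
  sid <- sim$truth$samples$sample_id[1]
  orig <- sim$reads[sim$reads$read_id %in%
    dm$reads$read_id[!is.na(dm$reads$sample) & dm$reads$sample == sid], ]
  sheet1 <- sample_sheet(sid, sim$truth$samples$barcode[1])
  dm2 <- demultiplex(orig, sheet1)
  first <- dm$reads[match(orig$read_id, dm$reads$read_id), ]
  expect_identical(dm2$reads$seq1, first$seq1)
  expect_identical(dm2$reads$sample, first$sample)
})
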