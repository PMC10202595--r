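# End-to-end orchestration: simulate -> write/read FASTQ -> demultiplex ->
# deduplicate -> assemble -> QC -> coancestry, with a manifest of every
# artifact written. A single config seed drives all randomness (the
# simulator derives its stage seeds as seed, seed+1, seed+2; every later
# stage is deterministic), so a rerun with the same config is
# byte-identical.

#' Default pipeline configuration
#'
#' Nested list of every pipeline parameter with its default. The `sim`
#' section holds the [sim_config()] arguments (without the seed, which is
#' global); `demux`, `assembly`, `qc` and `coancestry` hold the stage
#' parameters, all of which default to the thresholds of the emulated
#' protocol (minimum stack depth m = 3, merge distances M = n = 2, one
#' barcode mismatch, two adapter mismatches, sample dropout below 10,000
#' loci, extreme coverage above mean + 3 sd, confounded above 3 stacks).
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  sim_defaults <- formals(sim_config)
  sim_defaults$seed <- NULL
  sim_defaults <- lapply(sim_defaults, eval)
  list(
    seed = NULL,
    out_dir = NULL,
    sim = sim_defaults,
    demux = list(
      max_mismatch = 1L,
      window_frac = 0.15,
      phred_floor = 10,
      adapter = NULL,
      adapter_max_mismatch = 2L,
      screen_contaminants = TRUE,
      k = 31L,
      min_hit_frac = 0.5
    ),
    assembly = list(
      m = 3L,
      M = 2L,
      n = 2L,
      secondary_max_dist = 4L,
      max_stacks = 3L,
      sd_mult = 3,
      dedup = TRUE
    ),
    qc = list(min_loci = 10000L),
    coancestry = list(k = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a nested list or the path of a YAML file, fills in every
#' default, rejects unknown keys (reported with their key path), and
#' checks all cross-parameter constraints by constructing the underlying
#' [sim_config()]. The seed is mandatory.
#'
#' @param config Nested list or YAML file path.
#' @return The effective configuration (defaults filled in) with class
#'   `sagrad_pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("Config file '%s' does not exist.", config),
        class = "sagrad_config_error"
      )
    }
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      abort(sprintf("Failed to parse config file '%s'.", config),
        class = "sagrad_config_error", parent = e
      )
    })
  }
  if (!is.list(config)) {
    abort("`config` must be a list or a YAML file path.",
      class = "sagrad_config_error"
    )
  }
  defaults <- default_pipeline_config()
  merged <- merge_config(defaults, config, path = character())
  if (is.null(merged$seed)) {
    abort("Config key `seed` is mandatory.", class = "sagrad_config_error")
  }
  # range checks ride on the sim-config constructor, which also
  # normalises the field types (YAML parses integers as doubles)
  scfg <- unclass(do.call(sim_config, c(list(seed = merged$seed), merged$sim)))
  merged$seed <- scfg$seed
  merged$sim <- scfg[setdiff(names(scfg), "seed")]
  if (!is.numeric(merged$qc$min_loci) || merged$qc$min_loci < 0) {
    abort("Config key `qc.min_loci` must be a non-negative count.",
      class = "sagrad_config_error"
    )
  }
  structure(merged, class = "sagrad_pipeline_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf(
      "Unknown config key(s): %s",
      paste(paste(c(path, unknown[1L]), collapse = "."), collapse = ", ")
    ), class = "sagrad_config_error")
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(
        defaults[[nm]], as.list(user[[nm]]), c(path, nm)
      )
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' A small complete pipeline configuration
#'
#' Three populations of three individuals at 200 loci -- large enough to
#' exercise every stage (including population-structure recovery) while
#' running in well under two minutes.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A validated `sagrad_pipeline_config`.
#' @export
tiny_pipeline_config <- function(seed, out_dir = tempfile("sagrad_run_")) {
  validate_pipeline_config(list(
    seed = seed,
    out_dir = out_dir,
    sim = list(
      n_populations = 3L,
      n_individuals_per_pop = 3L,
      n_loci = 200L,
      n_bulk_replicates = 0L,
      reads_per_sample = 5000L,
      mda_sigma = 0.8,
      dropout_prob = 0.2,
      het_rate = 0.05,
      divergence = 0.02
    ),
    qc = list(min_loci = 50L),
    coancestry = list(k = 3L)
  ))
}

write_stage_tsv <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

flatten_loci <- function(loci) {
  loci |>
    mutate(
      allele_seqs = map_chr(.data$alleles, function(a) paste(a$seq, collapse = ",")),
      allele_depths = map_chr(.data$alleles, function(a) paste(a$depth, collapse = ",")),
      snp_positions = map_chr(.data$snp_positions, paste, collapse = ",")
    ) |>
    select(-"alleles")
}

#' Run the complete pipeline
#'
#' Executes simulation, demultiplexing, PCR deduplication, per-sample
#' assembly, catalog construction and matching, quality control (with bulk
#' concordance and allelic dropout when bulk libraries are configured),
#' and coancestry clustering. Every artifact is written under `out_dir`
#' and listed, with its MD5 checksum, in `run_manifest.tsv`; progress is
#' logged to stderr. A stage failure aborts with the stage name.
#'
#' @param config A `sagrad_pipeline_config` (see
#'   [validate_pipeline_config()]), a nested list, or a YAML file path.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with `manifest` (tibble of artifacts),
#'   `summary` (headline numbers) and in-memory stage results (`truth`,
#'   `qc`, `coancestry`, `clustering`, `ari`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "sagrad_pipeline_config")) {
    config <- validate_pipeline_config(config)
  }
  out_dir <- out_dir %||% config$out_dir %||% tempfile("sagrad_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  note <- function(...) inform(sprintf(...))
  stage <- function(name, expr) {
    note("[%s] starting", name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed.", name),
        class = "sagrad_stage_error", parent = e
      )
    })
  }

  # --- sim ----------------------------------------------------------------
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  sim_dir <- file.path(out_dir, "sim")
  dir.create(sim_dir, showWarnings = FALSE)
  truth <- NULL
  reads <- NULL
  stage("sim", {
    truth <- simulate_population(scfg) |> apply_mda_bias()
    reads <- generate_reads(truth)
    paths <- write_fastq(reads, sim_dir, prefix = "library", samples = truth$samples)
    tpath <- write_truth(truth, file.path(sim_dir, "truth.jsonl"))
    cpath <- file.path(sim_dir, "contaminants.fasta")
    ref <- Biostrings::DNAStringSet(truth$contaminant_genome)
    names(ref) <- "contaminant_1"
    Biostrings::writeXStringSet(ref, cpath)
    artifacts <- c(artifacts, unname(paths), tpath, cpath)
    note(
      "[sim] %d read pairs across %d libraries (%d loci)",
      nrow(reads), nrow(truth$samples), scfg$n_loci
    )
  })

  # --- demux --------------------------------------------------------------
  demux_dir <- file.path(out_dir, "demux")
  dir.create(demux_dir, showWarnings = FALSE)
  dm <- NULL
  stage("demux", {
    fq <- read_fastq(
      file.path(sim_dir, "library_R1.fastq"),
      file.path(sim_dir, "library_R2.fastq")
    )
    sheet <- sample_sheet(truth$samples$sample_id, truth$samples$barcode)
    dm <- demultiplex(
      fq, sheet,
      max_mismatch = config$demux$max_mismatch,
      remnant = scfg$cutsite_remnant,
      window_frac = config$demux$window_frac,
      phred_floor = config$demux$phred_floor,
      adapter = config$demux$adapter,
      adapter_max_mismatch = config$demux$adapter_max_mismatch,
      contaminant_ref = if (isTRUE(config$demux$screen_contaminants)) {
        truth$contaminant_genome
      } else {
        NULL
      },
      k = config$demux$k,
      min_hit_frac = config$demux$min_hit_frac
    )
    apath <- write_stage_tsv(dm$accounting, file.path(demux_dir, "accounting.tsv"))
    artifacts <- c(artifacts, apath)
    note(
      "[demux] %d/%d read pairs assigned",
      sum(dm$accounting$n[dm$accounting$category == "assigned"]),
      sum(dm$accounting$n)
    )
  })

  # --- assembly -----------------------------------------------------------
  asm_dir <- file.path(out_dir, "assembly")
  dir.create(asm_dir, showWarnings = FALSE)
  acfg <- config$assembly
  assemblies <- list()
  catalog <- NULL
  matches <- list()
  stage("assembly", {
    assigned <- dm$reads[!is.na(dm$reads$sample), , drop = FALSE]
    if (isTRUE(acfg$dedup)) {
      assigned <- dedup_pcr(assigned)$reads
    }
    split_reads <- split(assigned$seq1, assigned$sample)
    sample_ids <- truth$samples$sample_id[truth$samples$sample_id %in% names(split_reads)]
    assemblies <- lapply(
      stats::setNames(sample_ids, sample_ids),
      function(sid) {
        assemble_sample(split_reads[[sid]],
          m = acfg$m, M = acfg$M,
          secondary_max_dist = acfg$secondary_max_dist,
          max_stacks = acfg$max_stacks, sd_mult = acfg$sd_mult
        )
      }
    )
    loci_paths <- purrr::imap_chr(assemblies, function(a, sid) {
      write_stage_tsv(
        flatten_loci(a$loci),
        file.path(asm_dir, sprintf("loci_%s.tsv", sid))
      )
    })
    retained <- purrr::imap(assemblies, function(a, sid) {
      mutate(a$loci[a$loci$retained, , drop = FALSE], sample = sid, .before = 1L)
    }) |> list_rbind()
    catalog <- build_catalog(retained, n = acfg$n)
    cpath <- file.path(asm_dir, "catalog.fasta")
    cseq <- Biostrings::DNAStringSet(catalog$consensus)
    names(cseq) <- sprintf(
      "catalog_%d n_alleles=%d n_samples=%d",
      catalog$catalog_id, catalog$n_alleles, catalog$n_samples
    )
    Biostrings::writeXStringSet(cseq, cpath)
    matches <- purrr::imap(assemblies, function(a, sid) {
      match_to_catalog(a$loci[a$loci$retained, , drop = FALSE],
        catalog,
        n = acfg$n, sample = sid
      )
    })
    mpath <- write_stage_tsv(
      list_rbind(lapply(matches, function(m) {
        select(as_tibble(m), -"alleles")
      })),
      file.path(asm_dir, "matches.tsv")
    )
    artifacts <- c(artifacts, unname(loci_paths), cpath, mpath)
    note(
      "[assembly] %d samples assembled, %d catalog loci",
      length(assemblies), nrow(catalog)
    )
  })

  # --- qc -----------------------------------------------------------------
  qc_dir <- file.path(out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  qc <- NULL
  bulk_matches <- NULL
  stage("qc", {
    bulk_ids <- truth$samples$sample_id[truth$samples$protocol == "bulk"]
    bulk_ids <- intersect(bulk_ids, names(assemblies))
    if (length(bulk_ids) > 0L) {
      bulk_loci <- purrr::imap(assemblies[bulk_ids], function(a, sid) {
        mutate(a$loci[a$loci$retained, , drop = FALSE], sample = sid, .before = 1L)
      }) |> list_rbind()
      bulk_catalog <- build_catalog(bulk_loci, n = acfg$n)
      sag_ids <- setdiff(names(assemblies), bulk_ids)
      bulk_matches <- lapply(
        stats::setNames(sag_ids, sag_ids),
        function(sid) {
          match_to_catalog(
            assemblies[[sid]]$loci[assemblies[[sid]]$loci$retained, , drop = FALSE],
            bulk_catalog,
            n = acfg$n, sample = sid
          )
        }
      )
    }
    qc <- qc_report(assemblies, bulk_matches, min_loci = config$qc$min_loci)
    qpath <- write_stage_tsv(
      select(as_tibble(qc), -"lorenz"),
      file.path(qc_dir, "qc_report.tsv")
    )
    lpath <- write_stage_tsv(
      qc |>
        as_tibble() |>
        select("sample", "lorenz") |>
        filter(!vapply(.data$lorenz, is.null, logical(1L))) |>
        tidyr::unnest("lorenz"),
      file.path(qc_dir, "lorenz.tsv")
    )
    artifacts <- c(artifacts, qpath, lpath)
    # replicate sharing for individuals sequenced more than once
    rep_groups <- truth$samples |>
      filter(.data$protocol == "sag", .data$sample_id %in% names(matches)) |>
      count(.data$individual_id) |>
      filter(.data$n > 1L)
    if (nrow(rep_groups) > 0L) {
      grp <- intersect(truth$samples$sample_id[
        truth$samples$individual_id == rep_groups$individual_id[1L] &
          truth$samples$protocol == "sag"
      ], names(matches))
      sh <- sharing_table(matches[grp])
      spath <- write_stage_tsv(sh$by_k, file.path(qc_dir, "sharing_k.tsv"))
      artifacts <- c(artifacts, spath)
    }
    note("[qc] %d/%d samples retained", sum(qc$retained), nrow(qc))
  })

  # --- coancestry ---------------------------------------------------------
  co_dir <- file.path(out_dir, "coancestry")
  dir.create(co_dir, showWarnings = FALSE)
  co <- NULL
  clustering <- NULL
  ari <- NA_real_
  stage("coancestry", {
    sag_retained <- qc$sample[qc$retained &
      qc$sample %in% truth$samples$sample_id[truth$samples$protocol == "sag"]]
    if (length(sag_retained) >= 2L) {
      pops <- stats::setNames(
        truth$samples$population[match(sag_retained, truth$samples$sample_id)],
        sag_retained
      )
      hap <- build_haplotype_matrix(matches[sag_retained], populations = pops)
      co <- coancestry(hap)
      k <- config$coancestry$k %||% scfg$n_populations
      clustering <- cluster_coancestry(co, k = k)
      ari <- score_recovery(
        clustering$labels$cluster,
        pops[clustering$labels$sample]
      )
      mpath <- write_stage_tsv(
        as_tibble(unclass(co), rownames = "sample"),
        file.path(co_dir, "coancestry.tsv")
      )
      lpath <- write_stage_tsv(clustering$labels, file.path(co_dir, "clusters.tsv"))
      artifacts <- c(artifacts, mpath, lpath)
      note(
        "[coancestry] %d individuals, %d shared loci, ARI %.3f",
        nrow(co), attr(co, "n_loci"), ari
      )
    } else {
      note("[coancestry] skipped: fewer than 2 retained single-cell samples")
    }
  })

  # --- summary + manifest -------------------------------------------------
  summary <- list(
    n_read_pairs = nrow(reads),
    n_samples = nrow(truth$samples),
    assigned_pairs = sum(dm$accounting$n[dm$accounting$category == "assigned"]),
    n_catalog_loci = nrow(catalog),
    median_loci = median(qc$n_loci),
    median_gini = median(qc$gini, na.rm = TRUE),
    samples_retained = sum(qc$retained),
    ari = ari
  )
  spath <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, spath)

  manifest <- tibble(
    path = sub(paste0("^", out_dir, "/?"), "", artifacts),
    bytes = file.size(artifacts),
    md5 = unname(tools::md5sum(artifacts))
  ) |> arrange(.data$path)
  write_stage_tsv(manifest, file.path(out_dir, "run_manifest.tsv"))

  invisible(list(
    manifest = manifest, summary = summary, out_dir = out_dir,
    truth = truth, demux = dm, assemblies = assemblies, catalog = catalog,
    matches = matches, qc = qc, coancestry = co, clustering = clustering,
    ari = ari
  ))
}
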