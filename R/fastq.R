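# FASTQ and manifest input/output. Files are standard 4-line Phred+33
# FASTQ written through Biostrings; the insert length of each pair is
# carried in the header comment (`insert=NNN`) so that downstream
# insert-length PCR deduplication works without alignment.

write_fastq_one <- function(seqs, quals, headers, path, compress) {
  x <- Biostrings::DNAStringSet(seqs)
  if (length(x) > 0L) {
    names(x) <- headers
  }
  # the constructor warns about dropping (empty) metadata columns
  qs <- suppressWarnings(
    Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(quals))
  )
  tryCatch(
    Biostrings::writeQualityScaledXStringSet(qs, path, compress = compress),
    error = function(e) {
      abort(sprintf("Failed to write FASTQ to '%s'.", path),
        class = "sagrad_io_error", parent = e
      )
    }
  )
  invisible(path)
}

#' Write read pairs to paired FASTQ files (plus optional manifest)
#'
#' @param reads Tibble of read pairs as produced by [generate_reads()]
#'   (columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`; `insert`
#'   optional and stored in the header comment when present).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` (plus `.gz` when `compress = TRUE`).
#' @param samples Optional sample table (e.g. `truth$samples`); when given,
#'   a `<prefix>_manifest.tsv` mapping sample to barcode and population is
#'   written alongside.
#' @param compress Gzip the FASTQ output.
#' @return Named character vector of the paths written.
#' @export
write_fastq <- function(reads, dir, prefix = "library", samples = NULL,
                        compress = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  r1 <- file.path(dir, paste0(prefix, "_R1", ext))
  r2 <- file.path(dir, paste0(prefix, "_R2", ext))
  headers <- if ("insert" %in% names(reads)) {
    paste0(reads$read_id, " insert=", reads$insert)
  } else {
    reads$read_id
  }
  write_fastq_one(reads$seq1, reads$qual1, headers, r1, compress)
  write_fastq_one(reads$seq2, reads$qual2, headers, r2, compress)
  out <- c(r1 = r1, r2 = r2)
  if (!is.null(samples)) {
    mpath <- file.path(dir, paste0(prefix, "_manifest.tsv"))
    readr::write_tsv(samples, mpath, progress = FALSE)
    out <- c(out, manifest = mpath)
  }
  out
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTQ file '%s' does not exist.", path),
      class = "sagrad_io_error"
    )
  }
  if (file.size(path) == 0L) {
    return(tibble(
      read_id = character(), insert = integer(),
      seq = character(), qual = character()
    ))
  }
  x <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      abort(sprintf("Failed to read FASTQ from '%s'.", path),
        class = "sagrad_io_error", parent = e
      )
    }
  )
  headers <- names(x)
  headers <- headers %||% character()
  tibble(
    read_id = sub(" .*$", "", headers),
    insert = suppressWarnings(as.integer(
      stringr::str_match(headers, " insert=(\\d+)")[, 2L]
    )),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Read paired FASTQ files into a tidy read-pair table
#'
#' @param r1,r2 Paths to the mate FASTQ files (optionally gzipped). Mates
#'   must be in matched order; a count or identifier mismatch is an error.
#' @return Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2` and
#'   `insert` (NA when the header carries no insert annotation).
#' @export
read_fastq <- function(r1, r2) {
  m1 <- read_fastq_one(r1)
  m2 <- read_fastq_one(r2)
  if (nrow(m1) != nrow(m2)) {
    abort(sprintf(
      "Mate-count mismatch: %d reads in '%s' vs %d in '%s'.",
      nrow(m1), r1, nrow(m2), r2
    ), class = "sagrad_format_error")
  }
  if (nrow(m1) > 0L && any(m1$read_id != m2$read_id)) {
    abort("Mate identifiers are not in matched order.",
      class = "sagrad_format_error"
    )
  }
  tibble(
    read_id = m1$read_id,
    seq1 = m1$seq, qual1 = m1$qual,
    seq2 = m2$seq, qual2 = m2$qual,
    insert = m1$insert
  )
}

#' Write simulation ground truth as JSON lines
#'
#' One JSON object per line; each line carries a `table` field naming the
#' section (`config`, `samples`, `haplotypes`, `weights`), so the file is
#' self-describing and diff-friendly.
#'
#' @param truth A `sagrad_truth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(
    c(list(table = "config", version = 1L), unclass(truth$config)),
    auto_unbox = TRUE
  ), con)
  sections <- list(samples = truth$samples, haplotypes = truth$haplotypes)
  if (!is.null(truth$weights)) sections$weights <- truth$weights
  for (nm in names(sections)) {
    df <- mutate(sections[[nm]], table = nm, .before = 1L)
    jsonlite::stream_out(df, con, verbose = FALSE)
  }
  invisible(path)
}
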