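# Demultiplexing and read-level filters. The filter cascade mirrors the
# standard RAD preprocessing: inline-barcode assignment (one mismatch
# rescued), exact cut-site remnant check, uncalled-base and sliding-window
# quality filters, optional adapter detection, and an optional exact k-mer
# contaminant screen. Each read receives at most one discard reason: the
# first failing filter.

DISCARD_REASONS <- c(
  "no_barcode", "ambiguous_barcode", "no_cutsite", "uncalled_base",
  "low_quality", "adapter", "contaminant"
)

#' Build and validate a sample sheet
#'
#' @param sample_id Character vector of sample names.
#' @param barcode Character vector of inline barcodes (equal lengths).
#' @param min_dist Pairwise Hamming distance below which a warning is
#'   raised (one-mismatch rescue is only unambiguous at distance >= 3).
#' @return Tibble with columns `sample_id` and `barcode`.
#' @export
#' @examples
#' sample_sheet(c("a", "b"), c("AAAAAAA", "CCCCCCC"))
sample_sheet <- function(sample_id, barcode, min_dist = 3L) {
  if (length(sample_id) == 0L) {
    abort("Sample sheet is empty.", class = "sagrad_sheet_error")
  }
  if (length(sample_id) != length(barcode)) {
    abort("`sample_id` and `barcode` must have equal length.",
      class = "sagrad_sheet_error"
    )
  }
  barcode <- toupper(barcode)
  if (anyDuplicated(barcode)) {
    abort("Barcodes must be unique.", class = "sagrad_sheet_error")
  }
  if (length(unique(nchar(barcode))) != 1L) {
    abort("Barcodes must share one length.", class = "sagrad_sheet_error")
  }
  if (length(barcode) > 1L) {
    pairs <- combn(seq_along(barcode), 2L)
    dmin <- min(str_hamming(barcode[pairs[1L, ]], barcode[pairs[2L, ]]))
    if (dmin < min_dist) {
      warn(sprintf(
        "Minimum pairwise barcode distance is %d (< %d); one-mismatch rescue may be ambiguous.",
        dmin, min_dist
      ))
    }
  }
  tibble(sample_id = as.character(sample_id), barcode = barcode)
}

#' Assign reads to samples by inline barcode
#'
#' An exact barcode match wins; otherwise the unique barcode within
#' `max_mismatch` substitutions wins (barcode rescue). Reads matching no
#' barcode are discarded as `no_barcode`; reads equidistant from two or
#' more barcodes as `ambiguous_barcode`. On assignment the barcode is
#' trimmed from `seq1`/`qual1`.
#'
#' @param reads Tibble with at least `seq1` and `qual1`.
#' @param sheet Sample sheet from [sample_sheet()].
#' @param max_mismatch Maximum substitutions allowed for rescue.
#' @return `reads` with columns `sample` (assigned sample or `NA`) and
#'   `discard_reason` added, and barcodes trimmed from assigned reads.
#' @export
assign_barcodes <- function(reads, sheet, max_mismatch = 1L) {
  if (!nrow(sheet)) {
    abort("Sample sheet is empty.", class = "sagrad_sheet_error")
  }
  bl <- nchar(sheet$barcode[1L])
  n <- nrow(reads)
  if (n == 0L) {
    return(mutate(reads,
      sample = character(), discard_reason = character()
    ))
  }
  if (any(nchar(reads$seq1) < bl)) {
    abort("All read-1 sequences must be at least as long as the barcode.",
      class = "sagrad_format_error"
    )
  }
  prefix <- substr(reads$seq1, 1L, bl)
  hit <- match(prefix, sheet$barcode)

  todo <- which(is.na(hit))
  reason <- rep(NA_character_, n)
  if (length(todo) > 0L && max_mismatch > 0L) {
    pm <- matrix(
      unlist(strsplit(prefix[todo], "", fixed = TRUE)),
      nrow = length(todo), byrow = TRUE
    )
    mm <- sapply(sheet$barcode, function(bc) {
      bcc <- strsplit(bc, "", fixed = TRUE)[[1L]]
      rowSums(pm != matrix(bcc, nrow(pm), bl, byrow = TRUE))
    })
    mm <- matrix(mm, nrow = length(todo))
    best <- apply(mm, 1L, min)
    nbest <- rowSums(mm == best)
    ok <- best <= max_mismatch & nbest == 1L
    hit[todo[ok]] <- apply(mm[ok, , drop = FALSE], 1L, which.min)
    reason[todo[best <= max_mismatch & nbest > 1L]] <- "ambiguous_barcode"
  }
  reason[is.na(hit) & is.na(reason)] <- "no_barcode"

  assigned <- !is.na(hit)
  reads$sample <- ifelse(assigned, sheet$sample_id[hit], NA_character_)
  reads$discard_reason <- reason
  reads$seq1[assigned] <- substr(reads$seq1[assigned], bl + 1L, nchar(reads$seq1[assigned]))
  reads$qual1[assigned] <- substr(reads$qual1[assigned], bl + 1L, nchar(reads$qual1[assigned]))
  reads
}

#' Read-level filter predicates
#'
#' Each predicate is vectorised over a read table and returns a logical
#' vector, `TRUE` where the read passes.
#'
#' * `check_cutsite()`: read 1 (barcode already trimmed) must begin with
#'   the exact cut-site remnant ("intact" is read literally, zero
#'   mismatches).
#' * `filter_uncalled()`: neither mate may contain an `N`.
#' * `filter_quality()`: fails when any sliding window of length
#'   `ceiling(window_frac * read length)` has mean Phred below
#'   `phred_floor` on either mate.
#' * `filter_adapter()`: fails when the adapter occurs at any offset in
#'   either mate with at most `max_mismatch` substitutions; at the 3' end
#'   a prefix of the adapter counts when the overlap is at least
#'   `min_overlap` bases.
#'
#' @param reads Tibble with `seq1`, `seq2`, `qual1`, `qual2` as relevant.
#' @param remnant Cut-site remnant string.
#' @param window_frac Sliding-window length as a fraction of read length.
#' @param phred_floor Minimum acceptable window mean Phred score.
#' @param adapter Adapter sequence to search for.
#' @param max_mismatch Substitutions tolerated in an adapter occurrence.
#' @param min_overlap Minimum 3'-overhang overlap considered.
#' @return Logical pass vector.
#' @name read_filters
NULL

#' @rdname read_filters
#' @export
check_cutsite <- function(reads, remnant = "TGCAGG") {
  startsWith(reads$seq1, remnant)
}

#' @rdname read_filters
#' @export
filter_uncalled <- function(reads) {
  !(grepl("N", reads$seq1, fixed = TRUE) | grepl("N", reads$seq2, fixed = TRUE))
}

#' @rdname read_filters
#' @export
filter_quality <- function(reads, window_frac = 0.15, phred_floor = 10) {
  ok_one <- function(quals) {
    if (any(!grepl("^[\\x21-\\x7e]*$", quals, perl = TRUE))) {
      abort("Malformed quality string (non-printable Phred+33 characters).",
        class = "sagrad_format_error"
      )
    }
    uq <- unique(quals)
    pass_u <- vapply(
      uq, function(q) min_window_mean(q, window_frac) >= phred_floor,
      logical(1L)
    )
    pass_u[match(quals, uq)]
  }
  ok_one(reads$qual1) & ok_one(reads$qual2)
}

# minimum substitution count of `adapter` over all placements in `seqs`,
# including 3'-end prefix overhangs of >= min_overlap bases
adapter_min_mismatch <- function(seqs, adapter, min_overlap = 8L) {
  n <- length(seqs)
  if (n == 0L) {
    return(integer())
  }
  len <- nchar(seqs[1L])
  k <- nchar(adapter)
  ac <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  sm <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = n, byrow = TRUE)
  best <- rep(k, n)
  for (off in seq_len(max(0L, len - k + 1L))) {
    mm <- rowSums(sm[, off:(off + k - 1L), drop = FALSE] !=
      matrix(ac, n, k, byrow = TRUE))
    best <- pmin(best, mm)
  }
  # 3' overhang: adapter prefix hanging off the read end
  max_ov <- min(k - 1L, len)
  if (max_ov >= min_overlap) {
    for (ov in seq.int(min_overlap, max_ov)) {
      off <- len - ov + 1L
      mm <- rowSums(sm[, off:len, drop = FALSE] !=
        matrix(ac[seq_len(ov)], n, ov, byrow = TRUE))
      best <- pmin(best, mm)
    }
  }
  best
}

#' @rdname read_filters
#' @export
filter_adapter <- function(reads, adapter, max_mismatch = 2L, min_overlap = 8L) {
  adapter <- toupper(adapter)
  if (nchar(adapter) > min(nchar(reads$seq1), nchar(reads$seq2))) {
    abort("Adapter longer than the reads.", class = "sagrad_config_error")
  }
  hit1 <- adapter_min_mismatch(reads$seq1, adapter, min_overlap) <= max_mismatch
  hit2 <- adapter_min_mismatch(reads$seq2, adapter, min_overlap) <= max_mismatch
  !(hit1 | hit2)
}

# exact k-mer set (both strands) of the reference sequences
kmer_index <- function(ref, k) {
  seqs <- c(ref, revcomp(ref))
  km <- lapply(seqs, function(s) {
    len <- nchar(s)
    if (len < k) {
      return(character())
    }
    substring(s, 1:(len - k + 1L), k:len)
  })
  unique(unlist(km))
}

kmer_hit_frac <- function(seqs, idx, k) {
  n <- length(seqs)
  if (n == 0L) {
    return(numeric())
  }
  nk <- pmax(nchar(seqs) - k + 1L, 0L)
  out <- numeric(n)
  has <- nk > 0L
  if (!any(has)) {
    return(out)
  }
  rid <- rep(seq_len(n), nk)
  starts <- unlist(lapply(nk, seq_len), use.names = FALSE)
  hits <- substring(seqs[rid], starts, starts + k - 1L) %in% idx
  agg <- rowsum(as.numeric(hits), rid)
  ids <- as.integer(rownames(agg))
  out[ids] <- agg[, 1L] / nk[ids]
  out
}

#' Screen reads against a contaminant reference by exact k-mer matching
#'
#' A deliberately simple, fully reproducible stand-in for taxonomic read
#' classification: a read pair is called contaminant when at least
#' `min_hit_frac` of the k-mers of either mate occur exactly (on either
#' strand) in the contaminant reference.
#'
#' @param reads Tibble with `seq1` and `seq2`.
#' @param contaminant_ref Path to a FASTA file, a `DNAStringSet`, or a
#'   character vector of reference sequences.
#' @param k K-mer length.
#' @param min_hit_frac Minimum fraction of matching k-mers to call a read
#'   contaminant.
#' @return List with elements `kept` and `contaminant` (both tibbles), and
#'   `flag`, the logical contaminant indicator aligned with `reads`.
#' @export
screen_contaminants <- function(reads, contaminant_ref, k = 31L,
                                min_hit_frac = 0.5) {
  ref <- contaminant_reference(contaminant_ref)
  if (length(ref) == 0L || all(nchar(ref) == 0L)) {
    abort("Contaminant reference is empty.", class = "sagrad_config_error")
  }
  if (nrow(reads) > 0L && k > min(nchar(reads$seq1), nchar(reads$seq2))) {
    abort("`k` exceeds the read length.", class = "sagrad_config_error")
  }
  idx <- kmer_index(ref, k)
  flag <- logical(nrow(reads))
  chunk <- 5000L
  starts <- seq(1L, max(nrow(reads), 1L), by = chunk)
  for (s in starts) {
    if (s > nrow(reads)) break
    ix <- s:min(s + chunk - 1L, nrow(reads))
    f1 <- kmer_hit_frac(reads$seq1[ix], idx, k)
    f2 <- kmer_hit_frac(reads$seq2[ix], idx, k)
    flag[ix] <- pmax(f1, f2) >= min_hit_frac
  }
  list(
    kept = reads[!flag, , drop = FALSE],
    contaminant = reads[flag, , drop = FALSE],
    flag = flag
  )
}

contaminant_reference <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    return(as.character(x))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(as.character(Biostrings::readDNAStringSet(x)))
  }
  if (is.character(x)) {
    return(toupper(x))
  }
  abort("`contaminant_ref` must be a FASTA path, DNAStringSet, or character vector.",
    class = "sagrad_config_error"
  )
}

#' Demultiplex a pooled paired-end read table
#'
#' Applies the filter cascade in fixed order -- barcode, cut site, uncalled
#' base, quality, adapter (when an adapter is given), contaminant screen
#' (when a reference is given) -- and assigns each read pair to exactly one
#' bin: a sample or its first failing discard category.
#'
#' @param reads Tibble from [read_fastq()] or [generate_reads()].
#' @param sheet Sample sheet from [sample_sheet()].
#' @param max_mismatch Barcode mismatches rescued.
#' @param remnant Cut-site remnant required at the start of trimmed read 1.
#' @param window_frac,phred_floor Sliding-window quality filter parameters.
#' @param adapter Optional adapter sequence; `NULL` skips the filter.
#' @param adapter_max_mismatch Substitutions tolerated in an adapter match.
#' @param contaminant_ref Optional contaminant reference; `NULL` skips the
#'   screen.
#' @param k,min_hit_frac Contaminant-screen parameters.
#' @return List of class `sagrad_demux`: `reads` (the input with `sample`,
#'   `discard_reason` and trimmed sequences) and `accounting`, a tibble of
#'   per-category read counts whose total equals the input count.
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 1L, remnant = "TGCAGG",
                        window_frac = 0.15, phred_floor = 10,
                        adapter = NULL, adapter_max_mismatch = 2L,
                        contaminant_ref = NULL, k = 31L, min_hit_frac = 0.5) {
  res <- assign_barcodes(reads, sheet, max_mismatch)
  alive <- is.na(res$discard_reason)

  fail <- alive & !check_cutsite(res, remnant)
  res$discard_reason[fail] <- "no_cutsite"
  alive <- alive & !fail

  fail <- alive & !filter_uncalled(res)
  res$discard_reason[fail] <- "uncalled_base"
  alive <- alive & !fail

  if (any(alive)) {
    fail <- rep(FALSE, nrow(res))
    fail[alive] <- !filter_quality(res[alive, ], window_frac, phred_floor)
    res$discard_reason[fail] <- "low_quality"
    alive <- alive & !fail
  }

  if (!is.null(adapter) && any(alive)) {
    fail <- rep(FALSE, nrow(res))
    fail[alive] <- !filter_adapter(res[alive, ], adapter, adapter_max_mismatch)
    res$discard_reason[fail] <- "adapter"
    alive <- alive & !fail
  }

  if (!is.null(contaminant_ref) && any(alive)) {
    scr <- screen_contaminants(res[alive, ], contaminant_ref, k, min_hit_frac)
    fail <- rep(FALSE, nrow(res))
    fail[alive] <- scr$flag
    res$discard_reason[fail] <- "contaminant"
    alive <- alive & !fail
  }

  res$sample[!is.na(res$discard_reason)] <- NA_character_
  category <- ifelse(is.na(res$discard_reason), "assigned", res$discard_reason)
  accounting <- tibble(
    category = factor(category, levels = c("assigned", DISCARD_REASONS))
  ) |>
    count(.data$category, name = "n", .drop = FALSE) |>
    mutate(category = as.character(.data$category))

  structure(list(reads = res, accounting = accounting), class = "sagrad_demux")
}

#' @export
print.sagrad_demux <- function(x, ...) {
  n <- sum(x$accounting$n)
  ass <- x$accounting$n[x$accounting$category == "assigned"]
  cat(sprintf(
    "<sagrad_demux> %d read pairs: %d assigned (%.1f%%), %d discarded\n",
    n, ass, if (n > 0) 100 * ass / n else 0, n - ass
  ))
  print(x$accounting)
  invisible(x)
}
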