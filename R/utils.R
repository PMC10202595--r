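# Low-level sequence utilities shared across the simulator, demultiplexer
# and assembler. All sequences are plain uppercase character vectors over
# {A,C,G,T,N}; Hamming distance is only defined for equal-length strings.

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between pairs of equal-length strings
#'
#' Vectorised over pairs: `str_hamming(a, b)[i]` is the number of positions
#' at which `a[i]` and `b[i]` differ.
#'
#' @param a,b Character vectors of equal-length strings (recycled to a
#'   common length).
#' @return Integer vector of distances.
#' @export
#' @examples
#' str_hamming("TGCAGG", "TGCAGC")
str_hamming <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    return(integer())
  }
  if (any(nchar(a) != nchar(b))) {
    abort("Hamming distance requires equal-length strings.",
      class = "sagrad_length_error"
    )
  }
  unname(mapply(
    function(x, y) sum(charToRaw(x) != charToRaw(y)),
    a, b,
    USE.NAMES = FALSE
  ))
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) {
    return(character())
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# n random DNA strings of a given length (consumes the current RNG stream)
random_dna <- function(n, len) {
  if (n == 0L || len == 0L) {
    return(rep("", n))
  }
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# substitute the base at `pos` of `seq` with a different random base
point_mutation <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(DNA_BASES, old), 1L)
  substr(seq, pos, pos) <- new
  seq
}

# per-site substitutions at probability `prob`, restricted to positions
# first_mutable..nchar (keeps the cut-site remnant intact)
mutate_seqs <- function(seqs, prob, first_mutable = 1L) {
  if (prob <= 0) {
    return(seqs)
  }
  for (i in seq_along(seqs)) {
    nsite <- nchar(seqs[i]) - first_mutable + 1L
    k <- rbinom(1L, nsite, prob)
    if (k > 0L) {
      pos <- sample.int(nsite, k) + first_mutable - 1L
      for (p in pos) seqs[i] <- point_mutation(seqs[i], p)
    }
  }
  seqs
}

# chunk boundaries used by the pigeonhole candidate search: any two strings
# within Hamming distance d must agree exactly on at least one of d+1 chunks
chunk_bounds <- function(len, n_chunks) {
  floor(seq(0L, len, length.out = n_chunks + 1L))
}

# all index pairs (i < j) of `seqs` with Hamming distance <= max_dist,
# found by exact-chunk bucketing then verified
hamming_edges <- function(seqs, max_dist) {
  empty <- cbind(i = integer(), j = integer())
  n <- length(seqs)
  if (n < 2L) {
    return(empty)
  }
  if (length(unique(nchar(seqs))) != 1L) {
    abort("All sequences must have equal length.", class = "sagrad_length_error")
  }
  nb <- chunk_bounds(nchar(seqs[[1L]]), max_dist + 1L)
  cand <- vector("list", max_dist + 1L)
  for (ci in seq_len(max_dist + 1L)) {
    grp <- split(seq_len(n), substr(seqs, nb[ci] + 1L, nb[ci + 1L]))
    grp <- grp[lengths(grp) > 1L]
    if (length(grp)) {
      cand[[ci]] <- do.call(rbind, lapply(grp, function(ix) {
        cb <- combn(ix, 2L)
        cbind(i = cb[1L, ], j = cb[2L, ])
      }))
    }
  }
  pr <- do.call(rbind, cand)
  if (is.null(pr) || nrow(pr) == 0L) {
    return(empty)
  }
  pr <- unique(pr)
  d <- str_hamming(seqs[pr[, 1L]], seqs[pr[, 2L]])
  pr[d <= max_dist, , drop = FALSE]
}

# connected-component membership (1-based, numbered by first occurrence)
# for n nodes joined by the given edge matrix
seq_components <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges[, c("i", "j"), drop = FALSE]))
  }
  memb <- igraph::components(g)$membership
  match(memb, unique(memb))
}

# for each query string, all reference strings within max_dist:
# tibble(query = index into `query`, ref = index into `ref`, dist)
nearest_neighbors <- function(query, ref, max_dist) {
  empty <- tibble(query = integer(), ref = integer(), dist = integer())
  if (length(query) == 0L || length(ref) == 0L) {
    return(empty)
  }
  lens <- unique(c(nchar(query), nchar(ref)))
  if (length(lens) != 1L) {
    abort("Query and reference sequences must share one common length.",
      class = "sagrad_length_error"
    )
  }
  nb <- chunk_bounds(lens, max_dist + 1L)
  cand <- vector("list", max_dist + 1L)
  for (ci in seq_len(max_dist + 1L)) {
    qc <- substr(query, nb[ci] + 1L, nb[ci + 1L])
    rmap <- split(seq_along(ref), substr(ref, nb[ci] + 1L, nb[ci + 1L]))
    hit <- rmap[qc]
    nper <- lengths(hit)
    if (sum(nper) > 0L) {
      cand[[ci]] <- cbind(
        q = rep(seq_along(query), nper),
        r = unlist(hit, use.names = FALSE)
      )
    }
  }
  pr <- do.call(rbind, cand)
  if (is.null(pr) || nrow(pr) == 0L) {
    return(empty)
  }
  pr <- unique(pr)
  d <- str_hamming(query[pr[, 1L]], ref[pr[, 2L]])
  keep <- d <= max_dist
  tibble(query = pr[keep, 1L], ref = pr[keep, 2L], dist = d[keep])
}

# minimum sliding-window mean of Phred scores (window = ceiling(frac * len))
min_window_mean <- function(qual, window_frac) {
  s <- utf8ToInt(qual) - 33L
  len <- length(s)
  w <- max(1L, ceiling(window_frac * len))
  if (w >= len) {
    return(mean(s))
  }
  cs <- cumsum(c(0L, s))
  min(cs[(w + 1L):(len + 1L)] - cs[1L:(len - w + 1L)]) / w
}
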