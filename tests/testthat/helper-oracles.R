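# Independent brute-force oracles the implementation is checked against.

# Hamming distance by direct character comparison (independent of the
# package's raw-byte implementation)
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# connected components under "Hamming distance <= max_dist" by all-pairs
# comparison and breadth-first search
oracle_components <- function(seqs, max_dist) {
  n <- length(seqs)
  if (n == 0L) {
    return(integer())
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- oracle_hamming(seqs[i], seqs[j]) <= max_dist
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (is.na(comp[s])) {
      cid <- cid + 1L
      queue <- s
      while (length(queue) > 0L) {
        v <- queue[1L]
        queue <- queue[-1L]
        if (is.na(comp[v])) {
          comp[v] <- cid
          queue <- c(queue, which(adj[v, ] & is.na(comp)))
        }
      }
    }
  }
  comp
}

# canonical form of a partition: list of sorted index sets, ordered by
# smallest member, so two partitions can be compared with identical()
canonical_partition <- function(membership) {
  sets <- lapply(split(seq_along(membership), membership), sort)
  unname(sets[order(vapply(sets, min, integer(1L)))])
}

# random set of related sequences: a few cluster centres plus mutated
# variants, so merge instances contain non-trivial components
random_related_seqs <- function(n, len = 30L, n_centres = 8L, max_mut = 3L) {
  bases <- c("A", "C", "G", "T")
  centres <- replicate(n_centres, paste(sample(bases, len, TRUE), collapse = ""))
  out <- character(n)
  for (i in seq_len(n)) {
    s <- sample(centres, 1L)
    for (p in sample.int(len, sample.int(max_mut + 1L, 1L) - 1L)) {
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, old), 1L)
    }
    out[i] <- s
  }
  unique(out)
}

# brute-force adapter scan: every full placement plus 3' prefix overhangs
oracle_adapter_hit <- function(seq, adapter, max_mismatch, min_overlap = 8L) {
  len <- nchar(seq)
  k <- nchar(adapter)
  for (off in seq_len(max(0L, len - k + 1L))) {
    if (oracle_hamming(substr(seq, off, off + k - 1L), adapter) <= max_mismatch) {
      return(TRUE)
    }
  }
  ovs <- seq_len(min(k - 1L, len))
  for (ov in ovs[ovs >= min_overlap]) {
    if (oracle_hamming(substr(seq, len - ov + 1L, len), substr(adapter, 1L, ov)) <= max_mismatch) {
      return(TRUE)
    }
  }
  FALSE
}

# two-sided 99% binomial confidence bounds on a count
binom_ci99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p)
}

expect_within_ci99 <- function(count, n, p) {
  ci <- binom_ci99(n, p)
  expect_gte(count, ci[1L])
  expect_lte(count, ci[2L])
}
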