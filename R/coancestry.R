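# Population-structure recovery from shared RAD loci: a simplified
# chromosome-painting coancestry matrix (nearest-haplotype attribution,
# ties split evenly) followed by average-linkage hierarchical clustering.
# This is a desk-scale stand-in for full coancestry model fitting: it
# preserves the semantics of the clustered coancestry heat map without any
# MCMC.

#' Build the individuals-by-loci haplotype matrix
#'
#' Keeps only catalog loci matched by every individual and records each
#' individual's allele sequences at those loci.
#'
#' @param matches List of `sagrad_matches` (one per individual, named by
#'   individual) or a combined tibble with a `sample` column. All match
#'   sets must target the same catalog.
#' @param populations Optional named character vector of population labels
#'   (names are individuals), stored for later evaluation.
#' @return Tibble of class `sagrad_hapmat` (`sample`, `catalog_id`,
#'   `alleles` list column) with attributes `samples`, `loci` and
#'   `populations`.
#' @export
build_haplotype_matrix <- function(matches, populations = NULL) {
  if (is.data.frame(matches)) {
    combined <- matches
  } else {
    hashes <- unique(unlist(lapply(matches, attr, "catalog_hash")))
    if (length(hashes) > 1L) {
      abort("Individuals were matched against different catalogs.",
        class = "sagrad_input_error"
      )
    }
    combined <- list_rbind(lapply(matches, as_tibble))
  }
  combined <- filter(combined, .data$status == "matched")
  samples <- sort(unique(combined$sample))
  shared <- combined |>
    distinct(.data$catalog_id, .data$sample) |>
    count(.data$catalog_id) |>
    filter(.data$n == length(samples)) |>
    pull(.data$catalog_id)
  if (length(shared) == 0L) {
    abort("No catalog locus is present in every individual.",
      class = "sagrad_degenerate_input"
    )
  }
  cells <- combined |>
    filter(.data$catalog_id %in% shared) |>
    group_by(.data$sample, .data$catalog_id) |>
    summarise(
      alleles = list(sort(unique(unlist(.data$alleles)))),
      .groups = "drop"
    ) |>
    arrange(.data$sample, .data$catalog_id)
  structure(cells,
    class = c("sagrad_hapmat", class(cells)),
    samples = samples, loci = sort(shared),
    populations = populations
  )
}

#' Nearest-haplotype coancestry matrix
#'
#' For every individual i and shared locus, the distance to every other
#' individual j is the minimum Hamming distance between any allele of i
#' and any allele of j at that locus; the nearest neighbours (the argmin
#' set) share one unit of coancestry equally. Every (individual, locus)
#' therefore contributes exactly 1, so each row sums to the number of
#' shared loci. The matrix is directional and has a zero diagonal.
#'
#' @param hap A `sagrad_hapmat` from [build_haplotype_matrix()].
#' @return Numeric matrix of class `sagrad_coancestry` with individuals as
#'   dimnames and attributes `n_loci` and `populations`.
#' @export
coancestry <- function(hap) {
  samples <- attr(hap, "samples")
  loci <- attr(hap, "loci")
  n <- length(samples)
  if (n < 2L) {
    abort("Coancestry requires at least two individuals.",
      class = "sagrad_input_error"
    )
  }
  mat <- matrix(0, n, n, dimnames = list(samples, samples))
  cell_list <- split(hap$alleles, hap$catalog_id)
  sample_list <- split(hap$sample, hap$catalog_id)
  for (loc in as.character(loci)) {
    alleles <- cell_list[[loc]][match(samples, sample_list[[loc]])]
    useq <- unique(unlist(alleles))
    dmat_u <- matrix(0L, length(useq), length(useq))
    if (length(useq) > 1L) {
      pr <- t(combn(length(useq), 2L))
      d <- str_hamming(useq[pr[, 1L]], useq[pr[, 2L]])
      dmat_u[pr] <- d
      dmat_u[pr[, 2:1, drop = FALSE]] <- d
    }
    idx <- lapply(alleles, match, useq)
    dmin <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) {
          dmin[i, j] <- min(dmat_u[idx[[i]], idx[[j]]])
        }
      }
    }
    for (i in seq_len(n)) {
      dv <- dmin[i, -i]
      nearest <- which(dv == min(dv))
      others <- seq_len(n)[-i]
      mat[i, others[nearest]] <- mat[i, others[nearest]] + 1 / length(nearest)
    }
  }
  structure(mat,
    class = "sagrad_coancestry",
    n_loci = length(loci),
    populations = attr(hap, "populations")
  )
}

#' @export
print.sagrad_coancestry <- function(x, ...) {
  cat(sprintf(
    "<sagrad_coancestry> %d individuals over %d shared loci\n",
    nrow(x), attr(x, "n_loci")
  ))
  print(unclass(x), ...)
  invisible(x)
}

#' Cluster a coancestry matrix
#'
#' Symmetrises the (directional) coancestry matrix, converts similarity to
#' dissimilarity (maximum minus value) and applies average-linkage
#' hierarchical clustering. The leaf order is suitable for heat-map
#' display; an optional cut at `k` yields cluster labels.
#'
#' @param mat A `sagrad_coancestry` matrix.
#' @param k Optional number of clusters to cut to.
#' @return List of class `sagrad_clustering`: `hclust`, `order` (leaf
#'   order of individual names) and `labels` (tibble `sample`, `cluster`;
#'   `NULL` when `k` is not given).
#' @export
cluster_coancestry <- function(mat, k = NULL) {
  n <- nrow(mat)
  if (!is.null(k) && (k < 1L || k > n)) {
    abort(sprintf("`k` must be between 1 and %d.", n),
      class = "sagrad_input_error"
    )
  }
  sym <- (unclass(mat) + t(unclass(mat))) / 2
  dis <- max(sym) - sym
  hc <- hclust(as.dist(dis), method = "average")
  labels <- NULL
  if (!is.null(k)) {
    cl <- cutree(hc, k = k)
    labels <- tibble(sample = names(cl), cluster = unname(cl))
  }
  structure(
    list(hclust = hc, order = rownames(mat)[hc$order], labels = labels),
    class = "sagrad_clustering"
  )
}

#' @export
print.sagrad_clustering <- function(x, ...) {
  cat(sprintf(
    "<sagrad_clustering> %d individuals%s\n",
    length(x$order),
    if (is.null(x$labels)) "" else sprintf(", cut to %d clusters", max(x$labels$cluster))
  ))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Quantifies how well inferred cluster labels recover known population
#' labels: 1 for identical partitions, about 0 for independent ones.
#' Computed from the contingency table by the standard
#' pair-counting formula.
#'
#' @param labels,truth Equal-length label vectors (any atomic type).
#' @return Adjusted Rand index in `[-1, 1]`.
#' @export
#' @examples
#' score_recovery(c(1, 1, 2, 2), c("a", "a", "b", "b"))
score_recovery <- function(labels, truth) {
  if (length(labels) != length(truth)) {
    abort("`labels` and `truth` must have equal length.",
      class = "sagrad_input_error"
    )
  }
  tab <- table(labels, truth)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  expected <- a * b / comb2(sum(tab))
  maximum <- (a + b) / 2
  if (maximum == expected) {
    return(1)
  }
  (sum_ij - expected) / (maximum - expected)
}

#' Mean within- and between-population coancestry
#'
#' @param mat A `sagrad_coancestry` matrix.
#' @param populations Named population labels (names are individuals);
#'   defaults to the labels stored on the matrix.
#' @return List with `within` and `between` mean off-diagonal coancestry.
#' @export
coancestry_contrast <- function(mat, populations = NULL) {
  populations <- populations %||% attr(mat, "populations")
  if (is.null(populations)) {
    abort("Population labels are required.", class = "sagrad_input_error")
  }
  pops <- populations[rownames(mat)]
  same <- outer(pops, pops, "==")
  diag(same) <- NA
  m <- unclass(mat)
  list(
    within = mean(m[which(same)]),
    between = mean(m[which(!same)])
  )
}
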