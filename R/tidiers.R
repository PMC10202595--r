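# broom-style tidiers for the fitted/derived result objects.

#' Tidy a coancestry matrix into long form
#'
#' @param x A `sagrad_coancestry` matrix.
#' @param ... Unused.
#' @return Tibble with `from`, `to` and `coancestry`.
#' @method tidy sagrad_coancestry
#' @export
tidy.sagrad_coancestry <- function(x, ...) {
  as_tibble(unclass(x), rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "coancestry")
}

#' One-row summary of a coancestry matrix
#'
#' Reports the number of individuals and shared loci and, when population
#' labels are attached, the mean within- and between-population
#' coancestry.
#'
#' @param x A `sagrad_coancestry` matrix.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance sagrad_coancestry
#' @export
glance.sagrad_coancestry <- function(x, ...) {
  out <- tibble(
    n_individuals = nrow(x),
    n_loci = attr(x, "n_loci"),
    within_mean = NA_real_,
    between_mean = NA_real_
  )
  if (!is.null(attr(x, "populations"))) {
    ct <- coancestry_contrast(x)
    out$within_mean <- ct$within
    out$between_mean <- ct$between
  }
  out
}

#' Tidy a coancestry clustering
#'
#' @param x A `sagrad_clustering` from [cluster_coancestry()].
#' @param ... Unused.
#' @return Tibble with `sample`, `order` (leaf position) and, when the
#'   tree was cut, `cluster`.
#' @method tidy sagrad_clustering
#' @export
tidy.sagrad_clustering <- function(x, ...) {
  out <- tibble(sample = x$order, order = seq_along(x$order))
  if (!is.null(x$labels)) {
    out <- left_join(out, x$labels, by = "sample")
  }
  out
}

#' One-row summary of a coancestry clustering
#'
#' @param x A `sagrad_clustering`.
#' @param ... Unused.
#' @return A one-row tibble with `n_individuals` and `k`.
#' @method glance sagrad_clustering
#' @export
glance.sagrad_clustering <- function(x, ...) {
  tibble(
    n_individuals = length(x$order),
    k = if (is.null(x$labels)) NA_integer_ else max(x$labels$cluster)
  )
}

#' Tidy a replicate sharing table
#'
#' @param x A `sagrad_sharing` from [sharing_table()].
#' @param ... Unused.
#' @return The `by_k` tibble (`k`, `n_loci`).
#' @method tidy sagrad_sharing
#' @export
tidy.sagrad_sharing <- function(x, ...) {
  x$by_k
}
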