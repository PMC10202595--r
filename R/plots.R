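# ggplot2 displays for the QC and coancestry result types.

#' Lorenz curves of coverage uniformity
#'
#' One curve per sample; the dashed diagonal is perfectly uniform
#' coverage.
#'
#' @param qc A `sagrad_qc` report (with its `lorenz` list column), or a
#'   tibble with columns `sample`, `frac_loci`, `frac_reads`.
#' @return A ggplot object.
#' @export
plot_lorenz <- function(qc) {
  df <- if ("lorenz" %in% names(qc)) {
    qc |>
      as_tibble() |>
      select("sample", "lorenz") |>
      filter(!vapply(.data$lorenz, is.null, logical(1L))) |>
      tidyr::unnest("lorenz")
  } else {
    qc
  }
  ggplot2::ggplot(df, ggplot2::aes(
    .data$frac_loci, .data$frac_reads,
    colour = .data$sample
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Cumulative fraction of loci",
      y = "Cumulative fraction of reads",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Depth distribution of assembled loci
#'
#' Density of per-locus total depth on a log axis, one panel-free layer
#' per sample, with the per-sample median marked.
#'
#' @param assemblies Named list of `sagrad_assembly` objects.
#' @return A ggplot object.
#' @export
plot_depth_distribution <- function(assemblies) {
  df <- purrr::imap(assemblies, function(a, sid) {
    tibble(sample = sid, depth = a$loci$total_depth[a$loci$retained])
  }) |> list_rbind()
  med <- df |>
    group_by(.data$sample) |>
    summarise(m = median(.data$depth))
  ggplot2::ggplot(df, ggplot2::aes(.data$depth, colour = .data$sample)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(
      data = med,
      ggplot2::aes(xintercept = .data$m, colour = .data$sample),
      linetype = "dotted"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Locus depth (reads)", y = "Density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of a clustered coancestry matrix
#'
#' @param object A `sagrad_coancestry` matrix.
#' @param order Optional leaf order (e.g. from [cluster_coancestry()]);
#'   defaults to the clustering's order.
#' @param ... Unused.
#' @method autoplot sagrad_coancestry
#' @export
autoplot.sagrad_coancestry <- function(object, order = NULL, ...) {
  order <- order %||% cluster_coancestry(object)$order
  df <- as_tibble(unclass(object), rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "coancestry") |>
    mutate(
      from = factor(.data$from, levels = order),
      to = factor(.data$to, levels = order)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from, fill = .data$coancestry)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Coancestry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
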