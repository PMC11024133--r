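#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a proportion estimate into a long tibble
#'
#' @param x a `spot_proportions`.
#' @param ... unused.
#' @return Tibble with columns `spot_id`, `cell_type`, `proportion` (and
#'   `domain` when available).
#' @method tidy spot_proportions
#' @export
tidy.spot_proportions <- function(x, ...) {
  out <- tibble::as_tibble(x$P, rownames = "spot_id") |>
    tidyr::pivot_longer(-"spot_id", names_to = "cell_type",
                        values_to = "proportion")
  if (!is.null(x$domains))
    out <- dplyr::left_join(out,
                            tibble::as_tibble(x$domains), by = "spot_id")
  out
}

#' @rdname tidy.spot_proportions
#' @method glance spot_proportions
#' @export
glance.spot_proportions <- function(x, ...) {
  tibble::tibble(n_spots = nrow(x$P), n_cell_types = ncol(x$P),
                 mean_objective = mean(x$objective),
                 max_row_sum_error = max(abs(rowSums(x$P) - 1)))
}

#' Tidy a full pipeline fit
#'
#' @param x a `spot_deconvolution` from [run_pipeline()].
#' @param ... unused.
#' @return `tidy()`: long tibble of per-spot proportions with domain labels;
#'   `glance()`: one-row run summary.
#' @method tidy spot_deconvolution
#' @export
tidy.spot_deconvolution <- function(x, ...) tidy(x$proportions)

#' @rdname tidy.spot_deconvolution
#' @method glance spot_deconvolution
#' @export
glance.spot_deconvolution <- function(x, ...) {
  tibble::tibble(n_spots = nrow(x$proportions$P),
                 n_cell_types = ncol(x$proportions$P),
                 n_domains = n_domains(x$domains),
                 n_feature_genes = x$log$n_feature_genes,
                 mean_objective = mean(x$proportions$objective),
                 median_lambda = stats::median(x$selection$lambda))
}

#' Tidy a cell-type selection
#'
#' @param x a `celltype_selection`.
#' @param ... unused.
#' @return Long tibble with `spot_id`, `cell_type`, `beta`, `selected`.
#' @method tidy celltype_selection
#' @export
tidy.celltype_selection <- function(x, ...) {
  beta <- tibble::as_tibble(x$beta, rownames = "spot_id") |>
    tidyr::pivot_longer(-"spot_id", names_to = "cell_type",
                        values_to = "beta")
  bin <- tibble::as_tibble(x$binary == 1, rownames = "spot_id") |>
    tidyr::pivot_longer(-"spot_id", names_to = "cell_type",
                        values_to = "selected")
  dplyr::left_join(beta, bin, by = c("spot_id", "cell_type"))
}

#' Spatial map of estimated proportions
#'
#' One panel per cell type, spots placed at their array coordinates and
#' coloured by the estimated proportion.
#'
#' @param object a `spot_proportions` or `spot_deconvolution`.
#' @param coords spot coordinate tibble (`spot_id`, `row`, `col`); taken
#'   from the fit when a `spot_deconvolution` carries none.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot spot_proportions
#' @export
autoplot.spot_proportions <- function(object, coords, ...) {
  df <- tidy(object) |>
    dplyr::left_join(tibble::as_tibble(coords), by = "spot_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   colour = .data$proportion)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$cell_type) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "array col", y = "array row",
                  colour = "proportion") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.spot_proportions
#' @param spatial unused alternative coordinate source.
#' @method autoplot spot_deconvolution
#' @export
autoplot.spot_deconvolution <- function(object, coords = NULL,
                                        spatial = NULL, ...) {
  if (is.null(coords)) {
    if (is.null(spatial))
      stop("supply coords or the spatial_dataset used for the fit")
    coords <- spatial$coords
  }
  autoplot(object$proportions, coords = coords)
}

#' Heatmap of cell-type colocalization correlations
#'
#' @param P proportions (any form accepted by [colocalization_matrix()]) or
#'   a precomputed correlation matrix.
#' @return A ggplot tile plot of pairwise Pearson correlations.
#' @export
plot_colocalization <- function(P) {
  cc <- if (is.matrix(P) && nrow(P) == ncol(P) &&
            isTRUE(all.equal(unname(P), unname(t(P)), tolerance = 1e-8))) {
    P
  } else {
    suppressWarnings(colocalization_matrix(P))
  }
  df <- tibble::as_tibble(cc, rownames = "type_a") |>
    tidyr::pivot_longer(-"type_a", names_to = "type_b",
                        values_to = "correlation")
  ggplot2::ggplot(df, ggplot2::aes(.data$type_a, .data$type_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182c") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter plot of estimated versus true proportions
#'
#' @param P_est,P_true aligned proportion matrices (any accepted form).
#' @return A ggplot with one point per (spot, cell type) and the identity
#'   line.
#' @export
plot_estimate_vs_truth <- function(P_est, P_true) {
  m <- align_proportions(P_est, P_true)
  df <- tibble::tibble(
    true = as.vector(m$true), estimated = as.vector(m$est),
    cell_type = rep(colnames(m$est) %||% as.character(seq_len(ncol(m$est))),
                    each = nrow(m$est)))
  ggplot2::ggplot(df, ggplot2::aes(.data$true, .data$estimated,
                                   colour = .data$cell_type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "true proportion", y = "estimated proportion") +
    ggplot2::theme_minimal()
}
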