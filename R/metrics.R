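#' Agreement between estimated and true proportion matrices
#'
#' Pools all (spot, cell type) entries: mAD is the mean absolute
#' difference, RMSE the root mean squared difference, and R the Pearson
#' correlation of the flattened matrices. With `by = "cell_type"` the same
#' three metrics are computed within each cell-type column.
#'
#' @param P_est,P_true spots x cell-types matrices (or `spot_proportions`
#'   objects / wide tibbles with a `spot_id` column), aligned by row and
#'   column names when present.
#' @param by `"overall"` (default) or `"cell_type"`.
#' @return Tibble with columns `scope`, `mad`, `rmse`, `r`.
#' @export
#' @examples
#' est <- matrix(c(0.6, 0.4), 1); true <- matrix(c(0.5, 0.5), 1)
#' proportion_metrics(est, true)  # mad 0.1, rmse 0.1
proportion_metrics <- function(P_est, P_true,
                               by = c("overall", "cell_type")) {
  by <- match.arg(by)
  m <- align_proportions(P_est, P_true)
  est <- m$est; true <- m$true
  if (by == "overall") {
    return(tibble::tibble(scope = "overall",
                          mad = mean(abs(est - true)),
                          rmse = sqrt(mean((est - true)^2)),
                          r = safe_pearson(as.vector(est), as.vector(true))))
  }
  purrr::map_dfr(seq_len(ncol(est)), function(j) {
    tibble::tibble(scope = colnames(est)[j] %||% as.character(j),
                   mad = mean(abs(est[, j] - true[, j])),
                   rmse = sqrt(mean((est[, j] - true[, j])^2)),
                   r = safe_pearson(est[, j], true[, j]))
  })
}

align_proportions <- function(P_est, P_true) {
  est <- as_proportion_matrix(P_est)
  true <- as_proportion_matrix(P_true)
  if (!is.null(rownames(est)) && !is.null(rownames(true)) &&
      all(rownames(est) %in% rownames(true)))
    true <- true[rownames(est), , drop = FALSE]
  if (!is.null(colnames(est)) && !is.null(colnames(true)) &&
      setequal(colnames(est), colnames(true)))
    true <- true[, colnames(est), drop = FALSE]
  if (!all(dim(est) == dim(true)))
    stop("estimated and true proportion matrices have different shapes")
  list(est = est, true = true)
}

safe_pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NaN)
  }
  stats::cor(x, y)
}

#' Per-domain true/false positive rates of a cell-type selection
#'
#' `tpr = |S_est intersect S_true| / |S_true|`;
#' `fpr = |S_est \\ S_true| / |all_types \\ S_true|` (0 when every type is
#' truly present).
#'
#' @param S_est,S_true named lists mapping domain label to character vectors
#'   of cell types (e.g. `selection$domain_sets` and
#'   [true_domain_sets()]).
#' @param all_types character vector of all candidate cell types.
#' @return Tibble with columns `domain`, `tpr`, `fpr`.
#' @export
selection_metrics <- function(S_est, S_true, all_types) {
  doms <- names(S_true)
  purrr::map_dfr(doms, function(d) {
    st <- S_true[[d]]
    se <- S_est[[d]] %||% character()
    if (!all(se %in% all_types))
      stop("unknown cell type in estimated set: ",
           setdiff(se, all_types)[1])
    stopifnot(length(st) > 0, all(st %in% all_types))
    neg <- setdiff(all_types, st)
    tibble::tibble(
      domain = d,
      tpr = length(intersect(se, st)) / length(st),
      fpr = if (length(neg)) length(setdiff(se, st)) / length(neg) else 0)
  })
}

#' Cell-type colocalization correlation matrix
#'
#' Pearson correlation of every pair of cell-type proportion profiles
#' across spots, the standard readout for spatial co-occurrence of cell
#' types.
#'
#' @param P spots x cell-types proportions (matrix, `spot_proportions`, or
#'   wide tibble).
#' @param spots optional character vector restricting to a subset of spots
#'   (at least 3).
#' @return K x K symmetric correlation matrix; zero-variance cell types
#'   yield NaN rows/columns with a warning.
#' @export
colocalization_matrix <- function(P, spots = NULL) {
  m <- as_proportion_matrix(P)
  if (!is.null(spots)) m <- m[spots, , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 spots for colocalization")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance cell type(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  cc <- suppressWarnings(stats::cor(m))
  cc[sds == 0, ] <- NaN
  cc[, sds == 0] <- NaN
  cc
}

#' Score a deconvolution run against simulation truth
#'
#' Convenience wrapper combining [proportion_metrics()],
#' [selection_metrics()] and [colocalization_matrix()] into one report.
#'
#' @param P a `spot_proportions` (or matrix).
#' @param truth a `simulation_truth`.
#' @param selection optional `celltype_selection`; enables the per-domain
#'   TPR/FPR block.
#' @return Object of class `evaluation_report`: list with `overall`
#'   (one-row tibble), `per_cell_type` (tibble), `per_domain_selection`
#'   (tibble or NULL), `colocalization` (matrix).
#' @export
evaluate_deconvolution <- function(P, truth, selection = NULL) {
  est <- as_proportion_matrix(P)
  sel_tbl <- NULL
  if (!is.null(selection)) {
    sel_tbl <- selection_metrics(selection$domain_sets,
                                 true_domain_sets(truth),
                                 colnames(truth$true_P))
  }
  structure(list(
    overall = proportion_metrics(est, truth$true_P),
    per_cell_type = proportion_metrics(est, truth$true_P, by = "cell_type"),
    per_domain_selection = sel_tbl,
    colocalization = suppressWarnings(colocalization_matrix(est))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n  overall: mAD ",
      signif(x$overall$mad, 4), ", RMSE ", signif(x$overall$rmse, 4),
      ", R ", signif(x$overall$r, 4), "\n", sep = "")
  if (!is.null(x$per_domain_selection)) {
    cat("  selection: mean TPR ",
        signif(mean(x$per_domain_selection$tpr), 4), ", mean FPR ",
        signif(mean(x$per_domain_selection$fpr), 4), "\n", sep = "")
  }
  invisible(x)
}
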