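#' Run the full deconvolution pipeline
#'
#' Executes the three stages in order: reference construction from the
#' annotated single-cell data (gene filtering, library-size scaling, marker
#' detection, signature building), per-domain cell-type selection (per-spot
#' Lasso, adaptive thresholding, aggregation), and simplex-constrained LAD
#' proportion estimation. Domains may be supplied (e.g. from an external
#' spatial-domain caller); otherwise the fallback clusterer is run with
#' `n_domains_fallback` clusters.
#'
#' @param spatial a [spatial_dataset()].
#' @param sc a raw-count [single_cell_dataset()].
#' @param domains optional [domain_assignment()].
#' @param config a [pipeline_config()].
#' @param signature optional precomputed `signature_matrix` (skips reference
#'   construction).
#' @param user_markers optional character vector of marker gene ids for the
#'   reference filter.
#' @param keep_types optional cell types to retain from `sc`.
#' @param n_domains_fallback number of domains for the fallback clusterer
#'   when `domains` is missing.
#' @param method LAD backend passed to [deconvolve_dataset()].
#' @return Object of class `spot_deconvolution`: list with `proportions`
#'   (a `spot_proportions`), `selection`, `signature`, `domains`, `config`
#'   and `log` (gene counts after each filter, per-spot penalty summary,
#'   per-domain sets, per-spot objective values).
#' @export
run_pipeline <- function(spatial, sc, domains = NULL,
                         config = pipeline_config(), signature = NULL,
                         user_markers = NULL, keep_types = NULL,
                         n_domains_fallback = NULL,
                         method = c("lp", "admm")) {
  method <- match.arg(method)
  validate_spatial_dataset(spatial)
  validate_pipeline_config(config)
  log <- list(n_genes_spatial = nrow(spatial$counts))
  if (is.null(domains)) {
    if (is.null(n_domains_fallback))
      stop("domains: supply a domain_assignment or n_domains_fallback")
    domains <- stage("domains", assign_domains_fallback(
      spatial, D = n_domains_fallback, seed = config$seed))
  }
  missing_dom <- setdiff(colnames(spatial$counts), domains$spot_id)
  if (length(missing_dom))
    stop("domains: unlabeled spot: ", missing_dom[1])
  if (is.null(signature)) {
    signature <- stage("reference", build_reference(
      sc, spatial_genes = rownames(spatial$counts),
      keep_types = keep_types, user_markers = user_markers))
  }
  log$n_feature_genes <- nrow(signature$values)
  selection <- stage("selection",
                     select_cell_types(spatial, signature, domains, config))
  log$lambda_summary <- unclass(summary(selection$lambda))
  log$domain_sets <- selection$domain_sets
  proportions <- stage("deconvolution", deconvolve_dataset(
    spatial, signature, selection, domains, config, method = method))
  log$objective_summary <- unclass(summary(proportions$objective))
  structure(list(proportions = proportions, selection = selection,
                 signature = signature, domains = domains, config = config,
                 log = log),
            class = "spot_deconvolution")
}

# prefix stage name onto any error
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, ": ", conditionMessage(e), call. = FALSE))
}

#' @export
print.spot_deconvolution <- function(x, ...) {
  cat("<spot_deconvolution> ", nrow(x$proportions$P), " spots, ",
      ncol(x$proportions$P), " cell types, ",
      n_domains(x$domains), " domains\n", sep = "")
  cat("  feature genes: ", x$log$n_feature_genes,
      "; median LAD objective: ",
      signif(stats::median(x$proportions$objective), 4), "\n", sep = "")
  for (d in names(x$selection$domain_sets))
    cat("  domain ", d, ": ",
        paste(x$selection$domain_sets[[d]], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Write the run log of a pipeline fit as JSON
#'
#' @param fit a `spot_deconvolution`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(fit, path) {
  stopifnot(inherits(fit, "spot_deconvolution"))
  log <- fit$log
  log$per_spot_objective <- stats::setNames(
    as.numeric(fit$proportions$objective), rownames(fit$proportions$P))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
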