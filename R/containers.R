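#' Construct a spatial expression dataset
#'
#' Bundles a gene-by-spot count (or normalized expression) matrix with the
#' array coordinates of each capture spot. Coordinates follow the 0-based
#' (row, col) array convention used by 10x spot-position files; pixel x/y
#' inputs should be mapped as x -> col, y -> row before construction.
#'
#' @param counts numeric matrix, genes x spots, non-negative. Row names are
#'   gene ids, column names spot barcodes (set from `gene_ids`/`spot_ids`
#'   when missing).
#' @param coords data frame with columns `spot_id`, `row`, `col` (numeric),
#'   one row per spot. Optionally extra columns are kept.
#' @param gene_ids,spot_ids optional character vectors overriding dimnames.
#' @param histology_rgb optional spots x 3 matrix of mean RGB values in
#'   \[0, 255\] per spot.
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `counts` (dense matrix with dimnames), `coords` (tibble) and optionally
#'   `histology_rgb`.
#' @export
#' @examples
#' counts <- matrix(rpois(20, 4), 5, 4,
#'   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' coords <- data.frame(spot_id = paste0("s", 1:4),
#'   row = c(0, 0, 1, 1), col = c(0, 1, 0, 1))
#' sp <- spatial_dataset(counts, coords)
#' sp
spatial_dataset <- function(counts, coords, gene_ids = NULL, spot_ids = NULL,
                            histology_rgb = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(spot_ids)) colnames(counts) <- spot_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and spot ids (colnames)")
  coords <- tibble::as_tibble(coords)
  if (!all(c("spot_id", "row", "col") %in% names(coords)))
    stop("coords must have columns spot_id, row, col")
  coords <- coords[match(colnames(counts), coords$spot_id), , drop = FALSE]
  obj <- structure(
    list(counts = counts, coords = coords, histology_rgb = histology_rgb),
    class = "spatial_dataset")
  validate_spatial_dataset(obj)
}

validate_spatial_dataset <- function(x) {
  stopifnot(inherits(x, "spatial_dataset"))
  counts <- x$counts
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids, first duplicate: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts))) stop("duplicate spot ids")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  if (nrow(x$coords) != ncol(counts) ||
      any(is.na(x$coords$spot_id)) ||
      !identical(as.character(x$coords$spot_id), colnames(counts)))
    stop("coords must have exactly one row per spot, matching counts columns")
  if (!is.numeric(x$coords$row) || !is.numeric(x$coords$col) ||
      anyNA(x$coords$row) || anyNA(x$coords$col))
    stop("coords row/col must be numeric and non-missing")
  if (!is.null(x$histology_rgb)) {
    rgb <- x$histology_rgb
    if (nrow(rgb) != ncol(counts) || ncol(rgb) != 3)
      stop("histology_rgb must be spots x 3")
  }
  x
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("<spatial_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " spots\n", sep = "")
  cat("  coords: rows ", paste(range(x$coords$row), collapse = ".."),
      ", cols ", paste(range(x$coords$col), collapse = ".."), "\n", sep = "")
  invisible(x)
}

#' Construct a labeled single-cell expression dataset
#'
#' @param counts numeric matrix, genes x cells, non-negative (raw counts or
#'   library-size-scaled expression).
#' @param meta data frame with columns `cell_id`, `cell_type`, `sample_id`;
#'   one row per cell, matched to `counts` columns by `cell_id`.
#'
#' @return Object of class `single_cell_dataset` with elements `counts`
#'   (matrix) and `meta` (tibble aligned to the columns of `counts`).
#' @export
single_cell_dataset <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and cell ids (colnames)")
  meta <- tibble::as_tibble(meta)
  if (!"cell_id" %in% names(meta)) stop("meta must have a cell_id column")
  if (!"cell_type" %in% names(meta)) stop("meta must have a cell_type column")
  if (!"sample_id" %in% names(meta)) meta$sample_id <- "sample1"
  meta <- meta[match(colnames(counts), meta$cell_id), , drop = FALSE]
  obj <- structure(list(counts = counts, meta = meta),
                   class = "single_cell_dataset")
  validate_single_cell_dataset(obj)
}

validate_single_cell_dataset <- function(x) {
  stopifnot(inherits(x, "single_cell_dataset"))
  if (any(is.na(x$counts)) || any(x$counts < 0))
    stop("counts must be non-negative and free of NA")
  if (anyDuplicated(rownames(x$counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(x$counts))) stop("duplicate cell ids")
  if (anyNA(x$meta$cell_id) ||
      !identical(as.character(x$meta$cell_id), colnames(x$counts)))
    stop("every count column needs a metadata row (matched by cell_id)")
  ct <- x$meta$cell_type
  if (anyNA(ct) || any(!nzchar(as.character(ct))))
    stop("every cell needs a non-empty cell_type")
  x
}

#' @export
print.single_cell_dataset <- function(x, ...) {
  tab <- table(x$meta$cell_type)
  cat("<single_cell_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells, ", length(tab), " cell types\n", sep = "")
  print(tab)
  invisible(x)
}

#' Construct a spot-to-domain assignment
#'
#' Domain labels are re-coded to contiguous integers `0..D-1` in order of
#' first appearance, so arbitrary label sets (e.g. exported cluster names)
#' are accepted.
#'
#' @param spot_ids character vector of spot barcodes.
#' @param domain vector of domain labels, one per spot (any type; re-coded).
#' @return Object of class `domain_assignment`: a tibble with columns
#'   `spot_id` and integer `domain`, plus attribute `D` (number of domains).
#' @export
domain_assignment <- function(spot_ids, domain) {
  if (length(spot_ids) != length(domain))
    stop("spot_ids and domain must have equal length")
  if (anyNA(domain)) stop("domain labels must not be missing")
  lev <- unique(domain)
  dom <- match(domain, lev) - 1L
  out <- tibble::tibble(spot_id = as.character(spot_ids), domain = dom)
  attr(out, "D") <- length(lev)
  class(out) <- c("domain_assignment", class(out))
  out
}

#' Number of spatial domains in an assignment
#' @param x a `domain_assignment`.
#' @return integer count of domains.
#' @export
n_domains <- function(x) {
  stopifnot(inherits(x, "domain_assignment"))
  attr(x, "D")
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the deconvolution pipeline with the
#' package defaults. All randomness (CV fold assignment, fallback clustering
#' initialisation, simulation) flows from the single integer `seed`.
#'
#' @param lambda_grid optional numeric vector of Lasso penalties; when `NULL`
#'   a 50-value log-spaced grid from `lambda_max` down to `lambda_max * 1e-4`
#'   is built per spot (`lambda_max` = smallest penalty shrinking all
#'   coefficients to zero).
#' @param cv_folds number of cross-validation folds over genes (>= 2).
#' @param threshold_window integer length-2 (rows, cols) of the local-mean
#'   window used by adaptive thresholding, both odd. Rows run over spots
#'   (ordered by domain, then array row, then col), cols over cell types.
#'   The default `c(15, 3)` pools each coefficient's local mean over nearby
#'   spots and the two adjacent cell-type columns, which suppresses the
#'   small spurious coefficients of absent cell types.
#' @param domain_fraction_tau fraction of a domain's spots that must select a
#'   cell type for it to enter the domain set, in \[0, 1\].
#' @param solver_tolerance tolerance of the simplex-constrained LAD solver.
#' @param normalization_mode `"spot"` scales each spot's expression over the
#'   feature genes to sum 1 and scales signature columns to sum 1 before
#'   fitting; `"none"` fits raw values.
#' @param seed integer RNG seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lambda_grid = NULL, cv_folds = 10,
                            threshold_window = c(15L, 3L),
                            domain_fraction_tau = 0.25,
                            solver_tolerance = 1e-8,
                            normalization_mode = c("spot", "none"),
                            seed = 1L) {
  normalization_mode <- match.arg(normalization_mode)
  cfg <- structure(list(
    lambda_grid = lambda_grid,
    cv_folds = as.integer(cv_folds),
    threshold_window = as.integer(threshold_window),
    domain_fraction_tau = domain_fraction_tau,
    solver_tolerance = solver_tolerance,
    normalization_mode = normalization_mode,
    seed = as.integer(seed)), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.na(cfg$cv_folds) || cfg$cv_folds < 2)
    stop("cv_folds must be >= 2")
  w <- cfg$threshold_window
  if (length(w) != 2 || any(is.na(w)) || any(w < 1) || any(w %% 2 == 0))
    stop("threshold_window must be two odd integers >= 1")
  if (is.na(cfg$domain_fraction_tau) || cfg$domain_fraction_tau < 0 ||
      cfg$domain_fraction_tau > 1)
    stop("domain_fraction_tau must lie in [0, 1]")
  if (!is.null(cfg$lambda_grid) && any(cfg$lambda_grid < 0))
    stop("lambda_grid must be non-negative")
  cfg
}

# internal: subset a spatial dataset to a gene and/or spot set, keeping order
subset_spatial <- function(sp, genes = NULL, spots = NULL) {
  counts <- sp$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  coords <- sp$coords
  if (!is.null(spots)) {
    counts <- counts[, spots, drop = FALSE]
    coords <- coords[match(spots, coords$spot_id), , drop = FALSE]
  }
  rgb <- sp$histology_rgb
  if (!is.null(rgb) && !is.null(spots))
    rgb <- rgb[match(spots, sp$coords$spot_id), , drop = FALSE]
  spatial_dataset(counts, coords, histology_rgb = rgb)
}
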