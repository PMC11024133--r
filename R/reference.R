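#' Filter single-cell data before reference construction
#'
#' Removes genes with zero total count and, optionally, cells whose annotated
#' type is not in `keep_types` (useful for dropping doublets or redundant
#' annotations from the original study).
#'
#' @param sc a [single_cell_dataset()].
#' @param keep_types optional character vector of cell types to retain.
#' @return Filtered [single_cell_dataset()], order preserved.
#' @export
filter_cells_genes <- function(sc, keep_types = NULL) {
  validate_single_cell_dataset(sc)
  counts <- sc$counts
  meta <- sc$meta
  if (!is.null(keep_types)) {
    keep <- meta$cell_type %in% keep_types
    counts <- counts[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  nonzero <- rowSums(counts) > 0
  if (!any(nonzero)) stop("all genes removed: no gene has a nonzero count")
  counts <- counts[nonzero, , drop = FALSE]
  single_cell_dataset(counts, meta)
}

#' Scale each cell's expression by its library size
#'
#' Divides every cell's counts by its total (the sum over all genes), so each
#' column sums to 1. Cells with zero total are dropped with a warning.
#'
#' @param sc a [single_cell_dataset()].
#' @return A [single_cell_dataset()] of scaled expression.
#' @export
scale_by_library_size <- function(sc) {
  validate_single_cell_dataset(sc)
  lib <- colSums(sc$counts)
  zero <- lib == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) dropped: zero library size")
  }
  counts <- sweep(sc$counts[, !zero, drop = FALSE], 2, lib[!zero], "/")
  single_cell_dataset(counts, sc$meta[!zero, , drop = FALSE])
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the pooled sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction. The statistic is the Mann-Whitney U for `x`.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return Named list with `statistic` (U for `x`) and `p_value`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  p <- ht$p.value
  # degenerate all-tied comparison: zero variance, no evidence either way
  if (is.na(p)) p <- 1
  list(statistic = unname(ht$statistic), p_value = min(p, 1))
}

#' One-vs-rest marker gene detection
#'
#' For each cell type, tests every gene with a two-sided rank-sum test of
#' the type's cells against all other cells, on library-size-scaled
#' expression. P-values are Benjamini-Hochberg-adjusted within each cell
#' type. The log fold change is `ln(mean_in + eps) - ln(mean_out + eps)`
#' with `eps = 1e-9`. With `pairwise = TRUE` each type is instead compared
#' against every other type separately and a gene is kept for a type if any
#' pairwise comparison passes the cutoffs (the reported row is the best
#' pair by adjusted p).
#'
#' @param sc_scaled a [single_cell_dataset()] of scaled expression
#'   (see [scale_by_library_size()]).
#' @param min_lfc minimum natural-log fold change (default 0.25).
#' @param max_adj_p maximum BH-adjusted p-value (default 0.05).
#' @param pairwise compare each pair of types instead of one-vs-rest.
#' @return Tibble of class `marker_tests` with columns `gene_id`,
#'   `cell_type`, `statistic`, `p_value`, `adjusted_p`, `log_fold_change`,
#'   filtered to the cutoffs. Cell types with fewer than 3 cells are
#'   excluded with a warning.
#' @export
find_marker_genes <- function(sc_scaled, min_lfc = 0.25, max_adj_p = 0.05,
                              pairwise = FALSE) {
  validate_single_cell_dataset(sc_scaled)
  types <- unique(sc_scaled$meta$cell_type)
  sizes <- table(sc_scaled$meta$cell_type)[types]
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("cell type(s) with < 3 cells excluded: ",
            paste(small, collapse = ", "))
    types <- setdiff(types, small)
  }
  if (length(types) < 2) stop("need >= 2 cell types with >= 3 cells")
  expr <- sc_scaled$counts
  labels <- sc_scaled$meta$cell_type
  test_group <- function(in_idx, out_idx, type) {
    res <- apply_rank_sum(expr, in_idx, out_idx)
    res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
    res$cell_type <- type
    res
  }
  if (!pairwise) {
    res <- purrr::map_dfr(types, function(tp) {
      test_group(which(labels == tp),
                 which(labels != tp & labels %in% types), tp)
    })
  } else {
    res <- purrr::map_dfr(types, function(tp) {
      per_pair <- purrr::map_dfr(setdiff(types, tp), function(other) {
        test_group(which(labels == tp), which(labels == other), tp)
      })
      per_pair |>
        dplyr::group_by(.data$gene_id) |>
        dplyr::slice_min(.data$adjusted_p, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
    })
  }
  out <- res |>
    dplyr::filter(.data$adjusted_p <= max_adj_p,
                  .data$log_fold_change >= min_lfc) |>
    dplyr::select("gene_id", "cell_type", "statistic", "p_value",
                  "adjusted_p", "log_fold_change") |>
    dplyr::arrange(.data$cell_type, .data$adjusted_p)
  class(out) <- c("marker_tests", class(out))
  out
}

# one-group-vs-another rank-sum over all genes
apply_rank_sum <- function(expr, in_idx, out_idx) {
  tests <- apply(expr, 1, function(v)
    wilcoxon_rank_sum(v[in_idx], v[out_idx]))
  eps <- 1e-9
  m_in <- rowMeans(expr[, in_idx, drop = FALSE])
  m_out <- rowMeans(expr[, out_idx, drop = FALSE])
  tibble::tibble(gene_id = rownames(expr),
                 statistic = vapply(tests, `[[`, 0, "statistic"),
                 p_value = vapply(tests, `[[`, 0, "p_value"),
                 log_fold_change = log(m_in + eps) - log(m_out + eps))
}

#' Build the gene-by-cell-type signature matrix
#'
#' Feature genes are those satisfying any of three criteria -- shared with
#' the spatial data, listed as user-supplied markers, or detected as
#' differentially expressed -- and are then intersected with the spatial
#' gene set so every downstream fit is well-posed. Each signature column is
#' the arithmetic mean of scaled expression over the cells of that type
#' (or, with `per_sample_mean = TRUE`, the mean of per-sample means).
#'
#' @param sc_scaled a [single_cell_dataset()] of scaled expression.
#' @param spatial_genes character vector of gene ids present in the spatial
#'   data.
#' @param user_markers optional character vector of marker gene ids.
#' @param deg optional `marker_tests` tibble from [find_marker_genes()].
#' @param per_sample_mean average within `sample_id` first, then across
#'   samples (default pools all cells).
#' @return Object of class `signature_matrix`: list with `values` (genes x
#'   types matrix), `provenance` (tibble of per-gene flags `shared`,
#'   `user_marker`, `deg`) and `cell_types`.
#' @export
build_signature <- function(sc_scaled, spatial_genes, user_markers = NULL,
                            deg = NULL, per_sample_mean = FALSE) {
  validate_single_cell_dataset(sc_scaled)
  genes <- rownames(sc_scaled$counts)
  deg_genes <- if (!is.null(deg)) unique(deg$gene_id) else character()
  shared <- genes %in% spatial_genes
  user <- genes %in% (user_markers %||% character())
  in_deg <- genes %in% deg_genes
  dropped_markers <- setdiff(user_markers %||% character(), spatial_genes)
  if (length(dropped_markers))
    message(length(dropped_markers),
            " user marker(s) absent from spatial data excluded")
  feature <- (shared | user | in_deg) & (genes %in% spatial_genes)
  if (sum(feature) < 2) stop("fewer than 2 feature genes after filtering")
  types <- unique(sc_scaled$meta$cell_type)
  expr <- sc_scaled$counts[feature, , drop = FALSE]
  vals <- vapply(types, function(tp) {
    idx <- which(sc_scaled$meta$cell_type == tp)
    if (!length(idx)) stop("cell type with zero cells: ", tp)
    if (!per_sample_mean) return(rowMeans(expr[, idx, drop = FALSE]))
    samples <- unique(sc_scaled$meta$sample_id[idx])
    per <- vapply(samples, function(s) {
      rowMeans(expr[, idx[sc_scaled$meta$sample_id[idx] == s],
                    drop = FALSE])
    }, numeric(nrow(expr)))
    rowMeans(as.matrix(per))
  }, numeric(nrow(expr)))
  vals <- as.matrix(vals)
  dimnames(vals) <- list(genes[feature], types)
  prov <- tibble::tibble(gene_id = genes[feature],
                         shared = shared[feature],
                         user_marker = user[feature],
                         deg = in_deg[feature])
  structure(list(values = vals, provenance = prov, cell_types = types),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix> ", nrow(x$values), " feature genes x ",
      ncol(x$values), " cell types\n", sep = "")
  cat("  provenance: shared ", sum(x$provenance$shared), ", user_marker ",
      sum(x$provenance$user_marker), ", deg ", sum(x$provenance$deg), "\n",
      sep = "")
  invisible(x)
}

#' Full reference construction from raw single-cell counts
#'
#' Convenience wrapper: filter, library-size scale, detect markers, build
#' the signature against the spatial gene set. Also records per-gene
#' cross-sample variance of the scaled expression within each cell type in
#' `attr(, "cross_sample_variance")` for diagnostic use.
#'
#' @inheritParams build_signature
#' @inheritParams find_marker_genes
#' @param sc raw-count [single_cell_dataset()].
#' @param keep_types optional cell types to retain.
#' @return A `signature_matrix`.
#' @export
build_reference <- function(sc, spatial_genes, keep_types = NULL,
                            user_markers = NULL, min_lfc = 0.25,
                            max_adj_p = 0.05, pairwise = FALSE,
                            per_sample_mean = FALSE) {
  sc <- filter_cells_genes(sc, keep_types)
  sc <- scale_by_library_size(sc)
  # a single-type reference has no contrast to test: all genes enter via
  # the shared-with-spatial criterion
  deg <- if (length(unique(sc$meta$cell_type)) >= 2) {
    find_marker_genes(sc, min_lfc = min_lfc, max_adj_p = max_adj_p,
                      pairwise = pairwise)
  } else NULL
  sig <- build_signature(sc, spatial_genes, user_markers = user_markers,
                         deg = deg, per_sample_mean = per_sample_mean)
  attr(sig, "markers") <- deg
  attr(sig, "cross_sample_variance") <- cross_sample_variance(sc)
  sig
}

# per-gene variance of per-(sample, type) mean scaled expression
cross_sample_variance <- function(sc_scaled) {
  key <- interaction(sc_scaled$meta$cell_type, sc_scaled$meta$sample_id,
                     drop = TRUE)
  groups <- split(seq_along(key), key)
  means <- vapply(groups, function(idx)
    rowMeans(sc_scaled$counts[, idx, drop = FALSE]),
    numeric(nrow(sc_scaled$counts)))
  tibble::tibble(gene_id = rownames(sc_scaled$counts),
                 variance = apply(as.matrix(means), 1, stats::var))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
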