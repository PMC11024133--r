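#' Load precomputed spatial-domain labels
#'
#' Reads a `spot_id,domain` CSV (the export format of external spatial
#' domain callers) and validates it against a spatial dataset. Labels of any
#' type are re-coded to contiguous integers `0..D-1` preserving
#' first-appearance order.
#'
#' @param path CSV with columns `spot_id` (or `barcode`) and `domain`.
#' @param spatial a [spatial_dataset()]; every spot must be labeled.
#' @return A [domain_assignment()] aligned to the spots of `spatial`.
#' @export
load_domain_labels <- function(path, spatial) {
  if (!file.exists(path)) stop("domain file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nms <- tolower(names(df))
  names(df)[nms %in% c("barcode", "spot", "spot_id")] <- "spot_id"
  names(df)[nms %in% c("domain", "cluster", "label")] <- "domain"
  if (!all(c("spot_id", "domain") %in% names(df)))
    stop("domain file needs columns spot_id and domain")
  spots <- colnames(spatial$counts)
  idx <- match(spots, df$spot_id)
  if (anyNA(idx))
    stop("unlabeled spot: ", spots[which(is.na(idx))[1]])
  domain_assignment(spots, df$domain[idx])
}

#' Expression + coordinates fallback domain clusterer
#'
#' A deliberately simple stand-in for dedicated spatial-domain callers, so
#' the pipeline runs standalone: log1p of spot-normalised expression, top
#' principal components, z-scaled spatial coordinates (and mean spot RGB if
#' present) appended with weight `coord_weight`, k-means with `D` centres,
#' then one round of spatial smoothing in which each spot takes the
#' majority label among its `n_neighbors` nearest spatial neighbours (ties
#' keep the spot's own label). Deterministic given `seed`.
#'
#' @param spatial a [spatial_dataset()].
#' @param D number of domains (>= 1, at most the number of spots).
#' @param seed RNG seed for the k-means initialisation.
#' @param n_pcs number of principal components (default 50, clamped).
#' @param coord_weight weight of the scaled coordinate block (default 1).
#' @param n_neighbors neighbours used in the smoothing round (default 6,
#'   matching the hexagonal neighbourhood of common spatial arrays).
#' @return A [domain_assignment()].
#' @export
assign_domains_fallback <- function(spatial, D, seed = 1, n_pcs = 50,
                                    coord_weight = 1, n_neighbors = 6) {
  validate_spatial_dataset(spatial)
  n_spot <- ncol(spatial$counts)
  if (D < 1) stop("D must be >= 1")
  if (D > n_spot) stop("D (", D, ") exceeds the number of spots (",
                       n_spot, ")")
  spots <- colnames(spatial$counts)
  if (D == 1)
    return(domain_assignment(spots, rep(0L, n_spot)))
  lib <- colSums(spatial$counts)
  lib[lib == 0] <- 1
  expr <- log1p(t(sweep(spatial$counts, 2, lib, "/")) * 1e4)
  keep <- apply(expr, 2, stats::sd) > 0
  expr <- expr[, keep, drop = FALSE]
  n_pcs <- min(n_pcs, ncol(expr), n_spot - 1)
  pcs <- stats::prcomp(expr, rank. = n_pcs, center = TRUE,
                       scale. = FALSE)$x
  coords <- cbind(spatial$coords$row, spatial$coords$col)
  if (!is.null(spatial$histology_rgb))
    coords <- cbind(coords, spatial$histology_rgb)
  coords <- scale(coords)
  coords[is.na(coords)] <- 0
  feats <- cbind(scale(pcs), coord_weight * coords)
  feats[is.na(feats)] <- 0
  km <- withr::with_seed(as.integer(seed),
    stats::kmeans(feats, centers = D, nstart = 10, iter.max = 100))
  labels <- km$cluster
  labels <- smooth_labels(labels, cbind(spatial$coords$row,
                                        spatial$coords$col), n_neighbors)
  domain_assignment(spots, labels)
}

# one round of majority-vote smoothing over nearest spatial neighbours
smooth_labels <- function(labels, coords, k) {
  n <- length(labels)
  k <- min(k, n - 1)
  if (k < 1) return(labels)
  d2 <- as.matrix(stats::dist(coords))^2
  out <- labels
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1)]
    tab <- table(labels[nb])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) out[i] <- as.integer(top)
    # ties keep the spot's own label
  }
  out
}
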