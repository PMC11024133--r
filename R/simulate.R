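#' Lay out simulated spots on a grid of banded domains
#'
#' Spots sit on an integer `grid_rows` x `grid_cols` array; contiguous
#' horizontal bands of rows are assigned to domains `0..D-1`.
#'
#' @param grid_rows,grid_cols grid dimensions.
#' @param D number of domains (at most `grid_rows`).
#' @return List with `layout` (a [domain_assignment()]) and `coords`
#'   (tibble `spot_id`, `row`, `col`).
#' @export
#' @examples
#' make_domain_layout(4, 4, 2)$layout
make_domain_layout <- function(grid_rows, grid_cols, D) {
  if (D > grid_rows)
    stop("D (", D, ") exceeds grid_rows (", grid_rows, ")")
  rows <- rep(seq_len(grid_rows) - 1L, each = grid_cols)
  cols <- rep(seq_len(grid_cols) - 1L, times = grid_rows)
  spot_ids <- sprintf("spot_%d_%d", rows, cols)
  band <- floor(rows * D / grid_rows)
  list(layout = domain_assignment(spot_ids, band),
       coords = tibble::tibble(spot_id = spot_ids, row = rows, col = cols))
}

#' Generate a toy annotated single-cell reference
#'
#' Block-structured Poisson counts: every cell type expresses a shared set
#' of housekeeping genes plus its own block of marker genes, with equal
#' expected library size across types (so simulated cell-count proportions
#' and expression proportions coincide). Cells are split over two
#' pseudo-samples. Intended as the reference for simulation benchmarks and
#' tests; it does not emulate real scRNA-seq dropout or overdispersion.
#'
#' @param n_types number of cell types K.
#' @param markers_per_type marker genes private to each type.
#' @param n_housekeeping genes expressed by all types.
#' @param cells_per_type cells simulated per type.
#' @param total_expression expected library size of every cell.
#' @param marker_fraction fraction of a cell's expression concentrated in
#'   its type's marker block.
#' @param seed RNG seed.
#' @return A [single_cell_dataset()] with cell types `type1..typeK`.
#' @export
simulate_reference <- function(n_types = 6, markers_per_type = 25,
                               n_housekeeping = 30, cells_per_type = 60,
                               total_expression = 2000,
                               marker_fraction = 0.6, seed = 1) {
  types <- paste0("type", seq_len(n_types))
  n_marker <- n_types * markers_per_type
  genes <- c(sprintf("mk%02d_%03d", rep(seq_len(n_types),
                                        each = markers_per_type),
                     seq_len(n_marker)),
             sprintf("hk_%03d", seq_len(n_housekeeping)))
  withr::with_seed(as.integer(seed), {
    # per-gene relative rates, same total for every type
    rate <- matrix(0, length(genes), n_types,
                   dimnames = list(genes, types))
    for (k in seq_len(n_types)) {
      own <- (k - 1) * markers_per_type + seq_len(markers_per_type)
      w_mark <- stats::rgamma(markers_per_type, shape = 2, rate = 2)
      rate[own, k] <- marker_fraction * w_mark / sum(w_mark)
      w_hk <- stats::rgamma(n_housekeeping, shape = 4, rate = 4)
      rate[n_marker + seq_len(n_housekeeping), k] <-
        (1 - marker_fraction) * w_hk / sum(w_hk)
    }
    counts <- matrix(0L, length(genes), n_types * cells_per_type)
    cell_type <- rep(types, each = cells_per_type)
    for (k in seq_len(n_types)) {
      idx <- (k - 1) * cells_per_type + seq_len(cells_per_type)
      lam <- rate[, k] * total_expression
      counts[, idx] <- stats::rpois(length(lam) * cells_per_type, lam)
    }
    dimnames(counts) <- list(genes,
                             sprintf("cell_%04d", seq_len(ncol(counts))))
    meta <- tibble::tibble(
      cell_id = colnames(counts), cell_type = cell_type,
      sample_id = rep_len(c("sampleA", "sampleB"), ncol(counts)))
    single_cell_dataset(counts, meta)
  })
}

#' Default per-domain Dirichlet concentrations for the benchmark layout
#'
#' Each domain gets one dominant cell type (`alpha = 5`) and a varying set
#' of minor types (`alpha = 1`); types absent from a domain get 0. Types
#' `1..D` are the dominants of domains `0..D-1`; each remaining type becomes
#' a minor of two consecutive domains (cyclically), so every type is present
#' somewhere and domains carry varying minor sets.
#'
#' @param K number of cell types.
#' @param D number of domains (`D <= K`).
#' @param dominant,minor concentration of the dominant / each minor type.
#' @return D x K numeric matrix of concentrations (rows = domains).
#' @export
benchmark_alpha <- function(K, D, dominant = 5, minor = 1) {
  if (D > K) stop("need at least one dominant type per domain (D <= K)")
  alpha <- matrix(0, D, K,
                  dimnames = list(paste0("domain", seq_len(D) - 1L),
                                  paste0("type", seq_len(K))))
  for (d in seq_len(D)) alpha[d, d] <- dominant
  extra <- setdiff(seq_len(K), seq_len(D))
  for (i in seq_along(extra)) {
    # each leftover type becomes a minor of two consecutive domains
    d1 <- (i - 1) %% D + 1
    d2 <- i %% D + 1
    alpha[d1, extra[i]] <- minor
    alpha[d2, extra[i]] <- minor
  }
  alpha
}

#' Simulate pseudo-spatial transcriptomics data with ground truth
#'
#' Three-step generator: (1) per spot, draw mixing proportions from the
#' Dirichlet distribution of its domain (restricted to types with positive
#' concentration) -- these draws are the ground truth; (2) allocate
#' `cells_per_spot` cells to types by largest-remainder rounding of the
#' draw and sample that many cells (with replacement) per type from the
#' single-cell data; (3) sum the sampled cells' raw counts into the spot's
#' column of a gene x spot matrix. With `noise_sigma > 0`, every count is
#' multiplied by an independent lognormal(0, sigma) factor and rounded to
#' the nearest integer.
#'
#' @param sc a [single_cell_dataset()] of raw counts.
#' @param layout result of [make_domain_layout()] (or a list with `layout`
#'   and `coords` elements of the same shape).
#' @param alpha_per_domain D x K matrix of Dirichlet concentrations, columns
#'   named by cell type; zeros mark types absent from a domain.
#' @param cells_per_spot cells mixed into each spot (default 10).
#' @param noise_sigma standard deviation of the multiplicative lognormal
#'   noise on counts (default 0 = noise-free).
#' @param seed RNG seed.
#' @return List with `spatial` (a [spatial_dataset()]) and `truth` (class
#'   `simulation_truth`: `true_P` spots x K on the simplex, `layout`,
#'   `alpha`, `cells_per_spot`, `noise_sigma`, `seed`).
#' @export
simulate_spatial_dataset <- function(sc, layout, alpha_per_domain,
                                     cells_per_spot = 10, noise_sigma = 0,
                                     seed = 1) {
  validate_single_cell_dataset(sc)
  alpha <- as.matrix(alpha_per_domain)
  if (is.null(colnames(alpha)))
    stop("alpha_per_domain needs cell-type column names")
  if (any(alpha < 0)) stop("Dirichlet concentrations must be >= 0")
  types <- colnames(alpha)
  present <- types[colSums(alpha) > 0]
  missing <- setdiff(present, unique(sc$meta$cell_type))
  if (length(missing))
    stop("cell type with positive concentration absent from reference: ",
         missing[1])
  dom <- layout$layout$domain
  spots <- layout$layout$spot_id
  if (max(dom) + 1 > nrow(alpha))
    stop("alpha_per_domain has fewer rows than domains")
  cells_by_type <- split(seq_len(ncol(sc$counts)), sc$meta$cell_type)
  G <- nrow(sc$counts)
  withr::with_seed(as.integer(seed), {
    counts <- matrix(0, G, length(spots),
                     dimnames = list(rownames(sc$counts), spots))
    true_P <- matrix(0, length(spots), length(types),
                     dimnames = list(spots, types))
    for (s in seq_along(spots)) {
      a <- alpha[dom[s] + 1L, ]
      pos <- which(a > 0)
      p <- rdirichlet1(a[pos])
      true_P[s, pos] <- p
      alloc <- largest_remainder(p, cells_per_spot)
      col <- numeric(G)
      for (t in seq_along(pos)) {
        if (alloc[t] == 0) next
        pool <- cells_by_type[[types[pos[t]]]]
        picked <- pool[sample.int(length(pool), alloc[t], replace = TRUE)]
        col <- col + rowSums(sc$counts[, picked, drop = FALSE])
      }
      counts[, s] <- col
    }
    if (noise_sigma > 0) {
      fac <- matrix(stats::rlnorm(length(counts), 0, noise_sigma),
                    nrow(counts))
      counts <- round(counts * fac)
    }
    spatial <- spatial_dataset(counts, layout$coords)
    truth <- structure(list(true_P = true_P, layout = layout$layout,
                            alpha = alpha, cells_per_spot = cells_per_spot,
                            noise_sigma = noise_sigma, seed = seed),
                       class = "simulation_truth")
    list(spatial = spatial, truth = truth)
  })
}

# one Dirichlet draw via normalised gamma variates
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate tiny-alpha guard
  g / sum(g)
}

# integer allocation summing exactly to n (largest-remainder rounding)
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth> ", nrow(x$true_P), " spots x ", ncol(x$true_P),
      " cell types, ", n_domains(x$layout), " domains\n", sep = "")
  cat("  cells_per_spot ", x$cells_per_spot, ", noise_sigma ",
      x$noise_sigma, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Per-domain true cell-type sets of a simulation
#'
#' @param truth a `simulation_truth`.
#' @return Named list: domain label (character) -> character vector of the
#'   cell types with positive Dirichlet concentration in that domain.
#' @export
true_domain_sets <- function(truth) {
  alpha <- truth$alpha
  sets <- lapply(seq_len(nrow(alpha)), function(d)
    colnames(alpha)[alpha[d, ] > 0])
  names(sets) <- as.character(seq_len(nrow(alpha)) - 1L)
  sets
}
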