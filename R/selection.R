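#' Per-spot Lasso fit with cross-validated penalty
#'
#' Minimises the penalised residual sum of squares
#' `sum_i (y_i - sum_j beta_j x_ij)^2 + lambda * sum_j |beta_j|`
#' (no intercept, no standardisation, no `1/2M` factor) by cyclic coordinate
#' descent on the Gram matrix. The penalty is chosen from `lambda_grid` by
#' k-fold cross-validation with genes as the observations: folds are a
#' seeded shuffle of the genes, the score is mean squared prediction error
#' on held-out genes.
#'
#' @param y numeric vector of spot expression over the feature genes (length
#'   M).
#' @param X numeric M x K signature matrix (no all-zero column).
#' @param lambda_grid numeric vector of candidate penalties; default is 50
#'   log-spaced values from `lambda_max` (the smallest penalty with an
#'   all-zero solution, `2 * max |X'y|`) down to `lambda_max * 1e-4`.
#' @param cv_folds number of folds (genes must be >= folds).
#' @param seed RNG seed for the fold shuffle (ignored when `folds` given).
#' @param folds optional integer vector of fold labels per gene, for sharing
#'   one fold assignment across spots.
#' @return List with `beta` (K-vector, entries below 1e-10 in absolute value
#'   snapped to 0), `lambda_chosen`, `lambda_grid`, and `cv_error` (mean CV
#'   MSE per grid value).
#' @export
#' @examples
#' X <- diag(2); y <- c(1, 0.2)
#' fit_spot_lasso(y, X, lambda_grid = 0.5, cv_folds = 2)$beta  # 0.75, 0
fit_spot_lasso <- function(y, X, lambda_grid = NULL, cv_folds = 10,
                           seed = 1, folds = NULL) {
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X) || any(!is.finite(y)) || any(!is.finite(X)))
    stop("NaN or non-finite values in lasso inputs")
  M <- length(y)
  if (nrow(X) != M) stop("y and X disagree on the number of genes")
  if (any(colSums(abs(X)) == 0)) stop("X has an all-zero column")
  if (M < cv_folds) stop("fewer genes (", M, ") than folds (", cv_folds, ")")
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, y)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  G <- crossprod(X)
  b <- drop(crossprod(X, y))
  if (length(lambda_grid) > 1L) {
    if (is.null(folds)) folds <- make_cv_folds(M, cv_folds, seed)
    cv_err <- cv_lasso_path(y, X, lambda_grid, folds)
    lambda_chosen <- lambda_grid[which.min(cv_err)]
  } else {
    cv_err <- NA_real_
    lambda_chosen <- lambda_grid
  }
  beta <- lasso_cd(G, b, lambda_chosen)
  beta[abs(beta) < 1e-10] <- 0
  list(beta = stats::setNames(beta, colnames(X)),
       lambda_chosen = lambda_chosen, lambda_grid = lambda_grid,
       cv_error = cv_err)
}

default_lambda_grid <- function(X, y, n = 50, ratio = 1e-4) {
  lambda_max <- 2 * max(abs(crossprod(X, y)))
  if (lambda_max <= 0) lambda_max <- 1
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = n))
}

make_cv_folds <- function(M, k, seed) {
  withr::with_seed(as.integer(seed),
    sample(rep_len(seq_len(k), M)))
}

# cyclic coordinate descent on the Gram system; penalty RSS + lambda*|beta|_1
lasso_cd <- function(G, b, lambda, beta = NULL, tol = 1e-12,
                     max_iter = 10000L) {
  K <- length(b)
  if (is.null(beta)) beta <- numeric(K)
  d <- diag(G)
  thr <- lambda / 2
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(K)) {
      r <- b[j] - sum(G[j, ] * beta) + d[j] * beta[j]
      bj <- sign(r) * max(abs(r) - thr, 0) / d[j]
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta < tol * (1 + max(abs(beta)))) break
  }
  beta
}

cv_lasso_path <- function(y, X, lambda_grid, folds) {
  errs <- matrix(NA_real_, length(lambda_grid), max(folds))
  for (f in sort(unique(folds))) {
    test <- folds == f
    Gtr <- crossprod(X[!test, , drop = FALSE])
    btr <- drop(crossprod(X[!test, , drop = FALSE], y[!test]))
    Xte <- X[test, , drop = FALSE]
    yte <- y[test]
    beta <- numeric(ncol(X))
    for (l in seq_along(lambda_grid)) {
      beta <- lasso_cd(Gtr, btr, lambda_grid[l], beta)
      errs[l, f] <- mean((yte - drop(Xte %*% beta))^2)
    }
  }
  rowMeans(errs)
}

#' Adaptive thresholding of a coefficient matrix
#'
#' Negative coefficients are clipped to 0, the matrix is smoothed by a
#' local-mean 2D convolution (uniform window, half-sample symmetric boundary
#' padding, computed via the FFT), and each entry is set to 1 exactly when
#' the clipped coefficient strictly exceeds its local mean. The comparison
#' carries a small numerical guard (1e-9 relative to the coefficient scale)
#' so FFT round-off cannot promote exact ties -- a constant matrix always
#' binarises to all zeros.
#'
#' @param beta numeric spots x cell-types coefficient matrix. Rows should be
#'   ordered so that adjacent rows are spatial neighbours (see
#'   [select_cell_types()], which orders spots by domain, then array row,
#'   then col).
#' @param window integer length-2 (rows, cols), both odd; windows larger
#'   than the matrix are clamped with a warning.
#' @param order optional integer permutation putting rows into spatial
#'   order before filtering; the result is returned in the original order.
#' @return Binary integer matrix of the same shape as `beta`.
#' @export
adaptive_threshold <- function(beta, window = c(15L, 3L), order = NULL) {
  beta <- as.matrix(beta)
  window <- clamp_window(window, dim(beta))
  perm <- order %||% seq_len(nrow(beta))
  bp <- pmax(beta[perm, , drop = FALSE], 0)
  filtered <- fft_local_mean(bp, window)
  guard <- 1e-9 * (1 + max(bp))
  bin <- matrix(0L, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  bin[perm, ] <- (bp > filtered + guard) * 1L
  bin
}

clamp_window <- function(window, dims) {
  w <- as.integer(window)
  if (length(w) != 2 || any(w < 1) || any(w %% 2 == 0))
    stop("window must be two odd integers >= 1")
  clamped <- pmin(w, dims - (dims + 1) %% 2)  # largest odd value <= dim
  if (any(clamped < w))
    warning("threshold window clamped from (", paste(w, collapse = "x"),
            ") to (", paste(clamped, collapse = "x"), ")")
  clamped
}

# local mean under half-sample symmetric padding, computed with the FFT
fft_local_mean <- function(m, window) {
  n <- nrow(m); p <- ncol(m)
  hr <- (window[1] - 1L) / 2L
  hc <- (window[2] - 1L) / 2L
  padded <- m[reflect_index(n, hr), reflect_index(p, hc), drop = FALSE]
  N1 <- nrow(padded) + window[1] - 1L
  N2 <- ncol(padded) + window[2] - 1L
  A <- matrix(0, N1, N2); A[seq_len(nrow(padded)), seq_len(ncol(padded))] <- padded
  Km <- matrix(0, N1, N2); Km[seq_len(window[1]), seq_len(window[2])] <- 1
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(Km), inverse = TRUE)) /
    (N1 * N2)
  conv[window[1] + seq_len(n) - 1L, window[2] + seq_len(p) - 1L,
       drop = FALSE] / prod(window)
}

reflect_index <- function(n, h) {
  idx <- (1L - h):(n + h)
  idx[idx < 1L] <- 1L - idx[idx < 1L]
  idx[idx > n] <- 2L * n + 1L - idx[idx > n]
  idx
}

#' Aggregate a spot-level binary selection into per-domain cell-type sets
#'
#' A cell type enters a domain's set when it is selected in at least a
#' fraction `tau` of the domain's spots. A domain whose set would be empty
#' falls back to the single cell type with the largest mean coefficient in
#' that domain (with a warning).
#'
#' @param binary spots x cell-types binary matrix (rows named by spot).
#' @param beta matching coefficient matrix, used for the empty-set fallback.
#' @param domains a [domain_assignment()] covering all rows of `binary`.
#' @param tau fraction threshold in \[0, 1\].
#' @return Named list mapping domain label (as character) to a character
#'   vector of selected cell types.
#' @export
aggregate_selection <- function(binary, beta, domains, tau = 0.25) {
  stopifnot(tau >= 0, tau <= 1)
  dom <- domains$domain[match(rownames(binary), domains$spot_id)]
  if (anyNA(dom)) stop("binary matrix contains spots without a domain")
  types <- colnames(binary)
  sets <- lapply(sort(unique(dom)), function(d) {
    rows <- dom == d
    if (!any(rows)) stop("domain with 0 spots: ", d)
    frac <- colMeans(binary[rows, , drop = FALSE])
    sel <- types[frac >= tau]
    if (!length(sel)) {
      sel <- types[which.max(colMeans(beta[rows, , drop = FALSE]))]
      warning("domain ", d, ": empty selection, falling back to top ",
              "mean-coefficient type ", sel)
    }
    sel
  })
  names(sets) <- as.character(sort(unique(dom)))
  sets
}

#' Select the cell types present in each spatial domain
#'
#' Runs the full selection stage: per-spot Lasso against the signature
#' (penalty by 10-fold CV over genes), adaptive thresholding of the
#' spot-by-type coefficient matrix into a binary presence matrix, and
#' aggregation into per-domain cell-type sets.
#'
#' @param spatial a [spatial_dataset()].
#' @param signature a `signature_matrix` from [build_signature()] /
#'   [build_reference()].
#' @param domains a [domain_assignment()] covering every spot.
#' @param config a [pipeline_config()].
#' @return Object of class `celltype_selection`: list with `beta`
#'   (spots x K), `lambda` (per spot), `binary`, `domain_sets`, `domains`,
#'   `cell_types`.
#' @export
select_cell_types <- function(spatial, signature, domains,
                              config = pipeline_config()) {
  validate_spatial_dataset(spatial)
  validate_pipeline_config(config)
  prep <- prepare_fit_inputs(spatial, signature, config)
  Y <- prep$Y; X <- prep$X
  M <- nrow(X); K <- ncol(X)
  folds <- make_cv_folds(M, config$cv_folds, config$seed)
  n_spot <- ncol(Y)
  beta <- matrix(0, n_spot, K, dimnames = list(colnames(Y), colnames(X)))
  lambda <- numeric(n_spot)
  for (s in seq_len(n_spot)) {
    fit <- fit_spot_lasso(Y[, s], X, lambda_grid = config$lambda_grid,
                          cv_folds = config$cv_folds, folds = folds)
    beta[s, ] <- fit$beta
    lambda[s] <- fit$lambda_chosen
  }
  ord <- spot_spatial_order(spatial, domains, rownames(beta))
  binary <- adaptive_threshold(beta, config$threshold_window, order = ord)
  sets <- aggregate_selection(binary, beta, domains,
                              tau = config$domain_fraction_tau)
  structure(list(beta = beta, lambda = lambda, binary = binary,
                 domain_sets = sets, domains = domains,
                 cell_types = colnames(X)),
            class = "celltype_selection")
}

# permutation ordering spots by (domain, array row, array col)
spot_spatial_order <- function(spatial, domains, spot_ids) {
  co <- spatial$coords[match(spot_ids, spatial$coords$spot_id), ]
  dom <- domains$domain[match(spot_ids, domains$spot_id)]
  if (anyNA(dom)) stop("spot without a domain label: ",
                       spot_ids[which(is.na(dom))[1]])
  order(dom, co$row, co$col)
}

# shared preprocessing for selection and deconvolution: intersect the gene
# spaces, optionally scale spots and signature columns to sum 1
prepare_fit_inputs <- function(spatial, signature, config) {
  genes <- intersect(rownames(signature$values), rownames(spatial$counts))
  if (length(genes) < 2) stop("fewer than 2 shared feature genes")
  X <- signature$values[genes, , drop = FALSE]
  Y <- spatial$counts[genes, , drop = FALSE]
  if (config$normalization_mode == "spot") {
    ysum <- colSums(Y)
    ysum[ysum == 0] <- 1
    Y <- sweep(Y, 2, ysum, "/")
    xsum <- colSums(X)
    if (any(xsum == 0)) stop("signature column with zero total: ",
                             colnames(X)[xsum == 0][1])
    X <- sweep(X, 2, xsum, "/")
  }
  list(Y = Y, X = X, genes = genes)
}

#' @export
print.celltype_selection <- function(x, ...) {
  cat("<celltype_selection> ", nrow(x$beta), " spots x ", ncol(x$beta),
      " cell types\n", sep = "")
  for (d in names(x$domain_sets))
    cat("  domain ", d, ": ", paste(x$domain_sets[[d]], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
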