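#' Least-absolute-deviation fit on the probability simplex
#'
#' Solves `argmin_p sum_i | y_i - sum_j p_j x_ij |` subject to `p_j >= 0`
#' and `sum_j p_j = 1`. The problem is convex -- a linear program after
#' splitting each residual into its positive and negative parts -- so the
#' default backend solves the LP
#' `min sum(r+ + r-)  s.t.  X p + r+ - r- = y, 1'p = 1, all vars >= 0`
#' exactly with the two-phase simplex method. An ADMM backend (an
#' augmented-Lagrangian / alternating-direction scheme on the same
#' constraints) is kept as an alternative; both meet the same contract.
#'
#' @param y numeric vector of length M (spot expression over feature genes).
#' @param X numeric M x K matrix of signature columns for the candidate
#'   cell types.
#' @param tol solver tolerance on the simplex-sum constraint and (for ADMM)
#'   on convergence.
#' @param method `"lp"` (default) or `"admm"`.
#' @return List with `p` (length-K proportion vector, named by `colnames(X)`)
#'   and `objective` (the attained L1 loss).
#' @export
#' @examples
#' X <- diag(2); solve_simplex_lad(c(0.7, 0.3), X)$p  # 0.7, 0.3
solve_simplex_lad <- function(y, X, tol = 1e-8, method = c("lp", "admm")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  K <- ncol(X); M <- nrow(X)
  if (K == 0) stop("no candidate cell types (empty S)")
  if (length(y) != M) stop("y and X disagree on the number of genes")
  if (anyNA(y) || anyNA(X) || any(!is.finite(y)) || any(!is.finite(X)))
    stop("non-finite values in LAD inputs")
  if (all(y == 0)) {
    warning("all-zero spot expression: returning uniform proportions")
    p <- rep(1 / K, K)
    return(list(p = stats::setNames(p, colnames(X)),
                objective = sum(abs(rowSums(X) / K))))
  }
  if (K == 1) {
    return(list(p = stats::setNames(1, colnames(X)),
                objective = sum(abs(y - X[, 1]))))
  }
  res <- switch(method,
                lp = lad_lp(y, X, tol),
                admm = lad_admm(y, X, tol))
  p <- pmax(res$p, 0)
  p <- p / sum(p)
  list(p = stats::setNames(p, colnames(X)),
       objective = sum(abs(y - drop(X %*% p))))
}

# residual-splitting LP solved with the two-phase simplex method
lad_lp <- function(y, X, tol) {
  M <- nrow(X); K <- ncol(X)
  # boot::simplex requires non-negative right-hand sides: flip rows with
  # y_i < 0 (swaps the roles of the split residuals, objective unchanged)
  sgn <- ifelse(y < 0, -1, 1)
  Xs <- X * sgn
  cc <- c(rep(0, K), rep(1, 2 * M))
  A3 <- rbind(cbind(Xs, diag(M), -diag(M)),
              c(rep(1, K), rep(0, 2 * M)))
  b3 <- c(abs(y), 1)
  sol <- boot::simplex(a = cc, A3 = A3, b3 = b3, maxi = FALSE,
                       n.iter = 50 * (M + K + 10), eps = 1e-10)
  if (sol$solved != 1) {
    # fall back on the iterative backend rather than fail outright
    warning("LP solver did not certify optimality; using ADMM backend")
    return(lad_admm(y, X, max(tol, 1e-10)))
  }
  list(p = unname(sol$soln[seq_len(K)]), objective = unname(sol$value))
}

# ADMM on  min ||z||_1  s.t.  z = y - X p,  p in simplex
lad_admm <- function(y, X, tol, rho = 1, max_iter = 20000L) {
  M <- nrow(X); K <- ncol(X)
  p <- rep(1 / K, K)
  z <- y - drop(X %*% p)
  u <- numeric(M)
  L <- max(eigen(crossprod(X), symmetric = TRUE,
                 only.values = TRUE)$values, .Machine$double.eps)
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    # p-update: projected gradient on (rho/2)||y - Xp - z + u||^2
    target <- y - z + u
    for (inner in seq_len(200L)) {
      grad <- drop(crossprod(X, drop(X %*% p) - target))
      p_new <- project_simplex(p - grad / L)
      if (max(abs(p_new - p)) < 1e-12) { p <- p_new; break }
      p <- p_new
    }
    r <- y - drop(X %*% p)
    z <- soft_threshold(r + u, 1 / rho)
    u <- u + r - z
    if (it %% 25L == 0L) {
      obj <- sum(abs(r))
      if (abs(obj - obj_old) < tol * (1 + abs(obj)) &&
          max(abs(r - z)) < 1e-9) break
      obj_old <- obj
    }
  }
  list(p = p, objective = sum(abs(y - drop(X %*% p))))
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

# Euclidean projection onto the probability simplex (sort-based)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Estimate per-spot cell-type proportions by constrained LAD
#'
#' For every spot, the signature is restricted to the cell types selected
#' for the spot's domain, [solve_simplex_lad()] is run on the spot's
#' (optionally normalised) expression over the feature genes, and the
#' solution is embedded into the full cell-type vector with exact zeros for
#' unselected types.
#'
#' @param spatial a [spatial_dataset()].
#' @param signature a `signature_matrix`.
#' @param selection a `celltype_selection` from [select_cell_types()], or a
#'   named list of per-domain cell-type vectors.
#' @param domains a [domain_assignment()] (defaults to the one stored in
#'   `selection`).
#' @param config a [pipeline_config()].
#' @param method LAD backend, `"lp"` or `"admm"`.
#' @return Object of class `spot_proportions`: list with `P` (spots x K
#'   matrix on the simplex), `objective` (per-spot L1 loss), `cell_types`,
#'   `domains`.
#' @export
deconvolve_dataset <- function(spatial, signature, selection,
                               domains = NULL, config = pipeline_config(),
                               method = c("lp", "admm")) {
  method <- match.arg(method)
  validate_spatial_dataset(spatial)
  validate_pipeline_config(config)
  if (inherits(selection, "celltype_selection")) {
    sets <- selection$domain_sets
    domains <- domains %||% selection$domains
  } else {
    sets <- selection
  }
  if (is.null(domains)) stop("a domain_assignment is required")
  prep <- prepare_fit_inputs(spatial, signature, config)
  Y <- prep$Y; X <- prep$X
  spots <- colnames(Y)
  dom <- domains$domain[match(spots, domains$spot_id)]
  if (anyNA(dom)) stop("spot without a domain label: ",
                       spots[which(is.na(dom))[1]])
  K <- ncol(X)
  P <- matrix(0, length(spots), K, dimnames = list(spots, colnames(X)))
  objective <- numeric(length(spots))
  for (s in seq_along(spots)) {
    S <- sets[[as.character(dom[s])]]
    if (is.null(S) || !length(S))
      stop("spot ", spots[s], ": domain ", dom[s], " has no cell-type set")
    fit <- tryCatch(
      solve_simplex_lad(Y[, s], X[, S, drop = FALSE],
                        tol = config$solver_tolerance, method = method),
      error = function(e) stop("spot ", spots[s], ": ", conditionMessage(e)))
    P[s, S] <- fit$p
    objective[s] <- fit$objective
  }
  structure(list(P = P, objective = objective, cell_types = colnames(X),
                 domains = domains),
            class = "spot_proportions")
}

#' @export
print.spot_proportions <- function(x, ...) {
  cat("<spot_proportions> ", nrow(x$P), " spots x ", ncol(x$P),
      " cell types\n", sep = "")
  cat("  mean proportions: ",
      paste(sprintf("%s %.3f", colnames(x$P), colMeans(x$P)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
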