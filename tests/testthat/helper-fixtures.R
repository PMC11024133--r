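# shared fixtures and independent oracles used across test files

# tiny deterministic single-cell dataset: 2 types x 4 cells, 4 genes
tiny_sc <- function() {
  counts <- matrix(
    c(5, 2, 0, 0,   # gA: marker of typeX
      4, 1, 0, 0,   # gB: marker of typeX
      0, 0, 6, 2,   # gC: marker of typeY
      1, 1, 3, 5),  # gD: shared
    nrow = 4, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC", "gD"),
                    c("c1", "c2", "c3", "c4")))
  meta <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                     cell_type = c("typeX", "typeX", "typeY", "typeY"),
                     sample_id = c("s1", "s2", "s1", "s2"))
  single_cell_dataset(counts, meta)
}

# small grid spatial dataset with the given count matrix
grid_spatial <- function(counts, nrow_grid = NULL) {
  n <- ncol(counts)
  if (is.null(nrow_grid)) nrow_grid <- max(1, floor(sqrt(n)))
  rows <- (seq_len(n) - 1) %/% ceiling(n / nrow_grid)
  cols <- (seq_len(n) - 1) %% ceiling(n / nrow_grid)
  spatial_dataset(counts,
                  data.frame(spot_id = colnames(counts),
                             row = rows, col = cols))
}

# nested-loop local-mean convolution oracle (half-sample symmetric padding),
# written independently of the package's FFT path
direct_local_mean <- function(m, window) {
  n <- nrow(m); p <- ncol(m)
  hr <- (window[1] - 1) / 2; hc <- (window[2] - 1) / 2
  refl <- function(i, n) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      ri <- refl(i + (-hr:hr), n)
      cj <- refl(j + (-hc:hc), p)
      out[i, j] <- mean(m[ri, cj])
    }
  }
  out
}

# independent LP oracle for the simplex-constrained LAD problem
lad_lp_oracle <- function(y, X) {
  M <- nrow(X); K <- ncol(X)
  cc <- c(rep(0, K), rep(1, 2 * M))
  Aeq <- rbind(cbind(X, diag(M), -diag(M)),
               c(rep(1, K), rep(0, 2 * M)))
  sol <- pracma::linprog(cc, Aeq = Aeq, beq = c(y, 1),
                         maxiter = 100 * (M + K))
  list(p = sol$x[seq_len(K)], objective = sol$fval)
}

# exhaustive-permutation two-sided p-value oracle for the rank-sum test
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(idx, 2, function(ii)
    sum(rank(pooled)[ii]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# adjusted Rand index between two labelings (contingency-table formula)
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# projected-gradient least-squares-on-simplex baseline (L2 counterpart of
# the package's LAD fit), used in robustness comparisons
nnls_simplex <- function(y, X, iters = 5000) {
  K <- ncol(X)
  p <- rep(1 / K, K)
  L <- max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values)
  proj <- function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    pmax(v - (css[rho] - 1) / rho, 0)
  }
  for (i in seq_len(iters)) {
    g <- drop(crossprod(X, drop(X %*% p) - y))
    p_new <- proj(p - g / L)
    if (max(abs(p_new - p)) < 1e-12) return(p_new)
    p <- p_new
  }
  p
}

# standard benchmark study conditions shared by several tests
benchmark_inputs <- function(grid = c(20, 20), cells_per_spot = 50,
                             noise_sigma = 0, sim_seed = 11) {
  sc <- simulate_reference(seed = 7)
  lay <- make_domain_layout(grid[1], grid[2], 3)
  sim <- simulate_spatial_dataset(sc, lay, benchmark_alpha(6, 3),
                                  cells_per_spot = cells_per_spot,
                                  noise_sigma = noise_sigma,
                                  seed = sim_seed)
  list(sc = sc, sim = sim)
}
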