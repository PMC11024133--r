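test_that("identity-design lasso reproduces the soft-threshold solution", {
  fit <- fit_spot_lasso(c(1, 0.2), diag(2), lambda_grid = 0.5,
                        cv_folds = 2)
  expect_equal(unname(fit$beta), c(0.75, 0), tolerance = 1e-10)
  # penalty dominance
  fit0 <- fit_spot_lasso(c(1, 0.2), diag(2), lambda_grid = 1e6,
                         cv_folds = 2)
  expect_equal(unname(fit0$beta), c(0, 0))
})

test_that("unpenalised lasso equals the least-squares solution", {
  set.seed(20)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  fit <- fit_spot_lasso(y, X, lambda_grid = 0, cv_folds = 3)
  expect_equal(unname(fit$beta), unname(qr.solve(X, y)), tolerance = 1e-6)
})

test_that("lasso agrees with glmnet under the matching penalty scaling", {
  set.seed(21)
  M <- 40; K <- 5
  X <- matrix(abs(rnorm(M * K)), M, K)
  y <- drop(X %*% runif(K)) + rnorm(M, 0, 0.05)
  for (lam in c(0.5, 2, 10)) {
    mine <- fit_spot_lasso(y, X, lambda_grid = lam, cv_folds = 2)$beta
    gl <- glmnet::glmnet(X, y, lambda = lam / (2 * M), standardize = FALSE,
                         intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(mine), as.numeric(gl$beta), tolerance = 1e-5)
  }
})

test_that("sparsity along the penalty path is monotone", {
  set.seed(22)
  X <- matrix(abs(rnorm(50 * 6)), 50, 6)
  for (i in 1:5) {
    y <- drop(X %*% runif(6)) + rnorm(50, 0, 0.1)
    grid <- spotdecon:::default_lambda_grid(X, y, n = 25)
    nnz <- sapply(grid, function(l)
      sum(fit_spot_lasso(y, X, lambda_grid = l, cv_folds = 2)$beta != 0))
    expect_true(all(diff(nnz[order(grid, decreasing = TRUE)]) >= 0))
  }
})

test_that("lasso input validation catches degenerate problems", {
  expect_error(fit_spot_lasso(c(1, NA), diag(2), cv_folds = 2), "NaN")
  expect_error(fit_spot_lasso(c(1, 2), cbind(c(1, 1), 0), cv_folds = 2),
               "all-zero")
  expect_error(fit_spot_lasso(rnorm(5), matrix(1, 5, 1), cv_folds = 10),
               "fewer genes")
})

test_that("cross-validation picks a small penalty on noise-free mixtures", {
  set.seed(23)
  X <- matrix(abs(rnorm(100 * 4)), 100, 4)
  p <- c(0.4, 0.3, 0.2, 0.1)
  fit <- fit_spot_lasso(drop(X %*% p), X, cv_folds = 10, seed = 2)
  expect_equal(unname(fit$beta), p, tolerance = 0.01)
  expect_equal(length(fit$lambda_grid), 50)
  expect_gt(fit$lambda_chosen, 0)
})

test_that("FFT local mean equals the nested-loop convolution oracle", {
  set.seed(24)
  for (i in 1:10) {
    n <- sample(3:50, 1); p <- sample(2:20, 1)
    m <- matrix(rnorm(n * p), n, p)
    w <- c(min(2 * sample(1:5, 1) + 1, n - (n + 1) %% 2),
           min(2 * sample(0:2, 1) + 1, p - (p + 1) %% 2))
    expect_lt(max(abs(spotdecon:::fft_local_mean(m, w) -
                        direct_local_mean(m, w))), 1e-10)
  }
})

test_that("adaptive threshold applies the strict-inequality tie rule", {
  const <- matrix(5, 6, 4)
  expect_true(all(adaptive_threshold(const, c(3, 3)) == 0))

  z <- matrix(0, 3, 3); z[2, 2] <- 1
  bin <- adaptive_threshold(z, c(3, 3))
  expect_equal(sum(bin), 1)
  expect_equal(bin[2, 2], 1L)

  neg <- matrix(-1, 4, 4); neg[1, 1] <- -0.1
  expect_true(all(adaptive_threshold(neg, c(3, 3)) == 0))

  expect_warning(adaptive_threshold(matrix(rnorm(12), 4, 3), c(15, 5)),
                 "clamped")
  expect_error(adaptive_threshold(matrix(0, 4, 3), c(2, 3)), "odd")
})

test_that("domain aggregation follows the fraction rule with fallback", {
  binary <- matrix(0L, 10, 3,
                   dimnames = list(paste0("s", 1:10), c("A", "B", "C")))
  binary[1:6, "A"] <- 1L
  beta <- matrix(0.1, 10, 3, dimnames = dimnames(binary))
  beta[, "B"] <- 0.5
  dom <- domain_assignment(paste0("s", 1:10), rep(0, 10))
  sets <- aggregate_selection(binary, beta, dom, tau = 0.25)
  expect_equal(sets[["0"]], "A")  # 0.6 >= 0.25; B,C never selected

  binary[] <- 0L
  expect_warning(sets2 <- aggregate_selection(binary, beta, dom,
                                              tau = 0.25), "empty")
  expect_equal(sets2[["0"]], "B")  # largest mean coefficient
})

test_that("selection with a width-1 type window is column-order invariant", {
  set.seed(25)
  bench <- benchmark_inputs(grid = c(6, 6), cells_per_spot = 30)
  sig <- build_reference(bench$sc, rownames(bench$sim$spatial$counts))
  cfg <- pipeline_config(threshold_window = c(5, 1), seed = 9)
  sel <- select_cell_types(bench$sim$spatial, sig,
                           bench$sim$truth$layout, cfg)

  perm <- sample(ncol(sig$values))
  sig2 <- sig
  sig2$values <- sig$values[, perm]
  sig2$cell_types <- sig$cell_types[perm]
  sel2 <- select_cell_types(bench$sim$spatial, sig2,
                            bench$sim$truth$layout, cfg)
  expect_equal(sel2$beta, sel$beta[, perm])
  expect_equal(sel2$binary, sel$binary[, perm])
  for (d in names(sel$domain_sets))
    expect_setequal(sel$domain_sets[[d]], sel2$domain_sets[[d]])
})
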