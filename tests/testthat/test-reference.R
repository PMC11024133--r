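test_that("gene and cell filters drop exactly the right rows and columns", {
  sc <- tiny_sc()
  sc$counts["gB", ] <- 0
  sc <- single_cell_dataset(sc$counts, sc$meta)
  out <- filter_cells_genes(sc)
  expect_false("gB" %in% rownames(out$counts))
  expect_equal(ncol(out$counts), 4)

  out2 <- filter_cells_genes(tiny_sc(), keep_types = "typeX")
  expect_true(all(out2$meta$cell_type == "typeX"))

  expect_equal(filter_cells_genes(tiny_sc())$counts, tiny_sc()$counts)
  zero <- tiny_sc(); zero$counts[] <- 0
  expect_error(filter_cells_genes(
    single_cell_dataset(zero$counts, zero$meta)))
})

test_that("library-size scaling normalises every cell to sum 1", {
  sc <- tiny_sc()
  scaled <- scale_by_library_size(sc)
  expect_equal(unname(colSums(scaled$counts)), rep(1, 4))
  expect_equal(unname(scaled$counts[, "c1"]),
               c(5, 4, 0, 1) / 10)

  counts <- cbind(sc$counts, c0 = c(0, 0, 0, 0))
  meta <- rbind(sc$meta, data.frame(cell_id = "c0", cell_type = "typeX",
                                    sample_id = "s1"))
  expect_warning(out <- scale_by_library_size(
    single_cell_dataset(counts, meta)), "1 cell")
  expect_false("c0" %in% colnames(out$counts))
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)

  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p_value, 1)

  set.seed(42)
  for (i in 1:10) {
    x <- sample(1:100, 6); y <- sample(101:200, 6) - 100.5
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, perm_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("marker detection finds constructed markers and respects filters", {
  set.seed(7)
  G <- 20; n <- 10
  # build scaled expression directly so g2 is identical in every cell
  expr <- matrix(stats::runif(G * 2 * n, 0.01, 0.1), G,
                 dimnames = list(paste0("g", 1:G),
                                 paste0("c", 1:(2 * n))))
  expr["g1", 1:n] <- runif(n, 0.5, 0.6)       # marker of A
  expr["g1", n + 1:n] <- runif(n, 0.001, 0.002)
  expr["g2", ] <- 0.05                        # identical everywhere
  expr <- sweep(expr, 2, colSums(expr), "/")
  expr["g2", ] <- 0.05  # pin after normalisation; still constant
  meta <- data.frame(cell_id = colnames(expr),
                     cell_type = rep(c("A", "B"), each = n))
  sc <- single_cell_dataset(expr, meta)
  mk <- find_marker_genes(sc)
  expect_true(any(mk$gene_id == "g1" & mk$cell_type == "A"))
  expect_false("g2" %in% mk$gene_id)
  expect_true(all(mk$adjusted_p >= mk$p_value - 1e-15))
  expect_true(all(mk$adjusted_p <= 0.05))
  expect_true(all(mk$log_fold_change >= 0.25))
})

test_that("marker detection is equivariant under cell-type relabeling", {
  set.seed(8)
  G <- 15; n <- 8
  counts <- matrix(rpois(G * 3 * n, 4) + 1, G,
                   dimnames = list(paste0("g", 1:G),
                                   paste0("c", 1:(3 * n))))
  counts["g3", 1:n] <- rpois(n, 40)
  counts["g7", n + 1:n] <- rpois(n, 40)
  meta <- data.frame(cell_id = colnames(counts),
                     cell_type = rep(c("A", "B", "C"), each = n))
  sc <- scale_by_library_size(single_cell_dataset(counts, meta))
  mk1 <- find_marker_genes(sc)

  relab <- c(A = "C", B = "A", C = "B")
  meta2 <- meta; meta2$cell_type <- unname(relab[meta$cell_type])
  sc2 <- scale_by_library_size(single_cell_dataset(counts, meta2))
  mk2 <- find_marker_genes(sc2)
  for (tp in c("A", "B", "C")) {
    expect_setequal(mk1$gene_id[mk1$cell_type == tp],
                    mk2$gene_id[mk2$cell_type == relab[tp]])
  }
})

test_that("small cell types are excluded from testing with a warning", {
  sc <- tiny_sc()  # 2 cells per type, both below the minimum of 3
  expect_error(expect_warning(
    find_marker_genes(scale_by_library_size(sc)), "< 3 cells"))
})

test_that("signature columns are per-type means of scaled expression", {
  sc <- scale_by_library_size(tiny_sc())
  sig <- build_signature(sc, spatial_genes = rownames(sc$counts))
  # brute-force loop oracle
  for (tp in c("typeX", "typeY")) {
    idx <- which(sc$meta$cell_type == tp)
    manual <- rowMeans(sc$counts[, idx, drop = FALSE])
    expect_equal(sig$values[, tp], manual)
  }
  # disjoint marker blocks give zero off-blocks
  expect_equal(unname(sig$values["gC", "typeX"]), 0)
  expect_equal(unname(sig$values["gA", "typeY"]), 0)
})

test_that("signature gene filtering follows the three-criteria rule", {
  sc <- scale_by_library_size(tiny_sc())
  # spatial shares only gA and gD; user marker gZ does not exist spatially
  expect_message(
    sig <- build_signature(sc, spatial_genes = c("gA", "gD"),
                           user_markers = c("gZ")),
    "absent from spatial")
  expect_setequal(rownames(sig$values), c("gA", "gD"))
  expect_true(all(sig$provenance$shared))
  expect_error(build_signature(sc, spatial_genes = "gA"), "fewer than 2")
})

test_that("single-cell-per-type signature equals that cell's scaled vector", {
  counts <- matrix(c(2, 1, 1, 0, 0, 4), 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  meta <- data.frame(cell_id = c("c1", "c2"), cell_type = c("A", "B"))
  sc <- scale_by_library_size(single_cell_dataset(counts, meta))
  sig <- build_signature(sc, spatial_genes = c("g1", "g2", "g3"))
  expect_equal(unname(sig$values[, "A"]), c(0.5, 0.25, 0.25))
  expect_equal(unname(sig$values[, "B"]), c(0, 0, 1))
})

test_that("full reference construction runs end to end on simulated cells", {
  sc <- simulate_reference(n_types = 3, markers_per_type = 8,
                           n_housekeeping = 6, cells_per_type = 12,
                           seed = 5)
  sig <- build_reference(sc, spatial_genes = rownames(sc$counts))
  expect_equal(ncol(sig$values), 3)
  expect_true(all(sig$values >= 0))
  expect_s3_class(attr(sig, "markers"), "marker_tests")
  # every type's own markers rank among its DEGs
  mk <- attr(sig, "markers")
  expect_true(all(grepl("^mk01", mk$gene_id[mk$cell_type == "type1"]) |
                    !grepl("^mk0", mk$gene_id[mk$cell_type == "type1"])))
  expect_true(nrow(attr(sig, "cross_sample_variance")) > 0)
})
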