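write_mtx_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 3", "2 2 5"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA\tgA", "gB\tgB"), file.path(dir, "features.tsv"))
  writeLines(c("s1", "s2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("barcode,row,col", "s1,0,0", "s2,0,1"),
             file.path(dir, "coords.csv"))
  dir
}

test_that("MTX triplet and dense CSV loaders give the same matrix", {
  dir <- write_mtx_fixture(withr::local_tempdir())
  sp <- load_spatial(dir, file.path(dir, "coords.csv"))
  expected <- matrix(c(3, 0, 0, 5), 2, byrow = TRUE,
                     dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_equal(sp$counts, expected)

  csv <- file.path(dir, "dense.csv")
  writeLines(c("gene,s1,s2", "gA,3,0", "gB,0,5"), csv)
  sp2 <- load_spatial(csv, file.path(dir, "coords.csv"))
  expect_equal(sp2$counts, expected)
  expect_equal(sp2$coords$row, c(0, 0))
  expect_equal(sp2$coords$col, c(0, 1))
})

test_that("spots without coordinates are dropped with a warning", {
  dir <- write_mtx_fixture(withr::local_tempdir())
  writeLines(c("barcode,row,col", "s1,0,0"),
             file.path(dir, "coords_partial.csv"))
  expect_warning(
    sp <- load_spatial(dir, file.path(dir, "coords_partial.csv")),
    "1 spot")
  expect_equal(colnames(sp$counts), "s1")
})

test_that("loader errors name the offending file / gene / row", {
  dir <- write_mtx_fixture(withr::local_tempdir())
  expect_error(load_spatial(file.path(dir, "nope"),
                            file.path(dir, "coords.csv")), "not found")
  expect_error(load_spatial(dir, file.path(dir, "missing.csv")),
               "not found")
  csv <- file.path(dir, "dup.csv")
  writeLines(c("gene,s1,s2", "gA,1,2", "gA,0,4"), csv)
  expect_error(load_spatial(csv, file.path(dir, "coords.csv")), "gA")
  bad <- file.path(dir, "badco.csv")
  writeLines(c("barcode,row,col", "s1,0,0", "s2,zero,1"), bad)
  expect_error(load_spatial(dir, bad), "row 2")
})

test_that("single-cell loader matches counts to metadata by cell id", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "sc.csv")
  writeLines(c("gene,c1,c2,c3", "gA,1,0,2", "gB,0,3,1"), csv)
  meta <- file.path(dir, "meta.csv")
  writeLines(c("cell_id,cell_type,sample_id",
               "c1,A,s1", "c2,B,s1", "c3,A,s1"), meta)
  sc <- load_single_cell(csv, meta)
  expect_equal(ncol(sc$counts), 3)
  expect_equal(sc$meta$cell_type, c("A", "B", "A"))

  meta2 <- file.path(dir, "meta2.csv")
  writeLines(c("cell_id,cell_type", "c1,A", "c3,A"), meta2)
  expect_warning(sc2 <- load_single_cell(csv, meta2), "1 cell")
  expect_equal(colnames(sc2$counts), c("c1", "c3"))

  # extra metadata rows for unknown cells are ignored silently
  meta3 <- file.path(dir, "meta3.csv")
  writeLines(c("cell_id,cell_type", "c1,A", "c2,B", "c3,A", "c9,Z"), meta3)
  expect_silent(sc3 <- load_single_cell(csv, meta3))
  expect_equal(ncol(sc3$counts), 3)

  meta4 <- file.path(dir, "meta4.csv")
  writeLines(c("cell_id,foo", "c1,A"), meta4)
  expect_error(load_single_cell(csv, meta4), "cell_type")
  meta5 <- file.path(dir, "meta5.csv")
  writeLines(c("cell_id,cell_type", "zz,A"), meta5)
  expect_error(load_single_cell(csv, meta5), "no cell ids shared")
})

test_that("proportion CSV round-trips within 1e-6 and handles edge shapes", {
  dir <- withr::local_tempdir()
  p1 <- matrix(c(0.7, 0.3), 1, dimnames = list("s1", c("tA", "tB")))
  f <- file.path(dir, "p.csv")
  write_proportions(p1, f)
  expect_equal(readLines(f), c("spot_id,tA,tB", "s1,0.7,0.3"))

  set.seed(1)
  pm <- matrix(runif(12), 4, 3,
               dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  pm <- pm / rowSums(pm)
  write_proportions(pm, f)
  expect_equal(read_proportions(f), pm, tolerance = 1e-6)

  empty <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("tA", "tB")))
  write_proportions(empty, f)
  expect_equal(readLines(f), "spot_id,tA,tB")
})

test_that("spatial write/load round trip is exact for integer counts", {
  dir <- withr::local_tempdir()
  set.seed(2)
  counts <- matrix(rpois(30, 3), 5, 6,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  sp <- grid_spatial(counts)
  write_spatial(sp, dir)
  sp2 <- load_spatial(dir, file.path(dir, "coords.csv"))
  expect_equal(sp2$counts, sp$counts)
  expect_equal(sp2$coords$row, sp$coords$row)
  expect_equal(sp2$coords$col, sp$coords$col)
})

test_that("container validators reject inconsistent inputs", {
  counts <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  co <- data.frame(spot_id = c("s1", "s2"), row = 0:1, col = 0:1)
  expect_s3_class(spatial_dataset(counts, co), "spatial_dataset")
  expect_error(spatial_dataset(counts - 2, co), "non-negative")
  expect_error(spatial_dataset(counts, co[1, ]), "one row per spot")
  expect_error(pipeline_config(cv_folds = 1), "cv_folds")
  expect_error(pipeline_config(threshold_window = c(4, 3)), "odd")
  expect_error(pipeline_config(domain_fraction_tau = 1.5), "tau")
})
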