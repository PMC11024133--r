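#' Load spatial transcriptomics counts and spot coordinates
#'
#' Reads either a 10x-style Matrix Market triplet directory
#' (`matrix.mtx[.gz]` plus `features.tsv`/`genes.tsv` and `barcodes.tsv`) or
#' a dense CSV with gene rows and spot columns, together with a spot
#' coordinate table. Spots without a coordinate row are dropped with a
#' warning; gene order is preserved from the file.
#'
#' @param path directory containing the MTX triplet, or path to a dense CSV
#'   (first column gene id, remaining columns one per spot).
#' @param coords_path CSV/TSV mapping every barcode to two numeric
#'   coordinates. Columns may be named (`spot_id`/`barcode`, `row`/`y`,
#'   `col`/`x`) or positional (barcode, row, col). Pixel x/y columns are
#'   mapped x -> col, y -> row.
#' @return A [spatial_dataset()].
#' @export
load_spatial <- function(path, coords_path) {
  if (!file.exists(path)) stop("spatial input not found: ", path)
  if (!file.exists(coords_path)) stop("coordinate file not found: ", coords_path)
  if (dir.exists(path)) {
    counts <- read_mtx_triplet(path)
  } else {
    counts <- read_dense_csv(path)
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene ids in spatial input, first duplicate: ", dup[1])
  coords <- read_coords(coords_path)
  keep <- colnames(counts) %in% coords$spot_id
  if (!all(keep)) {
    warning(sum(!keep), " spot(s) dropped: no coordinate row")
    counts <- counts[, keep, drop = FALSE]
  }
  coords <- coords[match(colnames(counts), coords$spot_id), , drop = FALSE]
  spatial_dataset(counts, coords)
}

read_mtx_triplet <- function(dir) {
  mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- as.matrix(Matrix::readMM(mtx))
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(features) != nrow(m))
    stop("features file has ", nrow(features), " rows but matrix has ",
         nrow(m), " genes")
  if (length(barcodes) != ncol(m))
    stop("barcodes file has ", length(barcodes), " rows but matrix has ",
         ncol(m), " spots")
  # 10x features files put the gene symbol in column 2 when present
  gene_ids <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  dimnames(m) <- list(gene_ids, barcodes)
  m
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("missing file in ", dir, ": expected one of ",
       paste(names, collapse = ", "))
}

read_dense_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

read_coords <- function(path) {
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nms <- tolower(names(df))
  id_col <- which(nms %in% c("spot_id", "barcode", "spot"))[1]
  row_col <- which(nms %in% c("row", "array_row", "y"))[1]
  col_col <- which(nms %in% c("col", "array_col", "x"))[1]
  if (is.na(id_col) || is.na(row_col) || is.na(col_col)) {
    # positional fallback: barcode, row, col
    if (ncol(df) < 3) stop("coordinate file needs >= 3 columns")
    id_col <- 1; row_col <- 2; col_col <- 3
  }
  rows <- suppressWarnings(as.numeric(df[[row_col]]))
  cols <- suppressWarnings(as.numeric(df[[col_col]]))
  bad <- which(is.na(rows) | is.na(cols))
  if (length(bad))
    stop("non-numeric coordinate at row ", bad[1], " of ", path)
  tibble::tibble(spot_id = as.character(df[[id_col]]), row = rows, col = cols)
}

#' Load single-cell counts with cell metadata
#'
#' @param path MTX triplet directory or dense CSV of gene x cell counts.
#' @param metadata_path CSV/TSV with columns `cell_id` (or `barcode`),
#'   `cell_type`, and optionally `sample_id`.
#' @return A [single_cell_dataset()]. Cells absent from the metadata are
#'   dropped with a warning; metadata rows for unknown cells are ignored.
#' @export
load_single_cell <- function(path, metadata_path) {
  if (!file.exists(path)) stop("single-cell input not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  counts <- if (dir.exists(path)) read_mtx_triplet(path) else
    read_dense_csv(path)
  sep <- if (grepl("\\.tsv(\\.gz)?$", metadata_path)) "\t" else ","
  meta <- utils::read.table(metadata_path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
  nms <- tolower(names(meta))
  names(meta)[nms %in% c("barcode", "cell", "cell_id")] <- "cell_id"
  names(meta)[nms %in% c("cell_type", "celltype", "label")] <- "cell_type"
  names(meta)[nms %in% c("sample_id", "sample", "orig.ident")] <- "sample_id"
  if (!"cell_type" %in% names(meta)) stop("metadata lacks a cell_type column")
  if (!"cell_id" %in% names(meta)) stop("metadata lacks a cell_id column")
  keep <- colnames(counts) %in% meta$cell_id
  if (!any(keep)) stop("no cell ids shared between counts and metadata")
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) dropped: no metadata row")
    counts <- counts[, keep, drop = FALSE]
  }
  meta <- meta[match(colnames(counts), meta$cell_id), , drop = FALSE]
  single_cell_dataset(counts, meta)
}

#' Write / read a spot-by-cell-type proportion table
#'
#' The CSV has header `spot_id,<type1>,...,<typeK>` and one row per spot;
#' values keep full double precision so a write/read round trip reproduces
#' the matrix within 1e-6.
#'
#' @param P a `spot_proportions` object (see [estimate_proportions()]) or a
#'   numeric spots x cell-types matrix with dimnames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(P, path) {
  m <- as_proportion_matrix(P)
  ids <- rownames(m)
  if (is.null(ids)) ids <- character(nrow(m))
  df <- data.frame(spot_id = ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write proportions to ", path)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) stop("proportion file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a spatial dataset as a Matrix Market triplet plus coordinate CSV
#'
#' @param sp a [spatial_dataset()].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv` and `coords.csv`.
#' @return `dir`, invisibly.
#' @export
write_spatial <- function(sp, dir) {
  validate_spatial_dataset(sp)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(sp$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(sp$counts), rownames(sp$counts)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(colnames(sp$counts), file.path(dir, "barcodes.tsv"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(sp$coords[, c("spot_id", "row", "col")],
                   file.path(dir, "coords.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

# coerce proportion-like inputs to a plain spots x types matrix
as_proportion_matrix <- function(P) {
  if (inherits(P, "spot_proportions")) return(P$P)
  if (is.data.frame(P)) {
    if ("spot_id" %in% names(P)) {
      m <- as.matrix(P[setdiff(names(P), "spot_id")])
      rownames(m) <- as.character(P$spot_id)
      return(m)
    }
    return(as.matrix(P))
  }
  as.matrix(P)
}
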