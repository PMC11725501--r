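#' Gene-by-cell count matrix with cell metadata
#'
#' The package's basic data container: a non-negative integer matrix with
#' genes as rows and cells as columns, plus a per-cell metadata table
#' (`batch`, `time_point`, optional `label`). Matrices are always gene x
#' cell in memory, with identifiers carried as dimnames.
#'
#' @param counts Numeric matrix or sparse `dgCMatrix`, genes x cells, with
#'   unique rownames (genes) and colnames (cells). Entries must be
#'   non-negative integers.
#' @param cell_meta Optional `data.frame` with a `cell_id` column (or
#'   rownames) and any of `batch`, `time_point`, `label`. Cells missing from
#'   it are assigned `batch = "default"`.
#' @return An object of class `count_matrix`: list with elements `counts`
#'   (dgCMatrix) and `cell_meta` (data.frame keyed by `cell_id`).
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have rownames (genes) and colnames (cells)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell identifiers")
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  vals <- counts@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    stop("counts must be non-negative integers")
  cells <- colnames(counts)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cells, batch = "default",
                            time_point = NA_real_, label = NA_character_,
                            stringsAsFactors = FALSE)
  } else {
    cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(cell_meta)) {
      if (is.null(rownames(cell_meta)))
        stop("cell_meta needs a cell_id column or rownames")
      cell_meta$cell_id <- rownames(cell_meta)
    }
    for (col in c("batch", "time_point", "label")) {
      if (!col %in% names(cell_meta))
        cell_meta[[col]] <- if (col == "time_point") NA_real_ else NA_character_
    }
    cell_meta <- cell_meta[, c("cell_id", "batch", "time_point", "label")]
    missing <- setdiff(cells, cell_meta$cell_id)
    if (length(missing)) {
      cell_meta <- rbind(cell_meta,
                         data.frame(cell_id = missing, batch = "default",
                                    time_point = NA_real_,
                                    label = NA_character_))
    }
    cell_meta <- cell_meta[match(cells, cell_meta$cell_id), ]
    cell_meta$batch[is.na(cell_meta$batch)] <- "default"
  }
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d batch(es)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$batch))))
  invisible(x)
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @export
genes <- function(x) rownames(x$counts)

#' @rdname count_matrix
#' @export
cells <- function(x) colnames(x$counts)

# Subset a count_matrix by gene/cell identifiers or indices.
subset_counts <- function(x, genes = NULL, cells = NULL) {
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  count_matrix(m, x$cell_meta[match(colnames(m), x$cell_meta$cell_id), ])
}

#' Read a count matrix from disk
#'
#' Reads MatrixMarket triplet files (with companion `genes.tsv` /
#' `barcodes.tsv` identifier files, 1-based indices) or dense CSV/TSV with
#' genes as rows, and an optional cell-metadata TSV with columns `cell_id`,
#' `batch`, `time_point`, `label`.
#'
#' @param path Matrix file (`.mtx`, `.csv` or `.tsv`).
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`; guessed from the file
#'   extension when missing.
#' @param meta_path Optional metadata TSV.
#' @param genes_path,cells_path Identifier files for `mtx` input; default to
#'   `genes.tsv` and `barcodes.tsv` next to the matrix.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("mtx", "csv", "tsv"),
                              meta_path = NULL,
                              genes_path = NULL, cells_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mtx", "csv", "tsv")) ext else "tsv"
  }
  format <- match.arg(format)
  if (format == "mtx") {
    dir <- dirname(path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    cells_path <- cells_path %||% file.path(dir, "barcodes.tsv")
    if (!file.exists(genes_path)) stop("no such file: ", genes_path)
    if (!file.exists(cells_path)) stop("no such file: ", cells_path)
    m <- as.matrix(Matrix::readMM(path))
    gn <- fread(genes_path, header = FALSE, sep = "\t")[[1]]
    cn <- fread(cells_path, header = FALSE, sep = "\t")[[1]]
    if (length(gn) != nrow(m) || length(cn) != ncol(m))
      stop(sprintf(
        "format error: matrix is %d x %d but identifier files list %d genes and %d cells",
        nrow(m), ncol(m), length(gn), length(cn)))
    dimnames(m) <- list(gn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dt <- fread(path, sep = sep, header = TRUE)
    gn <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- gn
  }
  if (any(m < 0) || any(m != round(m)))
    stop("validation error: counts must be non-negative integers")
  meta <- if (!is.null(meta_path)) {
    as.data.frame(fread(meta_path, sep = "\t", header = TRUE))
  } else NULL
  count_matrix(m, meta)
}

#' Write a count matrix as MatrixMarket triplets
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `meta.tsv` into a
#' directory, the layout [read_count_matrix()] reads back.
#'
#' @param x A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  fwrite(x$cell_meta, file.path(dir, "meta.tsv"), sep = "\t")
  invisible(dir)
}

#' Write a prediction table
#'
#' One TSV row per query cell, in input cell order, with columns `cell_id`,
#' `predicted_label`, `probability` (empty for the abstention labels
#' `ambiguous`, `nonrelated` and `nb_failed`), `flags` and `neighborhood_ids`
#' (semicolon-separated).
#'
#' @param pred A prediction result from [predict_identities()].
#' @param path Output TSV path.
#' @return The number of data rows written, invisibly.
#' @export
write_prediction_table <- function(pred, path) {
  df <- as.data.frame(pred)
  out <- data.frame(
    cell_id = df$cell_id,
    predicted_label = df$label,
    probability = ifelse(is.na(df$probability), "",
                         format(df$probability, digits = 8)),
    flags = df$flags,
    neighborhood_ids = df$neighborhood_ids,
    stringsAsFactors = FALSE)
  fwrite(out, path, sep = "\t")
  invisible(nrow(out))
}
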