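SCHEMA_VERSION <- 1L

REQUIRED_MODEL_FIELDS <- c(
  "config", "gene_selection", "rescale", "grand_centers", "rotation",
  "merge_records", "corrected_coords", "clusters", "lineages",
  "embed2", "embed_latent", "classifiers", "ref_unit_matrix",
  "dataset_of_cell")

write_array <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(as.numeric(x)), con, size = 8L, endian = "little")
}

read_array <- function(path, dims, dimnames = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(dims), size = 8L, endian = "little")
  if (length(v) != prod(dims))
    stop("array file ", basename(path), " is truncated")
  if (length(dims) == 1) return(setNames(v, dimnames[[1]]))
  matrix(v, dims[1], dims[2], dimnames = dimnames)
}

#' Save a reference model to a directory
#'
#' Writes a JSON manifest (schema version, config, shapes, identifiers,
#' merge records, md5 checksums) plus flat little-endian binary arrays, the
#' serialized classifier set, and the two embedding models — everything
#' needed to replay a projection bit-identically after reload. Refuses to
#' save a model with missing fields, listing them.
#'
#' @param model A `reference_model`.
#' @param path Output directory (created; must not contain a manifest
#'   already unless `overwrite`).
#' @param overwrite Allow writing over an existing model directory.
#' @return Invisibly, a manifest summary list (`files`, `n_cells`,
#'   `n_genes`).
#' @export
save_reference_model <- function(model, path, overwrite = FALSE) {
  missing <- REQUIRED_MODEL_FIELDS[vapply(REQUIRED_MODEL_FIELDS, function(f)
    is.null(model[[f]]), TRUE)]
  if (length(missing))
    stop("model is incomplete; missing fields: ",
         paste(missing, collapse = ", "))
  if (file.exists(file.path(path, "manifest.json")) && !overwrite)
    stop("model directory already exists: ", path)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrays <- list(
    grand_centers = as.matrix(model$grand_centers),
    rotation = model$rotation,
    corrected_coords = model$corrected_coords,
    ref_unit_matrix = as.matrix(model$ref_unit_matrix))
  for (nm in names(arrays)) write_array(arrays[[nm]],
                                        file.path(path, paste0(nm, ".bin")))
  saveRDS(model$classifiers, file.path(path, "classifiers.rds"))
  uwot::save_uwot(model$embed2, file.path(path, "embed2.uwot"))
  uwot::save_uwot(model$embed_latent, file.path(path, "embed_latent.uwot"))
  cfg <- unclass(model$config)
  cfg$qc <- unclass(cfg$qc); cfg$deg <- unclass(cfg$deg)
  if (!is.finite(cfg$qc$max_genes)) cfg$qc$max_genes <- NULL  # JSON-safe Inf
  merge_records <- lapply(model$merge_records, function(r)
    list(step = r$step, batch = r$batch,
         batch_vector = r$batch_vector, target_mean = r$target_mean,
         applied = !isFALSE(r$applied),
         sigma = r$sigma, n_pairs = r$n_pairs,
         pair_a = r$pairs$a_cell, pair_b = r$pairs$b_cell))
  manifest <- list(
    package = "embryomap",
    schema_version = SCHEMA_VERSION,
    config = cfg,
    gene_selection = model$gene_selection,
    rescale = model$rescale,
    cells = rownames(model$corrected_coords),
    clusters = unname(model$clusters),
    lineages = unname(model$lineages),
    dataset_of_cell = unname(model$dataset_of_cell),
    merge_records = merge_records,
    shapes = lapply(arrays, dim))
  # JSON decimal text loses the last ulp; the replay scalars (rescale
  # factors, batch vectors, target means) must survive bit-exactly, so they
  # also go into a binary sidecar that takes precedence on load.
  exact <- c(unname(model$rescale$scale), model$rescale$target_coverage,
             unlist(lapply(model$merge_records, function(r)
               c(r$batch_vector, r$target_mean, r$sigma))))
  write_array(exact, file.path(path, "exact_scalars.bin"))
  manifest$exact_layout <- list(n_batches = length(model$rescale$scale),
                                d = ncol(model$rotation),
                                n_records = length(model$merge_records))
  files <- c(paste0(names(arrays), ".bin"), "exact_scalars.bin",
             "classifiers.rds", "embed2.uwot", "embed_latent.uwot")
  manifest$checksums <- as.list(setNames(
    unname(tools::md5sum(file.path(path, files))), files))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(list(files = c("manifest.json", files),
                 n_cells = nrow(model$corrected_coords),
                 n_genes = length(model$gene_selection)))
}

#' Load a reference model from a directory
#'
#' Verifies the schema version and every file checksum, rebuilds the model
#' (arrays bit-identical to what was saved), and re-validates its
#' invariants.
#'
#' @param path Directory written by [save_reference_model()].
#' @return A `reference_model`.
#' @export
load_reference_model <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", path)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.integer(man$schema_version), SCHEMA_VERSION))
    stop("incompatible schema version ", man$schema_version,
         " (this build reads version ", SCHEMA_VERSION, ")")
  for (f in names(man$checksums)) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing model file: ", f)
    if (!identical(unname(tools::md5sum(fp)), man$checksums[[f]]))
      stop("checksum mismatch for ", f, "; model directory is corrupt")
  }
  cfgl <- man$config
  cfg <- embryomap_config(
    k_mnn_query = cfgl$k_mnn_query, k_mnn_small = cfgl$k_mnn_small,
    k_mnn_merge = cfgl$k_mnn_merge, subsample_size = cfgl$subsample_size,
    n_repeats = cfgl$n_repeats, corr_threshold = cfgl$corr_threshold,
    top_n_corr = cfgl$top_n_corr, prob_threshold = cfgl$prob_threshold,
    n_pcs = cfgl$n_pcs, n_hvg_total = cfgl$n_hvg_total,
    n_hvg_stage1 = cfgl$n_hvg_stage1, latent_dim = cfgl$latent_dim,
    nhood_prop = cfgl$nhood_prop, nhood_k = cfgl$nhood_k,
    ndist = cfgl$ndist, leiden_resolution = cfgl$leiden_resolution,
    umap_neighbors = cfgl$umap_neighbors,
    umap_min_dist = cfgl$umap_min_dist, rng_seed = cfgl$rng_seed,
    svm_cost_grid = cfgl$svm_cost_grid,
    svm_gamma_grid = cfgl$svm_gamma_grid,
    mnn_on_cosine = cfgl$mnn_on_cosine,
    per_cell_mnn_support = cfgl$per_cell_mnn_support,
    sparse_gene_floor = cfgl$sparse_gene_floor,
    size_factor_method = cfgl$size_factor_method,
    qc = do.call(qc_thresholds, lapply(cfgl$qc, function(x)
      if (is.null(x)) Inf else x)),
    deg = do.call(deg_criteria, {
      d <- lapply(cfgl$deg, function(x) if (is.null(x)) NA else x)
      d$exclude_genes <- as.character(cfgl$deg$exclude_genes %||% character())
      d
    }),
    ambiguous_lineage_pairs = lapply(
      if (is.matrix(cfgl$ambiguous_lineage_pairs))
        split(cfgl$ambiguous_lineage_pairs,
              row(cfgl$ambiguous_lineage_pairs))
      else cfgl$ambiguous_lineage_pairs, as.character))
  shapes <- man$shapes
  cells_ <- man$cells
  sel <- man$gene_selection
  grand <- read_array(file.path(path, "grand_centers.bin"),
                      shapes$grand_centers)
  rotation <- read_array(file.path(path, "rotation.bin"), shapes$rotation,
                         list(sel, paste0("PC", seq_len(shapes$rotation[2]))))
  coords <- read_array(file.path(path, "corrected_coords.bin"),
                       shapes$corrected_coords,
                       list(cells_, paste0("PC",
                                           seq_len(shapes$corrected_coords[2]))))
  units <- read_array(file.path(path, "ref_unit_matrix.bin"),
                      shapes$ref_unit_matrix, list(sel, cells_))
  mr_raw <- man$merge_records
  merge_records <- if (is.data.frame(mr_raw)) {
    lapply(seq_len(nrow(mr_raw)), function(i)
      list(step = mr_raw$step[i], batch = mr_raw$batch[i],
           batch_vector = as.numeric(mr_raw$batch_vector[[i]]),
           applied = !isFALSE(mr_raw$applied[i]),
           target_mean = mr_raw$target_mean[i], sigma = mr_raw$sigma[i],
           n_pairs = mr_raw$n_pairs[i],
           pairs = data.frame(a_cell = as.character(mr_raw$pair_a[[i]]),
                              b_cell = as.character(mr_raw$pair_b[[i]]))))
  } else {
    lapply(mr_raw, function(r)
      list(step = r$step, batch = r$batch,
           batch_vector = as.numeric(r$batch_vector),
           applied = !isFALSE(r$applied),
           target_mean = r$target_mean, sigma = r$sigma,
           n_pairs = r$n_pairs,
           pairs = data.frame(a_cell = as.character(r$pair_a),
                              b_cell = as.character(r$pair_b))))
  }
  rescale <- man$rescale
  rescale$scale <- unlist(rescale$scale)
  lay <- man$exact_layout
  exact <- read_array(file.path(path, "exact_scalars.bin"),
                      lay$n_batches + 1L + lay$n_records * (lay$d + 2L))
  rescale$scale <- setNames(exact[seq_len(lay$n_batches)],
                            names(rescale$scale))
  rescale$target_coverage <- exact[lay$n_batches + 1L]
  off <- lay$n_batches + 1L
  for (i in seq_len(lay$n_records)) {
    if (i <= length(merge_records)) {
      merge_records[[i]]$batch_vector <- exact[off + seq_len(lay$d)]
      merge_records[[i]]$target_mean <- exact[off + lay$d + 1L]
      merge_records[[i]]$sigma <- exact[off + lay$d + 2L]
    }
    off <- off + lay$d + 2L
  }
  model <- structure(list(
    config = cfg,
    gene_selection = sel,
    rescale = rescale,
    grand_centers = setNames(as.numeric(grand), sel),
    rotation = rotation,
    merge_records = merge_records,
    corrected_coords = coords,
    clusters = setNames(as.integer(man$clusters), cells_),
    lineages = setNames(as.character(man$lineages), cells_),
    embed2 = uwot::load_uwot(file.path(path, "embed2.uwot")),
    embed_latent = uwot::load_uwot(file.path(path, "embed_latent.uwot")),
    classifiers = readRDS(file.path(path, "classifiers.rds")),
    ref_unit_matrix = units,
    dataset_of_cell = setNames(as.character(man$dataset_of_cell), cells_)),
    class = "reference_model")
  validate_reference_model(model)
  model
}
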