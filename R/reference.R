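#' Build the integrated embryo reference model
#'
#' Runs the full reference construction and freezes everything a query
#' projection needs: QC filtering, size factors, cross-batch rescaling to
#' the lowest-coverage batch, two-stage integration-feature selection,
#' cosine normalization, grand-centered SVD, sequential MNN merging in
#' developmental-time order (recording every batch vector, target mean and
#' bandwidth), 2-D and latent embedding models with a transform contract,
#' Leiden clustering, per-lineage SVM classifiers, and the cosine unit
#' matrix used for correlation filtering.
#'
#' @param batches Named list of [count_matrix()] objects, one per dataset.
#' @param order Character vector giving the merge order (developmental
#'   time); defaults to the list order.
#' @param lineage_labels Named character vector: lineage per cell. Must
#'   cover every cell that survives QC.
#' @param cfg An [embryomap_config()].
#' @param stage1_batches Batches voted in the first feature-selection pass
#'   (e.g. the preimplantation datasets); default all.
#' @param mito_genes Passed to [qc_filter()].
#' @return An object of class `reference_model`.
#' @export
build_reference <- function(batches, order = names(batches), lineage_labels,
                            cfg = embryomap_config(),
                            stage1_batches = names(batches),
                            mito_genes = "^MT-") {
  stopifnot(length(batches) >= 1, !is.null(names(batches)))
  filtered <- with_stage("qc_filter",
    lapply(batches, qc_filter, t = cfg$qc, mito_genes = mito_genes))
  all_cells <- unlist(lapply(filtered, cells), use.names = FALSE)
  missing <- setdiff(all_cells, names(lineage_labels))
  if (length(missing))
    stop("[lineages] unlabeled cells after QC: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  sized <- with_stage("compute_size_factors",
    lapply(filtered, function(b)
      list(counts = b,
           size_factors = compute_size_factors(b, cfg$size_factor_method))))
  resc <- with_stage("multibatch_rescale", multibatch_rescale(sized))
  sel <- with_stage("select_integration_features",
    select_integration_features(resc$logmats, stage1_batches, cfg))
  units <- with_stage("cosine_normalize",
    lapply(resc$logmats, cosine_normalize, gene_selection = as.character(sel)))
  pca <- with_stage("multibatch_pca", multibatch_pca(units, cfg$n_pcs))
  mb <- with_stage("merge_batches", merge_batches(pca$coords, order, cfg))
  embeds <- with_stage("fit_embedding_models",
    fit_embedding_models(mb$corrected_coords,
                         dims = unique(c(2L, cfg$latent_dim)), cfg = cfg))
  clusters <- with_stage("leiden_cluster",
    leiden_cluster(mb$corrected_coords, cfg))
  cell_order <- rownames(mb$corrected_coords)
  lineages <- lineage_labels[cell_order]
  latent <- embeds[[paste0("d", cfg$latent_dim)]]$embedding
  classifiers <- with_stage("train_lineage_classifiers",
    train_lineage_classifiers(latent, lineages, cfg))
  unit_all <- do.call(cbind, units)[, cell_order, drop = FALSE]
  dataset_of_cell <- setNames(
    rep(names(filtered), vapply(filtered, function(b) length(cells(b)), 0L)),
    unlist(lapply(filtered, cells), use.names = FALSE))[cell_order]
  model <- structure(list(
    config = cfg,
    gene_selection = as.character(sel),
    rescale = resc$record,
    grand_centers = pca$grand_centers,
    rotation = pca$rotation,
    merge_records = mb$merge_records,
    corrected_coords = mb$corrected_coords,
    clusters = clusters[cell_order],
    lineages = lineages,
    embed2 = embeds[["d2"]],
    embed_latent = embeds[[paste0("d", cfg$latent_dim)]],
    classifiers = classifiers,
    ref_unit_matrix = unit_all,
    dataset_of_cell = dataset_of_cell),
    class = "reference_model")
  validate_reference_model(model)
  model
}

# Invariant checks shared by build and load.
validate_reference_model <- function(m) {
  rtr <- crossprod(m$rotation)
  if (max(abs(rtr - diag(ncol(m$rotation)))) > 1e-8)
    stop("rotation columns are not orthonormal")
  if (nrow(m$corrected_coords) != length(m$lineages))
    stop("corrected_coords row count does not match lineage labels")
  if (any(table(m$lineages) < 1)) stop("empty lineage")
  if (!identical(rownames(m$corrected_coords), colnames(m$ref_unit_matrix)))
    stop("cell order mismatch between coordinates and unit matrix")
  invisible(TRUE)
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(
    "reference_model: %d cells, %d datasets, %d lineages, %d features, %d PCs\n",
    nrow(x$corrected_coords), length(unique(x$dataset_of_cell)),
    length(unique(x$lineages)), length(x$gene_selection),
    ncol(x$rotation)))
  cat(sprintf("  merge steps: %d; clusters: %d; latent dim: %d\n",
              length(x$merge_records), length(unique(x$clusters)),
              x$config$latent_dim))
  invisible(x)
}
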