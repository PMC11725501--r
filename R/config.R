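#' Quality-control thresholds
#'
#' Per-cell and per-gene filters applied before normalization. The defaults
#' are the full-length (Smart-seq2-style) cutoffs used for deep embryo
#' datasets: at least 2,000 expressed genes per cell and a mitochondrial
#' fraction below 0.125; genes must be expressed in at least five remaining
#' cells.
#'
#' @param min_genes Integer floor on expressed genes per cell.
#' @param max_genes Optional integer ceiling on expressed genes per cell
#'   (doublet guard for droplet data); `Inf` disables it.
#' @param max_mito_frac Cells with a mitochondrial count fraction at or above
#'   this value are removed. In `[0, 1]`.
#' @param min_cells_per_gene Genes expressed in fewer cells than this (after
#'   cell filtering) are removed.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 2000L, max_genes = Inf,
                          max_mito_frac = 0.125, min_cells_per_gene = 5L) {
  stopifnot(min_genes >= 0, max_genes > 0, min_cells_per_gene >= 0)
  if (is.finite(max_genes) && min_genes >= max_genes)
    stop("min_genes must be < max_genes")
  if (max_mito_frac < 0 || max_mito_frac > 1)
    stop("max_mito_frac must be in [0, 1]")
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = max_genes,
                 max_mito_frac = max_mito_frac,
                 min_cells_per_gene = as.integer(min_cells_per_gene)),
            class = "qc_thresholds")
}

#' Consensus differential-expression criteria
#'
#' Multi-comparison filters a gene must satisfy to be called a consensus DEG
#' when the two sides of a contrast come from different datasets and single
#' comparisons are unreliable. `NA` for a `min_comparisons_*` field means
#' "all comparisons". Defaults reproduce the strict variant: mean expression
#' in the upregulated group above 10, log2 fold change above 0.25 in every
#' comparison, adjusted p below 0.05 in at least four comparisons, and the
#' expressing fraction above 50% in the high group and below 25% in the low
#' group.
#'
#' @param min_mean_expr_up Floor on mean (de-logged, normalized) expression
#'   in the upregulated group; `NA` disables.
#' @param min_log2fc Log2 fold-change floor per comparison.
#' @param min_comparisons_fc Number of comparisons that must pass the fold
#'   change floor (`NA` = all).
#' @param min_comparisons_p Number of comparisons that must pass `alpha` on
#'   the adjusted p-value (`NA` = all).
#' @param alpha Adjusted p-value cutoff.
#' @param pct_high_floor Minimum expressing fraction in the high group;
#'   `NA` disables the percentage rule.
#' @param pct_low_ceiling Maximum expressing fraction in the low group.
#' @param min_comparisons_pct Comparisons that must pass the percentage rule
#'   (`NA` = all).
#' @param require_stouffer If `TRUE`, the Bonferroni-adjusted Stouffer-combined
#'   p-value across comparisons must also fall below `alpha`.
#' @param exclude_genes Character vector of genes excluded a priori (e.g.
#'   sex-chromosome genes when comparing embryos of different sex).
#' @return An object of class `deg_criteria`.
#' @export
deg_criteria <- function(min_mean_expr_up = 10, min_log2fc = 0.25,
                         min_comparisons_fc = NA, min_comparisons_p = 4L,
                         alpha = 0.05, pct_high_floor = 0.5,
                         pct_low_ceiling = 0.25, min_comparisons_pct = NA,
                         require_stouffer = FALSE,
                         exclude_genes = character()) {
  stopifnot(alpha > 0, alpha <= 1)
  if (!is.na(pct_high_floor) && (pct_high_floor < 0 || pct_high_floor > 1))
    stop("pct_high_floor must be in [0, 1]")
  if (!is.na(pct_low_ceiling) && (pct_low_ceiling < 0 || pct_low_ceiling > 1))
    stop("pct_low_ceiling must be in [0, 1]")
  structure(list(min_mean_expr_up = min_mean_expr_up,
                 min_log2fc = min_log2fc,
                 min_comparisons_fc = min_comparisons_fc,
                 min_comparisons_p = min_comparisons_p,
                 alpha = alpha,
                 pct_high_floor = pct_high_floor,
                 pct_low_ceiling = pct_low_ceiling,
                 min_comparisons_pct = min_comparisons_pct,
                 require_stouffer = isTRUE(require_stouffer),
                 exclude_genes = as.character(exclude_genes)),
            class = "deg_criteria")
}

#' Pipeline configuration
#'
#' All tunable parameters of the reference build, query projection and
#' identity prediction, with the published defaults: query MNN search uses
#' K = 30 neighbours on 200-cell subsamples repeated five times (K = 5 when
#' the query has fewer than 50 cells); Spearman filtering uses the mean of
#' the top 20 correlations against a 0.5 cutoff; classifier assignment
#' requires probability >= 0.5; the corrected subspace has 50 dimensions and
#' the classifier latent space 20; integration uses 4,000 features of which
#' 2,000 come from a first-pass vote; neighbourhood sampling uses prop 0.15.
#'
#' @param k_mnn_query Neighbours for query-reference MNN search.
#' @param k_mnn_small K used when the query has fewer than 50 cells.
#' @param k_mnn_merge Neighbours per side for reference merge steps.
#' @param subsample_size Query cells per subsample chunk.
#' @param n_repeats Random re-chunking repeats whose pairs are unioned.
#' @param corr_threshold Spearman cutoff in `[0, 1]` for pair filtering and
#'   nonrelated flagging.
#' @param top_n_corr Number of top correlations averaged / inspected.
#' @param prob_threshold Minimum classifier probability for assignment.
#' @param n_pcs Dimension of the corrected subspace.
#' @param n_hvg_total Total integration features.
#' @param n_hvg_stage1 First-pass features voted from the early-stage batches.
#' @param latent_dim Classifier latent-space dimension (`<= n_pcs`).
#' @param nhood_prop Fraction of cells sampled as neighbourhood indices.
#' @param nhood_k Neighbours per neighbourhood.
#' @param ndist Kernel-bandwidth multiplier for correction smoothing.
#' @param leiden_resolution Resolution of Leiden clustering.
#' @param umap_neighbors,umap_min_dist UMAP graph parameters.
#' @param rng_seed Seed controlling every stochastic step.
#' @param svm_cost_grid,svm_gamma_grid Grids searched for the RBF-SVM cost
#'   and kernel width.
#' @param mnn_on_cosine If `TRUE`, query MNN search runs on cosine-normalized
#'   expression instead of the orthogonalized subspace (default).
#' @param per_cell_mnn_support If `TRUE`, MNN support for a predicted lineage
#'   is required per cell rather than per query dataset.
#' @param sparse_gene_floor Median expressed-genes threshold below which a
#'   query is treated as sparse and aggregated into neighbourhoods.
#' @param size_factor_method `"pooling"` (deconvolution) or `"library"`.
#' @param qc A [qc_thresholds()] object.
#' @param deg A [deg_criteria()] object.
#' @param ambiguous_lineage_pairs List of length-2 character vectors naming
#'   lineage pairs with confounded signatures; query cells pairing to both
#'   members lose all their MNN pairs. Default: trophectoderm vs amnion.
#' @return An object of class `embryomap_config`.
#' @export
embryomap_config <- function(k_mnn_query = 30L, k_mnn_small = 5L,
                             k_mnn_merge = 20L,
                             subsample_size = 200L, n_repeats = 5L,
                             corr_threshold = 0.5, top_n_corr = 20L,
                             prob_threshold = 0.5, n_pcs = 50L,
                             n_hvg_total = 4000L, n_hvg_stage1 = 2000L,
                             latent_dim = 20L, nhood_prop = 0.15,
                             nhood_k = 10L, ndist = 3,
                             leiden_resolution = 1,
                             umap_neighbors = 30L, umap_min_dist = 0.3,
                             rng_seed = 42L,
                             svm_cost_grid = 2^seq(-2L, 6L),
                             svm_gamma_grid = 2^seq(-8L, 2L),
                             mnn_on_cosine = FALSE,
                             per_cell_mnn_support = FALSE,
                             sparse_gene_floor = 5000L,
                             size_factor_method = c("pooling", "library"),
                             qc = qc_thresholds(),
                             deg = deg_criteria(),
                             ambiguous_lineage_pairs = list(c("TE", "Amnion"))) {
  size_factor_method <- match.arg(size_factor_method)
  counts <- c(k_mnn_query = k_mnn_query, k_mnn_small = k_mnn_small,
              k_mnn_merge = k_mnn_merge, subsample_size = subsample_size,
              n_repeats = n_repeats, top_n_corr = top_n_corr, n_pcs = n_pcs,
              n_hvg_total = n_hvg_total, n_hvg_stage1 = n_hvg_stage1,
              latent_dim = latent_dim, nhood_k = nhood_k,
              umap_neighbors = umap_neighbors)
  if (any(counts < 1))
    stop("count parameters must all be >= 1: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  for (nm in c("corr_threshold", "prob_threshold", "nhood_prop")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(nm, " must be in [0, 1]")
  }
  if (latent_dim > n_pcs) stop("latent_dim must be <= n_pcs")
  if (subsample_size < k_mnn_query)
    stop("subsample_size must be >= k_mnn_query")
  stopifnot(inherits(qc, "qc_thresholds"), inherits(deg, "deg_criteria"),
            ndist > 0, all(svm_cost_grid > 0), all(svm_gamma_grid > 0))
  stopifnot(is.list(ambiguous_lineage_pairs),
            all(vapply(ambiguous_lineage_pairs, length, 1L) == 2L))
  structure(list(
    k_mnn_query = as.integer(k_mnn_query),
    k_mnn_small = as.integer(k_mnn_small),
    k_mnn_merge = as.integer(k_mnn_merge),
    subsample_size = as.integer(subsample_size),
    n_repeats = as.integer(n_repeats),
    corr_threshold = corr_threshold,
    top_n_corr = as.integer(top_n_corr),
    prob_threshold = prob_threshold,
    n_pcs = as.integer(n_pcs),
    n_hvg_total = as.integer(n_hvg_total),
    n_hvg_stage1 = as.integer(n_hvg_stage1),
    latent_dim = as.integer(latent_dim),
    nhood_prop = nhood_prop,
    nhood_k = as.integer(nhood_k),
    ndist = ndist,
    leiden_resolution = leiden_resolution,
    umap_neighbors = as.integer(umap_neighbors),
    umap_min_dist = umap_min_dist,
    rng_seed = as.integer(rng_seed),
    svm_cost_grid = svm_cost_grid,
    svm_gamma_grid = svm_gamma_grid,
    mnn_on_cosine = isTRUE(mnn_on_cosine),
    per_cell_mnn_support = isTRUE(per_cell_mnn_support),
    sparse_gene_floor = as.integer(sparse_gene_floor),
    size_factor_method = size_factor_method,
    qc = qc, deg = deg,
    ambiguous_lineage_pairs = ambiguous_lineage_pairs),
    class = "embryomap_config")
}

#' @export
print.embryomap_config <- function(x, ...) {
  cat("embryomap configuration\n")
  cat(sprintf("  query MNN: K=%d (K=%d if <50 cells), %d-cell chunks x %d repeats\n",
              x$k_mnn_query, x$k_mnn_small, x$subsample_size, x$n_repeats))
  cat(sprintf("  filtering: Spearman >= %.2f over top %d; prob >= %.2f\n",
              x$corr_threshold, x$top_n_corr, x$prob_threshold))
  cat(sprintf("  subspace: %d PCs, latent %d; HVG %d (stage-1 %d)\n",
              x$n_pcs, x$latent_dim, x$n_hvg_total, x$n_hvg_stage1))
  invisible(x)
}
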