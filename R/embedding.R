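#' Fit stabilized embedding models
#'
#' Fits one UMAP model per requested output dimension on the corrected
#' subspace coordinates, keeping the fitted model so new points can later be
#' transformed into the same space without recomputing or perturbing the
#' reference embedding. PCA initialization and single-threaded SGD make the
#' fit reproducible for a fixed seed.
#'
#' @param corrected_coords Cells x n_pcs matrix.
#' @param dims Integer vector of output dimensions, e.g. `c(2, 20)`.
#' @param cfg An [embryomap_config()] (`umap_neighbors`, `umap_min_dist`,
#'   `rng_seed`).
#' @return Named list (`"d2"`, `"d20"`, ...) of uwot models with
#'   `$embedding` holding the reference coordinates.
#' @export
fit_embedding_models <- function(corrected_coords, dims = c(2L, 20L),
                                 cfg = embryomap_config()) {
  stopifnot(all(is.finite(corrected_coords)))
  if (any(dims > ncol(corrected_coords)))
    stop("embedding dimension exceeds the subspace dimension (",
         ncol(corrected_coords), ")")
  n <- nrow(corrected_coords)
  models <- lapply(dims, function(d) {
    set.seed(cfg$rng_seed)
    uwot::umap(corrected_coords,
               n_neighbors = min(cfg$umap_neighbors, n - 1L),
               min_dist = cfg$umap_min_dist,
               n_components = d,
               init = "pca", init_sdev = "range",
               seed = cfg$rng_seed,
               n_threads = 1, n_sgd_threads = 0,
               ret_model = TRUE, verbose = FALSE)
  })
  names(models) <- paste0("d", dims)
  for (m in models) rownames(m$embedding) <- rownames(corrected_coords)
  models
}

# Transform new points into a fitted embedding without altering it.
transform_embedding <- function(model, coords, cfg) {
  set.seed(cfg$rng_seed)
  out <- uwot::umap_transform(coords, model, n_threads = 1,
                              n_sgd_threads = 0, verbose = FALSE)
  rownames(out) <- rownames(coords)
  out
}

#' Leiden clustering on the shared-nearest-neighbour graph
#'
#' Builds a kNN graph (`umap_neighbors` neighbours, exact search) on the
#' corrected coordinates, weights edges by the Jaccard overlap of neighbour
#' sets (pruned below 1/15), and partitions with the Leiden algorithm under
#' the modularity objective.
#'
#' @param corrected_coords Cells x dims matrix with rownames.
#' @param cfg An [embryomap_config()] (`umap_neighbors`,
#'   `leiden_resolution`, `rng_seed`).
#' @return Named integer vector of cluster ids (1-based).
#' @export
leiden_cluster <- function(corrected_coords, cfg = embryomap_config()) {
  n <- nrow(corrected_coords)
  stopifnot(n >= 2)
  k <- min(cfg$umap_neighbors, n - 1L)
  nn <- knn_index(corrected_coords, corrected_coords, k + 1L)  # incl. self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = ncol(nn)),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)            # |N(i) ∩ N(j)|
  sz <- ncol(nn)
  jac <- shared
  jac@x <- jac@x / (2 * sz - jac@x)          # Jaccard of equal-size sets
  jac@x[jac@x < 1 / 15] <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(cfg$rng_seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = cfg$leiden_resolution,
                               n_iterations = 10L)
  setNames(as.integer(igraph::membership(cl)), rownames(corrected_coords))
}
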