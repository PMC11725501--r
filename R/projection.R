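# Rank-transform and standardize columns so that crossprod() of two such
# matrices is the Spearman correlation of the original columns. Constant
# columns map to zero (correlation defined as 0).
spearman_standardize <- function(M) {
  R <- apply(M, 2, rank)
  if (is.null(dim(R))) R <- matrix(R, ncol = ncol(M))
  R <- sweep(R, 2, colMeans(R))
  nrm <- sqrt(colSums(R^2))
  nz <- nrm > 0
  R[, nz] <- sweep(R[, nz, drop = FALSE], 2, nrm[nz], "/")
  R[, !nz] <- 0
  colnames(R) <- colnames(M)
  R
}

#' Project query cells into the frozen reference subspace
#'
#' Replays the recorded reference transformations on a query: rescales the
#' query to the reference's lowest-coverage target, cosine-normalizes over
#' the reference gene selection (missing genes imputed as zero, with an 80%
#' coverage floor), subtracts the recorded grand centers, rotates by the
#' recorded left singular vectors, and applies every recorded merge-step
#' orthogonalization in order. The reference is never modified.
#'
#' @param query A [count_matrix()].
#' @param ref A reference model from [build_reference()].
#' @return List with `raw_coords` (query cells x n_pcs), `units` (cosine
#'   matrix over the gene selection), `coverage` (fraction of selection
#'   genes present) and `imputed_genes`.
#' @export
embed_query <- function(query, ref) {
  sel <- ref$gene_selection
  coverage <- mean(sel %in% genes(query))
  if (coverage < 0.8)
    stop(sprintf(
      "query covers only %.1f%% of the reference gene selection (floor 80%%)",
      100 * coverage))
  logmat <- rescale_query(query, ref$rescale,
                          ref$config$size_factor_method)
  units <- cosine_normalize(logmat, sel)
  centered <- units - ref$grand_centers[sel]
  coords <- crossprod(centered, ref$rotation)
  for (rec in ref$merge_records) {
    if (isFALSE(rec$applied)) next
    coords <- orthogonalize_along_vector(coords, rec$batch_vector,
                                         rec$target_mean)
  }
  rownames(coords) <- colnames(units)
  list(raw_coords = coords, units = units, coverage = coverage,
       imputed_genes = attr(units, "imputed_genes"))
}

#' Subsampled query-reference MNN pairs
#'
#' Shuffles the query `n_repeats` times (seeded), partitions each shuffle
#' into chunks of `subsample_size` cells (the last, smaller chunk kept as
#' its own chunk), and runs a mutual nearest-neighbour search between every
#' chunk and every reference dataset separately with K = `k_mnn_query`
#' (or `k_mnn_small` when the whole query has fewer than 50 cells).
#' Subsampling keeps K meaningful for queries of very different sizes;
#' repeating and unioning removes the bias of any one partition. Each
#' retained pair carries the reference dataset, reference lineage and the
#' Spearman correlation of the two cells over the gene selection.
#'
#' @param raw_coords Query coordinates from [embed_query()].
#' @param ref Reference model.
#' @param cfg An [embryomap_config()].
#' @param query_units Cosine matrix from [embed_query()] (needed for the
#'   correlations and for `mnn_on_cosine` search).
#' @return data.frame of class `pair_set`: `query_cell`, `ref_cell`,
#'   `ref_dataset`, `ref_lineage`, `spearman_corr`, `repeat_idx`,
#'   `chunk_idx`; attribute `K`.
#' @export
subsampled_mnn_pairs <- function(raw_coords, ref, cfg = ref$config,
                                 query_units = NULL) {
  n <- nrow(raw_coords)
  K <- if (n < 50) cfg$k_mnn_small else cfg$k_mnn_query
  ref_space <- if (cfg$mnn_on_cosine) t(ref$ref_unit_matrix)
               else ref$corrected_coords
  qry_space <- if (cfg$mnn_on_cosine) t(query_units) else raw_coords
  datasets <- split(rownames(ref_space),
                    ref$dataset_of_cell[rownames(ref_space)])
  found <- list()
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(cfg$rng_seed + r)
    perm <- sample(n)
    chunks <- split(perm, ceiling(seq_along(perm) / cfg$subsample_size))
    for (ci in seq_along(chunks)) {
      qc_ <- qry_space[chunks[[ci]], , drop = FALSE]
      for (ds in names(datasets)) {
        rc <- ref_space[datasets[[ds]], , drop = FALSE]
        pr <- find_mnn_pairs(rc, qc_, K, K)
        if (nrow(pr))
          found[[length(found) + 1L]] <- data.frame(
            query_cell = pr$b_cell, ref_cell = pr$a_cell,
            ref_dataset = ds, repeat_idx = r, chunk_idx = ci,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found)) {
    out <- data.frame(query_cell = character(), ref_cell = character(),
                      ref_dataset = character(), ref_lineage = character(),
                      spearman_corr = numeric(), repeat_idx = integer(),
                      chunk_idx = integer())
  } else {
    out <- do.call(rbind, found)
    out <- out[!duplicated(out[, c("query_cell", "ref_cell")]), ]
    out$ref_lineage <- unname(ref$lineages[out$ref_cell])
    qs <- spearman_standardize(query_units)
    rs <- spearman_standardize(ref$ref_unit_matrix)
    out$spearman_corr <- colSums(qs[, out$query_cell, drop = FALSE] *
                                   rs[, out$ref_cell, drop = FALSE])
    out <- out[, c("query_cell", "ref_cell", "ref_dataset", "ref_lineage",
                   "spearman_corr", "repeat_idx", "chunk_idx")]
    rownames(out) <- NULL
  }
  attr(out, "K") <- K
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Filter query-reference MNN pairs
#'
#' Three filters, reported in the `filter_counts` attribute:
#' (1) query cells paired to *both* lineages of any configured
#' mutually-exclusive pair (by default trophectoderm and amnion, whose
#' transcriptomes are too similar to trust mixed signatures) lose all their
#' pairs; (2) pairs with Spearman correlation below `corr_threshold` are
#' dropped; (3) any reference lineage whose `top_n_corr` best pair
#' correlations are all below the threshold loses every pair.
#'
#' @param pairs A `pair_set` from [subsampled_mnn_pairs()].
#' @param ref Reference model (unused beyond validation; lineages ride on
#'   the pairs).
#' @param cfg An [embryomap_config()].
#' @return Filtered `pair_set` (subset of the input) with attribute
#'   `filter_counts`.
#' @export
filter_mnn_pairs <- function(pairs, ref = NULL, cfg = embryomap_config()) {
  att_K <- attr(pairs, "K")
  counts <- c(ambiguous_lineage = 0L, low_correlation = 0L,
              lineage_dropped = 0L)
  if (nrow(pairs)) {
    drop_cells <- character()
    for (ap in cfg$ambiguous_lineage_pairs) {
      q1 <- unique(pairs$query_cell[pairs$ref_lineage == ap[1]])
      q2 <- unique(pairs$query_cell[pairs$ref_lineage == ap[2]])
      drop_cells <- union(drop_cells, intersect(q1, q2))
    }
    keep <- !(pairs$query_cell %in% drop_cells)
    counts["ambiguous_lineage"] <- sum(!keep)
    pairs2 <- pairs[keep, , drop = FALSE]
    # lineage-level support, judged before the per-pair cut
    lin_drop <- vapply(split(pairs2$spearman_corr, pairs2$ref_lineage),
                       function(v) {
                         top <- head(sort(v, decreasing = TRUE),
                                     cfg$top_n_corr)
                         all(top < cfg$corr_threshold)
                       }, TRUE)
    bad_lin <- names(lin_drop)[lin_drop]
    keep_lin <- !(pairs2$ref_lineage %in% bad_lin)
    counts["lineage_dropped"] <- sum(!keep_lin)
    pairs3 <- pairs2[keep_lin, , drop = FALSE]
    keep_corr <- pairs3$spearman_corr >= cfg$corr_threshold
    counts["low_correlation"] <- sum(!keep_corr)
    pairs <- pairs3[keep_corr, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  if (!nrow(pairs))
    warning("all MNN pairs were filtered out; downstream predictions ",
            "will be ambiguous")
  attr(pairs, "K") <- att_K
  attr(pairs, "filter_counts") <- counts
  class(pairs) <- c("pair_set", "data.frame")
  pairs
}

#' Correct query coordinates using filtered MNN pairs
#'
#' Computes the kernel-smoothed, variance-adjusted correction field
#' (reference cells as targets, query as incoming batch) and adds it to the
#' raw query coordinates. Reference coordinates are untouched. With an
#' empty pair set the query is returned unchanged and every cell flagged
#' `no_mnn_support`.
#'
#' @param raw_coords Query coordinates from [embed_query()].
#' @param pairs Filtered `pair_set`.
#' @param ref Reference model.
#' @param cfg An [embryomap_config()].
#' @return Corrected coordinates; attribute `no_mnn_support` (logical per
#'   cell) marks cells of an empty pair set.
#' @export
correct_query <- function(raw_coords, pairs, ref, cfg = ref$config) {
  if (!nrow(pairs)) {
    attr(raw_coords, "no_mnn_support") <-
      setNames(rep(TRUE, nrow(raw_coords)), rownames(raw_coords))
    return(raw_coords)
  }
  idx <- data.frame(a = match(pairs$ref_cell, rownames(ref$corrected_coords)),
                    b = match(pairs$query_cell, rownames(raw_coords)))
  k_bw <- min(attr(pairs, "K") %||% cfg$k_mnn_query, nrow(raw_coords) - 1L)
  fld <- compute_correction_field(idx, ref$corrected_coords, raw_coords,
                                  ndist = cfg$ndist, k = max(k_bw, 1L),
                                  adjust_variance = TRUE)
  out <- raw_coords + fld$correction
  attr(out, "no_mnn_support") <-
    setNames(rep(FALSE, nrow(out)), rownames(out))
  attr(out, "batch_vector") <- fld$batch_vector
  out
}

#' Flag query cells outside the reference's biological scope
#'
#' For every query cell, computes the Spearman correlation against all
#' reference cells over the gene selection, averages the `top_n_corr`
#' largest values, and flags the cell as nonrelated when that mean is
#' strictly below `corr_threshold` (a mean of exactly the threshold is kept).
#'
#' @param query_units Cosine matrix over the gene selection.
#' @param ref Reference model.
#' @param cfg An [embryomap_config()].
#' @return List with `mask` (named logical) and `corr_stats` (named
#'   numeric, the per-cell mean top correlation).
#' @export
flag_nonrelated <- function(query_units, ref, cfg = ref$config) {
  qs <- spearman_standardize(query_units)
  rs <- spearman_standardize(ref$ref_unit_matrix)
  rho <- crossprod(qs, rs)                    # query x ref
  topn <- min(cfg$top_n_corr, ncol(rho))
  stats <- apply(rho, 1, function(v)
    mean(sort(v, decreasing = TRUE)[seq_len(topn)]))
  mask <- stats < cfg$corr_threshold
  list(mask = setNames(mask, colnames(query_units)),
       corr_stats = setNames(stats, colnames(query_units)))
}

#' Full query projection
#'
#' Orchestrates the projection pipeline: optional neighbourhood aggregation
#' for sparse droplet-style queries, subspace replay ([embed_query()]),
#' subsampled MNN pairing, pair filtering, MNN correction, transformation
#' through the frozen 2-D and latent embedding models, and nonrelated
#' flagging. Deterministic for a fixed `cfg$rng_seed`; the reference is
#' never modified.
#'
#' @param query A [count_matrix()].
#' @param ref Reference model from [build_reference()].
#' @param cfg An [embryomap_config()]; defaults to the reference's snapshot.
#' @param aggregate `"auto"` (aggregate when the median expressed-gene count
#'   is below `cfg$sparse_gene_floor`), `"never"`, or `"always"`.
#' @return An object of class `embryo_projection`: `raw_coords`,
#'   `corrected_coords`, `embed2_coords`, `latent_coords`, `pair_set`
#'   (filtered), `pair_set_raw`, `nonrelated_mask`, `corr_stats`, `nhoods`
#'   (NULL unless aggregated), `cells` (original query cells), `coverage`.
#' @export
project_query <- function(query, ref, cfg = ref$config,
                          aggregate = c("auto", "never", "always")) {
  aggregate <- match.arg(aggregate)
  median_ngene <- median(Matrix::colSums(query$counts > 0))
  do_agg <- switch(aggregate,
                   always = TRUE, never = FALSE,
                   auto = median_ngene < cfg$sparse_gene_floor)
  nhoods <- NULL
  working <- query
  if (do_agg) {
    working <- with_stage("make_neighborhoods", {
      sf <- Matrix::colSums(query$counts)
      lg <- log2(1 + as.matrix(query$counts) %*% diag(mean(sf) / sf))
      rownames(lg) <- rownames(query$counts)
      colnames(lg) <- colnames(query$counts)
      u <- cosine_normalize(lg, intersect(ref$gene_selection,
                                          genes(query)))
      nhoods <- make_neighborhoods(query, coords = t(u),
                                    prop = cfg$nhood_prop,
                                    k = cfg$nhood_k, seed = cfg$rng_seed)
      nhoods$aggregated
    })
  }
  emb <- with_stage("embed_query", embed_query(working, ref))
  pairs_raw <- with_stage("subsampled_mnn_pairs",
    subsampled_mnn_pairs(emb$raw_coords, ref, cfg, emb$units))
  pairs <- with_stage("filter_mnn_pairs",
    filter_mnn_pairs(pairs_raw, ref, cfg))
  corrected <- with_stage("correct_query",
    correct_query(emb$raw_coords, pairs, ref, cfg))
  embed2 <- with_stage("umap_transform",
    transform_embedding(ref$embed2, corrected, cfg))
  latent <- with_stage("umap_transform",
    transform_embedding(ref$embed_latent, corrected, cfg))
  fl <- with_stage("flag_nonrelated", flag_nonrelated(emb$units, ref, cfg))
  structure(list(raw_coords = emb$raw_coords,
                 corrected_coords = corrected,
                 embed2_coords = embed2,
                 latent_coords = latent,
                 pair_set = pairs,
                 pair_set_raw = pairs_raw,
                 nonrelated_mask = fl$mask,
                 corr_stats = fl$corr_stats,
                 nhoods = nhoods,
                 cells = cells(query),
                 coverage = emb$coverage,
                 aggregated = do_agg),
            class = "embryo_projection")
}

#' @export
print.embryo_projection <- function(x, ...) {
  cat(sprintf(
    "embryo_projection: %d unit(s) (%saggregated), %d filtered MNN pairs, %d nonrelated\n",
    nrow(x$raw_coords), if (x$aggregated) "" else "not ",
    nrow(x$pair_set), sum(x$nonrelated_mask)))
  invisible(x)
}
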