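#' Quality-control filtering
#'
#' Keeps cells whose expressed-gene count lies in `[min_genes, max_genes]`
#' and whose mitochondrial count fraction is strictly below `max_mito_frac`;
#' then removes mitochondrial genes; then keeps genes expressed in at least
#' `min_cells_per_gene` of the remaining cells. Gene and cell order is
#' preserved.
#'
#' @param m A [count_matrix()].
#' @param t A [qc_thresholds()].
#' @param mito_genes Either a regular expression matched against gene names
#'   (default `"^MT-"`) or a character vector of mitochondrial gene names.
#' @return A filtered [count_matrix()].
#' @export
qc_filter <- function(m, t = qc_thresholds(), mito_genes = "^MT-") {
  stopifnot(inherits(m, "count_matrix"), inherits(t, "qc_thresholds"))
  cm <- m$counts
  mito <- if (length(mito_genes) == 1L && !mito_genes[1] %in% rownames(cm)) {
    grepl(mito_genes, rownames(cm))
  } else {
    rownames(cm) %in% mito_genes
  }
  n_expr <- Matrix::colSums(cm > 0)
  totals <- Matrix::colSums(cm)
  mito_frac <- if (any(mito)) {
    Matrix::colSums(cm[mito, , drop = FALSE]) / pmax(totals, 1)
  } else rep(0, ncol(cm))
  keep_cells <- n_expr >= t$min_genes & n_expr <= t$max_genes &
    mito_frac < t$max_mito_frac
  if (!any(keep_cells))
    stop("QC removed every cell (min_genes=", t$min_genes,
         ", max_mito_frac=", t$max_mito_frac, ")")
  cm <- cm[!mito, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(cm > 0) >= t$min_cells_per_gene
  cm <- cm[keep_genes, , drop = FALSE]
  subset_counts(m, genes = rownames(cm), cells = colnames(cm))
}

#' Per-cell size factors
#'
#' `method = "library"` scales by total counts, normalized to mean one.
#' `method = "pooling"` uses the pool-and-deconvolve strategy (summing cells
#' in overlapping pools of sizes 21, 41, 61, 81, 101 against an average
#' pseudo-cell and solving the linear system by least squares), as
#' implemented in scran's `calculateSumFactors`; factors are rescaled to
#' mean one and guaranteed positive.
#'
#' @param m A [count_matrix()].
#' @param method `"library"` or `"pooling"`.
#' @return Named numeric vector of positive per-cell factors with attribute
#'   `method`.
#' @export
compute_size_factors <- function(m, method = c("pooling", "library")) {
  stopifnot(inherits(m, "count_matrix"))
  method <- match.arg(method)
  totals <- Matrix::colSums(m$counts)
  zero <- totals == 0
  if (any(zero))
    stop("cells with zero total counts: ",
         paste(head(colnames(m$counts)[zero], 5), collapse = ", "))
  if (method == "library") {
    sf <- totals / mean(totals)
  } else {
    sizes <- pmin(c(21L, 41L, 61L, 81L, 101L), ncol(m$counts))
    sizes <- unique(sizes[sizes >= 1L])
    sf <- scran::calculateSumFactors(as.matrix(m$counts), sizes = sizes,
                                     clusters = NULL, positive = TRUE,
                                     min.mean = 0.1)
    sf <- sf / mean(sf)
  }
  names(sf) <- colnames(m$counts)
  attr(sf, "method") <- method
  sf
}

#' Cross-batch rescaling to the lowest-coverage batch
#'
#' Scales every batch's size factors by a batch-level factor `s_b` so that
#' the expected normalized coverage of each batch matches the
#' lowest-coverage batch, then returns `log2(1 + count / (factor * s_b))`
#' matrices over the shared gene axis. The record stores `s_b` and the
#' target coverage so that queries are later rescaled to the *reference*
#' target, not their own minimum.
#'
#' @param batches Named list; each element a list with fields `counts`
#'   (a [count_matrix()]) and `size_factors`.
#' @return List with `logmats` (named list of genes x cells dense matrices),
#'   and `record` (list with `shared_genes`, `scale` per batch,
#'   `target_coverage`).
#' @export
multibatch_rescale <- function(batches) {
  stopifnot(length(batches) >= 1)
  gene_sets <- lapply(batches, function(b) genes(b$counts))
  shared <- Reduce(intersect, gene_sets)
  if (!length(shared)) stop("empty gene intersection across batches")
  coverage <- vapply(batches, function(b) {
    sf <- b$size_factors / mean(b$size_factors)
    mean(Matrix::colSums(b$counts$counts[shared, , drop = FALSE]) / sf)
  }, 0)
  target <- min(coverage)
  scale <- coverage / target
  logmats <- mapply(function(b, s_b) {
    sf <- b$size_factors / mean(b$size_factors)
    cm <- b$counts$counts[shared, , drop = FALSE]
    norm <- as.matrix(cm) / rep(sf * s_b, each = length(shared))
    log2(1 + norm)
  }, batches, scale, SIMPLIFY = FALSE)
  list(logmats = logmats,
       record = list(shared_genes = shared,
                     scale = setNames(as.numeric(scale), names(batches)),
                     target_coverage = as.numeric(target)))
}

# Rescale a query to the reference target coverage recorded at build time.
rescale_query <- function(query, record, method = "library") {
  shared <- intersect(genes(query), record$shared_genes)
  sf <- tryCatch(compute_size_factors(query, method),
                 error = function(e) compute_size_factors(query, "library"))
  sf <- sf / mean(sf)
  coverage <- mean(Matrix::colSums(query$counts[shared, , drop = FALSE]) / sf)
  s_q <- coverage / record$target_coverage
  cm <- as.matrix(query$counts)
  log2(1 + cm / rep(sf * s_q, each = nrow(cm)))
}

# Per-batch HVG scores: residual variance of log-expression about a
# loess mean-variance trend (span 0.3). Larger is more variable.
hvg_scores <- function(logmat, span = 0.3) {
  mu <- rowMeans(logmat)
  v <- apply(logmat, 1, var)
  ok <- v > 0
  res <- rep(-Inf, length(v))
  if (sum(ok) > 10) {
    fit <- suppressWarnings(
      loess(v[ok] ~ mu[ok], span = span, degree = 2,
            family = "symmetric"))
    res[ok] <- v[ok] - fitted(fit)
  } else {
    res[ok] <- v[ok]
  }
  names(res) <- rownames(logmat)
  res
}

#' Two-stage integration-feature selection
#'
#' Per batch, genes are ranked by residual variance about a loess
#' mean-variance trend of log expression. Stage 1 selects `n_hvg_stage1`
#' genes by voting over `stage1_group` batches (count of batches ranking a
#' gene in their top `n_hvg_stage1`, ties broken by median rank then name);
#' stage 2 extends the list to `n_hvg_total` by the same vote over all
#' batches, skipping genes already chosen. The two-pass vote exists to stop
#' the numerically dominant early-stage batches from drowning out features
#' specific to later ones.
#'
#' @param logmats Named list of genes x cells log-expression matrices sharing
#'   a gene axis.
#' @param stage1_group Character vector of batch names voted in stage 1
#'   (default: all batches, collapsing to a single-stage vote).
#' @param n_total,n_stage1 Feature counts (defaults from `cfg`).
#' @param cfg An [embryomap_config()].
#' @return Character vector of selected genes with attributes `ranks`
#'   (per-batch rank matrix) and `truncated` (TRUE when fewer shared genes
#'   than `n_total` existed).
#' @export
select_integration_features <- function(logmats, stage1_group = names(logmats),
                                        cfg = embryomap_config(),
                                        n_total = cfg$n_hvg_total,
                                        n_stage1 = cfg$n_hvg_stage1) {
  stopifnot(length(logmats) >= 1, all(stage1_group %in% names(logmats)))
  if (!length(stage1_group)) stop("stage1_group must be non-empty")
  shared <- Reduce(intersect, lapply(logmats, rownames))
  if (length(shared) <= n_total) {
    warning("fewer shared genes (", length(shared),
            ") than requested features (", n_total, "); using all")
    out <- shared
    attr(out, "truncated") <- TRUE
    return(out)
  }
  ranks <- vapply(logmats, function(lm_) {
    sc <- hvg_scores(lm_[shared, , drop = FALSE])
    rank(-sc, ties.method = "first")
  }, numeric(length(shared)))
  rownames(ranks) <- shared

  vote <- function(batch_names, top_n, exclude, n_pick) {
    r <- ranks[, batch_names, drop = FALSE]
    votes <- rowSums(r <= top_n)
    med <- apply(r, 1, median)
    cand <- setdiff(shared, exclude)
    ord <- cand[order(-votes[cand], med[cand], cand)]
    head(ord, n_pick)
  }
  n_stage1 <- min(n_stage1, n_total)
  stage1 <- vote(stage1_group, n_stage1, character(), n_stage1)
  stage2 <- vote(names(logmats), n_total, stage1, n_total - length(stage1))
  out <- c(stage1, stage2)
  attr(out, "ranks") <- ranks
  attr(out, "truncated") <- FALSE
  out
}

#' Cosine normalization over the integration features
#'
#' Restricts a log-expression matrix to the selected genes and scales every
#' cell column to unit Euclidean norm, so that Euclidean distances
#' approximate cosine distances and per-cell scale is removed. All-zero
#' columns are left as zeros and reported in the `zero_cells` attribute.
#'
#' @param m Genes x cells log-expression matrix.
#' @param gene_selection Character vector of genes (subset of rownames;
#'   genes absent from `m` are imputed as zero rows and reported in the
#'   `imputed_genes` attribute).
#' @return Genes x cells unit-column matrix over `gene_selection`.
#' @export
cosine_normalize <- function(m, gene_selection) {
  present <- intersect(gene_selection, rownames(m))
  out <- matrix(0, length(gene_selection), ncol(m),
                dimnames = list(gene_selection, colnames(m)))
  out[present, ] <- as.matrix(m[present, , drop = FALSE])
  nrm <- sqrt(colSums(out^2))
  nz <- nrm > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, nrm[nz], "/")
  attr(out, "zero_cells") <- colnames(m)[!nz]
  attr(out, "imputed_genes") <- setdiff(gene_selection, present)
  out
}
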