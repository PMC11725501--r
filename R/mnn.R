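# Squared Euclidean cross-distances between row sets (n x d, m x d).
cross_dist2 <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

# For each row of X, indices of its k nearest rows of Y (ties broken by
# distance then index; exact, dense). Returns n x k integer matrix.
knn_index <- function(X, Y, k, exclude_self = FALSE) {
  d2 <- cross_dist2(X, Y)
  k <- min(k, ncol(d2) - if (exclude_self) 1L else 0L)
  res <- vapply(seq_len(nrow(d2)), function(i) {
    o <- order(d2[i, ])           # stable: ties fall back to index order
    if (exclude_self) o <- o[o != i]
    o[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

# k-th nearest-neighbour distance within one point set, per queried row.
kth_neighbor_dist <- function(X, rows, k) {
  d2 <- cross_dist2(X[rows, , drop = FALSE], X)
  k <- min(k + 1L, ncol(d2))     # +1: self is among the neighbours
  vapply(seq_len(nrow(d2)), function(i) sqrt(sort(d2[i, ])[k]), 0)
}

#' Mutual nearest-neighbour pairs between two coordinate sets
#'
#' A pair `(a, b)` is reported iff `b` is among the `k_b` nearest neighbours
#' of `a` within `B` *and* `a` is among the `k_a` nearest neighbours of `b`
#' within `A` (Euclidean metric, exact search, ties broken by distance then
#' index). Such reciprocal pairs are taken to link the same cell type across
#' batches. `k`s larger than the opposing set are capped.
#'
#' @param A,B Numeric matrices (cells x dims) with rownames.
#' @param k_a Neighbours checked within `A`; `k_b` within `B`.
#' @param k_b See `k_a`.
#' @return data.frame with integer columns `a`, `b` (row indices into `A`,
#'   `B`) and character columns `a_cell`, `b_cell`; zero rows when either
#'   set is empty.
#' @export
find_mnn_pairs <- function(A, B, k_a = 20L, k_b = k_a) {
  empty <- data.frame(a = integer(), b = integer(),
                      a_cell = character(), b_cell = character())
  if (!nrow(A) || !nrow(B)) return(empty)
  nb_of_a <- knn_index(A, B, min(k_b, nrow(B)))   # a's neighbours in B
  na_of_b <- knn_index(B, A, min(k_a, nrow(A)))   # b's neighbours in A
  # membership lookup: is a among b's neighbours?
  in_a <- matrix(FALSE, nrow(B), nrow(A))
  for (j in seq_len(ncol(na_of_b))) {
    in_a[cbind(seq_len(nrow(B)), na_of_b[, j])] <- TRUE
  }
  aa <- rep(seq_len(nrow(A)), each = ncol(nb_of_a))
  bb <- as.vector(t(nb_of_a))
  keep <- in_a[cbind(bb, aa)]
  out <- data.frame(a = aa[keep], b = bb[keep])
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out$a_cell <- rownames(A)[out$a]
  out$b_cell <- rownames(B)[out$b]
  out
}

#' Kernel-smoothed, variance-adjusted batch-correction field
#'
#' Raw pair vectors are `A[a_p, ] - B[b_p, ]` for each MNN pair `p`. Every
#' `B` cell receives the Gaussian-kernel weighted average of the pair
#' vectors, with weights `exp(-||x_b - x_{b_p}||^2 / sigma^2)` and bandwidth
#' `sigma = ndist * median` distance of paired `B` cells to their `k`-th
#' nearest `B` neighbour. With `adjust_variance`, each cell's correction is
#' additionally scaled (factor >= 1) along the overall batch-vector
#' direction so that the cell's projected quantile within `B` matches the
#' corresponding quantile of `A`, preventing under-correction of batch
#' spread; components orthogonal to the batch vector are untouched.
#'
#' @param pairs data.frame from [find_mnn_pairs()] (columns `a`, `b`).
#' @param A_coords,B_coords Coordinate matrices the pair indices refer to.
#' @param ndist Bandwidth multiplier.
#' @param k Neighbour index used for the bandwidth rule.
#' @param adjust_variance Apply the quantile-matching scale-up.
#' @return List: `correction` (matrix, one row per `B` cell),
#'   `batch_vector` (unit direction of the mean pair vector), `sigma`,
#'   `scale_factors`.
#' @export
compute_correction_field <- function(pairs, A_coords, B_coords, ndist = 3,
                                     k = 20L, adjust_variance = TRUE) {
  if (!nrow(pairs)) stop("need at least one MNN pair")
  V <- A_coords[pairs$a, , drop = FALSE] - B_coords[pairs$b, , drop = FALSE]
  mean_vec <- unname(colMeans(V))
  nv <- sqrt(sum(mean_vec^2))
  batch_vector <- if (nv > 0) mean_vec / nv else mean_vec

  anchors <- B_coords[pairs$b, , drop = FALSE]
  kd <- kth_neighbor_dist(B_coords, unique(pairs$b), k)
  sigma <- ndist * median(kd)
  d2 <- cross_dist2(B_coords, anchors)
  if (sigma > 0) {
    W <- exp(-d2 / sigma^2)
  } else {
    warning("degenerate geometry (zero bandwidth); using unweighted mean")
    W <- matrix(1, nrow(d2), ncol(d2))
  }
  wsum <- rowSums(W)
  flat <- wsum < .Machine$double.eps
  if (any(flat)) {                     # cells beyond kernel reach
    W[flat, ] <- 1
    wsum[flat] <- ncol(W)
  }
  correction <- (W %*% V) / wsum

  mean_pair_norm <- mean(sqrt(rowSums(V^2)))
  scale_factors <- rep(1, nrow(B_coords))
  # quantile matching along the batch vector is only meaningful when the
  # mean pair vector is a real direction, not cancellation noise
  if (adjust_variance && nv > 0.05 * mean_pair_norm) {
    proj_A <- drop(A_coords %*% batch_vector)
    proj_B <- drop(B_coords %*% batch_vector)
    c_v <- drop(correction %*% batch_vector)
    q <- (rank(proj_B, ties.method = "average") - 0.5) / length(proj_B)
    target <- quantile(proj_A, q, names = FALSE, type = 7)
    desired <- target - proj_B
    ok <- abs(c_v) > 1e-8 & sign(desired) == sign(c_v)
    f <- rep(1, length(c_v))
    f[ok] <- pmax(1, desired[ok] / c_v[ok])
    correction <- correction + (f - 1) * c_v %o% batch_vector
    scale_factors <- f
  }
  rownames(correction) <- rownames(B_coords)
  list(correction = correction, batch_vector = batch_vector,
       batch_vector_norm = nv, mean_pair_norm = mean_pair_norm,
       sigma = sigma, scale_factors = scale_factors)
}

#' Collapse variation along a direction
#'
#' Replaces each row `x` by `x - (x . v - target_mean) v` for a unit vector
#' `v`, so all projections onto `v` equal `target_mean` and components
#' orthogonal to `v` are unchanged. This is the orthogonalization step that
#' removes residual variation along a recorded batch-correction vector.
#'
#' @param coords Cells x dims matrix.
#' @param v Unit vector of length `ncol(coords)`.
#' @param target_mean Scalar projection every row is moved to.
#' @return Matrix of the same shape.
#' @export
orthogonalize_along_vector <- function(coords, v, target_mean = 0) {
  stopifnot(abs(sqrt(sum(v^2)) - 1) < 1e-6)
  proj <- drop(coords %*% v)
  coords - (proj - target_mean) %o% v
}

#' Sequential MNN merge of batches
#'
#' Merges batches in the given order (developmental time order for an
#' embryo reference): at each step, mutual nearest neighbours are found
#' between the merged set and the incoming batch, a kernel-smoothed and
#' variance-adjusted correction field moves the incoming cells onto the
#' merged set, and both sides are then orthogonalized along the recorded
#' batch vector to the pooled mean projection. Each step's batch vector,
#' target mean and bandwidth are recorded so queries can replay the same
#' transformation later.
#'
#' @param spaces Named list of cells x dims coordinate matrices (one per
#'   batch, same dimension).
#' @param order Character vector: every batch name exactly once.
#' @param cfg An [embryomap_config()] (uses `k_mnn_merge`, `ndist`).
#' @return List with `corrected_coords` (all cells, merge order) and
#'   `merge_records` (one record per merge step: `step`, `batch`,
#'   `batch_vector`, `target_mean`, `sigma`, `n_pairs`, `pairs`).
#' @export
merge_batches <- function(spaces, order = names(spaces),
                          cfg = embryomap_config()) {
  stopifnot(setequal(order, names(spaces)),
            !anyDuplicated(order))
  merged <- spaces[[order[1]]]
  records <- list()
  for (step in seq_along(order)[-1]) {
    incoming <- spaces[[order[step]]]
    k <- cfg$k_mnn_merge
    pairs <- find_mnn_pairs(merged, incoming, k, k)
    if (!nrow(pairs))
      stop("merge step ", step - 1L, " (batch '", order[step],
           "'): zero MNN pairs; batches do not share cell populations")
    fld <- compute_correction_field(pairs, merged, incoming,
                                    ndist = cfg$ndist, k = k,
                                    adjust_variance = TRUE)
    incoming <- incoming + fld$correction
    v <- fld$batch_vector
    # a vanishing mean pair vector (no batch effect) leaves no direction to
    # orthogonalize; record the step but skip the collapse. The magnitude is
    # judged against the typical pair vector, not in absolute units.
    applied <- fld$mean_pair_norm > 0 &&
      fld$batch_vector_norm > 0.05 * fld$mean_pair_norm
    tm <- 0
    if (applied) {
      pooled_proj <- c(drop(merged %*% v), drop(incoming %*% v))
      tm <- mean(pooled_proj)
      merged <- orthogonalize_along_vector(merged, v, tm)
      incoming <- orthogonalize_along_vector(incoming, v, tm)
    }
    records[[step - 1L]] <- list(step = step - 1L, batch = order[step],
                                 batch_vector = v, target_mean = tm,
                                 applied = applied,
                                 sigma = fld$sigma, n_pairs = nrow(pairs),
                                 pairs = pairs[, c("a_cell", "b_cell")])
    merged <- rbind(merged, incoming)
  }
  list(corrected_coords = merged, merge_records = records)
}
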