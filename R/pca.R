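#' Grand-centered multi-batch PCA
#'
#' Concatenates the cosine-normalized batches, subtracts the unweighted
#' per-gene grand mean over all cells ("grand centers"), and takes the top
#' `d` left singular vectors of the centered matrix as the rotation. Signs
#' are fixed so the largest-magnitude loading of each component is positive,
#' making the rotation deterministic across platforms. Scores are
#' `t(X - grand_centers) %*% rotation`.
#'
#' @param units List of genes x cells unit-column matrices sharing a gene
#'   axis, one per batch, or a single such matrix.
#' @param d Subspace dimension (reduced with a warning if above the rank).
#' @return List with `grand_centers` (named numeric), `rotation` (genes x d,
#'   orthonormal columns), `coords` (named list of cells x d scores per
#'   batch), `singular_values`.
#' @export
multibatch_pca <- function(units, d = 50L) {
  if (is.matrix(units)) units <- list(units)
  gene_axis <- rownames(units[[1]])
  for (u in units) stopifnot(identical(rownames(u), gene_axis))
  X <- do.call(cbind, units)
  if (ncol(X) <= 1) stop("need more than one cell")
  grand <- rowMeans(X)
  Xc <- X - grand
  d_req <- as.integer(d)
  sv <- svd(Xc, nu = min(d_req, dim(Xc)), nv = 0)
  pos <- sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank_ <- sum(pos)
  if (d_req > rank_) {
    warning("requested d=", d_req, " exceeds rank ", rank_, "; reducing")
    d_req <- rank_
  }
  rot <- sv$u[, seq_len(d_req), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  rownames(rot) <- gene_axis
  colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  coords <- lapply(units, function(u) crossprod(u - grand, rot))
  names(coords) <- names(units)
  list(grand_centers = setNames(grand, gene_axis), rotation = rot,
       coords = coords, singular_values = sv$d[seq_len(d_req)])
}
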