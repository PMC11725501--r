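#' Milo-style neighbourhood assignment and count aggregation
#'
#' Samples `ceiling(prop * n)` candidate index cells uniformly, refines each
#' candidate to the member of its k-NN set closest to that set's mean
#' position, deduplicates the refined indices, and defines each
#' neighbourhood as the index cell plus its `k` nearest neighbours. Raw
#' counts are summed within each neighbourhood, turning sparse droplet-style
#' cells into deep pseudo-cells; cells belonging to no neighbourhood are
#' reported as unassigned (and are later labelled `nb_failed`).
#'
#' @param m A [count_matrix()] of raw counts.
#' @param coords Cells x dims numeric matrix used for the kNN graph. When
#'   `NULL`, the top principal components (up to 30) of log
#'   library-normalized expression are used, which suppresses the sampling
#'   noise that dominates raw droplet profiles.
#' @param prop Fraction of cells sampled as index candidates.
#' @param k Neighbours per neighbourhood.
#' @param seed RNG seed for the candidate sample.
#' @return An object of class `nhood_assignment`: `index_cells`, `members`
#'   (named list), `aggregated` (a [count_matrix()] of neighbourhoods),
#'   `cell_to_nhoods` (named list), `unassigned` (character).
#' @export
make_neighborhoods <- function(m, coords = NULL, prop = 0.15, k = 10L,
                               seed = 42L) {
  stopifnot(inherits(m, "count_matrix"))
  n <- ncol(m$counts)
  if (n < k + 1L) stop("need at least k+1 = ", k + 1L, " cells, have ", n)
  if (is.null(coords)) {
    sf <- Matrix::colSums(m$counts)
    lg <- log2(1 + as.matrix(m$counts) %*% diag(mean(sf) / sf))
    lg <- lg - rowMeans(lg)
    d <- min(30L, n - 1L, nrow(lg))
    sv <- svd(lg, nu = d, nv = d)
    coords <- sv$v * rep(sv$d[seq_len(d)], each = n)
    rownames(coords) <- colnames(m$counts)
  }
  stopifnot(nrow(coords) == n)
  nn <- knn_index(coords, coords, k + 1L)  # self is column 1 by tie rule
  set.seed(seed)
  cand <- sample(n, ceiling(prop * n))
  refined <- vapply(cand, function(s) {
    S <- nn[s, ]
    ctr <- colMeans(coords[S, , drop = FALSE])
    d2 <- rowSums((coords[S, , drop = FALSE] -
                     rep(ctr, each = length(S)))^2)
    S[which.min(d2)]
  }, integer(1))
  idx <- sort(unique(refined))
  members <- lapply(idx, function(i) rownames(coords)[nn[i, ]])
  ids <- paste0("nh", seq_along(idx))
  names(members) <- ids
  agg <- vapply(members, function(mm)
    Matrix::rowSums(m$counts[, mm, drop = FALSE]),
    numeric(nrow(m$counts)))
  rownames(agg) <- rownames(m$counts)
  index_cells <- rownames(coords)[idx]
  meta <- data.frame(cell_id = ids,
                     batch = m$cell_meta$batch[match(index_cells,
                                                     m$cell_meta$cell_id)],
                     time_point = NA_real_, label = NA_character_)
  assigned <- unique(unlist(members))
  cell_to_nhoods <- lapply(setNames(assigned, assigned), function(cc)
    ids[vapply(members, function(mm) cc %in% mm, TRUE)])
  structure(list(index_cells = setNames(index_cells, ids),
                 members = members,
                 aggregated = count_matrix(agg, meta),
                 cell_to_nhoods = cell_to_nhoods,
                 unassigned = setdiff(rownames(coords), assigned)),
            class = "nhood_assignment")
}

#' @export
print.nhood_assignment <- function(x, ...) {
  cat(sprintf("nhood_assignment: %d neighbourhoods, %d unassigned cells\n",
              length(x$members), length(x$unassigned)))
  invisible(x)
}
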