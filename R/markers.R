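#' Wilcoxon rank-sum marker detection
#'
#' Two-sided Wilcoxon rank-sum test per gene on log expression, either each
#' group against all others (`one_vs_rest`) or one pair of groups
#' (`pairwise`). Fold changes are computed on de-logged means with a
#' pseudocount of one: `log2((mean(2^x - 1) + 1) / (mean(2^x - 1) + 1))`;
#' expressing fractions are reported per side, and p-values are
#' Bonferroni-adjusted over the tested genes within each group.
#'
#' @param expr Genes x cells log2 expression matrix.
#' @param groups Character/factor vector of group labels, aligned with the
#'   columns of `expr` (or named by cell).
#' @param mode `"one_vs_rest"` or `"pairwise"`.
#' @param group_a,group_b The two groups compared when `mode = "pairwise"`
#'   (`group_a` is the "in"/upregulated side).
#' @param min_cells Groups below this size are skipped with a warning.
#' @return data.frame of class `marker_table` with columns `gene`, `group`,
#'   `log2_fold_change`, `pct_in`, `pct_out`, `mean_expr_in`, `p_value`,
#'   `p_adjusted`, sorted by group then adjusted p.
#' @export
wilcoxon_markers <- function(expr, groups, mode = c("one_vs_rest", "pairwise"),
                             group_a = NULL, group_b = NULL,
                             min_cells = 3L) {
  mode <- match.arg(mode)
  if (!is.null(names(groups))) groups <- groups[colnames(expr)]
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(expr))
  tasks <- if (mode == "one_vs_rest") {
    lapply(sort(unique(groups)), function(g)
      list(group = g, inside = groups == g, outside = groups != g))
  } else {
    stopifnot(!is.null(group_a), !is.null(group_b))
    list(list(group = group_a, inside = groups == group_a,
              outside = groups == group_b))
  }
  res <- lapply(tasks, function(tk) {
    n_in <- sum(tk$inside); n_out <- sum(tk$outside)
    if (n_in < min_cells || n_out < min_cells) {
      warning("group '", tk$group, "' skipped: ", n_in, " vs ", n_out,
              " cells (floor ", min_cells, ")")
      return(NULL)
    }
    Xi <- expr[, tk$inside, drop = FALSE]
    Xo <- expr[, tk$outside, drop = FALSE]
    p <- vapply(seq_len(nrow(expr)), function(i)
      suppressWarnings(wilcox.test(Xi[i, ], Xo[i, ])$p.value),
      0)
    mean_in <- rowMeans(2^Xi - 1)
    mean_out <- rowMeans(2^Xo - 1)
    data.frame(gene = rownames(expr), group = tk$group,
               log2_fold_change = log2((mean_in + 1) / (mean_out + 1)),
               pct_in = rowMeans(Xi > 0), pct_out = rowMeans(Xo > 0),
               mean_expr_in = mean_in,
               p_value = p,
               p_adjusted = pmin(1, p * nrow(expr)),  # Bonferroni
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) stop("no group large enough to test")
  out <- out[order(out$group, out$p_adjusted, out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Expression-program module score
#'
#' For each program gene, `n_ctrl` control genes are drawn (seeded) from
#' the same average-expression bin, and the score of a cell is the mean
#' expression of the program genes minus the mean expression of the pooled
#' control genes — so scores are centred near zero for random programs
#' regardless of expression level.
#'
#' @param expr Genes x cells log expression matrix.
#' @param gene_set Character vector of program genes.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes drawn per program gene.
#' @param seed RNG seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 42L) {
  prog <- intersect(gene_set, rownames(expr))
  if (!length(prog)) stop("gene_set has no genes in the expression matrix")
  avg <- rowMeans(expr)
  bin <- ceiling(rank(avg, ties.method = "first") / length(avg) * n_bins)
  names(bin) <- rownames(expr)
  set.seed(seed)
  ctrl <- unlist(lapply(prog, function(g) {
    pool <- names(bin)[bin == bin[g]]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  prog_score <- colMeans(expr[prog, , drop = FALSE])
  ctrl_score <- colMeans(expr[ctrl, , drop = FALSE])
  prog_score - ctrl_score
}

#' Stouffer combination of p-values
#'
#' One-sided convention: each p-value is mapped to a normal quantile
#' `z_i = qnorm(1 - p_i)`, the quantiles are combined as
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))`, and the combined p-value is
#' `1 - pnorm(Z)`. Zero p-values are clamped to the smallest positive
#' double with a warning.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param weights Optional positive weights (default equal).
#' @return Combined p-value.
#' @export
stouffer_combine <- function(p, weights = NULL) {
  stopifnot(length(p) >= 1, all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warning("zero p-values clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  w <- weights %||% rep(1, length(p))
  stopifnot(length(w) == length(p), all(w > 0))
  z <- qnorm(p, lower.tail = FALSE)     # = qnorm(1 - p), stable for tiny p
  Z <- sum(w * z) / sqrt(sum(w^2))
  pnorm(Z, lower.tail = FALSE)
}

# Directional Stouffer for two-sided inputs: halve, sign by the effect
# direction, combine, re-two-side.
stouffer_two_sided <- function(p, direction, weights = NULL) {
  p <- pmin(pmax(p, .Machine$double.xmin), 1 - 1e-16)
  w <- weights %||% rep(1, length(p))
  z <- sign(direction) * qnorm(p / 2, lower.tail = FALSE)
  Z <- sum(w * z) / sqrt(sum(w^2))
  2 * pnorm(abs(Z), lower.tail = FALSE)
}

#' Consensus differential expression across comparisons
#'
#' When the two sides of a contrast come from different datasets, a gene is
#' only called differentially expressed if it passes every enabled
#' criterion of [deg_criteria()] across the per-comparison results: a floor
#' on mean expression in the upregulated group, a log2 fold-change floor in
#' at least `min_comparisons_fc` comparisons, an adjusted-p cutoff in at
#' least `min_comparisons_p` comparisons, expressing-fraction rules, and
#' optionally a Bonferroni-adjusted directional Stouffer-combined p-value.
#' The boolean pass matrix is returned for audit.
#'
#' @param results Named list of per-comparison data.frames with columns
#'   `gene`, `log2fc`, `p`, `p_adj`, `pct_high`, `pct_low`, `mean_expr_up`
#'   (a `marker_table` from [wilcoxon_markers()] in pairwise mode is
#'   converted automatically).
#' @param criteria A [deg_criteria()].
#' @return List with `genes` (the surviving genes) and `pass_table`
#'   (data.frame of per-criterion logicals per gene).
#' @export
consensus_deg <- function(results, criteria = deg_criteria()) {
  stopifnot(length(results) >= 1)
  results <- lapply(results, function(r) {
    if (inherits(r, "marker_table")) {
      data.frame(gene = r$gene, log2fc = r$log2_fold_change,
                 p = r$p_value, p_adj = r$p_adjusted,
                 pct_high = r$pct_in, pct_low = r$pct_out,
                 mean_expr_up = r$mean_expr_in)
    } else r
  })
  ncmp <- length(results)
  need <- function(x) if (is.na(x)) ncmp else as.integer(x)
  m_fc <- need(criteria$min_comparisons_fc)
  m_p <- need(criteria$min_comparisons_p)
  m_pct <- need(criteria$min_comparisons_pct)
  if (any(c(m_fc, m_p, m_pct) > ncmp))
    stop("criteria reference more comparisons (", max(m_fc, m_p, m_pct),
         ") than provided (", ncmp, ")")
  gene_sets <- lapply(results, `[[`, "gene")
  genes <- Reduce(intersect, gene_sets)
  genes <- setdiff(genes, criteria$exclude_genes)
  field <- function(col) vapply(results, function(r)
    r[[col]][match(genes, r$gene)], numeric(length(genes)))
  fc <- field("log2fc"); padj <- field("p_adj"); praw <- field("p")
  pct_hi <- field("pct_high"); pct_lo <- field("pct_low")
  meu <- field("mean_expr_up")
  if (length(genes) == 1L) {     # vapply collapsed to vectors
    fc <- t(fc); padj <- t(padj); praw <- t(praw)
    pct_hi <- t(pct_hi); pct_lo <- t(pct_lo); meu <- t(meu)
  }
  pass <- data.frame(gene = genes)
  pass$fold_change <- rowSums(fc > criteria$min_log2fc) >= m_fc
  pass$adjusted_p <- rowSums(padj < criteria$alpha) >= m_p
  if (!is.na(criteria$min_mean_expr_up))
    pass$mean_expression <- rowMeans(meu) > criteria$min_mean_expr_up
  if (!is.na(criteria$pct_high_floor))
    pass$pct_expressing <- rowSums(pct_hi > criteria$pct_high_floor &
                                     pct_lo < criteria$pct_low_ceiling) >=
      m_pct
  if (criteria$require_stouffer) {
    p_comb <- vapply(seq_along(genes), function(i)
      stouffer_two_sided(praw[i, ], fc[i, ]), 0)
    pass$stouffer <- pmin(1, p_comb * length(genes)) < criteria$alpha
  }
  ok <- Reduce(`&`, pass[-1])
  list(genes = genes[ok], pass_table = pass)
}
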