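test_that("Wilcoxon marker p-values match exact enumeration for tiny groups", {
  set.seed(61)
  for (trial in 1:12) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    x <- round(rnorm(n1, 2, 1), 6); y <- round(rnorm(n2, 3, 1), 6)
    expr <- matrix(c(x, y), 1,
                   dimnames = list("g1", paste0("c", seq_len(n1 + n2))))
    groups <- rep(c("in", "out"), c(n1, n2))
    tab <- wilcoxon_markers(expr, groups, mode = "pairwise",
                            group_a = "in", group_b = "out")
    expect_equal(tab$p_value, oracle_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("marker detection finds planted shifts and reports honest fold changes", {
  set.seed(62)
  n_genes <- 120; n <- 50
  expr <- matrix(abs(rnorm(n_genes * 2 * n, 2, 0.5)), n_genes, 2 * n,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 sprintf("c%03d", 1:(2 * n))))
  groups <- rep(c("A", "B"), each = n)
  planted <- sprintf("g%03d", 1:10)
  expr[planted, groups == "A"] <- expr[planted, groups == "A"] + 2
  tab <- wilcoxon_markers(expr, groups)
  a <- tab[tab$group == "A" & tab$gene %in% planted, ]
  expect_true(all(a$p_adjusted < 0.05))
  expect_true(all(a$log2_fold_change > 1))
  # a gene identical across groups is near-null
  null_rows <- tab[tab$gene == "g050", ]
  expect_true(all(abs(null_rows$log2_fold_change) < 0.3))
  expect_true(all(null_rows$p_adjusted > 0.5))
  # Bonferroni never shrinks a p-value; table sorted within groups
  expect_true(all(tab$p_adjusted >= tab$p_value))
  expect_true(all(tab$pct_in >= 0 & tab$pct_in <= 1))
  expect_false(is.unsorted(tab$p_adjusted[tab$group == "A"]))
  # groups below the floor are skipped with a warning, others still tested
  expect_warning(
    small <- wilcoxon_markers(expr[, c(1:100, 1:2)],
                              c(groups, "C", "C")), "skipped")
  expect_setequal(unique(small$group), c("A", "B"))
})

test_that("module scores are centred for random programs and high for planted ones", {
  sim <- fixture_sim()$sim
  cm <- sim$batches[[1]]
  sf <- compute_size_factors(cm, "library")
  expr <- log2(1 + sweep(as.matrix(cm$counts), 2, sf, "/"))
  labels <- setNames(cm$cell_meta$label, cm$cell_meta$cell_id)
  # null: random gene set scores centre near zero
  set.seed(63)
  rnd <- sample(rownames(expr), 15)
  s0 <- module_score(expr, rnd, seed = 63)
  expect_lt(abs(mean(s0)), 0.05)
  # planted: TE markers score highest in TE cells
  te_markers <- sim$truth$markers$TE[1:15]
  s1 <- module_score(expr, te_markers, seed = 63)
  in_te <- mean(s1[labels[names(s1)] == "TE"])
  out_te <- mean(s1[labels[names(s1)] != "TE"])
  expect_gt(in_te, out_te + 0.5)
  # constant matrix scores exactly zero
  const <- matrix(1, 40, 30, dimnames = list(sprintf("g%02d", 1:40),
                                             sprintf("c%02d", 1:30)))
  expect_true(all(module_score(const, rownames(const)[1:5]) == 0))
  expect_error(module_score(expr, c("nope1", "nope2")), "no genes")
})

test_that("Stouffer combination matches closed forms and an integration oracle", {
  expect_equal(stouffer_combine(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(stouffer_combine(0.123), 0.123, tolerance = 1e-12)
  # (0.05, 0.05): Z = 2 qnorm(0.95) / sqrt(2) -> 0.0100 at printed precision
  expect_equal(stouffer_combine(c(0.05, 0.05)), 0.0100, tolerance = 1e-3)
  expect_warning(p0 <- stouffer_combine(c(0, 0.5)), "clamped")
  expect_lt(p0, 1e-100)
  # independent oracle: quantiles and tail probabilities via numerical
  # integration of the normal density (no qnorm/pnorm on the oracle path)
  int_tail <- function(z) {
    if (z >= 0) 0.5 - stats::integrate(stats::dnorm, 0, z,
                                       rel.tol = 1e-13)$value
    else 0.5 + stats::integrate(stats::dnorm, z, 0, rel.tol = 1e-13)$value
  }
  int_quantile <- function(p) stats::uniroot(function(z) int_tail(z) - p,
                                             c(-10, 10), tol = 1e-12)$root
  oracle_stouffer <- function(p, w = rep(1, length(p))) {
    z <- vapply(p, int_quantile, 0)
    int_tail(sum(w * z) / sqrt(sum(w^2)))
  }
  set.seed(64)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    p <- runif(k, 0.001, 0.999)
    w <- runif(k, 0.5, 2)
    expect_equal(stouffer_combine(p, w), oracle_stouffer(p, w),
                 tolerance = 1e-6)
  }
})

# Construct a toy multi-comparison table around a single gene.
toy_result <- function(log2fc, p_adj, pct_high = 0.8, pct_low = 0.1,
                       mean_expr = 20, p = p_adj / 10) {
  data.frame(gene = "g1", log2fc = log2fc, p = p, p_adj = p_adj,
             pct_high = pct_high, pct_low = pct_low, mean_expr_up = mean_expr)
}

test_that("consensus DEG criteria reproduce the published decision rules", {
  crit <- deg_criteria()       # strict variant: fc all 5, p in >= 4
  pass5 <- lapply(1:5, function(i) toy_result(0.8, 0.001))
  expect_identical(consensus_deg(pass5, crit)$genes, "g1")
  # log2fc 0.24 in one of five comparisons fails the "all five" rule
  fc_fail <- pass5; fc_fail[[3]]$log2fc <- 0.24
  expect_length(consensus_deg(fc_fail, crit)$genes, 0)
  # pct_high 0.45 under the 50% floor fails
  pct_fail <- lapply(1:5, function(i) toy_result(0.8, 0.001,
                                                 pct_high = 0.45))
  expect_length(consensus_deg(pct_fail, crit)$genes, 0)
  # adjusted p significant in only 3 of 5 fails the >= 4 rule
  p_fail <- pass5
  p_fail[[1]]$p_adj <- 0.9; p_fail[[2]]$p_adj <- 0.9
  expect_length(consensus_deg(p_fail, crit)$genes, 0)
  # mean expression floor
  low_expr <- lapply(1:5, function(i) toy_result(0.8, 0.001, mean_expr = 5))
  expect_length(consensus_deg(low_expr, crit)$genes, 0)
  # sex-chromosome style a-priori exclusion
  crit_x <- deg_criteria(exclude_genes = "g1")
  expect_length(consensus_deg(pass5, crit_x)$genes, 0)
  # criteria referencing more comparisons than provided: error
  expect_error(consensus_deg(pass5[1:3], crit), "more comparisons")
  # relaxed variant: 3-of-n with Stouffer and no pct rule
  crit3 <- deg_criteria(min_mean_expr_up = NA, min_comparisons_fc = 3,
                        min_comparisons_p = 3, pct_high_floor = NA,
                        require_stouffer = TRUE)
  expect_identical(consensus_deg(p_fail, crit3)$genes, "g1")
})

test_that("consensus DEG is monotone under criterion tightening", {
  set.seed(65)
  genes <- sprintf("g%03d", 1:60)
  mk <- function() data.frame(
    gene = genes, log2fc = rnorm(60, 0.3, 0.3),
    p = runif(60, 1e-6, 0.5), p_adj = runif(60, 1e-4, 1),
    pct_high = runif(60), pct_low = runif(60, 0, 0.5),
    mean_expr_up = runif(60, 1, 40))
  results <- lapply(1:5, function(i) mk())
  base_crit <- deg_criteria(min_comparisons_fc = 3, min_comparisons_p = 3)
  base <- consensus_deg(results, base_crit)$genes
  tighter <- list(
    deg_criteria(min_comparisons_fc = 4, min_comparisons_p = 3),
    deg_criteria(min_comparisons_fc = 3, min_comparisons_p = 4),
    deg_criteria(min_comparisons_fc = 3, min_comparisons_p = 3,
                 min_log2fc = 0.5),
    deg_criteria(min_comparisons_fc = 3, min_comparisons_p = 3,
                 alpha = 0.01),
    deg_criteria(min_comparisons_fc = 3, min_comparisons_p = 3,
                 pct_high_floor = 0.7, pct_low_ceiling = 0.1))
  for (ct in tighter)
    expect_true(all(consensus_deg(results, ct)$genes %in% base))
})

test_that("planted DEGs are recovered with high sensitivity and low FDP", {
  set.seed(66)
  n_genes <- 200; n <- 100
  genes <- sprintf("g%03d", 1:n_genes)
  planted <- genes[1:20]
  results <- lapply(1:5, function(cmp) {
    expr <- matrix(abs(rnorm(n_genes * 2 * n, 4, 0.5)), n_genes, 2 * n,
                   dimnames = list(genes, sprintf("c%d_%03d", cmp,
                                                  1:(2 * n))))
    grp <- rep(c("up", "down"), each = n)
    expr[planted, grp == "up"] <- expr[planted, grp == "up"] + 1  # log2fc 1
    wilcoxon_markers(expr, grp, mode = "pairwise",
                     group_a = "up", group_b = "down")
  })
  crit <- deg_criteria(min_mean_expr_up = 10, min_comparisons_fc = 3,
                       min_comparisons_p = 3, pct_high_floor = NA,
                       require_stouffer = TRUE)
  hits <- consensus_deg(results, crit)$genes
  sensitivity <- mean(planted %in% hits)
  fdp <- if (length(hits)) mean(!hits %in% planted) else 0
  expect_gte(sensitivity, 0.9)
  expect_lte(fdp, 0.1)
})
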