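# Shared fixtures: a reduced-scale synthetic atlas and a reference model
# built once per test run (sized so the whole pipeline stays fast on one
# CPU while keeping the lineage/batch structure the method assumes).

test_cfg <- function(...) {
  embryomap_config(
    n_pcs = 20L, latent_dim = 10L,
    n_hvg_total = 300L, n_hvg_stage1 = 150L,
    umap_neighbors = 15L,
    svm_cost_grid = 2^seq(-2, 6, 2), svm_gamma_grid = 2^seq(-6, 0, 2),
    qc = qc_thresholds(min_genes = 200L, min_cells_per_gene = 5L),
    ...)
}

.fixtures <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$scfg <- sim_config()
    .fixtures$sim <- simulate_reference_series(.fixtures$scfg)
  }
  list(scfg = .fixtures$scfg, sim = .fixtures$sim)
}

fixture_labels <- function() {
  sim <- fixture_sim()$sim
  setNames(sim$truth$cells$label, sim$truth$cells$cell_id)
}

# Stratified half-split of every batch: the halves kept build the
# reference, the held-out halves serve as a self-projection query.
fixture_split <- function() {
  if (is.null(.fixtures$split)) {
    sim <- fixture_sim()$sim
    set.seed(20260927)
    train <- list(); test_cells <- character()
    for (b in names(sim$batches)) {
      meta <- sim$batches[[b]]$cell_meta
      tr <- unlist(lapply(split(meta$cell_id, meta$label), function(cc)
        sample(cc, ceiling(length(cc) / 2))))
      train[[b]] <- embryomap:::subset_counts(sim$batches[[b]], cells = tr)
      test_cells <- c(test_cells, setdiff(meta$cell_id, tr))
    }
    counts_all <- do.call(cbind,
                          lapply(sim$batches, function(b) as.matrix(b$counts)))
    meta_all <- do.call(rbind, lapply(sim$batches, function(b) b$cell_meta))
    query <- count_matrix(counts_all[, test_cells],
                          meta_all[match(test_cells, meta_all$cell_id), ])
    .fixtures$split <- list(train = train, query = query)
  }
  .fixtures$split
}

fixture_ref <- function() {
  if (is.null(.fixtures$ref)) {
    sp <- fixture_split()
    .fixtures$ref <- build_reference(sp$train, names(sp$train),
                                     fixture_labels(), test_cfg())
  }
  .fixtures$ref
}

fixture_self_projection <- function() {
  if (is.null(.fixtures$selfproj)) {
    .fixtures$selfproj <- project_query(fixture_split()$query, fixture_ref(),
                                        aggregate = "never")
  }
  .fixtures$selfproj
}

# Brute-force O(n^2) mutual nearest-neighbour oracle (independent of the
# package's search: plain loops over a full distance matrix).
oracle_mnn <- function(A, B, k_a, k_b) {
  d <- as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                           nrow(A) + seq_len(nrow(B)),
                                           drop = FALSE]
  k_a <- min(k_a, nrow(A)); k_b <- min(k_b, nrow(B))
  nb <- lapply(seq_len(nrow(A)), function(i) order(d[i, ])[seq_len(k_b)])
  na <- lapply(seq_len(nrow(B)), function(j) order(d[, j])[seq_len(k_a)])
  out <- list()
  for (i in seq_len(nrow(A)))
    for (j in nb[[i]])
      if (i %in% na[[j]]) out[[length(out) + 1L]] <- c(i, j)
  if (!length(out)) return(data.frame(a = integer(), b = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(a = m[, 1], b = m[, 2])
  df[order(df$a, df$b), ]
}

# Closed-form metrics from a confusion matrix (rows = predicted).
oracle_metrics <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  rowm <- rowSums(tab); colm <- colSums(tab)
  pe <- sum(rowm * colm) / n^2
  list(accuracy = po, kappa = (po - pe) / (1 - pe),
       precision = diag(tab) / rowm, recall = diag(tab) / colm)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
# (valid for tie-free data).
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); nn <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(nn, n1)
  us <- apply(combs, 2, function(id) sum(rank(c(x, y))[id])) -
    n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

run_quiet <- function(expr) suppressWarnings(suppressMessages(expr))
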