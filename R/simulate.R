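#' Simulation configuration
#'
#' Defines the generative model the test fixtures come from: a branching
#' lineage hierarchy (zygote -> ICM/TE -> epiblast/hypoblast by default),
#' per-lineage marker programs, gene-wise multiplicative log-normal batch
#' distortions, log-normal library sizes and negative-binomial counts —
#' the statistical structure a multi-batch embryo atlas presents to the
#' integration method, without any claim to real embryo biology.
#'
#' @param lineage_tree Named character vector mapping each lineage to its
#'   parent (`NA` for the root).
#' @param n_batches Reference batches (datasets).
#' @param n_cells_per_lineage_per_batch Cells per lineage per batch.
#' @param n_genes Genes simulated.
#' @param n_markers_per_lineage Marker genes upregulated per lineage.
#' @param marker_log2fc Log2 shift of marker genes over the parent program.
#' @param batch_effect_sd SD of the gene-wise log-normal batch factors
#'   (0 disables batch effects).
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param nb_dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param sparse_depth_fraction Binomial downsampling fraction for
#'   droplet-style ("sparse") data.
#' @param seed Master seed; lineage programs derive deterministically from
#'   it so reference and query share the same biology.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(lineage_tree = c(Zygote = NA, ICM = "Zygote",
                                        TE = "Zygote", Epiblast = "ICM",
                                        Hypoblast = "ICM"),
                       n_batches = 3L,
                       n_cells_per_lineage_per_batch = 40L,
                       n_genes = 1000L,
                       n_markers_per_lineage = 60L,
                       marker_log2fc = 2,
                       batch_effect_sd = 0.15,
                       libsize_meanlog = log(2e4),
                       libsize_sdlog = 0.3,
                       nb_dispersion = 10,
                       sparse_depth_fraction = 0.05,
                       seed = 1L) {
  lineages <- names(lineage_tree)
  stopifnot(!is.null(lineages), sum(is.na(lineage_tree)) == 1,
            all(stats::na.omit(lineage_tree) %in% lineages),
            n_batches >= 1, n_cells_per_lineage_per_batch >= 1,
            n_genes >= 1, n_markers_per_lineage >= 1,
            sparse_depth_fraction > 0, sparse_depth_fraction <= 1)
  # acyclicity: walking to the root must terminate for every lineage
  for (l in lineages) {
    seen <- character(); cur <- l
    while (!is.na(lineage_tree[cur])) {
      if (cur %in% seen) stop("lineage_tree contains a cycle at ", cur)
      seen <- c(seen, cur); cur <- lineage_tree[[cur]]
    }
  }
  if (n_markers_per_lineage * length(lineages) > n_genes)
    stop("not enough genes for disjoint marker sets")
  structure(as.list(environment())[c(
    "lineage_tree", "n_batches", "n_cells_per_lineage_per_batch",
    "n_genes", "n_markers_per_lineage", "marker_log2fc", "batch_effect_sd",
    "libsize_meanlog", "libsize_sdlog", "nb_dispersion",
    "sparse_depth_fraction", "seed")],
    class = "sim_config")
}

# Deterministic lineage programs shared by reference and query generators:
# baseline relative abundances plus marker multipliers walked down the tree.
sim_programs <- function(cfg) {
  set.seed(cfg$seed)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  base <- setNames(exp(rnorm(cfg$n_genes, 0, 1)), gene_ids)
  lineages <- names(cfg$lineage_tree)
  marker_pool <- sample(gene_ids)
  markers <- split(marker_pool[seq_len(cfg$n_markers_per_lineage *
                                         length(lineages))],
                   rep(lineages, each = cfg$n_markers_per_lineage))
  progs <- list()
  remaining <- lineages
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(l) {
      p <- cfg$lineage_tree[[l]]; is.na(p) || p %in% names(progs)
    }, TRUE)]
    for (l in ready) {
      p <- cfg$lineage_tree[[l]]
      prog <- if (is.na(p)) base else progs[[p]]
      prog[markers[[l]]] <- prog[markers[[l]]] * 2^cfg$marker_log2fc
      progs[[l]] <- prog
    }
    remaining <- setdiff(remaining, ready)
  }
  depth <- vapply(lineages, function(l) {
    d <- 0; cur <- l
    while (!is.na(cfg$lineage_tree[cur])) { d <- d + 1; cur <- cfg$lineage_tree[[cur]] }
    d
  }, 0)
  list(gene_ids = gene_ids, base = base, markers = markers,
       programs = progs, depth = depth)
}

# Draw NB counts for one batch given programs and a gene-wise batch factor.
sim_draw_batch <- function(cfg, pg, batch_name, batch_factor,
                           lineages = names(cfg$lineage_tree),
                           n_per_lineage = cfg$n_cells_per_lineage_per_batch,
                           cell_prefix = batch_name) {
  n_cells <- n_per_lineage * length(lineages)
  counts <- matrix(0L, cfg$n_genes, n_cells,
                   dimnames = list(pg$gene_ids, NULL))
  lab <- character(n_cells); libs <- numeric(n_cells)
  cellnames <- character(n_cells)
  i <- 0L
  for (l in lineages) {
    p <- pg$programs[[l]] * batch_factor
    p <- p / sum(p)
    for (cidx in seq_len(n_per_lineage)) {
      i <- i + 1L
      libs[i] <- rlnorm(1, cfg$libsize_meanlog, cfg$libsize_sdlog)
      counts[, i] <- rnbinom(cfg$n_genes, mu = libs[i] * p,
                             size = cfg$nb_dispersion)
      lab[i] <- l
      cellnames[i] <- sprintf("%s_%s_%03d", cell_prefix, l, cidx)
    }
  }
  colnames(counts) <- cellnames
  meta <- data.frame(cell_id = cellnames, batch = batch_name,
                     time_point = pg$depth[lab], label = lab,
                     stringsAsFactors = FALSE)
  list(cm = count_matrix(counts, meta), libs = setNames(libs, cellnames))
}

#' Simulate a multi-batch reference series
#'
#' Generates `n_batches` count matrices over the same lineage hierarchy,
#' each with its own gene-wise multiplicative log-normal batch distortion,
#' emulating several deep full-length-style embryo datasets. Deterministic
#' for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `batches` (named list of [count_matrix()]), and
#'   `truth` (`cells` data.frame with lineage/batch/library size,
#'   `markers`, `programs`, `batch_factors`).
#' @export
simulate_reference_series <- function(cfg = sim_config()) {
  pg <- sim_programs(cfg)
  set.seed(cfg$seed + 1L)
  batch_names <- paste0("batch", seq_len(cfg$n_batches))
  factors <- lapply(batch_names, function(b)
    exp(rnorm(cfg$n_genes, 0, cfg$batch_effect_sd)))
  names(factors) <- batch_names
  batches <- list(); cells_df <- list()
  for (b in batch_names) {
    drawn <- sim_draw_batch(cfg, pg, b, factors[[b]])
    batches[[b]] <- drawn$cm
    cells_df[[b]] <- cbind(drawn$cm$cell_meta, library_size = drawn$libs)
  }
  list(batches = batches,
       truth = list(cells = do.call(rbind, cells_df),
                    markers = pg$markers, programs = pg$programs,
                    batch_factors = factors))
}

#' Simulate a query dataset from the same biology
#'
#' Draws a query batch from the same deterministic lineage programs as
#' [simulate_reference_series()] under the same config, with a fresh batch
#' distortion (`new_batch_effect`). `mode = "sparse"` binomially
#' downsamples every count to `sparse_depth_fraction` of the deep depth,
#' emulating droplet data that needs neighbourhood aggregation.
#' `extra_lineages` adds novel lineages absent from the reference tree
#' (fresh marker programs) to probe abstention behaviour.
#'
#' @param cfg A [sim_config()].
#' @param mode `"deep"` or `"sparse"`.
#' @param new_batch_effect Draw a fresh gene-wise batch factor.
#' @param n_cells_per_lineage Cells per lineage (default from `cfg`).
#' @param extra_lineages Number of novel lineages to add.
#' @param seed_offset Offset added to `cfg$seed` for the query's own RNG
#'   stream (programs stay shared).
#' @return List with `query` (a [count_matrix()]) and `truth`.
#' @export
simulate_query <- function(cfg = sim_config(), mode = c("deep", "sparse"),
                           new_batch_effect = TRUE,
                           n_cells_per_lineage = cfg$n_cells_per_lineage_per_batch,
                           extra_lineages = 0L, seed_offset = 1000L) {
  mode <- match.arg(mode)
  pg <- sim_programs(cfg)
  set.seed(cfg$seed + seed_offset)
  if (extra_lineages > 0) {
    used <- unlist(pg$markers)
    free <- setdiff(pg$gene_ids, used)
    for (i in seq_len(extra_lineages)) {
      nm <- paste0("Novel", i)
      mk <- sample(free, cfg$n_markers_per_lineage)
      free <- setdiff(free, mk)
      prog <- pg$base
      prog[mk] <- prog[mk] * 2^cfg$marker_log2fc
      pg$programs[[nm]] <- prog
      pg$markers[[nm]] <- mk
      pg$depth[nm] <- 1
    }
  }
  bf <- if (new_batch_effect)
    exp(rnorm(cfg$n_genes, 0, cfg$batch_effect_sd)) else
      rep(1, cfg$n_genes)
  drawn <- sim_draw_batch(cfg, pg, "query", bf,
                          lineages = names(pg$programs),
                          n_per_lineage = n_cells_per_lineage)
  cm <- drawn$cm
  if (mode == "sparse") {
    thinned <- matrix(rbinom(length(cm$counts),
                             size = as.vector(as.matrix(cm$counts)),
                             prob = cfg$sparse_depth_fraction),
                      nrow(cm$counts), ncol(cm$counts),
                      dimnames = dimnames(as.matrix(cm$counts)))
    cm <- count_matrix(thinned, cm$cell_meta)
  }
  list(query = cm,
       truth = list(cells = cbind(cm$cell_meta, library_size = drawn$libs),
                    markers = pg$markers, batch_factor = bf))
}

#' Simulate a biologically unrelated dataset
#'
#' Same depth and noise model, but gene programs drawn independently of the
#' reference tree (fresh baseline abundances over permuted gene
#' identities), so query cells should fall below the nonrelated
#' correlation threshold.
#'
#' @param cfg A [sim_config()].
#' @param n_cells Cells to simulate.
#' @param n_types Unrelated cell types (fresh marker programs each).
#' @return A [count_matrix()].
#' @export
simulate_unrelated <- function(cfg = sim_config(), n_cells = 100L,
                               n_types = 3L) {
  pg <- sim_programs(cfg)                  # only for gene ids / depth model
  set.seed(cfg$seed + 2000L)
  base <- setNames(exp(rnorm(cfg$n_genes, 0, 1))[sample(cfg$n_genes)],
                   pg$gene_ids)
  progs <- lapply(seq_len(n_types), function(i) {
    mk <- sample(pg$gene_ids, cfg$n_markers_per_lineage)
    p <- base; p[mk] <- p[mk] * 2^cfg$marker_log2fc; p
  })
  counts <- matrix(0L, cfg$n_genes, n_cells,
                   dimnames = list(pg$gene_ids,
                                   sprintf("unrel_%03d", seq_len(n_cells))))
  type <- rep_len(seq_len(n_types), n_cells)
  for (i in seq_len(n_cells)) {
    p <- progs[[type[i]]]; p <- p / sum(p)
    lib <- rlnorm(1, cfg$libsize_meanlog, cfg$libsize_sdlog)
    counts[, i] <- rnbinom(cfg$n_genes, mu = lib * p,
                           size = cfg$nb_dispersion)
  }
  meta <- data.frame(cell_id = colnames(counts), batch = "unrelated",
                     time_point = NA_real_,
                     label = paste0("type", type))
  count_matrix(counts, meta)
}
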