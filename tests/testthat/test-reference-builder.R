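test_that("multibatch PCA reconstructs low-rank data and centers scores", {
  set.seed(31)
  # points exactly on a 2-plane in 6-d gene space
  basis <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  scores <- matrix(rnorm(80), 40, 2)
  X <- t(scores %*% t(basis)) + rnorm(6)
  dimnames(X) <- list(paste0("g", 1:6), paste0("c", 1:40))
  p <- multibatch_pca(X, d = 2)
  recon <- p$rotation %*% t(p$coords[[1]]) + p$grand_centers
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_lt(max(abs(colMeans(p$coords[[1]]))), 1e-8)        # centering
  expect_lt(max(abs(crossprod(p$rotation) - diag(2))), 1e-8)
  # duplicating every cell leaves the subspace projector unchanged
  X2 <- cbind(X, X); colnames(X2) <- paste0("c", 1:80)
  p2 <- multibatch_pca(X2, d = 2)
  P1 <- tcrossprod(p$rotation); P2 <- tcrossprod(p2$rotation)
  expect_lt(max(abs(P1 - P2)), 1e-8)
  # d above the rank is reduced with a warning
  expect_warning(p3 <- multibatch_pca(X, d = 5), "rank")
  expect_lte(ncol(p3$rotation), 3)
})

test_that("mutual nearest-neighbour search matches the brute-force oracle", {
  A1 <- matrix(0, 1, 2, dimnames = list("a1", NULL))
  B1 <- matrix(0, 1, 2, dimnames = list("b1", NULL))
  expect_identical(find_mnn_pairs(A1, B1, 1, 1)[, c("a", "b")],
                   data.frame(a = 1L, b = 1L))
  # one-sided k: nearest B point only
  B2 <- matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("b1", "b2"), NULL))
  pr <- find_mnn_pairs(A1, B2, k_a = 1, k_b = 1)
  expect_identical(pr[, c("a", "b")], data.frame(a = 1L, b = 1L))
  # seeded random instance vs exhaustive scan, several k
  set.seed(32)
  A <- matrix(rnorm(100), 50, 2, dimnames = list(paste0("a", 1:50), NULL))
  B <- matrix(rnorm(100), 50, 2, dimnames = list(paste0("b", 1:50), NULL))
  for (k in c(1, 3, 7)) {
    got <- find_mnn_pairs(A, B, k, k)[, c("a", "b")]
    want <- oracle_mnn(A, B, k, k)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
  # asymmetric k and capping beyond the set size
  got <- find_mnn_pairs(A, B, 4, 90)[, c("a", "b")]
  want <- oracle_mnn(A, B, 4, 90); rownames(want) <- NULL
  expect_identical(got, want)
  expect_identical(nrow(find_mnn_pairs(A[0, , drop = FALSE], B, 3, 3)), 0L)
})

test_that("correction field recovers constructed offsets and respects spread", {
  # single pair, single B cell: correction is exactly the pair vector
  A <- matrix(c(3, 4), 1, 2, dimnames = list("a1", NULL))
  B <- matrix(c(1, 1), 1, 2, dimnames = list("b1", NULL))
  expect_warning(
    fld <- compute_correction_field(data.frame(a = 1L, b = 1L), A, B, k = 1,
                                    adjust_variance = FALSE),
    "zero bandwidth")
  expect_equal(unname(fld$correction[1, ]), c(2, 3))
  # A = B + constant offset: every correction equals the offset
  set.seed(33)
  B2 <- matrix(rnorm(200), 100, 2,
               dimnames = list(paste0("b", 1:100), NULL))
  off <- c(5, -2)
  A2 <- sweep(B2, 2, -off)
  rownames(A2) <- paste0("a", 1:100)
  pairs <- find_mnn_pairs(A2, B2, 10, 10)
  fld2 <- compute_correction_field(pairs, A2, B2, k = 10,
                                   adjust_variance = TRUE)
  offnorm <- sqrt(sum(off^2))
  err <- sweep(fld2$correction, 2, off)
  # MNN pairs between offset clouds are edge-biased, so recovery is
  # approximate: small relative to both the cloud scale and the offset
  expect_lt(mean(abs(err)), 0.1)
  expect_lt(max(abs(err)), 0.1 * offnorm)
  expect_gt(sum(fld2$batch_vector * off) / offnorm, 0.995)
  # the quantile adjustment closes the under-correction the raw kernel
  # average leaves behind
  raw <- compute_correction_field(pairs, A2, B2, k = 10,
                                  adjust_variance = FALSE)
  expect_lt(max(abs(err)), max(abs(sweep(raw$correction, 2, off))) / 2)
  expect_true(all(fld2$scale_factors >= 1))
  # fully overlapping equal-spread sets: nothing to adjust, factors all 1
  ident <- find_mnn_pairs(A2, {
    C <- A2; rownames(C) <- paste0("c", seq_len(nrow(C))); C
  }, 10, 10)
  fld3 <- compute_correction_field(ident, A2, A2, k = 10,
                                   adjust_variance = TRUE)
  expect_true(all(fld3$scale_factors == 1))
  expect_lt(max(abs(fld3$correction)), 0.1)
})

test_that("variance adjustment stretches under-dispersed corrections", {
  set.seed(34)
  # B compressed toward its centre relative to A along the offset axis
  A <- cbind(rnorm(300, 10, 4), rnorm(300))
  B <- cbind(rnorm(300, 0, 1), rnorm(300))
  rownames(A) <- paste0("a", 1:300); rownames(B) <- paste0("b", 1:300)
  pairs <- find_mnn_pairs(A, B, 20, 20)
  adj <- compute_correction_field(pairs, A, B, k = 20, adjust_variance = TRUE)
  raw <- compute_correction_field(pairs, A, B, k = 20, adjust_variance = FALSE)
  v <- adj$batch_vector
  spread <- function(coords, corr) sd((coords + corr) %*% v)
  expect_gt(spread(B, adj$correction), spread(B, raw$correction))
  expect_true(all(adj$scale_factors >= 1))
  # corrected projections approximate the reference spread
  expect_gt(spread(B, adj$correction) / sd(A %*% v), 0.7)
})

test_that("orthogonalization collapses exactly the targeted direction", {
  v <- c(1, 0)
  expect_equal(orthogonalize_along_vector(matrix(c(2, 0), 1), v, 0.5),
               matrix(c(0.5, 0), 1))
  # coords already orthogonal to v are unchanged
  M <- cbind(0, rnorm(20))
  expect_equal(orthogonalize_along_vector(M, v, 0), M)
  # defining property: zero variance of projections, orthogonal part intact
  set.seed(35)
  M2 <- matrix(rnorm(60), 20, 3)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  out <- orthogonalize_along_vector(M2, u, 1.25)
  expect_lt(var(drop(out %*% u)), 1e-10)
  expect_equal(mean(out %*% u), 1.25, tolerance = 1e-10)
  orth <- diag(3) - u %o% u
  expect_equal(M2 %*% orth, out %*% orth, tolerance = 1e-10)
})

test_that("merging removes a constant subspace offset between batches", {
  set.seed(36)
  n <- 150
  base <- cbind(rnorm(n), rnorm(n), rnorm(n))
  off <- c(8, -6, 3)
  spaces <- list(b1 = base, b2 = sweep(base, 2, -off))
  rownames(spaces$b1) <- paste0("x", 1:n)
  rownames(spaces$b2) <- paste0("y", 1:n)
  pre_nn <- function(A, B) {
    d <- embryomap:::cross_dist2(A, B)
    mean(sqrt(apply(d, 1, min)))
  }
  d_pre <- pre_nn(spaces$b1, spaces$b2)
  mg <- merge_batches(spaces, c("b1", "b2"), test_cfg())
  c1 <- mg$corrected_coords[paste0("x", 1:n), ]
  c2 <- mg$corrected_coords[paste0("y", 1:n), ]
  d_post <- pre_nn(c1, c2)
  expect_lt(d_post, 0.2 * d_pre)                 # >= 80% reduction
  # the paired twins end up close relative to the original offset
  expect_lt(mean(sqrt(rowSums((c1 - c2)^2))), 0.1 * sqrt(sum(off^2)))
  # orthogonalization invariant on the merged set
  rec <- mg$merge_records[[1]]
  expect_lt(var(drop(mg$corrected_coords %*% rec$batch_vector)), 1e-10)
})

test_that("merging is a no-op without batch structure", {
  set.seed(37)
  base <- matrix(rnorm(300), 100, 3,
                 dimnames = list(paste0("c", 1:100), NULL))
  # single batch: unchanged, no records
  mg1 <- merge_batches(list(b1 = base), "b1", test_cfg())
  expect_identical(mg1$corrected_coords, base)
  expect_length(mg1$merge_records, 0)
  # three identical batches: corrections stay small relative to the spread
  sp <- list(b1 = base, b2 = base, b3 = base)
  rownames(sp$b2) <- paste0("d", 1:100)
  rownames(sp$b3) <- paste0("e", 1:100)
  mg3 <- merge_batches(sp, names(sp), test_cfg())
  shift <- mg3$corrected_coords[paste0("d", 1:100), ] - base
  expect_lt(mean(sqrt(rowSums(shift^2))), 0.05 * sd(base) * sqrt(3))
  # a merge step that finds no pairs (degenerate empty batch) is a hard
  # error naming the step
  degen <- list(b1 = base, b2 = base[0, , drop = FALSE])
  expect_error(merge_batches(degen, names(degen), test_cfg()),
               "zero MNN pairs")
})

test_that("embedding models preserve separation and transform deterministically", {
  set.seed(38)
  blob <- function(center, n = 60) sweep(matrix(rnorm(n * 5, 0, 0.5), n, 5),
                                         2, -center)
  coords <- rbind(blob(rep(0, 5)), blob(rep(10, 5)))
  rownames(coords) <- paste0("c", 1:120)
  cfg <- test_cfg()
  m1 <- fit_embedding_models(coords, dims = 2L, cfg)
  m2 <- fit_embedding_models(coords, dims = 2L, cfg)
  expect_identical(m1$d2$embedding, m2$d2$embedding)       # same seed
  emb <- m1$d2$embedding
  ctr1 <- colMeans(emb[1:60, ]); ctr2 <- colMeans(emb[61:120, ])
  rad <- function(e, ctr) quantile(sqrt(rowSums(sweep(e, 2, ctr)^2)), 0.95)
  gap <- sqrt(sum((ctr1 - ctr2)^2))
  expect_gt(gap, rad(emb[1:60, ], ctr1))
  expect_gt(gap, rad(emb[61:120, ], ctr2))
  # transform maps points next to their source blob, reference untouched
  before <- m1$d2$embedding
  tr <- embryomap:::transform_embedding(m1$d2, coords[1:5, ] + 0.01, cfg)
  expect_identical(m1$d2$embedding, before)
  expect_lt(max(sqrt(rowSums((tr - emb[1:5, ])^2))), gap / 2)
  expect_error(fit_embedding_models(coords, dims = 10L, cfg), "dimension")
})

test_that("Leiden clustering recovers planted blobs and ignores cell order", {
  set.seed(39)
  blob <- function(center, n = 50) sweep(matrix(rnorm(n * 4, 0, 0.4), n, 4),
                                         2, -center)
  coords <- rbind(blob(rep(0, 4)), blob(rep(8, 4)))
  rownames(coords) <- paste0("c", 1:100)
  cfg <- test_cfg()
  cl <- leiden_cluster(coords, cfg)
  expect_identical(length(unique(cl)), 2L)
  expect_true(all(table(cl[1:50]) %in% c(0, 50)))          # blob purity
  # permutation invariance up to label renaming
  perm <- sample(100)
  cl_p <- leiden_cluster(coords[perm, ], cfg)[rownames(coords)]
  expect_identical(length(unique(paste(cl, cl_p))), 2L)
  # a single tight blob at low resolution is one cluster
  one <- blob(rep(0, 4), 80); rownames(one) <- paste0("c", 1:80)
  cfg_lo <- test_cfg(leiden_resolution = 0.1)
  expect_identical(length(unique(leiden_cluster(one, cfg_lo))), 1L)
})

test_that("build_reference assembles a complete, reproducible model", {
  ref <- fixture_ref()
  expect_s3_class(ref, "reference_model")
  expect_length(ref$merge_records, 2)                       # 3 batches
  expect_setequal(names(ref$classifiers),
                  c("Zygote", "ICM", "TE", "Epiblast", "Hypoblast"))
  expect_identical(ncol(ref$rotation), 20L)
  expect_lt(max(abs(crossprod(ref$rotation) - diag(20))), 1e-8)
  expect_identical(rownames(ref$corrected_coords),
                   colnames(ref$ref_unit_matrix))
  # unlabeled cells are a hard error naming them
  sp <- fixture_split()
  lab <- fixture_labels()
  lab2 <- lab[setdiff(names(lab), cells(sp$train[[1]])[1])]
  expect_error(build_reference(sp$train, names(sp$train), lab2, test_cfg()),
               "unlabeled")
})

test_that("rebuilding the reference under the same seed is identical", {
  sp <- fixture_split()
  ref1 <- fixture_ref()
  ref2 <- build_reference(sp$train, names(sp$train), fixture_labels(),
                          test_cfg())
  expect_identical(ref1$corrected_coords, ref2$corrected_coords)
  expect_identical(ref1$embed2$embedding, ref2$embed2$embedding)
  expect_identical(ref1$gene_selection, ref2$gene_selection)
  expect_identical(lapply(ref1$classifiers, `[[`, "best"),
                   lapply(ref2$classifiers, `[[`, "best"))
})
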