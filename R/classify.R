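#' Train one-vs-rest lineage classifiers in the latent space
#'
#' For every reference lineage, fits a binary RBF-kernel SVM (one lineage
#' against the rest) on the latent embedding coordinates, with balanced
#' class weights and Platt-calibrated probability output. Hyperparameters
#' `C` and `gamma` are chosen by stratified five-fold cross-validation over
#' a powers-of-two grid, maximizing the mean held-out Cohen's kappa;
#' everything is seeded so selection is reproducible.
#'
#' @param latent_coords Cells x latent_dim matrix with rownames.
#' @param lineages Named character vector of lineage labels covering the
#'   rows of `latent_coords`.
#' @param cfg An [embryomap_config()] (`svm_cost_grid`, `svm_gamma_grid`,
#'   `rng_seed`).
#' @param n_folds Cross-validation folds.
#' @return An object of class `classifier_set`: per lineage a list with
#'   `model`, `best` (C, gamma, mean kappa) and `cv` (the full grid record).
#' @export
train_lineage_classifiers <- function(latent_coords, lineages,
                                      cfg = embryomap_config(),
                                      n_folds = 5L) {
  lineages <- lineages[rownames(latent_coords)]
  if (anyNA(lineages)) stop("lineage labels must cover all cells")
  lins <- sort(unique(lineages))
  grid <- expand.grid(cost = cfg$svm_cost_grid, gamma = cfg$svm_gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  out <- lapply(lins, function(L) {
    y <- factor(ifelse(lineages == L, "yes", "no"), levels = c("no", "yes"))
    n_pos <- sum(y == "yes")
    if (n_pos < 2) stop("lineage '", L, "' has fewer than 2 cells")
    wts <- length(y) / (2 * table(y))
    cv <- NULL
    if (n_pos < 10) {
      warning("lineage '", L, "' has ", n_pos,
              " cells; skipping CV and training on all data")
      best <- data.frame(cost = 1, gamma = 1 / ncol(latent_coords),
                         kappa = NA_real_)
    } else {
      set.seed(cfg$rng_seed)
      folds <- integer(length(y))
      for (cl in levels(y)) {
        i <- which(y == cl)
        folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
      }
      kap <- vapply(seq_len(nrow(grid)), function(g) {
        ks <- vapply(seq_len(n_folds), function(f) {
          tr <- folds != f
          if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1)
            return(NA_real_)
          fit <- e1071::svm(latent_coords[tr, , drop = FALSE], y[tr],
                            kernel = "radial", cost = grid$cost[g],
                            gamma = grid$gamma[g], class.weights = wts,
                            scale = FALSE)
          pred <- predict(fit, latent_coords[!tr, , drop = FALSE])
          tab <- table(factor(pred, levels(y)), factor(y[!tr], levels(y)))
          kappa_from_table(tab)
        }, 0)
        mean(ks, na.rm = TRUE)
      }, 0)
      cv <- cbind(grid, kappa = kap)
      best <- cv[which.max(kap), ]          # first max: deterministic
    }
    set.seed(cfg$rng_seed)
    model <- e1071::svm(latent_coords, y, kernel = "radial",
                        cost = best$cost, gamma = best$gamma,
                        class.weights = wts, probability = TRUE,
                        scale = FALSE)
    list(model = model, best = best, cv = cv)
  })
  names(out) <- lins
  structure(out, class = "classifier_set")
}

#' @export
print.classifier_set <- function(x, ...) {
  cat("classifier_set over", length(x), "lineages:\n")
  for (L in names(x))
    cat(sprintf("  %s: C=%g gamma=%g (CV kappa %.3f)\n", L,
                x[[L]]$best$cost, x[[L]]$best$gamma, x[[L]]$best$kappa))
  invisible(x)
}

# Units x lineages probability matrix from a classifier_set.
lineage_probabilities <- function(classifiers, coords) {
  probs <- vapply(classifiers, function(cl) {
    pr <- predict(cl$model, coords, probability = TRUE)
    attr(pr, "probabilities")[, "yes"]
  }, numeric(nrow(coords)))
  if (nrow(coords) == 1L) probs <- matrix(probs, 1,
                                          dimnames = list(rownames(coords),
                                                          names(classifiers)))
  rownames(probs) <- rownames(coords)
  probs
}

#' Gate per-unit probabilities into labels with abstention
#'
#' Implements the assignment rule: the candidate lineage is the probability
#' argmax (ties broken by lineage name order and flagged); units whose top
#' probability is below `prob_threshold` become `ambiguous`
#' (flag `below_threshold`); units whose candidate lineage has no support
#' in the filtered MNN pair set become `ambiguous` (flag `no_mnn_support`);
#' units in the nonrelated mask become `nonrelated` (flag `low_correlation`)
#' regardless of probabilities. A top probability exactly at the threshold
#' is assigned ("no less than").
#'
#' @param prob Units x lineages probability matrix.
#' @param supported_lineages Character vector of lineages present in the
#'   filtered MNN pair set (dataset-level support).
#' @param nonrelated_mask Logical vector per unit.
#' @param prob_threshold Assignment threshold.
#' @param support_by_unit Optional named list: per unit, the lineages its
#'   own MNN pairs touch (the stricter per-cell support mode).
#' @return data.frame with `unit`, `label`, `probability`, `flags`.
#' @export
gate_predictions <- function(prob, supported_lineages,
                             nonrelated_mask = rep(FALSE, nrow(prob)),
                             prob_threshold = 0.5,
                             support_by_unit = NULL) {
  prob <- prob[, order(colnames(prob)), drop = FALSE]
  units <- rownames(prob)
  n <- nrow(prob)
  label <- character(n); p_out <- rep(NA_real_, n); flags <- vector("list", n)
  for (i in seq_len(n)) {
    fl <- character()
    top <- max(prob[i, ])
    cand_i <- which(prob[i, ] == top)
    if (length(cand_i) > 1) fl <- c(fl, "tie_broken")
    cand <- colnames(prob)[cand_i[1]]
    supp <- if (!is.null(support_by_unit))
      support_by_unit[[units[i]]] %||% character() else supported_lineages
    if (isTRUE(nonrelated_mask[i])) {
      label[i] <- "nonrelated"; fl <- c(fl, "low_correlation")
    } else if (top < prob_threshold) {
      label[i] <- "ambiguous"; fl <- c(fl, "below_threshold")
    } else if (!cand %in% supp) {
      label[i] <- "ambiguous"; fl <- c(fl, "no_mnn_support")
    } else {
      label[i] <- cand; p_out[i] <- top
    }
    flags[[i]] <- fl
  }
  data.frame(unit = units, label = label, probability = p_out,
             flags = vapply(flags, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Predict query cell identities with abstention
#'
#' Evaluates every lineage classifier on the latent coordinates of the
#' projected query, gates assignments by probability, MNN support and the
#' nonrelated mask (see [gate_predictions()]), and — when the query was
#' aggregated into neighbourhoods — propagates neighbourhood labels back to
#' member cells, resolving conflicts by the highest assigned probability.
#' Cells in no neighbourhood are labelled `nb_failed` (flag
#' `not_in_neighborhood`).
#'
#' @param proj A projection from [project_query()].
#' @param classifiers A `classifier_set` (defaults to the reference's).
#' @param nhoods Optional [make_neighborhoods()] result; defaults to the
#'   one recorded in `proj` when the query was aggregated.
#' @param cfg An [embryomap_config()].
#' @return An object of class `embryo_prediction`: data.frame with
#'   `cell_id`, `label` (a lineage or `ambiguous` / `nonrelated` /
#'   `nb_failed`), `probability` (NA for non-lineage labels), `flags` and
#'   `neighborhood_ids` (semicolon-separated); probability matrix in
#'   attribute `prob_matrix`.
#' @export
predict_identities <- function(proj, classifiers, nhoods = proj$nhoods,
                               cfg = embryomap_config()) {
  prob <- lineage_probabilities(classifiers, proj$latent_coords)
  supported <- unique(proj$pair_set$ref_lineage)
  support_by_unit <- NULL
  if (isTRUE(cfg$per_cell_mnn_support)) {
    support_by_unit <- split(proj$pair_set$ref_lineage,
                             proj$pair_set$query_cell)
    support_by_unit <- lapply(support_by_unit, unique)
  }
  gated <- gate_predictions(prob, supported, proj$nonrelated_mask,
                            cfg$prob_threshold, support_by_unit)
  if (is.null(nhoods)) {
    out <- data.frame(cell_id = gated$unit, label = gated$label,
                      probability = gated$probability, flags = gated$flags,
                      neighborhood_ids = "", stringsAsFactors = FALSE)
  } else {
    by_nh <- gated; rownames(by_nh) <- by_nh$unit
    cells_all <- proj$cells
    rows <- lapply(cells_all, function(cc) {
      nh_ids <- nhoods$cell_to_nhoods[[cc]]
      if (is.null(nh_ids) || !length(nh_ids)) {
        return(data.frame(cell_id = cc, label = "nb_failed",
                          probability = NA_real_,
                          flags = "not_in_neighborhood",
                          neighborhood_ids = "", stringsAsFactors = FALSE))
      }
      sub <- by_nh[nh_ids, , drop = FALSE]
      # conflict resolution: highest assigned probability wins; if no
      # neighbourhood got a lineage, inherit the first one's abstention
      score <- ifelse(is.na(sub$probability), -Inf, sub$probability)
      best <- if (all(!is.finite(score))) 1L else which.max(score)
      data.frame(cell_id = cc, label = sub$label[best],
                 probability = sub$probability[best],
                 flags = sub$flags[best],
                 neighborhood_ids = paste(nh_ids, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "prob_matrix") <- prob
  class(out) <- c("embryo_prediction", "data.frame")
  out
}
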