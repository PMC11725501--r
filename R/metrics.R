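# Cohen's kappa from a square confusion table (rows = predicted,
# columns = truth): (p_o - p_e) / (1 - p_e).
kappa_from_table <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Score predictions against reference annotations
#'
#' Builds the confusion table between predicted and true labels and reports
#' accuracy, Cohen's kappa (chance-corrected agreement) and per-class
#' precision/recall. The abstention labels (`ambiguous`, `nonrelated`,
#' `nb_failed`) are excluded by default (`policy = "exclude"`), matching how
#' annotation-transfer tools are usually scored; `policy = "as_error"`
#' keeps them as (always wrong) predicted classes instead.
#'
#' @param pred An `embryo_prediction` or a named character vector of labels.
#' @param truth Named character vector of reference labels.
#' @param label_map Optional named character vector applied to both sides
#'   before scoring (fine-to-coarse label collapsing).
#' @param policy `"exclude"` or `"as_error"` for abstention labels.
#' @return List with `confusion` (rows = predicted, cols = truth),
#'   `accuracy`, `kappa`, `per_class` (data.frame: class, precision,
#'   recall), `n_scored`, `n_abstained`.
#' @export
evaluate_predictions <- function(pred, truth, label_map = NULL,
                                 policy = c("exclude", "as_error")) {
  policy <- match.arg(policy)
  if (inherits(pred, "data.frame")) {
    pred <- setNames(pred$label, pred$cell_id)
  }
  abstain <- c("ambiguous", "nonrelated", "nb_failed")
  common <- intersect(names(pred), names(truth))
  if (!length(common)) stop("no cells shared between predictions and truth")
  p <- pred[common]; t_ <- truth[common]
  n_abst <- sum(p %in% abstain)
  if (policy == "exclude") {
    keep <- !(p %in% abstain)
    if (!any(keep)) stop("all predictions are abstentions; nothing to score")
    p <- p[keep]; t_ <- t_[keep]
  }
  if (!is.null(label_map)) {
    p <- ifelse(p %in% names(label_map), label_map[p], p)
    t_ <- ifelse(t_ %in% names(label_map), label_map[t_], t_)
  }
  lv <- sort(union(p, t_))
  tab <- table(factor(p, lv), factor(t_, lv))
  per_class <- data.frame(
    class = lv,
    precision = vapply(lv, function(cl) {
      d <- sum(tab[cl, ]); if (d == 0) NA_real_ else tab[cl, cl] / d
    }, 0),
    recall = vapply(lv, function(cl) {
      d <- sum(tab[, cl]); if (d == 0) NA_real_ else tab[cl, cl] / d
    }, 0),
    row.names = NULL)
  list(confusion = tab,
       accuracy = sum(diag(tab)) / sum(tab),
       kappa = kappa_from_table(tab),
       per_class = per_class,
       n_scored = length(p),
       n_abstained = n_abst)
}
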