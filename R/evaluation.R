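#' Image-level score
#'
#' The per-image score is the maximum candidate score; images with no
#' candidates receive `-Inf` so they rank below every scored image.
#'
#' @param scores numeric vector of candidate scores (possibly empty).
#' @return scalar.
#' @export
image_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(-Inf)
  max(scores)
}

eval_report <- function(tp, fp, tn, fn, criterion,
                        roc_points = NULL, auc = NA_real_) {
  sens <- if ((tp + fn) > 0) tp / (tp + fn) else NA_real_
  spec <- if ((tn + fp) > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 roc_points = roc_points, auc = auc,
                 criterion = criterion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report [%s]: TP %s FP %s TN %s FN %s | sens %.4g spec %.4g%s>\n",
    x$criterion, x$tp, x$fp, x$tn, x$fn,
    x$sensitivity, x$specificity,
    if (is.finite(x$auc)) sprintf(" auc %.4g", x$auc) else ""))
  invisible(x)
}

#' Confusion counts and sensitivity/specificity
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`;
#' zero-denominator rates are reported as `NA` (undefined), not 0.
#'
#' @param labels logical ground truth (`TRUE` = positive).
#' @param predictions logical predictions.
#' @param criterion tag stored in the report.
#' @return an `eval_report`.
#' @export
confusion_and_rates <- function(labels, predictions,
                                criterion = "image_based") {
  labels <- as.logical(labels); predictions <- as.logical(predictions)
  stopifnot(length(labels) == length(predictions))
  eval_report(tp = sum(labels & predictions),
              fp = sum(!labels & predictions),
              tn = sum(!labels & !predictions),
              fn = sum(labels & !predictions),
              criterion = criterion)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped into a single
#' step); points are `(1 - specificity, sensitivity)` sorted by x, with the
#' trapezoid-rule area. Equals the normalized Mann-Whitney statistic.
#'
#' @param scores numeric scores, higher = more positive. `-Inf` allowed.
#' @param labels logical ground truth.
#' @return list `roc_points` (matrix with columns `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0)
    stop("roc_auc: need both positive and negative labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))          # tie groups share one threshold
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(diff(c(grp, Inf)) != 0)  # last index of each group
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = cbind(fpr = fpr, tpr = tpr), auc = auc)
}

#' Pixel-based (connected-component) validation
#'
#' Ground-truth lesion components are matched against the predicted mask:
#' a component is a true positive when the prediction covers at least
#' `min_overlap` (default 75%) of its area -- with `strict_upper = TRUE`
#' a fully covered (100%) component is instead counted as a false
#' detection, reproducing the stricter printed reading. Uncovered
#' components are false negatives; predicted components touching no ground
#' truth are false positives. True negatives are ill-defined at component
#' level: supply `n_negatives` (e.g. non-red candidates not touching any
#' ground truth) to obtain a specificity.
#'
#' @param pred_mask logical predicted lesion mask.
#' @param gt_mask logical ground-truth mask (same shape).
#' @param min_overlap fraction in (0, 1]; default 0.75.
#' @param strict_upper reject 100% overlap (default `FALSE`).
#' @param n_negatives optional count of true-negative units.
#' @return an `eval_report` with `criterion = "pixel_based"`; attribute
#'   `per_component` holds each GT component's overlap fraction.
#' @export
pixel_based_validation <- function(pred_mask, gt_mask, min_overlap = 0.75,
                                   strict_upper = FALSE, n_negatives = 0L) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("pixel_based_validation: mask shapes differ")
  gl <- label_components(gt_mask, 8)
  ng <- max(gl)
  overlap <- numeric(ng)
  tp <- 0L; fn <- 0L; fp_full <- 0L
  if (ng > 0) {
    areas <- tabulate(gl[gl > 0], ng)
    hits <- tabulate(gl[gl > 0 & pred_mask], ng)
    overlap <- hits / areas
    ok <- overlap >= min_overlap
    if (strict_upper) {
      full <- overlap >= 1
      fp_full <- sum(ok & full)
      ok <- ok & !full
    }
    tp <- sum(ok)
    fn <- ng - tp - fp_full
  }
  pl <- label_components(pred_mask, 8)
  npred <- max(pl)
  fp <- fp_full
  if (npred > 0) {
    touched <- unique(pl[pl > 0 & gt_mask])
    fp <- fp + (npred - length(touched))
  }
  rep <- eval_report(tp = tp, fp = fp, tn = as.integer(n_negatives), fn = fn,
                     criterion = "pixel_based")
  attr(rep, "per_component") <- overlap
  rep
}
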