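# Pixel-level segmentation metrics. The five scores follow the printed
# formulas verbatim, including the idiosyncratic "specificity" TP/(TP+FP)
# (algebraically the precision); the textbook TN/(TN+FP) form is exposed
# separately so reports can state which was used.

#' Pixel confusion counts
#'
#' Tallies TP/FP/TN/FN between a predicted and a ground-truth binary mask,
#' with foreground (1) as the positive class.
#'
#' @param pred,truth binary matrices/arrays of identical shape with values in
#'   \{0, 1\}.
#' @return object of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  pv <- as.numeric(pred); tv <- as.numeric(truth)
  if (!all(pv %in% c(0, 1)) || !all(tv %in% c(0, 1))) {
    stop("masks must be binary (0/1)")
  }
  structure(list(tp = sum(pv == 1 & tv == 1),
                 fp = sum(pv == 1 & tv == 0),
                 tn = sum(pv == 0 & tv == 0),
                 fn = sum(pv == 0 & tv == 1)),
            class = "confusion_counts")
}

counts_of <- function(tp, fp, tn, fn) {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

# degenerate convention: overlap scores of two empty masks are 1
safe_div <- function(num, den, empty_value = 1) {
  if (den == 0) empty_value else num / den
}

#' Dice score
#'
#' `2 TP / (2 TP + FP + FN)`. When both masks are empty (TP+FP+FN = 0) the
#' score is defined as `empty_value` (default 1: two empty masks agree).
#'
#' @param c a [confusion_counts()].
#' @param empty_value value returned for the all-background degenerate case.
#' @return fraction in `[0,1]`.
#' @export
dice <- function(c, empty_value = 1) {
  safe_div(2 * c$tp, 2 * c$tp + c$fp + c$fn, empty_value)
}

#' Jaccard score
#'
#' `TP / (TP + FP + FN)`; same degenerate convention as [dice()].
#'
#' @inheritParams dice
#' @return fraction in `[0,1]`.
#' @export
jaccard <- function(c, empty_value = 1) {
  safe_div(c$tp, c$tp + c$fp + c$fn, empty_value)
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @inheritParams dice
#' @return fraction in `[0,1]`.
#' @export
accuracy <- function(c) {
  (c$tp + c$tn) / (c$tp + c$tn + c$fp + c$fn)
}

#' Sensitivity (recall)
#'
#' `TP / (TP + FN)`.
#'
#' @inheritParams dice
#' @return fraction in `[0,1]`.
#' @export
sensitivity <- function(c, empty_value = 1) {
  safe_div(c$tp, c$tp + c$fn, empty_value)
}

#' Specificity, as printed in the evaluation protocol
#'
#' Implemented verbatim as `TP / (TP + FP)` — algebraically this is the
#' precision, not the textbook specificity; it is kept for fidelity with the
#' protocol being reproduced. See [corrected_specificity()] for the textbook
#' `TN / (TN + FP)` form. Reports label which form was used.
#'
#' @inheritParams dice
#' @return fraction in `[0,1]`.
#' @export
specificity <- function(c, empty_value = 1) {
  safe_div(c$tp, c$tp + c$fp, empty_value)
}

#' Textbook specificity
#'
#' `TN / (TN + FP)` (true-negative rate), offered alongside the verbatim
#' [specificity()].
#'
#' @inheritParams dice
#' @return fraction in `[0,1]`.
#' @export
corrected_specificity <- function(c, empty_value = 1) {
  safe_div(c$tn, c$tn + c$fp, empty_value)
}

metric_row <- function(c) {
  list(accuracy = accuracy(c), dice = dice(c), specificity = specificity(c),
       sensitivity = sensitivity(c), jaccard = jaccard(c),
       corrected_specificity = corrected_specificity(c))
}

swap_classes <- function(c) counts_of(c$tn, c$fn, c$tp, c$fp)

#' Averaged metric report over a batch of masks
#'
#' Three averaging modes over a list of prediction/truth mask pairs:
#' \describe{
#'   \item{none}{per-image foreground scores, averaged over images (unweighted).}
#'   \item{micro}{confusion counts pooled over all images before scoring.}
#'   \item{macro}{pooled counts scored once with foreground positive and once
#'     with background positive, then averaged.}
#' }
#'
#' @param preds,truths equal-length lists of shape-matched binary masks.
#' @param mode `"none"`, `"micro"` or `"macro"`.
#' @return object of class `metric_report`: the five scores plus
#'   `corrected_specificity` and the `averaging_mode` used.
#' @export
averaged_scores <- function(preds, truths, mode = c("none", "micro", "macro")) {
  mode <- match.arg(mode)
  if (length(preds) == 0L || length(preds) != length(truths)) {
    stop("need equal-length, non-empty mask lists")
  }
  cs <- Map(confusion_counts, preds, truths)
  rep <- switch(mode,
    none = {
      rows <- lapply(cs, metric_row)
      as.list(colMeans(do.call(rbind, lapply(rows, as.data.frame))))
    },
    micro = {
      pooled <- counts_of(sum(vapply(cs, `[[`, 0, "tp")),
                          sum(vapply(cs, `[[`, 0, "fp")),
                          sum(vapply(cs, `[[`, 0, "tn")),
                          sum(vapply(cs, `[[`, 0, "fn")))
      metric_row(pooled)
    },
    macro = {
      pooled <- counts_of(sum(vapply(cs, `[[`, 0, "tp")),
                          sum(vapply(cs, `[[`, 0, "fp")),
                          sum(vapply(cs, `[[`, 0, "tn")),
                          sum(vapply(cs, `[[`, 0, "fn")))
      fg <- metric_row(pooled)
      bg <- metric_row(swap_classes(pooled))
      Map(function(a, b) (a + b) / 2, fg, bg)
    })
  structure(c(rep, list(averaging_mode = mode)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "mode=%s accuracy=%.4f dice=%.4f jaccard=%.4f sensitivity=%.4f specificity=%.4f (printed form; corrected=%.4f)\n",
    x$averaging_mode, x$accuracy, x$dice, x$jaccard, x$sensitivity,
    x$specificity, x$corrected_specificity))
  invisible(x)
}

#' Per-image metric table
#'
#' One row per image with the foreground scores; the per-image analogue
#' behind the `"none"` averaging mode.
#'
#' @inheritParams averaged_scores
#' @return data.frame with one row per pair.
#' @export
per_image_scores <- function(preds, truths) {
  cs <- Map(confusion_counts, preds, truths)
  do.call(rbind, lapply(cs, function(c) as.data.frame(metric_row(c))))
}
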