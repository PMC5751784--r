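# Confusion-matrix metrics and ROC/AUC for benchmarking DEG callers.

#' Direction-aware confusion matrix and derived metrics
#'
#' Compares a set of DEG calls against known truth over a gene universe. A
#' call is a true positive only when the gene is truly differentially
#' expressed *and* the called direction matches; a call in the wrong
#' direction is a false positive (and the gene remains a false negative).
#' Ratios with a zero denominator are reported as `NA` and listed in the
#' `undefined` field rather than being silently imputed.
#'
#' @param calls Data frame with columns `gene_id` and `direction`
#'   (`"up"`/`"down"`), or a character vector of directions named by gene.
#' @param truth Truth in the same format.
#' @param universe Character vector of all gene IDs under evaluation.
#' @return An object of class `"eval_result"`: list with counts `tp`, `fp`,
#'   `fn`, `tn`, metrics `sensitivity`, `ppv`, `fscore`, `fpr`, and
#'   `undefined`, the names of metrics with a 0/0 denominator.
#' @examples
#' truth <- c(g1 = "up", g2 = "down")
#' calls <- c(g1 = "up", g3 = "up")
#' confusion(calls, truth, universe = paste0("g", 1:5))
#' @export
confusion <- function(calls, truth, universe) {
  calls <- as_direction_set(calls, "calls")
  truth <- as_direction_set(truth, "truth")
  if (!is.character(universe) || anyDuplicated(universe))
    stop("'universe' must be a character vector of unique gene IDs")
  bad <- setdiff(names(calls), universe)
  if (length(bad))
    stop(sprintf("called gene(s) not in the universe: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  bad <- setdiff(names(truth), universe)
  if (length(bad))
    stop(sprintf("truth gene(s) not in the universe: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))

  tp <- sum(names(calls) %in% names(truth) &
              calls == truth[names(calls)])
  fp <- length(calls) - tp
  fn <- length(truth) - tp
  tn <- length(universe) - length(union(names(calls), names(truth)))

  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sensitivity <- ratio(tp, tp + fn)
  ppv <- ratio(tp, tp + fp)
  fpr <- ratio(fp, fp + tn)
  fscore <- if (!is.na(sensitivity) && !is.na(ppv) && sensitivity + ppv > 0)
    2 * sensitivity * ppv / (sensitivity + ppv) else NA_real_

  metrics <- c(sensitivity = sensitivity, ppv = ppv, fscore = fscore,
               fpr = fpr)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = sensitivity, ppv = ppv, fscore = fscore, fpr = fpr,
         undefined = names(metrics)[is.na(metrics)]),
    class = "eval_result")
}

as_direction_set <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "direction") %in% names(x)))
      stop(sprintf("'%s' must have columns 'gene_id' and 'direction'", what))
    x <- x[x$direction != "none", , drop = FALSE]
    out <- x$direction
    names(out) <- x$gene_id
  } else if (is.character(x)) {
    if (length(x) && is.null(names(x)))
      stop(sprintf("'%s' given as a vector must be named by gene ID", what))
    out <- x[x != "none"]
  } else stop(sprintf("'%s' must be a data frame or named character vector", what))
  if (anyDuplicated(names(out)))
    stop(sprintf("duplicated gene IDs in '%s'", what))
  if (length(out) && !all(out %in% c("up", "down")))
    stop(sprintf("'%s' directions must be 'up' or 'down'", what))
  out
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Confusion: TP = %d, FP = %d, FN = %d, TN = %d\n",
              x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("  sensitivity = %s, PPV = %s, F-score = %s, FPR = %s\n",
              fmt(x$sensitivity), fmt(x$ppv), fmt(x$fscore), fmt(x$fpr)))
  invisible(x)
}

#' Trapezoid area under an ROC curve
#'
#' Computes the raw trapezoid AUC of a set of (FPR, TPR) points after
#' augmenting them with the trivial endpoints (0, 0) and (1, 1) and sorting
#' by FPR. No convex-hull smoothing is applied.
#'
#' @param points Data frame (or matrix) with columns `fpr` and `tpr`, all
#'   values in `[0, 1]`.
#' @return The AUC, a number in `[0, 1]`.
#' @examples
#' roc_auc(data.frame(fpr = c(0.1, 0.3), tpr = c(0.6, 0.9))) # 0.845
#' @export
roc_auc <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("fpr", "tpr") %in% names(points)))
    stop("'points' must have columns 'fpr' and 'tpr'")
  fpr <- as.numeric(points$fpr)
  tpr <- as.numeric(points$tpr)
  if (any(!is.finite(fpr)) || any(!is.finite(tpr)) ||
      any(fpr < 0) || any(fpr > 1) || any(tpr < 0) || any(tpr > 1))
    stop("'fpr' and 'tpr' must lie in [0, 1]")
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]
  tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
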