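# The coverage-aware DEG decision rule.
#
# For each gene the true-count posteriors of the two samples are compared:
# take the sample with the larger posterior mean, compute its lower
# (1-alpha)/2 percentile, and divide by the upper (1+alpha)/2 percentile of
# the other sample. The gene is called differentially expressed when that
# ratio reaches the fold threshold phi. With the defaults alpha = 0.99 and
# phi = 1.5 a call states, with joint credibility 0.995^2 ~ 0.99, that the
# true counts differ by at least 1.5 fold.

# Vectorized core of the decision rule. x0/x1 observed counts, b0/b1 their
# coverages (scalars or vectors). Returns a data.frame, one row per gene.
deg_decide <- function(x0, b0, x1, b1, alpha, phi) {
  g0 <- posterior_gamma(x0, b0)
  g1 <- posterior_gamma(x1, b1)
  q_lo <- (1 - alpha) / 2
  q_hi <- (1 + alpha) / 2

  treat_higher <- g1$mu > g0$mu
  tie <- g1$mu == g0$mu

  hi_shape <- ifelse(treat_higher, g1$shape, g0$shape)
  hi_scale <- ifelse(treat_higher, g1$scale, g0$scale)
  lo_shape <- ifelse(treat_higher, g0$shape, g1$shape)
  lo_scale <- ifelse(treat_higher, g0$scale, g1$scale)

  lower_high <- stats::qgamma(q_lo, shape = hi_shape, scale = hi_scale)
  upper_low <- stats::qgamma(q_hi, shape = lo_shape, scale = lo_scale)
  fold_bound <- lower_high / upper_low

  called <- !tie & fold_bound >= phi
  direction <- rep("none", length(x0))
  direction[called & treat_higher] <- "up"
  direction[called & !treat_higher] <- "down"

  data.frame(
    x_control = x0, x_treatment = x1,
    mean_control = g0$mu, mean_treatment = g1$mu,
    lower_high = lower_high, upper_low = upper_low,
    fold_bound = fold_bound,
    direction = direction,
    stringsAsFactors = FALSE)
}

check_alpha_phi <- function(alpha, phi) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1")
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("'phi' must be a single positive number")
  invisible(NULL)
}

#' Call one gene from a pair of observed counts
#'
#' Applies the posterior fold-bound rule to a single gene: the lower extreme
#' percentile of the higher-mean posterior must be at least `phi` times the
#' upper extreme percentile of the lower-mean posterior. Sample 1 is the
#' treatment, so `direction = "up"` means higher in treatment.
#'
#' @param x0,x1 Observed counts in the control and treatment sample.
#' @param b0,b1 Coverages of the control and treatment sample, in (0, 1).
#' @param alpha Credibility parameter in (0, 1); default 0.99, giving the
#'   0.5th and 99.5th percentiles and joint credibility `0.995^2`.
#' @param phi Fold-change threshold; default 1.5.
#' @return A one-row data frame of class `"deg_call"` with the observed
#'   counts, posterior means, the two percentile bounds, `fold_bound`
#'   (their ratio), `direction` (`"up"`, `"down"` or `"none"`), `alpha`,
#'   `phi` and the implied `joint_credibility`.
#' @examples
#' call_gene(100, 0.25, 1000, 0.25)
#' @export
call_gene <- function(x0, b0, x1, b1, alpha = 0.99, phi = 1.5) {
  check_alpha_phi(alpha, phi)
  check_coverage(b0, "b0")
  check_coverage(b1, "b1")
  if (length(x0) != 1L || length(x1) != 1L)
    stop("'x0' and 'x1' must be single counts; use call_table() for tables")
  out <- deg_decide(x0, b0, x1, b1, alpha, phi)
  out$alpha <- alpha
  out$phi <- phi
  out$joint_credibility <- ((1 + alpha) / 2)^2
  class(out) <- c("deg_call", "data.frame")
  out
}

#' Call every gene in a two-sample count table
#'
#' Vectorized application of [call_gene()] over a count matrix; row order is
#' preserved.
#'
#' @param counts A count matrix or data frame (genes x samples) with gene
#'   IDs as row names, or a data frame whose first column holds gene IDs.
#'   All counts must be non-negative integers; gene and sample IDs must be
#'   unique.
#' @param control,treatment Sample (column) names to compare.
#' @param coverage Named numeric vector of per-sample coverages containing
#'   entries for `control` and `treatment` (for example the result of
#'   [read_coverage_config()]), or an unnamed vector of length 2 taken as
#'   (control, treatment).
#' @inheritParams call_gene
#' @return A data frame with one row per gene: `gene_id`, observed counts,
#'   posterior means, percentile bounds, `fold_bound` and `direction`.
#' @examples
#' counts <- matrix(c(100L, 800L, 50L, 900L, 100L, 50L), nrow = 3,
#'                  dimnames = list(c("g1", "g2", "g3"), c("ctl", "trt")))
#' call_table(counts, "ctl", "trt", c(ctl = 0.25, trt = 0.25))
#' @export
call_table <- function(counts, control, treatment, coverage,
                       alpha = 0.99, phi = 1.5) {
  check_alpha_phi(alpha, phi)
  cm <- as_count_matrix(counts)
  for (s in c(control, treatment))
    if (!s %in% colnames(cm))
      stop(sprintf("sample '%s' not found in the count table (samples: %s)",
                   s, paste(colnames(cm), collapse = ", ")))
  cov <- resolve_coverage(coverage, control, treatment)
  if (nrow(cm) == 0L) {
    return(data.frame(
      gene_id = character(0), x_control = integer(0), x_treatment = integer(0),
      mean_control = numeric(0), mean_treatment = numeric(0),
      lower_high = numeric(0), upper_low = numeric(0),
      fold_bound = numeric(0), direction = character(0),
      stringsAsFactors = FALSE))
  }
  out <- deg_decide(cm[, control], cov[["control"]],
                    cm[, treatment], cov[["treatment"]], alpha, phi)
  cbind(data.frame(gene_id = rownames(cm), stringsAsFactors = FALSE), out)
}

resolve_coverage <- function(coverage, control, treatment) {
  if (!is.numeric(coverage))
    stop("'coverage' must be a numeric vector of per-sample coverages")
  if (!is.null(names(coverage)) && all(c(control, treatment) %in% names(coverage))) {
    b0 <- coverage[[control]]
    b1 <- coverage[[treatment]]
  } else if (length(coverage) == 2L && is.null(names(coverage))) {
    b0 <- coverage[[1L]]
    b1 <- coverage[[2L]]
  } else {
    stop(sprintf(
      "'coverage' must name both samples ('%s', '%s') or be an unnamed length-2 vector",
      control, treatment))
  }
  check_coverage(b0, sprintf("coverage[%s]", control))
  check_coverage(b1, sprintf("coverage[%s]", treatment))
  c(control = b0, treatment = b1)
}

#' Coverage-aware differential expression between two unreplicated samples
#'
#' The main entry point: compares one control and one treatment RNA-Seq
#' sample gene by gene through the posteriors of their true counts, and
#' returns a fitted object carrying the per-gene calls, the decision
#' parameters, and the coverages used. Because the comparison is made on the
#' posterior scale of true counts, no library-size normalization and no
#' transcript length information are required.
#'
#' @inheritParams call_table
#' @return An object of class `"cornas"`, a list with components `calls`
#'   (per-gene data frame, see [call_table()]), `control`, `treatment`,
#'   `coverage`, `alpha`, `phi` and `joint_credibility`. Supported methods:
#'   `print`, `summary`, `coef` (posterior mean matrix), `plot`,
#'   `as.data.frame`.
#' @examples
#' fx <- make_fixture(n_genes = 50, n_deg = 5, fold = 4,
#'                    coverage = c(0.25, 0.25), seed = 7)
#' fit <- cornas(fx$counts, "control", "treatment",
#'               coverage = c(control = 0.25, treatment = 0.25))
#' summary(fit)
#' @export
cornas <- function(counts, control = "control", treatment = "treatment",
                   coverage, alpha = 0.99, phi = 1.5) {
  calls <- call_table(counts, control, treatment, coverage, alpha, phi)
  cov <- resolve_coverage(coverage, control, treatment)
  structure(
    list(calls = calls, control = control, treatment = treatment,
         coverage = cov, alpha = alpha, phi = phi,
         joint_credibility = ((1 + alpha) / 2)^2),
    class = "cornas")
}

#' @export
print.cornas <- function(x, ...) {
  n <- nrow(x$calls)
  tab <- table(factor(x$calls$direction, levels = c("up", "down", "none")))
  cat(sprintf("Coverage-aware DEG comparison: '%s' (treatment) vs '%s' (control)\n",
              x$treatment, x$control))
  cat(sprintf("  coverages: control = %.4g, treatment = %.4g\n",
              x$coverage[["control"]], x$coverage[["treatment"]]))
  cat(sprintf("  alpha = %g (joint credibility %.4f), phi = %g\n",
              x$alpha, x$joint_credibility, x$phi))
  cat(sprintf("  %d genes: %d up, %d down, %d not called\n",
              n, tab[["up"]], tab[["down"]], tab[["none"]]))
  invisible(x)
}

#' @export
summary.cornas <- function(object, ...) {
  calls <- object$calls
  deg <- calls[calls$direction != "none", , drop = FALSE]
  deg <- deg[order(-deg$fold_bound), , drop = FALSE]
  out <- list(object = object, n_genes = nrow(calls),
              n_up = sum(calls$direction == "up"),
              n_down = sum(calls$direction == "down"),
              top = utils::head(deg, 10L))
  class(out) <- "summary.cornas"
  out
}

#' @export
print.summary.cornas <- function(x, ...) {
  print(x$object)
  if (nrow(x$top)) {
    cat("\nStrongest calls (by posterior fold bound):\n")
    print(x$top[, c("gene_id", "x_control", "x_treatment", "mean_control",
                    "mean_treatment", "fold_bound", "direction")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.cornas <- function(object, ...) {
  m <- cbind(control = object$calls$mean_control,
             treatment = object$calls$mean_treatment)
  rownames(m) <- object$calls$gene_id
  m
}

#' @export
as.data.frame.cornas <- function(x, ...) {
  x$calls
}

#' Posterior-mean scatter plot of a two-sample comparison
#'
#' Plots treatment against control posterior means on log axes, colouring
#' genes by their call, with the identity line for reference.
#'
#' @param x A [cornas()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cornas <- function(x, ...) {
  calls <- x$calls
  col <- c(up = "firebrick", down = "royalblue", none = "grey60")
  graphics::plot(pmax(calls$mean_control, 0.5),
                 pmax(calls$mean_treatment, 0.5),
                 log = "xy", col = col[calls$direction], pch = 16, cex = 0.6,
                 xlab = sprintf("posterior mean true count (%s)", x$control),
                 ylab = sprintf("posterior mean true count (%s)", x$treatment),
                 main = sprintf("DEG calls (alpha = %g, phi = %g)",
                                x$alpha, x$phi), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = names(col), col = col, pch = 16,
                   bty = "n")
  invisible(x)
}
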