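# The fragment-sampling chance mechanism and the simulation harness.
#
# A sequencing run draws S of the N cDNA fragments without replacement; the
# number of drawn fragments belonging to a gene with true count k is
# therefore Hypergeometric(N, k, S). The production sampler draws from that
# distribution directly; a literal shuffle-the-pool implementation is kept
# as a reference for small N. Built on the sampler are the mean/variance
# study (which motivates the Generalized Poisson model and m = 1/(1-b)), the
# power/FPR study over true-count grids, and the PCR-efficiency robustness
# study (coverage mis-specification and its effect on ROC curves).

#' Draw observed counts for a gene from the fragment pool
#'
#' Samples the observed count of a gene with true count `k` when `S` of the
#' `N` pool fragments are sequenced: `Hypergeometric(N, k, S)`.
#'
#' @param k True gene count(s), integers in `1..N` (vectorized).
#' @param S Number of fragments sequenced, in `1..N`.
#' @param N Fragment population size.
#' @param n Number of draws per element of `k` (default 1).
#' @return Integer vector of observed counts, `length(k) * n` values
#'   (recycled over `k` fastest).
#' @examples
#' set.seed(1)
#' sample_observed_count(40, S = 75, N = 300, n = 5)
#' @export
sample_observed_count <- function(k, S, N, n = 1L) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 1 ||
      N != round(N))
    stop("'N' must be a single positive integer")
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 1 || S > N ||
      S != round(S))
    stop("'S' must be an integer in 1..N")
  if (!is.numeric(k) || length(k) < 1L || any(!is.finite(k)) || any(k < 1) ||
      any(k > N) || any(k != round(k)))
    stop("'k' must contain integers in 1..N")
  ks <- rep(k, times = n)
  stats::rhyper(length(ks), m = ks, n = N - ks, k = S)
}

#' Reference sampler: literal shuffle of the fragment pool
#'
#' Indexes the `N` fragments, shuffles them with an explicit Fisher-Yates
#' pass, takes the first `S` as the sequenced fragments, and counts how many
#' belong to the gene (indices `<= k`). Distributionally identical to
#' [sample_observed_count()]; retained as an independent reference for small
#' pools, not for production use.
#'
#' @inheritParams sample_observed_count
#' @param k True gene count, a single integer in `1..N`.
#' @return A single observed count.
#' @export
sample_observed_count_shuffle <- function(k, S, N) {
  if (length(k) != 1L || k < 1 || k > N || k != round(k))
    stop("'k' must be a single integer in 1..N")
  if (S < 1 || S > N || S != round(S))
    stop("'S' must be an integer in 1..N")
  pool <- seq_len(N)
  # Fisher-Yates: swap position i with a uniform position in i..N
  for (i in seq_len(N - 1L)) {
    j <- i + floor(stats::runif(1L) * (N - i + 1L))
    tmp <- pool[i]; pool[i] <- pool[j]; pool[j] <- tmp
  }
  sum(pool[seq_len(S)] <= k)
}

#' Describe a simulated two-sample experiment
#'
#' Encodes one of the three effect scenarios used throughout the simulation
#' studies: `"none"` (fold 1, true counts up to 10,000), `"weak"` (fold 1.5,
#' up to 6,666) and `"strong"` (fold 2, up to 5,000), at a given coverage.
#' Sample 2 (treatment) carries `round(fold * k)` true counts for each
#' sample-1 true count `k`; rounding is round-half-to-even. The defaults use
#' a scaled-down fragment population of 3e6; coverage, not absolute pool
#' size, governs the sampling law whenever `k` is far below `N`.
#'
#' @param effect One of `"none"`, `"weak"`, `"strong"`.
#' @param coverage Coverage in (0, 1) shared by both samples.
#' @param max_true_count Largest sample-1 true count; defaults to the
#'   scenario's canonical maximum (10,000 / 6,666 / 5,000).
#' @param population_N Fragment population size (default 3e6).
#' @param iterations Independent trials per true count (default 100).
#' @param k_grid True-count grid; default ~10 points per decade,
#'   log-spaced over `1..max_true_count`.
#' @return An object of class `"simulation_scenario"`.
#' @examples
#' simulation_scenario("strong", coverage = 0.25)
#' @export
simulation_scenario <- function(effect = c("none", "weak", "strong"),
                                coverage, max_true_count = NULL,
                                population_N = 3e6, iterations = 100L,
                                k_grid = NULL) {
  effect <- match.arg(effect)
  fold <- c(none = 1.0, weak = 1.5, strong = 2.0)[[effect]]
  if (is.null(max_true_count))
    max_true_count <- c(none = 10000L, weak = 6666L, strong = 5000L)[[effect]]
  check_coverage(coverage, "coverage")
  if (!is.numeric(population_N) || length(population_N) != 1L ||
      population_N < 1 || population_N != round(population_N))
    stop("'population_N' must be a single positive integer")
  if (round(fold * max_true_count) > population_N)
    stop("fold * max_true_count exceeds the fragment population size")
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1 ||
      iterations != round(iterations))
    stop("'iterations' must be a single positive integer")
  if (is.null(k_grid))
    k_grid <- log_grid(max_true_count)
  if (any(k_grid < 1) || any(k_grid > max_true_count) ||
      any(k_grid != round(k_grid)))
    stop("'k_grid' must contain integers in 1..max_true_count")
  structure(
    list(effect = effect, fold = fold, max_true_count = as.integer(max_true_count),
         coverage = coverage, population_N = population_N,
         iterations = as.integer(iterations), k_grid = as.integer(k_grid)),
    class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario: effect '%s' (fold %.1f), coverage %g\n  true counts: %d grid points in 1..%d; N = %g; %d iterations\n",
    x$effect, x$fold, x$coverage, length(x$k_grid), x$max_true_count,
    x$population_N, x$iterations))
  invisible(x)
}

# log-spaced integer grid over 1..k_max, ~points_per_decade per decade
log_grid <- function(k_max, points_per_decade = 10L) {
  n <- max(2L, ceiling(log10(k_max) * points_per_decade))
  unique(round(10^seq(0, log10(k_max), length.out = n)))
}

#' Mean/variance behaviour of observed counts across coverages
#'
#' Draws repeated observed counts for each (coverage, true count) pair and
#' tabulates the empirical mean, variance and mean-to-variance ratio. The
#' empirical means track `b * k`, the ratio tracks `1/(1-b)`, and the
#' variance falls below the mean at every positive coverage
#' (underdispersion) -- the observations that motivate the Generalized
#' Poisson model for observed counts.
#'
#' @param coverages Coverage values in (0, 1).
#' @param k_values True gene counts.
#' @param iterations Draws per cell (default 2000).
#' @param population_N Fragment population size (default 3e6).
#' @return Data frame with columns `b`, `k`, `mean`, `variance`, `m_hat`.
#' @examples
#' set.seed(1)
#' mean_variance_study(0.5, 1000, iterations = 500)
#' @export
mean_variance_study <- function(coverages, k_values, iterations = 2000L,
                                population_N = 3e6) {
  for (b in coverages) check_coverage(b, "coverages")
  rows <- expand.grid(k = k_values, b = coverages)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    b <- rows$b[i]; k <- rows$k[i]
    S <- round(b * population_N)
    x <- sample_observed_count(k, S, population_N, n = iterations)
    data.frame(b = b, k = k, mean = mean(x), variance = stats::var(x),
               m_hat = mean(x) / stats::var(x))
  })
  do.call(rbind, res)
}

#' DEG call rates over a grid of true counts
#'
#' The core power/false-positive study: for each true count `k` on the
#' scenario grid, sample 1 has true count `k` and sample 2 has
#' `round(fold * k)`; observed counts are drawn independently for the two
#' samples at the scenario coverage, the decision rule is applied, and the
#' per-`k` call frequency over the scenario's iterations is recorded. Under
#' the no-effect scenario the call rate is a false positive rate; under the
#' weak/strong scenarios it is the sensitivity (only calls in the correct,
#' upward direction count).
#'
#' @param scenario A [simulation_scenario()].
#' @param alpha,phi Decision-rule parameters (defaults 0.99 and 1.5).
#' @param assumed_coverage Coverage handed to the caller; defaults to the
#'   scenario's true coverage. Setting it differently emulates coverage
#'   mis-specification (e.g. imperfect PCR amplification).
#' @return Data frame with one row per grid point: `b`, `k`, `fold`,
#'   `call_rate` (any call), `correct_rate` (calls in the true direction).
#' @examples
#' set.seed(1)
#' sc <- simulation_scenario("strong", coverage = 0.25, iterations = 20)
#' run_test1(sc)
#' @export
run_test1 <- function(scenario, alpha = 0.99, phi = 1.5,
                      assumed_coverage = scenario$coverage) {
  if (!inherits(scenario, "simulation_scenario"))
    stop("'scenario' must be a 'simulation_scenario' object")
  check_alpha_phi(alpha, phi)
  check_coverage(assumed_coverage, "assumed_coverage")
  draws <- simulate_pairs(scenario)
  dec <- deg_decide(draws$x0, assumed_coverage, draws$x1, assumed_coverage,
                    alpha, phi)
  called <- dec$direction != "none"
  correct <- if (scenario$fold > 1) dec$direction == "up" else called
  data.frame(
    b = scenario$coverage,
    k = scenario$k_grid,
    fold = scenario$fold,
    call_rate = rowMeans(matrix(called, nrow = length(scenario$k_grid))),
    correct_rate = rowMeans(matrix(correct, nrow = length(scenario$k_grid))))
}

# Draw all observed-count pairs for a scenario. Returns vectors ordered with
# k varying fastest within each iteration block, suitable for
# matrix(nrow = length(k_grid)) reduction by grid point.
simulate_pairs <- function(scenario) {
  N <- scenario$population_N
  S <- round(scenario$coverage * N)
  k1 <- scenario$k_grid
  k2 <- round(scenario$fold * k1)
  if (any(k2 > N))
    stop("fold * k exceeds the fragment population size")
  it <- scenario$iterations
  list(
    k = rep(k1, times = it),
    x0 = sample_observed_count(k1, S, N, n = it),
    x1 = sample_observed_count(k2, S, N, n = it))
}

#' Robustness of the caller to PCR-efficiency mis-specification
#'
#' Data are simulated once per expected coverage at the true coverage
#' (perfect amplification); the caller is then run with the coverage a user
#' would infer under each assumed amplification efficiency, i.e. inflated by
#' `1 / pcr_retention(efficiency, cycles)`. False positive rates come from
#' the no-effect scenario and sensitivities from the strong (2-fold)
#' scenario; an ROC curve is traced per (coverage, efficiency) cell by
#' sweeping the decision cut-offs (`alpha` fixed at 0.99 while `phi` runs
#' from 1.5 down to 0.75, then `phi` fixed at 0.75 while `alpha` runs from
#' 0.99 down to 0.01), and summarized by its trapezoid AUC. Cells whose
#' mis-specified coverage reaches 1 are skipped with a warning, mirroring
#' the recommendation against using the method at coverage >= 1.
#'
#' @param coverages Expected (true) coverages; default `c(0.5, 0.25, 0.1, 0.01)`.
#' @param efficiencies Assumed amplification efficiencies; default
#'   `c(1, 0.95, 0.9, 0.85, 0.8)`.
#' @param cycles PCR cycles used in the retention model (default 14).
#' @param iterations Trials per true count (default 50).
#' @param population_N Fragment population size (default 3e6).
#' @param phi_sweep,alpha_sweep Cut-off grids for the ROC sweep.
#' @return List with `auc` (data frame `coverage`, `efficiency`,
#'   `assumed_coverage`, `auc`; skipped cells have `NA` AUC) and `roc`
#'   (data frame of the underlying `fpr`/`tpr` points per cell).
#' @examples
#' set.seed(1)
#' st <- run_pcr_efficiency_study(coverages = 0.1, efficiencies = c(1, 0.8),
#'                                iterations = 10)
#' st$auc
#' @export
run_pcr_efficiency_study <- function(coverages = c(0.5, 0.25, 0.1, 0.01),
                                     efficiencies = c(1, 0.95, 0.9, 0.85, 0.8),
                                     cycles = DEFAULT_PCR_CYCLES,
                                     iterations = 50L,
                                     population_N = 3e6,
                                     phi_sweep = seq(1.5, 0.75, by = -0.075),
                                     alpha_sweep = seq(0.99, 0.01, by = -0.07)) {
  auc_rows <- list()
  roc_rows <- list()
  for (b in coverages) {
    sc_none <- simulation_scenario("none", coverage = b,
                                   population_N = population_N,
                                   iterations = iterations)
    sc_strong <- simulation_scenario("strong", coverage = b,
                                     population_N = population_N,
                                     iterations = iterations)
    draws_none <- simulate_pairs(sc_none)
    draws_strong <- simulate_pairs(sc_strong)
    for (e in efficiencies) {
      b_assumed <- b / pcr_retention(e, cycles)
      if (b_assumed >= 1) {
        warning(sprintf(
          "expected coverage %g at efficiency %g implies assumed coverage %.3g >= 1; cell skipped",
          b, e, b_assumed))
        auc_rows[[length(auc_rows) + 1L]] <- data.frame(
          coverage = b, efficiency = e, assumed_coverage = b_assumed,
          auc = NA_real_)
        next
      }
      pts <- roc_sweep(draws_none, draws_strong, b_assumed,
                       phi_sweep, alpha_sweep)
      auc_rows[[length(auc_rows) + 1L]] <- data.frame(
        coverage = b, efficiency = e, assumed_coverage = b_assumed,
        auc = roc_auc(pts))
      roc_rows[[length(roc_rows) + 1L]] <- cbind(
        data.frame(coverage = b, efficiency = e), pts)
    }
  }
  list(auc = do.call(rbind, auc_rows), roc = do.call(rbind, roc_rows))
}

# FPR/TPR pairs over the cut-off sweep for one assumed coverage.
roc_sweep <- function(draws_none, draws_strong, b_assumed,
                      phi_sweep, alpha_sweep) {
  fold_bound_at <- function(draws, alpha) {
    dec <- deg_decide(draws$x0, b_assumed, draws$x1, b_assumed, alpha, 1)
    # a tied posterior mean can never be a call at any phi
    ifelse(dec$mean_control == dec$mean_treatment, -Inf, dec$fold_bound)
  }
  pts <- list()
  # leg 1: alpha fixed at 0.99, phi from 1.5 down to 0.75
  fb_none <- fold_bound_at(draws_none, 0.99)
  fb_strong <- fold_bound_at(draws_strong, 0.99)
  for (phi in phi_sweep)
    pts[[length(pts) + 1L]] <- data.frame(
      alpha = 0.99, phi = phi,
      fpr = mean(fb_none >= phi), tpr = mean(fb_strong >= phi))
  # leg 2: phi fixed at 0.75, alpha from 0.99 down to 0.01
  for (a in alpha_sweep) {
    fb_none_a <- fold_bound_at(draws_none, a)
    fb_strong_a <- fold_bound_at(draws_strong, a)
    pts[[length(pts) + 1L]] <- data.frame(
      alpha = a, phi = 0.75,
      fpr = mean(fb_none_a >= 0.75), tpr = mean(fb_strong_a >= 0.75))
  }
  do.call(rbind, pts)
}
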