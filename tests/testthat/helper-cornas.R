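# Shared helpers for the suite.

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Total variation distance between a discrete posterior (posterior_pmf) and
# the gamma approximation discretized onto its integer support; gamma mass
# falling outside the support counts as discrepancy.
tvd_gamma_vs_exact <- function(x, b) {
  pp <- posterior_pmf(x, b)
  g <- posterior_gamma(x, b)
  gm <- stats::pgamma(pp$k + 0.5, shape = g$shape, scale = g$scale) -
    stats::pgamma(pp$k - 0.5, shape = g$shape, scale = g$scale)
  0.5 * (sum(abs(pp$prob - gm)) + (1 - sum(gm)))
}

# A tiny deterministic 3-gene table: one obvious up, one obvious down, one tie.
toy_counts <- function() {
  matrix(c(100L, 900L, 250L,
           1000L, 90L, 250L),
         nrow = 3,
         dimnames = list(c("gUp", "gDown", "gFlat"), c("ctl", "trt")))
}
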