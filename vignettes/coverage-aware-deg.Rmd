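---
title: "Coverage-aware differential expression without replicates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-aware differential expression without replicates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cornas)
set.seed(1)
```

This vignette is the package's account of its statistical machinery: the
observation model and its assumptions, the posterior used for calling, the
tunable parameters, the simulator behind the tests, and the numerical and
design choices a maintainer should know about.

## The observation model

A sequencing run is modelled as drawing $S$ fragments uniformly without
replacement from a library of $N$ cDNA fragments. For a gene whose true
count (its number of fragments in the library) is $k$, the observed count
$X$ is then $\mathrm{Hypergeometric}(N, k, S)$. Two consequences drive
everything else:

* $\mathbb{E}(X) = bk$ where $b = S/N$ is the **coverage**;
* $X$ is **underdispersed**: the mean-to-variance ratio is
  $m = \frac{N}{N-k}\cdot\frac{N-1}{N-S} \approx \frac{1}{1-b}$
  whenever $k \ll N$, so variance $\approx bk(1-b)$ is below the mean for
  any positive coverage.

Because $N$ is large and unknown in practice, the bounded hypergeometric is
replaced by a Generalized Poisson (GP) with
$\lambda_1 = bk\sqrt{m}$, $\lambda_2 = 1-\sqrt{m}$, which reproduces the
mean $bk$ and variance $bk/m$ and has unbounded support; $m = 1$ recovers
the Poisson. `mean_variance_study()` demonstrates the mechanism:

```{r mean-variance}
mean_variance_study(coverages = c(0.5, 0.1), k_values = 1000,
                    iterations = 2000)
```

The GP is a valid probability distribution for $0 < m < 4$. Coverages of
$0.75$ and above push $m$ past that bound; the exact-posterior code warns
there, and coverage $\geq 1$ is refused everywhere (deep sequencing that
exhausts the library breaks the sampling model, and the method is not
recommended in that regime).

## The posterior of the true count

With a uniform prior over true counts $1, 2, \dots$, Bayes' theorem gives a
discrete posterior $P(T = k \mid X = x)$ proportional to the GP likelihood
evaluated along $k$. `posterior_pmf()` computes it by truncated summation
and is the package's internal reference. The production path is a gamma
approximation with moments

$$\mu = \frac{x+1}{b} - \Bigl(1 + \frac{1}{2b}\Bigr)^{-1}, \qquad
  \sigma^2 = \frac{x+1}{\bigl(b(b+1)\bigr)^2},$$

shape $\mu^2/\sigma^2$ and scale $\sigma^2/\mu$, so that percentiles are a
single `qgamma` call per gene and a full comparison of two samples runs in
well under a second for tens of thousands of genes.

```{r posterior}
posterior_pmf(100, 0.25)$mean      # exact
posterior_gamma(100, 0.25)$mu      # closed form
```

**Accuracy regime.** The moment formulas are a calibration against the
exact posterior that is essentially exact for moderate-to-large observed
counts (relative mean error below $10^{-3}$ by $x = 500$) but degrades for
the very smallest counts: at $x = 1$ the closed-form mean overshoots the
exact posterior mean by roughly $\sqrt{m}$-related factors — about 4% at
$b = 0.1$, 10% at $b = 0.25$ and 19% at $b = 0.5$ — and the total variation
distance between the two distributions can reach $\sim$0.2. The property
suite pins the supported regime ($x \geq 5$: means within 5%, total
variation below 0.1) and the discrepancy at $x = 1$ is visible in the
acceptance suite by design. Practically this means calls that hinge on
observed counts of 0–2 lean conservative-to-noisy and should not be
over-interpreted; at such counts no single-sample method has real power
anyway.

Two support conventions are worth recording. The exact posterior is summed
over $k \geq \max(x, 1)$: the likelihood is zero below $x$, and the prior
starts at 1, which also covers $x = 0$. The gamma approximation is
continuous on $k \geq 0$ and is used as printed, including at $x = 0$
(where $\mu > 0$ still holds).

## The decision rule and its parameters

For control and treatment observed counts $(x_0, x_1)$ at coverages
$(b_0, b_1)$, both posteriors are formed and the sample with the larger
posterior mean is identified. With credibility $\alpha$ the rule compares
the $(1-\alpha)/2$ percentile of the higher posterior, $p^{+}$, against the
$(1+\alpha)/2$ percentile of the lower posterior, $p^{-}$, and calls the
gene when $p^{+}/p^{-} \geq \phi$.

| parameter | meaning | default | why |
|---|---|---|---|
| $\alpha$ | credibility of each one-sided bound (dimensionless) | 0.99 | joint statement $0.995^2 \approx 0.99$ that the true counts differ $\geq \phi$-fold |
| $\phi$ | fold-change threshold (ratio of true counts) | 1.5 | smallest effect commonly treated as biologically meaningful; lower to 1.0 to chase weak effects at the cost of FPR |

Ties on the posterior mean (identical $x$ and $b$) are never called — the
rule requires a strictly larger mean. Genes with $x = 0$ are processed like
any other; no minimum-count filter is applied. The per-gene output keeps
both posterior means, both percentile bounds and the fold bound
$p^{+}/p^{-}$, so a table can be re-thresholded at a different $\phi$
without recomputation.

Raising either parameter is monotone: the DEG set at $\phi = 2$ is a subset
of the one at $\phi = 1.5$, and widening the intervals (larger $\alpha$)
never adds calls. Sensitivity grows with the true count at fixed coverage:
a genuine 2-fold change at coverage 0.25 becomes callable around true
counts in the low thousands, because the posterior intervals tighten
relative to their location as counts grow.

## The simulator: what it emulates and what it does not

`simulation_scenario()` + `run_test1()` reproduce the canonical three-arm
power study: no effect (fold 1, true counts to 10,000), weak effect (fold
1.5, to 6,666) and strong effect (fold 2, to 5,000); sample 2 carries
`round(fold * k)` (round-half-to-even) and both samples are drawn
independently — no coupling between the two libraries is assumed. Observed
counts come from `sample_observed_count()`, a direct hypergeometric
sampler; a literal shuffle-the-pool implementation
(`sample_observed_count_shuffle()`) is retained as an independent
small-$N$ reference, and the two are checked against each other
distributionally in the tests.

The simulator emulates *sampling noise only*: ideal uniform fragment
sampling from a fixed library. It does not emulate library-preparation
biases (GC, priming, length), mapping and quantification errors, PCR
stochasticity, or biological replicate variability. Passing the simulation
suite therefore validates the chance-mechanism claims (mean $bk$,
underdispersion $1/(1-b)$, FPR control and power of the rule under the
stated model) — it does not certify performance on real libraries, where
coverage mis-specification and preparation bias are the dominant unmodelled
factors.

**Problem sizes.** The package runs its studies on a scaled-down population
of $N = 3\times 10^6$ with proportional read counts and log-spaced
true-count grids (about 10 points per decade), 100 iterations per grid
point and 2,000 iterations for the mean–variance study. Coverage is the
governing parameter: call-rate curves at $(N, S, k)$ and $(N/100, S/100,
k)$ agree within Monte-Carlo error when $k \ll N$ (a property the suite
checks), so the scaled runs probe the same regime as a 300 M-fragment
library.

## PCR efficiency and coverage mis-specification

Coverage derivations assume perfect amplification. If the per-cycle
efficiency is $e < 1$, the realized population is a fraction
$((1+e)/2)^{14}$ of the ideal one — 70%, 49%, 34%, 23% for $e$ = 0.95,
0.90, 0.85, 0.80 at the standard 14 cycles — so a user assuming ideal
amplification *underestimates* coverage, and one correcting for efficiency
divides it out (`adjusted_coverage()`). The closed form $((1+e)/2)^c$ was
adopted because it reproduces those four retention percentages exactly at
$c = 14$.

`run_pcr_efficiency_study()` quantifies the consequence: data are simulated
once at the true coverage, the caller is re-run with the coverage implied by
each assumed efficiency, and ROC curves (FPR from the no-effect arm,
sensitivity from the strong arm) are traced by the standard cut-off sweep —
$\phi: 1.5 \to 0.75$ at $\alpha = 0.99$, then $\alpha: 0.99 \to 0.01$ at
$\phi = 0.75$ — and summarized by trapezoid AUC. Mis-specifying efficiency
shifts both FPR and sensitivity upward but moves the AUC by under 5%
wherever the study can run at all. Note the feasibility boundary: at
expected coverage 0.5 an assumed efficiency of 90% or less — and at 0.25, of
80% — implies a coverage above 1, and those cells are refused and reported
as `NA` rather than computed with an invalid coverage.

## Numerical choices

* All GP pmf evaluation is in log space with `lgamma` for $x!$; observed
  counts up to $10^5$ and beyond are routine.
* Underdispersion makes $\lambda_2 < 0$; the pmf is set to zero wherever
  $\lambda_1 + x\lambda_2 \leq 0$ (truncated-GP convention) and no
  renormalization is applied inside the pmf — the posterior normalizes
  anyway.
* The exact posterior truncates its normalizing sum at
  $\lceil \mu + 12\sigma \rceil$ (gamma-approximation estimates), extends in
  blocks until the last term falls below `tol` times the running sum
  (default $10^{-12}$), and reports a geometric bound on the discarded tail
  mass; a hard cap turns pathological inputs into an error instead of a
  hang.
* Ratios with zero denominators in evaluation metrics (e.g. PPV with no
  calls) are reported as `NA` and flagged, never imputed as 0.
* ROC AUC is the raw trapezoid over the swept points augmented with (0,0)
  and (1,1); no convex-hull smoothing.
* All stochastic entry points consume the R RNG so a single `set.seed()`
  makes any study reproducible; fixtures additionally record their seed and
  restore the caller's RNG state.

## Known limitations

* One sample per condition by design; no replicate pooling or multi-sample
  extension.
* The gamma production path is least accurate for observed counts below
  about 5 (see above).
* Coverage must lie in (0, 1); libraries sequenced to saturation are out of
  scope.
* No count filtering, no multiple-testing adjustment: each call is a
  per-gene credibility statement, not a frequentist test, and genome-wide
  error control is the user's responsibility when screening.
* The benchmarking utilities are direction-aware (an up-call on a truly
  down-regulated gene counts as a false positive *and* a miss), which is
  the stricter of the common conventions.
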