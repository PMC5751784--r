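# Sequencing-coverage arithmetic.
#
# Coverage b is the fraction of the cDNA fragment population that was actually
# sequenced: b = S/N, with S the number of sequenced fragments (read pairs for
# paired-end libraries) and N the size of the cDNA fragment population prior
# to PCR. N is either supplied, derived from the post-PCR fragment yield and
# the cycle count, or derived from the loading concentration and volume.

#' Default cDNA fragment population size
#'
#' The canonical pre-PCR fragment population size of 300 million, obtained
#' from a standard Illumina library (40 uL of 200 nM post-PCR cDNA, i.e.
#' about 4.8e12 fragments, amplified over 14 PCR cycles).
#'
#' @export
DEFAULT_FRAGMENT_POPULATION <- 3e8

#' Default number of PCR amplification cycles
#' @export
DEFAULT_PCR_CYCLES <- 14L

AVOGADRO <- 6.022e23

#' Sequencing coverage from read and fragment counts
#'
#' Coverage is the fraction `S / N` of the cDNA fragment population that was
#' sequenced. Values of 1 or more are rejected: the posterior model assumes
#' sampling without exhaustion and its use is not recommended when the
#' estimated coverage reaches one.
#'
#' @param S Number of cDNA fragments sequenced (read pairs for paired-end).
#' @param N Total cDNA fragment population size prior to sequencing.
#' @return Coverage, a number in (0, 1).
#' @examples
#' coverage_from_reads(75e6, 300e6) # 0.25
#' @export
coverage_from_reads <- function(S, N = DEFAULT_FRAGMENT_POPULATION) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S <= 0)
    stop("'S' (fragments sequenced) must be a single positive number")
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0)
    stop("'N' (fragment population size) must be a single positive number")
  if (S >= N)
    stop(sprintf(
      "coverage S/N = %.4g is >= 1; use of the method is not recommended when the estimated coverage is one or more",
      S / N))
  S / N
}

#' Pre-PCR fragment population from post-PCR yield
#'
#' Undoes ideal PCR amplification: with perfect efficiency each fragment
#' doubles every cycle, so the pre-PCR population is the post-PCR fragment
#' count divided by `2^cycles`. For the standard library (4.818e12 post-PCR
#' fragments, 14 cycles) this gives approximately 300 million.
#'
#' @param post_pcr_fragments Fragment count after amplification.
#' @param cycles Number of PCR cycles (default 14).
#' @return Estimated fragment population size prior to PCR.
#' @examples
#' prepcr_fragments(4.818e12, 14) # ~2.94e8, i.e. ~300 M
#' @export
prepcr_fragments <- function(post_pcr_fragments, cycles = DEFAULT_PCR_CYCLES) {
  if (!is.numeric(post_pcr_fragments) || length(post_pcr_fragments) != 1L ||
      !is.finite(post_pcr_fragments) || post_pcr_fragments <= 0)
    stop("'post_pcr_fragments' must be a single positive number")
  cycles <- check_cycles(cycles)
  post_pcr_fragments / 2^cycles
}

#' Fragment count from loading concentration and volume
#'
#' Converts an RNA/cDNA loading concentration (picomolar) and loading volume
#' (microlitres; 120 uL is the usual flow-cell loading) into a molecule
#' count via the Avogadro constant.
#'
#' @param concentration_pM Loading concentration in pM.
#' @param volume_uL Loading volume in uL (default 120).
#' @return Number of fragments loaded.
#' @examples
#' fragments_from_concentration(3, 120) # ~2.17e8
#' @export
fragments_from_concentration <- function(concentration_pM, volume_uL = 120) {
  if (!is.numeric(concentration_pM) || length(concentration_pM) != 1L ||
      !is.finite(concentration_pM) || concentration_pM <= 0)
    stop("'concentration_pM' must be a single positive number")
  if (!is.numeric(volume_uL) || length(volume_uL) != 1L ||
      !is.finite(volume_uL) || volume_uL <= 0)
    stop("'volume_uL' must be a single positive number")
  (concentration_pM * 1e-12) * (volume_uL * 1e-6) * AVOGADRO
}

#' Fraction of the ideal fragment population retained under imperfect PCR
#'
#' With per-cycle amplification efficiency `e < 1`, each cycle multiplies the
#' population by `1 + e` instead of 2, so after `cycles` cycles the population
#' is a fraction `((1 + e) / 2)^cycles` of the perfect-amplification yield.
#' At 14 cycles this gives 70%, 49%, 34% and 23% for efficiencies of 95%,
#' 90%, 85% and 80%.
#'
#' @param efficiency Per-cycle amplification efficiency in (0, 1].
#' @param cycles Number of PCR cycles (default 14).
#' @return Retained fraction in (0, 1].
#' @examples
#' pcr_retention(0.95, 14) # ~0.70
#' @export
pcr_retention <- function(efficiency, cycles = DEFAULT_PCR_CYCLES) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      !is.finite(efficiency) || efficiency <= 0 || efficiency > 1)
    stop("'efficiency' must be a single number in (0, 1]")
  cycles <- check_cycles(cycles)
  ((1 + efficiency) / 2)^cycles
}

#' Coverage adjusted for PCR amplification efficiency
#'
#' When amplification is imperfect, the effective fragment population is
#' smaller than the nominal `N`, so the same sequencing depth corresponds to
#' a higher coverage: `S / (N * pcr_retention(efficiency, cycles))`. For
#' example 75 M reads against a nominal 300 M population at 95% efficiency
#' give coverage 75 / (300 * 0.70) = 0.36 rather than 0.25.
#'
#' @inheritParams coverage_from_reads
#' @inheritParams pcr_retention
#' @return Adjusted coverage in (0, 1).
#' @examples
#' adjusted_coverage(75e6, 300e6, efficiency = 0.95) # ~0.357
#' @export
adjusted_coverage <- function(S, N = DEFAULT_FRAGMENT_POPULATION,
                              efficiency = 1, cycles = DEFAULT_PCR_CYCLES) {
  retention <- pcr_retention(efficiency, cycles)
  coverage_from_reads(S, N * retention)
}

check_cycles <- function(cycles) {
  if (!is.numeric(cycles) || length(cycles) != 1L || !is.finite(cycles) ||
      cycles < 0 || cycles != round(cycles))
    stop("'cycles' must be a single non-negative integer")
  as.integer(cycles)
}
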