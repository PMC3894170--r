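#' Calibration parameters for mutation-scaled quantities
#'
#' Bundles the assumptions needed to convert mutation-scaled demographic
#' quantities (tau, theta) into years and diploid individuals: the
#' per-generation mutation rate at the filtered (non-CpG) sites actually
#' analysed, the generation time in years, and the fraction of all mutations
#' contributed by the CpG sites that were filtered out.
#'
#' @param mu_filtered Mutation rate per site per generation at filtered
#'   (non-CpG) sites. Default `1e-8`.
#' @param gen_time Generation time in years. Default `3`.
#' @param cpg_fraction Fraction of all mutations contributed by CpG sites,
#'   in `[0, 1)`. Default `0.30`.
#' @return An object of class `calibration_params`.
#' @examples
#' calibration_params()
#' @export
calibration_params <- function(mu_filtered = 1e-8, gen_time = 3,
                               cpg_fraction = 0.30) {
  if (!is.numeric(mu_filtered) || length(mu_filtered) != 1L || mu_filtered <= 0)
    stop("'mu_filtered' must be a single positive number", call. = FALSE)
  if (!is.numeric(gen_time) || length(gen_time) != 1L || gen_time <= 0)
    stop("'gen_time' must be a single positive number", call. = FALSE)
  if (!is.numeric(cpg_fraction) || length(cpg_fraction) != 1L ||
      cpg_fraction < 0 || cpg_fraction >= 1)
    stop("'cpg_fraction' must be in [0, 1)", call. = FALSE)
  structure(list(mu_filtered = mu_filtered, gen_time = gen_time,
                 cpg_fraction = cpg_fraction),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("Calibration parameters:\n")
  cat(sprintf("  mu (filtered sites): %.3g per site per generation\n",
              x$mu_filtered))
  cat(sprintf("  generation time:     %g years\n", x$gen_time))
  cat(sprintf("  CpG mutation share:  %g\n", x$cpg_fraction))
  invisible(x)
}

#' Convert a mutation-scaled divergence time to years
#'
#' tau is the expected number of mutations per site accumulated since
#' divergence; dividing by the per-generation mutation rate gives
#' generations, and multiplying by the generation time gives years.
#'
#' @param tau Mutation-scaled divergence time (per site), `>= 0`.
#' @param params A [calibration_params()] object.
#' @return Time in years.
#' @seealso [time_to_tau()] for the inverse.
#' @examples
#' calibrate_time(0.53e-4, calibration_params())  # 15,900 years
#' @export
calibrate_time <- function(tau, params = calibration_params()) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(tau < 0)) stop("'tau' must be >= 0", call. = FALSE)
  tau / params$mu_filtered * params$gen_time
}

#' Convert years to a mutation-scaled divergence time
#'
#' Inverse of [calibrate_time()]; round-trips to machine precision.
#'
#' @param years Time in years, `>= 0`.
#' @param params A [calibration_params()] object.
#' @return Mutation-scaled tau.
#' @export
time_to_tau <- function(years, params = calibration_params()) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(years < 0)) stop("'years' must be >= 0", call. = FALSE)
  years / params$gen_time * params$mu_filtered
}

#' Convert mutation-scaled diversity to effective population size
#'
#' Uses the diploid convention theta = 4 * Ne * mu, so Ne = theta / (4 mu).
#'
#' @param theta Mutation-scaled diversity, `>= 0`.
#' @param mu Mutation rate per site per generation, `> 0`.
#' @return Effective population size in diploid individuals.
#' @seealso [ne_to_theta()] for the inverse.
#' @examples
#' calibrate_ne(1.8e-3, 1e-8)  # 45,000
#' @export
calibrate_ne <- function(theta, mu) {
  if (any(theta < 0)) stop("'theta' must be >= 0", call. = FALSE)
  if (!is.numeric(mu) || any(mu <= 0))
    stop("'mu' must be > 0", call. = FALSE)
  theta / (4 * mu)
}

#' @rdname calibrate_ne
#' @param ne Effective population size in diploid individuals, `>= 0`.
#' @export
ne_to_theta <- function(ne, mu) {
  if (any(ne < 0)) stop("'ne' must be >= 0", call. = FALSE)
  if (!is.numeric(mu) || any(mu <= 0))
    stop("'mu' must be > 0", call. = FALSE)
  4 * ne * mu
}

#' Genome-wide mutation rate implied by a filtered-site rate
#'
#' CpG dinucleotides are hypermutable and are removed by the neutral-site
#' filters, but they still contribute a fraction `cpg_fraction` of all
#' mutations genome-wide. The genome-wide rate (including filtered sites)
#' is therefore `mu_filtered / (1 - cpg_fraction)`.
#'
#' @param mu_filtered Rate per site per generation at filtered sites.
#' @param cpg_fraction Fraction of all mutations contributed by CpG sites,
#'   in `[0, 1)`.
#' @return Genome-wide rate per site per generation.
#' @seealso [filtered_rate()] for the inverse.
#' @examples
#' genomewide_rate(1e-8, 0.30)  # 1.43e-8, ~1.4e-8 to 2 s.f.
#' @export
genomewide_rate <- function(mu_filtered, cpg_fraction) {
  if (any(mu_filtered <= 0)) stop("'mu_filtered' must be > 0", call. = FALSE)
  if (any(cpg_fraction < 0) || any(cpg_fraction >= 1))
    stop("'cpg_fraction' must be in [0, 1)", call. = FALSE)
  mu_filtered / (1 - cpg_fraction)
}

#' @rdname genomewide_rate
#' @param mu_genomewide Genome-wide rate per site per generation.
#' @export
filtered_rate <- function(mu_genomewide, cpg_fraction) {
  if (any(mu_genomewide <= 0))
    stop("'mu_genomewide' must be > 0", call. = FALSE)
  if (any(cpg_fraction < 0) || any(cpg_fraction >= 1))
    stop("'cpg_fraction' must be in [0, 1)", call. = FALSE)
  mu_genomewide * (1 - cpg_fraction)
}

#' Divergence-time interval under mutation-rate uncertainty
#'
#' Propagates a credible interval for the mutation-scaled divergence time
#' through a range of literature genome-wide mutation rates. Each
#' genome-wide rate bound is first converted to the filtered-site scale
#' (the scale on which tau was estimated) with [filtered_rate()]; the
#' widest time interval is then `(tau_lo / mu_max, tau_hi / mu_min)`
#' generations, converted to years.
#'
#' @param tau_interval Numeric length-2, `(lo, hi)` mutation-scaled tau.
#' @param mu_gw_interval Numeric length-2, `(lo, hi)` genome-wide
#'   per-generation mutation rates.
#' @param cpg_fraction CpG mutation fraction, `[0, 1)`.
#' @param gen_time Generation time in years.
#' @return A list with `years` (length-2 numeric) and `kya` (length-2,
#'   rounded to the nearest thousand years for reporting).
#' @examples
#' rate_sensitivity(c(0.46e-4, 0.53e-4), c(0.66e-8, 1.8e-8), 0.30, 3)$kya
#' # 11 34
#' @export
rate_sensitivity <- function(tau_interval, mu_gw_interval,
                             cpg_fraction = 0.30, gen_time = 3) {
  if (length(tau_interval) != 2L || length(mu_gw_interval) != 2L)
    stop("intervals must have length 2", call. = FALSE)
  if (tau_interval[1] > tau_interval[2] ||
      mu_gw_interval[1] > mu_gw_interval[2])
    stop("interval bounds are crossed (lo > hi)", call. = FALSE)
  if (any(tau_interval < 0) || any(mu_gw_interval <= 0) || gen_time <= 0)
    stop("intervals must be positive and gen_time > 0", call. = FALSE)
  mu_filt <- filtered_rate(mu_gw_interval, cpg_fraction)
  years <- c(tau_interval[1] / mu_filt[2] * gen_time,
             tau_interval[2] / mu_filt[1] * gen_time)
  list(years = years, kya = round(years / 1000))
}

#' Fold change between two effective population sizes
#'
#' @param ne_from Starting effective size, `> 0`.
#' @param ne_to Ending effective size, `> 0`.
#' @param digits If non-`NULL`, round the fold change for reporting
#'   (default one decimal, matching how such reductions are usually quoted).
#' @return The ratio `ne_from / ne_to`.
#' @examples
#' fold_reduction(45000, 12600)  # 3.6
#' fold_reduction(45000, 2000)   # 22.5
#' @export
fold_reduction <- function(ne_from, ne_to, digits = 1) {
  if (any(ne_from <= 0) || any(ne_to <= 0))
    stop("effective sizes must be > 0", call. = FALSE)
  f <- ne_from / ne_to
  if (!is.null(digits)) round(f, digits) else f
}

#' Migration-band rate conversions
#'
#' A migration band's total rate `m_tot` is the expected number of
#' migration events per lineage over the band's whole coexistence interval
#' (`m * duration`). This converts it to the per-generation rate, the
#' population-scaled number of migrants per generation `4 * Ne * m`, and
#' the probability that a lineage migrates through the band at least once,
#' `1 - exp(-m_tot)`.
#'
#' @param m_tot Total migration rate over the band, `>= 0`.
#' @param band_duration Duration of population coexistence in generations,
#'   `> 0`.
#' @param ne_target Effective size of the receiving population, `>= 0`.
#' @return A list with `m` (per generation), `migrants` (`4*Ne*m`) and
#'   `probability`.
#' @examples
#' migration_convert(1.24, 4000, 1000)
#' @export
migration_convert <- function(m_tot, band_duration, ne_target) {
  if (any(m_tot < 0) || any(ne_target < 0))
    stop("'m_tot' and 'ne_target' must be >= 0", call. = FALSE)
  if (any(band_duration <= 0))
    stop("'band_duration' must be > 0", call. = FALSE)
  m <- m_tot / band_duration
  list(m = m, migrants = 4 * ne_target * m, probability = 1 - exp(-m_tot))
}
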