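#' Seed-bank simulation parameters
#'
#' Parameters of the paired dry/rewetted community generator. The generator
#' draws a lognormal rank-abundance distribution for each experimental pair,
#' suppresses a dormant fraction of taxa to a small residual abundance in the
#' dry state, resuscitates each dormant taxon independently on rewetting with
#' a lognormal growth factor, and observes both states as multinomial reads.
#'
#' Defaults emulate a paired 4-ecosystem x 2-treatment x 3-replicate soil
#' rewetting design in which roughly 70% of the taxa detected after rewetting
#' were below detection in the dry member of the pair.
#'
#' @param n_taxa number of OTUs in the regional pool (>= 2).
#' @param lognormal_mean,lognormal_sd meanlog/sdlog of the lognormal
#'   rank-abundance law of true (latent) abundances.
#' @param dormant_fraction share of taxa inactive in the dry state, in
#'   \[0,1\]. Dormant taxa are suppressed to `dormant_eps` of their latent
#'   abundance, not to exact zero, so "below detection" arises from
#'   multinomial sampling as in real sequencing.
#' @param resuscitation_prob per-dormant-taxon probability of resuscitating
#'   on rewetting, in \[0,1\].
#' @param growth_log_mean,growth_log_sd meanlog offset and sdlog of the
#'   post-resuscitation abundance law. A resuscitated taxon grows to a
#'   fresh lognormal abundance `exp(lognormal_mean + growth_log_mean +
#'   growth_log_sd * z)` — a bloom level set by the rewetting resource
#'   pulse, independent of the taxon's latent dry-state abundance; the
#'   implied growth factor from the suppressed dormant state is itself
#'   lognormal.
#' @param active_turnover_sd sdlog of the multiplicative activity shift of
#'   non-dormant taxa between the dry and rewetted state (mean-preserving;
#'   0 = active taxa keep their abundance exactly).
#' @param seq_depth sequencing reads per sample (>= 1).
#' @param n_ecosystems,n_replicates factorial design dimensions.
#' @param ecosystem_effect_sd sdlog of the lognormal multiplicative
#'   between-ecosystem perturbation of baseline abundances (>= 0).
#' @param dormant_eps residual relative abundance of dormant taxa.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return an object of class `seed_bank_params` (a validated list).
#' @seealso [generate_paired_otu_tables()]
#' @export
seed_bank_params <- function(n_taxa = 2000L,
                             lognormal_mean = 0,
                             lognormal_sd = 2,
                             dormant_fraction = 0.7,
                             resuscitation_prob = 0.5,
                             growth_log_mean = 0.9,
                             growth_log_sd = 1.1,
                             active_turnover_sd = 1.4,
                             seq_depth = 1500L,
                             n_ecosystems = 4L,
                             n_replicates = 3L,
                             ecosystem_effect_sd = 0.6,
                             dormant_eps = 1e-6,
                             seed = 1L) {
  p <- list(
    n_taxa = check_count(n_taxa, "n_taxa", lower = 2L),
    lognormal_mean = check_scalar_number(lognormal_mean, "lognormal_mean"),
    lognormal_sd = check_scalar_number(lognormal_sd, "lognormal_sd", lower = 0),
    dormant_fraction = check_scalar_number(dormant_fraction,
                                           "dormant_fraction", 0, 1),
    resuscitation_prob = check_scalar_number(resuscitation_prob,
                                             "resuscitation_prob", 0, 1),
    growth_log_mean = check_scalar_number(growth_log_mean, "growth_log_mean"),
    growth_log_sd = check_scalar_number(growth_log_sd, "growth_log_sd",
                                        lower = 0),
    active_turnover_sd = check_scalar_number(active_turnover_sd,
                                             "active_turnover_sd", lower = 0),
    seq_depth = check_count(seq_depth, "seq_depth", lower = 1L),
    n_ecosystems = check_count(n_ecosystems, "n_ecosystems"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    ecosystem_effect_sd = check_scalar_number(ecosystem_effect_sd,
                                              "ecosystem_effect_sd", lower = 0),
    dormant_eps = check_scalar_number(dormant_eps, "dormant_eps", lower = 0,
                                      strict_lower = TRUE),
    seed = check_count(seed, "seed", lower = 0L)
  )
  structure(p, class = "seed_bank_params")
}

#' Field sensor simulation parameters
#'
#' Parameters for the generative side of the lagged moisture-to-CO2 pulse
#' model. Soil moisture is a baseline plus instantaneous jumps at rain times
#' that decay exponentially; CO2 is generated by iterating the lagged
#' regression
#' `co2(t) = intercept + beta_lag_co2 * co2(t-1) + beta_moist * moisture(t) +
#' beta_moist_lag * moisture(t-1) + e(t)` with AR(1) innovations
#' `e(t) = ar_rho * e(t-1) + n(t)`.
#'
#' Default slope coefficients (+23292, -3949 ppmv CO2 per m3 H2O m-3 soil)
#' reproduce a field-scale response in which the CO2 pulse tracks the current
#' moisture jump positively and the lagged moisture negatively.
#'
#' @param duration_h,step_h series length and spacing in hours; `step_h`
#'   must divide `duration_h`. The lag equation is defined on the
#'   analysis step, so the default generates directly at 12 h; a finer
#'   `step_h` emulates raw sensor output for exercising
#'   [aggregate_series()], at the cost of the 12-h lag structure no longer
#'   being the exact generative truth.
#' @param rain_times_h times of simulated rain events (hours, within
#'   `[0, duration_h]`).
#' @param rain_magnitude instantaneous moisture jump per event (m3 m-3).
#' @param decay_rate per-hour exponential decay of the moisture jumps.
#' @param moisture_baseline dry-state volumetric moisture (m3 m-3).
#' @param intercept,beta_lag_co2,beta_moist,beta_moist_lag coefficients of
#'   the lagged regression used to generate CO2.
#' @param noise_sd innovation standard deviation (ppmv; 0 = deterministic).
#' @param ar_rho AR(1) coefficient of the residual process, in (-1, 1).
#' @param seed integer seed.
#'
#' @return an object of class `sensor_sim_params`.
#' @seealso [generate_sensor_series()], [fit_pulse_model()]
#' @export
sensor_sim_params <- function(duration_h = 6000,
                              step_h = 12,
                              rain_times_h = c(500, 1500, 2500, 3500, 4500,
                                               5500),
                              rain_magnitude = 0.12,
                              decay_rate = 0.04,
                              moisture_baseline = 0.08,
                              intercept = 500,
                              beta_lag_co2 = 0.8,
                              beta_moist = 23292,
                              beta_moist_lag = -3949,
                              noise_sd = 25,
                              ar_rho = 0.4,
                              seed = 1L) {
  check_scalar_number(duration_h, "duration_h", lower = 0, strict_lower = TRUE)
  check_scalar_number(step_h, "step_h", lower = 0, strict_lower = TRUE)
  n_steps <- duration_h / step_h
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stopf("`step_h` (%g) must divide `duration_h` (%g)", step_h, duration_h)
  if (length(rain_times_h) &&
      (any(rain_times_h < 0) || any(rain_times_h > duration_h)))
    stopf("`rain_times_h` must lie within [0, duration_h]")
  check_scalar_number(ar_rho, "ar_rho", lower = -1, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  p <- list(
    duration_h = duration_h,
    step_h = step_h,
    rain_times_h = as.numeric(rain_times_h),
    rain_magnitude = check_scalar_number(rain_magnitude, "rain_magnitude",
                                         lower = 0),
    decay_rate = check_scalar_number(decay_rate, "decay_rate", lower = 0),
    moisture_baseline = check_scalar_number(moisture_baseline,
                                            "moisture_baseline", lower = 0),
    intercept = check_scalar_number(intercept, "intercept"),
    beta_lag_co2 = check_scalar_number(beta_lag_co2, "beta_lag_co2"),
    beta_moist = check_scalar_number(beta_moist, "beta_moist"),
    beta_moist_lag = check_scalar_number(beta_moist_lag, "beta_moist_lag"),
    noise_sd = check_scalar_number(noise_sd, "noise_sd", lower = 0),
    ar_rho = ar_rho,
    seed = check_count(seed, "seed", lower = 0L)
  )
  structure(p, class = "sensor_sim_params")
}

#' Density-gradient simulation parameters
#'
#' Parameters of the CsTFA buoyant-density gradient generator: 16S copy
#' numbers per fraction follow a Gaussian bump centred at the unlabeled or
#' 18O-labeled peak density, with multiplicative lognormal noise; the density
#' axis is linear in fraction index (fraction 1 densest, as fractions are
#' drawn from the bottom of the tube).
#'
#' Default peak densities (1.5395 and 1.5795 g/mL) are the midpoints of the
#' unlabeled (1.531-1.548) and labeled (1.574-1.585 g/mL) bands typical of
#' 16S qPCR profiles from dry versus heavy-water rewetted soil DNA; the
#' default axis places fractions 12-13 at those unlabeled densities and
#' fractions 9-10 at the labeled ones.
#'
#' @param n_fractions number of collected fractions (default 20).
#' @param fraction_volume_uL volume per fraction (default 235 uL).
#' @param density_top,density_bottom densities (g/mL) of the first and last
#'   fraction; the axis must be strictly monotone (`density_top >
#'   density_bottom` under the bottom-first collection convention).
#' @param peak_density_unlabeled,peak_density_labeled Gaussian peak centres
#'   (g/mL); the labeled peak must be denser than the unlabeled one and lie
#'   on the density axis.
#' @param peak_width Gaussian peak standard deviation (g/mL).
#' @param peak_copies 16S copies at the peak centre (> 0).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (0 = noiseless).
#' @param seed integer seed.
#'
#' @return an object of class `gradient_sim_params`.
#' @seealso [generate_fraction_profiles()], [select_peak_window()]
#' @export
gradient_sim_params <- function(n_fractions = 20L,
                                fraction_volume_uL = 235,
                                density_top = 1.691,
                                density_bottom = 1.444,
                                peak_density_unlabeled = 1.5395,
                                peak_density_labeled = 1.5795,
                                peak_width = 0.01,
                                peak_copies = 1e8,
                                noise_cv = 0.2,
                                seed = 1L) {
  n_fractions <- check_count(n_fractions, "n_fractions", lower = 2L)
  check_scalar_number(density_top, "density_top")
  check_scalar_number(density_bottom, "density_bottom")
  if (density_top == density_bottom)
    stopf("density axis must be strictly monotone")
  lo <- min(density_top, density_bottom)
  hi <- max(density_top, density_bottom)
  check_scalar_number(peak_density_unlabeled, "peak_density_unlabeled")
  check_scalar_number(peak_density_labeled, "peak_density_labeled")
  if (peak_density_labeled <= peak_density_unlabeled)
    stopf("labeled peak density (%g) must exceed unlabeled peak density (%g)",
          peak_density_labeled, peak_density_unlabeled)
  if (peak_density_labeled < lo || peak_density_labeled > hi ||
      peak_density_unlabeled < lo || peak_density_unlabeled > hi)
    stopf("peak densities must lie on the density axis [%g, %g]", lo, hi)
  p <- list(
    n_fractions = n_fractions,
    fraction_volume_uL = check_scalar_number(fraction_volume_uL,
                                             "fraction_volume_uL", lower = 0,
                                             strict_lower = TRUE),
    density_top = density_top,
    density_bottom = density_bottom,
    peak_density_unlabeled = peak_density_unlabeled,
    peak_density_labeled = peak_density_labeled,
    peak_width = check_scalar_number(peak_width, "peak_width", lower = 0,
                                     strict_lower = TRUE),
    peak_copies = check_scalar_number(peak_copies, "peak_copies", lower = 0),
    noise_cv = check_scalar_number(noise_cv, "noise_cv", lower = 0),
    seed = check_count(seed, "seed", lower = 0L)
  )
  structure(p, class = "gradient_sim_params")
}

#' Total recovered gradient volume
#'
#' @param params a [gradient_sim_params()] object.
#' @return total fraction volume in mL (e.g. 20 fractions x 235 uL = 4.7 mL).
#' @export
gradient_volume <- function(params) {
  stopifnot(inherits(params, "gradient_sim_params"))
  params$n_fractions * params$fraction_volume_uL / 1000
}

#' Headspace gas-accumulation simulation parameters
#'
#' Parameters for simulated microcosm headspace time courses sampled every
#' `step_h` hours over `n_increments` intervals (default eight 12-h
#' increments, i.e. a 96-h incubation). Rewetted vials receive a decaying
#' pulse of concentration increments; dry vials only baseline drift.
#' `pulse_amplitude_ppmv` may be negative to emulate net consumption (CH4
#' uptake).
#'
#' @param n_increments number of sampling intervals (>= 1).
#' @param step_h interval length in hours (default 12).
#' @param baseline_ppmv initial headspace concentration.
#' @param pulse_amplitude_ppmv first-interval concentration increment for
#'   rewetted vials (signed).
#' @param pulse_decay per-hour exponential decay of the pulse.
#' @param drift_ppmv per-interval concentration increment common to all
#'   vials (dry-soil background activity).
#' @param noise_sd measurement noise (ppmv).
#' @param headspace_mL,soil_g,temp_C,pressure_atm vial physical constants.
#'   The default headspace, 37.7 mL, is a 40-mL vial minus 3 g of soil at an
#'   assumed packed volume of 2.3 mL.
#' @param seed integer seed.
#'
#' @return an object of class `gas_sim_params`.
#' @seealso [generate_gas_timecourses()], [net_production()]
#' @export
gas_sim_params <- function(n_increments = 8L,
                           step_h = 12,
                           baseline_ppmv = 400,
                           pulse_amplitude_ppmv = 1500,
                           pulse_decay = 0.03,
                           drift_ppmv = 25,
                           noise_sd = 10,
                           headspace_mL = 37.7,
                           soil_g = 3,
                           temp_C = 25,
                           pressure_atm = 1,
                           seed = 1L) {
  p <- list(
    n_increments = check_count(n_increments, "n_increments", lower = 1L),
    step_h = check_scalar_number(step_h, "step_h", lower = 0,
                                 strict_lower = TRUE),
    baseline_ppmv = check_scalar_number(baseline_ppmv, "baseline_ppmv",
                                        lower = 0),
    pulse_amplitude_ppmv = check_scalar_number(pulse_amplitude_ppmv,
                                               "pulse_amplitude_ppmv"),
    pulse_decay = check_scalar_number(pulse_decay, "pulse_decay", lower = 0),
    drift_ppmv = check_scalar_number(drift_ppmv, "drift_ppmv"),
    noise_sd = check_scalar_number(noise_sd, "noise_sd", lower = 0),
    headspace_mL = check_scalar_number(headspace_mL, "headspace_mL",
                                       lower = 0, strict_lower = TRUE),
    soil_g = check_scalar_number(soil_g, "soil_g", lower = 0,
                                 strict_lower = TRUE),
    temp_C = check_scalar_number(temp_C, "temp_C", lower = -273.15,
                                 strict_lower = TRUE),
    pressure_atm = check_scalar_number(pressure_atm, "pressure_atm",
                                       lower = 0, strict_lower = TRUE),
    seed = check_count(seed, "seed", lower = 0L)
  )
  structure(p, class = "gas_sim_params")
}
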