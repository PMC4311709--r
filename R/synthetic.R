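#' Full-factorial experimental design
#'
#' Enumerates experimental units of an ecosystems x treatments x replicates
#' design. Dry/rewetted units of the same (ecosystem, replicate) share a pair
#' id, mirroring the paired microcosm layout (e.g. 4 ecosystems x 2 watering
#' treatments x 3 replicates = 24 samples; 4 x 1 x 3 = 12 composite soils).
#'
#' @param n_ecosystems,n_treatments,n_replicates positive integers.
#' @return data.frame with one row per unit: `unit`, `ecosystem`,
#'   `treatment`, `replicate`, `pair`. Treatments are labelled `dry` and
#'   `rewetted` when `n_treatments == 2`, `T1`, `T2`, ... otherwise.
#' @examples
#' nrow(generate_design(4, 2, 3))  # 24
#' @export
generate_design <- function(n_ecosystems, n_treatments, n_replicates) {
  n_ecosystems <- check_count(n_ecosystems, "n_ecosystems")
  n_treatments <- check_count(n_treatments, "n_treatments")
  n_replicates <- check_count(n_replicates, "n_replicates")
  ecosystems <- paste0("E", seq_len(n_ecosystems))
  treatments <- if (n_treatments == 2L) c("dry", "rewetted")
                else paste0("T", seq_len(n_treatments))
  d <- expand.grid(treatment = treatments,
                   replicate = seq_len(n_replicates),
                   ecosystem = ecosystems,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("ecosystem", "treatment", "replicate")]
  d$pair <- paste(d$ecosystem, d$replicate, sep = ".")
  d$unit <- paste(d$ecosystem, d$treatment, d$replicate, sep = ".")
  rownames(d) <- NULL
  d[, c("unit", "ecosystem", "treatment", "replicate", "pair")]
}

#' Simulate paired dry/rewetted OTU tables with ground truth
#'
#' For each (ecosystem, replicate) pair the generator draws latent lognormal
#' abundances (perturbed multiplicatively per ecosystem), suppresses a
#' dormant subset of taxa to `dormant_eps` of their latent abundance in the
#' dry state, resuscitates each dormant taxon independently with probability
#' `resuscitation_prob` on rewetting (growing it to a fresh lognormal bloom
#' abundance; see [seed_bank_params()]), shifts the abundances of active
#' taxa by a mean-preserving lognormal activity factor, and observes both
#' states as multinomial draws of `seq_depth` reads. A toy four-level
#' taxonomy is attached so that taxonomy-level summaries are exercisable.
#'
#' Random draws use one substream per pair, so adding replicates or
#' ecosystems never perturbs earlier pairs, and resuscitation indicators are
#' drawn as uniforms compared to `resuscitation_prob` (common random
#' numbers: raising the probability with a fixed seed can only add
#' resuscitated taxa).
#'
#' @param params a [seed_bank_params()] object.
#' @return a list with elements:
#'   \describe{
#'     \item{table}{an [otu_table()] with all dry and rewetted samples}
#'     \item{truth}{per-pair ground truth: `dormant` and `resuscitated` OTU
#'       id vectors}
#'     \item{true_abundances}{latent abundance matrix (units x taxa) before
#'       multinomial sampling}
#'   }
#' @export
generate_paired_otu_tables <- function(params) {
  stopifnot(inherits(params, "seed_bank_params"))
  p <- params
  design <- generate_design(p$n_ecosystems, 2L, p$n_replicates)
  otu_ids <- sprintf("OTU%04d", seq_len(p$n_taxa))
  with_seed(p$seed, {
    # community-wide baseline and per-ecosystem perturbations, drawn first
    # from the global stream so they are shared by all pairs
    lambda0 <- stats::rlnorm(p$n_taxa, p$lognormal_mean, p$lognormal_sd)
    eco_fact <- matrix(
      stats::rlnorm(p$n_ecosystems * p$n_taxa, 0, p$ecosystem_effect_sd),
      nrow = p$n_ecosystems)
    # responsiveness is a taxon trait: the same dormant taxa tend to
    # resuscitate in every unit, giving rewetted communities the shared
    # compositional signature seen in real rewetting responses
    propensity <- stats::runif(p$n_taxa)
    taxonomy <- simulate_taxonomy(otu_ids)

    pairs <- unique(design$pair)
    counts <- matrix(0L, nrow = nrow(design), ncol = p$n_taxa,
                     dimnames = list(design$unit, otu_ids))
    true_ab <- matrix(0, nrow = nrow(design), ncol = p$n_taxa,
                      dimnames = list(design$unit, otu_ids))
    truth <- vector("list", length(pairs))
    names(truth) <- pairs

    n_dormant <- round(p$dormant_fraction * p$n_taxa)
    for (i in seq_along(pairs)) {
      pr <- pairs[i]
      eco_i <- match(design$ecosystem[design$pair == pr][1L],
                     paste0("E", seq_len(p$n_ecosystems)))
      rep_i <- design$replicate[design$pair == pr][1L]
      lambda <- lambda0 * eco_fact[eco_i, ]
      # substream keyed by (ecosystem, replicate), not enumeration order,
      # so adding replicates never perturbs existing pairs
      sub <- with_seed(pair_seed(p$seed, eco_i * 1009L + rep_i), {
        dormant <- sort(sample.int(p$n_taxa, n_dormant))
        # post-resuscitation bloom abundances, fresh draws on the latent
        # abundance scale (common random numbers across growth settings)
        bloom <- exp(p$lognormal_mean + p$growth_log_mean +
                       p$growth_log_sd * stats::rnorm(n_dormant))
        activity <- if (p$active_turnover_sd > 0)
          stats::rlnorm(p$n_taxa, -p$active_turnover_sd^2 / 2,
                        p$active_turnover_sd) else rep(1, p$n_taxa)
        dry <- lambda
        dry[dormant] <- lambda[dormant] * p$dormant_eps
        sel <- propensity[dormant] < p$resuscitation_prob
        resus <- dormant[sel]
        rewet <- dry * activity
        rewet[resus] <- bloom[sel]
        dry_counts <- stats::rmultinom(1L, p$seq_depth, dry / sum(dry))[, 1L]
        rewet_counts <-
          stats::rmultinom(1L, p$seq_depth, rewet / sum(rewet))[, 1L]
        list(dormant = dormant, resus = resus, dry = dry, rewet = rewet,
             dry_counts = dry_counts, rewet_counts = rewet_counts)
      })
      dry_unit <- design$unit[design$pair == pr & design$treatment == "dry"]
      rew_unit <- design$unit[design$pair == pr &
                                design$treatment == "rewetted"]
      counts[dry_unit, ] <- sub$dry_counts
      counts[rew_unit, ] <- sub$rewet_counts
      true_ab[dry_unit, ] <- sub$dry
      true_ab[rew_unit, ] <- sub$rewet
      truth[[pr]] <- list(dormant = otu_ids[sub$dormant],
                          resuscitated = otu_ids[sub$resus])
    }
    md <- design[, c("unit", "ecosystem", "treatment", "replicate", "pair")]
    names(md)[1L] <- "sample"
    list(table = otu_table(counts, md, taxonomy),
         truth = truth,
         true_abundances = true_ab)
  })
}

# Toy lineage: phyla/classes/orders/families assigned cyclically so that
# every level has a handful of groups. Not meant to mimic real clades.
simulate_taxonomy <- function(otu_ids) {
  n <- length(otu_ids)
  phyla <- c("Proteobacteria", "Actinobacteria", "Acidobacteria",
             "Gemmatimonadetes", "Bacteroidetes")
  classes <- c("Alphaproteobacteria", "Betaproteobacteria",
               "Gammaproteobacteria")
  families <- c("Sphingomonadaceae", "Comamonadaceae", "Oxalobacteraceae",
                "Methylocystaceae", "Micrococcaceae", "Chitinophagaceae")
  ph <- phyla[(seq_len(n) - 1L) %% length(phyla) + 1L]
  cl <- ifelse(ph == "Proteobacteria",
               classes[(seq_len(n) - 1L) %% length(classes) + 1L],
               paste0(ph, "_class"))
  or <- paste0(cl, "_order")
  fa <- families[(seq_len(n) - 1L) %% length(families) + 1L]
  stats::setNames(paste(ph, cl, or, fa, sep = ";"), otu_ids)
}

#' Simulate a field sensor series driven by moisture pulses
#'
#' Moisture is `moisture_baseline` plus an instantaneous jump of
#' `rain_magnitude` at each rain time, decaying exponentially at
#' `decay_rate` per hour. CO2 is generated by iterating the lagged pulse
#' regression (see [sensor_sim_params()]) from its fixed point at baseline
#' moisture, with AR(1) innovations.
#'
#' @param params a [sensor_sim_params()] object.
#' @return a list with `series` (a [sensor_series()]) and `coefficients`
#'   (named vector of the generating intercept, co2_lag, moisture and
#'   moisture_lag coefficients).
#' @export
generate_sensor_series <- function(params) {
  stopifnot(inherits(params, "sensor_sim_params"))
  p <- params
  time_h <- seq(0, p$duration_h, by = p$step_h)
  n <- length(time_h)
  moist <- rep(p$moisture_baseline, n)
  for (rt in p$rain_times_h) {
    after <- time_h >= rt
    moist[after] <- moist[after] +
      p$rain_magnitude * exp(-p$decay_rate * (time_h[after] - rt))
  }
  with_seed(p$seed, {
    innov <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)
    eps <- numeric(n)
    for (t in 2:n) eps[t] <- p$ar_rho * eps[t - 1L] + innov[t]
    co2 <- numeric(n)
    # start at the deterministic fixed point under baseline moisture
    co2[1L] <- (p$intercept +
                  (p$beta_moist + p$beta_moist_lag) * p$moisture_baseline) /
      (1 - p$beta_lag_co2)
    for (t in 2:n) {
      co2[t] <- p$intercept + p$beta_lag_co2 * co2[t - 1L] +
        p$beta_moist * moist[t] + p$beta_moist_lag * moist[t - 1L] + eps[t]
    }
    temp <- 20 + 5 * sin(2 * pi * time_h / 24)
    list(series = sensor_series(time_h, moist, co2, temp),
         coefficients = c(intercept = p$intercept,
                          co2_lag = p$beta_lag_co2,
                          moisture = p$beta_moist,
                          moisture_lag = p$beta_moist_lag))
  })
}

#' Simulate a qPCR-across-fractions gradient profile
#'
#' 16S copies per fraction follow a Gaussian bump centred at the unlabeled
#' (`labeled = FALSE`) or 18O-labeled (`labeled = TRUE`) peak density, with
#' multiplicative lognormal noise of coefficient of variation `noise_cv`.
#' Densities are linear in fraction index from `density_top` (fraction 1,
#' bottom of the tube) to `density_bottom`.
#'
#' @param params a [gradient_sim_params()] object.
#' @param labeled logical; simulate the 18O-labeled (rewetted) profile?
#' @param unit optional unit id attached to the profile.
#' @return a [fraction_profile()].
#' @export
generate_fraction_profiles <- function(params, labeled = FALSE,
                                       unit = "sim") {
  stopifnot(inherits(params, "gradient_sim_params"))
  p <- params
  dens <- seq(p$density_top, p$density_bottom, length.out = p$n_fractions)
  mu <- if (labeled) p$peak_density_labeled else p$peak_density_unlabeled
  copies <- p$peak_copies * exp(-(dens - mu)^2 / (2 * p$peak_width^2))
  if (p$noise_cv > 0) {
    sdlog <- sqrt(log(1 + p$noise_cv^2))
    copies <- with_seed(p$seed + as.integer(labeled), {
      copies * stats::rlnorm(p$n_fractions, -sdlog^2 / 2, sdlog)
    })
  }
  fraction_profile(seq_len(p$n_fractions), dens, copies,
                   label = if (labeled) "rewetted" else "dry", unit = unit)
}

#' Simulate microcosm headspace gas time courses
#'
#' Rewetted vials accumulate a decaying concentration pulse
#' (`pulse_amplitude_ppmv * exp(-pulse_decay * t)` added per interval) on top
#' of a common linear drift; dry vials receive the drift only. Negative
#' amplitudes model net consumption (e.g. CH4 uptake by rewetted soil).
#' Concentrations are clamped at zero.
#'
#' @param params a [gas_sim_params()] object.
#' @param design unit descriptors from [generate_design()]; each row yields
#'   one time course.
#' @param species gas species label (`"CO2"`, `"CH4"` or `"N2O"`).
#' @return a list of [gas_timecourse()] objects, one per design row.
#' @export
generate_gas_timecourses <- function(params, design, species = "CO2") {
  stopifnot(inherits(params, "gas_sim_params"))
  p <- params
  times <- seq(0, by = p$step_h, length.out = p$n_increments + 1L)
  with_seed(p$seed, {
    lapply(seq_len(nrow(design)), function(i) {
      rewet <- design$treatment[i] == "rewetted"
      inc <- rep(p$drift_ppmv, p$n_increments)
      if (rewet)
        inc <- inc + p$pulse_amplitude_ppmv *
          exp(-p$pulse_decay * times[-length(times)])
      conc <- p$baseline_ppmv + c(0, cumsum(inc))
      if (p$noise_sd > 0)
        conc <- conc + stats::rnorm(length(conc), 0, p$noise_sd)
      conc <- pmax(conc, 0)
      gas_timecourse(times, conc,
                     unit = design$unit[i],
                     ecosystem = design$ecosystem[i],
                     treatment = design$treatment[i],
                     species = species,
                     soil_g = p$soil_g, headspace_mL = p$headspace_mL,
                     temp_C = p$temp_C, pressure_atm = p$pressure_atm)
    })
  })
}
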