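test_that("generate_design enumerates the full factorial with shared pair ids", {
  d <- generate_design(4, 2, 3)
  expect_equal(nrow(d), 24)
  expect_equal(nrow(generate_design(1, 1, 1)), 1)
  expect_equal(nrow(generate_design(4, 1, 3)), 12)
  # dry/rewetted members of one (ecosystem, replicate) share a pair id
  byp <- split(d, d$pair)
  expect_true(all(vapply(byp, nrow, integer(1)) == 2))
  expect_true(all(vapply(byp, function(g)
    setequal(g$treatment, c("dry", "rewetted")), logical(1))))
  expect_error(generate_design(0, 2, 3), "integer")
})

test_that("paired OTU tables: multinomial depth, determinism, ground truth containment", {
  p <- seed_bank_params(n_taxa = 300, seq_depth = 400, n_ecosystems = 2,
                        n_replicates = 2, seed = 7)
  sim <- generate_paired_otu_tables(p)
  expect_s3_class(sim$table, "otu_table")
  expect_equal(unname(sample_totals(sim$table)),
               rep(400L, 8))
  # identical seed -> bit-identical output
  sim2 <- generate_paired_otu_tables(p)
  expect_identical(sim$table$counts, sim2$table$counts)
  # resuscitated subset of dormant, per pair
  for (tr in sim$truth)
    expect_true(all(tr$resuscitated %in% tr$dormant))
  # adding replicates does not perturb earlier pairs
  p3 <- seed_bank_params(n_taxa = 300, seq_depth = 400, n_ecosystems = 2,
                         n_replicates = 3, seed = 7)
  sim3 <- generate_paired_otu_tables(p3)
  shared_units <- rownames(sim$table$counts)
  expect_identical(sim3$table$counts[shared_units, ],
                   sim$table$counts[shared_units, ])
})

test_that("expected resuscitation count is monotone in resuscitation_prob", {
  count_resus <- function(prob) {
    p <- seed_bank_params(n_taxa = 200, seq_depth = 200, n_ecosystems = 1,
                          n_replicates = 2, resuscitation_prob = prob,
                          seed = 11)
    sum(lengths(lapply(generate_paired_otu_tables(p)$truth,
                       `[[`, "resuscitated")))
  }
  ns <- vapply(c(0, 0.25, 0.5, 0.75, 1), count_resus, numeric(1))
  expect_true(all(diff(ns) >= 0))
  expect_equal(ns[1], 0)
  # prob = 1 resuscitates every dormant taxon
  p1 <- seed_bank_params(n_taxa = 200, seq_depth = 200, n_ecosystems = 1,
                         n_replicates = 2, resuscitation_prob = 1, seed = 11)
  tr <- generate_paired_otu_tables(p1)$truth
  for (t in tr) expect_setequal(t$resuscitated, t$dormant)
})

test_that("default seed-bank parameters yield a rare-responder majority", {
  # 20-seed Monte-Carlo mean of the rare-responder OTU fraction under the
  # documented defaults; band frozen from a one-off calibration run
  vals <- vapply(1:20, function(sd) {
    p <- seed_bank_params(n_ecosystems = 1, n_replicates = 1, seed = sd)
    sim <- generate_paired_otu_tables(p)
    pr <- pairs_from_table(sim$table, seed = sd)[[1]]
    rare_fractions(pr)$rare_otu_fraction
  }, numeric(1))
  expect_gt(mean(vals), 0.66)
  expect_lt(mean(vals), 0.82)
})

test_that("sensor series: fixed point, determinism, moisture pulses", {
  # no rain, no noise: CO2 sits at the fixed point of the lag equation
  p0 <- sensor_sim_params(duration_h = 240, step_h = 12, rain_times_h = numeric(0),
                          noise_sd = 0, seed = 1)
  s0 <- generate_sensor_series(p0)
  fp <- (p0$intercept + (p0$beta_moist + p0$beta_moist_lag) *
           p0$moisture_baseline) / (1 - p0$beta_lag_co2)
  expect_equal(s0$series$co2, rep(fp, nrow(s0$series)), tolerance = 1e-10)
  expect_equal(s0$series$moisture, rep(p0$moisture_baseline, nrow(s0$series)))
  # same seed -> identical series
  p <- sensor_sim_params(seed = 5)
  expect_identical(generate_sensor_series(p)$series,
                   generate_sensor_series(p)$series)
  # rain events raise moisture by the jump magnitude, then decay
  p1 <- sensor_sim_params(duration_h = 48, step_h = 1, rain_times_h = 10,
                          noise_sd = 0, seed = 1)
  m <- generate_sensor_series(p1)$series$moisture
  expect_equal(m[11], p1$moisture_baseline + p1$rain_magnitude)
  expect_true(all(diff(m[11:49]) < 0))
  expect_error(sensor_sim_params(ar_rho = 1), "ar_rho")
  expect_error(sensor_sim_params(duration_h = 10, step_h = 3), "divide")
})

test_that("fraction profiles peak at the right density and honor noise_cv = 0", {
  g <- gradient_sim_params(noise_cv = 0)
  un <- generate_fraction_profiles(g, labeled = FALSE)
  la <- generate_fraction_profiles(g, labeled = TRUE)
  # argmax fraction is the one whose density is nearest the band midpoint
  expect_equal(un$fraction[which.max(un$copies)],
               un$fraction[which.min(abs(un$density - 1.5395))])
  expect_equal(la$fraction[which.max(la$copies)],
               la$fraction[which.min(abs(la$density - 1.5795))])
  # labeled peak is denser
  expect_gt(la$density[which.max(la$copies)],
            un$density[which.max(un$copies)])
  # flat profile (no DNA) breaks peak selection downstream
  g0 <- gradient_sim_params(noise_cv = 0, peak_copies = 0)
  flat <- generate_fraction_profiles(g0)
  expect_error(select_peak_window(flat, 2), "no peak")
  expect_error(gradient_sim_params(peak_density_labeled = 1.5,
                                   peak_density_unlabeled = 1.55),
               "exceed")
})

test_that("gas time courses: null amplitude, sign control, determinism", {
  design <- generate_design(1, 2, 1)
  # amplitude 0, no noise: dry and rewetted identical
  p0 <- gas_sim_params(pulse_amplitude_ppmv = 0, noise_sd = 0)
  tcs <- generate_gas_timecourses(p0, design)
  expect_equal(tcs[[1]]$conc_ppmv, tcs[[2]]$conc_ppmv)
  # negative amplitude (consumption) -> negative rewetted net production
  pn <- gas_sim_params(pulse_amplitude_ppmv = -40, drift_ppmv = 0,
                       noise_sd = 0, baseline_ppmv = 400)
  tcs_n <- generate_gas_timecourses(pn, design, species = "CH4")
  rew <- tcs_n[[which(design$treatment == "rewetted")]]
  expect_true(all(diff(rew$conc_ppmv) < 0))
  expect_lt(net_production(rew)$value, 0)
  # determinism
  pg <- gas_sim_params(seed = 3)
  expect_identical(generate_gas_timecourses(pg, design),
                   generate_gas_timecourses(pg, design))
})
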