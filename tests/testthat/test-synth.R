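# Small-scale generator settings reused across tests.
tiny_axis <- seq(100, 3400, length.out = 400)

test_that("component libraries are reproducible and structured as requested", {
  l1 <- make_component_library(seed = 5, axis = tiny_axis)
  l2 <- make_component_library(seed = 5, axis = tiny_axis)
  expect_identical(l1$profiles, l2$profiles)
  expect_equal(nrow(l1$profiles), 7L)
  expect_true(all(l1$profiles >= 0))
  l3 <- make_component_library(seed = 6, axis = tiny_axis)
  expect_false(identical(l1$profiles, l3$profiles))
})

test_that("glutamine and glutamate are confusable, glucose and lactate are not", {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  ok_pair <- 0; ok_dist <- 0
  for (seed in 1:10) {
    lib <- make_component_library(seed = seed, axis = tiny_axis)
    ok_pair <- ok_pair + (cosine(lib$profiles["glutamine", ],
                                 lib$profiles["glutamate", ]) >= 0.7)
    ok_dist <- ok_dist + (cosine(lib$profiles["glucose", ],
                                 lib$profiles["lactate", ]) < 0.5)
  }
  expect_gte(ok_pair, 9)
  expect_gte(ok_dist, 9)
})

test_that("noiseless reference tables equal the trajectory at sampling times", {
  b <- make_batch(seed = 1, meas_noise = 0, days = 6)
  obs <- observables(b$trajectory)
  expect_equal(b$refs$glucose,
               approx(obs$time, obs$glucose, b$refs$timestamp / 3600)$y,
               tolerance = 1e-12)
  expect_equal(b$refs$vcc,
               approx(obs$time, obs$X_V, b$refs$timestamp / 3600)$y,
               tolerance = 1e-12)
  expect_true(all(b$refs$tcc >= b$refs$vcc))
})

test_that("measurement noise does not perturb the underlying trajectory", {
  b1 <- make_batch(seed = 1, days = 5)
  b2 <- make_batch(seed = 2, days = 5)
  expect_identical(b1$trajectory$states, b2$trajectory$states)
  expect_false(identical(b1$refs$glucose, b2$refs$glucose))
})

test_that("daily-bolus feeding produces the sawtooth glucose profile", {
  # a fixed daily bolus schedule: one upward jump per dosing event
  traj <- simulate_batch(kinetic_state(Glc0 = 6), cho_batch_params(),
                         daily_bolus_schedule(days = 14), t_end = 336)
  obs <- observables(traj)
  expect_equal(sum(diff(obs$glucose) > 0.1), 14L)
  # operator-style top-up dosing from the setpoint: daily sawtooth
  b <- make_batch(seed = 1, meas_noise = 0,
                  state0 = kinetic_state(Glc0 = 6))
  obs2 <- observables(b$trajectory)
  jumps <- diff(obs2$glucose)
  expect_gte(sum(jumps > 1e-9), 12)
  # between doses glucose only declines: negative day-scale differences
  expect_gt(sum(jumps < 0), 10 * sum(jumps > 1e-9))
})

test_that("spectra are linear in concentration when nuisances are off", {
  lib <- make_component_library(seed = 2, analytes = "glucose",
                                axis = tiny_axis, medium_strength = 0,
                                n_interferents = 0)
  p <- kinetic_params(k_G1S = 0, k_SG2M = 0, k_G2MG1 = 0, k_G1G0 = 0,
                      k_d = 0, Q_Gln = 0, K_deg = 0, Q_Glc = 0, m_Glc = 0,
                      q_G1G0 = 0, q_S = 0, q_G2M = 0)
  tr1 <- simulate_batch(kinetic_state(X_V0 = 0, Glc0 = 2), p, t_end = 24)
  tr2 <- simulate_batch(kinetic_state(X_V0 = 0, Glc0 = 4), p, t_end = 24)
  s1 <- make_spectra(tr1, lib, nuisance_off(), every_s = 7200, seed = 3)
  s2 <- make_spectra(tr2, lib, nuisance_off(), every_s = 7200, seed = 3)
  # constant concentration: identical rows (up to the tiny noise floor)
  expect_lt(max(abs(sweep(s1$spectra$intensities, 2,
                          s1$spectra$intensities[1, ]))), 1e-9)
  # doubled concentration doubles the spectrum
  expect_equal(s2$spectra$intensities[1, ], 2 * s1$spectra$intensities[1, ],
               tolerance = 1e-6)
})

test_that("half-hourly acquisition over 14 days yields 672 spectra", {
  lib <- make_component_library(seed = 2, axis = tiny_axis)
  b <- make_batch(seed = 1, meas_noise = 0)
  sp <- make_spectra(b$trajectory, lib, nuisance_off(), every_s = 1800,
                     seed = 1, extras = b$extras)
  expect_equal(nrow(sp$spectra$intensities), 14L * 48L)
})

test_that("the paired benchmark has the advertised shape and truth labels", {
  bm <- make_paired_benchmark(seed = 11, n_batches = 2, days = 6,
                              n_channels = 300, every_s = 7200)
  expect_equal(nrow(bm$refs), 2L * 6L * 2L)       # 2 refs/day, 2 batches
  expect_length(bm$batches, 2L)
  expect_true(all(bm$outliers %in% bm$spectra$ids))
  expect_gte(length(bm$outliers), 2L)
  bm2 <- make_paired_benchmark(seed = 11, n_batches = 2, days = 6,
                               n_channels = 300, every_s = 7200)
  expect_identical(bm$spectra$intensities, bm2$spectra$intensities)
  expect_identical(bm$outliers, bm2$outliers)
  # batches are far apart in time, so cross-batch pairing cannot occur
  expect_gt(min(diff(sort(bm$refs$timestamp))) >= 0, 0)
})

test_that("an oracle linear model on clean spectra explains the response exactly", {
  bm <- make_paired_benchmark(seed = 12, n_batches = 2, days = 8,
                              n_channels = 300, every_s = 3600,
                              meas_noise = 0, nuisance = nuisance_off(),
                              paired_outlier_rate = 0)
  prep <- preprocess_spectra(bm$spectra)
  ds <- pair_by_time(prep, bm$refs, "glucose", 1800)
  sp <- split_train_validation(ds, 0.8, seed = 1)
  fit <- pls_train(sp$train$X, sp$train$y, A = 10)
  expect_gt(r2(sp$validation$y, predict(fit, sp$validation$X)), 0.999)
})
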