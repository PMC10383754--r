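test_that("growth rate follows the doubling-time formula", {
  expect_equal(growth_rate(10, 5, 5), log(2) / 20, tolerance = 1e-12)
  expect_equal(growth_rate(20, 10, 10), growth_rate(10, 5, 5) / 2)
  expect_lt(growth_rate(1e6, 1e6, 1e6), 1e-6)
  expect_error(growth_rate(0, 5, 5), "> 0")
})

test_that("the derivative field vanishes at the trivial equilibrium", {
  p <- kinetic_params(k_G1S = 0, k_SG2M = 0, k_G2MG1 = 0, k_G1G0 = 0,
                      k_d = 0, Q_Gln = 0, K_deg = 0, Q_Glc = 0, m_Glc = 0,
                      q_G1G0 = 0, q_S = 0, q_G2M = 0)
  s <- kinetic_state()
  d <- cho_derivatives(s, p)
  expect_equal(unname(d), rep(0, 10))
})

test_that("mitosis doubles cells into G1 while G2/M loses one", {
  p <- kinetic_params(k_G1S = 0, k_SG2M = 0, k_G2MG1 = 0.2, k_G1G0 = 0,
                      k_d = 0, Q_Gln = 0, K_deg = 0, Q_Glc = 0, m_Glc = 0,
                      q_G1G0 = 0, q_S = 0, q_G2M = 0)
  s <- kinetic_state(X_V0 = 1, phase_fractions = c(G0 = 0, G1 = 0, S = 0,
                                                   G2M = 1))
  d <- cho_derivatives(s, p)
  expect_equal(d[["N_G1"]], 2 * 0.2 * s[["N_G2M"]])
  expect_equal(d[["N_G2M"]], -0.2 * s[["N_G2M"]])
  # net cell gain is one new cell per division
  expect_equal(sum(d[c("N_G0", "N_G1", "N_S", "N_G2M")]),
               0.2 * s[["N_G2M"]])
})

test_that("glutamine loss balances ammonia gain when the yield is unit-consistent", {
  p <- kinetic_params(Y_Amn = 1)
  s <- kinetic_state(X_V0 = 2, Gln0 = 1.5)
  d <- cho_derivatives(s, p, feeds = c(F_Glc = 0, F_Gln = 0, F_OUT = 0))
  expect_equal(d[["A_Gln"]] + d[["A_Amn"]], 0, tolerance = 1e-12)
})

test_that("total-cell balance: with no death or outflow, growth comes only from mitosis", {
  p <- kinetic_params(k_d = 0, Q_Gln = 0, K_deg = 0, Q_Glc = 0, m_Glc = 0)
  s0 <- kinetic_state(X_V0 = 1)
  traj <- simulate_batch(s0, p, t_end = 48, dt_out = 0.5)
  N <- rowSums(traj$states[, c("N_G0", "N_G1", "N_S", "N_G2M")])
  dN_num <- diff(N) / diff(traj$times)
  dN_model <- p$k_G2MG1 * traj$states[, "N_G2M"]
  mid <- (head(dN_model, -1) + tail(dN_model, -1)) / 2
  expect_equal(dN_num, mid, tolerance = 1e-3)
})

test_that("glutamine decays exponentially in a cell-free reactor", {
  p <- kinetic_params(K_deg = 0.01)
  s0 <- kinetic_state(X_V0 = 0, Gln0 = 2)
  traj <- simulate_batch(s0, p, t_end = 100)
  gln <- traj$states[, "A_Gln"]
  expect_equal(gln / gln[1], exp(-0.01 * traj$times), tolerance = 1e-6)
})

test_that("volume integrates feed rates exactly", {
  sch <- feed_schedule(rates = data.frame(time = 0, F_Glc = 0.001,
                                          F_Gln = 0, F_OUT = 0))
  traj <- simulate_batch(kinetic_state(), kinetic_params(), sch, t_end = 100)
  expect_equal(traj$states[nrow(traj$states), "V"],
               c(V = 8 + 0.1), tolerance = 1e-10)
})

test_that("lactate plus yield-weighted glucose is conserved without feeds or G0 cells", {
  # all G1 efflux continues to S (m_stress = 1) and the G1->G0 leak is off,
  # so the G0 maintenance pathway never engages
  p <- kinetic_params(m_stress = 1, k_G1G0 = 0, Q_Gln = 0, K_deg = 0)
  s0 <- kinetic_state(X_V0 = 1, phase_fractions = c(G0 = 0, G1 = 0.5,
                                                    S = 0.3, G2M = 0.2))
  traj <- simulate_batch(s0, p, t_end = 60)
  inv <- traj$states[, "A_Lac"] + p$Y_Lac * traj$states[, "A_Glc"]
  expect_equal(inv / inv[1], rep(1, length(inv)), tolerance = 1e-6)
})

test_that("boluses and samples apply as instantaneous amount/volume jumps", {
  p <- kinetic_params()
  sch <- feed_schedule(
    boluses = data.frame(time = 10, volume = 0.05, feed = "glucose"),
    samples = data.frame(time = 20, volume = 0.4))
  s0 <- kinetic_state(X_V0 = 0, Glc0 = 5)   # cell-free: glucose inert
  traj <- simulate_batch(s0, p, sch, t_end = 30)
  i10 <- which(traj$times == 10); i20 <- which(traj$times == 20)
  expect_equal(traj$states[i10, "V"], c(V = 8.05))
  expect_equal(traj$states[i10, "A_Glc"],
               c(A_Glc = 5 * 8 + 0.05 * p$Glc_feed))
  # sampling preserves concentrations
  conc_before <- traj$states[i20 - 1, "A_Glc"] / traj$states[i20 - 1, "V"]
  conc_after <- traj$states[i20, "A_Glc"] / traj$states[i20, "V"]
  expect_equal(unname(conc_after), unname(conc_before), tolerance = 1e-9)
  expect_equal(traj$states[i20, "V"], c(V = 8.05 - 0.4))
})

test_that("simultaneous boluses commute", {
  p <- kinetic_params()
  b1 <- data.frame(time = c(10, 10), volume = c(0.05, 0.02),
                   feed = c("glucose", "glutamine"))
  b2 <- b1[2:1, ]
  t1 <- simulate_batch(kinetic_state(), p, feed_schedule(boluses = b1),
                       t_end = 20)
  t2 <- simulate_batch(kinetic_state(), p, feed_schedule(boluses = b2),
                       t_end = 20)
  expect_equal(t1$states[nrow(t1$states), ], t2$states[nrow(t2$states), ],
               tolerance = 1e-10)
})

test_that("halving solver tolerances barely moves the endpoint", {
  p <- cho_batch_params()
  s0 <- kinetic_state()
  a <- simulate_batch(s0, p, t_end = 72, rtol = 1e-8, atol = 1e-10)
  b <- simulate_batch(s0, p, t_end = 72, rtol = 5e-9, atol = 5e-11)
  ea <- a$states[nrow(a$states), ]
  eb <- b$states[nrow(b$states), ]
  expect_lt(max(abs(ea - eb) / pmax(abs(ea), 1e-6)), 1e-6)
})

test_that("observables recompute exactly from the states", {
  p <- cho_batch_params()
  traj <- simulate_batch(kinetic_state(), p, t_end = 48)
  obs <- observables(traj)
  N <- rowSums(traj$states[, c("N_G0", "N_G1", "N_S", "N_G2M")])
  expect_equal(obs$X_V * obs$V, N, tolerance = 1e-12)
  expect_equal(obs$glucose * obs$V, unname(traj$states[, "A_Glc"]),
               tolerance = 1e-12)
  s_eq <- kinetic_state(X_V0 = 1, phase_fractions = c(G0 = 1, G1 = 1,
                                                      S = 1, G2M = 1))
  d <- observables(structure(list(times = 0,
                                  states = matrix(unclass(s_eq), 1,
                                                  dimnames = list(NULL, names(s_eq))),
                                  params = p), class = "cho_trajectory"))
  expect_equal(d$f_G0, 0.25)
})

test_that("parameter and state validation rejects impossible values", {
  expect_error(kinetic_params(k_d = -1), ">= 0")
  expect_error(kinetic_params(m_stress = 1.5), "m_stress")
  expect_error(kinetic_state(V = 0), "V must be > 0")
  expect_error(simulate_batch(kinetic_state(), kinetic_params(), t_end = -1),
               "t_end")
})
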