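#' Kinetic parameters of the fed-batch CHO cell-cycle model
#'
#' Parameter set for a four-compartment cell-cycle model (G0, G1, S,
#' G2/M) of a fed-batch CHO culture with glucose, glutamine, lactate,
#' ammonium and monoclonal-antibody (mAb) balances.
#'
#' Internal units: time h; volume L; cell amounts in 1e9 cells (so that
#' cell amount / volume is directly 1e6 cells/mL); glucose, glutamine,
#' lactate and mAb amounts in g; ammonium in mmol.
#'
#' Cell-cycle transition rates default to `ln(2) / t_phase` for the
#' corresponding phase duration, consistent with the doubling-time growth
#' rate `growth_rate()`; they can also be set freely. The transition G1
#' -> G0 (`k_G1G0`) represents temperature stress, and a fraction
#' `1 - m_stress` of the G1 -> S flux is diverted to G0 by metabolic
#' stress. Optional multiplicative modifier hooks (all default to a
#' constant 1) expose the dependencies that are process-specific:
#' `f_upt(gln)` limits glutamine uptake, `f_temp(t)` scales `k_G1G0`
#' (e.g. a temperature downshift arresting cells in G0), and
#' `f_inh(lac)` inhibits glucose uptake by lactate.
#'
#' @param t_G1,t_S,t_G2M Phase completion times (h).
#' @param k_G1S,k_SG2M,k_G2MG1 Cycle transition rates (1/h); default
#'   `ln(2)/t_phase` of the originating phase.
#' @param k_G1G0 G1 -> G0 transition rate (1/h, temperature stress).
#' @param k_d First-order death rate (1/h).
#' @param m_stress Fraction of the G1 efflux continuing to S (0-1).
#' @param Q_Gln Specific glutamine uptake (g / (1e9 cells * h)).
#' @param K_deg First-order glutamine degradation to ammonia (1/h).
#' @param Y_Amn Ammonia yield on consumed/degraded glutamine (mmol/g).
#' @param Q_Glc Specific glucose uptake of cycling cells
#'   (g / (1e9 cells * h)).
#' @param m_Glc Maintenance glucose uptake of quiescent (G0) cells
#'   (g / (1e9 cells * h)).
#' @param Y_Lac Lactate yield on consumed glucose (g/g).
#' @param Glc_feed,Gln_feed Feed concentrations (g/L).
#' @param q_G1G0,q_S,q_G2M Phase-specific mAb productivities
#'   (g / (1e9 cells)); the production term is scaled by the growth rate.
#' @param f_upt,f_temp,f_inh Optional modifier hooks (functions returning
#'   a multiplier; `NULL` = 1).
#' @return Named list of class `kinetic_params`.
#' @export
kinetic_params <- function(t_G1 = 11, t_S = 8, t_G2M = 3,
                           k_G1S = log(2) / t_G1,
                           k_SG2M = log(2) / t_S,
                           k_G2MG1 = log(2) / t_G2M,
                           k_G1G0 = 0.010, k_d = 0.004, m_stress = 0.90,
                           Q_Gln = 0.0015, K_deg = 0.0048, Y_Amn = 6.8,
                           Q_Glc = 0.015, m_Glc = 0.004, Y_Lac = 0.4,
                           Glc_feed = 400, Gln_feed = 40,
                           q_G1G0 = 0.010, q_S = 0.020, q_G2M = 0.015,
                           f_upt = NULL, f_temp = NULL, f_inh = NULL) {
  p <- list(t_G1 = t_G1, t_S = t_S, t_G2M = t_G2M,
            k_G1S = k_G1S, k_SG2M = k_SG2M, k_G2MG1 = k_G2MG1,
            k_G1G0 = k_G1G0, k_d = k_d, m_stress = m_stress,
            Q_Gln = Q_Gln, K_deg = K_deg, Y_Amn = Y_Amn,
            Q_Glc = Q_Glc, m_Glc = m_Glc, Y_Lac = Y_Lac,
            Glc_feed = Glc_feed, Gln_feed = Gln_feed,
            q_G1G0 = q_G1G0, q_S = q_S, q_G2M = q_G2M,
            f_upt = f_upt, f_temp = f_temp, f_inh = f_inh)
  num <- p[!names(p) %in% c("f_upt", "f_temp", "f_inh")]
  if (any(unlist(num) < 0)) stop("kinetic_params: rates/yields must be >= 0")
  if (m_stress < 0 || m_stress > 1) stop("kinetic_params: m_stress in [0,1]")
  if (any(c(t_G1, t_S, t_G2M) <= 0)) stop("kinetic_params: durations > 0")
  structure(p, class = "kinetic_params")
}

#' Initial state of the fed-batch model (amount form)
#'
#' State variables are amounts (concentration x volume): cell-cycle
#' compartments `N_G0`, `N_G1`, `N_S`, `N_G2M` (1e9 cells), volume `V`
#' (L), glutamine `A_Gln` (g), ammonium `A_Amn` (mmol), glucose `A_Glc`
#' (g), lactate `A_Lac` (g) and antibody `A_mAb` (g). The printed
#' balances are time-derivatives of concentration-times-volume products,
#' so the amount form is their literal transcription and sidesteps
#' quotient-rule bookkeeping; concentrations are derived views
#' ([observables()]).
#'
#' @param V Start volume (L).
#' @param X_V0 Start viable cell concentration (1e6 cells/mL).
#' @param phase_fractions Start split over (G0, G1, S, G2M).
#' @param Glc0,Gln0,Lac0 Start concentrations (g/L).
#' @param Amn0 Start ammonium concentration (mmol/L).
#' @param mAb0 Start antibody concentration (g/L).
#' @return Named numeric state vector of class `kinetic_state`.
#' @export
kinetic_state <- function(V = 8, X_V0 = 0.5,
                          phase_fractions = c(G0 = 0, G1 = 0.5, S = 0.3,
                                              G2M = 0.2),
                          Glc0 = 10, Gln0 = 1.5, Lac0 = 0, Amn0 = 0,
                          mAb0 = 0) {
  if (V <= 0) stop("kinetic_state: V must be > 0")
  pf <- phase_fractions / sum(phase_fractions)
  n <- X_V0 * V
  s <- c(N_G0 = n * pf[["G0"]], N_G1 = n * pf[["G1"]],
         N_S = n * pf[["S"]], N_G2M = n * pf[["G2M"]],
         V = V, A_Gln = Gln0 * V, A_Amn = Amn0 * V,
         A_Glc = Glc0 * V, A_Lac = Lac0 * V, A_mAb = mAb0 * V)
  if (any(s < 0)) stop("kinetic_state: amounts must be >= 0")
  structure(s, class = c("kinetic_state", "numeric"))
}

#' Doubling-time growth rate from phase durations
#'
#' `mu = ln(2) / (t_G1 + t_S + t_G2M)`: the specific growth rate implied
#' by the total time a cell needs to traverse the proliferative phases.
#'
#' @param t_G1,t_S,t_G2M Phase completion times (h), all > 0.
#' @return Growth rate (1/h).
#' @export
growth_rate <- function(t_G1, t_S, t_G2M) {
  if (any(c(t_G1, t_S, t_G2M) <= 0)) stop("growth_rate: durations must be > 0")
  log(2) / (t_G1 + t_S + t_G2M)
}

hook <- function(f, ...) if (is.null(f)) 1 else f(...)

#' Time-derivative of the fed-batch state
#'
#' The model field in amount form. Mitosis doubles cells leaving G2/M
#' into G1 (`+2 k_G2MG1 N_G2M` in the G1 balance against `-k_G2MG1
#' N_G2M` in G2/M, for a net gain of one cell per division); the G1
#' efflux `k_G1S N_G1` is split between S (`m_stress`) and G0
#' (`1 - m_stress`), and G1 additionally leaks to G0 at `k_G1G0`. Every
#' species is washed out by the outflow `F_OUT` at its current
#' concentration. Glutamine is consumed by all viable cells and degrades
#' to ammonia at `K_deg`; glucose is consumed at `Q_Glc` by cycling cells
#' (fraction `1 - f_G0`) and at the maintenance rate `m_Glc` by G0 cells,
#' with lactate coupled through `Y_Lac`; antibody production is the
#' growth-rate-scaled sum of phase-specific productivities.
#'
#' @param state Named state vector (see [kinetic_state()]).
#' @param params A [kinetic_params()].
#' @param feeds Named vector `c(F_Glc=, F_Gln=, F_OUT=)` (L/h).
#' @param t Simulation time (h), passed to the `f_temp` hook.
#' @return Named derivative vector, same layout as `state`.
#' @export
cho_derivatives <- function(state, params,
                            feeds = c(F_Glc = 0, F_Gln = 0, F_OUT = 0),
                            t = 0) {
  s <- state; p <- params
  V <- s[["V"]]
  if (V <= 0) stop("cho_derivatives: V must be > 0")
  N <- c(s[["N_G0"]], s[["N_G1"]], s[["N_S"]], s[["N_G2M"]])
  Ntot <- sum(N)
  f_G0 <- if (Ntot > 0) s[["N_G0"]] / Ntot else 0
  F_Glc <- feeds[["F_Glc"]]; F_Gln <- feeds[["F_Gln"]]
  F_OUT <- feeds[["F_OUT"]]
  out <- F_OUT / V                       # outflow removes at concentration
  k_G1G0 <- p$k_G1G0 * hook(p$f_temp, t)
  Q_Gln <- p$Q_Gln * hook(p$f_upt, s[["A_Gln"]] / V)
  Q_Glc <- p$Q_Glc * hook(p$f_inh, s[["A_Lac"]] / V)
  mu <- growth_rate(p$t_G1, p$t_S, p$t_G2M)

  dN_G1 <- 2 * p$k_G2MG1 * s[["N_G2M"]] - p$k_G1S * s[["N_G1"]] -
    k_G1G0 * s[["N_G1"]] - p$k_d * s[["N_G1"]] - out * s[["N_G1"]]
  dN_S <- p$k_G1S * p$m_stress * s[["N_G1"]] - p$k_SG2M * s[["N_S"]] -
    p$k_d * s[["N_S"]] - out * s[["N_S"]]
  dN_G2M <- p$k_SG2M * s[["N_S"]] - p$k_G2MG1 * s[["N_G2M"]] -
    p$k_d * s[["N_G2M"]] - out * s[["N_G2M"]]
  dN_G0 <- p$k_G1S * (1 - p$m_stress) * s[["N_G1"]] +
    k_G1G0 * s[["N_G1"]] - p$k_d * s[["N_G0"]] - out * s[["N_G0"]]
  dV <- F_Glc + F_Gln - F_OUT
  dA_Gln <- -Q_Gln * Ntot - p$K_deg * s[["A_Gln"]] +
    F_Gln * p$Gln_feed - out * s[["A_Gln"]]
  dA_Amn <- Q_Gln * p$Y_Amn * Ntot + p$K_deg * s[["A_Gln"]] -
    out * s[["A_Amn"]]
  dA_Glc <- -Q_Glc * Ntot * (1 - f_G0) - p$m_Glc * Ntot * f_G0 +
    F_Glc * p$Glc_feed - out * s[["A_Glc"]]
  dA_Lac <- p$Y_Lac * Q_Glc * Ntot * (1 - f_G0) -
    p$Y_Lac * p$m_Glc * Ntot * f_G0 - out * s[["A_Lac"]]
  dA_mAb <- mu * (p$q_G1G0 * (s[["N_G1"]] + s[["N_G0"]]) +
                  p$q_S * s[["N_S"]] + p$q_G2M * s[["N_G2M"]]) -
    out * s[["A_mAb"]]
  c(N_G0 = dN_G0, N_G1 = dN_G1, N_S = dN_S, N_G2M = dN_G2M, V = dV,
    A_Gln = dA_Gln, A_Amn = dA_Amn, A_Glc = dA_Glc, A_Lac = dA_Lac,
    A_mAb = dA_mAb)
}

#' Feed schedule: piecewise-constant rates plus instantaneous events
#'
#' @param rates Data frame with columns `time` (h, segment start),
#'   `F_Glc`, `F_Gln`, `F_OUT` (L/h); each row's rates apply from its
#'   `time` until the next row. Defaults to all-zero rates.
#' @param boluses Data frame with columns `time` (h), `volume` (L) and
#'   `feed` (`"glucose"` or `"glutamine"`): instantaneous additions of
#'   feed solution at feed concentration.
#' @param samples Data frame with columns `time` (h) and `volume` (L):
#'   instantaneous removals at current composition.
#' @return Object of class `feed_schedule`.
#' @export
feed_schedule <- function(rates = NULL, boluses = NULL, samples = NULL) {
  if (is.null(rates))
    rates <- data.frame(time = 0, F_Glc = 0, F_Gln = 0, F_OUT = 0)
  stopifnot(all(c("time", "F_Glc", "F_Gln", "F_OUT") %in% names(rates)))
  if (any(as.matrix(rates[, c("F_Glc", "F_Gln", "F_OUT")]) < 0))
    stop("feed_schedule: rates must be >= 0")
  rates <- rates[order(rates$time), , drop = FALSE]
  if (!is.null(boluses)) {
    stopifnot(all(c("time", "volume", "feed") %in% names(boluses)),
              all(boluses$volume >= 0),
              all(boluses$feed %in% c("glucose", "glutamine")))
    boluses <- boluses[order(boluses$time), , drop = FALSE]
  }
  if (!is.null(samples)) {
    stopifnot(all(c("time", "volume") %in% names(samples)),
              all(samples$volume >= 0))
    samples <- samples[order(samples$time), , drop = FALSE]
  }
  structure(list(rates = rates, boluses = boluses, samples = samples),
            class = "feed_schedule")
}

#' Daily bolus feeding schedule
#'
#' Convenience constructor for the manual dosing regime: one glucose and
#' one glutamine bolus per day plus a daily sampling draw, producing the
#' characteristic sawtooth nutrient profile.
#'
#' @param days Number of feeding days.
#' @param glc_vol,gln_vol Daily bolus volumes (L).
#' @param sample_vol Daily sample volume (L).
#' @param at Hour of day of dosing.
#' @return A [feed_schedule()].
#' @export
daily_bolus_schedule <- function(days = 14L, glc_vol = 0.05,
                                 gln_vol = 0.05, sample_vol = 0.01,
                                 at = 8) {
  tt <- at + 24 * (seq_len(days) - 1L)
  feed_schedule(
    boluses = data.frame(
      time = rep(tt, 2L),
      volume = rep(c(glc_vol, gln_vol), each = days),
      feed = rep(c("glucose", "glutamine"), each = days)),
    samples = data.frame(time = tt, volume = sample_vol))
}

apply_event <- function(state, type, volume, feed, params) {
  if (type == "bolus") {
    state[["V"]] <- state[["V"]] + volume
    if (feed == "glucose")
      state[["A_Glc"]] <- state[["A_Glc"]] + volume * params$Glc_feed
    else
      state[["A_Gln"]] <- state[["A_Gln"]] + volume * params$Gln_feed
  } else {                                # sample: remove at composition
    V <- state[["V"]]
    if (volume >= V) stop("simulate_batch: sample exceeds reactor volume")
    f <- (V - volume) / V
    amt <- setdiff(names(state), "V")
    state[amt] <- state[amt] * f
    state[["V"]] <- V - volume
  }
  state
}

rates_at <- function(rates, t) {
  i <- findInterval(t, rates$time)
  if (i < 1L) return(c(F_Glc = 0, F_Gln = 0, F_OUT = 0))
  c(F_Glc = rates$F_Glc[i], F_Gln = rates$F_Gln[i], F_OUT = rates$F_OUT[i])
}

#' Simulate a fed-batch run
#'
#' Integrates the kinetic model with `deSolve::lsoda` between
#' discontinuities; piecewise-constant feed rates and instantaneous
#' bolus/sampling events split the horizon into smooth segments, so the
#' stiff-capable adaptive integrator never steps across a jump. Boluses
#' add volume plus feed-concentration x volume of analyte; samples scale
#' all amounts by `(V - v)/V`. Small negative excursions (below
#' `-1e-9` of the state scale) abort; tinier ones are clamped to zero.
#'
#' @param state0 A [kinetic_state()].
#' @param params A [kinetic_params()].
#' @param schedule A [feed_schedule()].
#' @param t_end Simulation horizon (h).
#' @param dt_out Output grid spacing (h).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `cho_trajectory`: `times` (h), `states`
#'   (matrix, one row per time), plus the inputs.
#' @export
simulate_batch <- function(state0, params, schedule = feed_schedule(),
                           t_end = 336, dt_out = 1, rtol = 1e-8,
                           atol = 1e-10) {
  if (t_end <= 0) stop("simulate_batch: t_end must be > 0")
  ev <- data.frame(time = numeric(0), type = character(0),
                   volume = numeric(0), feed = character(0))
  if (!is.null(schedule$boluses))
    ev <- rbind(ev, data.frame(time = schedule$boluses$time, type = "bolus",
                               volume = schedule$boluses$volume,
                               feed = schedule$boluses$feed))
  if (!is.null(schedule$samples))
    ev <- rbind(ev, data.frame(time = schedule$samples$time, type = "sample",
                               volume = schedule$samples$volume, feed = NA))
  ev <- ev[ev$time > 0 & ev$time < t_end, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  breaks <- sort(unique(c(0, ev$time,
                          schedule$rates$time[schedule$rates$time > 0 &
                                              schedule$rates$time < t_end],
                          t_end)))
  grid <- sort(unique(c(seq(0, t_end, by = dt_out), t_end)))
  field <- function(t, y, parms) {
    list(cho_derivatives(y, params, parms$feeds, t = t))
  }
  state <- unclass(state0)
  out_t <- 0
  out_s <- matrix(state, nrow = 1, dimnames = list(NULL, names(state)))
  clamp_warned <- FALSE
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    seg_times <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
    feeds <- rates_at(schedule$rates, t0)
    sol <- deSolve::lsoda(state, seg_times, field, parms = list(feeds = feeds),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("simulate_batch: solver failure in segment starting at t = ", t0,
           " h; last good time ", max(sol[, 1]), " h")
    seg_s <- sol[-1L, -1L, drop = FALSE]
    scale <- max(abs(out_s[nrow(out_s), ]), 1)
    if (any(seg_s < -1e-9 * scale))
      stop("simulate_batch: state went negative beyond tolerance at t = ",
           seg_times[which(rowSums(seg_s < -1e-9 * scale) > 0)[1L] + 1L], " h")
    if (any(seg_s < 0)) {
      if (!clamp_warned) {
        warning("simulate_batch: clamped tiny negative state excursion to 0")
        clamp_warned <- TRUE
      }
      seg_s[seg_s < 0] <- 0
    }
    out_t <- c(out_t, seg_times[-1L])
    out_s <- rbind(out_s, seg_s)
    state <- out_s[nrow(out_s), ]
    for (k in which(ev$time == t1))
      state <- apply_event(state, ev$type[k], ev$volume[k], ev$feed[k], params)
    out_s[nrow(out_s), ] <- state
  }
  keep <- out_t %in% grid
  structure(list(times = out_t[keep],
                 states = out_s[keep, , drop = FALSE],
                 params = params, schedule = schedule),
            class = "cho_trajectory")
}

#' @export
print.cho_trajectory <- function(x, ...) {
  cat("<cho_trajectory> ", length(x$times), " time points over ",
      format(max(x$times)), " h; final X_V = ",
      format(sum(x$states[nrow(x$states), 1:4]) /
             x$states[nrow(x$states), "V"], digits = 4),
      " 1e6 cells/mL\n", sep = "")
  invisible(x)
}

#' Derived observables of a simulated trajectory
#'
#' Concentration-scale views of the amount-form states: viable cell
#' concentration `X_V` (sum over cycle compartments / volume, 1e6
#' cells/mL), quiescent fraction `f_G0`, and concentrations of glucose,
#' glutamine, lactate (g/L), ammonium (mmol/L) and antibody (g/L). All
#' values recompute exactly from the stored states.
#'
#' @param traj A `cho_trajectory` from [simulate_batch()].
#' @return Data frame with one row per trajectory time point.
#' @export
observables <- function(traj) {
  s <- traj$states
  Ntot <- rowSums(s[, c("N_G0", "N_G1", "N_S", "N_G2M"), drop = FALSE])
  V <- s[, "V"]
  data.frame(
    time = traj$times,
    X_V = Ntot / V,
    f_G0 = ifelse(Ntot > 0, s[, "N_G0"] / Ntot, 0),
    glucose = s[, "A_Glc"] / V,
    glutamine = s[, "A_Gln"] / V,
    lactate = s[, "A_Lac"] / V,
    ammonium = s[, "A_Amn"] / V,
    mab = s[, "A_mAb"] / V,
    V = V)
}

#' Interpolate one trajectory observable at arbitrary times
#'
#' Linear interpolation of an [observables()] column, e.g. to evaluate a
#' simulation at measurement times.
#'
#' @param traj A `cho_trajectory`.
#' @param variable An [observables()] column name.
#' @param times Numeric times (h).
#' @return Numeric vector of interpolated values.
#' @export
traj_interp <- function(traj, variable, times) {
  obs <- observables(traj)
  if (!variable %in% names(obs)) stop("unknown observable: ", variable)
  approx(obs$time, obs[[variable]], xout = times, rule = 2)$y
}
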