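#' Synthetic pure-component Raman library
#'
#' Builds a reproducible random pure-component profile (sum of Gaussian
#' peaks) per analyte on a shared wavenumber axis. Glutamine and
#' glutamate are structurally similar amino acids with similar active
#' Raman modes, so their synthetic profiles deliberately share most peak
#' positions — the library reproduces the confusability that makes the
#' glutamine soft sensor the hardest of the set.
#'
#' @param seed Integer seed.
#' @param analytes Character vector of analyte names; defaults to the
#'   seven reference variables of [reference_units].
#' @param axis Wavenumber axis (cm^-1); default 3000 channels over
#'   100-3400 cm^-1.
#' @param shared_fraction Fraction of glutamine peak positions reused for
#'   glutamate (when both are present).
#' @param sensitivities Named spectral response per unit concentration
#'   (signal counts per g/L, mmol/L or 1e6 cells/mL); analytes without an
#'   entry get 1.
#' @param medium_strength Intensity scale of the constant aqueous-medium
#'   background (water and media components dominate real bioreactor
#'   Raman spectra; this keeps per-spectrum normalisation close to
#'   affine, as it is on real spectra).
#' @param n_interferents Number of unmodelled media/by-product species:
#'   compounds with their own Raman signatures and time courses that are
#'   not among the reference variables (real media are complex mixtures,
#'   and most spectral variance belongs to species nobody calibrates
#'   for). They are what makes full-spectrum models overfit and
#'   wavelength selection worthwhile.
#' @return Object of class `component_library`: `axis`, `profiles`
#'   (matrix, one row per analyte), `sensitivities`, the `medium`
#'   background spectrum, and `interferents` (matrix of profiles).
#' @export
make_component_library <- function(seed = 1L,
                                   analytes = names(reference_units),
                                   axis = seq(100, 3400, length.out = 3000),
                                   shared_fraction = 0.8,
                                   sensitivities = c(ammonium = 0.3,
                                                     vcc = 0.5, tcc = 0.3),
                                   medium_strength = 100,
                                   n_interferents = 10L) {
  stopifnot(length(analytes) >= 1L)
  sens <- setNames(rep(1, length(analytes)), analytes)
  sens[names(sensitivities)[names(sensitivities) %in% analytes]] <-
    sensitivities[names(sensitivities) %in% analytes]
  with_seed(seed, {
    n_med <- 8L
    medium <- {
      ctr <- runif(n_med, min(axis), max(axis))
      wid <- runif(n_med, 80, 250)
      hgt <- runif(n_med, 0.3, 1)
      v <- numeric(length(axis))
      for (i in seq_len(n_med))
        v <- v + hgt[i] * exp(-0.5 * ((axis - ctr[i]) / wid[i])^2)
      medium_strength * v / max(v)
    }
    peaks <- list()
    for (a in analytes) {
      if (a == "glutamate" && "glutamine" %in% names(peaks)) {
        base <- peaks[["glutamine"]]
        n_sh <- ceiling(shared_fraction * nrow(base))
        sh <- base[seq_len(n_sh), , drop = FALSE]
        sh$height <- sh$height * runif(n_sh, 0.7, 1.3)
        n_own <- max(1L, nrow(base) - n_sh)
        own <- data.frame(center = runif(n_own, min(axis), max(axis)),
                          width = runif(n_own, 8, 25),
                          height = runif(n_own, 0.2, 1))
        peaks[[a]] <- rbind(sh, own)
      } else {
        n <- sample(6:12, 1L)
        peaks[[a]] <- data.frame(center = runif(n, min(axis), max(axis)),
                                 width = runif(n, 8, 25),
                                 height = runif(n, 0.2, 1))
      }
    }
    profiles <- t(vapply(peaks, function(pk) {
      v <- numeric(length(axis))
      for (i in seq_len(nrow(pk)))
        v <- v + pk$height[i] *
          exp(-0.5 * ((axis - pk$center[i]) / pk$width[i])^2)
      v / max(v)
    }, numeric(length(axis))))
    rownames(profiles) <- analytes
    interferents <- NULL
    if (n_interferents > 0L) {
      interferents <- t(vapply(seq_len(n_interferents), function(k) {
        np <- sample(6:12, 1L)
        ctr <- runif(np, min(axis), max(axis))
        wid <- runif(np, 8, 25)
        hgt <- runif(np, 0.2, 1)
        v <- numeric(length(axis))
        for (i in seq_len(np))
          v <- v + hgt[i] * exp(-0.5 * ((axis - ctr[i]) / wid[i])^2)
        v / max(v)
      }, numeric(length(axis))))
      rownames(interferents) <- paste0("interferent", seq_len(n_interferents))
    }
    structure(list(axis = axis, profiles = profiles, peaks = peaks,
                   sensitivities = sens, medium = medium,
                   interferents = interferents),
              class = "component_library")
  })
}

#' @export
print.component_library <- function(x, ...) {
  cat("<component_library> ", nrow(x$profiles), " analytes x ",
      length(x$axis), " channels\n", sep = "")
  invisible(x)
}

#' Spectral nuisance model
#'
#' Parameters of the non-analyte structure added to synthetic spectra:
#' a random polynomial baseline, a slowly growing broad fluorescence
#' background, per-spectrum multiplicative gain drift (lognormal around
#' 1), additive channel noise, slow per-channel drift, unmodelled
#' interferent species, and occasional whole-spectrum outliers of three
#' kinds — `spike` (a strong narrow peak, cosmic-ray-like),
#' `baseline-jump` (a fluorescence burst swamping the signal) and
#' `inhomogeneity` (unmixed sample or bubbles in front of the probe:
#' the spectrum reflects the wrong material state).
#'
#' @param baseline_amp Amplitude scale of the polynomial baseline.
#' @param fluor_amp Amplitude of the fluorescence drift at batch end.
#' @param gain_sdlog Lognormal sd of the per-spectrum gain.
#' @param noise_sd Additive noise standard deviation.
#' @param drift_amp Amplitude of slow per-channel drift over the batch
#'   (probe fouling / fluorescence build-up / detector aging): each
#'   channel follows its own random walk across acquisitions.
#' @param interferent_amp Concentration scale of the library's
#'   unmodelled interferent species; each follows a smooth random time
#'   course per batch.
#' @param outlier_rate Per-spectrum outlier probability in [0, 1).
#' @param outlier_magnitude Outlier strength relative to the signal.
#' @return List of class `nuisance_model`.
#' @export
nuisance_model <- function(baseline_amp = 30, fluor_amp = 30,
                           gain_sdlog = 0.05, noise_sd = 0.5,
                           drift_amp = 10, interferent_amp = 5,
                           outlier_rate = 0.02, outlier_magnitude = 5) {
  stopifnot(outlier_rate >= 0, outlier_rate < 1, noise_sd > 0)
  structure(list(baseline_amp = baseline_amp, fluor_amp = fluor_amp,
                 gain_sdlog = gain_sdlog, noise_sd = noise_sd,
                 drift_amp = drift_amp, interferent_amp = interferent_amp,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude),
            class = "nuisance_model")
}

#' Silent nuisance model (no baseline, gain, noise or outliers beyond a
#' numerically tiny additive noise floor)
#' @return A [nuisance_model()] with all structure switched off.
#' @export
nuisance_off <- function() {
  nuisance_model(baseline_amp = 0, fluor_amp = 0, gain_sdlog = 0,
                 noise_sd = 1e-12, drift_amp = 0, interferent_amp = 0,
                 outlier_rate = 0)
}

#' Default kinetic parameter set of the synthetic fed-batch world
#'
#' [kinetic_params()] plus the two state/time-dependent modifiers a
#' realistic two-week fed-batch needs: Monod-limited glutamine uptake
#' (`f_upt = gln / (gln + K_gln)`, so uptake saturates and vanishes as
#' glutamine depletes) and a temperature downshift at `t_shift` that
#' multiplies the G1 -> G0 transition by `temp_factor`, arresting the
#' culture in a quiescent, maintenance-metabolism plateau as production
#' processes do deliberately.
#'
#' @param K_gln Monod constant of glutamine uptake (g/L).
#' @param t_shift Time of the temperature downshift (h).
#' @param temp_factor Multiplier on `k_G1G0` after the shift.
#' @param ... Overrides passed to [kinetic_params()].
#' @return A [kinetic_params()] with the hooks installed.
#' @export
cho_batch_params <- function(K_gln = 0.1, t_shift = 168, temp_factor = 4,
                             ...) {
  kinetic_params(...,
                 f_upt = function(gln) gln / (gln + K_gln),
                 f_temp = function(t) ifelse(t >= t_shift, temp_factor, 1))
}

#' Simulate one synthetic fed-batch with daily reference measurements
#'
#' Runs the kinetic simulator over a two-week fed-batch and samples an
#' off-line reference table 1-2 times per day with relative measurement
#' noise. In `"daily-bolus"` mode nutrients are dosed once a day the way
#' an operator would: a sample is drawn, and glucose/glutamine are
#' topped back up to their setpoints with boluses of concentrated feed
#' sized from the measured concentration — which produces the
#' characteristic sawtooth nutrient profile. `"continuous"` mode applies
#' constant feed rates instead. Total cell count (TCC) and glutamate are
#' synthetic bookkeeping views derived from the trajectory: TCC adds the
#' cumulative death toll to the viable count, glutamate accumulates from
#' degraded glutamine.
#'
#' @param seed Integer seed (measurement noise only; the underlying
#'   trajectory is deterministic given `params`/`state0`/`feeding`).
#' @param params A [kinetic_params()]; default [cho_batch_params()].
#' @param state0 A [kinetic_state()].
#' @param feeding `"daily-bolus"` or `"continuous"`.
#' @param days Batch duration (days).
#' @param refs_per_day Reference measurements per day (1 or 2).
#' @param meas_noise Relative measurement noise sd (0 = noiseless).
#' @param glc_target,gln_target Daily top-up setpoints (g/L).
#' @param sample_vol Daily sample draw (L).
#' @param batch_id Batch label.
#' @return List with `trajectory` (a `cho_trajectory`), `refs` (a
#'   [reference_table()], timestamps in seconds), and `extras` (data
#'   frame of the synthetic glutamate/TCC series on the trajectory grid).
#' @export
make_batch <- function(seed = 1L, params = cho_batch_params(),
                       state0 = kinetic_state(),
                       feeding = c("daily-bolus", "continuous"),
                       days = 14L, refs_per_day = 2L, meas_noise = 0.02,
                       glc_target = 6, gln_target = 1.5,
                       sample_vol = 0.01, batch_id = "batch1") {
  feeding <- match.arg(feeding)
  t_end <- 24 * days
  if (feeding == "daily-bolus") {
    traj <- sim_adaptive_bolus(params, state0, days, glc_target,
                               gln_target, sample_vol)
  } else {
    sch <- feed_schedule(rates = data.frame(time = 0, F_Glc = 0.002,
                                            F_Gln = 0.002, F_OUT = 0))
    traj <- simulate_batch(state0, params, sch, t_end = t_end)
  }
  obs <- observables(traj)
  extras <- synth_extras(traj)
  ref_h <- as.vector(outer(if (refs_per_day >= 2L) c(9, 17) else 9,
                           24 * (0:(days - 1L)), `+`))
  ref_h <- sort(ref_h[ref_h <= t_end])
  vals <- data.frame(
    glucose = approx(obs$time, obs$glucose, ref_h)$y,
    glutamine = approx(obs$time, obs$glutamine, ref_h)$y,
    glutamate = approx(extras$time, extras$glutamate, ref_h)$y,
    lactate = approx(obs$time, obs$lactate, ref_h)$y,
    ammonium = approx(obs$time, obs$ammonium, ref_h)$y,
    vcc = approx(obs$time, obs$X_V, ref_h)$y,
    tcc = approx(extras$time, extras$tcc, ref_h)$y)
  if (meas_noise > 0)
    vals <- with_seed(seed, {
      as.data.frame(lapply(vals, function(v)
        v * (1 + rnorm(length(v), sd = meas_noise))))
    })
  refs <- reference_table(ref_h * 3600, vals, batch_id = batch_id)
  list(trajectory = traj, refs = refs, extras = extras)
}

# Day-by-day fed-batch simulation with operator-style dosing: every 24 h
# a sample is drawn and glucose/glutamine are topped up to their setpoints
# with boluses of concentrated feed sized from the current concentration.
sim_adaptive_bolus <- function(params, state0, days, glc_target,
                               gln_target, sample_vol) {
  state <- unclass(state0)
  times <- numeric(0); states <- NULL
  boluses <- NULL
  for (d in seq_len(days)) {
    # each day integrates on local time 0-24 h; shift the time-dependent
    # hook so it sees batch time
    params_d <- params
    if (!is.null(params$f_temp))
      params_d$f_temp <- local({
        off <- 24 * (d - 1L); bf <- params$f_temp
        function(t) bf(t + off)
      })
    tr <- simulate_batch(state, params_d, feed_schedule(), t_end = 24,
                         dt_out = 1)
    t_glob <- tr$times + 24 * (d - 1L)
    keep <- if (d == 1L) seq_along(t_glob) else -1L
    times <- c(times, t_glob[keep])
    states <- rbind(states, tr$states[keep, , drop = FALSE])
    state <- states[nrow(states), ]
    if (d < days) {
      state <- apply_event(state, "sample", sample_vol, NA, params)
      v_glc <- max(0, (glc_target * state[["V"]] - state[["A_Glc"]]) /
                        (params$Glc_feed - glc_target))
      v_gln <- max(0, (gln_target * state[["V"]] - state[["A_Gln"]]) /
                        (params$Gln_feed - gln_target))
      state <- apply_event(state, "bolus", v_glc, "glucose", params)
      state <- apply_event(state, "bolus", v_gln, "glutamine", params)
      boluses <- rbind(boluses,
                       data.frame(time = rep(24 * d, 2L),
                                  volume = c(v_glc, v_gln),
                                  feed = c("glucose", "glutamine")))
      states[nrow(states), ] <- state        # post-dose state at the joint
    }
  }
  structure(list(times = times, states = states, params = params,
                 schedule = feed_schedule(boluses = boluses,
                                          samples = data.frame(
                                            time = 24 * seq_len(days - 1L),
                                            volume = sample_vol))),
            class = "cho_trajectory")
}

# Synthetic glutamate and TCC series derived from a trajectory by
# trapezoidal accumulation of degradation/death fluxes.
synth_extras <- function(traj, glu_yield = 0.8) {
  s <- traj$states; tt <- traj$times
  p <- traj$params
  Ntot <- rowSums(s[, c("N_G0", "N_G1", "N_S", "N_G2M"), drop = FALSE])
  dt <- diff(tt)
  cum_trapz <- function(f) c(0, cumsum((head(f, -1) + tail(f, -1)) / 2 * dt))
  deg <- cum_trapz(p$K_deg * s[, "A_Gln"])    # g glutamine degraded
  dead <- cum_trapz(p$k_d * Ntot)             # 1e9 cells died
  data.frame(time = tt,
             glutamate = glu_yield * deg / s[, "V"],
             tcc = (Ntot + dead) / s[, "V"])
}

#' Generate Raman-like spectra along a simulated trajectory
#'
#' Spectra are linear mixtures of the pure-component profiles weighted by
#' the analyte concentrations at the acquisition time, wrapped in the
#' nuisance structure:
#' `spectrum(t) = gain(t) * (sum_a conc_a(t) * profile_a + baseline(t)) + noise`.
#' Outlier spectra are planted at the nuisance model's rate and their ids
#' returned as ground truth. The linear forward model is what justifies a
#' linear calibration (PLS) downstream; nonlinearity enters only through
#' the gain/baseline nuisances that SNV largely removes.
#'
#' @param traj A `cho_trajectory`.
#' @param library A [make_component_library()].
#' @param nuisance A [nuisance_model()].
#' @param every_s Acquisition cadence in seconds (default half-hourly).
#' @param seed Integer seed for nuisance draws.
#' @param extras Optional data frame (`time` in h plus analyte columns)
#'   supplying concentrations absent from [observables()], e.g. the
#'   synthetic glutamate/TCC series of [make_batch()].
#' @param id_prefix Prefix for spectrum ids.
#' @return List with `spectra` (a [spectra_set()], timestamps in
#'   seconds) and `outliers` (character ids of planted outlier spectra).
#' @export
make_spectra <- function(traj, library, nuisance = nuisance_model(),
                         every_s = 1800, seed = 1L, extras = NULL,
                         id_prefix = "s") {
  stopifnot(inherits(library, "component_library"))
  t_end_s <- max(traj$times) * 3600
  times_s <- seq(0, by = every_s,
                 length.out = max(1, round(t_end_s / every_s)))
  t_h <- times_s / 3600
  obs <- observables(traj)
  analytes <- rownames(library$profiles)
  conc <- matrix(0, length(t_h), length(analytes),
                 dimnames = list(NULL, analytes))
  for (a in analytes) {
    if (a == "vcc") conc[, a] <- approx(obs$time, obs$X_V, t_h)$y
    else if (a %in% names(obs)) conc[, a] <- approx(obs$time, obs[[a]], t_h)$y
    else if (!is.null(extras) && a %in% names(extras))
      conc[, a] <- approx(extras$time, extras[[a]], t_h)$y
  }
  axis <- library$axis
  n <- length(t_h); m <- length(axis)
  clean <- (conc * rep(library$sensitivities, each = n)) %*% library$profiles
  if (!is.null(library$medium))
    clean <- clean + rep(1, n) %o% library$medium
  with_seed(seed, {
    ax01 <- (axis - min(axis)) / diff(range(axis))
    mat <- clean
    if (!is.null(library$interferents) && nuisance$interferent_amp > 0 &&
        n > 1L) {
      n_int <- nrow(library$interferents)
      conc_int <- vapply(seq_len(n_int), function(k) {
        w <- cumsum(rnorm(n)) / sqrt(n)          # smooth random time course
        nuisance$interferent_amp * (w - min(w))
      }, numeric(n))
      mat <- mat + conc_int %*% library$interferents
    }
    sig_scale <- max(mean(abs(mat)), 1e-9)
    for (i in seq_len(n)) {
      cf <- rnorm(4L, sd = nuisance$baseline_amp / 2)
      baseline <- cf[1] + cf[2] * ax01 + cf[3] * ax01^2 + cf[4] * ax01^3 +
        nuisance$fluor_amp * (t_h[i] / max(t_h[n], 1)) * exp(-3 * ax01)
      gain <- exp(rnorm(1L, sd = nuisance$gain_sdlog))
      mat[i, ] <- gain * (clean[i, ] + baseline) +
        rnorm(m, sd = nuisance$noise_sd)
    }
    if (nuisance$drift_amp > 0 && n > 1L)
      mat <- mat + nuisance$drift_amp *
        apply(matrix(rnorm(n * m), n, m), 2L, cumsum) / sqrt(n)
    is_out <- runif(n) < nuisance$outlier_rate
    for (i in which(is_out)) {
      other <- mat[sample(setdiff(seq_len(n), i), 1L), ]
      mat[i, ] <- corrupt_spectrum(
        mat[i, ], sample(c("spike", "baseline-jump", "inhomogeneity"), 1L),
        nuisance$outlier_magnitude, sig_scale, other)
    }
    ids <- paste0(id_prefix, seq_len(n))
    list(spectra = spectra_set(axis, mat, times_s, ids),
         outliers = ids[is_out])
  })
}

# Apply one outlier corruption to a spectrum vector. Caller supplies the
# RNG state (spike position is drawn here). "spike" is a cosmic-ray-like
# narrow peak; "baseline-jump" a fluorescence burst; "inhomogeneity"
# (unmixed sample / probe seeing the wrong material) blends in the
# content of a spectrum from a different process state.
corrupt_spectrum <- function(x, type, mag, sig_scale, other = NULL) {
  m <- length(x)
  ax01 <- (seq_len(m) - 1) / (m - 1)
  switch(type,
    "spike" = {
      ctr <- sample.int(m, 1L)
      x + mag * sig_scale * exp(-0.5 * ((seq_len(m) - ctr) / 4)^2)
    },
    "baseline-jump" = x + mag * sig_scale * (0.5 + ax01),
    "inhomogeneity" = {
      if (is.null(other)) stop("inhomogeneity corruption needs a donor spectrum")
      0.3 * x + 0.7 * other
    },
    stop("unknown outlier type: ", type))
}

#' Canonical paired soft-sensor benchmark
#'
#' One call builds the standard synthetic test bed mimicking the study
#' setting: four two-week fed-batches with daily bolus feeding,
#' half-hourly Raman-like spectra (about 670 per batch), 1-2 off-line
#' reference measurements per day (about 100 usable training pairs in
#' total), and roughly 2% planted outlier spectra with ground-truth
#' labels. Batches differ slightly in inoculum, start glucose and uptake
#' rates. Timestamps of successive batches are offset far apart so the
#' combined tables pair correctly by time.
#'
#' @param seed Master seed; process, measurement and nuisance noise use
#'   independent sub-seeds derived from it.
#' @param n_batches Number of batches.
#' @param days Days per batch.
#' @param refs_per_day Reference measurements per day.
#' @param every_s Spectrum cadence (s).
#' @param n_channels Channels of the wavenumber axis.
#' @param meas_noise Relative reference measurement noise.
#' @param nuisance A [nuisance_model()].
#' @param paired_outlier_rate Fraction of the reference-matched spectra
#'   additionally corrupted (the outliers that actually matter for
#'   calibration sit inside the training pairs; the background
#'   `nuisance$outlier_rate` mostly hits unpaired spectra).
#' @return List with `spectra` (combined [spectra_set()]), `refs`
#'   (combined [reference_table()]), `outliers` (planted outlier ids),
#'   `library`, and `batches` (per-batch `make_batch()` results).
#' @export
make_paired_benchmark <- function(seed = 42L, n_batches = 4L, days = 14L,
                                  refs_per_day = 2L, every_s = 1800,
                                  n_channels = 3000L, meas_noise = 0.02,
                                  nuisance = nuisance_model(),
                                  paired_outlier_rate = 0.03) {
  library <- make_component_library(
    seed = seed, axis = seq(100, 3400, length.out = n_channels))
  sub <- with_seed(seed,
                   sample.int(.Machine$integer.max %/% 2, 3L * n_batches + 1L))
  batch_gap_s <- days * 86400 * 2
  all_sp <- NULL; all_refs <- NULL; outliers <- character(0)
  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    pv <- with_seed(sub[3L * b - 2L], runif(4L, 0.9, 1.1))
    params <- cho_batch_params(Q_Glc = 0.015 * pv[1], Q_Gln = 0.0015 * pv[2])
    state0 <- kinetic_state(X_V0 = 0.5 * pv[3], Glc0 = 10 * pv[4])
    bt <- make_batch(seed = sub[3L * b - 1L], params = params,
                     state0 = state0, days = days,
                     refs_per_day = refs_per_day, meas_noise = meas_noise,
                     batch_id = paste0("batch", b))
    sp <- make_spectra(bt$trajectory, library, nuisance = nuisance,
                       every_s = every_s, seed = sub[3L * b],
                       extras = bt$extras, id_prefix = paste0("b", b, "_s"))
    offset <- (b - 1L) * batch_gap_s
    sp$spectra$timestamps <- sp$spectra$timestamps + offset
    refs_df <- as.data.frame(bt$refs)
    refs_df$timestamp <- refs_df$timestamp + offset
    batches[[b]] <- c(bt, list(spectra = sp$spectra, outliers = sp$outliers))
    outliers <- c(outliers, sp$outliers)
    all_sp <- if (is.null(all_sp)) {
      sp$spectra
    } else {
      spectra_set(library$axis,
                  rbind(all_sp$intensities, sp$spectra$intensities),
                  c(all_sp$timestamps, sp$spectra$timestamps),
                  c(all_sp$ids, sp$spectra$ids))
    }
    all_refs <- rbind(all_refs, refs_df)
  }
  refs <- reference_table(all_refs$timestamp,
                          all_refs[, setdiff(names(all_refs), "timestamp"),
                                   drop = FALSE],
                          batch_id = "combined")
  if (paired_outlier_rate > 0) {
    # corrupt a few of the spectra that pairing will select: these are the
    # outliers that end up inside the calibration set
    paired_idx <- unique(vapply(refs$timestamp, function(tt)
      which.min(abs(all_sp$timestamps - tt)), integer(1)))
    n_plant <- max(2L, round(paired_outlier_rate * length(paired_idx)))
    sig_scale <- mean(abs(all_sp$intensities))
    planted <- with_seed(sub[3L * n_batches + 1L], {
      pick <- sample(paired_idx, n_plant)
      for (i in pick) {
        # calibration-pair outliers are reference/spectrum mismatches
        # (unmixed sample, probe seeing another process state): the kind
        # that actually corrupts a calibration, unlike gain artifacts
        # that SNV absorbs
        donor <- sample(setdiff(seq_len(nrow(all_sp$intensities)), i), 1L)
        all_sp$intensities[i, ] <- corrupt_spectrum(
          all_sp$intensities[i, ], "inhomogeneity",
          nuisance$outlier_magnitude, sig_scale,
          all_sp$intensities[donor, ])
      }
      all_sp$ids[pick]
    })
    outliers <- unique(c(outliers, planted))
  }
  list(spectra = all_sp, refs = refs, outliers = outliers,
       library = library, batches = batches)
}
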