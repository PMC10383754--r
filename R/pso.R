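#' Particle swarm optimisation (global best)
#'
#' Standard gbest PSO on a box: velocities update as
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with uniform
#' per-dimension random factors, positions reflect at the bounds, and
#' velocities are clamped to a fraction of the box width. Defaults are
#' the constriction-equivalent coefficients `w = 0.729`,
#' `c1 = c2 = 1.494`. Fully deterministic per seed.
#'
#' @param f Objective function of a numeric vector, to minimise.
#' @param lower,upper Finite box bounds (equal lengths).
#' @param n_particles Swarm size (>= 2).
#' @param n_iterations Iteration budget.
#' @param w,c1,c2 Inertia, cognitive and social coefficients.
#' @param v_clamp Velocity clamp as a fraction of the box width.
#' @param seed Integer seed.
#' @return Object of class `pso_result`: `par` (best-ever position),
#'   `value`, `trace` (best value after each iteration, non-increasing),
#'   `n_evaluations`, `seed`.
#' @export
pso_minimize <- function(f, lower, upper, n_particles = 30L,
                         n_iterations = 300L, w = 0.729, c1 = 1.494,
                         c2 = 1.494, v_clamp = 0.5, seed = 1L) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(c(lower, upper))),
            all(lower < upper), n_particles >= 2L, c1 > 0, c2 > 0)
  width <- upper - lower
  vmax <- v_clamp * width
  with_seed(seed, {
    X <- matrix(runif(n_particles * d, lower, upper), n_particles, d,
                byrow = TRUE)
    Vm <- matrix(runif(n_particles * d, -vmax, vmax), n_particles, d,
                 byrow = TRUE)
    fx <- apply(X, 1L, f)
    Pb <- X; fpb <- fx
    g <- which.min(fpb)
    gbest <- Pb[g, ]; fgb <- fpb[g]
    trace <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      r1 <- matrix(runif(n_particles * d), n_particles, d)
      r2 <- matrix(runif(n_particles * d), n_particles, d)
      Vm <- w * Vm + c1 * r1 * (Pb - X) +
        c2 * r2 * (rep(1, n_particles) %o% gbest - X)
      Vm <- pmin(pmax(Vm, rep(1, n_particles) %o% -vmax),
                 rep(1, n_particles) %o% vmax)
      X <- X + Vm
      # reflect at bounds, damping the velocity component
      for (j in seq_len(d)) {
        lo <- X[, j] < lower[j]; hi <- X[, j] > upper[j]
        X[lo, j] <- 2 * lower[j] - X[lo, j]
        X[hi, j] <- 2 * upper[j] - X[hi, j]
        Vm[lo | hi, j] <- -Vm[lo | hi, j]
        X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
      }
      fx <- apply(X, 1L, f)
      better <- fx < fpb
      Pb[better, ] <- X[better, , drop = FALSE]
      fpb[better] <- fx[better]
      g <- which.min(fpb)
      if (fpb[g] < fgb) { gbest <- Pb[g, ]; fgb <- fpb[g] }
      trace[it] <- fgb
    }
    structure(list(par = gbest, value = fgb, trace = trace,
                   n_evaluations = n_particles * (n_iterations + 1L),
                   seed = seed),
              class = "pso_result")
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat("<pso_result> best value ", format(x$value, digits = 6), " after ",
      x$n_evaluations, " evaluations\n", sep = "")
  invisible(x)
}

#' Define a kinetic parameter-estimation problem
#'
#' @param free Named list of box bounds for the free parameters, e.g.
#'   `list(K_deg = c(0, 0.05))`; names must be numeric fields of
#'   [kinetic_params()].
#' @param params Baseline [kinetic_params()] supplying the fixed values.
#' @param state0 Initial [kinetic_state()].
#' @param schedule A [feed_schedule()].
#' @param observed Data frame with columns `variable` (an [observables()]
#'   column name), `time` (h) and `value`; optional `weight` per row
#'   group.
#' @param t_end Simulation horizon (h); defaults to the last observation.
#' @return Object of class `fit_problem`.
#' @export
fit_problem <- function(free, params, state0, schedule, observed,
                        t_end = NULL) {
  stopifnot(is.list(free),
            all(c("variable", "time", "value") %in% names(observed)))
  for (nm in names(free)) {
    b <- free[[nm]]
    if (!nm %in% names(params) || !is.numeric(params[[nm]]))
      stop("fit_problem: unknown free parameter '", nm, "'")
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("fit_problem: bounds for '", nm, "' must be finite with lower < upper")
  }
  if (is.null(t_end)) t_end <- max(observed$time)
  if (any(observed$time > t_end)) stop("fit_problem: observations beyond t_end")
  structure(list(free = free, params = params, state0 = state0,
                 schedule = schedule, observed = observed, t_end = t_end),
            class = "fit_problem")
}

#' Combined RMSE criterion for a kinetic fit
#'
#' Simulates the model with the candidate parameter values and scores the
#' match to the observed series: per-variable RMSE between the simulated
#' observables (linearly interpolated to the observation times) and the
#' observations, with each variable normalised by the standard deviation
#' of its observations so that g/L, mmol/L and cell-count series combine
#' on one scale; the combined criterion is the weighted mean of the
#' normalised per-variable RMSEs. A failed simulation scores a large
#' finite penalty instead of raising.
#'
#' @param theta Numeric vector of free-parameter values, in the order of
#'   `problem$free`.
#' @param problem A [fit_problem()].
#' @param penalty Value returned when the simulation fails.
#' @return Single numeric criterion value (attribute `per_variable`
#'   carries the raw per-variable RMSEs).
#' @export
kinetic_criterion <- function(theta, problem, penalty = 1e6) {
  p <- problem$params
  for (i in seq_along(problem$free)) p[[names(problem$free)[i]]] <- theta[i]
  traj <- tryCatch(
    suppressWarnings(simulate_batch(problem$state0, p, problem$schedule,
                                    t_end = problem$t_end)),
    error = function(e) NULL)
  if (is.null(traj)) return(penalty)
  obs <- problem$observed
  vars <- unique(obs$variable)
  per_var <- numeric(length(vars)); names(per_var) <- vars
  scaled <- numeric(length(vars)); wts <- numeric(length(vars))
  for (i in seq_along(vars)) {
    o <- obs[obs$variable == vars[i], , drop = FALSE]
    sim <- traj_interp(traj, vars[i], o$time)
    per_var[i] <- sqrt(mean((o$value - sim)^2))
    s <- sd(o$value)
    scaled[i] <- per_var[i] / if (s > 0) s else 1
    wts[i] <- if ("weight" %in% names(o)) o$weight[1L] else 1
  }
  out <- sum(scaled * wts) / sum(wts)
  attr(out, "per_variable") <- per_var
  out
}

#' Estimate kinetic parameters by particle swarm optimisation
#'
#' Minimises [kinetic_criterion()] over the free parameters of a
#' [fit_problem()] and reports per-variable RMSE and R-squared of the
#' final fit. With no free parameters the criterion is evaluated once at
#' the baseline (identity fit).
#'
#' @param problem A [fit_problem()].
#' @param n_particles,n_iterations,seed PSO settings ([pso_minimize()]).
#' @param ... Further arguments to [pso_minimize()].
#' @return Object of class `fit_result`: `par` (named best parameters),
#'   `params` (full [kinetic_params()] with the fit inserted),
#'   `criterion`, `per_variable` (data frame of RMSE and R2), `trace`,
#'   `seed`.
#' @export
fit_kinetics <- function(problem, n_particles = 30L, n_iterations = 300L,
                         seed = 1L, ...) {
  stopifnot(inherits(problem, "fit_problem"))
  nm <- names(problem$free)
  if (!length(nm)) {
    value <- kinetic_criterion(numeric(0), problem)
    best <- numeric(0); trace <- as.numeric(value)
  } else {
    lower <- vapply(problem$free, `[`, numeric(1), 1L)
    upper <- vapply(problem$free, `[`, numeric(1), 2L)
    res <- pso_minimize(function(th) kinetic_criterion(th, problem),
                        lower, upper, n_particles = n_particles,
                        n_iterations = n_iterations, seed = seed, ...)
    best <- setNames(res$par, nm); value <- res$value; trace <- res$trace
  }
  p <- problem$params
  for (i in seq_along(best)) p[[nm[i]]] <- best[i]
  crit <- kinetic_criterion(unname(best), problem)
  per_var <- attr(crit, "per_variable")
  traj <- suppressWarnings(simulate_batch(problem$state0, p,
                                          problem$schedule,
                                          t_end = problem$t_end))
  stats <- do.call(rbind, lapply(names(per_var), function(v) {
    o <- problem$observed[problem$observed$variable == v, , drop = FALSE]
    sim <- traj_interp(traj, v, o$time)
    data.frame(variable = v, rmse = per_var[[v]],
               r2 = if (length(o$value) >= 2 && sd(o$value) > 0)
                 r2(o$value, sim) else NA_real_)
  }))
  structure(list(par = best, params = p, criterion = as.numeric(value),
                 per_variable = stats, trace = trace, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> criterion ", format(x$criterion, digits = 6), "\n",
      sep = "")
  if (length(x$par)) {
    cat("  parameters:\n")
    for (nm in names(x$par))
      cat("    ", nm, " = ", format(x$par[[nm]], digits = 6), "\n", sep = "")
  }
  invisible(x)
}
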