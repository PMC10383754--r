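#' Variable importance in projection (VIP) scores
#'
#' Computes the standard Wold VIP score for every retained predictor of a
#' fitted PLS model:
#' `VIP_j = sqrt( m * sum_a SSY_a * w_ja^2 / sum_a SSY_a )` with
#' `SSY_a = q_a^2 * t_a' t_a`, the response variance explained by
#' component `a`, and `w_ja` the unit-norm weights. The squared scores
#' average to exactly 1 over predictors, so the conventional selection
#' threshold is 1: variables scoring above carry more than an average
#' share of the explained response variance.
#'
#' @param model A `pls_model` from [pls_train()] (scores `T` retained).
#' @param threshold Selection threshold on the VIP score.
#' @return Object of class `vip_result`: `scores` (one per retained
#'   predictor, named by original column index), `threshold`, and
#'   `selected`, the original-grid indices with `score >= threshold`.
#' @export
vip_scores <- function(model, threshold = 1) {
  stopifnot(inherits(model, "pls_model"))
  if (model$A < 1L) stop("vip_scores: model has no components")
  m <- nrow(model$W)
  ssy <- model$Q[1L, ]^2 * colSums(model$T^2)        # per-component SSY
  scores <- sqrt(m * as.numeric(model$W^2 %*% ssy) / sum(ssy))
  names(scores) <- model$variable_mask
  structure(list(scores = scores, threshold = threshold,
                 selected = model$variable_mask[scores >= threshold]),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat("<vip_result> ", length(x$scores), " predictors, ",
      length(x$selected), " selected at threshold ", x$threshold, "\n",
      sep = "")
  invisible(x)
}

#' Competitive adaptive reweighted sampling (CARS) variable selection
#'
#' Monte-Carlo wavelength selection: each iteration fits a PLS model on a
#' random row subsample of the currently retained variables, weights
#' every variable by the magnitude of its standardised regression
#' coefficient, enforces an exponentially decreasing retained-variable
#' count (from all `m` variables down to 2 across the iterations), and
#' resamples the retained set with probability proportional to weight
#' (adaptive reweighted sampling). Every candidate subset is scored by
#' RMSECV on the full data; the winner is the subset with the smallest
#' RMSECV.
#'
#' @param X Predictor matrix (n x m, m >= 2).
#' @param y Response vector.
#' @param n_iterations Number of CARS iterations (>= 2).
#' @param mc_fraction Row fraction drawn (without replacement) for each
#'   iteration's calibration subsample.
#' @param A_max Maximum latent variables for the internal PLS fits and
#'   the RMSECV scoring.
#' @param folds Cross-validation folds for subset scoring.
#' @param scheme Fold scheme for subset scoring (see [cross_validate()]).
#' @param seed Integer seed; the whole run is reproducible per seed.
#' @return Object of class `cars_result`: `masks` (list of per-iteration
#'   retained index sets), `rmsecv` (per-iteration subset score),
#'   `n_retained`, `winner` (best mask), `winner_rmsecv`, `iterations`
#'   actually run, and `seed`.
#' @export
cars_select <- function(X, y, n_iterations = 100L, mc_fraction = 0.8,
                        A_max = 10L, folds = 5L,
                        scheme = c("blocks", "random"), seed = 1L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  if (m < 2L) stop("cars_select: need >= 2 predictors")
  if (n_iterations < 2L) stop("cars_select: need >= 2 iterations")
  lambda <- log(m / 2) / (n_iterations - 1L)
  with_seed(seed, {
    retained <- seq_len(m)
    masks <- vector("list", n_iterations)
    scores <- rep(NA_real_, n_iterations)
    n_ret <- integer(n_iterations)
    ran <- 0L
    for (i in seq_len(n_iterations)) {
      r_i <- max(2L, min(m, round(m * exp(-lambda * (i - 1L)))))
      rows <- sample.int(n, max(2L, round(mc_fraction * n)))
      w <- abs(cars_coef(X[rows, retained, drop = FALSE], y[rows], A_max))
      # enforced exponentially decreasing count: keep the top r_i by |b|
      r_i <- min(r_i, length(retained))
      forced <- retained[order(w, decreasing = TRUE)[seq_len(r_i)]]
      wf <- w[match(forced, retained)]
      # adaptive reweighted sampling among the survivors: m draws with
      # replacement, weighted by |b|; the unique draws survive
      prob <- if (sum(wf) > 0) wf else rep(1, length(forced))
      retained <- sort(unique(sample(forced, size = m,
                                     replace = TRUE, prob = prob)))
      if (length(retained) < 1L) break
      cv <- suppressMessages(
        cross_validate(X[, retained, drop = FALSE], y,
                       A_max = min(A_max, length(retained)), folds = folds,
                       scheme = scheme, seed = seed))
      masks[[i]] <- retained
      scores[i] <- min(cv$rmsecv)
      n_ret[i] <- length(retained)
      ran <- i
    }
    if (ran == 0L) stop("cars_select: subset collapsed before any evaluation")
    masks <- masks[seq_len(ran)]
    scores <- scores[seq_len(ran)]
    n_ret <- n_ret[seq_len(ran)]
    best <- which.min(scores)
    structure(list(masks = masks, rmsecv = scores, n_retained = n_ret,
                   winner = masks[[best]], winner_rmsecv = scores[best],
                   iterations = ran, seed = seed),
              class = "cars_result")
  })
}

# Standardised-scale PLS coefficients for CARS variable weighting; columns
# that are constant within the subsample get weight 0.
cars_coef <- function(Xsub, ysub, A_max) {
  st <- standardize(Xsub, ysub)
  a <- min(A_max, qr(st$Xs)$rank, nrow(Xsub) - 1L)
  fit <- nipals_fit(st$Xs, st$Ys, a, on_exhaust = "truncate")
  b <- numeric(ncol(Xsub))
  b[st$keep] <- as.numeric(fit$B)
  b
}

#' @export
print.cars_result <- function(x, ...) {
  cat("<cars_result> ", x$iterations, " iteration(s); winner keeps ",
      length(x$winner), " variable(s), RMSECV ",
      format(x$winner_rmsecv, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Refit a PLS model on a selected variable subset
#'
#' Runs the full calibration pipeline (standardise, cross-validated
#' component selection, NIPALS fit) restricted to `mask`, e.g. the
#' winning CARS subset or the VIP selection.
#'
#' @inheritParams pls_train
#' @param mask Indices of predictor columns to keep (non-empty).
#' @return A `pls_model` whose `variable_mask` records the subset.
#' @export
refit_with_mask <- function(X, y, mask, A_max = 10L, folds = 5L,
                            scheme = c("blocks", "random"), seed = 1L) {
  scheme <- match.arg(scheme)
  if (!length(mask)) stop("refit_with_mask: empty mask")
  pls_train(X, y, A_max = A_max, folds = folds, scheme = scheme,
            seed = seed, mask = mask)
}
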