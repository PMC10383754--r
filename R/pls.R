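#' Standardise predictor and response matrices
#'
#' Centres and scales every column to mean 0, sample standard deviation 1
#' (divisor `n - 1`). Zero-variance predictor columns carry no calibration
#' information and are dropped; their indices are reported so downstream
#' bookkeeping can map coefficients back to the original grid.
#'
#' @param X Numeric predictor matrix (n x m).
#' @param Y Numeric response matrix or vector.
#' @return List with `Xs`, `Ys`, the centring/scaling constants
#'   (`x_center`, `x_scale`, `y_center`, `y_scale`) and `keep`, the
#'   retained predictor column indices.
#' @export
standardize <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2L) stop("standardize: need n >= 2")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, sd)
  keep <- which(x_scale > 1e-12)
  if (!length(keep)) stop("standardize: all predictor columns constant")
  y_center <- colMeans(Y)
  y_scale <- apply(Y, 2L, sd)
  if (any(y_scale <= 1e-12)) stop("standardize: zero-variance response")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, x_center[keep]),
              2L, x_scale[keep], `/`)
  Ys <- sweep(sweep(Y, 2L, y_center), 2L, y_scale, `/`)
  list(Xs = Xs, Ys = Ys,
       x_center = x_center[keep], x_scale = x_scale[keep],
       y_center = y_center, y_scale = y_scale, keep = keep)
}

#' NIPALS partial least squares on standardised data
#'
#' Extracts `A` latent variables by the NIPALS iteration: the score
#' surrogate `u` starts from the first response column; weights
#' `w = X'u / u'u` are normalised to unit length; scores `t = Xw`;
#' `u = Y't / t't`; iterate until the relative change of `t` falls below
#' `tol`. After convergence `X` and `Y` are deflated by the rank-one
#' contributions `t p'` and `t q'` with loadings `p = X't / t't`,
#' `q = Y't / t't`. Regression coefficients on the standardised scale are
#' `B = W (P'W)^{-1} Q'`. For a single-column response the inner loop
#' converges in one pass per component.
#'
#' @param Xs,Ys Standardised matrices (see [standardize()]).
#' @param A Number of latent variables to extract.
#' @param tol Convergence tolerance on the relative score change.
#' @param max_iter Maximum inner iterations per component (warn and accept
#'   on hitting it).
#' @param on_exhaust What to do when the residual rank is exhausted before
#'   `A` components: `"error"` (default) or `"truncate"` to return the
#'   achieved components.
#' @return List of class `nipals_fit` with `W`, `P`, `Q`, `T`, `U` and the
#'   coefficient matrix `B` for `A` components.
#' @export
nipals_fit <- function(Xs, Ys, A, tol = 1e-10, max_iter = 500L,
                       on_exhaust = c("error", "truncate")) {
  on_exhaust <- match.arg(on_exhaust)
  Xs <- as.matrix(Xs); Ys <- as.matrix(Ys)
  n <- nrow(Xs); m <- ncol(Xs); p <- ncol(Ys)
  if (A < 1L) stop("A must be >= 1")
  W <- matrix(0, m, A); P <- matrix(0, m, A)
  Q <- matrix(0, p, A); Tm <- matrix(0, n, A); U <- matrix(0, n, A)
  Xd <- Xs; Yd <- Ys
  achieved <- 0L
  for (a in seq_len(A)) {
    u <- Yd[, 1L]
    t_old <- rep(0, n)
    converged <- FALSE
    exhausted <- FALSE
    for (it in seq_len(max_iter)) {
      w <- as.numeric(crossprod(Xd, u)) / sum(u * u)
      nw <- sqrt(sum(w * w))
      if (nw < 1e-14) { exhausted <- TRUE; break }
      w <- w / nw
      t <- as.numeric(Xd %*% w)
      tt <- sum(t * t)
      if (tt < 1e-14) { exhausted <- TRUE; break }
      qv <- as.numeric(crossprod(Yd, t)) / tt
      u <- as.numeric(Yd %*% qv)
      if (sqrt(sum((t - t_old)^2)) <= tol * sqrt(tt)) {
        converged <- TRUE
        break
      }
      t_old <- t
    }
    if (exhausted) {
      if (on_exhaust == "error")
        stop("nipals_fit: rank exhausted after ", a - 1L, " component(s)")
      break
    }
    if (!converged)
      warning("nipals_fit: component ", a, " not converged after ",
              max_iter, " iterations; accepted")
    pa <- as.numeric(crossprod(Xd, t)) / tt
    qa <- as.numeric(crossprod(Yd, t)) / tt
    Xd <- Xd - tcrossprod(t, pa)
    Yd <- Yd - tcrossprod(t, qa)
    W[, a] <- w; P[, a] <- pa; Q[, a] <- qa; Tm[, a] <- t; U[, a] <- u
    achieved <- a
  }
  idx <- seq_len(achieved)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Q <- Q[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
  U <- U[, idx, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(W = W, P = P, Q = Q, T = Tm, U = U, B = B, A = achieved),
            class = "nipals_fit")
}

# Coefficients truncated to the first `a` components.
nipals_coef <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  Q <- fit$Q[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Fit a PLS soft-sensor model
#'
#' Full calibration pipeline for a single response: standardise, select
#' the number of latent variables by cross-validation (unless `A` is
#' given), and fit the NIPALS model. Both predictors and the response are
#' standardised; coefficients are stored on the standardised scale and
#' back-transformed at prediction time.
#'
#' @param X Predictor matrix (spectra, one row per observation).
#' @param y Response vector.
#' @param A_max Largest candidate number of latent variables.
#' @param A Fixed number of latent variables; `NULL` selects by
#'   cross-validation.
#' @param folds,scheme,seed Cross-validation settings, see
#'   [cross_validate()].
#' @param rel_tol Parsimony tolerance for [select_components()].
#' @param mask Optional predictor column indices to restrict the model to
#'   (variable selection); recorded in the model.
#' @return Object of class `pls_model` with centring/scaling constants,
#'   `W`, `P`, `Q`, `T`, coefficients `B`, component count `A`,
#'   `variable_mask` (indices into the original predictor grid), the
#'   original predictor count `m_full`, and the CV curve when computed.
#' @export
pls_train <- function(X, y, A_max = 10L, A = NULL, folds = 5L,
                      scheme = c("blocks", "random"), seed = 1L,
                      rel_tol = 0.05, mask = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  m_full <- ncol(X)
  if (is.null(mask)) mask <- seq_len(m_full)
  if (!length(mask)) stop("pls_train: empty variable mask")
  if (any(mask < 1L | mask > m_full)) stop("pls_train: mask out of range")
  Xm <- X[, mask, drop = FALSE]
  curve <- NULL
  if (is.null(A)) {
    curve <- cross_validate(Xm, y, A_max = A_max, folds = folds,
                            scheme = scheme, seed = seed)
    A <- select_components(curve, rel_tol = rel_tol)
  }
  st <- standardize(Xm, y)
  A <- min(A, qr(st$Xs)$rank, nrow(Xm) - 1L)
  fit <- nipals_fit(st$Xs, st$Ys, A, on_exhaust = "truncate")
  structure(list(
    x_center = st$x_center, x_scale = st$x_scale,
    y_center = st$y_center, y_scale = st$y_scale,
    W = fit$W, P = fit$P, Q = fit$Q, T = fit$T, B = fit$B, A = fit$A,
    variable_mask = mask[st$keep], m_full = m_full, cv = curve),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$A, " latent variable(s), ",
      length(x$variable_mask), "/", x$m_full, " predictors retained\n",
      sep = "")
  invisible(x)
}

#' Predict responses from a fitted PLS model
#'
#' @param object A `pls_model` from [pls_train()].
#' @param newdata Predictor matrix: either on the full original grid
#'   (columns are subset by the model's `variable_mask`) or already
#'   restricted to the retained predictors.
#' @param ... Unused.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  nm <- length(object$variable_mask)
  if (ncol(Xn) == object$m_full) {
    Xn <- Xn[, object$variable_mask, drop = FALSE]
  } else if (ncol(Xn) != nm) {
    stop("predict: newdata has ", ncol(Xn), " columns; expected ",
         object$m_full, " (full grid) or ", nm, " (masked)")
  }
  Xs <- sweep(sweep(Xn, 2L, object$x_center), 2L, object$x_scale, `/`)
  Ys <- Xs %*% object$B
  as.numeric(sweep(sweep(Ys, 2L, object$y_scale, `*`), 2L, object$y_center, `+`))
}

#' Root-mean-square error and coefficient of determination
#'
#' `rmse(y, yhat) = sqrt(mean((y - yhat)^2))`;
#' `r2(y, yhat) = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return A single number.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("rmse: length mismatch")
  if (length(y) < 2L) stop("rmse: need >= 2 values")
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
r2 <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("r2: length mismatch")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("r2: zero-variance y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Cross-validated error curve over latent-variable counts
#'
#' Computes RMSECV for `a = 1..A_max` by K-fold cross-validation with
#' standardisation refitted inside every fold (no information leakage).
#' The default fold scheme is contiguous blocks in row order: spectra are
#' a time series, and block folds reduce leakage between temporally
#' adjacent spectra. `scheme = "random"` gives shuffled folds (seeded).
#' `folds = n` is leave-one-out and is deterministic.
#'
#' If some training fold cannot support `A_max` components the curve is
#' truncated to the attainable count, with a message.
#'
#' @inheritParams pls_train
#' @return Object of class `cv_curve`: list with `rmsecv` (one value per
#'   candidate component count), `A_max`, `folds`, `scheme`, `seed` and
#'   `chosen` (filled by [select_components()] via [pls_train()]).
#' @export
cross_validate <- function(X, y, A_max = 10L, folds = 5L,
                           scheme = c("blocks", "random"), seed = 1L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need n >= folds")
  fold_id <- sort(rep(seq_len(folds), length.out = n))   # contiguous blocks
  if (scheme == "random")
    fold_id <- with_seed(seed, sample(fold_id))
  a_cap <- A_max
  preds <- matrix(NA_real_, n, A_max)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); va <- which(fold_id == f)
    st <- standardize(X[tr, , drop = FALSE], y[tr])
    a_f <- min(A_max, qr(st$Xs)$rank, length(tr) - 1L)
    fit <- nipals_fit(st$Xs, st$Ys, a_f, on_exhaust = "truncate")
    a_f <- fit$A                 # NIPALS may exhaust the rank earlier
    a_cap <- min(a_cap, a_f)
    Xv <- sweep(sweep(X[va, st$keep, drop = FALSE], 2L, st$x_center),
                2L, st$x_scale, `/`)
    for (a in seq_len(a_f)) {
      yh <- Xv %*% nipals_coef(fit, a)
      preds[va, a] <- yh * st$y_scale + st$y_center
    }
  }
  if (a_cap < A_max)
    message("cross_validate: curve truncated to ", a_cap,
            " attainable component(s)")
  rmsecv <- vapply(seq_len(a_cap), function(a) rmse(y, preds[, a]), numeric(1))
  structure(list(rmsecv = rmsecv, A_max = a_cap, folds = folds,
                 scheme = scheme, seed = seed, chosen = NA_integer_),
            class = "cv_curve")
}

#' Choose the number of latent variables from a CV curve
#'
#' Formalises the usual elbow reading of an RMSECV curve ("no drastic
#' drop beyond here") as a parsimony rule: the smallest component count
#' whose RMSECV is within `rel_tol` (default 5%) of the curve minimum.
#'
#' @param curve A `cv_curve` from [cross_validate()], or a bare numeric
#'   vector of RMSECV values.
#' @param rel_tol Relative tolerance above the minimum.
#' @return Integer component count.
#' @export
select_components <- function(curve, rel_tol = 0.05) {
  v <- if (inherits(curve, "cv_curve")) curve$rmsecv else as.numeric(curve)
  if (!length(v)) stop("select_components: empty curve")
  which(v <= (1 + rel_tol) * min(v))[1L]
}
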