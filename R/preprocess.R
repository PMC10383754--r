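#' Savitzky-Golay filter specification
#'
#' Describes a local least-squares polynomial filter over a moving window
#' of `2k + 1` channels: fit a polynomial of order `poly_order` through
#' the window and evaluate either the fitted value (`smooth`) or its
#' first/second derivative (`d1`, `d2`) at the window centre.
#'
#' @param half_window Integer `k >= 1`; window length is `2k + 1`
#'   channels (the conventional "window length 15" equals `k = 7`).
#' @param poly_order Integer polynomial order `>= 0`; must satisfy
#'   `poly_order <= 2k`, and `>= 1` (`>= 2`) for target `d1` (`d2`).
#' @param target One of `"smooth"`, `"d1"`, `"d2"`.
#' @return An object of class `savgol_spec`.
#' @export
savgol_spec <- function(half_window = 7L, poly_order = 2L,
                        target = c("smooth", "d1", "d2")) {
  target <- match.arg(target)
  k <- as.integer(half_window); p <- as.integer(poly_order)
  if (k < 1L) stop("half_window must be >= 1")
  if (p < 0L || p > 2L * k) stop("poly_order must be in [0, 2k]")
  d <- c(smooth = 0L, d1 = 1L, d2 = 2L)[[target]]
  if (p < d) stop("target '", target, "' needs poly_order >= ", d)
  structure(list(half_window = k, poly_order = p, target = target, deriv = d),
            class = "savgol_spec")
}

# Exact integer determinant via cofactor expansion (matrices up to ~8x8;
# all intermediates are integers representable in doubles).
int_det <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m[1, 1])
  if (n == 2L) return(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  acc <- 0
  for (j in seq_len(n)) {
    if (m[1, j] == 0) next
    acc <- acc + (-1)^(1 + j) * m[1, j] * int_det(m[-1, -j, drop = FALSE])
  }
  acc
}

int_adjugate_col <- function(m, col) {
  n <- nrow(m)
  # adj(m)[i, col] = (-1)^(col + i) * det(m[-col, -i])
  vapply(seq_len(n), function(i) {
    (-1)^(col + i) * int_det(m[-col, -i, drop = FALSE])
  }, numeric(1))
}

#' Savitzky-Golay convolution weights, exact
#'
#' Derives the convolution weights of the least-squares polynomial filter
#' by exact integer arithmetic (Gram determinant and adjugate of the
#' window design matrix), so the classical printed integer tables are
#' reproduced bit-exactly. The filtered value at channel `j` is
#' `sum(c[h] * x[j + h]) / N` for offsets `h = -k..k`; derivative weights
#' assume unit channel spacing and include the `d!` evaluation factor.
#'
#' For the 5-point quadratic window (`k = 2`) this yields the classical
#' tables: smoothing `(-3, 12, 17, 12, -3) / 35`, first derivative
#' `(-2, -1, 0, 1, 2) / 10`, second derivative `(2, -1, -2, -1, 2) / 7`.
#'
#' @param spec A [savgol_spec()].
#' @return List with integer `weights` (named by offset `-k..k`, reduced
#'   by their gcd with `N`) and integer normalisation `N`.
#' @export
savgol_coefficients <- function(spec) {
  stopifnot(inherits(spec, "savgol_spec"))
  k <- spec$half_window; p <- spec$poly_order; d <- spec$deriv
  h <- -k:k
  S <- outer(h, 0:p, `^`)            # (2k+1) x (p+1) integer design
  G <- crossprod(S)                  # integer Gram matrix
  N <- int_det(G)
  adj_col <- int_adjugate_col(G, d + 1L)
  w <- as.numeric(S %*% adj_col) * factorial(d)
  # reduce weights and N by their common divisor; keep N > 0
  g <- Reduce(gcd2, c(abs(w[w != 0]), abs(N)))
  if (is.na(g) || g == 0) g <- 1
  w <- w / g; N <- N / g
  if (N < 0) { w <- -w; N <- -N }
  if (max(abs(c(w, N))) >= 2^53)
    stop("window/order too large for exact integer arithmetic")
  list(weights = setNames(w, h), N = N)
}

gcd2 <- function(a, b) {
  while (b > 0.5) { r <- a %% b; a <- b; b <- r }
  a
}

# Least-squares polynomial filter weights for an arbitrary (possibly
# asymmetric) offset window, evaluated at offset 0; floating point.
ls_fit_weights <- function(offsets, poly_order, deriv) {
  S <- outer(offsets, 0:poly_order, `^`)
  G <- crossprod(S)
  a <- solve(G, t(S))                # (p+1) x n: x -> polynomial coeffs
  a[deriv + 1L, ] * factorial(deriv)
}

#' Apply a Savitzky-Golay filter to one spectrum
#'
#' Interior channels get the exact symmetric-window convolution; the `k`
#' channels at each edge are computed by asymmetric least-squares fits of
#' the same polynomial order over the available window, so the output has
#' the same length as the input.
#'
#' @param x Numeric vector, `length(x) >= 2k + 1`.
#' @param spec A [savgol_spec()].
#' @return Numeric vector of filtered values, same length as `x`.
#' @export
savgol_apply <- function(x, spec) {
  stopifnot(inherits(spec, "savgol_spec"))
  k <- spec$half_window
  n <- length(x)
  if (n < 2L * k + 1L)
    stop("spectrum shorter than filter window (", n, " < ", 2L * k + 1L, ")")
  cf <- savgol_coefficients(spec)
  out <- as.numeric(stats::filter(x, rev(cf$weights), sides = 2)) / cf$N
  for (j in seq_len(k)) {
    off <- (1L - j):k                        # left edge: offsets -(j-1)..k
    w <- ls_fit_weights(off, spec$poly_order, spec$deriv)
    out[j] <- sum(w * x[j + off])
    jr <- n - j + 1L                         # right edge, mirrored window
    off <- -k:(j - 1L)
    w <- ls_fit_weights(off, spec$poly_order, spec$deriv)
    out[jr] <- sum(w * x[jr + off])
  }
  out
}

#' Standard normal variate (SNV) normalisation
#'
#' Centres one spectrum to mean zero and scales it to unit standard
#' deviation, using the population standard deviation (divisor `N`).
#' SNV removes per-spectrum offset and multiplicative gain effects
#' (laser power or alignment drift between acquisitions).
#'
#' @param x Numeric vector, `length(x) >= 2`, non-constant.
#' @return Normalised numeric vector with mean 0 and population sd 1.
#' @export
snv <- function(x) {
  if (length(x) < 2L) stop("snv: need at least 2 channels")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("snv: zero-variance (constant) spectrum")
  (x - m) / s
}

#' Preprocess a spectra set: Savitzky-Golay filter, then SNV
#'
#' Applies the filter and (optionally) SNV to every spectrum. The default
#' specification is the calibration setting used throughout the package:
#' quadratic smoothing over a 15-sample window (`k = 7`) followed by SNV.
#'
#' @param s A [spectra_set()].
#' @param spec A [savgol_spec()]; `NULL` skips filtering.
#' @param do_snv Apply SNV per spectrum after filtering?
#' @return A `spectra_set` with filtered intensities; the applied spec and
#'   SNV flag are recorded in the `"preprocess"` attribute.
#' @export
preprocess_spectra <- function(s, spec = savgol_spec(7L, 2L, "smooth"),
                               do_snv = TRUE) {
  stopifnot(inherits(s, "spectra_set"))
  mat <- s$intensities
  if (!is.null(spec))
    mat <- savgol_apply_matrix(mat, spec)
  if (do_snv) {
    ctr <- mat - rowMeans(mat)
    sds <- sqrt(rowMeans(ctr^2))
    if (any(sds == 0)) stop("snv: zero-variance (constant) spectrum")
    mat <- ctr / sds
  }
  out <- spectra_set(s$axis, mat, s$timestamps, s$ids)
  attr(out, "preprocess") <- list(savgol = spec, snv = do_snv)
  out
}

# Row-wise Savitzky-Golay with the edge weights computed once per call;
# equivalent to savgol_apply() per row.
savgol_apply_matrix <- function(mat, spec) {
  k <- spec$half_window
  n <- ncol(mat)
  if (n < 2L * k + 1L)
    stop("spectrum shorter than filter window (", n, " < ", 2L * k + 1L, ")")
  cf <- savgol_coefficients(spec)
  out <- t(stats::filter(t(mat), rev(cf$weights), sides = 2)) / cf$N
  for (j in seq_len(k)) {
    off <- (1L - j):k
    w <- ls_fit_weights(off, spec$poly_order, spec$deriv)
    out[, j] <- mat[, j + off, drop = FALSE] %*% w
    jr <- n - j + 1L
    off <- -k:(j - 1L)
    w <- ls_fit_weights(off, spec$poly_order, spec$deriv)
    out[, jr] <- mat[, jr + off, drop = FALSE] %*% w
  }
  dimnames(out) <- dimnames(mat)
  out
}
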