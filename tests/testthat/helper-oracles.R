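# Independent oracles used across tests. These are deliberately separate,
# naive implementations: they share no code with the package internals.

# Textbook NIPALS, transcribed step by step with explicit loops and
# repeated matrix deflation; single-response only.
oracle_nipals_b <- function(Xs, ys, A) {
  Xd <- as.matrix(Xs)
  Yd <- matrix(as.numeric(ys), ncol = 1)
  m <- ncol(Xd)
  W <- NULL; P <- NULL; Q <- NULL
  for (a in seq_len(A)) {
    u <- Yd[, 1]
    repeat {
      w <- t(Xd) %*% u / drop(t(u) %*% u)
      w <- w / sqrt(drop(t(w) %*% w))
      t_score <- Xd %*% w
      u_new <- Yd %*% (t(Yd) %*% t_score / drop(t(t_score) %*% t_score))
      if (sqrt(sum((u_new - u)^2)) < 1e-12 * max(sqrt(sum(u^2)), 1)) break
      u <- u_new
    }
    tt <- drop(t(t_score) %*% t_score)
    p <- t(Xd) %*% t_score / tt
    q <- t(Yd) %*% t_score / tt
    Xd <- Xd - t_score %*% t(p)
    Yd <- Yd - t_score %*% t(q)
    W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q)
  }
  W %*% solve(t(P) %*% W) %*% t(Q)
}

# Brute-force Savitzky-Golay: per-window polynomial least squares via lm(),
# evaluated (or differentiated) at the window centre.
oracle_savgol_point <- function(x, j, k, order, deriv) {
  n <- length(x)
  off <- max(1L, j - k):min(n, j + k) - j
  df <- data.frame(h = off, y = x[j + off])
  fit <- lm(y ~ poly(h, degree = order, raw = TRUE), data = df)
  cf <- coef(fit)
  unname(cf[deriv + 1L] * factorial(deriv))
}

# Standardise columns (divisor n - 1), matching the package's convention.
oracle_scale <- function(M) {
  M <- as.matrix(M)
  sweep(sweep(M, 2, colMeans(M)), 2, apply(M, 2, sd), "/")
}

# Small latent-structure regression problem: y depends on `informative`
# columns of X only.
make_varsel_problem <- function(seed, n = 60, m = 50,
                                informative = c(3L, 17L), noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  beta <- numeric(m)
  beta[informative] <- c(3, -2)[seq_along(informative)]
  y <- as.numeric(X %*% beta + rnorm(n, sd = noise))
  list(X = X, y = y, informative = informative)
}
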