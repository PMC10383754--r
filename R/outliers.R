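#' Monte-Carlo prediction-error profile per spectrum
#'
#' Repeated random sub-sampling validation for outlier screening: in each
#' repeat the data are split 4:1 (by default) into training and test
#' sets, a full PLS pipeline is fitted on the training part, and the
#' absolute prediction error of every test spectrum is recorded. Each
#' spectrum lands in many different test sets, so a mean error and an
#' error standard deviation accumulate per spectrum. Spectra that are
#' consistently mispredicted — regardless of which spectra they were
#' modelled with — are outlier candidates.
#'
#' @param X Predictor matrix (preprocessed spectra), n >= 10 rows.
#' @param y Reference values.
#' @param n_repeats Number of Monte-Carlo splits (>= 20).
#' @param train_fraction Training share of each split.
#' @param A_max,folds,scheme Settings for the inner PLS pipeline
#'   ([pls_train()]).
#' @param seed Integer seed.
#' @param ids Optional spectrum labels (defaults to row numbers).
#' @return Object of class `outlier_report`: data frame `profile` with
#'   columns `id`, `n_appearances`, `mean_err`, `std_err`, `flagged`,
#'   plus fields `n_repeats`, `train_fraction`, `seed` and (after
#'   [flag_outliers()]) the thresholds used.
#' @export
mc_error_profile <- function(X, y, n_repeats = 100L, train_fraction = 0.8,
                             A_max = 10L, folds = 5L,
                             scheme = c("blocks", "random"), seed = 1L,
                             ids = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 10L) stop("mc_error_profile: need n >= 10")
  if (n_repeats < 20L) stop("mc_error_profile: need n_repeats >= 20")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  cnt <- integer(n); s1 <- numeric(n); s2 <- numeric(n)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      tr <- sample.int(n, round(train_fraction * n))
      te <- setdiff(seq_len(n), tr)
      fit <- pls_train(X[tr, , drop = FALSE], y[tr],
                       A_max = A_max, folds = folds, scheme = scheme)
      err <- abs(y[te] - predict(fit, X[te, , drop = FALSE]))
      cnt[te] <- cnt[te] + 1L
      s1[te] <- s1[te] + err
      s2[te] <- s2[te] + err^2
    }
  })
  if (any(cnt == 0L))
    stop("mc_error_profile: some spectra never entered a test set; ",
         "increase n_repeats")
  mean_err <- s1 / cnt
  var_err <- pmax(0, (s2 - s1^2 / cnt) / pmax(1L, cnt - 1L))
  std_err <- ifelse(cnt > 1L, sqrt(var_err), 0)
  structure(list(
    profile = data.frame(id = ids, n_appearances = cnt,
                         mean_err = mean_err, std_err = std_err,
                         flagged = FALSE, stringsAsFactors = FALSE),
    n_repeats = n_repeats, train_fraction = train_fraction, seed = seed,
    thresholds = NULL),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", nrow(x$profile), " spectra, ", x$n_repeats,
      " repeats; ", sum(x$profile$flagged), " flagged\n", sep = "")
  invisible(x)
}

#' Flag outlier spectra from a Monte-Carlo error profile
#'
#' Robust thresholding of the per-spectrum error profile: spectrum `i` is
#' flagged when `mean_i > median(mean) + c_mean * MAD(mean)` or when the
#' combined statistic `mean_i + std_i` exceeds the analogous robust
#' threshold. Median/MAD are used (rather than mean/sd) because the error
#' population is itself contaminated by the outliers being hunted.
#'
#' @param report An `outlier_report` from [mc_error_profile()].
#' @param c_mean,c_combined Robust cut-off factors.
#' @return The report with `profile$flagged` and `thresholds` filled in.
#' @export
flag_outliers <- function(report, c_mean = 3.5, c_combined = 3.5) {
  stopifnot(inherits(report, "outlier_report"))
  p <- report$profile
  thr_mean <- median(p$mean_err) + c_mean * mad(p$mean_err)
  comb <- p$mean_err + p$std_err
  thr_comb <- median(comb) + c_combined * mad(comb)
  report$profile$flagged <- p$mean_err > thr_mean | comb > thr_comb
  report$thresholds <- list(mean = thr_mean, combined = thr_comb,
                            c_mean = c_mean, c_combined = c_combined)
  report
}

#' Remove flagged outlier spectra and refit the soft sensor
#'
#' Drops flagged spectra and refits the full PLS pipeline; with
#' `max_rounds > 1` the error profile is recomputed and the removal
#' repeated until no new spectra are flagged. As a guard against
#' over-zealous pruning (which over-fits the model to "typical" spectra),
#' never more than `max_removal` of the original rows are removed in
#' total; hitting the cap stops with a warning and returns the model
#' fitted so far.
#'
#' @inheritParams mc_error_profile
#' @param report An `outlier_report`; if unflagged, [flag_outliers()] is
#'   applied with default factors.
#' @param max_rounds Maximum profile/flag/remove rounds (0 = remove
#'   nothing, just fit on all rows).
#' @param max_removal Cap on the total removed fraction.
#' @return List with `model` (final `pls_model`), `kept` (row indices
#'   retained), `removed_ids`, and `report` (last round's profile).
#' @export
remove_and_refit <- function(X, y, report = NULL, max_rounds = 1L,
                             n_repeats = 100L, train_fraction = 0.8,
                             A_max = 10L, folds = 5L,
                             scheme = c("blocks", "random"), seed = 1L,
                             max_removal = 0.2, ids = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  keep <- seq_len(n)
  removed <- character(0)
  round_i <- 0L
  while (round_i < max_rounds) {
    round_i <- round_i + 1L
    if (is.null(report)) {
      report <- mc_error_profile(X[keep, , drop = FALSE], y[keep],
                                 n_repeats = n_repeats,
                                 train_fraction = train_fraction,
                                 A_max = A_max, folds = folds,
                                 scheme = scheme, seed = seed + round_i,
                                 ids = ids[keep])
    }
    if (is.null(report$thresholds)) report <- flag_outliers(report)
    bad <- report$profile$id[report$profile$flagged]
    report_out <- report
    report <- NULL                      # force re-profile next round
    if (!length(bad)) break
    if ((length(removed) + length(bad)) > max_removal * n) {
      warning("remove_and_refit: removal cap of ", 100 * max_removal,
              "% reached; stopping with the current model")
      break
    }
    removed <- c(removed, bad)
    keep <- which(!ids %in% removed)
  }
  if (round_i == 0L)
    report_out <- structure(list(profile = data.frame(
      id = ids, n_appearances = 0L, mean_err = NA_real_, std_err = NA_real_,
      flagged = FALSE, stringsAsFactors = FALSE),
      n_repeats = 0L, train_fraction = train_fraction, seed = seed,
      thresholds = NULL), class = "outlier_report")
  model <- pls_train(X[keep, , drop = FALSE], y[keep],
                     A_max = A_max, folds = folds, scheme = scheme)
  list(model = model, kept = keep, removed_ids = removed,
       report = report_out)
}

#' Write an outlier report as CSV
#'
#' @param report An `outlier_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  stopifnot(inherits(report, "outlier_report"))
  write.csv(report$profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
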