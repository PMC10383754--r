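#' Serialise a PLS model to JSON
#'
#' Writes all constants, masks and matrices (`W`, `P`, `Q`, `B`) plus
#' metadata needed to reload and apply the model elsewhere.
#'
#' @param model A `pls_model`.
#' @param path Output path; `read_pls_model()` inverts it.
#' @return `path` invisibly.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(
    class = "pls_model",
    A = model$A, m_full = model$m_full,
    variable_mask = model$variable_mask,
    x_center = model$x_center, x_scale = model$x_scale,
    y_center = model$y_center, y_scale = model$y_scale,
    W = model$W, P = model$P, Q = model$Q, B = model$B,
    cv = if (!is.null(model$cv)) list(rmsecv = model$cv$rmsecv,
                                      folds = model$cv$folds,
                                      scheme = model$cv$scheme))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    x_center = obj$x_center, x_scale = obj$x_scale,
    y_center = obj$y_center, y_scale = obj$y_scale,
    W = as.matrix(obj$W), P = as.matrix(obj$P), Q = matrix(obj$Q, nrow = 1),
    T = NULL, B = as.matrix(obj$B), A = obj$A,
    variable_mask = obj$variable_mask, m_full = obj$m_full,
    cv = obj$cv), class = "pls_model")
}

#' Run the full soft-sensor pipeline and tabulate per-variable results
#'
#' Wires the whole calibration chain for each requested reference
#' variable: preprocess spectra (Savitzky-Golay + SNV), pair with
#' reference measurements by acquisition time, split train/validation,
#' then fit and validate four calibration variants — plain PLS,
#' VIP-selected PLS, CARS-selected PLS, and CARS followed by Monte-Carlo
#' outlier removal. The report lists validation RMSEP and R-squared per
#' variable and method. After calibration the chosen model can be
#' applied to every spectrum (not only the paired ones) via
#' [reconstruct_series()] to recover densely sampled time courses.
#'
#' @param spectra A [spectra_set()] of raw spectra.
#' @param refs A [reference_table()].
#' @param variables Reference columns to model; defaults to every known
#'   variable present in `refs`.
#' @param methods Subset of `c("pls", "vip", "cars", "cars_outlier")`.
#' @param max_lag_s Pairing tolerance (s).
#' @param savgol A [savgol_spec()] for preprocessing.
#' @param train_fraction Train share of the paired data.
#' @param A_max,folds PLS settings.
#' @param cars_iterations CARS iteration budget.
#' @param mc_repeats Monte-Carlo splits for outlier profiling.
#' @param seed Master seed (splits, CARS, outlier profiling).
#' @param out_dir Optional directory; when given, the report (CSV) and
#'   per-variable model JSONs are written there.
#' @return List with `report` (data frame: variable, method, n_pairs,
#'   A, n_vars, rmsep, r2) and `models` (nested list of `pls_model`s).
#' @export
run_pipeline <- function(spectra, refs,
                         variables = intersect(names(reference_units),
                                               names(refs)),
                         methods = c("pls", "vip", "cars", "cars_outlier"),
                         max_lag_s = 1800,
                         savgol = savgol_spec(7L, 2L, "smooth"),
                         train_fraction = 0.8, A_max = 10L, folds = 5L,
                         cars_iterations = 50L, mc_repeats = 50L,
                         seed = 1L, out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(variables)) stop("run_pipeline: no variables to model")
  prep <- preprocess_spectra(spectra, spec = savgol, do_snv = TRUE)
  rows <- list(); models <- list()
  for (v in variables) {
    ds <- pair_by_time(prep, refs, v, max_lag_s = max_lag_s)
    sp <- split_train_validation(ds, fraction = train_fraction, seed = seed)
    tr <- sp$train; va <- sp$validation
    evaluate <- function(model) {
      yhat <- predict(model, va$X)
      c(rmsep = rmse(va$y, yhat), r2 = r2(va$y, yhat))
    }
    fits <- list()
    plain <- pls_train(tr$X, tr$y, A_max = A_max, folds = folds, seed = seed)
    if ("pls" %in% methods) fits$pls <- plain
    if ("vip" %in% methods) {
      vip <- vip_scores(plain)
      mask <- if (length(vip$selected)) vip$selected else plain$variable_mask
      fits$vip <- refit_with_mask(tr$X, tr$y, mask, A_max = A_max,
                                  folds = folds, seed = seed)
    }
    if (any(c("cars", "cars_outlier") %in% methods)) {
      cars <- cars_select(tr$X, tr$y, n_iterations = cars_iterations,
                          A_max = A_max, folds = folds, seed = seed)
      if ("cars" %in% methods)
        fits$cars <- refit_with_mask(tr$X, tr$y, cars$winner,
                                     A_max = A_max, folds = folds,
                                     seed = seed)
      if ("cars_outlier" %in% methods) {
        Xm <- tr$X[, cars$winner, drop = FALSE]
        rr <- remove_and_refit(Xm, tr$y, max_rounds = 1L,
                               n_repeats = mc_repeats, A_max = A_max,
                               folds = folds, seed = seed, ids = tr$ids)
        m <- rr$model
        # re-express the mask on the original grid for prediction
        m$variable_mask <- cars$winner[m$variable_mask]
        m$m_full <- ncol(tr$X)
        fits$cars_outlier <- m
      }
    }
    for (meth in names(fits)) {
      ev <- evaluate(fits[[meth]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, method = meth, n_pairs = length(ds$y),
        A = fits[[meth]]$A, n_vars = length(fits[[meth]]$variable_mask),
        rmsep = ev[["rmsep"]], r2 = ev[["r2"]])
    }
    models[[v]] <- fits
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    for (v in names(models))
      for (meth in names(models[[v]]))
        write_pls_model(models[[v]][[meth]],
                        file.path(out_dir, paste0("model_", v, "_", meth,
                                                  ".json")))
  }
  list(report = report, models = models)
}

#' Reconstruct a dense time series by applying a soft sensor to all
#' spectra
#'
#' Calibration uses only the few spectra paired with off-line reference
#' measurements, but once a model is built every collected spectrum can
#' be scored, turning the half-hourly Raman record into a dense time
#' course of the process variable.
#'
#' @param model A `pls_model`.
#' @param spectra A [spectra_set()] of *raw* spectra.
#' @param savgol,do_snv Preprocessing to apply before prediction (must
#'   match the calibration preprocessing).
#' @return Data frame with `timestamp` (s), `id` and `value`.
#' @export
reconstruct_series <- function(model, spectra,
                               savgol = savgol_spec(7L, 2L, "smooth"),
                               do_snv = TRUE) {
  prep <- preprocess_spectra(spectra, spec = savgol, do_snv = do_snv)
  data.frame(timestamp = prep$timestamps, id = prep$ids,
             value = predict(model, prep$intensities))
}
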