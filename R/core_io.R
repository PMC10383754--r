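#' Canonical reference variables and their units
#'
#' Named character vector mapping the reference variables measured by the
#' daily off-line analyser to their units: analyte concentrations in g/L,
#' ammonium in mmol/L, viable and total cell concentration (VCC, TCC) in
#' 1e6 cells/mL.
#'
#' @export
reference_units <- c(
  glucose   = "g/L",
  glutamine = "g/L",
  glutamate = "g/L",
  lactate   = "g/L",
  ammonium  = "mmol/L",
  vcc       = "1e6 cells/mL",
  tcc       = "1e6 cells/mL"
)

#' Construct a spectra set
#'
#' A `spectra_set` holds a batch of Raman spectra on a common wavenumber
#' axis: the axis (cm^-1, strictly increasing), one intensity row per
#' spectrum, an acquisition timestamp per row (seconds since batch start)
#' and a unique id per row. Rows are stored sorted by timestamp.
#'
#' @param axis Numeric vector of Raman shifts (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, one row per spectrum; `ncol` must
#'   equal `length(axis)`.
#' @param timestamps Numeric vector of acquisition times (s), one per row.
#' @param ids Character vector of unique spectrum labels; defaults to
#'   `"s1", "s2", ...` in timestamp order.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(axis, intensities, timestamps, ids = NULL) {
  axis <- as.numeric(axis)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  timestamps <- as.numeric(timestamps)
  if (ncol(intensities) != length(axis))
    stop("spectra_set: each spectrum must have one value per axis channel (",
         ncol(intensities), " != ", length(axis), ")")
  if (nrow(intensities) != length(timestamps))
    stop("spectra_set: need one timestamp per spectrum")
  if (length(axis) >= 2L && any(diff(axis) <= 0))
    stop("spectra_set: wavenumber axis must be strictly increasing")
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(intensities)))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("spectra_set: duplicate spectrum id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(timestamps)
  structure(
    list(axis = axis,
         intensities = intensities[ord, , drop = FALSE],
         timestamps = timestamps[ord],
         ids = ids[ord]),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$intensities), " spectra x ",
      length(x$axis), " channels (",
      format(min(x$axis)), "-", format(max(x$axis)), " cm^-1), t = ",
      format(min(x$timestamps)), "-", format(max(x$timestamps)), " s\n",
      sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$intensities)

#' Subset a spectra set by row
#'
#' @param x A `spectra_set`.
#' @param i Row index (integer, logical or id character vector).
#' @param ... Unused.
#' @return A `spectra_set` with the selected spectra.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  spectra_set(x$axis, x$intensities[i, , drop = FALSE],
              x$timestamps[i], x$ids[i])
}

parse_times <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) return(num)
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                 "%Y-%m-%d"))
  if (anyNA(t)) stop("cannot parse timestamps: ",
                     paste(head(x[is.na(t)], 3), collapse = ", "))
  as.numeric(t)
}

#' Read / write spectra as delimited text
#'
#' One documented dialect: comma-separated, decimal point, UTF-8. Columns
#' `id`, `timestamp`, then one column per wavenumber with the numeric
#' Raman shift as the header. Timestamps may be numeric seconds or
#' ISO-8601 date-times; they are normalised to numeric seconds on read.
#'
#' @param path File path.
#' @return `read_spectra()` returns a [spectra_set()];
#'   `write_spectra()` returns `path` invisibly.
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 3L) stop("spectra file needs id, timestamp and >= 1 channel")
  nm <- names(df)
  if (!identical(nm[1:2], c("id", "timestamp")))
    stop("spectra file must start with 'id,timestamp' columns")
  axis <- suppressWarnings(as.numeric(nm[-(1:2)]))
  if (anyNA(axis)) stop("spectra header: non-numeric wavenumber column name")
  if (length(axis) >= 2L && any(diff(axis) <= 0))
    stop("spectra header: wavenumber axis must be strictly increasing")
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(mat)) stop("spectra file: ragged or non-numeric intensity rows")
  if (anyNA(mat)) stop("spectra file: missing intensity values")
  spectra_set(axis, mat, parse_times(df$timestamp), df$id)
}

#' @rdname read_spectra
#' @param s A `spectra_set` to write.
#' @export
write_spectra <- function(s, path) {
  df <- data.frame(id = s$ids, timestamp = s$timestamps, check.names = FALSE)
  mat <- as.data.frame(s$intensities)
  names(mat) <- format(s$axis, trim = TRUE, digits = 15)
  write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a reference measurement table
#'
#' Holds daily (or twice-daily) off-line reference measurements: a
#' timestamp column (seconds since batch start) plus named analyte /
#' cell-count columns in the units of [reference_units]. Missing values
#' are allowed per cell; each row must carry at least one measurement.
#'
#' @param timestamps Numeric vector (s) or ISO-8601 strings.
#' @param variables Data frame (or named list) of measurement columns.
#' @param batch_id Single string identifying the batch.
#' @return A data frame of class `reference_table` with a `timestamp`
#'   column first and a `batch_id` attribute.
#' @export
reference_table <- function(timestamps, variables, batch_id = "batch1") {
  variables <- as.data.frame(variables, check.names = FALSE)
  timestamps <- parse_times(timestamps)
  if (nrow(variables) != length(timestamps))
    stop("reference_table: one timestamp per row required")
  if (any(rowSums(!is.na(variables)) == 0L))
    stop("reference_table: every row needs at least one non-missing value")
  df <- cbind(data.frame(timestamp = timestamps), variables)
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, batch_id = as.character(batch_id),
            class = c("reference_table", "data.frame"))
}

#' @rdname read_spectra
#' @export
read_reference <- function(path) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"timestamp" %in% names(df)) stop("reference file needs a 'timestamp' column")
  batch <- if ("batch_id" %in% names(df)) as.character(df$batch_id[1]) else "batch1"
  vars <- df[, setdiff(names(df), c("timestamp", "batch_id")), drop = FALSE]
  reference_table(df$timestamp, vars, batch)
}

#' @rdname read_spectra
#' @param r A `reference_table` to write.
#' @export
write_reference <- function(r, path) {
  out <- cbind(as.data.frame(r), batch_id = attr(r, "batch_id"))
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair spectra with reference measurements by acquisition time
#'
#' Each reference row (the scarce resource: 1-2 measurements per day
#' against half-hourly spectra) is matched to the nearest-in-time
#' spectrum. A spectrum may serve at most one reference row; conflicts
#' are resolved greedily by smallest lag, then by earlier spectrum, and a
#' displaced reference falls back to its next-nearest free spectrum.
#' References with no free spectrum within `max_lag_s`, or with a missing
#' value for `variable`, are dropped and reported in the result.
#'
#' @param spectra A [spectra_set()].
#' @param refs A [reference_table()].
#' @param variable Name of the reference column to extract as response.
#' @param max_lag_s Maximum allowed |t_spectrum - t_reference| in seconds.
#' @return A `paired_dataset`: list with `X` (spectra matrix, one row per
#'   pair), `y` (reference values), `axis`, `ids`, `timestamps` (spectrum
#'   times), `pair_lags` (s), `variable`, and `dropped_refs` (timestamps of
#'   unmatched reference rows).
#' @export
pair_by_time <- function(spectra, refs, variable, max_lag_s = 1800) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(refs, "reference_table"))
  if (max_lag_s <= 0) stop("max_lag_s must be > 0")
  if (!variable %in% names(refs))
    stop("unknown reference variable: ", variable)
  rt <- refs$timestamp
  rv <- refs[[variable]]
  keep <- !is.na(rv)
  rt <- rt[keep]; rv <- rv[keep]
  st <- spectra$timestamps
  if (length(rt) == 0L || length(st) == 0L) stop("nothing to pair")

  # candidate (ref, spectrum) pairs within tolerance, greedy by (lag, s-time)
  cand <- do.call(rbind, lapply(seq_along(rt), function(i) {
    lag <- abs(st - rt[i])
    j <- which(lag <= max_lag_s)
    if (!length(j)) return(NULL)
    data.frame(ref = i, spec = j, lag = lag[j])
  }))
  sel_ref <- integer(0); sel_spec <- integer(0); sel_lag <- numeric(0)
  if (!is.null(cand)) {
    cand <- cand[order(cand$lag, st[cand$spec], cand$ref), , drop = FALSE]
    used_ref <- logical(length(rt)); used_spec <- logical(length(st))
    for (k in seq_len(nrow(cand))) {
      i <- cand$ref[k]; j <- cand$spec[k]
      if (used_ref[i] || used_spec[j]) next
      used_ref[i] <- TRUE; used_spec[j] <- TRUE
      sel_ref <- c(sel_ref, i); sel_spec <- c(sel_spec, j)
      sel_lag <- c(sel_lag, cand$lag[k])
    }
  }
  if (length(sel_ref) == 0L)
    stop("pair_by_time: no spectrum within ", max_lag_s, " s of any reference")
  ord <- order(rt[sel_ref])
  sel_ref <- sel_ref[ord]; sel_spec <- sel_spec[ord]; sel_lag <- sel_lag[ord]
  dropped <- rt[setdiff(seq_along(rt), sel_ref)]
  structure(
    list(X = spectra$intensities[sel_spec, , drop = FALSE],
         y = rv[sel_ref],
         axis = spectra$axis,
         ids = spectra$ids[sel_spec],
         timestamps = st[sel_spec],
         pair_lags = sel_lag,
         variable = variable,
         dropped_refs = dropped),
    class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("<paired_dataset> ", length(x$y), " pairs for '", x$variable,
      "', max lag ", format(max(x$pair_lags)), " s, ",
      length(x$dropped_refs), " reference row(s) dropped\n", sep = "")
  invisible(x)
}

#' Reproducible train/validation split of a paired data set
#'
#' @param ds A `paired_dataset` from [pair_by_time()].
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed; the split is reproducible per seed.
#' @return List with elements `train` and `validation`, both
#'   `paired_dataset`s; row sets are disjoint and exhaustive.
#' @export
split_train_validation <- function(ds, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "paired_dataset"))
  n <- length(ds$y)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  if (n < 2L) stop("need at least 2 rows to split")
  n_train <- round(fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = subset_pairs(ds, sort(idx)),
       validation = subset_pairs(ds, setdiff(seq_len(n), idx)))
}

subset_pairs <- function(ds, i) {
  out <- ds
  out$X <- ds$X[i, , drop = FALSE]
  out$y <- ds$y[i]
  out$ids <- ds$ids[i]
  out$timestamps <- ds$timestamps[i]
  out$pair_lags <- ds$pair_lags[i]
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
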