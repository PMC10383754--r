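make_tiny_spectra <- function() {
  spectra_set(axis = c(100, 200, 300, 400, 500),
              intensities = matrix(seq_len(15) + 0.5, 3, 5, byrow = TRUE),
              timestamps = c(0, 1800, 3600),
              ids = c("a", "b", "c"))
}

test_that("spectra CSV write/read is an identity round trip", {
  s <- make_tiny_spectra()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  s2 <- read_spectra(path)
  expect_equal(s2$axis, s$axis)
  expect_equal(unname(s2$intensities), unname(s$intensities))
  expect_equal(s2$timestamps, s$timestamps)
  expect_equal(s2$ids, s$ids)
  expect_equal(dim(s2), c(3L, 5L))
})

test_that("spectra_set enforces its invariants", {
  expect_error(spectra_set(1:5, matrix(1, 2, 4), c(0, 1)), "per axis channel")
  expect_error(
    spectra_set(c(1001, 1000, 999), matrix(1, 1, 3), 0),
    "strictly increasing")
  expect_error(
    spectra_set(1:3, matrix(1, 2, 3), c(0, 1), ids = c("x", "x")),
    "duplicate spectrum id.*x")
  # rows are sorted by timestamp on construction
  s <- spectra_set(1:3, rbind(c(9, 9, 9), c(1, 1, 1)), c(100, 0))
  expect_equal(s$timestamps, c(0, 100))
  expect_equal(s$intensities[1, ], c(1, 1, 1))
})

test_that("reference tables validate rows and parse ISO-8601 timestamps", {
  expect_error(
    reference_table(c(0, 1), data.frame(glucose = c(1, NA),
                                        lactate = c(2, NA))),
    "non-missing")
  r <- reference_table(c("2024-05-01T00:00:00", "2024-05-01T06:00:00"),
                       data.frame(glucose = c(5, 4)))
  expect_equal(diff(r$timestamp), 6 * 3600)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference(r, path)
  r2 <- read_reference(path)
  expect_equal(r2$glucose, r$glucose)
  expect_equal(r2$timestamp, r$timestamp)
})

test_that("pairing matches each reference to its nearest spectrum in time", {
  s <- spectra_set(1:4, matrix(rnorm(4 * 4 * 48), 4 * 48, 4)[1:96, ],
                   timestamps = seq(0, by = 1800, length.out = 96))
  refs <- reference_table(c(0, 86400),
                          data.frame(glucose = c(5, 4)))
  ds <- pair_by_time(s, refs, "glucose", max_lag_s = 1800)
  expect_length(ds$y, 2L)
  expect_equal(ds$pair_lags, c(0, 0))
  expect_equal(ds$timestamps, c(0, 86400))
})

test_that("equal-lag ties resolve to the earlier spectrum", {
  s <- spectra_set(1:3, matrix(1:6, 2, 3), timestamps = c(0, 1800))
  refs <- reference_table(900, data.frame(glucose = 5))
  ds <- pair_by_time(s, refs, "glucose", max_lag_s = 1800)
  expect_equal(ds$timestamps, 0)
})

test_that("a spectrum serves at most one reference; the loser falls back", {
  # two refs closest to the same spectrum at t=1000; the second-best free
  # spectrum (t=2000) takes the displaced reference
  s <- spectra_set(1:3, matrix(rnorm(9), 3, 3),
                   timestamps = c(0, 1000, 2000))
  refs <- reference_table(c(900, 1100), data.frame(glucose = c(5, 4)))
  ds <- pair_by_time(s, refs, "glucose", max_lag_s = 1800)
  expect_equal(sort(ds$timestamps), c(1000, 2000))
  expect_equal(anyDuplicated(ds$ids), 0L)
})

test_that("pairing over a two-week timeline yields one pair per reference", {
  # half-hourly spectra, daily references: the counting oracle is the
  # number of reference rows
  st <- seq(0, 14 * 86400 - 1, by = 1800)
  s <- spectra_set(1:2, matrix(rnorm(2 * length(st)), length(st), 2),
                   timestamps = st)
  rt <- 86400 * (0:13) + 9 * 3600
  refs <- reference_table(rt, data.frame(glucose = rnorm(14, 5)))
  ds <- pair_by_time(s, refs, "glucose", max_lag_s = 1800)
  expect_length(ds$y, 14L)
  expect_length(ds$dropped_refs, 0L)
  expect_true(all(ds$pair_lags <= 1800))
})

test_that("pairing drops missing cells and errors usefully", {
  s <- spectra_set(1:2, matrix(1:4, 2, 2), timestamps = c(0, 1800))
  refs <- reference_table(c(0, 1800),
                          data.frame(glucose = c(5, NA),
                                     lactate = c(NA, 1)))
  ds <- pair_by_time(s, refs, "glucose", 1800)
  expect_length(ds$y, 1L)
  expect_error(pair_by_time(s, refs, "ammonium", 1800), "unknown")
  far <- reference_table(1e7, data.frame(glucose = 5))
  expect_error(pair_by_time(s, far, "glucose", 1800), "no spectrum")
})

test_that("train/validation splits are disjoint, exhaustive and reproducible", {
  s <- spectra_set(1:3, matrix(rnorm(30), 10, 3),
                   timestamps = seq(0, by = 1800, length.out = 10))
  refs <- reference_table(seq(0, by = 1800, length.out = 10),
                          data.frame(glucose = rnorm(10, 5)))
  ds <- pair_by_time(s, refs, "glucose", 1800)
  sp <- split_train_validation(ds, fraction = 0.8, seed = 1)
  expect_length(sp$train$y, 8L)
  expect_length(sp$validation$y, 2L)
  expect_length(intersect(sp$train$ids, sp$validation$ids), 0L)
  expect_setequal(c(sp$train$ids, sp$validation$ids), ds$ids)
  sp2 <- split_train_validation(ds, fraction = 0.8, seed = 1)
  expect_identical(sp$train$ids, sp2$train$ids)
  sp3 <- split_train_validation(ds, fraction = 0.8, seed = 2)
  expect_false(identical(sp$train$ids, sp3$train$ids))
})

test_that("every row lands in validation at the nominal rate across seeds", {
  n <- 50
  s <- spectra_set(1:2, matrix(rnorm(2 * n), n, 2),
                   timestamps = seq(0, by = 1800, length.out = n))
  refs <- reference_table(seq(0, by = 1800, length.out = n),
                          data.frame(glucose = rnorm(n, 5)))
  ds <- pair_by_time(s, refs, "glucose", 1800)
  n_seeds <- 400
  counts <- setNames(numeric(n), ds$ids)
  for (seed in seq_len(n_seeds)) {
    sp <- split_train_validation(ds, fraction = 0.8, seed = seed)
    counts[sp$validation$ids] <- counts[sp$validation$ids] + 1
  }
  freq <- counts / n_seeds
  # exactly 10 of 50 rows per validation set, so the mean is exactly 0.2
  expect_equal(mean(freq), 0.2, tolerance = 1e-12)
  # per-row frequency is Binomial(400, 0.2)/400: keep within 5 sigma
  sigma <- sqrt(0.2 * 0.8 / n_seeds)
  expect_true(all(abs(freq - 0.2) < 5 * sigma))
})
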