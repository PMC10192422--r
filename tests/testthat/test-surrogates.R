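test_that("every surrogate is exactly a permutation of the source values", {
  withr::with_seed(31, {
    s <- tibble::tibble(time = 0:199, value = stats::rnorm(200))
  })
  ens <- markov_surrogates(s, n_surrogates = 25, seed = 4)
  sorted_src <- sort(s$value)
  for (r in seq_len(ens$n_surrogates)) {
    expect_identical(sort(ens$values[r, ]), sorted_src)
  }
  # hence mean, variance and the whole value distribution are preserved
  expect_equal(rowMeans(ens$values), rep(mean(s$value), 25))
})

test_that("surrogates preserve strong short-term autocorrelation", {
  withr::with_seed(32, {
    x <- as.numeric(stats::arima.sim(list(ar = 0.9), 500))
  })
  s <- tibble::tibble(time = 0:499, value = x)
  ens <- markov_surrogates(s, n_surrogates = 50, seed = 5)
  ac1 <- function(v) stats::cor(v[-1], v[-length(v)])
  expect_lt(abs(mean(apply(ens$values, 1, ac1)) - ac1(x)), 0.1)
})

test_that("iid input yields surrogates indistinguishable from shuffles", {
  withr::with_seed(33, {
    s <- tibble::tibble(time = 0:299, value = stats::rnorm(300))
  })
  ens <- markov_surrogates(s, n_surrogates = 100, seed = 6)
  ac1 <- function(v) stats::cor(v[-1], v[-length(v)])
  lag1 <- apply(ens$values, 1, ac1)
  expect_lt(abs(mean(lag1)), 3 / sqrt(300)) # centered on zero
})

test_that("the ensemble is deterministic given its seed", {
  s <- make_sinusoid(8, 0, 100, 1, noise_sd = 0.5, seed = 1)
  e1 <- markov_surrogates(s, n_surrogates = 20, seed = 9)
  e2 <- markov_surrogates(s, n_surrogates = 20, seed = 9)
  expect_identical(e1$values, e2$values)
  e3 <- markov_surrogates(s, n_surrogates = 20, seed = 10)
  expect_false(identical(e1$values, e3$values))
})

test_that("tied values shrink the bin count with a warning rather than failing", {
  v <- rep(c(0, 0, 0, 0, 1), 20)
  s <- tibble::tibble(time = 0:99, value = v)
  expect_warning(
    ens <- markov_surrogates(s, n_surrogates = 19, n_bins = 10, seed = 2),
    "reducing"
  )
  expect_lt(ens$n_bins, 10)
  expect_identical(sort(ens$values[1, ]), sort(v))
})

test_that("surrogate guardrails reject unusable requests", {
  s <- make_sinusoid(8, 0, 100, 1)
  expect_error(markov_surrogates(s, n_surrogates = 5), "19")
  expect_error(
    markov_surrogates(tibble::tibble(time = 1:10, value = stats::rnorm(10)), 20),
    "short"
  )
})

test_that("a periodic signal is flagged along its period row inside the cone", {
  s <- make_sinusoid(8, 0, 100, 1)
  ws <- morlet_cwt(s)
  # noiseless sinusoid: only 8 distinct values, bins collapse by design
  ens <- suppressWarnings(markov_surrogates(s, n_surrogates = 100, seed = 3))
  msk <- significance_mask(ws, ens, confidence = 0.95)
  row8 <- which.min(abs(ws$periods - 8))
  interior <- ws$coi >= ws$periods[row8]
  expect_gt(mean(msk$mask[row8, interior]), 0.95)
})

test_that("raising the confidence level never adds flagged cells", {
  withr::with_seed(34, {
    s <- tibble::tibble(time = 0:127, value = stats::rnorm(128))
  })
  ws <- morlet_cwt(s)
  ens <- markov_surrogates(s, n_surrogates = 100, seed = 8)
  m90 <- significance_mask(ws, ens, confidence = 0.90)
  m99 <- significance_mask(ws, ens, confidence = 0.99)
  expect_true(all(m90$mask[m99$mask])) # 99% flags are a subset of 90% flags
  expect_lt(mean(m99$mask), mean(m90$mask))
})

test_that("testing a surrogate against its own ensemble matches the nominal level", {
  withr::with_seed(35, {
    x <- as.numeric(stats::arima.sim(list(ar = 0.5), 200))
  })
  s <- tibble::tibble(time = 0:199, value = x)
  ens <- markov_surrogates(s, n_surrogates = 60, seed = 12)
  self <- tibble::tibble(time = 0:199, value = ens$values[1, ])
  ws <- morlet_cwt(self)
  msk <- significance_mask(ws, ens, confidence = 0.95)
  valid <- outer(ws$periods, ws$coi, `<=`)
  expect_lt(mean(msk$mask[valid]), 0.15)
})

test_that("mismatched ensembles and bad confidence levels are rejected", {
  s <- make_sinusoid(8, 0, 100, 1)
  ws <- morlet_cwt(s)
  other <- markov_surrogates(
    tibble::tibble(time = 0:49, value = stats::rnorm(50)), 20,
    seed = 1
  )
  expect_error(significance_mask(ws, other), "disagree")
  ens <- suppressWarnings(markov_surrogates(s, 20, seed = 1))
  expect_error(significance_mask(ws, ens, confidence = 0.4), "confidence")
})

test_that("mask CSV writer round-trips the flag matrix", {
  s <- make_sinusoid(8, 0, 100, 1)
  ws <- morlet_cwt(s)
  ens <- suppressWarnings(markov_surrogates(s, 30, seed = 2))
  msk <- significance_mask(ws, ens, confidence = 0.9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mask_csv(msk, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(unname(as.matrix(back[, -1])), unname(1L * msk$mask))
})
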