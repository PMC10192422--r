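toy_counts <- function(mat, times = seq_len(ncol(mat))) {
  taxa <- rownames(mat) %||% sprintf("t%d", seq_len(nrow(mat)))
  tibble::tibble(
    taxon = rep(taxa, times = ncol(mat)),
    time = rep(times, each = nrow(mat)),
    count = as.vector(mat)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("depth filter uses a strict less-than boundary and preserves order", {
  m <- rbind(a = c(100, 300, 200), b = c(300, 300, 300))
  cc <- toy_counts(m) # column sums 400, 600, 500
  kept <- filter_low_depth(cc, min_reads = 500)
  expect_equal(sort(unique(kept$time)), c(2, 3)) # 500 itself is kept
  expect_equal(attr(kept, "dropped_samples"), 1)
  expect_equal(filter_low_depth(cc, min_reads = 0)$count, cc$count)
  expect_error(filter_low_depth(cc, min_reads = 1e6), "fewer than")
})

test_that("relative abundances sum to one per sample", {
  cc <- small_community()
  rel <- relative_abundance(cc)
  sums <- dplyr::summarise(rel, s = sum(fraction), .by = time)
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("core selection applies the detection/prevalence criterion", {
  # taxon a: fraction 0.006 in 30% of samples; taxon b: 0.004 everywhere
  n <- 100
  frac <- rbind(
    a = c(rep(0.006, 30), rep(0.001, 70)),
    b = rep(0.004, n),
    c = rep(0.989 + 0.001, n) - c(rep(0.006, 30), rep(0.001, 70)) - 0.004
  )
  rel <- toy_counts(frac)
  names(rel)[names(rel) == "count"] <- "fraction"
  keep <- select_core_taxa(rel, detection = 0.005, prevalence = 0.25, n_boot = 0)
  expect_true("a" %in% keep)
  expect_false("b" %in% keep)
  # b is dropped at any prevalence
  expect_false("b" %in% select_core_taxa(rel, prevalence = 0.01, n_boot = 0))
})

test_that("bootstrapped core selection agrees with the direct criterion on a clear community", {
  cc <- make_synthetic_community(
    n_taxa = 19, groups = list(c(30, 5), c(64, 5)), span = 450,
    mean_dt = 1.6, jitter = 0.2, depth = 10000, seed = 1
  )
  rel <- relative_abundance(cc)
  direct <- select_core_taxa(rel, n_boot = 0)
  # brute-force evaluation of the criterion, taxon by taxon
  m <- counts_matrix(rel, value_col = "fraction")
  brute <- rownames(m)[rowSums(m > 0.005) >= 0.25 * ncol(m)]
  expect_identical(direct, brute)
  boot <- select_core_taxa(rel, n_boot = 50, seed = 2)
  # group taxa are unambiguous; the bootstrap must keep them all
  truth <- community_truth(cc)
  expect_true(all(truth$taxon[!is.na(truth$group)] %in% boot))
  expect_identical(
    boot, select_core_taxa(rel, n_boot = 50, seed = 2) # deterministic
  )
})

test_that("union across subjects is an ordered, stable union", {
  expect_identical(union_across_subjects(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_identical(union_across_subjects(c("A"), character(0)), "A")
  expect_identical(union_across_subjects(list(c("B", "A"), c("A", "C"))), c("B", "A", "C"))
  expect_error(union_across_subjects(), "at least one")
})

test_that("CLR columns sum to zero, are monotone, and vanish at the barycenter", {
  frac <- rbind(a = c(1 / 2, 1 / 3), b = c(1 / 4, 1 / 3), c = c(1 / 4, 1 / 3))
  rel <- toy_counts(frac)
  names(rel)[names(rel) == "count"] <- "fraction"
  out <- clr_transform(rel)
  m <- counts_matrix(out, value_col = "clr")
  expect_true(all(abs(colSums(m)) < 1e-9))
  expect_equal(which.max(m[, 1]), c(a = 1L)) # largest fraction -> largest CLR
  expect_equal(unname(m[, 2]), c(0, 0, 0)) # uniform column
})

test_that("half-min zero policy equals the hand-computed replacement", {
  frac <- rbind(a = 0.6, b = 0.4, c = 0)
  rel <- toy_counts(frac)
  names(rel)[names(rel) == "count"] <- "fraction"
  out <- counts_matrix(clr_transform(rel, "half-min"), value_col = "clr")
  x <- c(0.6, 0.4, 0.2) # zero -> (min nonzero)/2
  x <- x / sum(x)
  expect_equal(unname(out[, 1]), log(x) - mean(log(x)))
})

test_that("an all-zero sample fails CLR loudly", {
  frac <- rbind(a = c(0.5, 0), b = c(0.5, 0))
  rel <- toy_counts(frac)
  names(rel)[names(rel) == "count"] <- "fraction"
  expect_error(clr_transform(rel), "only zeros")
})

test_that("Hermite interpolation reproduces nodes, linears, and the grid-count formula", {
  # equidistant input at matching dt is returned unchanged
  s <- tibble::tibble(time = seq(0, 16, by = 1.6), value = sin(seq(0, 16, by = 1.6)))
  out <- interpolate_equidistant(s, 1.6)
  expect_equal(out$value, s$value)
  # exactly linear data interpolate exactly linearly
  lin <- tibble::tibble(time = c(0, 1, 2.5, 4, 5.5, 7), value = 2 * c(0, 1, 2.5, 4, 5.5, 7) + 1)
  out <- interpolate_equidistant(lin, 1.6)
  expect_equal(out$value, 2 * out$time + 1)
  # floor(T/dt) + 1 grid points, no extrapolation
  for (span in c(7, 100, 450)) {
    tt <- sort(c(0, stats::runif(48, 0, span), span))
    out <- interpolate_equidistant(tibble::tibble(time = tt, value = stats::rnorm(50)), 1.6)
    expect_equal(nrow(out), floor(span / 1.6) + 1)
    expect_lte(max(out$time), span)
  }
  expect_error(
    interpolate_equidistant(tibble::tibble(time = c(0, 1, 1, 3), value = 1:4), 1),
    "duplicate"
  )
  expect_error(
    interpolate_equidistant(tibble::tibble(time = 0:2, value = 1:3), 1),
    "at least 4"
  )
})

test_that("Box-Cox PPCC recovers the generating exponent", {
  withr::with_seed(11, {
    ln <- tibble::tibble(time = 1:500, value = exp(stats::rnorm(500)))
    fit0 <- boxcox_rescale(ln)
    expect_gt(fit0$lambda, -0.2)
    expect_lt(fit0$lambda, 0.2)
    nm <- tibble::tibble(time = 1:500, value = stats::rnorm(500, 10, 2))
    fit1 <- boxcox_rescale(nm)
    # PPCC at lambda = 1 is within 0.005 of the optimum: near-affine
    x <- sort(nm$value)
    q <- stats::qnorm((seq_along(x) - 3 / 8) / (length(x) + 1 / 4))
    expect_lt(fit1$ppcc - stats::cor(x, q), 0.005)
  })
  # transformed output is standardized
  fit <- boxcox_rescale(tibble::tibble(time = 1:50, value = exp(seq(0, 3, length.out = 50))))
  expect_equal(mean(fit$series$value), 0, tolerance = 1e-12)
  expect_equal(stats::sd(fit$series$value), 1, tolerance = 1e-12)
  expect_error(
    boxcox_rescale(tibble::tibble(time = 1:20, value = rep(1, 20))),
    "constant"
  )
})

test_that("the zero-lambda branch is the natural log and negatives are rejected", {
  x <- c(0.5, 1, 2, 4)
  expect_equal(boxcox_apply(x, 0), log(x))
  expect_equal(boxcox_apply(x, 1), x - 1)
  expect_error(boxcox_apply(c(-1, 1), 0.5), "positive")
})

test_that("full preprocessing returns one standardized equidistant series per retained taxon", {
  cc <- small_community()
  prep <- preprocess_counts(cc, preprocess_config(n_boot = 0, target_dt = 1.6))
  expect_s3_class(prep, "regular_series_set")
  per <- split(prep$series, prep$series$label)
  n_grid <- unique(vapply(per, nrow, integer(1)))
  expect_length(n_grid, 1)
  span <- max(cc$time) - min(cc$time)
  expect_equal(n_grid, floor(span / 1.6) + 1)
  for (s in per) {
    expect_equal(diff(s$time), rep(1.6, n_grid - 1), tolerance = 1e-9)
    expect_equal(mean(s$value), 0, tolerance = 1e-9)
  }
  expect_setequal(prep$params$label, prep$taxa)
})
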