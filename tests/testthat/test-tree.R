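test_that("tree cutting produces the expected coarse and fine partitions", {
  h <- random_tree(letters[1:8], seed = 1)
  k2 <- cut_tree(h, 2)
  expect_equal(length(unique(k2)), 2)
  kfine <- cut_tree(h, 7) # n - 1: exactly one co-clustered pair
  expect_equal(sort(as.numeric(table(kfine)), decreasing = TRUE), c(2, rep(1, 6)))
  expect_error(cut_tree(h, 1), "k")
  expect_error(cut_tree(h, 8), "k")
})

test_that("Bk equals 1 for identical partitions and 0 for disjoint pairings", {
  c1 <- stats::setNames(c(1, 1, 2, 2, 3), letters[1:5])
  expect_equal(bk_statistic(c1, c1), 1)
  # relabeling clusters changes nothing
  c1r <- stats::setNames(c(2, 2, 3, 3, 1), letters[1:5])
  expect_equal(bk_statistic(c1, c1r), 1)
  # AB|CD vs AC|BD share no co-clustered pair
  a <- stats::setNames(c(1, 1, 2, 2), LETTERS[1:4])
  b <- stats::setNames(c(1, 2, 1, 2), LETTERS[1:4])
  expect_equal(bk_statistic(a, b), 0)
  # ABC|DEF vs ABD|CEF: 2 shared pairs / 6 within-tree pairs each
  a6 <- stats::setNames(c(1, 1, 1, 2, 2, 2), LETTERS[1:6])
  b6 <- stats::setNames(c(1, 1, 2, 1, 2, 2), LETTERS[1:6])
  expect_equal(bk_statistic(a6, b6), 2 / 6)
  expect_equal(bk_statistic(a6, b6), bk_pair_oracle(a6, b6))
})

test_that("Bk agrees exhaustively with the pair-counting oracle on small n", {
  # every pair of set partitions for n = 4 and 5
  for (n in 4:5) {
    parts <- all_partitions(n)
    labs <- letters[1:n]
    for (p1 in parts) {
      c1 <- stats::setNames(p1, labs)
      for (p2 in parts) {
        c2 <- stats::setNames(p2, labs)
        expect_equal(bk_statistic(c1, c2), bk_pair_oracle(c1, c2))
      }
    }
  }
  # random partition pairs at n = 6 and 7
  withr::with_seed(51, {
    for (r in 1:300) {
      n <- sample(6:7, 1)
      labs <- letters[1:n]
      c1 <- random_partition(labs, sample(2:(n - 1), 1))
      c2 <- random_partition(labs, sample(2:(n - 1), 1))
      expect_equal(bk_statistic(c1, c2), bk_pair_oracle(c1, c2))
      expect_equal(bk_statistic(c1, c2), bk_statistic(c2, c1))
    }
  })
})

test_that("Bk is undefined (NA) when a partition has no co-clustered pair", {
  singletons <- stats::setNames(1:4, LETTERS[1:4])
  pairs <- stats::setNames(c(1, 1, 2, 2), LETTERS[1:4])
  expect_true(is.na(bk_statistic(singletons, pairs)))
})

test_that("a tree against itself gives Bk = 1 everywhere, above the line", {
  h <- random_tree(letters[1:10], seed = 2)
  curve <- bk_curve(h, h)
  expect_equal(curve$bk, rep(1, 8))
  expect_true(all(curve$bk > curve$rejection))
  expect_true(all(curve$bk >= 0 & curve$bk <= 1))
})

test_that("asymptotic and permutation nulls agree at n = 19", {
  h1 <- random_tree(sprintf("g%02d", 1:19), seed = 3)
  h2 <- random_tree(sprintf("g%02d", 1:19), seed = 4)
  ca <- bk_curve(h1, h2, null_method = "asymptotic")
  cp <- bk_curve(h1, h2, null_method = "permutation", n_perm = 1500, seed = 5)
  expect_lt(max(abs(ca$rejection - cp$rejection)), 0.05)
  expect_lt(max(abs(ca$null_mean - cp$null_mean)), 0.05)
})

test_that("unrelated random trees exceed the rejection line at about the nominal rate", {
  withr::with_seed(52, {
    above <- numeric(0)
    for (r in 1:100) {
      h1 <- random_tree(sprintf("g%02d", 1:19), seed = 1000 + r)
      h2 <- random_tree(sprintf("g%02d", 1:19), seed = 5000 + r)
      cv <- bk_curve(h1, h2, alpha = 0.05)
      above <- c(above, cv$bk > cv$rejection)
    }
  })
  expect_lt(abs(mean(above) - 0.05), 0.04)
})

test_that("Bk curve guards its preconditions", {
  h1 <- random_tree(letters[1:3], seed = 6)
  expect_error(bk_curve(h1, h1), "at least 4")
  h2 <- random_tree(letters[1:8], seed = 7)
  h3 <- random_tree(letters[2:9], seed = 8)
  expect_error(bk_curve(h2, h3), "a|i") # names the symmetric difference
})

test_that("total branch length matches the explicit edge-sum oracle", {
  # two leaves merging at height h have total length 2h
  h2 <- structure(
    list(
      merge = matrix(c(-1L, -2L), 1), height = 3.5, order = 1:2,
      labels = c("x", "y"), method = "ward.D2"
    ),
    class = "hclust"
  )
  expect_equal(total_branch_length(h2), 7)
  expect_equal(branch_length_oracle(h2), 7)
  # three leaves: (A,B) at h1 = 1, + C at h2 = 4
  h3 <- structure(
    list(
      merge = rbind(c(-1L, -2L), c(1L, -3L)), height = c(1, 4),
      order = 1:3, labels = c("A", "B", "C"), method = "ward.D2"
    ),
    class = "hclust"
  )
  expect_equal(branch_length_oracle(h3), 1 + 1 + 4 + (4 - 1))
  expect_equal(total_branch_length(h3), branch_length_oracle(h3))
  # random trees: oracle agreement, leaf-order invariance, linear scaling
  for (seed in 1:5) {
    h <- random_tree(letters[1:9], seed = seed)
    expect_equal(total_branch_length(h), branch_length_oracle(h))
    hs <- h
    hs$height <- 3 * hs$height
    expect_equal(total_branch_length(hs), 3 * total_branch_length(h))
  }
})

test_that("Newick export preserves partitions and branch lengths", {
  h <- random_tree(letters[1:8], seed = 9)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(h, path)
  back <- read_tree_newick(path)
  for (k in c(2, 4, 7)) {
    p1 <- cut_tree(h, k)
    p2 <- cut_tree(back, k)[names(p1)]
    expect_equal(bk_statistic(p1, p2), 1) # same partition up to labels
  }
  expect_equal(total_branch_length(back), total_branch_length(h), tolerance = 1e-6)
})

test_that("tidy and glance summarize a Bk curve faithfully", {
  h1 <- random_tree(letters[1:8], seed = 10)
  cv <- bk_curve(h1, h1)
  td <- tidy(cv)
  expect_named(td, c("k", "bk", "null_mean", "null_sd", "rejection"))
  g <- glance(cv)
  expect_equal(g$n, 8)
  expect_equal(g$frac_above, 1)
  expect_equal(g$mean_bk, 1)
})
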