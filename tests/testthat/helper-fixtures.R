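# Shared, lazily computed fixtures: the demo panel's spectra/masks and the
# full demo run are expensive, so they are built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

demo_spectra <- function() {
  cached("demo_spectra", {
    panel <- make_demo_panel()
    # noiseless sinusoids have few distinct values: bin collapse is expected
    sp <- suppressWarnings(panel_spectra(panel$series,
      n_surrogates = 100, confidence = 0.90, seed = 1
    ))
    c(sp, list(panel = panel))
  })
}

demo_run <- function() {
  cached("demo_run", suppressWarnings(run_demo_analysis(n_surrogates = 100, seed = 1)))
}

small_community <- function() {
  cached(
    "small_community",
    make_synthetic_community(
      n_taxa = 8, groups = list(c(20, 3), c(40, 3)),
      span = 160, mean_dt = 1.6, jitter = 0.2, depth = 5000, seed = 3
    )
  )
}

# brute-force pair-concordance oracle for the Bk statistic: count label
# pairs co-clustered in both partitions / geometric mean of within-partition
# co-clustered pair counts
bk_pair_oracle <- function(c1, c2) {
  c2 <- c2[names(c1)]
  n <- length(c1)
  pairs <- utils::combn(n, 2)
  same1 <- c1[pairs[1, ]] == c1[pairs[2, ]]
  same2 <- c2[pairs[1, ]] == c2[pairs[2, ]]
  if (sum(same1) == 0 || sum(same2) == 0) {
    return(NA_real_)
  }
  sum(same1 & same2) / sqrt(sum(same1) * sum(same2))
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxval) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxval + 1)) {
      rec(c(prefix, v), max(maxval, v))
    }
  }
  rec(integer(0), 0L)
  out
}

# explicit edge-sum oracle for total branch length: walk the merge list and
# add every child-to-parent vertical segment (leaves at height 0)
branch_length_oracle <- function(h) {
  node_height <- function(idx) {
    if (idx < 0) 0 else h$height[idx]
  }
  total <- 0
  for (m in seq_len(nrow(h$merge))) {
    for (child in h$merge[m, ]) {
      total <- total + h$height[m] - node_height(child)
    }
  }
  total
}

random_partition <- function(labels, k) {
  repeat {
    p <- sample.int(k, length(labels), replace = TRUE)
    if (length(unique(p)) == k) break
  }
  stats::setNames(p, labels)
}

random_tree <- function(labels, seed) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(length(labels) * 5), length(labels))
    rownames(x) <- labels
    stats::hclust(stats::dist(x), method = "ward.D2")
  })
}
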