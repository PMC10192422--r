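#' Preprocessing configuration
#'
#' Bundles the parameters of the count-table preprocessing pipeline:
#' depth filter -> relative abundance -> bootstrapped core-taxon selection ->
#' centered log-ratio transform -> monotone cubic Hermite interpolation to an
#' equidistant grid -> Box-Cox rescaling with PPCC-optimal lambda.
#'
#' @param min_reads Samples with fewer reads are dropped (default 500).
#' @param prevalence Core-selection prevalence: fraction of samples in which
#'   a taxon must exceed `detection` (default 0.25).
#' @param detection Relative-abundance detection threshold (default 0.005).
#' @param n_boot Bootstrap resamples for core selection; 0 applies the plain
#'   criterion (default 100).
#' @param target_dt Equidistant grid spacing in days (default 1.6).
#' @param boxcox_lambda_grid Search grid for the Box-Cox exponent.
#' @param pseudocount_policy How CLR handles zeros: `"half-min"` replaces
#'   zeros per sample with half the smallest nonzero fraction, `"pseudocount"`
#'   adds a global constant (see [clr_transform()]).
#' @param pseudocount Constant for the `"pseudocount"` policy.
#' @param seed Seed for the core-selection bootstrap.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_reads = 500, prevalence = 0.25,
                              detection = 0.005, n_boot = 100,
                              target_dt = 1.6,
                              boxcox_lambda_grid = seq(-2, 2, by = 0.01),
                              pseudocount_policy = c("half-min", "pseudocount"),
                              pseudocount = 1e-6, seed = 1L) {
  stopifnot(prevalence > 0, prevalence <= 1, detection > 0, target_dt > 0,
            min_reads >= 0, n_boot >= 0)
  structure(
    list(
      min_reads = min_reads, prevalence = prevalence, detection = detection,
      n_boot = n_boot, target_dt = target_dt,
      boxcox_lambda_grid = boxcox_lambda_grid,
      pseudocount_policy = match.arg(pseudocount_policy),
      pseudocount = pseudocount, seed = seed
    ),
    class = "preprocess_config"
  )
}

#' Drop samples with low sequencing depth
#'
#' Removes samples whose total read count is strictly below `min_reads`;
#' taxa and the order of the remaining samples are untouched.
#'
#' @param counts Tibble of `taxon`, `time`, `count`.
#' @param min_reads Minimum reads per retained sample.
#' @return The filtered tibble; dropped sample times are recorded in the
#'   `dropped_samples` attribute.
#' @export
filter_low_depth <- function(counts, min_reads = 500) {
  stopifnot(min_reads >= 0)
  depth <- dplyr::summarise(counts, reads = sum(.data$count), .by = "time")
  keep <- depth$time[depth$reads >= min_reads]
  if (length(keep) == 0) {
    rlang::abort(sprintf(
      "all %d samples have fewer than %d reads; nothing left to analyse.",
      nrow(depth), min_reads
    ))
  }
  out <- dplyr::filter(counts, .data$time %in% keep)
  attr(out, "dropped_samples") <- setdiff(depth$time, keep)
  out
}

#' Convert counts to relative abundances
#'
#' @param counts Tibble of `taxon`, `time`, `count`.
#' @return Tibble of `taxon`, `time`, `fraction`; fractions sum to 1 within
#'   each sample.
#' @export
relative_abundance <- function(counts) {
  out <- dplyr::mutate(counts,
    fraction = .data$count / sum(.data$count),
    .by = "time"
  )
  dplyr::select(out, "taxon", "time", "fraction")
}

#' Select core taxa by detection and prevalence, optionally bootstrapped
#'
#' A taxon is core when its relative abundance exceeds `detection` in at
#' least `prevalence * n_samples` samples. With `n_boot > 0` the samples are
#' resampled with replacement `n_boot` times and taxa passing the criterion
#' in more than half of the resamples are retained, which stabilises the
#' selection against a handful of influential samples.
#'
#' @param rel Tibble of `taxon`, `time`, `fraction`.
#' @param detection Relative-abundance threshold (strict `>`).
#' @param prevalence Required fraction of samples.
#' @param n_boot Number of bootstrap resamples (0 = plain criterion).
#' @param seed Seed for the bootstrap.
#' @return Character vector of retained taxon labels, in input order. Warns
#'   (rather than fails) when empty.
#' @export
select_core_taxa <- function(rel, detection = 0.005, prevalence = 0.25,
                             n_boot = 0, seed = 1L) {
  stopifnot(n_boot >= 0)
  m <- counts_matrix(rel, value_col = "fraction")
  ns <- ncol(m)
  pass <- function(cols) {
    rowSums(m[, cols, drop = FALSE] > detection) >= prevalence * length(cols)
  }
  if (n_boot == 0) {
    keep <- pass(seq_len(ns))
  } else {
    votes <- withr::with_seed(seed, {
      rowSums(vapply(
        seq_len(n_boot),
        function(i) pass(sample.int(ns, ns, replace = TRUE)),
        logical(nrow(m))
      ))
    })
    keep <- votes > n_boot / 2
  }
  out <- rownames(m)[keep]
  if (length(out) == 0) {
    rlang::warn("no taxa pass the core-selection criterion.")
  }
  out
}

#' Union of per-subject core taxon lists
#'
#' Taxa judged core in at least one subject, ordered by first appearance.
#'
#' @param ... Character vectors of taxon labels (or a single list of them).
#' @return Character vector.
#' @export
union_across_subjects <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) {
    lists <- lists[[1]]
  }
  if (length(lists) == 0) {
    rlang::abort("need at least one taxon list.")
  }
  Reduce(union, lists)
}

#' Centered log-ratio transform of relative abundances
#'
#' Per sample: zeros are imputed according to `pseudocount_policy`, the
#' column is renormalized, and each fraction is mapped to
#' `log(x_i) - mean_j log(x_j)` — so every transformed sample sums to zero.
#'
#' @param rel Tibble of `taxon`, `time`, `fraction`.
#' @param pseudocount_policy `"half-min"`: zeros become half the smallest
#'   nonzero fraction of that sample. `"pseudocount"`: `pseudocount` is added
#'   to every fraction.
#' @param pseudocount Constant for the `"pseudocount"` policy.
#' @return Tibble of `taxon`, `time`, `clr`.
#' @export
clr_transform <- function(rel, pseudocount_policy = c("half-min", "pseudocount"),
                          pseudocount = 1e-6) {
  pseudocount_policy <- match.arg(pseudocount_policy)
  m <- counts_matrix(rel, value_col = "fraction")
  if (any(m < 0)) {
    rlang::abort("fractions must be non-negative.")
  }
  zero_cols <- colSums(m) == 0
  if (any(zero_cols)) {
    rlang::abort(sprintf(
      "sample(s) at time %s contain only zeros; CLR is undefined.",
      paste(attr(m, "sample_times")[zero_cols], collapse = ", ")
    ))
  }
  clr_m <- apply(m, 2, function(x) {
    if (pseudocount_policy == "half-min") {
      nz <- x[x > 0]
      x[x == 0] <- min(nz) / 2
    } else {
      x <- x + pseudocount
    }
    x <- x / sum(x)
    lx <- log(x)
    lx - mean(lx)
  })
  tibble::tibble(
    taxon = rep(rownames(m), times = ncol(m)),
    time = rep(attr(m, "sample_times"), each = nrow(m)),
    clr = as.vector(clr_m)
  )
}

#' Interpolate a series onto an equidistant grid
#'
#' Monotone piecewise-cubic Hermite interpolation (Fritsch-Carlson slopes,
#' via `stats::splinefun(method = "monoH.FC")`) evaluated on the grid
#' `t0, t0 + dt, ...` up to the last observation. The interpolant passes
#' through every original point exactly and never extrapolates; the monotone
#' slope choice avoids overshoot around sharp peaks.
#'
#' @param series Tibble with columns `time`, `value` (at least 4 rows,
#'   strictly increasing times).
#' @param target_dt Grid spacing, days.
#' @return Tibble of `time`, `value` on the equidistant grid
#'   (`floor(span/dt) + 1` points).
#' @export
interpolate_equidistant <- function(series, target_dt = 1.6) {
  stopifnot(target_dt > 0)
  t <- series$time
  v <- series$value
  if (anyDuplicated(t)) {
    rlang::abort("duplicate timestamps; interpolation is undefined.")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    rlang::abort("`time` must be strictly increasing.")
  }
  if (length(t) < 4) {
    rlang::abort("need at least 4 observations to interpolate.")
  }
  f <- stats::splinefun(t, v, method = "monoH.FC")
  grid <- t[1] + target_dt * seq(0, floor((t[length(t)] - t[1]) / target_dt))
  tibble::tibble(time = grid, value = f(grid))
}

#' Box-Cox power transform with the PPCC-optimal exponent
#'
#' Rescales a series to suppress sharp peaks and approximate normality.
#' Box-Cox needs a positive domain, but CLR output can be negative: a series
#' whose minimum is not strictly positive is first lifted so its minimum
#' equals `eps` (already-positive series are left unshifted, so e.g. a
#' log-normal sample keeps its `lambda = 0` optimum). Then the exponent `lambda`
#' is chosen on a grid (with a local continuous refinement) to maximize the
#' probability-plot correlation coefficient — the correlation between the
#' ordered transformed values and standard normal quantiles at plotting
#' positions `(i - 3/8) / (n + 1/4)`. The transformed series is returned
#' standardized to zero mean and unit variance.
#'
#' @param series Tibble with columns `time`, `value` (at least 10 rows).
#' @param lambda_grid Numeric grid of candidate exponents.
#' @param eps Positive floor a non-positive series is lifted to (default 1).
#' @return A list of class `boxcox_rescaled`: `series` (tibble `time`,
#'   `value`), `lambda`, `shift`, `ppcc`.
#' @export
boxcox_rescale <- function(series, lambda_grid = seq(-2, 2, by = 0.01),
                           eps = 1) {
  v <- series$value
  if (length(v) < 10) {
    rlang::abort("need at least 10 observations for the PPCC fit.")
  }
  if (stats::sd(v) == 0) {
    rlang::abort("constant series: the PPCC objective is undefined.")
  }
  shift <- if (min(v) > 0) 0 else eps - min(v)
  x <- sort(v + shift)
  n <- length(x)
  q <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  obj <- function(lambda) stats::cor(boxcox_apply(x, lambda), q)
  ppcc <- vapply(lambda_grid, obj, numeric(1))
  i <- which.max(ppcc)
  # continuous refinement inside the bracketing grid cells
  lo <- lambda_grid[max(i - 1, 1)]
  hi <- lambda_grid[min(i + 1, length(lambda_grid))]
  lambda <- lambda_grid[i]
  best <- ppcc[i]
  if (hi > lo) {
    opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE)
    if (opt$objective > best) {
      lambda <- opt$maximum
      best <- opt$objective
    }
  }
  y <- boxcox_apply(series$value + shift, lambda)
  y <- (y - mean(y)) / stats::sd(y)
  structure(
    list(
      series = tibble::tibble(time = series$time, value = y),
      lambda = lambda, shift = shift, ppcc = best
    ),
    class = "boxcox_rescaled"
  )
}

#' Box-Cox kernel
#'
#' `(x^lambda - 1) / lambda`, with the `log(x)` limit at `lambda = 0`.
#'
#' @param x Positive numeric vector.
#' @param lambda Exponent.
#' @return Transformed vector.
#' @export
boxcox_apply <- function(x, lambda) {
  if (any(x <= 0)) {
    rlang::abort("Box-Cox requires strictly positive values.")
  }
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Full preprocessing pipeline for a count table
#'
#' Applies, in order: depth filter, relative abundance, core-taxon selection
#' (optionally restricted to an externally supplied taxon list, e.g. a union
#' across subjects), CLR, per-taxon interpolation to the equidistant grid,
#' and Box-Cox rescaling. The fixed order mirrors standard practice for
#' compositional time series: normalization must precede the transform, and
#' interpolation must precede spectral analysis.
#'
#' @param counts Tibble of `taxon`, `time`, `count`.
#' @param config A [preprocess_config()].
#' @param taxa Optional character vector overriding core selection (taxa to
#'   retain; still intersected with the table's taxa).
#' @return A list of class `regular_series_set`: `series` (tibble `label`,
#'   `time`, `value` on a shared equidistant grid), `dt`, `params` (tibble of
#'   per-taxon Box-Cox `lambda`, `shift`, `ppcc`), `dropped_samples`,
#'   `taxa`.
#' @export
preprocess_counts <- function(counts, config = preprocess_config(),
                              taxa = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  filtered <- filter_low_depth(counts, config$min_reads)
  dropped <- attr(filtered, "dropped_samples")
  rel <- relative_abundance(filtered)
  if (is.null(taxa)) {
    taxa <- select_core_taxa(
      rel,
      detection = config$detection, prevalence = config$prevalence,
      n_boot = config$n_boot, seed = config$seed
    )
  } else {
    taxa <- intersect(taxa, unique(rel$taxon))
  }
  if (length(taxa) == 0) {
    rlang::abort("no taxa retained; nothing to preprocess.")
  }
  clr <- clr_transform(
    dplyr::filter(rel, .data$taxon %in% taxa),
    pseudocount_policy = config$pseudocount_policy,
    pseudocount = config$pseudocount
  )
  per_taxon <- lapply(taxa, function(tx) {
    s <- dplyr::filter(clr, .data$taxon == tx)
    eq <- interpolate_equidistant(
      tibble::tibble(time = s$time, value = s$clr),
      target_dt = config$target_dt
    )
    bc <- boxcox_rescale(eq, lambda_grid = config$boxcox_lambda_grid)
    list(
      series = dplyr::mutate(bc$series, label = tx, .before = 1),
      params = tibble::tibble(
        label = tx, lambda = bc$lambda, shift = bc$shift, ppcc = bc$ppcc
      )
    )
  })
  structure(
    list(
      series = dplyr::bind_rows(lapply(per_taxon, `[[`, "series")),
      dt = config$target_dt,
      params = dplyr::bind_rows(lapply(per_taxon, `[[`, "params")),
      dropped_samples = dropped,
      taxa = taxa
    ),
    class = "regular_series_set"
  )
}

#' @export
print.regular_series_set <- function(x, ...) {
  n_grid <- sum(x$series$label == x$taxa[[1]])
  cat(sprintf(
    "<regular_series_set> %d taxa x %d grid points (dt = %g days)\n",
    length(x$taxa), n_grid, x$dt
  ))
  if (length(x$dropped_samples)) {
    cat(sprintf("  %d low-depth samples dropped\n", length(x$dropped_samples)))
  }
  invisible(x)
}
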