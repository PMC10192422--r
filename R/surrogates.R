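#' Markov surrogate series
#'
#' Builds surrogate series preserving the source's mean, variance, value
#' distribution and short-term autocorrelation: values are discretized into
#' equal-frequency bins, a first-order transition matrix is estimated on the
#' bin sequence, and each surrogate is a simulated chain whose states are
#' filled by drawing the source's own values without replacement from the
#' corresponding bin.
#'
#' The chain is simulated *conditioned on the remaining pool sizes*: the
#' next-state probabilities are the estimated transition row reweighted by
#' how many unused values each bin still holds. Every surrogate is therefore
#' exactly a permutation of the source values (the first three preserved
#' moments hold exactly), while the transition reweighting preserves the
#' short-term autocorrelation approximately.
#'
#' @param series Tibble with columns `time`, `value` (equidistant, >= 25
#'   points).
#' @param n_surrogates Number of surrogates (>= 19 for a pointwise 95% test).
#' @param n_bins Number of equal-frequency bins; default
#'   `min(15, floor(n/10))`. Automatically reduced (with a warning) when
#'   tied values leave a bin empty.
#' @param seed Integer seed; the ensemble is deterministic given it.
#' @return An object of class `surrogate_ensemble`: list with `values`
#'   (n_surrogates x n matrix), `n_bins`, `n_surrogates`, `seed`, `dt`,
#'   `label`.
#' @export
markov_surrogates <- function(series, n_surrogates = 1000, n_bins = NULL,
                              seed = 1L) {
  v <- series$value
  n <- length(v)
  if (n < 25) {
    rlang::abort("series too short: at least 25 points are required.")
  }
  if (n_surrogates < 19) {
    rlang::abort("`n_surrogates` must be at least 19 (pointwise 95% test).")
  }
  if (is.null(n_bins)) {
    n_bins <- min(15L, floor(n / 10))
  }
  if (n_bins < 2) {
    rlang::abort("`n_bins` must be at least 2.")
  }
  dts <- diff(series$time)
  dt <- stats::median(dts)

  # equal-frequency discretization; ties can collapse quantile breaks
  breaks <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  nb <- length(breaks) - 1
  if (nb < 1) {
    rlang::abort("series is constant; surrogates are undefined.")
  }
  if (nb < n_bins) {
    rlang::warn(sprintf(
      "tied values leave empty bins; reducing `n_bins` from %d to %d.",
      n_bins, nb
    ))
    n_bins <- nb
  }
  states <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  # boundary assignment can still leave a bin unused; relabel to dense states
  used <- sort(unique(states))
  states <- match(states, used)
  b <- length(used)
  n_bins <- b

  trans <- matrix(0, b, b)
  for (i in seq_len(n - 1)) {
    trans[states[i], states[i + 1]] <- trans[states[i], states[i + 1]] + 1
  }
  rs <- rowSums(trans)
  trans[rs == 0, ] <- 1
  trans <- trans / rowSums(trans)

  pools <- split(v, states)

  out <- withr::with_seed(seed, {
    t(vapply(seq_len(n_surrogates), function(r) {
      remaining <- vapply(pools, length, integer(1))
      shuffled <- lapply(pools, sample) # random draw order within each bin
      surr <- numeric(n)
      cur <- sample.int(b, 1, prob = remaining)
      for (i in seq_len(n)) {
        remaining[cur] <- remaining[cur] - 1L
        surr[i] <- shuffled[[cur]][remaining[cur] + 1L]
        if (i == n) break
        w <- trans[cur, ] * remaining
        if (sum(w) == 0) w <- remaining
        cur <- sample.int(b, 1, prob = w)
      }
      surr
    }, numeric(n)))
  })

  structure(
    list(
      values = out, n_bins = b, n_surrogates = n_surrogates, seed = seed,
      dt = dt, n = n,
      label = if ("label" %in% names(series)) as.character(series$label[[1]]) else "series"
    ),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "<surrogate_ensemble> '%s': %d surrogates of length %d (%d bins)\n",
    x$label, x$n_surrogates, x$n, x$n_bins
  ))
  invisible(x)
}

#' Significance mask for a wavelet spectrum
#'
#' Wavelet-transforms every surrogate with the same parameters as the
#' observed spectrum and flags each (period, time) cell where the observed
#' power exceeds the pointwise `confidence`-quantile of the surrogate power
#' at that cell.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @param ensemble A `surrogate_ensemble` built from the same series.
#' @param confidence Confidence level in (0.5, 1); 0.95 for displayed
#'   significance areas, 0.90 for clustering input.
#' @return An object of class `significance_mask`: list with `mask`
#'   (logical periods x times matrix), `confidence`, `n_surrogates`,
#'   `periods`, `times`, `label`.
#' @export
significance_mask <- function(spectrum, ensemble, confidence = 0.95) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"),
            inherits(ensemble, "surrogate_ensemble"))
  if (confidence <= 0.5 || confidence >= 1) {
    rlang::abort("`confidence` must lie in (0.5, 1).")
  }
  p <- spectrum$params
  if (ensemble$n != p$n || abs(ensemble$dt - p$dt) > 1e-9 * p$dt) {
    rlang::abort("ensemble and spectrum disagree on series length or sampling interval.")
  }
  npd <- length(spectrum$periods)
  nt <- length(spectrum$times)
  m <- ensemble$n_surrogates
  surr_pow <- array(0, c(npd, nt, m))
  for (r in seq_len(m)) {
    sw <- morlet_cwt(
      tibble::tibble(time = spectrum$times, value = ensemble$values[r, ]),
      omega0 = p$omega0, dj = p$dj, s0 = p$s0, n_scales = p$n_scales
    )
    surr_pow[, , r] <- sw$power
  }
  # pointwise per-cell quantile of the surrogate null
  thr <- apply(surr_pow, c(1, 2), stats::quantile, probs = confidence, names = FALSE)
  structure(
    list(
      mask = spectrum$power > thr, confidence = confidence,
      n_surrogates = m, periods = spectrum$periods, times = spectrum$times,
      label = spectrum$label
    ),
    class = "significance_mask"
  )
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf(
    "<significance_mask> '%s' at %.0f%% confidence: %.1f%% of cells flagged\n",
    x$label, 100 * x$confidence, 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Write a significance mask as 0/1 CSV
#'
#' Same layout as [write_spectrum_csv()]: rows = periods, columns = times.
#'
#' @param mask A `significance_mask`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  m <- as.data.frame(1L * mask$mask)
  names(m) <- format(mask$times, trim = TRUE)
  readr::write_csv(dplyr::bind_cols(tibble::tibble(period = mask$periods), m), path)
  invisible(path)
}
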