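#' Morlet continuous wavelet transform
#'
#' Computes the wavelet power spectrum of an equidistant series using the
#' Morlet mother wavelet (a complex sinusoid under a Gaussian envelope),
#' which is well suited to detecting periodicities. The series is
#' standardized to zero mean and unit variance, zero-padded to the next
#' power of two, and convolved in the frequency domain at log-spaced scales
#' `s_j = s0 * 2^(j * dj)`. Power is the squared modulus of the transform;
#' scales convert to Fourier periods through the Morlet Fourier factor
#' `4*pi / (omega0 + sqrt(2 + omega0^2))`.
#'
#' Defaults follow common continuous-wavelet practice: `omega0 = 6`,
#' twelve sub-octaves per octave, smallest scale `2 * dt`, and a scale range
#' capped so the largest period does not exceed a third of the series span
#' (longer periods are not trustworthy in a record this short).
#'
#' @param series Tibble with columns `time`, `value` (equidistant; at least
#'   25 points — the practical minimum for resolving periodicities), and
#'   optionally `label`.
#' @param omega0 Nondimensional frequency of the Morlet wavelet (>= 5 for
#'   admissibility in practice).
#' @param dj Scale resolution, octaves per scale step.
#' @param s0 Smallest scale; default `2 * dt`.
#' @param n_scales Number of scales; default caps the largest period at
#'   `span / 3`.
#' @param label Series label; defaults to a `label` column when present.
#' @return An object of class `wavelet_spectrum`: list with `label`, `times`,
#'   `periods` (days, increasing), `scales`, `power` (periods x times
#'   matrix), `coi` (maximum trustworthy period per time) and `params`.
#' @examples
#' s <- make_sinusoid(period = 8, span = 100, dt = 1)
#' ws <- morlet_cwt(s)
#' dominant_period(ws)
#' @export
morlet_cwt <- function(series, omega0 = 6, dj = 1 / 12, s0 = NULL,
                       n_scales = NULL, label = NULL) {
  t <- series$time
  v <- series$value
  n <- length(v)
  if (n < 25) {
    rlang::abort("series too short: at least 25 equidistant points are required.")
  }
  dts <- diff(t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    rlang::abort("series is not equidistant; interpolate first.")
  }
  if (omega0 < 5) {
    rlang::abort("`omega0` must be at least 5.")
  }
  if (stats::sd(v) == 0) {
    rlang::abort("constant series has no spectrum.")
  }
  if (is.null(label)) {
    label <- if ("label" %in% names(series)) as.character(series$label[[1]]) else "series"
  }

  ff <- morlet_fourier_factor(omega0)
  if (is.null(s0)) s0 <- 2 * dt
  if (is.null(n_scales)) {
    max_period <- n * dt / 3
    n_scales <- max(1L, floor(log2(max_period / (ff * s0)) / dj) + 1L)
  }
  scales <- s0 * 2^((seq_len(n_scales) - 1) * dj)
  periods <- ff * scales

  x <- (v - mean(v)) / stats::sd(v)
  n2 <- 2^ceiling(log2(n))
  xhat <- stats::fft(c(x, numeric(n2 - n)))
  k <- seq_len(n2) - 1
  omega <- ifelse(k <= n2 / 2, 1, -1) * 2 * pi * pmin(k, n2 - k) / (n2 * dt)

  power <- matrix(0, n_scales, n)
  for (j in seq_len(n_scales)) {
    s <- scales[j]
    psi_hat <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    w <- stats::fft(xhat * psi_hat, inverse = TRUE) / n2
    power[j, ] <- Mod(w[seq_len(n)])^2
  }

  dist_edge <- dt * pmin(seq_len(n) - 1, n - seq_len(n))
  coi <- ff * dist_edge / sqrt(2)

  structure(
    list(
      label = label, times = t, periods = periods, scales = scales,
      power = power, coi = coi,
      params = list(
        omega0 = omega0, dj = dj, s0 = s0, n_scales = n_scales,
        dt = dt, n = n
      )
    ),
    class = "wavelet_spectrum"
  )
}

morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spectrum> '%s': %d periods (%.2f-%.2f days) x %d times (dt = %g)\n",
    x$label, length(x$periods), min(x$periods), max(x$periods),
    length(x$times), x$params$dt
  ))
  invisible(x)
}

#' Cone of influence of a wavelet spectrum
#'
#' The maximum period at each time point not contaminated by edge effects:
#' the period whose scale's e-folding time (`sqrt(2) * scale`) equals the
#' distance to the nearer series endpoint.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @return Tibble of `time`, `max_period`.
#' @export
cone_of_influence <- function(spectrum) {
  tibble::tibble(time = spectrum$times, max_period = spectrum$coi)
}

coi_valid <- function(spectrum) {
  outer(spectrum$periods, spectrum$coi, `<=`)
}

#' Time-averaged (global) wavelet spectrum
#'
#' Average power per period over time — an estimator of the classical
#' Fourier spectrum. With `coi_masked = TRUE` (default) cells outside the
#' cone of influence are excluded from the average; a period with no valid
#' cells gets `NA`.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @param coi_masked Exclude edge-affected cells?
#' @return Tibble of `period`, `power`.
#' @export
global_spectrum <- function(spectrum, coi_masked = TRUE) {
  p <- spectrum$power
  if (coi_masked) {
    p[!coi_valid(spectrum)] <- NA_real_
  }
  mp <- rowMeans(p, na.rm = TRUE)
  mp[is.nan(mp)] <- NA_real_
  tibble::tibble(period = spectrum$periods, power = mp)
}

#' Dominant period within a time window
#'
#' The period maximizing the cone-of-influence-masked, time-averaged power
#' over the given window. Ties are broken toward the shorter period.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @param window Length-2 numeric `c(from, to)` in days, or `NULL` for the
#'   full span.
#' @return The dominant period in days (scalar).
#' @export
dominant_period <- function(spectrum, window = NULL) {
  sel <- rep(TRUE, length(spectrum$times))
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    sel <- spectrum$times >= window[1] & spectrum$times <= window[2]
    if (!any(sel)) {
      rlang::abort("`window` contains no time points.")
    }
  }
  p <- spectrum$power[, sel, drop = FALSE]
  p[!coi_valid(spectrum)[, sel, drop = FALSE]] <- NA_real_
  mp <- rowMeans(p, na.rm = TRUE)
  mp[is.nan(mp)] <- NA_real_
  if (all(is.na(mp))) {
    rlang::abort("no spectrum cell inside both the window and the cone of influence.")
  }
  best <- max(mp, na.rm = TRUE)
  # ties (within numerical noise) resolve to the shortest period
  spectrum$periods[which(mp >= best * (1 - 1e-12))][1]
}

#' Write a wavelet spectrum to CSV + JSON header
#'
#' The CSV holds the power matrix (rows = periods, columns = times, first
#' column `period`); the JSON sidecar records the transform parameters and
#' the cone-of-influence vector.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @param path CSV path; the JSON sidecar gets the same path with a `.json`
#'   extension appended.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  m <- as.data.frame(spectrum$power)
  names(m) <- format(spectrum$times, trim = TRUE)
  readr::write_csv(dplyr::bind_cols(tibble::tibble(period = spectrum$periods), m), path)
  jsonlite::write_json(
    list(label = spectrum$label, params = spectrum$params, coi = spectrum$coi),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
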