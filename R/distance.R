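#' Maximum-covariance distance between two wavelet spectra
#'
#' Compares two spectra through maximum covariance analysis (MCA): power
#' outside each spectrum's significance mask is zeroed, the cross-covariance
#' matrix between the two masked spectra is decomposed by SVD, and the
#' leading singular axes holding at least `cum_cov_threshold` of the squared
#' covariance are compared. Per retained axis the discrepancy is
#' `(1 - |cos angle|)` between the two spectra's paired singular vectors
#' plus half the L2 gap between their unit-normalized leading patterns (the
#' projections of each spectrum onto its singular vector), sign-aligned;
#' discrepancies are weighted by the axis' squared-covariance fraction.
#' Identical spectra have distance exactly 0.
#'
#' With `orientation = "time"` (default) the MCA is computed on each
#' spectrum's temporal anomaly field (power minus its time mean, per scale)
#' with time points as variables: singular vectors are time profiles and
#' leading patterns are scale profiles, so two series whose significant
#' power migrates through the same epochs are close even when their exact
#' periods differ slightly, while series sharing only a time-averaged
#' spectrum (the same periods in different epochs) stay far apart — the
#' time-localized comparison that motivates clustering on spectra rather
#' than on average spectra. `orientation = "scale"` uses raw masked power
#' with scales as variables and times as observations.
#'
#' @param spec_a,spec_b `wavelet_spectrum` objects sharing period axis, time
#'   axis and transform parameters.
#' @param mask_a,mask_b Optional `significance_mask`s (typically at the 90%
#'   confidence level); `NULL` uses the full spectra.
#' @param cum_cov_threshold Cumulative squared-covariance fraction retained.
#' @param orientation Which axis supplies the MCA variables (see Details).
#' @return A non-negative scalar distance; `NA` when either masked spectrum
#'   is entirely zero (no significant power anywhere).
#' @export
mca_distance <- function(spec_a, spec_b, mask_a = NULL, mask_b = NULL,
                         cum_cov_threshold = 0.95,
                         orientation = c("time", "scale")) {
  orientation <- match.arg(orientation)
  check_axes(spec_a, spec_b)
  a <- masked_power(spec_a, mask_a)
  b <- masked_power(spec_b, mask_b)
  if (all(a == 0) || all(b == 0)) {
    return(NA_real_)
  }
  if (orientation == "time") {
    # temporal anomalies: a stationary band contributes nothing, so the
    # comparison keys on when power occurs, not only on which scales hold it
    a <- t(a - rowMeans(a))
    b <- t(b - rowMeans(b))
  }
  nobs <- ncol(a)
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  cc <- ac %*% t(bc) / (nobs - 1)
  sv <- svd(cc)
  sq <- sv$d^2
  tot <- sum(sq)
  if (tot == 0) {
    # masked anomalies share no covariance at all: maximal discrepancy
    return(2)
  }
  frac <- sq / tot
  k_max <- which(cumsum(frac) >= cum_cov_threshold)[1]
  d <- 0
  for (k in seq_len(k_max)) {
    u <- sv$u[, k]
    v <- sv$v[, k]
    cuv <- sum(u * v)
    s <- if (cuv < 0) -1 else 1
    pat_a <- drop(u %*% ac)
    pat_b <- s * drop(v %*% bc)
    na_ <- sqrt(sum(pat_a^2))
    nb_ <- sqrt(sum(pat_b^2))
    gap <- if (na_ == 0 || nb_ == 0) 1 else sqrt(sum((pat_a / na_ - pat_b / nb_)^2)) / 2
    d <- d + frac[k] * ((1 - abs(cuv)) + gap)
  }
  d
}

masked_power <- function(spectrum, mask) {
  p <- spectrum$power
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "significance_mask"))
    if (!isTRUE(all.equal(mask$periods, spectrum$periods)) ||
        !isTRUE(all.equal(mask$times, spectrum$times))) {
      rlang::abort("mask axes do not match the spectrum.")
    }
    p[!mask$mask] <- 0
  }
  p
}

check_axes <- function(a, b) {
  same <- isTRUE(all.equal(a$periods, b$periods)) &&
    isTRUE(all.equal(a$times, b$times)) &&
    isTRUE(all.equal(a$params[c("omega0", "dj", "s0", "n_scales", "dt")],
                     b$params[c("omega0", "dj", "s0", "n_scales", "dt")]))
  if (!same) {
    rlang::abort("spectra have incompatible axes or transform parameters.")
  }
  invisible(TRUE)
}

#' Pairwise wavelet-spectrum distance matrix
#'
#' All pairwise [mca_distance()] values over a list of spectra, symmetrized
#' by averaging the two orientations. Pairs where both masked spectra are
#' entirely non-significant get the largest distance observed in the panel
#' (with a message naming them).
#'
#' @param spectra List of `wavelet_spectrum` objects (>= 3) with consistent
#'   axes.
#' @param masks Optional list of `significance_mask`s, same length/order.
#' @param cum_cov_threshold,orientation Passed to [mca_distance()].
#' @return A `stats::dist` object with labels and attribute
#'   `method = "wavelet_mca"`.
#' @export
wavelet_distance_matrix <- function(spectra, masks = NULL,
                                    cum_cov_threshold = 0.95,
                                    orientation = c("time", "scale")) {
  orientation <- match.arg(orientation)
  n <- length(spectra)
  if (n < 3) {
    rlang::abort("need at least 3 spectra.")
  }
  if (!is.null(masks) && length(masks) != n) {
    rlang::abort("`masks` must match `spectra` in length.")
  }
  labels <- vapply(spectra, `[[`, character(1), "label")
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- mca_distance(
        spectra[[i]], spectra[[j]], masks[[i]], masks[[j]],
        cum_cov_threshold = cum_cov_threshold, orientation = orientation
      )
      dji <- mca_distance(
        spectra[[j]], spectra[[i]], masks[[j]], masks[[i]],
        cum_cov_threshold = cum_cov_threshold, orientation = orientation
      )
      m[i, j] <- m[j, i] <- mean(c(dij, dji))
    }
  }
  if (anyNA(m)) {
    worst <- max(m, na.rm = TRUE)
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    rlang::inform(sprintf(
      "pair(s) with no significant power set to the panel maximum (%.3g): %s",
      worst,
      paste(sprintf("%s-%s", labels[bad[, 1]], labels[bad[, 2]]), collapse = ", ")
    ))
    m[is.na(m)] <- worst
  }
  d <- stats::as.dist(m)
  attr(d, "method") <- "wavelet_mca"
  d
}

#' Correlation-based dissimilarity between series
#'
#' `d = 1 - rho` with `rho` the Spearman (default) or Pearson correlation
#' computed over all shared time points, giving dissimilarities in `[0, 2]`
#' (2 = perfect anticorrelation).
#'
#' @param series_set A `regular_series_set`, or a tibble with columns
#'   `label`, `time`, `value` (all series of equal length on a shared grid).
#' @param method `"spearman"` or `"pearson"`.
#' @return A `stats::dist` object with attribute `method`.
#' @export
correlation_dissimilarity <- function(series_set,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  tbl <- if (inherits(series_set, "regular_series_set")) series_set$series else series_set
  wide <- tidyr::pivot_wider(
    tbl[, c("label", "time", "value")],
    names_from = "label", values_from = "value"
  )
  x <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(x) < 3) {
    rlang::abort("need at least 3 series.")
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(sprintf(
      "constant series (correlation undefined): %s",
      paste(colnames(x)[sds == 0], collapse = ", ")
    ))
  }
  d <- stats::as.dist(1 - stats::cor(x, method = method))
  attr(d, "method") <- method
  d
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion in the
#' `ward.D2` convention (the Lance-Williams update applied to squared
#' dissimilarities), as implemented by `stats::hclust`. Merge heights are
#' monotone non-decreasing.
#'
#' @param dist A `stats::dist` object (all entries finite).
#' @return An `hclust` object.
#' @export
ward_cluster <- function(dist) {
  if (!inherits(dist, "dist")) {
    rlang::abort("`dist` must be a stats::dist object.")
  }
  if (any(!is.finite(dist))) {
    rlang::abort("dissimilarities must all be finite.")
  }
  stats::hclust(dist, method = "ward.D2")
}

#' Write / read a labeled square distance matrix as CSV
#'
#' @param dist A `stats::dist` object.
#' @param path CSV path. The first column (`label`) carries row labels.
#' @return `write_dist_csv` returns `path` invisibly; `read_dist_csv`
#'   returns a `stats::dist`.
#' @export
write_dist_csv <- function(dist, path) {
  m <- as.matrix(dist)
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(label = rownames(m)), tibble::as_tibble(m)),
    path
  )
  invisible(path)
}

#' @rdname write_dist_csv
#' @export
read_dist_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}
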