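#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a wavelet spectrum into a long tibble
#'
#' @param x A `wavelet_spectrum`.
#' @param ... Unused.
#' @return Tibble of `label`, `time`, `period`, `power`, `in_coi`.
#' @method tidy wavelet_spectrum
#' @export
tidy.wavelet_spectrum <- function(x, ...) {
  valid <- coi_valid(x)
  tibble::tibble(
    label = x$label,
    time = rep(x$times, each = length(x$periods)),
    period = rep(x$periods, times = length(x$times)),
    power = as.vector(x$power),
    in_coi = as.vector(valid)
  )
}

#' Tidy a significance mask into a long tibble
#'
#' @param x A `significance_mask`.
#' @param ... Unused.
#' @return Tibble of `label`, `time`, `period`, `significant`.
#' @method tidy significance_mask
#' @export
tidy.significance_mask <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    time = rep(x$times, each = length(x$periods)),
    period = rep(x$periods, times = length(x$times)),
    significant = as.vector(x$mask)
  )
}

#' Tidy a Bk curve
#'
#' @param x A `bk_curve`.
#' @param ... Unused.
#' @return Tibble of `k`, `bk`, `null_mean`, `null_sd`, `rejection`.
#' @method tidy bk_curve
#' @export
tidy.bk_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("k", "bk", "null_mean", "null_sd", "rejection")])
}

#' One-row summary of a Bk curve
#'
#' @param x A `bk_curve`.
#' @param ... Unused.
#' @return Tibble with `n` (leaves), `alpha`, `null_method`, `n_levels`,
#'   `frac_above` (fraction of levels with `Bk` above the rejection line)
#'   and `mean_bk`.
#' @method glance bk_curve
#' @export
glance.bk_curve <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    alpha = attr(x, "alpha"),
    null_method = attr(x, "null_method"),
    n_levels = nrow(x),
    frac_above = mean(x$bk > x$rejection, na.rm = TRUE),
    mean_bk = mean(x$bk, na.rm = TRUE)
  )
}

#' Tidy a distance matrix into a long pair table
#'
#' @param x A `stats::dist` object.
#' @param ... Unused.
#' @return Tibble of `item1`, `item2`, `distance` (unique unordered pairs).
#' @export
tidy_dist <- function(x, ...) {
  m <- as.matrix(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    item1 = rownames(m)[idx[, 1]],
    item2 = colnames(m)[idx[, 2]],
    distance = m[idx]
  )
}
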