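#' Simulate a microbiome-like compositional count table
#'
#' Emulates a densely sampled 16S genus table: irregular sampling times,
#' a handful of abundant taxa whose latent log-abundances wax and wane at a
#' shared group period, spiky low-abundance filler taxa, and per-sample
#' compositional (multinomial) count sampling at a fixed sequencing depth.
#'
#' Group members share a period but receive phases spread evenly over the
#' circle, so that members of one group can be mutually anticorrelated in
#' abundance while sharing the same spectral signature — the regime in which
#' spectrum-based clustering recovers the groups and correlation-based
#' clustering does not.
#'
#' @param n_taxa Total number of taxa; must be at least the summed group sizes.
#'   Taxa beyond the groups are spiky fillers drawn from a heavy-tailed
#'   (Student-t, df 3) latent process around a low baseline, which puts their
#'   relative abundance near a typical core-selection detection threshold.
#' @param groups List of ground-truth groups, each a numeric vector
#'   `c(period, size)`: oscillation period in days, number of member taxa.
#' @param span Duration of the sampling campaign, days.
#' @param mean_dt Mean sampling interval, days.
#' @param jitter Multiplicative jitter on sampling gaps: each gap is
#'   `mean_dt * (1 + jitter * u)`, `u ~ U(-1, 1)`. Must be in `[0, 0.5)` so
#'   times stay strictly increasing; 0 gives an equidistant design.
#' @param depth Sequencing depth (reads per sample), the multinomial total.
#' @param amp Amplitude of the group oscillation on the latent log scale.
#' @param noise_sd Taxon-level Gaussian noise on the latent log scale.
#' @param seed Integer seed; the whole table is deterministic given it.
#'
#' @return An object of class `community_counts`: a tibble with columns
#'   `taxon`, `time`, `count`, plus attributes `truth` (tibble of `taxon`,
#'   `group`; filler taxa have group `NA`), `latent` (taxa x samples matrix
#'   of latent log-abundances) and `depth`.
#' @examples
#' cc <- make_synthetic_community(seed = 1)
#' dplyr::summarise(cc, reads = sum(count), .by = time)
#' @export
make_synthetic_community <- function(n_taxa = 19,
                                     groups = list(c(30, 5), c(64, 5)),
                                     span = 450, mean_dt = 1.6, jitter = 0.2,
                                     depth = 10000, amp = 1.5, noise_sd = 0.3,
                                     seed = 1) {
  sizes <- vapply(groups, `[`, numeric(1), 2)
  periods <- vapply(groups, `[`, numeric(1), 1)
  if (n_taxa < sum(sizes)) {
    rlang::abort("`n_taxa` must be at least the summed group sizes.")
  }
  if (any(periods <= 2 * mean_dt)) {
    rlang::abort("every group period must exceed 2 * mean_dt (sub-Nyquist).")
  }
  if (jitter < 0 || jitter >= 0.5) {
    rlang::abort("`jitter` must lie in [0, 0.5).")
  }
  if (depth < 1000) {
    rlang::abort("`depth` must be at least 1000 reads.")
  }

  withr::with_seed(seed, {
    n_samp <- round(span / mean_dt)
    gaps <- mean_dt * (1 + jitter * stats::runif(n_samp - 1, -1, 1))
    times <- c(0, cumsum(gaps))

    n_group_taxa <- sum(sizes)
    taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
    truth <- rep(NA_character_, n_taxa)

    latent <- matrix(0, n_taxa, n_samp)
    row <- 1L
    for (g in seq_along(groups)) {
      phases <- 2 * pi * (seq_len(sizes[g]) - 1) / sizes[g]
      for (m in seq_len(sizes[g])) {
        latent[row, ] <- amp * sin(2 * pi * times / periods[g] + phases[m]) +
          stats::rnorm(n_samp, 0, noise_sd)
        truth[row] <- sprintf("group_p%g", periods[g])
        row <- row + 1L
      }
    }
    # spiky low-abundance fillers: heavy tails give rare sharp peaks
    for (f in seq_len(n_taxa - n_group_taxa)) {
      latent[row, ] <- -2.5 + 0.8 * stats::rt(n_samp, df = 3)
      row <- row + 1L
    }
    rownames(latent) <- taxa
    colnames(latent) <- NULL

    counts <- apply(latent, 2, function(col) {
      p <- exp(col - max(col))
      stats::rmultinom(1, depth, p / sum(p))[, 1]
    })
  })

  out <- tibble::tibble(
    taxon = rep(taxa, times = n_samp),
    time = rep(times, each = n_taxa),
    count = as.integer(counts)
  )
  structure(
    out,
    truth = tibble::tibble(taxon = taxa, group = truth),
    latent = latent,
    depth = depth,
    class = c("community_counts", class(out))
  )
}

#' Ground-truth group membership of a synthetic community
#'
#' @param counts A `community_counts` object.
#' @return A tibble of `taxon`, `group` (`NA` for filler taxa).
#' @export
community_truth <- function(counts) {
  truth <- attr(counts, "truth")
  if (is.null(truth)) {
    rlang::abort("`counts` carries no ground-truth annotation.")
  }
  truth
}

#' Convert a long count tibble to a taxa-by-samples matrix
#'
#' @param counts A tibble with columns `taxon`, `time`, `count` (or `fraction`
#'   / `value`, via `value_col`).
#' @param value_col Name of the value column to spread.
#' @return A numeric matrix, taxa as rows (in order of first appearance),
#'   sample times (sorted, as character) as columns.
#' @export
counts_matrix <- function(counts, value_col = "count") {
  taxa <- unique(counts$taxon)
  times <- sort(unique(counts$time))
  m <- matrix(0, length(taxa), length(times),
    dimnames = list(taxa, format(times, trim = TRUE))
  )
  i <- match(counts$taxon, taxa)
  j <- match(counts$time, times)
  m[cbind(i, j)] <- counts[[value_col]]
  attr(m, "sample_times") <- times
  m
}

#' Write / read a count table as TSV
#'
#' Layout: taxa as rows, samples as columns; the header row carries the
#' sample timestamps (days).
#'
#' @param counts A tibble with columns `taxon`, `time`, `count`.
#' @param path File path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns a tibble of `taxon`, `time`, `count`.
#' @export
write_counts_tsv <- function(counts, path) {
  m <- counts_matrix(counts)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  names(df) <- c("taxon", format(attr(m, "sample_times"), trim = TRUE))
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  times <- as.numeric(names(df)[-1])
  if (anyNA(times)) {
    rlang::abort("TSV header must carry numeric sample timestamps after `taxon`.")
  }
  long_counts(as.matrix(df[, -1, drop = FALSE]), df[[1]], times)
}

#' Read a BIOM-format count table
#'
#' Reads a BIOM file (JSON or HDF5, via the biomformat package) and attaches
#' per-sample collection times taken either from a named numeric vector or
#' from a sample-metadata column.
#'
#' @param path Path to a BIOM file.
#' @param times Either a named numeric vector (sample id -> day) or the name
#'   of a numeric sample-metadata column holding the collection day.
#' @return A tibble of `taxon`, `time`, `count`, sorted by time.
#' @export
read_counts_biom <- function(path, times = "collection_day") {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    rlang::abort("Package `biomformat` is required to read BIOM files.")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  if (is.character(times) && length(times) == 1) {
    sm <- biomformat::sample_metadata(b)
    if (is.null(sm) || is.null(dim(sm))) {
      rlang::abort("BIOM file carries no sample metadata; pass `times` as a named vector.")
    }
    col <- times
    if (!col %in% names(sm)) {
      # JSON BIOM round-trips can drop column names; accept a lone column
      if (ncol(sm) == 1) {
        col <- names(sm)[[1]]
      } else {
        rlang::abort(sprintf("sample metadata column `%s` not found in BIOM file.", times))
      }
    }
    tvec <- as.numeric(sm[[col]])
    names(tvec) <- rownames(sm)
  } else {
    tvec <- times
  }
  tvec <- tvec[colnames(m)]
  if (anyNA(tvec)) {
    rlang::abort("every BIOM sample needs a numeric collection time.")
  }
  ord <- order(tvec)
  long_counts(m[, ord, drop = FALSE], rownames(m), unname(tvec[ord]))
}

long_counts <- function(m, taxa, times) {
  if (is.unsorted(times, strictly = TRUE)) {
    rlang::abort("sample times must be strictly increasing.")
  }
  tibble::tibble(
    taxon = rep(taxa, times = ncol(m)),
    time = rep(times, each = nrow(m)),
    count = as.vector(m)
  )
}
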