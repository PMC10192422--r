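#' Wavelet spectra and significance masks for a set of series
#'
#' Convenience stage shared by the pipeline runners: one Morlet spectrum and
#' one Markov-surrogate significance mask per series.
#'
#' @param series Tibble of `label`, `time`, `value` (all series equidistant
#'   on a shared grid).
#' @param n_surrogates Surrogates per series.
#' @param confidence Mask confidence level.
#' @param seed Base seed; series `i` uses `seed + i`.
#' @param ... Passed to [morlet_cwt()].
#' @return List with `spectra` and `masks`, both named by label.
#' @export
panel_spectra <- function(series, n_surrogates = 100, confidence = 0.90,
                          seed = 1L, ...) {
  per <- panel_split(series)
  spectra <- lapply(per, morlet_cwt, ...)
  masks <- vector("list", length(per))
  for (i in seq_along(per)) {
    ens <- markov_surrogates(per[[i]],
      n_surrogates = n_surrogates, seed = seed + i
    )
    masks[[i]] <- significance_mask(spectra[[i]], ens, confidence = confidence)
  }
  names(masks) <- names(per)
  list(spectra = spectra, masks = masks)
}

#' End-to-end demonstration on the synthetic eight-signal panel
#'
#' Generates the [make_demo_panel()] signals, computes Morlet spectra and
#' 90%-confidence Markov-surrogate masks, builds the wavelet (MCA) and
#' Spearman dissimilarity matrices, clusters both with the Ward criterion,
#' and compares the two trees with the Bk statistic. Asserts the headline
#' contrast: at `k = 4`, the antiphase pair `{s1, s2}` and the
#' slow-then-fast pair `{s5, s8}` co-cluster in the wavelet tree while the
#' Spearman tree separates both pairs.
#'
#' @param outdir Optional directory; when given, emits the panel CSV,
#'   spectra + mask CSVs, both distance CSVs, both Newick trees, the Bk
#'   curve CSV and a JSON run report.
#' @param n_surrogates Surrogates per series (default 200).
#' @param confidence Mask confidence for clustering input (default 0.90).
#' @param alpha Significance level of the Bk rejection line.
#' @param seed Seed for the surrogate ensembles.
#' @param assert Stop (with diagnostics) when the contrast property fails?
#' @return A list of class `demo_analysis`: `panel`, `spectra`, `masks`,
#'   `dist_wavelet`, `dist_spearman`, `tree_wavelet`, `tree_spearman`,
#'   `bk` (a `bk_curve`), `branch_length` (named vector), `contrast`
#'   (named logical), `files`.
#' @export
run_demo_analysis <- function(outdir = NULL, n_surrogates = 200,
                              confidence = 0.90, alpha = 0.05, seed = 1L,
                              assert = TRUE) {
  panel <- make_demo_panel()
  sp <- panel_spectra(panel$series,
    n_surrogates = n_surrogates,
    confidence = confidence, seed = seed
  )
  d_wave <- wavelet_distance_matrix(sp$spectra, sp$masks)
  d_spear <- correlation_dissimilarity(panel$series, method = "spearman")
  tree_wave <- ward_cluster(d_wave)
  tree_spear <- ward_cluster(d_spear)
  bk <- bk_curve(tree_wave, tree_spear, alpha = alpha)

  contrast <- c(
    wavelet_s1_s2 = co_clustered(tree_wave, c("s1", "s2"), k = 4),
    wavelet_s5_s8 = co_clustered(tree_wave, c("s5", "s8"), k = 4),
    spearman_s1_s2_apart = !co_clustered(tree_spear, c("s1", "s2"), k = 4),
    spearman_s5_s8_apart = !co_clustered(tree_spear, c("s5", "s8"), k = 4)
  )
  if (assert && !all(contrast)) {
    rlang::abort(c(
      "demo contrast property failed:",
      stats::setNames(
        sprintf("%s: %s", names(contrast), contrast),
        rep("x", length(contrast))
      )
    ))
  }

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- function(...) file.path(outdir, sprintf(...))
    files <- c(write_panel_csv(panel, f("panel.csv")))
    for (lab in names(sp$spectra)) {
      files <- c(
        files,
        write_spectrum_csv(sp$spectra[[lab]], f("spectrum_%s.csv", lab)),
        write_mask_csv(sp$masks[[lab]], f("mask_%s.csv", lab))
      )
    }
    files <- c(
      files,
      write_dist_csv(d_wave, f("dist_wavelet.csv")),
      write_dist_csv(d_spear, f("dist_spearman.csv")),
      write_tree_newick(tree_wave, f("tree_wavelet.nwk")),
      write_tree_newick(tree_spear, f("tree_spearman.nwk"))
    )
    readr::write_csv(tibble::as_tibble(bk), f("bk_curve.csv"))
    files <- c(files, f("bk_curve.csv"))
    jsonlite::write_json(
      list(
        n_surrogates = n_surrogates, confidence = confidence, alpha = alpha,
        seed = seed, contrast = as.list(contrast),
        branch_length = list(
          wavelet = total_branch_length(tree_wave),
          spearman = total_branch_length(tree_spear)
        ),
        files = files
      ),
      f("report.json"),
      auto_unbox = TRUE, digits = NA
    )
    files <- c(files, f("report.json"))
  }

  structure(
    list(
      panel = panel, spectra = sp$spectra, masks = sp$masks,
      dist_wavelet = d_wave, dist_spearman = d_spear,
      tree_wavelet = tree_wave, tree_spearman = tree_spear,
      bk = bk,
      branch_length = c(
        wavelet = total_branch_length(tree_wave),
        spearman = total_branch_length(tree_spear)
      ),
      contrast = contrast, files = files
    ),
    class = "demo_analysis"
  )
}

co_clustered <- function(tree, labels, k) {
  cl <- cut_tree(tree, k)
  length(unique(cl[labels])) == 1
}

#' @export
print.demo_analysis <- function(x, ...) {
  cat("<demo_analysis>\n")
  cat(sprintf(
    "  contrast at k = 4: %s\n",
    if (all(x$contrast)) "holds" else "FAILED"
  ))
  cat(sprintf(
    "  total branch length: wavelet %.2f, spearman %.2f\n",
    x$branch_length[["wavelet"]], x$branch_length[["spearman"]]
  ))
  cat(sprintf(
    "  Bk curve: %d/%d levels above the %.0f%% rejection line\n",
    sum(x$bk$bk > x$bk$rejection, na.rm = TRUE), nrow(x$bk),
    100 * (1 - attr(x$bk, "alpha"))
  ))
  invisible(x)
}

#' Full pipeline for one community count table
#'
#' Preprocesses the table ([preprocess_counts()]), computes spectra and
#' 90%-confidence masks, the wavelet (MCA), Spearman and Pearson trees, the
#' Bk curves wavelet-vs-Spearman and Pearson-vs-Spearman, and total branch
#' lengths. Every excluded sample or taxon is recorded in the result.
#'
#' @param counts Tibble of `taxon`, `time`, `count`.
#' @param config A [preprocess_config()].
#' @param taxa Optional externally fixed taxon list (e.g.
#'   [union_across_subjects()] output).
#' @param n_surrogates Surrogates per series.
#' @param confidence Mask confidence for clustering input.
#' @param cum_cov_threshold Passed to [wavelet_distance_matrix()].
#' @param alpha Bk rejection-line level.
#' @param seed Seed for surrogates.
#' @param outdir Optional output directory (CSV/Newick/JSON, as in
#'   [run_demo_analysis()]).
#' @return A list of class `community_analysis`: `preprocessed`, `spectra`,
#'   `masks`, `dist_wavelet`, trees (`tree_wavelet`, `tree_spearman`,
#'   `tree_pearson`), `bk_wavelet_spearman`, `bk_pearson_spearman`,
#'   `branch_length`, `files`.
#' @export
run_community_analysis <- function(counts, config = preprocess_config(),
                                   taxa = NULL, n_surrogates = 100,
                                   confidence = 0.90,
                                   cum_cov_threshold = 0.95, alpha = 0.05,
                                   seed = 1L, outdir = NULL) {
  prep <- preprocess_counts(counts, config = config, taxa = taxa)
  if (length(prep$taxa) < 3) {
    rlang::abort(sprintf(
      "only %d taxa retained; need at least 3 to cluster.", length(prep$taxa)
    ))
  }
  n_grid <- sum(prep$series$label == prep$taxa[[1]])
  if (n_grid < 25) {
    rlang::abort(sprintf(
      "only %d interpolated points; at least 25 are required for wavelet analysis.",
      n_grid
    ))
  }
  sp <- panel_spectra(prep$series,
    n_surrogates = n_surrogates,
    confidence = confidence, seed = seed
  )
  d_wave <- wavelet_distance_matrix(sp$spectra, sp$masks,
    cum_cov_threshold = cum_cov_threshold
  )
  d_spear <- correlation_dissimilarity(prep, method = "spearman")
  d_pear <- correlation_dissimilarity(prep, method = "pearson")
  tree_wave <- ward_cluster(d_wave)
  tree_spear <- ward_cluster(d_spear)
  tree_pear <- ward_cluster(d_pear)

  out <- structure(
    list(
      preprocessed = prep, spectra = sp$spectra, masks = sp$masks,
      dist_wavelet = d_wave,
      tree_wavelet = tree_wave, tree_spearman = tree_spear,
      tree_pearson = tree_pear,
      bk_wavelet_spearman = bk_curve(tree_wave, tree_spear, alpha = alpha),
      bk_pearson_spearman = bk_curve(tree_pear, tree_spear, alpha = alpha),
      branch_length = c(
        wavelet = total_branch_length(tree_wave),
        spearman = total_branch_length(tree_spear),
        pearson = total_branch_length(tree_pear)
      ),
      files = character(0)
    ),
    class = "community_analysis"
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- function(...) file.path(outdir, sprintf(...))
    files <- c(
      write_dist_csv(d_wave, f("dist_wavelet.csv")),
      write_tree_newick(tree_wave, f("tree_wavelet.nwk")),
      write_tree_newick(tree_spear, f("tree_spearman.nwk")),
      write_tree_newick(tree_pear, f("tree_pearson.nwk"))
    )
    readr::write_csv(prep$series, f("preprocessed.csv"))
    readr::write_csv(tibble::as_tibble(out$bk_wavelet_spearman), f("bk_wavelet_spearman.csv"))
    files <- c(files, f("preprocessed.csv"), f("bk_wavelet_spearman.csv"))
    jsonlite::write_json(
      list(
        taxa = prep$taxa,
        dropped_samples = prep$dropped_samples,
        boxcox = prep$params,
        branch_length = as.list(out$branch_length),
        n_surrogates = n_surrogates, confidence = confidence,
        alpha = alpha, seed = seed, files = files
      ),
      f("report.json"),
      auto_unbox = TRUE, digits = NA
    )
    out$files <- c(files, f("report.json"))
  }
  out
}

#' @export
print.community_analysis <- function(x, ...) {
  cat(sprintf(
    "<community_analysis> %d taxa, %d grid points\n",
    length(x$preprocessed$taxa),
    sum(x$preprocessed$series$label == x$preprocessed$taxa[[1]])
  ))
  cat(sprintf(
    "  total branch length: wavelet %.2f, spearman %.2f, pearson %.2f\n",
    x$branch_length[["wavelet"]], x$branch_length[["spearman"]],
    x$branch_length[["pearson"]]
  ))
  invisible(x)
}

#' Multi-subject pipeline with cross-subject tree comparisons
#'
#' Runs [run_community_analysis()] independently on each subject's count
#' table (no cross-subject normalization), restricting all subjects to the
#' union of their core taxa so trees share a leaf set, then compares trees
#' within and across subjects: wavelet-vs-Spearman and Pearson-vs-Spearman
#' within each subject, and wavelet-vs-wavelet / Spearman-vs-Spearman for
#' every subject pair.
#'
#' @param tables Named list of count tibbles (`taxon`, `time`, `count`), one
#'   per subject.
#' @param config A [preprocess_config()] applied to every subject.
#' @param ... Passed to [run_community_analysis()].
#' @param alpha Bk rejection-line level.
#' @return A list of class `multisubject_analysis`: `subjects` (named list
#'   of `community_analysis`), `comparisons` (named list of `bk_curve`s),
#'   `core_taxa`.
#' @export
run_multisubject_analysis <- function(tables, config = preprocess_config(),
                                      alpha = 0.05, ...) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    rlang::abort("`tables` must be a named list, one count table per subject.")
  }
  cores <- lapply(tables, function(tb) {
    rel <- relative_abundance(filter_low_depth(tb, config$min_reads))
    select_core_taxa(rel,
      detection = config$detection, prevalence = config$prevalence,
      n_boot = config$n_boot, seed = config$seed
    )
  })
  core <- union_across_subjects(cores)
  subjects <- lapply(tables, run_community_analysis,
    config = config, taxa = core, alpha = alpha, ...
  )
  comparisons <- list()
  for (s in names(subjects)) {
    comparisons[[paste0(s, "_wavelet_vs_spearman")]] <-
      subjects[[s]]$bk_wavelet_spearman
    comparisons[[paste0(s, "_pearson_vs_spearman")]] <-
      subjects[[s]]$bk_pearson_spearman
  }
  pairs <- utils::combn(names(subjects), 2, simplify = FALSE)
  for (pr in pairs) {
    comparisons[[paste0(pr[1], "_vs_", pr[2], "_wavelet")]] <- bk_curve(
      subjects[[pr[1]]]$tree_wavelet, subjects[[pr[2]]]$tree_wavelet,
      alpha = alpha
    )
    comparisons[[paste0(pr[1], "_vs_", pr[2], "_spearman")]] <- bk_curve(
      subjects[[pr[1]]]$tree_spearman, subjects[[pr[2]]]$tree_spearman,
      alpha = alpha
    )
  }
  structure(
    list(subjects = subjects, comparisons = comparisons, core_taxa = core),
    class = "multisubject_analysis"
  )
}
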