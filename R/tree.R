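#' Cut a dendrogram into k flat clusters
#'
#' Thin wrapper over `stats::cutree` returning a named membership vector
#' with exactly `k` non-empty clusters (ties in merge heights resolve by
#' merge order, as in `cutree`).
#'
#' @param dend An `hclust` object (or anything `stats::as.hclust` accepts).
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @return Named integer vector mapping each leaf label to its cluster.
#' @export
cut_tree <- function(dend, k) {
  h <- stats::as.hclust(dend)
  n <- length(h$labels)
  if (k < 2 || k > n - 1) {
    rlang::abort(sprintf("`k` must lie in [2, %d].", n - 1))
  }
  stats::cutree(h, k = k)
}

#' Fowlkes-Mallows Bk statistic for two flat partitions
#'
#' With `m[i, j]` the number of objects shared between cluster `i` of the
#' first partition and cluster `j` of the second,
#' `Tk = sum(m^2) - n`, `Pk = sum(rowSums(m)^2) - n`,
#' `Qk = sum(colSums(m)^2) - n`, and `Bk = Tk / sqrt(Pk * Qk)`. `Bk` lies in
#' `[0, 1]`; 1 means the partitions coincide (up to cluster relabeling), 0
#' means no co-clustered pair is shared.
#'
#' @param c1,c2 Named membership vectors over the same label set (e.g. from
#'   [cut_tree()]).
#' @return `Bk` as a scalar; `NA` when either partition is all singletons
#'   (`Pk` or `Qk` is 0, leaving the statistic undefined).
#' @export
bk_statistic <- function(c1, c2) {
  if (is.null(names(c1)) || is.null(names(c2)) ||
      !setequal(names(c1), names(c2))) {
    rlang::abort("`c1` and `c2` must be named over the same label set.")
  }
  c2 <- c2[names(c1)]
  m <- table(c1, c2)
  n <- length(c1)
  tk <- sum(m^2) - n
  pk <- sum(rowSums(m)^2) - n
  qk <- sum(colSums(m)^2) - n
  if (pk == 0 || qk == 0) {
    return(NA_real_)
  }
  tk / sqrt(pk * qk)
}

# Asymptotic null moments of Bk under random permutation of labels with the
# partitions' marginal cluster sizes held fixed (Fowlkes & Mallows 1983).
bk_null_moments <- function(c1, c2) {
  n <- length(c1)
  pi_ <- as.numeric(table(c1))
  qj <- as.numeric(table(c2))
  pk <- sum(pi_^2) - n
  qk <- sum(qj^2) - n
  if (pk == 0 || qk == 0) {
    return(c(mean = NA_real_, sd = NA_real_))
  }
  pk1 <- sum(pi_ * (pi_ - 1) * (pi_ - 2))
  qk1 <- sum(qj * (qj - 1) * (qj - 2))
  e_bk <- sqrt(pk * qk) / (n * (n - 1))
  v_bk <- 2 / (n * (n - 1)) +
    4 * pk1 * qk1 / (n * (n - 1) * (n - 2) * pk * qk) +
    (pk - 2 - 4 * pk1 / pk) * (qk - 2 - 4 * qk1 / qk) /
      (n * (n - 1) * (n - 2) * (n - 3)) -
    pk * qk / (n^2 * (n - 1)^2)
  c(mean = e_bk, sd = sqrt(max(v_bk, 0)))
}

#' Bk similarity curve between two dendrograms
#'
#' Cuts both trees at every `k = 2, ..., n - 1`, computes the
#' Fowlkes-Mallows `Bk` at each level, and draws a one-sided upper rejection
#' line `null_mean + z(1 - alpha) * null_sd` under the null hypothesis that
#' the two trees are unrelated. Null moments come either from the asymptotic
#' distribution under random label permutation with fixed marginal cluster
#' sizes, or from an empirical permutation null (`n_perm` random relabelings
#' of the second tree).
#'
#' @param dend1,dend2 `hclust` objects over the same leaf labels.
#' @param alpha One-sided significance level (default 0.05).
#' @param null_method `"asymptotic"` or `"permutation"`.
#' @param n_perm Number of label permutations for the permutation null.
#' @param seed Seed for the permutation null.
#' @return An object of class `bk_curve`: a tibble with columns `k`, `bk`,
#'   `null_mean`, `null_sd`, `rejection`, plus attributes `alpha`,
#'   `null_method`, `n` and `labels`.
#' @export
bk_curve <- function(dend1, dend2, alpha = 0.05,
                     null_method = c("asymptotic", "permutation"),
                     n_perm = 999, seed = 1L) {
  null_method <- match.arg(null_method)
  h1 <- stats::as.hclust(dend1)
  h2 <- stats::as.hclust(dend2)
  if (!setequal(h1$labels, h2$labels)) {
    extra <- c(setdiff(h1$labels, h2$labels), setdiff(h2$labels, h1$labels))
    rlang::abort(sprintf(
      "trees have different leaf sets; mismatched: %s",
      paste(extra, collapse = ", ")
    ))
  }
  n <- length(h1$labels)
  if (n < 4) {
    rlang::abort("need at least 4 leaves for a non-trivial Bk curve.")
  }
  ks <- 2:(n - 1)
  cuts1 <- lapply(ks, function(k) cut_tree(h1, k))
  cuts2 <- lapply(ks, function(k) cut_tree(h2, k))
  bk <- mapply(bk_statistic, cuts1, cuts2)

  if (null_method == "asymptotic") {
    mom <- t(mapply(bk_null_moments, cuts1, cuts2))
    null_mean <- mom[, "mean"]
    null_sd <- mom[, "sd"]
  } else {
    perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        prm <- sample(n)
        vapply(seq_along(ks), function(i) {
          p2 <- cuts2[[i]]
          names(p2) <- names(p2)[prm]
          bk_statistic(cuts1[[i]], p2)
        }, numeric(1))
      }, numeric(length(ks)))
    })
    null_mean <- rowMeans(perm, na.rm = TRUE)
    null_sd <- apply(perm, 1, stats::sd, na.rm = TRUE)
  }
  rejection <- null_mean + stats::qnorm(1 - alpha) * null_sd

  out <- tibble::tibble(
    k = ks, bk = as.numeric(bk),
    null_mean = as.numeric(null_mean), null_sd = as.numeric(null_sd),
    rejection = as.numeric(rejection)
  )
  structure(out,
    alpha = alpha, null_method = null_method, n = n, labels = h1$labels,
    class = c("bk_curve", class(out))
  )
}

#' Total branch length of a dendrogram
#'
#' The sum of the lengths of all connecting segments of the merge tree, with
#' leaves at height 0 (computed via `vegan::treeheight`). Used as an
#' indicator of how much structural diversity a cluster tree expresses.
#'
#' @param dend An `hclust` object.
#' @return Total branch length (scalar).
#' @export
total_branch_length <- function(dend) {
  vegan::treeheight(stats::as.hclust(dend))
}

#' Write / read a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights (leaves at height 0).
#' Reading requires an ultrametric tree and returns an `hclust`.
#'
#' @param dend An `hclust` object.
#' @param path File path.
#' @return `write_tree_newick` returns `path` invisibly; `read_tree_newick`
#'   returns an `hclust`.
#' @export
write_tree_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(stats::as.hclust(dend)), file = path)
  invisible(path)
}

#' @rdname write_tree_newick
#' @export
read_tree_newick <- function(path) {
  stats::as.hclust(ape::read.tree(path))
}

#' Compare two cluster trees with the Bk statistic
#'
#' Standalone entry point: accepts `hclust` objects or Newick file paths and
#' returns the [bk_curve()] between them.
#'
#' @param tree_a,tree_b `hclust` objects or paths to Newick files.
#' @inheritParams bk_curve
#' @return A `bk_curve`.
#' @export
compare_trees <- function(tree_a, tree_b, alpha = 0.05,
                          null_method = c("asymptotic", "permutation"),
                          n_perm = 999, seed = 1L) {
  as_tree <- function(x) {
    if (is.character(x) && length(x) == 1) read_tree_newick(x) else stats::as.hclust(x)
  }
  bk_curve(as_tree(tree_a), as_tree(tree_b),
    alpha = alpha, null_method = match.arg(null_method),
    n_perm = n_perm, seed = seed
  )
}
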