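# Clustering of recovered gamma-kernel parameter vectors and the
# cluster-level significance scan: Ward linkage on the standardized
# (a, b, tau, n, d) feature space, Fisher-Z statistics per cluster,
# Bonferroni-corrected two-sided Z-tests across dendrogram divisions.

#' Standardized feature matrix from fit results
#'
#' Each fit contributes a 5-dimensional feature vector (a, b, tau, n, d);
#' columns are standardized to zero mean and unit variance using
#' population (ddof 0) statistics. The transform is retained so cluster
#' means can be mapped back to physical parameters.
#'
#' @param fits list of `fit_result`.
#' @param use_continuous_n use the continuous shape estimate from simplex
#'   refinement (default) rather than the rounded integer.
#' @return object of class `feature_matrix`: standardized matrix `x` plus
#'   `center` and `scale`.
#' @export
build_features <- function(fits, use_continuous_n = TRUE) {
  if (length(fits) < 2L) stop("need at least 2 fits to build features")
  raw <- t(vapply(fits, function(f) c(
    a = f$a, b = f$b, tau = f$params$tau,
    n = if (use_continuous_n && is.finite(f$n_continuous)) f$n_continuous
        else f$params$n,
    d = f$params$d), numeric(5)))
  center <- colMeans(raw)
  scale <- sqrt(colMeans(sweep(raw, 2, center)^2))  # population sd
  if (any(scale < 1e-12)) {
    bad <- colnames(raw)[scale < 1e-12]
    stop(sprintf("zero-variance feature column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  x <- sweep(sweep(raw, 2, center), 2, scale, "/")
  structure(list(x = x, center = center, scale = scale),
            class = "feature_matrix")
}

#' Ward-linkage hierarchical clustering
#'
#' Agglomerative merges minimizing the within-cluster variance increase
#' (Lance-Williams Ward recursion on Euclidean distances); for two
#' singletons the merge height is their Euclidean distance.
#'
#' @param fm a `feature_matrix` (or plain numeric matrix).
#' @return object of class `linkage_tree` wrapping the merge history.
#' @export
ward_linkage <- function(fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 n = nrow(x)),
            class = "linkage_tree")
}

#' Cut the dendrogram into N clusters
#'
#' @param tree a `linkage_tree`.
#' @param N number of clusters (1..n).
#' @return integer labels, one per original feature vector.
#' @export
cut_tree <- function(tree, N) {
  stopifnot(inherits(tree, "linkage_tree"))
  if (N < 1 || N > tree$n) stop("N outside 1..n")
  as.integer(stats::cutree(tree$hclust, k = N))
}

#' Fisher Z transform
#'
#' `z = atanh(r)`, variance-stabilizing for Pearson correlations.
#' Correlations at or beyond +/-1 are clamped just inside with a warning.
#'
#' @param r Pearson correlation(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  clip <- abs(r) >= 1
  if (any(clip, na.rm = TRUE)) {
    warning("|r| >= 1 clamped to 1 - 1e-12 before Fisher Z")
    r[clip] <- sign(r[clip]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Cluster Z statistic
#'
#' `z* = sqrt(n) * mean(z)` over the cluster's members' Fisher-Z values.
#'
#' @param zs Fisher-Z values of one cluster's fits.
#' @return list with `z_bar` and `z_star`.
#' @export
cluster_zstat <- function(zs) {
  if (length(zs) == 0L) stop("empty cluster")
  z_bar <- mean(zs)
  list(z_bar = z_bar, z_star = sqrt(length(zs)) * z_bar)
}

#' Significance scan across dendrogram divisions
#'
#' For every division `C_N` in `n_range`: cut the tree, form each
#' cluster's `z*` from its members' Fisher-Z-transformed prediction
#' correlations, and compare `|z*|` against the Bonferroni-corrected
#' two-sided threshold `z_alpha = qnorm(1 - (alpha / N) / 2)`. `C_S` is
#' the count of significant clusters in the division.
#'
#' The reported P-values are approximate (the per-fit correlations are
#' neither independent nor exactly normal after transformation); the
#' report flags this.
#'
#' @param tree a `linkage_tree`.
#' @param per_fit_r Pearson r of every fit, in feature-row order.
#' @param n_range divisions to scan (default 2..12).
#' @param alpha family-wise significance level.
#' @return object of class `cluster_report`: per-division tables
#'   (`divisions`), the `cs` profile, `labels` per division, `alpha`, and
#'   metadata marking the P-values approximate.
#' @export
significance_scan <- function(tree, per_fit_r, n_range = 2:12,
                              alpha = 0.05) {
  stopifnot(inherits(tree, "linkage_tree"))
  if (length(per_fit_r) != tree$n)
    stop("need one correlation per clustered fit")
  n_range <- n_range[n_range >= 1 & n_range <= tree$n]
  z <- fisher_z(per_fit_r)
  divisions <- list()
  labels <- list()
  cs <- integer(length(n_range))
  for (i in seq_along(n_range)) {
    N <- n_range[i]
    lab <- cut_tree(tree, N)
    z_alpha <- stats::qnorm(1 - (alpha / N) / 2)
    rows <- lapply(sort(unique(lab)), function(k) {
      st <- cluster_zstat(z[lab == k])
      data.frame(cluster = k, size = sum(lab == k), z_bar = st$z_bar,
                 z_star = st$z_star, z_alpha = z_alpha,
                 significant = abs(st$z_star) > z_alpha,
                 sign = sign(st$z_bar))
    })
    tab <- do.call(rbind, rows)
    divisions[[as.character(N)]] <- tab
    labels[[as.character(N)]] <- lab
    cs[i] <- sum(tab$significant)
  }
  structure(list(divisions = divisions, labels = labels,
                 cs = stats::setNames(cs, as.character(n_range)),
                 n_range = n_range, alpha = alpha,
                 p_values_approximate = TRUE),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report>\n divisions scanned:",
      paste(x$n_range, collapse = ", "), "\n")
  cat(" significant clusters per division:\n")
  print(x$cs)
  opt <- select_optimal(x)
  cat(" optimal division:", if (is.na(opt)) "none" else opt, "\n")
  cat(" note: P values are approximate\n")
  invisible(x)
}

#' Optimal cluster division
#'
#' Among divisions attaining the maximal number of significant clusters,
#' the largest division is returned (more clustered parameter sets give
#' greater modeling flexibility). Returns `NA` when no division has a
#' significant cluster.
#'
#' @param report a `cluster_report`.
#' @return integer division, or `NA_integer_`.
#' @export
select_optimal <- function(report) {
  stopifnot(inherits(report, "cluster_report"))
  if (all(report$cs == 0L)) return(NA_integer_)
  best <- max(report$cs)
  max(report$n_range[report$cs == best])
}

#' Representative gamma kernels per cluster
#'
#' Per cluster: the unstandardized mean of the members' parameters (shape
#' rounded to the nearest integer for kernel evaluation, continuous mean
#' also reported), with the sampled kernel rescaled to unit discrete area.
#'
#' @param labels cluster labels (one per fit).
#' @param fits list of `fit_result` in the same order.
#' @param fs sampling rate for the kernel evaluation (Hz).
#' @param duration_s kernel support (default covers the slowest member).
#' @return list per cluster: `params` (mean tau/n/d/a/b), `n_continuous`,
#'   `kernel` (`nvc_ts`, unit area), `size`.
#' @export
representative_kernels <- function(labels, fits, fs = 25,
                                   duration_s = NULL) {
  stopifnot(length(labels) == length(fits))
  out <- list()
  for (k in sort(unique(labels))) {
    sub <- fits[labels == k]
    tau <- mean(vapply(sub, function(f) f$params$tau, numeric(1)))
    ncont <- mean(vapply(sub, function(f)
      if (is.finite(f$n_continuous)) f$n_continuous else f$params$n,
      numeric(1)))
    d <- mean(vapply(sub, function(f) f$params$d, numeric(1)))
    a <- mean(vapply(sub, function(f) f$a, numeric(1)))
    b <- mean(vapply(sub, function(f) f$b, numeric(1)))
    gp <- gamma_params(tau, max(1, round(ncont)), d)
    dur <- if (is.null(duration_s)) gp$d + 10 * gp$n * gp$tau + 1 / fs
           else duration_s
    h <- gamma_kernel(gp, fs, dur)
    h <- h / (sum(h) / fs)  # unit discrete area
    out[[as.character(k)]] <- list(
      params = list(tau = tau, n = gp$n, d = d, a = a, b = b),
      n_continuous = ncont, size = length(sub),
      kernel = nvc_ts(h, fs, 0))
  }
  out
}
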