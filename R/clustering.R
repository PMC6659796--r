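# Variance filtering, feature scaling, average-linkage hierarchical
# clustering of samples and gap-statistic estimation of the number of
# clusters.

#' Variance filter on peptides
#'
#' Retains peptide `i` iff `sd_i / sd_max >= threshold`, where `sd_i` is
#' the sample standard deviation of the peptide across samples and
#' `sd_max` the largest such value.  The ratio uses standard deviations,
#' not variances.
#'
#' @param pm a collapsed `peptide_matrix` (samples x peptides).
#' @param threshold ratio threshold in `[0, 1]` (default 0.15).
#' @return A `peptide_matrix` at stage `filtered` containing the retained
#'   peptides, with attribute `sd_ratio` (named vector over all input
#'   peptides).
#' @export
variance_filter <- function(pm, threshold = 0.15) {
  stopifnot(inherits(pm, "peptide_matrix"), pm$level == "peptide")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  .pm_advance(pm, "filtered")
  sds <- apply(pm$values, 2, sd)
  smax <- max(sds)
  if (smax == 0) stop("all peptides constant: sd_max is 0")
  ratio <- sds / smax
  keep <- ratio >= threshold
  res <- peptide_matrix(pm$values[, keep, drop = FALSE], stage = "filtered",
                        level = "peptide", group = pm$group,
                        log_transformed = pm$log_transformed)
  attr(res, "sd_ratio") <- ratio
  res
}

#' Scale peptide features
#'
#' Optionally applies `log2(1 + x)`, then z-scores each peptide (mean 0,
#' sd 1 across samples).  Peptides that are constant across samples after
#' filtering carry no clustering information and are dropped with a
#' warning.
#'
#' @param pm a filtered (or collapsed) `peptide_matrix`.
#' @param log_transform apply `log2(1 + x)` first (default `TRUE`).
#' @return A `peptide_matrix` at stage `scaled`.
#' @export
scale_features <- function(pm, log_transform = TRUE) {
  stopifnot(inherits(pm, "peptide_matrix"), pm$level == "peptide")
  .pm_advance(pm, "scaled")
  m <- pm$values
  logged <- pm$log_transformed
  if (log_transform && !logged) {
    if (min(m) < 0) stop("log transform needs non-negative values")
    m <- log2(1 + m)
    logged <- TRUE
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance peptide(s) dropped at scaling")
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  m <- scale(m)          # column-wise: mean 0, sd 1 per peptide
  attr(m, "scaled:center") <- attr(m, "scaled:scale") <- NULL
  peptide_matrix(m, stage = "scaled", level = "peptide", group = pm$group,
                 log_transformed = logged, scaled = TRUE)
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering of sample profiles with UPGMA (average)
#' linkage on Euclidean distances.
#'
#' @param pm a scaled `peptide_matrix`, or a bare numeric matrix with one
#'   row per sample.
#' @param metric `"euclidean"` (default) or `"correlation"`
#'   (`1 - Pearson r` between sample profiles).
#' @return An [stats::hclust] tree over the samples.
#' @export
hierarchical_cluster <- function(pm, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  m <- if (is.matrix(pm)) pm else pm$values
  if (nrow(m) < 2) stop("need >= 2 samples to cluster")
  d <- if (metric == "euclidean") dist(m) else as.dist(1 - cor(t(m)))
  hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' Cluster ids are renumbered `1, 2, ...` by order of first member in the
#' sample ordering, so that with `k = 2` the group containing the first
#' sample is always cluster 1.
#'
#' @param tree an `hclust` tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster labels.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k out of range 1..", n)
  raw <- cutree(tree, k = k)
  relabel <- match(raw, unique(raw))      # renumber by first appearance
  setNames(as.integer(relabel), names(raw))
}

#' Within-cluster dispersion
#'
#' `W = sum_r D_r / (2 n_r)`, where `D_r` is the sum of all pairwise
#' squared Euclidean distances within cluster `r`; algebraically equal to
#' the total within-cluster sum of squared distances to centroids, which
#' is how it is computed here.
#'
#' @param pm a `peptide_matrix` or bare matrix (rows = samples).
#' @param labels integer cluster labels, one per sample.
#' @return The scalar dispersion `W`.
#' @export
within_dispersion <- function(pm, labels) {
  m <- if (is.matrix(pm)) pm else pm$values
  stopifnot(length(labels) == nrow(m))
  w <- 0
  for (g in unique(labels)) {
    x <- m[labels == g, , drop = FALSE]
    if (nrow(x) > 1) {
      ctr <- colMeans(x)
      w <- w + sum(sweep(x, 2, ctr)^2)
    }
  }
  w
}

#' Gap statistic for the number of clusters
#'
#' For each `k` in `1..k_max` the observed data are clustered with
#' [hierarchical_cluster()] + [cut_tree()] and `log W_k` recorded; `B`
#' reference datasets, drawn uniformly over each feature's observed
#' range, are clustered identically.  `Gap(k)` is the mean reference
#' `log W` minus the observed `log W`, `s_k` the reference standard
#' deviation times `sqrt(1 + 1/B)`, and the selected `k` is the smallest
#' `k` with `Gap(k) >= Gap(k+1) - s_(k+1)` (the one-standard-error rule);
#' if no `k` satisfies the rule, `k_max` is returned.
#'
#' @param pm a scaled `peptide_matrix` or bare matrix (rows = samples).
#' @param k_max largest number of clusters considered (default 6).
#' @param B number of reference datasets (default 100).
#' @param seed integer seed for the reference draws.
#' @param metric distance metric, see [hierarchical_cluster()].
#' @return A list with `k_hat`, `curve` (data.frame `k`, `log_W`, `gap`,
#'   `s`).
#' @export
gap_statistic <- function(pm, k_max = 6, B = 100, seed = 1,
                          metric = "euclidean") {
  m <- if (is.matrix(pm)) pm else pm$values
  n <- nrow(m)
  if (n < 3) stop("need >= 3 samples for gap-statistic model selection")
  if (k_max >= n) stop("k_max must be smaller than the number of samples")

  log_w_curve <- function(x) {
    tree <- hierarchical_cluster(x, metric = metric)
    vapply(seq_len(k_max), function(k)
      log(within_dispersion(x, cutree(tree, k = k))), numeric(1))
  }
  obs <- log_w_curve(m)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  set.seed(seed)
  ref <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    x <- matrix(runif(n * ncol(m), rep(lo, each = n), rep(hi, each = n)),
                nrow = n)
    ref[b, ] <- log_w_curve(x)
  }
  gap <- colMeans(ref) - obs
  s <- apply(ref, 2, sd) * sqrt(1 + 1 / B)
  k_hat <- k_max
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) { k_hat <- k; break }
  }
  list(k_hat = k_hat,
       curve = data.frame(k = seq_len(k_max), log_W = obs, gap = gap,
                          s = s))
}

#' Run the clustering stage
#'
#' Variance filter, scaling, gap-statistic model selection, and labels at
#' the selected number of clusters.
#'
#' @param pm a collapsed `peptide_matrix` (samples x peptides); pass only
#'   the samples to stratify (e.g. AML samples, not controls).
#' @param variance_threshold `sd/sd_max` filter threshold (default 0.15).
#' @param log_transform apply `log2(1+x)` before z-scoring.
#' @param k_max,B,seed,metric passed to [gap_statistic()].
#' @return A list of class `cluster_result`: `tree` (hclust), `labels`
#'   (named labels at `k_hat`), `labels_by_k` (matrix, one column per k),
#'   `k_hat`, `gap` (curve data.frame), `filtered_peptides` (ids),
#'   `n_filtered`.
#' @export
run_clustering <- function(pm, variance_threshold = 0.15,
                           log_transform = TRUE, k_max = 6, B = 100,
                           seed = 1, metric = "euclidean") {
  filt <- variance_filter(pm, threshold = variance_threshold)
  scaled <- scale_features(filt, log_transform = log_transform)
  gap <- gap_statistic(scaled, k_max = k_max, B = B, seed = seed,
                       metric = metric)
  tree <- hierarchical_cluster(scaled, metric = metric)
  labels_by_k <- vapply(seq_len(k_max), function(k) cut_tree(tree, k),
                        integer(nrow(scaled$values)))
  colnames(labels_by_k) <- paste0("k", seq_len(k_max))
  structure(
    list(tree = tree,
         labels = setNames(labels_by_k[, gap$k_hat],
                           rownames(scaled$values)),
         labels_by_k = labels_by_k,
         k_hat = gap$k_hat,
         gap = gap$curve,
         filtered_peptides = colnames(filt$values),
         n_filtered = ncol(filt$values)),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: ", length(x$labels), " samples, ",
      x$n_filtered, " peptides after variance filter; k_hat = ",
      x$k_hat, " (sizes ",
      paste(table(x$labels), collapse = "/"), ")\n", sep = "")
  invisible(x)
}
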