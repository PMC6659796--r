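collapsed_pm <- function(m) {
  dimnames(m) <- list(sprintf("s%02d", seq_len(nrow(m))),
                      sprintf("p%02d", seq_len(ncol(m))))
  peptide_matrix(m, stage = "collapsed", level = "peptide")
}

test_that("variance filter retains by sd ratio", {
  # four peptides with sd 10, 2, 1.6, 0.1 -> ratios 1, .2, .16, .01
  set.seed(1)
  base <- scale(rnorm(40))[, 1]              # mean 0, sd 1 exactly
  m <- cbind(base * 10, base * 2, base * 1.6, base * 0.1)
  pm <- collapsed_pm(m - min(m))             # keep values non-negative
  filt <- variance_filter(pm, threshold = 0.15)
  expect_identical(colnames(filt$values), c("p01", "p02", "p03"))

  # the sd_max peptide survives any threshold <= 1; threshold 0 keeps all
  expect_true("p01" %in% colnames(variance_filter(pm, 1)$values))
  expect_equal(ncol(variance_filter(pm, 0)$values), 4)
  expect_error(variance_filter(pm, 1.2), "\\[0, 1\\]")
  expect_error(variance_filter(collapsed_pm(matrix(1, 5, 3)), 0.15),
               "constant")

  # retention is monotone non-increasing in the threshold
  set.seed(2)
  m2 <- collapsed_pm(matrix(rlnorm(200), 10, 20))
  kept <- vapply(c(0, 0.1, 0.15, 0.25, 0.5, 1),
                 function(t) ncol(variance_filter(m2, t)$values),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("feature scaling z-scores each peptide and is idempotent", {
  set.seed(3)
  pm <- collapsed_pm(matrix(rlnorm(300), 15, 20))
  sc <- scale_features(pm)
  expect_true(all(abs(colMeans(sc$values)) < 1e-12))
  expect_true(all(abs(apply(sc$values, 2, sd) - 1) < 1e-12))
  expect_true(sc$log_transformed && sc$scaled)

  # rank preservation without the log transform
  sc2 <- scale_features(pm, log_transform = FALSE)
  for (j in 1:5)
    expect_equal(order(sc2$values[, j]), order(pm$values[, j]))

  # applying the z-score again changes nothing (already mean 0, sd 1)
  again <- scale(sc$values)
  expect_equal(unname(again[, ]), unname(sc$values), tolerance = 1e-12)

  # zero-variance peptide is dropped with a warning
  m <- pm$values; m[, 1] <- 7
  expect_warning(s3 <- scale_features(collapsed_pm(m)), "zero-variance")
  expect_equal(ncol(s3$values), 19)
})

test_that("UPGMA matches hand computation and handles duplicates", {
  # collinear points at 0, 1, 10: first merge {0,1} at height 1, then the
  # pair cluster joins 10 at the average distance (9 + 10) / 2 = 9.5
  m <- matrix(c(0, 1, 10), ncol = 1)
  tree <- hierarchical_cluster(m)
  expect_equal(sort(tree$height), c(1, 9.5))
  expect_equal(sort(cutree(tree, 2)[1:2]), c(1, 1), ignore_attr = TRUE)

  # a duplicated sample merges first at height 0
  m2 <- matrix(c(5, 5, 9, 30), ncol = 1)
  tree2 <- hierarchical_cluster(m2)
  expect_equal(min(tree2$height), 0)
  expect_equal(unname(cutree(tree2, 3)[1]), unname(cutree(tree2, 3)[2]))
})

test_that("UPGMA agrees with the brute-force oracle on random instances", {
  set.seed(44)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 3), n, 3)
    tree <- hierarchical_cluster(m)
    oracle <- upgma_oracle(dist(m))
    expect_equal(sort(tree$height), sort(oracle$heights),
                 tolerance = 1e-10)
    for (k in seq_len(n - 1)) {
      got <- cutree(tree, k = k)
      want <- oracle$partitions[[n - k]]
      expect_true(same_partition(unname(got), want),
                  label = paste("partition at k =", k, "instance", i))
    }
  }
})

test_that("cut_tree labels are a valid partition in first-member order", {
  set.seed(5)
  m <- matrix(rnorm(24), 8, 3)
  rownames(m) <- sprintf("s%d", 1:8)
  tree <- hierarchical_cluster(m)
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 8))
  expect_equal(sort(unname(cut_tree(tree, 8))), 1:8)
  for (k in c(2, 3, 5)) {
    lab <- cut_tree(tree, k)
    expect_equal(sort(unique(lab)), seq_len(k))
    expect_equal(lab[[1]], 1L)               # first sample anchors cluster 1
  }
  expect_error(cut_tree(tree, 0), "out of range")
  expect_error(cut_tree(tree, 9), "out of range")
})

test_that("within-cluster dispersion matches its closed forms", {
  m <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)   # two points, distance 5
  expect_equal(within_dispersion(m, c(1, 1)), 25 / 2)
  expect_equal(within_dispersion(m, c(1, 2)), 0)   # singletons

  # equals the centroid sum of squares == pairwise formula on random data
  set.seed(6)
  for (i in 1:10) {
    x <- matrix(rnorm(60), 12, 5)
    lab <- sample(1:3, 12, replace = TRUE)
    w_pair <- 0
    for (g in unique(lab)) {
      xs <- x[lab == g, , drop = FALSE]
      d2 <- as.matrix(dist(xs))^2
      w_pair <- w_pair + sum(d2) / (2 * nrow(xs))
    }
    expect_equal(within_dispersion(x, lab), w_pair, tolerance = 1e-10)
  }
})

test_that("gap statistic selects k on reference geometries", {
  # two well-separated spherical blobs -> k_hat = 2 every time
  hits2 <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    m <- rbind(matrix(rnorm(20 * 4, 0), 20, 4),
               matrix(rnorm(20 * 4, 10), 20, 4))
    g <- gap_statistic(m, k_max = 5, B = 30, seed = s)
    hits2 <- hits2 + (g$k_hat == 2)
    expect_equal(nrow(g$curve), 5)
    expect_true(all(g$curve$s > 0))
  }
  expect_gte(hits2, 9)

  # a single spherical blob -> k_hat = 1 most of the time
  hits1 <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    m <- matrix(rnorm(30 * 4), 30, 4)
    hits1 <- hits1 + (gap_statistic(m, k_max = 5, B = 30,
                                    seed = s)$k_hat == 1)
  }
  expect_gte(hits1, 8)

  expect_error(gap_statistic(matrix(rnorm(4), 2, 2), k_max = 1),
               ">= 3 samples")
})

test_that("W_k is non-increasing in k along the dendrogram cut", {
  set.seed(7)
  m <- matrix(rnorm(40 * 6), 40, 6)
  tree <- hierarchical_cluster(m)
  w <- vapply(1:8, function(k) within_dispersion(m, cutree(tree, k)),
              numeric(1))
  expect_true(all(diff(w) <= 1e-10))
})

test_that("run_clustering recovers the planted two-cluster structure", {
  co <- generate_cohort(fast_cfg(seed = 21))
  prep <- run_preprocess(co$scan)
  grp <- prep$matrix$group
  aml <- names(grp)[grp == "AML"]
  pm <- peptide_matrix(prep$matrix$values[aml, , drop = FALSE],
                       stage = "collapsed", level = "peptide")
  res <- run_clustering(pm, B = 30, seed = 21)
  # at this reduced cohort size the gap statistic may subdivide further,
  # but the k = 2 cut must recover the planted partition
  lab2 <- res$labels_by_k[, 2]
  ari <- mclust::adjustedRandIndex(lab2, co$truth$cluster[aml])
  expect_gte(ari, 0.9)

  # a stricter variance filter never retains more peptides
  n25 <- ncol(variance_filter(pm, 0.25)$values)
  expect_lte(n25, res$n_filtered)

  # permuting samples permutes labels consistently
  perm <- sample(nrow(pm$values))
  pm_p <- peptide_matrix(pm$values[perm, , drop = FALSE],
                         stage = "collapsed", level = "peptide")
  res_p <- run_clustering(pm_p, B = 30, seed = 21)
  expect_equal(res_p$k_hat, res$k_hat)
  agree <- mclust::adjustedRandIndex(
    res_p$labels_by_k[rownames(res$labels_by_k), 2], lab2)
  expect_equal(agree, 1)
})
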