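test_that("background subtraction floors negatives and keeps shape", {
  scan <- make_scan(ns = 2, np = 3, seed = 1)
  scan$fg[1, 1, 1] <- 100; scan$bg[1, 1, 1] <- 30   # -> 70
  scan$fg[2, 1, 1] <- 10;  scan$bg[2, 1, 1] <- 30   # -> floored 0
  pm <- subtract_background(scan)
  expect_equal(pm$values["p01.r1", "s01"], 70)
  expect_equal(pm$values["p02.r1", "s01"], 0)
  expect_gte(attr(pm, "n_floored")[["s01"]], 1)
  expect_equal(dim(pm$values), c(3 * 3, 2))
  expect_true(all(pm$values >= 0))
})

test_that("spot matrix shape on a default cohort is (976*3) x n", {
  co <- generate_cohort(fast_cfg(seed = 2))
  pm <- subtract_background(co$scan)
  expect_equal(dim(pm$values), c(120 * 3, 24 + 2 + 2))
})

test_that("quantile normalization follows the rank-mean procedure", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  # original ranks decide the assignment
  m2 <- cbind(a = c(3, 1, 2), b = c(10, 30, 20))
  out2 <- quantile_normalize(m2)
  expect_equal(order(out2[, "a"]), order(m2[, "a"]))
  expect_equal(order(out2[, "b"]), order(m2[, "b"]))

  # ties receive the mean of the rank means they span
  m3 <- cbind(a = c(1, 1, 2), b = c(1, 2, 3))
  out3 <- quantile_normalize(m3)
  expect_equal(unname(out3[, "a"]), c(1.25, 1.25, 2.5))

  # identical columns are a fixed point
  m4 <- cbind(a = c(2, 7, 5), b = c(2, 7, 5))
  expect_equal(quantile_normalize(m4), m4)

  expect_error(quantile_normalize(cbind(a = 1:3)), "nothing to normalize")
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- matrix(rlnorm(600), 100, 6)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("normalized columns share one value multiset (property)", {
  set.seed(123)
  for (i in 1:25) {
    nr <- sample(5:60, 1); nc <- sample(2:8, 1)
    m <- matrix(rlnorm(nr * nc), nr, nc)
    out <- quantile_normalize(m)
    sorted <- apply(out, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  }
  # with ties, each tie group holds the mean of the rank means it spans
  m <- cbind(a = c(5, 5, 5, 9), b = c(1, 2, 3, 4))
  mu <- rowMeans(apply(m, 2, sort))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(rep(mean(mu[1:3]), 3), mu[4]))
})

test_that("replicate concordance behaves at its reference points", {
  # three identical replicate vectors -> r2 = 1
  scan <- make_scan(ns = 1, np = 50, seed = 3)
  scan$fg[, 2, ] <- scan$fg[, 1, ]; scan$fg[, 3, ] <- scan$fg[, 1, ]
  scan$bg[, 2, ] <- scan$bg[, 1, ]; scan$bg[, 3, ] <- scan$bg[, 1, ]
  pm <- subtract_background(scan)
  expect_equal(replicate_concordance(pm, "s01"), 1)

  # rep3 a random permutation of rep1: pairs (1,2) identical, (1,3) and
  # (2,3) near zero -> mean r2 about 1/3 (976 peptides)
  set.seed(99)
  np <- 976
  base <- rlnorm(np, log(200), 0.6)
  fg <- array(0, c(np, 3, 1)); bg <- array(1, c(np, 3, 1))
  fg[, 1, 1] <- base + 1; fg[, 2, 1] <- base + 1
  fg[, 3, 1] <- sample(base) + 1
  scan2 <- array_scan_set(fg, bg, sprintf("p%04d", 1:np), "s01", "AML")
  pm2 <- subtract_background(scan2)
  expect_equal(replicate_concordance(pm2, "s01"), 1 / 3, tolerance = 0.05)

  # zero-variance replicate contributes 0 to its pairs
  fgz <- array(rlnorm(60, log(100), 0.5), c(20, 3, 1))
  fgz[, 3, 1] <- 5
  scanz <- array_scan_set(fgz, array(1, c(20, 3, 1)),
                          sprintf("p%02d", 1:20), "s01", "AML")
  pmz <- subtract_background(scanz)
  r2 <- replicate_concordance(pmz, "s01")
  expect_lt(r2, 0.5)
})

test_that("QC filtering respects the threshold and reports every sample", {
  co <- generate_cohort(fast_cfg(seed = 6))
  norm <- quantile_normalize(subtract_background(co$scan))

  res <- qc_filter_samples(norm, threshold = 0.6)
  expect_setequal(res$qc$sample_id[!res$qc$included], co$truth$corrupt_ids)
  expect_equal(nrow(res$qc), length(co$scan$samples))
  expect_true(all(res$qc$included == (res$qc$r2 >= 0.6)))

  # threshold 0 excludes nothing; impossible threshold empties the cohort
  expect_true(all(qc_filter_samples(norm, threshold = 0)$qc$included))
  expect_error(qc_filter_samples(norm, threshold = 1.01), "empty cohort")

  # monotone: raising the threshold never re-admits a sample
  keep_low <- qc_filter_samples(norm, 0.3)$qc$included
  keep_high <- qc_filter_samples(norm, 0.8)$qc$included
  expect_true(all(keep_low | !keep_high))
})

test_that("median collapse is exact and replicate-order invariant", {
  scan <- make_scan(ns = 1, np = 2, seed = 5)
  scan$bg[] <- 0
  scan$fg[1, , 1] <- c(2, 9, 4)
  scan$fg[2, , 1] <- c(5, 5, 5)
  cm <- collapse_replicates(subtract_background(scan))
  expect_equal(unname(cm$values[1, ]), c(4, 5))
  expect_equal(cm$stage, "collapsed")
  expect_equal(dim(cm$values), c(1, 2))

  # permuting the replicate axis leaves the medians unchanged
  set.seed(10)
  for (i in 1:10) {
    scan2 <- make_scan(ns = 3, np = 6, seed = 20 + i)
    perm <- sample(3)
    scan3 <- scan2
    scan3$fg <- scan2$fg[, perm, , drop = FALSE]
    scan3$bg <- scan2$bg[, perm, , drop = FALSE]
    dimnames(scan3$fg)[[2]] <- dimnames(scan3$bg)[[2]] <- paste0("r", 1:3)
    c1 <- collapse_replicates(subtract_background(scan2))
    c2 <- collapse_replicates(subtract_background(scan3))
    expect_equal(c1$values, c2$values)
  }
})

test_that("run_preprocess composes the stages and is sample-order equivariant", {
  co <- generate_cohort(fast_cfg(seed = 12))
  prep <- run_preprocess(co$scan)
  expect_equal(dim(prep$matrix$values),
               c(24 + 2, 120))               # corrupt extras removed
  expect_equal(unname(prep$log["n_samples_excluded"]), 2)

  # two clean handmade samples are both retained
  scan <- make_scan(ns = 2, np = 40, seed = 31)
  prep2 <- run_preprocess(scan)
  expect_equal(nrow(prep2$matrix$values), 2)

  # permuting input sample order permutes outputs consistently
  perm <- c(2, 1)
  scan_p <- array_scan_set(scan$fg[, , perm, drop = FALSE],
                           scan$bg[, , perm, drop = FALSE],
                           scan$peptides, scan$samples[perm],
                           unname(scan$group[perm]))
  prep3 <- run_preprocess(scan_p)
  expect_equal(prep3$matrix$values[scan$samples, ],
               prep2$matrix$values[scan$samples, ])
})

test_that("stage transitions only move forward", {
  scan <- make_scan(ns = 2, np = 4)
  raw <- subtract_background(scan)
  norm <- quantile_normalize(raw)
  expect_error(quantile_normalize(norm), "invalid stage transition")
})
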