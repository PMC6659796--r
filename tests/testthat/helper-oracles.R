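# Independent oracles, deliberately brute-force and separate from the
# implementation paths they check.

# O(n^3) UPGMA: clusters as index sets, inter-cluster distance = mean of
# all pairwise original distances; merge the closest pair each step
# (lowest-index pair on ties).  Returns merge heights and the partition
# after each merge.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  labels <- seq_len(n)
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d - 1e-12) { best_d <- dij; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_d)
    part <- integer(n)
    for (g in seq_along(clusters)) part[clusters[[g]]] <- g
    partitions[[length(partitions) + 1]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(nx+ny, nx) labelings (tie-free inputs only).
mw_enumeration_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_stat(seq_len(nx))
  all_u <- apply(utils::combn(nx + ny, nx), 2, u_stat)
  p <- 2 * min(mean(all_u <= obs), mean(all_u >= obs))
  min(1, p)
}

# Numeric root of the piecewise-linear interpolant of the viability curve
# at 50%, found by dense bisection on the bracketing segment.
lc50_root_oracle <- function(conc, viab) {
  f <- stats::approxfun(conc, viab)
  i <- which(viab < 50)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  stats::uniroot(function(c) f(c) - 50, c(conc[i - 1], conc[i]),
                 tol = 1e-14)$root
}

# Partition equality up to label renaming.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
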