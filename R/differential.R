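# Per-peptide three-group comparison (cluster-1, cluster-2, NBM) with
# Bonferroni correction and fold changes.  Testing runs on collapsed
# (pre-scaling) normalized intensities, since fold differences are
# reported in natural intensity space.

#' Per-peptide one-way ANOVA across groups
#'
#' Standard fixed-effects one-way ANOVA per peptide
#' (`F = MS_between / MS_within`, p from `F(g-1, N-g)`), with Bonferroni
#' adjustment over the tested peptides and fold changes between all group
#' pairs.  By default the test statistics are computed on `log2(1 + x)`
#' intensities, where the intensity noise is close to normal and the
#' Bonferroni family-wise error holds its nominal level; group means and
#' folds are always reported in natural intensity space.  Peptides with
#' zero between- and within-group variance are degenerate; they are
#' reported with `F = 0`, `p = 1` and flagged.  Pairwise two-sample
#' t-tests (pooled variance) between all group pairs are reported
#' alongside the omnibus test, likewise Bonferroni-adjusted.
#'
#' @param pm a collapsed `peptide_matrix` (samples x peptides) or bare
#'   matrix.
#' @param groups factor (or coercible) of group membership, one entry per
#'   sample, with `>= 2` levels each holding `>= 2` samples.
#' @param n_tested number of tests used for the Bonferroni adjustment;
#'   defaults to the number of peptides in `pm` (i.e. the
#'   variance-filtered set when a filtered matrix is supplied).
#' @param alpha significance level for the `significant` flag (applied to
#'   the adjusted omnibus p; default 0.05).
#' @param log_transform compute F and t statistics on `log2(1 + x)`
#'   (default `TRUE`); set `FALSE` to test on the natural intensity
#'   scale.
#' @return A data.frame of class `differential_table`: per peptide the
#'   group means, `F`, `df1`, `df2`, `p`, `p_bonferroni`, pairwise
#'   adjusted p-values, all pairwise folds (ratios of natural-scale group
#'   means), `significant` and `degenerate` flags.
#' @export
anova_per_peptide <- function(pm, groups, n_tested = NULL, alpha = 0.05,
                              log_transform = TRUE) {
  m <- if (is.matrix(pm)) pm else pm$values
  groups <- factor(groups)
  if (length(groups) != nrow(m))
    stop("groups must have one entry per sample")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2))
    stop("group with < 2 samples: ", names(sizes)[sizes < 2][1])
  if (is.null(n_tested)) n_tested <- ncol(m)
  g <- nlevels(groups); n <- nrow(m)
  idx <- split(seq_len(n), groups)

  if (log_transform && min(m) < 0)
    stop("log-scale testing needs non-negative intensities")
  mt <- if (log_transform) log2(1 + m) else m   # test scale

  grp_means <- function(x)
    vapply(idx, function(i) colMeans(x[i, , drop = FALSE]),
           numeric(ncol(x)))
  means <- grp_means(m)                         # natural scale, reported
  means_t <- grp_means(mt)
  if (ncol(m) == 1) {
    means <- matrix(means, 1, dimnames = list(NULL, names(idx)))
    means_t <- matrix(means_t, 1, dimnames = list(NULL, names(idx)))
  }
  grand <- colMeans(mt)
  ssb <- as.numeric(means_t^2 %*% lengths(idx)) - n * grand^2
  ssw <- colSums(mt^2) - as.numeric(means_t^2 %*% lengths(idx))
  ssw <- pmax(ssw, 0); ssb <- pmax(ssb, 0)
  df1 <- g - 1; df2 <- n - g
  msb <- ssb / df1; msw <- ssw / df2
  degenerate <- msw <= 0 & msb <= .Machine$double.eps
  f <- ifelse(msw > 0, msb / msw, ifelse(degenerate, 0, Inf))
  p <- ifelse(degenerate, 1, pf(f, df1, df2, lower.tail = FALSE))

  out <- data.frame(peptide = colnames(m) %||% seq_len(ncol(m)),
                    stringsAsFactors = FALSE)
  for (lv in levels(groups)) out[[paste0("mean_", lv)]] <- means[, lv]
  out$F <- f; out$df1 <- df1; out$df2 <- df2; out$p <- p
  out$p_bonferroni <- bonferroni_adjust(p, n_tested)

  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  for (pr in pairs) {
    i1 <- idx[[pr[1]]]; i2 <- idx[[pr[2]]]
    tt <- .pooled_t(mt[i1, , drop = FALSE], mt[i2, , drop = FALSE])
    out[[paste0("p_", pr[1], "_vs_", pr[2])]] <-
      bonferroni_adjust(tt, n_tested)
    out[[paste0("fold_", pr[2], "_vs_", pr[1])]] <-
      .fold_vec(means[, pr[2]], means[, pr[1]])
  }
  out$significant <- out$p_bonferroni < alpha
  out$degenerate <- degenerate
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorized pooled-variance two-sample t-test p-values per column
.pooled_t <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- 2 * stats::pt(abs(t), n1 + n2 - 2, lower.tail = FALSE)
  ifelse(se > 0, p, 1)
}

.fold_vec <- function(num, den) ifelse(den > 0, num / den, Inf)

#' Bonferroni correction
#'
#' `p_adj = min(1, p * n_tested)`.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @param n_tested number of tests in the family; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, n_tested = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * n_tested)
}

#' Fold changes between two groups
#'
#' Per-peptide ratio of group means, `mean(groupA) / mean(groupB)`.
#' A zero denominator yields `Inf` with a flag.
#'
#' @param pm collapsed `peptide_matrix` or bare matrix (samples x
#'   peptides).
#' @param samplesA,samplesB sample identifiers (or logical/integer row
#'   indices) of the two groups; both must be non-empty.
#' @param geometric use geometric instead of arithmetic means.
#' @return data.frame with `peptide`, `fold`, `zero_denominator`.
#' @export
fold_changes <- function(pm, samplesA, samplesB, geometric = FALSE) {
  m <- if (is.matrix(pm)) pm else pm$values
  a <- m[samplesA, , drop = FALSE]
  b <- m[samplesB, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty group")
  avg <- if (geometric) function(x) exp(colMeans(log(pmax(x, 1e-12))))
         else colMeans
  ma <- avg(a); mb <- avg(b)
  data.frame(peptide = colnames(m) %||% seq_len(ncol(m)),
             fold = .fold_vec(ma, mb),
             zero_denominator = mb <= 0,
             stringsAsFactors = FALSE)
}
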