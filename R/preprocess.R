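# Spot-level preprocessing: background subtraction, quantile
# normalization, triplicate-concordance QC and median collapse, in that
# order.

#' Subtract background from spot intensities
#'
#' Computes `max(fg - bg, 0)` per spot.  Spots whose foreground falls
#' below the background are floored at zero (the kinase activity readout
#' is non-negative) and counted in the attached log.
#'
#' @param scan an [array_scan_set()].
#' @return A spot-level [peptide_matrix()] (stage `raw`): one row per
#'   peptide x replicate, one column per sample, with attribute
#'   `n_floored` giving the per-sample count of floored spots.
#' @export
subtract_background <- function(scan) {
  stopifnot(inherits(scan, "array_scan_set"))
  np <- length(scan$peptides)
  diffs <- scan$fg - scan$bg
  floored <- diffs < 0
  diffs[floored] <- 0
  # flatten (peptide, replicate, sample) -> (spot row, sample)
  m <- matrix(diffs, nrow = np * 3L, ncol = length(scan$samples))
  pep_rows <- rep(scan$peptides, times = 3L)
  rep_rows <- rep(1:3, each = np)
  rownames(m) <- paste0(pep_rows, ".r", rep_rows)
  colnames(m) <- scan$samples
  pm <- peptide_matrix(m, stage = "raw", level = "spot",
                       peptide = pep_rows, replicate = rep_rows,
                       group = scan$group)
  attr(pm, "n_floored") <- setNames(colSums(matrix(floored, nrow = np * 3L)),
                                    scan$samples)
  pm
}

# Quantile-normalize one column given the vector of rank means `mu`.
# Ties within the column receive the mean of the rank means they span.
.qn_column <- function(x, mu) {
  v <- mu[rank(x, ties.method = "first")]
  if (anyDuplicated(x)) v <- ave(v, factor(x), FUN = mean)
  v
}

#' Quantile normalization across samples
#'
#' The classic rank/mean procedure: each sample column is sorted, values
#' are averaged across samples at each rank, and the rank means are
#' assigned back by each column's original ranks.  Ties within a column
#' receive the mean of the rank means they span.  Afterwards every column
#' holds the same multiset of values.
#'
#' @param pm a spot-level `peptide_matrix` (stage `raw`), or a bare
#'   numeric matrix (columns = samples).
#' @return Object of the same kind at stage `normalized`.
#' @export
quantile_normalize <- function(pm) {
  bare <- is.matrix(pm)
  m <- if (bare) pm else pm$values
  if (ncol(m) < 2) stop("nothing to normalize across: need >= 2 samples")
  mu <- rowMeans(apply(m, 2, sort, method = "radix"))
  out <- apply(m, 2, .qn_column, mu = mu)
  dimnames(out) <- dimnames(m)
  if (bare) return(out)
  .pm_advance(pm, "normalized")
  res <- peptide_matrix(out, stage = "normalized", level = pm$level,
                        peptide = pm$peptide, replicate = pm$replicate,
                        group = pm$group)
  attr(res, "n_floored") <- attr(pm, "n_floored")
  res
}

#' Triplicate concordance of one sample
#'
#' Splits a sample's spot column into its three replicate vectors (one
#' value per peptide each) and returns the mean of the three pairwise
#' squared Pearson correlations (replicates 1-2, 1-3, 2-3).  A pair
#' involving a zero-variance replicate vector contributes 0.  With
#' `method = "min"` the minimum pairwise r-squared is returned instead.
#'
#' @param pm a spot-level `peptide_matrix`.
#' @param sample sample identifier.
#' @param method `"mean"` (default) or `"min"` aggregation over the three
#'   replicate pairs.
#' @return r-squared in `[0, 1]`.
#' @export
replicate_concordance <- function(pm, sample, method = c("mean", "min")) {
  method <- match.arg(method)
  stopifnot(inherits(pm, "peptide_matrix"), pm$level == "spot")
  if (!sample %in% colnames(pm$values)) stop("unknown sample ", sample)
  x <- pm$values[, sample]
  reps <- lapply(1:3, function(r) x[pm$replicate == r])
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  r2 <- vapply(pairs, function(p) {
    a <- reps[[p[1]]]; b <- reps[[p[2]]]
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)^2
  }, numeric(1))
  if (method == "mean") mean(r2) else min(r2)
}

#' Filter samples on triplicate concordance
#'
#' Removes samples whose triplicate concordance r-squared falls strictly
#' below `threshold` (default 0.6) and reports every sample's value and
#' decision.
#'
#' @param pm a spot-level `peptide_matrix`.
#' @param threshold exclusion threshold on r-squared (samples with
#'   `r2 < threshold` are excluded).
#' @param method concordance aggregation, see [replicate_concordance()].
#' @return A list with `matrix` (the filtered `peptide_matrix`) and `qc`,
#'   a data.frame of class `qc_report` with columns `sample_id`, `r2`,
#'   `included`, `threshold`.
#' @export
qc_filter_samples <- function(pm, threshold = 0.6,
                              method = c("mean", "min")) {
  method <- match.arg(method)
  samples <- colnames(pm$values)
  r2 <- vapply(samples, replicate_concordance, numeric(1), pm = pm,
               method = method)
  keep <- r2 >= threshold
  if (!any(keep)) stop("empty cohort after QC: all samples excluded")
  qc <- data.frame(sample_id = samples, r2 = unname(r2),
                   included = unname(keep), threshold = threshold,
                   stringsAsFactors = FALSE)
  class(qc) <- c("qc_report", "data.frame")
  res <- peptide_matrix(pm$values[, keep, drop = FALSE], stage = pm$stage,
                        level = "spot", peptide = pm$peptide,
                        replicate = pm$replicate,
                        group = pm$group[samples[keep]])
  list(matrix = res, qc = qc)
}

#' Collapse triplicate spots to per-peptide medians
#'
#' For each (sample, peptide) the median of the three replicate values is
#' taken.  The result is oriented samples x peptides, the layout used by
#' all downstream stages.
#'
#' @param pm a spot-level `peptide_matrix`.
#' @return A `peptide_matrix` at stage `collapsed` (samples x peptides).
#' @export
collapse_replicates <- function(pm) {
  stopifnot(inherits(pm, "peptide_matrix"), pm$level == "spot")
  .pm_advance(pm, "collapsed")
  peptides <- unique(pm$peptide)
  np <- length(peptides)
  stopifnot(nrow(pm$values) == np * 3L)
  # rows are ordered peptide-major within replicate blocks
  a <- array(pm$values[order(pm$replicate, match(pm$peptide, peptides)), ,
                       drop = FALSE],
             dim = c(np, 3L, ncol(pm$values)))
  x1 <- a[, 1, ]; x2 <- a[, 2, ]; x3 <- a[, 3, ]
  med <- x1 + x2 + x3 - pmax(x1, x2, x3) - pmin(x1, x2, x3)  # median of 3
  out <- t(med)
  dimnames(out) <- list(colnames(pm$values), peptides)
  peptide_matrix(out, stage = "collapsed", level = "peptide",
                 group = pm$group)
}

#' Run the full preprocessing chain
#'
#' Composes the four preprocessing steps in order: background subtraction,
#' quantile normalization, concordance QC, median collapse.
#'
#' @param scan an [array_scan_set()].
#' @param r2_threshold QC exclusion threshold (default 0.6).
#' @param concordance_method see [replicate_concordance()].
#' @return A list with `matrix` (collapsed samples x peptides
#'   `peptide_matrix`), `normalized` (the spot-level normalized matrix),
#'   `qc` (the QC report) and `log` (named counts at each stage).
#' @export
run_preprocess <- function(scan, r2_threshold = 0.6,
                           concordance_method = c("mean", "min")) {
  concordance_method <- match.arg(concordance_method)
  raw <- subtract_background(scan)
  norm <- quantile_normalize(raw)
  qcres <- qc_filter_samples(norm, threshold = r2_threshold,
                             method = concordance_method)
  collapsed <- collapse_replicates(qcres$matrix)
  list(matrix = collapsed,
       normalized = norm,
       qc = qcres$qc,
       log = c(n_samples_in = length(scan$samples),
               n_spots_floored = sum(attr(raw, "n_floored")),
               n_samples_excluded = sum(!qcres$qc$included),
               n_samples_out = nrow(collapsed$values)))
}
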