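# LC50 estimation by bracketing linear interpolation on the measured
# viability curve, and between-cluster comparison of LC50 distributions.

#' LC50 by bracketing interpolation
#'
#' Scans the ascending concentration series for the first adjacent pair
#' where viability crosses from above 50% to below 50% and linearly
#' interpolates:
#' `LC50 = (V_above - 50) / (V_above - V_below) * (c_below - c_above) + c_above`,
#' where `V_above` is the viability just above 50% at concentration
#' `c_above` and `V_below` just below at the next concentration
#' `c_below`.  Interpolation is on the linear concentration scale.
#' A viability of exactly 50% at a measured concentration returns that
#' concentration (`exact_50`).  Curves that never dip below 50% are
#' censored above the maximum concentration; curves already below 50% at
#' the lowest concentration are censored below the minimum.  When a noisy
#' curve crosses 50% more than once, the first (lowest-concentration)
#' crossing is used.
#'
#' @param concentration ascending positive concentrations (length >= 2).
#' @param viability_pct viability percentages, same length.
#' @return A list of class `lc50_result`: `lc50`, `status` (one of
#'   `interpolated`, `exact_50`, `censored_above_max`,
#'   `censored_below_min`) and `bracket` (the concentration pair used, or
#'   `NULL`).  For censored curves `lc50` is the boundary concentration.
#' @export
compute_lc50 <- function(concentration, viability_pct) {
  n <- length(concentration)
  if (n < 2) stop("need at least 2 concentrations")
  if (length(viability_pct) != n)
    stop("concentration and viability lengths differ")
  if (any(diff(concentration) <= 0) || any(concentration <= 0))
    stop("concentrations must be strictly increasing and positive")
  res <- function(lc50, status, bracket = NULL)
    structure(list(lc50 = lc50, status = status, bracket = bracket),
              class = "lc50_result")
  for (i in seq_len(n)) {
    if (viability_pct[i] == 50)
      return(res(concentration[i], "exact_50"))
    if (viability_pct[i] < 50) {
      if (i == 1) return(res(concentration[1], "censored_below_min"))
      va <- viability_pct[i - 1]; vb <- viability_pct[i]
      ca <- concentration[i - 1]; cb <- concentration[i]
      lc <- (va - 50) / (va - vb) * (cb - ca) + ca
      return(res(lc, "interpolated", bracket = c(ca, cb)))
    }
  }
  res(concentration[n], "censored_above_max")
}

#' @export
print.lc50_result <- function(x, ...) {
  cat("LC50 = ", format(x$lc50, digits = 4), " (", x$status, ")\n",
      sep = "")
  invisible(x)
}

#' LC50 table for a dose-response set
#'
#' Applies [compute_lc50()] to every (sample, drug) record.
#'
#' @param dr a `dose_response_set`.
#' @return data.frame with `sample`, `drug`, `lc50`, `status`.
#' @export
lc50_table <- function(dr) {
  df <- as.data.frame(dr)
  keys <- unique(df[, c("sample", "drug")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    rec <- df[df$sample == keys$sample[i] & df$drug == keys$drug[i], ]
    r <- compute_lc50(rec$concentration, rec$viability_pct)
    data.frame(sample = keys$sample[i], drug = keys$drug[i],
               lc50 = r$lc50, status = r$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare LC50 distributions between clusters
#'
#' Per drug: median LC50 per cluster, the fold difference
#' `median(cluster-2) / median(cluster-1)`, and a two-sided Mann-Whitney
#' U test on the LC50 values.  Censored values (curves never crossing
#' 50%) enter the test as their boundary-concentration values
#' (max-concentration ties) but are excluded from the medians; both
#' behaviours are switchable.
#'
#' @param lc50 data.frame as returned by [lc50_table()].
#' @param labels named cluster labels (1/2) covering the samples.
#' @param censored_in_test include censored values (at their boundary
#'   concentration) in the Mann-Whitney test (default `TRUE`).
#' @param censored_in_median include them in the medians (default
#'   `FALSE`).
#' @return data.frame, one row per drug: `drug`, `n1`, `n2`,
#'   `median_cluster1`, `median_cluster2`, `fold`, `U`, `p`,
#'   `n_censored`.
#' @export
compare_lc50 <- function(lc50, labels, censored_in_test = TRUE,
                         censored_in_median = FALSE) {
  df <- as.data.frame(lc50)
  df$cluster <- as.integer(labels[df$sample])
  if (anyNA(df$cluster)) stop("samples without cluster labels: ",
                              paste(unique(df$sample[is.na(df$cluster)]),
                                    collapse = ", "))
  evaluable <- df$status %in% c("interpolated", "exact_50")
  rows <- lapply(unique(df$drug), function(dg) {
    d <- df[df$drug == dg, ]
    ev <- d$status %in% c("interpolated", "exact_50")
    med_set <- if (censored_in_median) d else d[ev, ]
    test_set <- if (censored_in_test) d else d[ev, ]
    for (k in 1:2)
      if (sum(med_set$cluster == k) == 0 || sum(test_set$cluster == k) == 0)
        stop("no evaluable LC50 in cluster ", k, " for drug ", dg)
    m1 <- median(med_set$lc50[med_set$cluster == 1])
    m2 <- median(med_set$lc50[med_set$cluster == 2])
    tr <- mann_whitney_u(test_set$lc50[test_set$cluster == 1],
                         test_set$lc50[test_set$cluster == 2])
    data.frame(drug = dg,
               n1 = sum(test_set$cluster == 1),
               n2 = sum(test_set$cluster == 2),
               median_cluster1 = m1, median_cluster2 = m2,
               fold = m2 / m1,
               U = tr$statistic, p = tr$p_two_sided,
               n_censored = sum(!ev),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
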