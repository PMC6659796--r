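# Cluster-versus-outcome statistics: Kaplan-Meier / log-rank overall
# survival, cumulative incidence of relapse with Pearson chi-square, and
# Mann-Whitney / chi-square comparisons of patient characteristics.

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival curve starting at `S(0) = 1`.
#'
#' @param times event/censoring times, `>= 0`.
#' @param events binary event indicators (1 = event, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`
#'   (one row per distinct event/censoring time, preceded by time 0).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be binary")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(times), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Log-rank test between two groups
#'
#' Standard log-rank chi-square statistic (df = 1), two-sided p.
#'
#' @param times event/censoring times.
#' @param events binary event indicators.
#' @param group two-level group membership.
#' @return A [test_result()].
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("need exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  test_result(sd$chisq, p, "log-rank test", df = 1)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1), as reported
#' by SPSS's "Pearson Chi-Square" line; Yates' correction is available
#' via `correct = TRUE`.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correct apply Yates' continuity correction (default `FALSE`).
#' @return A [test_result()].
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  test_result(unname(ct$statistic), unname(ct$p.value),
              if (correct) "Pearson chi-square (Yates)"
              else "Pearson chi-square", df = 1)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test.  The p-value is exact
#' by full enumeration when `length(x) + length(y) <= 12` and there are
#' no ties, otherwise the normal approximation with tie and continuity
#' correction is used.  The reported statistic is U for the first sample.
#'
#' @param x,y numeric samples, both non-empty.
#' @return A [test_result()].
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE))
  test_result(unname(wt$statistic), wt$p.value,
              paste0("Mann-Whitney U (",
                     if (exact) "exact" else "normal approximation", ")"))
}

#' Cumulative incidence of relapse by cluster
#'
#' Relapse frequency during follow-up per cluster: the raw proportion
#' (relapses / cluster size), a Pearson chi-square test on the 2x2
#' relapse x cluster counts, and a per-cluster cumulative-incidence curve
#' computed as `1 - KM` of time-to-relapse.
#'
#' @param clinical a `clinical_table`.
#' @param labels named cluster labels (values 1/2) for the samples to
#'   include; samples with a missing relapse flag are excluded (and
#'   reported in `n_excluded`).
#' @return A list: `proportions` (data.frame cluster, n, relapses,
#'   proportion), `test` ([test_result()]), `curves` (list of 1-KM
#'   data.frames per cluster), `n_excluded`.
#' @export
cumulative_incidence_relapse <- function(clinical, labels) {
  df <- as.data.frame(clinical)
  df <- df[match(names(labels), df$sample_id), ]
  df$cluster <- as.integer(labels)
  drop <- is.na(df$relapse)
  n_excluded <- sum(drop)
  df <- df[!drop, ]
  counts <- table(factor(df$cluster, levels = sort(unique(df$cluster))),
                  factor(df$relapse, levels = c(1, 0)))
  props <- data.frame(
    cluster = as.integer(rownames(counts)),
    n = as.integer(rowSums(counts)),
    relapses = as.integer(counts[, "1"]),
    proportion = as.numeric(counts[, "1"] / rowSums(counts)))
  test <- if (any(colSums(counts) == 0))
    # no relapses (or no non-relapses) anywhere: no difference to test
    test_result(0, 1, "Pearson chi-square (degenerate margin)", df = 1)
  else chi_square_2x2(as.matrix(counts))
  curves <- lapply(split(df, df$cluster), function(d) {
    km <- km_estimate(d$time_to_relapse, d$relapse)
    km$incidence <- 1 - km$survival
    km[, c("time", "n_risk", "n_event", "incidence")]
  })
  list(proportions = props, test = test, curves = curves,
       n_excluded = n_excluded)
}

#' Compare patient characteristics between two clusters
#'
#' Mann-Whitney U for continuous variables (age, blast %, WBC, RBC, PLT)
#' and Pearson chi-square for categorical ones (sex, relapse, death,
#' complete response), one row per variable.  Unknowns are excluded per
#' variable; unknown sex in particular is excluded from the sex
#' contingency test, never imputed.
#'
#' @param clinical a `clinical_table`.
#' @param labels named cluster labels (1/2).
#' @return data.frame with `variable`, `type`, `statistic`, `p`,
#'   `method`, `n_used`.
#' @export
characteristics_table <- function(clinical, labels) {
  df <- as.data.frame(clinical)
  df <- df[match(names(labels), df$sample_id), ]
  cl <- as.integer(labels)
  cont <- c("age", "blast_pct", "wbc", "rbc", "plt")
  cate <- c("sex", "relapse", "death", "complete_response")
  rows <- list()
  for (v in cont) {
    ok <- !is.na(df[[v]])
    tr <- mann_whitney_u(df[[v]][ok & cl == 1], df[[v]][ok & cl == 2])
    rows[[v]] <- data.frame(variable = v, type = "continuous",
                            statistic = tr$statistic, p = tr$p_two_sided,
                            method = tr$method, n_used = sum(ok))
  }
  for (v in cate) {
    x <- df[[v]]
    ok <- !is.na(x) & x != "unknown"
    tab <- table(factor(cl[ok]), factor(x[ok]))
    if (all(dim(tab) == c(2, 2))) {
      tr <- chi_square_2x2(tab)
      rows[[v]] <- data.frame(variable = v, type = "categorical",
                              statistic = tr$statistic,
                              p = tr$p_two_sided, method = tr$method,
                              n_used = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
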