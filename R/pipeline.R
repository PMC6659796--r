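# Orchestration: one call from (simulated or supplied) inputs to the full
# set of pipeline products and a run report.

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (unless inputs are supplied),
#' preprocessing (background subtraction, quantile normalization,
#' concordance QC, median collapse), clustering of the AML samples
#' (variance filter, scaling, gap statistic), per-peptide differential
#' activation of cluster-1 / cluster-2 / NBM, outcome statistics
#' (characteristics, relapse incidence, overall survival) and LC50-based
#' chemosensitivity comparison.  With identical `config` (including its
#' seed) the report and all written artifacts are byte-identical across
#' runs.
#'
#' @param config a [sim_config()]; its `seed` drives simulation and the
#'   gap-statistic reference draws.
#' @param inputs optional list with `scan`, `clinical`, `dose_response`
#'   and optionally `truth`; when supplied, simulation is skipped.
#' @param out_dir optional output directory for [write_outputs()].
#' @param r2_threshold concordance QC threshold (default 0.6).
#' @param variance_threshold `sd/sd_max` peptide filter (default 0.15).
#' @param alpha significance level (default 0.05).
#' @param k_max,B gap-statistic search range and reference count.
#' @param simulate_only generate and return inputs (and write them to
#'   `out_dir` if given) without running the analysis.
#' @return A list of class `pipeline_report`; see the `summary` element
#'   for headline numbers (QC exclusions, filtered peptide count, chosen
#'   k, cluster sizes, adjusted Rand index versus truth when available,
#'   counts of significant peptides, outcome tests, per-drug LC50 folds).
#' @export
run_all <- function(config = sim_config(), inputs = NULL, out_dir = NULL,
                    r2_threshold = 0.6, variance_threshold = 0.15,
                    alpha = 0.05, k_max = 6, B = 100,
                    simulate_only = FALSE) {
  cfg <- validate_sim_config(config)
  truth <- NULL
  if (is.null(inputs)) {
    cohort <- generate_cohort(cfg)
    truth <- cohort$truth
    dr <- generate_dose_response(cfg, truth)
    scan <- cohort$scan
    clinical <- cohort$clinical
  } else {
    scan <- inputs$scan
    clinical <- inputs$clinical
    dr <- inputs$dose_response
    truth <- inputs$truth
  }
  if (simulate_only) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_spot_table(scan, file.path(out_dir, "spot_table.tsv"))
      write_clinical_table(clinical, file.path(out_dir, "clinical.csv"))
      write_dose_response(dr, file.path(out_dir, "dose_response.csv"))
      if (!is.null(truth))
        export_truth(truth, file.path(out_dir, "truth.json"))
    }
    return(list(scan = scan, clinical = clinical, dose_response = dr,
                truth = truth))
  }

  prep <- run_preprocess(scan, r2_threshold = r2_threshold)
  grp <- prep$matrix$group
  aml_ids <- names(grp)[grp == "AML"]
  nbm_ids <- names(grp)[grp == "NBM"]
  aml_pm <- peptide_matrix(
    prep$matrix$values[aml_ids, , drop = FALSE], stage = "collapsed",
    level = "peptide", group = grp[aml_ids])

  clus <- run_clustering(aml_pm, variance_threshold = variance_threshold,
                         k_max = k_max, B = B, seed = cfg$seed)

  # the downstream contrasts are defined for the two main clusters, so
  # they use the k = 2 cut; k_hat and the gap curve are reported alongside
  labels <- clus$labels_by_k[aml_ids, 2]

  # differential activation on collapsed intensities of the filtered set
  diff_tab <- NULL
  if (length(nbm_ids) >= 2 && all(table(labels) >= 2)) {
    use <- c(aml_ids, nbm_ids)
    groups <- c(paste0("cluster", labels[aml_ids]),
                rep("NBM", length(nbm_ids)))
    dm <- prep$matrix$values[use, clus$filtered_peptides, drop = FALSE]
    diff_tab <- anova_per_peptide(dm, groups, n_tested = clus$n_filtered,
                                  alpha = alpha)
  }
  cir <- cumulative_incidence_relapse(clinical, labels)
  clin <- as.data.frame(clinical)
  clin <- clin[match(names(labels), clin$sample_id), ]
  os <- logrank_test(clin$followup_time, clin$death, labels)
  chars <- characteristics_table(clinical, labels)

  lc <- lc50_table(dr)
  chemo <- tryCatch(compare_lc50(lc, labels),
                    error = function(e) NULL)

  ari <- if (!is.null(truth))
    mclust::adjustedRandIndex(labels, truth$cluster[names(labels)])
  else NULL

  summary <- list(
    n_samples_in = length(scan$samples),
    n_qc_excluded = sum(!prep$qc$included),
    qc_excluded_ids = prep$qc$sample_id[!prep$qc$included],
    n_peptides = length(scan$peptides),
    n_peptides_filtered = clus$n_filtered,
    k_hat = clus$k_hat,
    cluster_sizes = as.integer(table(labels)),
    ari_vs_truth = ari,
    n_significant_peptides =
      if (!is.null(diff_tab)) sum(diff_tab$significant) else NA,
    relapse = list(
      proportions = cir$proportions,
      chisq = cir$test$statistic, p = cir$test$p_two_sided),
    overall_survival = list(chisq = os$statistic, p = os$p_two_sided),
    lc50 = chemo)
  outcome_tests <- list(
    relapse_chi_square = unclass(cir$test),
    overall_survival_logrank = unclass(os),
    characteristics = chars)

  results <- list(
    normalized = prep$normalized, qc = prep$qc, labels = labels,
    gap = clus$gap, differential = diff_tab,
    outcome_tests = outcome_tests, lc50 = lc,
    config = .config_echo(cfg, r2_threshold, variance_threshold, alpha,
                          k_max, B),
    summary = summary)
  manifest <- if (!is.null(out_dir)) write_outputs(results, out_dir)
              else character(0)
  structure(
    list(summary = summary, qc = prep$qc, clustering = clus,
         differential = diff_tab, cir = cir, overall_survival = os,
         characteristics = chars, lc50 = lc, lc50_comparison = chemo,
         truth = truth, labels = labels, manifest = manifest,
         config = results$config),
    class = "pipeline_report")
}

.config_echo <- function(cfg, r2_threshold, variance_threshold, alpha,
                         k_max, B) {
  c(unclass(cfg)[setdiff(names(cfg), "conc_grids")],
    list(conc_grids = cfg$conc_grids,
         r2_threshold = r2_threshold,
         variance_threshold = variance_threshold,
         alpha = alpha, k_max = k_max, B = B))
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("pipeline_report\n",
      "  samples: ", s$n_samples_in, " in, ", s$n_qc_excluded,
      " excluded by QC\n",
      "  peptides: ", s$n_peptides, " -> ", s$n_peptides_filtered,
      " after variance filter\n",
      "  clusters: k_hat = ", s$k_hat, " (sizes ",
      paste(s$cluster_sizes, collapse = "/"), ")",
      if (!is.null(s$ari_vs_truth))
        paste0(", ARI vs truth = ", format(s$ari_vs_truth, digits = 3)),
      "\n  relapse: ",
      paste(sprintf("%.1f%%", 100 * s$relapse$proportions$proportion),
            collapse = " vs "),
      " (chi-square p = ", format(s$relapse$p, digits = 2), ")\n",
      sep = "")
  invisible(x)
}
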