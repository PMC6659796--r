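# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: lognormal spot
# intensities over a background floor, triplicate replicate noise, a binary
# two-cluster activation pattern on a subset of peptides, a few planted
# low-concordance samples, CD34+ normal-bone-marrow controls drawn from the
# baseline, relapse probabilities differing by cluster, censored follow-up,
# and sigmoid viability curves whose true LC50 distributions differ by
# cluster.  Ground truth is returned alongside the data so every pipeline
# stage can be validated.

#' Simulation configuration
#'
#' Returns the default configuration of the synthetic cohort generator;
#' any field can be overridden by name.  Defaults mirror the study design
#' the pipeline targets: 96 evaluable AML samples plus 4 low-concordance
#' ones (100 arrays total), 4 CD34+ NBM controls, 976 peptides of which
#' 192 carry a binary two-cluster pattern, cluster sizes 39/57, relapse
#' probabilities 0.26/0.47, and per-drug true-LC50 fold differences of
#' 31 (mitoxantrone), 31 (etoposide) and 104 (amsacrine) between clusters.
#'
#' @param ... named overrides of any default field, e.g.
#'   `sim_config(n_aml = 24, effect = 0)`.
#' @return A list of class `sim_config`.
#' @details Noise fields (all on the natural-log scale unless noted):
#' `act_meanlog`/`act_sdlog` - per-peptide baseline activity;
#' `bio_sdlog` - per (sample, peptide) biological noise;
#' `rep_sdlog` - replicate spot noise; `corrupt_rep_mult` - multiplier
#' applied to replicate noise for planted corrupt samples (default 6,
#' large enough that expected triplicate r-squared falls below 0.6);
#' `effect` - the log-scale shift between clusters on informative
#' peptides; `bg_meanlog`/`bg_sdlog` - additive background;
#' `bg_measure_sdlog` - noise of the reported background measurement.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_aml = 96L, n_corrupt_extra = 4L, n_nbm = 4L,
    n_peptides = 976L, n_informative = 192L,
    cluster_sizes = c(39L, 57L),
    relapse_prob = c(0.26, 0.47),
    # array noise model (log scale)
    act_meanlog = log(500), act_sdlog = 0.5,
    bio_sdlog = 0.25, rep_sdlog = 0.07, corrupt_rep_mult = 6,
    effect = 1.5,
    bg_meanlog = log(50), bg_sdlog = 0.3, bg_measure_sdlog = 0.05,
    # outcomes
    relapse_median_months = 12, censor_min = 12, censor_max = 60,
    death_prob = 0.45, followup_min = 6, followup_max = 72,
    cr_prob = 0.667,
    # chemosensitivity
    drugs = c("mitoxantrone", "etoposide", "amsacrine"),
    median_lc50_fold = c(31, 31, 104),
    lc50_c1_median = c(0.1, 0.3, 0.03),
    lc50_sdlog = 0.15,
    conc_grids = list(
      mitoxantrone = 10^seq(-2, 1, by = 0.5),   # 0.01-10 ug/mL
      etoposide = 10^seq(-2, 2, by = 0.5),      # 0.01-100 uM
      amsacrine = 10^seq(-2, 1, by = 0.5)),     # 0.01-10 ug/mL
    hill = 1, viab_noise_pct = 3,
    n_chemo_per_cluster = 5L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  if (sum(cfg$cluster_sizes) != cfg$n_aml)
    stop("cluster sizes must sum to n_aml")
  if (any(cfg$relapse_prob < 0 | cfg$relapse_prob > 1))
    stop("relapse probabilities must lie in [0, 1]")
  if (cfg$n_informative > cfg$n_peptides)
    stop("n_informative must not exceed n_peptides")
  if (length(cfg$median_lc50_fold) != length(cfg$drugs) ||
      length(cfg$lc50_c1_median) != length(cfg$drugs))
    stop("per-drug parameter lengths must match the drug list")
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws a full spot-level cohort plus clinical metadata and the ground
#' truth used by recovery tests.  The spot model is
#' `fg = bg + activity`, with per-peptide baseline activity lognormal,
#' informative peptides shifted by plus/minus `effect/2` on the log scale
#' according to the sample's cluster, triplicate spots multiplied by
#' lognormal replicate noise (inflated by `corrupt_rep_mult` for the
#' planted corrupt samples), and NBM controls drawn from the unshifted
#' baseline.  Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with fields `scan` ([array_scan_set()]), `clinical`
#'   (`clinical_table` for the AML samples), `truth` (list: per-sample
#'   `cluster`, `informative` peptide table with directions,
#'   `corrupt_ids`, `lc50` table of true values, generative parameters).
#' @export
generate_cohort <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n_arr <- cfg$n_aml + cfg$n_corrupt_extra
  aml_ids <- sprintf("AML_%03d", seq_len(n_arr))
  nbm_ids <- sprintf("NBM_%02d", seq_len(cfg$n_nbm))
  samples <- c(aml_ids, nbm_ids)
  peptides <- sprintf("pep_%04d", seq_len(cfg$n_peptides))

  # cluster labels: clean samples fixed at the configured sizes (shuffled),
  # corrupt extras assigned proportionally (they are excluded by QC anyway)
  clean <- rep(1:2, times = cfg$cluster_sizes)
  clean <- sample(clean)
  corrupt <- 1L + rbinom(cfg$n_corrupt_extra, 1L,
                         cfg$cluster_sizes[2] / cfg$n_aml)
  cluster <- setNames(c(clean, corrupt), aml_ids)
  corrupt_ids <- aml_ids[seq_len(cfg$n_corrupt_extra) + cfg$n_aml]

  # informative peptides, half up in each cluster
  inf_idx <- sort(sample(cfg$n_peptides, cfg$n_informative))
  dir_up2 <- rep(c(1, -1), length.out = cfg$n_informative)
  dir_up2 <- sample(dir_up2)
  informative <- data.frame(
    peptide = peptides[inf_idx],
    direction = ifelse(dir_up2 > 0, "up_in_cluster2", "up_in_cluster1"),
    stringsAsFactors = FALSE)

  # log-scale true activity per (peptide, sample)
  base <- rnorm(cfg$n_peptides, cfg$act_meanlog, cfg$act_sdlog)
  shift_col <- numeric(cfg$n_peptides)
  shift_col[inf_idx] <- dir_up2 * cfg$effect / 2
  ns <- length(samples)
  cluster_sign <- c(`1` = -1, `2` = 1)
  t_mat <- matrix(base, cfg$n_peptides, ns)   # peptides x samples
  for (s in seq_along(aml_ids))
    t_mat[, s] <- t_mat[, s] + cluster_sign[cluster[s]] * shift_col
  t_mat <- t_mat + matrix(rnorm(cfg$n_peptides * ns, 0, cfg$bio_sdlog),
                          cfg$n_peptides, ns)

  rep_mult <- rep(1, ns)
  rep_mult[match(corrupt_ids, samples)] <- cfg$corrupt_rep_mult
  dims <- c(cfg$n_peptides, 3L, ns)
  eps <- array(rnorm(prod(dims)), dims)
  eps <- sweep(eps, 3, cfg$rep_sdlog * rep_mult, `*`)
  # replicate the (peptide x sample) log-activity across the 3 spots
  activity <- array(0, dims)
  for (r in 1:3) activity[, r, ] <- exp(t_mat + eps[, r, ])

  bg_true <- array(rlnorm(prod(dims), cfg$bg_meanlog, cfg$bg_sdlog), dims)
  fg <- bg_true + activity
  bg_obs <- bg_true * exp(array(rnorm(prod(dims), 0, cfg$bg_measure_sdlog),
                                dims))
  scan <- array_scan_set(fg, bg_obs, peptides, samples,
                         c(rep("AML", n_arr), rep("NBM", cfg$n_nbm)))

  clinical <- .simulate_clinical(cfg, aml_ids, cluster)
  lc50 <- .simulate_true_lc50(cfg, aml_ids, cluster, corrupt_ids)

  truth <- list(
    cluster = cluster,
    informative = informative,
    corrupt_ids = corrupt_ids,
    lc50 = lc50,
    relapse_prob = cfg$relapse_prob,
    effect = cfg$effect,
    seed = cfg$seed)
  list(scan = scan, clinical = clinical, truth = truth)
}

# Clinical covariates drawn from the marginal distribution of the target
# cohort (no covariate differs by cluster by construction); relapse is the
# only outcome whose probability depends on the cluster.
.simulate_clinical <- function(cfg, aml_ids, cluster) {
  n <- length(aml_ids)
  tnorm <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)
  sex <- sample(c("M", "F", "unknown"), n, replace = TRUE,
                prob = c(0.656, 0.313, 0.031))
  relapse <- rbinom(n, 1L, cfg$relapse_prob[cluster[aml_ids]])
  rate <- log(2) / cfg$relapse_median_months
  ttr <- ifelse(relapse == 1, rexp(n, rate),
                runif(n, cfg$censor_min, cfg$censor_max))
  death <- rbinom(n, 1L, cfg$death_prob)
  fu <- ifelse(death == 1, rexp(n, log(2) / 18),
               runif(n, cfg$followup_min, cfg$followup_max))
  df <- data.frame(
    sample_id = aml_ids,
    age = round(tnorm(n, 8.3, 4.7, 0.2, 18), 1),
    sex = sex,
    source = sample(c("PB", "BM"), n, replace = TRUE),
    blast_pct = round(tnorm(n, 71.7, 20, 5, 100), 1),
    wbc = round(tnorm(n, 29.9, 22.1, 0.5, 200), 1),
    rbc = round(tnorm(n, 4.4, 1.4, 1, 10), 1),
    plt = round(tnorm(n, 37.9, 30, 1, 250), 1),
    relapse = relapse,
    time_to_relapse = round(pmax(ttr, 0.1), 2),
    death = death,
    followup_time = round(pmax(fu, 0.1), 2),
    complete_response = rbinom(n, 1L, cfg$cr_prob),
    stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

# True LC50 values for the chemosensitivity subset: n_chemo_per_cluster
# evaluable samples per cluster, cluster-2 shifted by the configured fold.
.simulate_true_lc50 <- function(cfg, aml_ids, cluster, corrupt_ids) {
  clean <- setdiff(aml_ids, corrupt_ids)
  pick <- unlist(lapply(1:2, function(k) {
    ids <- clean[cluster[clean] == k]
    sample(ids, min(cfg$n_chemo_per_cluster, length(ids)))
  }))
  rows <- lapply(seq_along(cfg$drugs), function(d) {
    med <- ifelse(cluster[pick] == 2L,
                  cfg$lc50_c1_median[d] * cfg$median_lc50_fold[d],
                  cfg$lc50_c1_median[d])
    data.frame(sample = pick, drug = cfg$drugs[d],
               lc50_true = med * rlnorm(length(pick), 0, cfg$lc50_sdlog),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate dose-response viability tables from ground truth
#'
#' Evaluates a Hill-type viability curve
#' `viability(c) = 100 / (1 + (c / LC50_true)^h)` on each drug's
#' log-spaced concentration grid (mitoxantrone 0.01-10 ug/mL, etoposide
#' 0.01-100 uM, amsacrine 0.01-10 ug/mL by default) and adds bounded
#' uniform observation noise.  The generator uses a parametric curve on
#' purpose while the estimator is model-free interpolation, so the two
#' stay independent.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` component of [generate_cohort()] (needs the
#'   `lc50` table of true values).
#' @return A `dose_response_set` (long data.frame: sample, drug,
#'   concentration, viability_pct).
#' @export
generate_dose_response <- function(config, truth) {
  cfg <- validate_sim_config(config)
  if (is.null(truth$lc50)) stop("truth does not contain true LC50 values")
  set.seed(cfg$seed + 104729L)  # distinct stream from generate_cohort
  rows <- lapply(seq_len(nrow(truth$lc50)), function(i) {
    rec <- truth$lc50[i, ]
    conc <- cfg$conc_grids[[rec$drug]]
    v <- 100 / (1 + (conc / rec$lc50_true)^cfg$hill)
    v <- v + runif(length(conc), -cfg$viab_noise_pct, cfg$viab_noise_pct)
    v <- pmin(pmax(v, 0), 100)
    data.frame(sample = rec$sample, drug = rec$drug, concentration = conc,
               viability_pct = v, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$sample, df$drug, df$concentration), ]
  rownames(df) <- NULL
  class(df) <- c("dose_response_set", "data.frame")
  df
}

#' Export / read ground truth
#'
#' Serializes the truth object of [generate_cohort()] to JSON and reads it
#' back losslessly.
#'
#' @param truth truth list from [generate_cohort()].
#' @param path JSON path.
#' @return `export_truth` returns `path` invisibly; `read_truth` returns
#'   the truth list.
#' @export
export_truth <- function(truth, path) {
  out <- list(
    cluster = as.list(truth$cluster),
    informative = truth$informative,
    corrupt_ids = truth$corrupt_ids,
    lc50 = truth$lc50,
    relapse_prob = truth$relapse_prob,
    effect = truth$effect,
    seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    cluster = setNames(as.integer(unlist(x$cluster)), names(x$cluster)),
    informative = as.data.frame(x$informative),
    corrupt_ids = as.character(unlist(x$corrupt_ids)),
    lc50 = as.data.frame(x$lc50),
    relapse_prob = as.numeric(x$relapse_prob),
    effect = as.numeric(x$effect),
    seed = as.integer(x$seed))
}
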