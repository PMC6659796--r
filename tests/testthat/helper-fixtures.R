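# Fixture builders shared across test files.

# Small scan set built by hand: ns samples x np peptides x 3 replicates.
# Per-peptide activity is shared across the triplicate (with small
# replicate noise) so the samples pass concordance QC.
make_scan <- function(ns = 2, np = 4, seed = 42, group = NULL) {
  set.seed(seed)
  dims <- c(np, 3, ns)
  bg <- array(runif(prod(dims), 10, 20), dims)
  base <- matrix(rlnorm(np * ns, log(100), 0.6), np, ns)
  act <- array(0, dims)
  for (r in 1:3)
    act[, r, ] <- base * exp(rnorm(np * ns, 0, 0.05))
  array_scan_set(bg + act, bg,
                 peptides = sprintf("p%02d", seq_len(np)),
                 samples = sprintf("s%02d", seq_len(ns)),
                 group = group %||% rep("AML", ns))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reduced-size simulation config for fast unit tests; acceptance tests use
# the full defaults.
fast_cfg <- function(seed = 1, ...) {
  sim_config(n_aml = 24, n_corrupt_extra = 2, n_nbm = 2,
             n_peptides = 120, n_informative = 24,
             cluster_sizes = c(10L, 14L), n_chemo_per_cluster = 3L,
             seed = seed, ...)
}

# A minimal clinical table for io tests.
make_clinical <- function(n = 6, unknown_sex = 0) {
  sex <- rep(c("M", "F"), length.out = n)
  if (unknown_sex > 0) sex[seq_len(unknown_sex)] <- "unknown"
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    age = seq(2, 16, length.out = n),
    sex = sex,
    source = rep(c("PB", "BM"), length.out = n),
    blast_pct = rep(70, n), wbc = rep(30, n), rbc = rep(4.4, n),
    plt = rep(38, n),
    relapse = rep(c(0, 1), length.out = n),
    time_to_relapse = seq(5, 30, length.out = n),
    death = rep(c(0, 1), length.out = n),
    followup_time = seq(10, 60, length.out = n),
    complete_response = rep(1, n),
    stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}
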