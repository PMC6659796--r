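# Readers/writers for the three input table dialects and pipeline outputs.
#
# Spot table: TSV, columns sample_id, group, peptide_id, replicate, fg, bg.
# Clinical and dose-response tables: CSV.  All writers emit full-precision
# numbers (%.15g) so that write/read round-trips are lossless.

.fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- ""
  out
}

#' Read a spot-level intensity table
#'
#' Reads a tab-separated table with header columns `sample_id`, `group`,
#' `peptide_id`, `replicate`, `fg`, `bg` (one row per spot) into an
#' [array_scan_set()].  Input order of samples and peptides is preserved.
#'
#' @param path path to the TSV file.
#' @return An `array_scan_set`.
#' @export
read_spot_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "group", "peptide_id", "replicate", "fg", "bg")
  if (!all(required %in% names(df)))
    stop("spot table must have columns: ", paste(required, collapse = ", "))
  if (nrow(df) == 0) stop("no records in spot table")
  samples <- unique(df$sample_id)
  peptides <- unique(df$peptide_id)
  if (!all(df$replicate %in% 1:3))
    stop("replicate index outside 1..3 for sample ",
         df$sample_id[which(!df$replicate %in% 1:3)[1]])
  if (nrow(df) != length(samples) * length(peptides) * 3L)
    stop("expected exactly 3 replicates per (sample, peptide); got ",
         nrow(df), " rows for ", length(samples), " samples x ",
         length(peptides), " peptides")
  if (any(df$fg < 0) || any(df$bg < 0)) {
    bad <- which(df$fg < 0 | df$bg < 0)[1]
    stop("negative intensity at sample ", df$sample_id[bad],
         ", peptide ", df$peptide_id[bad])
  }
  # index each row into the (peptide, replicate, sample) array
  pi <- match(df$peptide_id, peptides)
  si <- match(df$sample_id, samples)
  idx <- cbind(pi, df$replicate, si)
  if (anyDuplicated(idx))
    stop("duplicate (sample, peptide, replicate) row in spot table")
  dims <- c(length(peptides), 3L, length(samples))
  fg <- array(NA_real_, dims); bg <- array(NA_real_, dims)
  fg[idx] <- df$fg; bg[idx] <- df$bg
  if (anyNA(fg))
    stop("missing replicate: not all 3 replicates present for every ",
         "(sample, peptide)")
  grp <- df$group[match(samples, df$sample_id)]
  array_scan_set(fg, bg, peptides, samples, grp)
}

#' Write a spot-level intensity table
#'
#' Inverse of [read_spot_table()]; `read_spot_table(write_spot_table(x))`
#' reproduces `x` exactly.
#'
#' @param scan an `array_scan_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(scan, path) {
  np <- length(scan$peptides); ns <- length(scan$samples)
  df <- data.frame(
    sample_id = rep(scan$samples, each = np * 3L),
    group = rep(unname(scan$group), each = np * 3L),
    peptide_id = rep(rep(scan$peptides, times = 3L), times = ns),
    replicate = rep(rep(1:3, each = np), times = ns),
    fg = .fmt_num(as.vector(scan$fg)),
    bg = .fmt_num(as.vector(scan$bg)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.clinical_cols <- c("sample_id", "age", "sex", "source", "blast_pct",
                    "wbc", "rbc", "plt", "relapse", "time_to_relapse",
                    "death", "followup_time", "complete_response")

#' Read a clinical metadata table
#'
#' CSV with one row per sample and columns `sample_id`, `age`, `sex`
#' (`M`/`F`/`unknown`), `source` (`PB`/`BM`), `blast_pct`, `wbc`, `rbc`,
#' `plt`, `relapse`, `time_to_relapse`, `death`, `followup_time`,
#' `complete_response`.  Empty cells are read as unknown (`NA`, or the
#' literal category `"unknown"` for sex) and are never imputed.
#'
#' @param path path to the CSV file.
#' @return A `data.frame` of class `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(.clinical_cols %in% names(df)))
    stop("clinical table must have columns: ",
         paste(.clinical_cols, collapse = ", "))
  if (nrow(df) == 0) stop("no records in clinical table")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id: ",
         df$sample_id[anyDuplicated(df$sample_id)])
  df$sex[is.na(df$sex) | df$sex == ""] <- "unknown"
  if (!all(df$sex %in% c("M", "F", "unknown")))
    stop("sex must be one of M, F, unknown")
  num <- setdiff(.clinical_cols, c("sample_id", "sex", "source"))
  for (v in num) df[[v]] <- as.numeric(df[[v]])
  tms <- c("time_to_relapse", "followup_time", "age")
  for (v in tms)
    if (any(df[[v]] < 0, na.rm = TRUE)) stop("negative ", v)
  for (v in c("relapse", "death", "complete_response"))
    if (!all(df[[v]] %in% c(0, 1, NA)))
      stop(v, " must be binary (0/1)")
  df <- df[, .clinical_cols]
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical metadata table
#' @param clinical a `clinical_table` (or compatible data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  df <- as.data.frame(clinical)[, .clinical_cols]
  num <- setdiff(.clinical_cols, c("sample_id", "sex", "source"))
  for (v in num) df[[v]] <- .fmt_num(df[[v]])
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a dose-response viability table
#'
#' Long-format CSV with columns `sample`, `drug`, `concentration`,
#' `viability_pct`.  Rows are grouped by (sample, drug) and sorted by
#' ascending concentration; duplicate or non-positive concentrations
#' within a (sample, drug) record are rejected.
#'
#' @param path path to the CSV file.
#' @return A `data.frame` of class `dose_response_set`, sorted by sample,
#'   drug, concentration.
#' @export
read_dose_response <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample", "drug", "concentration", "viability_pct")
  if (!all(required %in% names(df)))
    stop("dose-response table must have columns: ",
         paste(required, collapse = ", "))
  if (nrow(df) == 0) stop("no records in dose-response table")
  df <- df[, required]
  df$concentration <- as.numeric(df$concentration)
  df$viability_pct <- as.numeric(df$viability_pct)
  if (any(df$concentration <= 0))
    stop("non-positive concentration")
  if (any(!is.finite(df$viability_pct)))
    stop("non-finite viability")
  key <- paste(df$sample, df$drug, df$concentration, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df[which(duplicated(key))[1], ]
    stop("duplicate concentration ", bad$concentration, " for sample ",
         bad$sample, ", drug ", bad$drug)
  }
  df <- df[order(df$sample, df$drug, df$concentration), ]
  rownames(df) <- NULL
  class(df) <- c("dose_response_set", "data.frame")
  df
}

#' Write a dose-response viability table
#' @param dr a `dose_response_set` (or compatible data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(dr, path) {
  df <- as.data.frame(dr)
  df$concentration <- .fmt_num(df$concentration)
  df$viability_pct <- .fmt_num(df$viability_pct)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline products to a directory
#'
#' Writes whichever products are present in `results` plus a run report,
#' with deterministic field order and full-precision numeric formatting so
#' that two runs with identical seed and configuration produce
#' byte-identical files.
#'
#' @param results a named list with any subset of: `normalized`
#'   (spot-level `peptide_matrix`), `qc` (QC report data.frame), `labels`
#'   (named integer cluster labels), `gap` (gap-curve data.frame),
#'   `differential` (differential table), `outcome_tests` (list of
#'   `test_result`/numeric summaries), `lc50` (LC50 table),
#'   `config` (list echoed into the run report).
#' @param directory output directory (created if needed).
#' @return Character vector of written file paths (the manifest); the run
#'   report `run_report.json` is always included.
#' @export
write_outputs <- function(results, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  manifest <- character(0)
  put <- function(name) file.path(directory, name)

  if (!is.null(results$normalized)) {
    m <- results$normalized$values
    df <- data.frame(spot_id = rownames(m),
                     apply(m, 2, .fmt_num),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, put("normalized_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, put("normalized_matrix.tsv"))
  }
  if (!is.null(results$qc)) {
    qc <- results$qc
    qc$r2 <- .fmt_num(qc$r2)
    write.csv(qc, put("qc_report.csv"), row.names = FALSE, quote = FALSE)
    manifest <- c(manifest, put("qc_report.csv"))
  }
  if (!is.null(results$labels)) {
    df <- data.frame(sample_id = names(results$labels),
                     cluster = as.integer(results$labels))
    write.csv(df, put("cluster_labels.csv"), row.names = FALSE,
              quote = FALSE)
    manifest <- c(manifest, put("cluster_labels.csv"))
  }
  if (!is.null(results$gap)) {
    g <- results$gap
    for (v in c("log_W", "gap", "s")) g[[v]] <- .fmt_num(g[[v]])
    write.csv(g, put("gap_curve.csv"), row.names = FALSE, quote = FALSE)
    manifest <- c(manifest, put("gap_curve.csv"))
  }
  if (!is.null(results$differential)) {
    d <- results$differential
    for (v in names(d)) if (is.numeric(d[[v]])) d[[v]] <- .fmt_num(d[[v]])
    write.table(d, put("differential.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- c(manifest, put("differential.tsv"))
  }
  if (!is.null(results$outcome_tests)) {
    jsonlite::write_json(results$outcome_tests, put("outcome_tests.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    manifest <- c(manifest, put("outcome_tests.json"))
  }
  if (!is.null(results$lc50)) {
    l <- results$lc50
    for (v in names(l)) if (is.numeric(l[[v]])) l[[v]] <- .fmt_num(l[[v]])
    write.csv(l, put("lc50.csv"), row.names = FALSE, quote = FALSE)
    manifest <- c(manifest, put("lc50.csv"))
  }
  report <- list(
    package = "pepkinome",
    version = as.character(packageVersion("pepkinome")),
    config = results$config,
    summary = results$summary,
    files = basename(manifest))
  jsonlite::write_json(report, put("run_report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  manifest <- c(manifest, put("run_report.json"))
  manifest
}
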