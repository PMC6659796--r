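# S3 containers shared by the pipeline stages.

#' Construct a spot-level array scan set
#'
#' The raw input of the pipeline: per sample, foreground and background
#' intensity for every (peptide, replicate) spot.  Peptides are spotted as
#' triplicates, so the replicate dimension is always 3.
#'
#' @param fg,bg numeric arrays of dimension
#'   `c(n_peptides, 3, n_samples)` (peptide x replicate x sample) holding
#'   foreground and background intensities; all values must be `>= 0`.
#' @param peptides character vector of unique peptide identifiers
#'   (length `dim(fg)[1]`).
#' @param samples character vector of unique sample identifiers
#'   (length `dim(fg)[3]`).
#' @param group character vector, one of `"AML"` or `"NBM"` per sample.
#' @return An object of class `array_scan_set` with fields `fg`, `bg`,
#'   `peptides`, `samples`, `group`.
#' @seealso [read_spot_table()], [subtract_background()]
#' @export
array_scan_set <- function(fg, bg, peptides, samples, group) {
  stopifnot(is.array(fg), is.array(bg), length(dim(fg)) == 3L)
  if (!identical(dim(fg), dim(bg)))
    stop("fg and bg must have identical dimensions")
  if (dim(fg)[2] != 3L)
    stop("replicate count must be exactly 3 for every (sample, peptide)")
  if (dim(fg)[1] != length(peptides) || dim(fg)[3] != length(samples))
    stop("array dimensions do not match peptide/sample identifier lengths")
  if (anyDuplicated(peptides)) stop("peptide identifiers must be unique")
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  if (length(group) != length(samples) || !all(group %in% c("AML", "NBM")))
    stop("group must be one of 'AML', 'NBM' per sample")
  if (anyNA(fg) || anyNA(bg)) stop("missing intensities are not allowed")
  if (min(fg) < 0 || min(bg) < 0)
    stop("negative intensity encountered; fg and bg must be >= 0")
  dimnames(fg) <- dimnames(bg) <-
    list(peptides, paste0("r", 1:3), samples)
  structure(
    list(fg = fg, bg = bg, peptides = peptides, samples = samples,
         group = setNames(group, samples)),
    class = "array_scan_set")
}

#' @export
print.array_scan_set <- function(x, ...) {
  cat("array_scan_set:", length(x$samples), "samples (",
      sum(x$group == "AML"), "AML,", sum(x$group == "NBM"), "NBM ) x",
      length(x$peptides), "peptides x 3 replicate spots\n")
  invisible(x)
}

# Stage order for peptide_matrix; transitions must move rightwards.
.pm_stages <- c("raw", "normalized", "collapsed", "filtered", "scaled")

#' Construct a peptide activation matrix
#'
#' Carrier for activation values as they move through the pipeline.  At
#' stages `raw` and `normalized` the matrix is spot-level (one row per
#' peptide x replicate, one column per sample); from `collapsed` onwards it
#' is one row per sample, one column per peptide.
#'
#' @param values numeric matrix with dimnames set.
#' @param stage one of `"raw"`, `"normalized"`, `"collapsed"`,
#'   `"filtered"`, `"scaled"`.
#' @param level `"spot"` or `"peptide"` (orientation of `values`).
#' @param peptide,replicate at spot level, the peptide id and replicate
#'   number of each row.
#' @param group optional named group vector (`"AML"`/`"NBM"`) per sample.
#' @param log_transformed,scaled bookkeeping flags recording which
#'   transforms have been applied.
#' @return An object of class `peptide_matrix`.
#' @export
peptide_matrix <- function(values, stage, level = c("spot", "peptide"),
                           peptide = NULL, replicate = NULL, group = NULL,
                           log_transformed = FALSE, scaled = FALSE) {
  level <- match.arg(level)
  stage <- match.arg(stage, .pm_stages)
  stopifnot(is.matrix(values))
  if (level == "spot" && (is.null(peptide) || is.null(replicate)))
    stop("spot-level matrix needs per-row peptide and replicate metadata")
  if (stage %in% c("collapsed", "filtered", "scaled") && anyNA(values))
    stop("no missing values allowed at stage ", stage, " or later")
  structure(
    list(values = values, stage = stage, level = level,
         peptide = peptide, replicate = replicate, group = group,
         log_transformed = log_transformed, scaled = scaled),
    class = "peptide_matrix")
}

# Guard stage transitions: only forward moves along .pm_stages.
.pm_advance <- function(pm, to) {
  from <- match(pm$stage, .pm_stages)
  dest <- match(to, .pm_stages)
  if (dest <= from)
    stop("invalid stage transition ", pm$stage, " -> ", to)
  invisible(TRUE)
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat("peptide_matrix [stage=", x$stage, ", level=", x$level, "]: ",
      nrow(x$values), " x ", ncol(x$values),
      if (x$log_transformed) " (log2)", if (x$scaled) " (z-scored)", "\n",
      sep = "")
  invisible(x)
}

#' Samples held in a peptide matrix
#' @param pm a `peptide_matrix`.
#' @return Character vector of sample identifiers.
#' @export
pm_samples <- function(pm) {
  if (pm$level == "spot") colnames(pm$values) else rownames(pm$values)
}

#' Construct a generic statistical test result
#'
#' Uniform container for the chi-square, Mann-Whitney U, ANOVA F and
#' log-rank statistics reported throughout the package.
#'
#' @param statistic test statistic value.
#' @param p two-sided p-value in `[0, 1]`.
#' @param method human-readable test name.
#' @param df degrees of freedom (optional; may be a length-2 vector).
#' @return An object of class `test_result` with fields `statistic`, `df`,
#'   `p_two_sided`, `method`.
#' @export
test_result <- function(statistic, p, method, df = NULL) {
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_two_sided = unname(p), method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.null(x$df)) paste0(", df = ", paste(x$df, collapse = ",")),
      ", two-sided p = ", format(x$p_two_sided, digits = 3), "\n", sep = "")
  invisible(x)
}
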