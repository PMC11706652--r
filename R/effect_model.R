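# Core effect-size transforms: Fisher's Z, its sampling variance, and the
# inverse-variance weight used throughout the fixed-effect pooling machinery.

#' Fisher's Z transformation of a correlation coefficient
#'
#' Transforms a Pearson correlation `r` to Fisher's Z,
#' \eqn{Z = \tfrac{1}{2}[\ln(1+r) - \ln(1-r)]}, which is approximately normal
#' with sampling variance \eqn{1/(n-3)} for a correlation estimated from `n`
#' paired annual observations.
#'
#' @param r Numeric vector of correlations, each strictly inside (-1, 1).
#'   A value with |r| >= 1 is rejected rather than clamped: a perfect
#'   correlation over four or more years of field data signals an extraction
#'   mistake upstream, and clamping would silently distort pooling weights.
#' @return Numeric vector of Fisher's Z values.
#' @seealso [inverse_fisher()], [fisher_var()], [to_z_effect()]
#' @examples
#' fisher_z(0.5)
#' fisher_z(c(-0.9, 0, 0.9))
#' @export
fisher_z <- function(r) {
  r <- as.numeric(r)
  if (any(!is.finite(r))) {
    stop("`r` must be finite", call. = FALSE)
  }
  if (any(abs(r) >= 1)) {
    stop("|r| >= 1: Fisher's Z is undefined; correlations must lie strictly ",
         "in (-1, 1). Check the extracted effect sizes.", call. = FALSE)
  }
  0.5 * (log(1 + r) - log(1 - r))
}

#' Sampling variance of Fisher's Z
#'
#' For a correlation computed from `n_years` paired annual observations the
#' large-sample variance of Fisher's Z is \eqn{1/(n-3)}, independent of the
#' correlation itself. At least 4 years are required (the inclusion minimum
#' for an interannual correlation; fewer leaves the variance undefined or
#' non-positive).
#'
#' @param n_years Integer vector of year counts, each >= 4.
#' @return Numeric vector of sampling variances.
#' @examples
#' fisher_var(28)  # 1/25
#' @export
fisher_var <- function(n_years) {
  n_years <- as.numeric(n_years)
  if (any(!is.finite(n_years)) || any(n_years != round(n_years))) {
    stop("`n_years` must be whole numbers", call. = FALSE)
  }
  if (any(n_years < 4)) {
    stop("`n_years` must be >= 4: Var(Z) = 1/(n - 3) requires at least 4 ",
         "years of observations.", call. = FALSE)
  }
  1 / (n_years - 3)
}

#' Back-transform Fisher's Z to a correlation
#'
#' Inverse of [fisher_z()]: \eqn{r = (e^{2Z} - 1)/(e^{2Z} + 1)}, i.e.
#' \eqn{\tanh(Z)}. Used to report pooled effects on the familiar correlation
#' scale.
#'
#' @param z Numeric vector of Fisher's Z values (any finite real).
#' @return Numeric vector of correlations in (-1, 1).
#' @examples
#' inverse_fisher(fisher_z(0.3))
#' @export
inverse_fisher <- function(z) {
  z <- as.numeric(z)
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  tanh(z)
}

#' Attach Fisher's Z, variance and weight to validated effect records
#'
#' Augments a table of effect records with the transformed effect size `z`,
#' its sampling variance `var` (= 1/(n_years - 3)) and the inverse-variance
#' weight `weight` (= n_years - 3). Both the correlation `r` and `z` are
#' carried through the pipeline: `z` drives the pooling arithmetic, `r` the
#' human-readable reports.
#'
#' @param records Data frame of effect records as returned by
#'   [align_sign()] or validated by [validate_effects()]; must contain
#'   columns `r` and `n_years`.
#' @return The input data frame with columns `z`, `var` and `weight` added.
#' @examples
#' rec <- data.frame(effect_id = "e1", r = 0.6, n_years = 13)
#' to_z_effect(rec)
#' @export
to_z_effect <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("r", "n_years") %in% names(records))) {
    stop("`records` must have columns `r` and `n_years`", call. = FALSE)
  }
  records$z <- fisher_z(records$r)
  records$var <- fisher_var(records$n_years)
  records$weight <- 1 / records$var
  records
}

#' Validate a table of effect records
#'
#' Checks the schema and invariants of an effect table: required columns,
#' enumerated factor levels, correlations strictly inside (-1, 1), a minimum
#' of 4 years per effect, and unique effect identifiers. Optional columns
#' (`population`, `phenology_metric`, `predictor_metric`) are filled with
#' neutral defaults when absent; a missing `population` defaults to the
#' effect id, meaning no two rows are treated as re-measurements of the same
#' fish observations.
#'
#' @param records Data frame of effect records (columns `study_id`,
#'   `effect_id`, `species`, `season`, `process`, `system_type`, `predictor`,
#'   `r`, `n_years`).
#' @param skip_invalid If `TRUE`, rows violating row-level rules (|r| >= 1,
#'   n_years < 4, bad enum labels) are dropped and reported in the
#'   `"problems"` attribute instead of aborting.
#' @return The validated (possibly filtered) data frame, invisibly carrying a
#'   `"problems"` attribute describing dropped rows when `skip_invalid = TRUE`.
#' @export
validate_effects <- function(records, skip_invalid = FALSE) {
  stopifnot(is.data.frame(records))
  required <- c("study_id", "effect_id", "species", "season", "process",
                "system_type", "predictor", "r", "n_years")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("effect table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"population" %in% names(records)) records$population <- records$effect_id
  if (!"phenology_metric" %in% names(records)) records$phenology_metric <- ""
  if (!"predictor_metric" %in% names(records)) records$predictor_metric <- ""

  problems <- row_problems(records)
  if (nrow(problems) > 0) {
    if (!skip_invalid) {
      stop("invalid effect rows:\n",
           paste(sprintf("  row %d (%s): %s", problems$row,
                         problems$effect_id, problems$problem),
                 collapse = "\n"),
           "\nUse skip_invalid = TRUE to drop them instead.", call. = FALSE)
    }
    records <- records[-unique(problems$row), , drop = FALSE]
    rownames(records) <- NULL
  }
  if (anyDuplicated(records$effect_id)) {
    stop("`effect_id` must be unique within a dataset", call. = FALSE)
  }
  attr(records, "problems") <- problems
  records
}

# Row-level rule violations as a data frame (row, effect_id, problem).
row_problems <- function(records) {
  probs <- list()
  note <- function(rows, msg) {
    if (any(rows)) {
      probs[[length(probs) + 1L]] <<- data.frame(
        row = which(rows),
        effect_id = as.character(records$effect_id[rows]),
        problem = msg, stringsAsFactors = FALSE)
    }
  }
  r <- suppressWarnings(as.numeric(records$r))
  n <- suppressWarnings(as.numeric(records$n_years))
  note(is.na(r), "correlation `r` is missing or non-numeric")
  note(!is.na(r) & abs(r) >= 1, "|r| >= 1: Fisher's Z undefined")
  note(is.na(n), "`n_years` is missing or non-numeric")
  note(!is.na(n) & n < 4,
       "fewer than the minimum of 4 years of observations")
  note(!records$season %in% c("spring", "autumn"),
       "season must be 'spring' or 'autumn'")
  note(!records$process %in% c("spawning", "migration"),
       "process must be 'spawning' or 'migration'")
  note(!records$system_type %in% c("lentic", "lotic", "unknown"),
       "system_type must be 'lentic', 'lotic' or 'unknown'")
  note(!records$predictor %in% c("temperature", "year"),
       "predictor must be 'temperature' or 'year'")
  if (length(probs) == 0) {
    return(data.frame(row = integer(), effect_id = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, probs)
  out[order(out$row), , drop = FALSE]
}
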