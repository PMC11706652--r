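# Interannual variability of spawning dates: date ranges, Tukey-fence outlier
# screening, and the range ~ duration + season ANCOVA with estimated marginal
# means at the grand-mean study duration.

#' Interannual range of spawning dates
#'
#' Reduces a series of annual reproductive day-of-year observations to its
#' range (latest minus earliest day across all years sampled) and the number
#' of observed years. Autumn spawners near the calendar boundary are handled
#' by circular unwrapping: when the raw spread exceeds half a year, early
#' January dates are interpreted as the continuation of a December spawning
#' season and shifted by +365 before taking max - min. Without this, a
#' population spawning around New Year would show a spuriously huge range.
#'
#' @param doy Numeric vector of annual day-of-year values, at least 4.
#' @param unwrap Apply the calendar-boundary unwrapping rule (default TRUE).
#' @return List with `range_days` (max - min on the unwrapped axis) and
#'   `n_years` (count of annual values, not the calendar span).
#' @examples
#' compute_range(c(100, 110, 95, 120))        # range 25
#' compute_range(c(360, 5, 350, 355))         # boundary-crossing: range 20
#' @export
compute_range <- function(doy, unwrap = TRUE) {
  doy <- as.numeric(doy)
  doy <- doy[!is.na(doy)]
  if (length(doy) < 4) {
    stop("a date range needs at least 4 annual observations (got ",
         length(doy), ")", call. = FALSE)
  }
  if (unwrap) doy <- unwrap_doy(doy)
  list(range_days = max(doy) - min(doy), n_years = length(doy))
}

# Shift early-calendar dates by +365 when the raw spread exceeds half a year,
# so December-January spawning seasons sit on a continuous axis.
unwrap_doy <- function(doy, threshold = 365 / 2) {
  if (max(doy) - min(doy) > threshold) {
    doy[doy < threshold] <- doy[doy < threshold] + 365
  }
  doy
}

#' Date ranges for every population in a long date series
#'
#' Aggregates a long table of annual reproductive dates (one row per
#' population-year) into one date-range record per population via
#' [compute_range()]. Populations with fewer than 4 observed years are
#' excluded and listed, with reasons, in the `"excluded"` attribute.
#'
#' @param series Data frame with columns `population_id`, `season`, `year`,
#'   and either `day_of_year` or an ISO-8601 `date` (converted internally).
#' @param unwrap Passed to [compute_range()].
#' @return Data frame of date-range records: `population_id`, `season`,
#'   `n_years`, `range_days`; attribute `"excluded"` lists dropped
#'   populations.
#' @export
compute_ranges <- function(series, unwrap = TRUE) {
  stopifnot(is.data.frame(series))
  required <- c("population_id", "season", "year")
  if (!all(required %in% names(series))) {
    stop("series table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!"day_of_year" %in% names(series)) {
    if (!"date" %in% names(series)) {
      stop("series table needs a `day_of_year` or ISO-8601 `date` column",
           call. = FALSE)
    }
    d <- as.Date(as.character(series$date))
    if (anyNA(d)) stop("unparseable date(s) in series table", call. = FALSE)
    series$day_of_year <- as.integer(strftime(d, "%j"))
  }
  out <- list()
  excluded <- list()
  for (pid in unique(series$population_id)) {
    sub <- series[series$population_id == pid, , drop = FALSE]
    if (nrow(sub) < 4) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        population_id = pid,
        reason = sprintf("only %d observed year(s); minimum is 4", nrow(sub)),
        stringsAsFactors = FALSE)
      next
    }
    rng <- compute_range(sub$day_of_year, unwrap = unwrap)
    out[[length(out) + 1L]] <- data.frame(
      population_id = pid, season = sub$season[1],
      n_years = rng$n_years, range_days = rng$range_days,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(population_id = character(), season = character(),
               n_years = integer(), range_days = numeric())
  rownames(res) <- NULL
  attr(res, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(population_id = character(), reason = character())
  res
}

#' Tukey-fence screening of date-range records
#'
#' Removes date-range observations lying beyond 1.5 interquartile ranges of
#' the quartiles of all pooled range values (both seasons together): the
#' standard Tukey fence, applied two-sided. Quartiles use linear
#' interpolation between order statistics (R's default, type 7); on edge
#' cases a different quantile convention could move a point across the fence,
#' so the convention is exposed.
#'
#' @param records Data frame of date-range records with a `range_days`
#'   column; at least 4 rows so quartiles are meaningful.
#' @param k Fence multiplier (default 1.5).
#' @param type Quantile type passed to [stats::quantile()] (default 7).
#' @return List with `kept` and `removed` data frames and the `fences` used.
#' @export
iqr_screen <- function(records, k = 1.5, type = 7) {
  stopifnot(is.data.frame(records), "range_days" %in% names(records))
  if (nrow(records) < 4) {
    stop("IQR screening needs at least 4 records for meaningful quartiles",
         call. = FALSE)
  }
  q <- stats::quantile(records$range_days, c(0.25, 0.75), type = type,
                       names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  out <- records$range_days > fences["upper"] |
    records$range_days < fences["lower"]
  kept <- records[!out, , drop = FALSE]
  removed <- records[out, , drop = FALSE]
  rownames(kept) <- NULL
  rownames(removed) <- NULL
  list(kept = kept, removed = removed, fences = fences)
}

#' ANCOVA of date range on study duration and spawning season
#'
#' Fits the interannual spawning-date range against study duration
#' (`n_years`, the covariate) and spawning season (the factor) by ordinary
#' least squares. An interaction term `n_years:season` is fitted first; if
#' its p-value exceeds `alpha` it is dropped and the additive model is the
#' final model. Per-season estimated marginal means (EMMs) are computed at
#' the grand-mean duration of the records entering the model, via the
#' emmeans package.
#'
#' Migration records are a separate process from spawning and should be
#' excluded before calling (see [run_full_analysis()], which does so).
#'
#' @param records Data frame of date-range records: `season` (both levels
#'   present), `n_years` (>= 2 distinct values), `range_days`.
#' @param alpha Significance level for the interaction screen (default 0.05).
#' @param emm_at Duration at which to evaluate the EMMs; defaults to the
#'   grand mean of `n_years` over the fitted records.
#' @param ci_level Confidence level for EMM intervals.
#' @return An `ancova_result`: the final `lm` fit plus `coefficients`,
#'   `interaction_p`, `dropped_interaction`, `r_squared`, `f_stat`, `df`,
#'   `model_p`, `emm` (per-season EMM table), `emm_at`, `season_contrast_p`,
#'   and `n`.
#' @export
fit_ancova <- function(records, alpha = 0.05, emm_at = NULL,
                       ci_level = 0.95) {
  stopifnot(is.data.frame(records))
  needed <- c("season", "n_years", "range_days")
  if (!all(needed %in% names(records))) {
    stop("records need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  records$season <- factor(as.character(records$season))
  if (nlevels(records$season) < 2) {
    stop("both spawning seasons must be represented to estimate a season ",
         "contrast", call. = FALSE)
  }
  if (length(unique(records$n_years)) < 2) {
    stop("need at least 2 distinct study durations to fit the covariate",
         call. = FALSE)
  }
  full <- stats::lm(range_days ~ n_years * season, data = records)
  if (anyNA(stats::coef(full))) {
    stop("collinear design: interaction model is rank-deficient",
         call. = FALSE)
  }
  cf_full <- stats::coef(summary(full))
  inter_rows <- grep(":", rownames(cf_full))
  interaction_p <- min(cf_full[inter_rows, "Pr(>|t|)"])
  # a saturated (noiseless) fit leaves the test undefined: no evidence, drop
  dropped <- !is.finite(interaction_p) || interaction_p > alpha
  final <- if (dropped) {
    stats::lm(range_days ~ n_years + season, data = records)
  } else {
    full
  }
  smry <- summary(final)
  fstat <- smry$fstatistic
  model_p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)

  if (is.null(emm_at)) emm_at <- mean(records$n_years)
  emm_obj <- suppressMessages(
    emmeans::emmeans(final, "season", at = list(n_years = emm_at),
                     level = ci_level))
  emm <- as.data.frame(summary(emm_obj, level = ci_level))
  contrast <- as.data.frame(summary(emmeans::contrast(emm_obj, "pairwise")))

  structure(
    list(model = final,
         coefficients = stats::coef(smry),
         interaction_p = unname(interaction_p),
         dropped_interaction = dropped,
         r_squared = smry$r.squared,
         f_stat = unname(fstat[1L]),
         df = unname(fstat[2:3]),
         model_p = unname(model_p),
         emm = emm,
         emm_at = emm_at,
         season_contrast_p = contrast$p.value[1L],
         alpha = alpha,
         n = nrow(records)),
    class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, digits = 3, ...) {
  cat(sprintf("ANCOVA: date range ~ duration %s season (n = %d)\n",
              if (x$dropped_interaction) "+" else "*", x$n))
  if (x$dropped_interaction) {
    cat(sprintf("  interaction dropped (p = %.3f > %.2f)\n",
                x$interaction_p, x$alpha))
  }
  cat(sprintf("  R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r_squared, x$df[1], x$df[2], x$f_stat, x$model_p))
  cat(sprintf("  EMMs at duration = %.1f years:\n", x$emm_at))
  for (i in seq_len(nrow(x$emm))) {
    cat(sprintf("    %s: %.1f +/- %.1f days\n", x$emm$season[i],
                x$emm$emmean[i], x$emm$SE[i]))
  }
  cat(sprintf("  season contrast p = %.3g\n", x$season_contrast_p))
  invisible(x)
}
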