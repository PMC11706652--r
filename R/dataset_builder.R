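# Construction of the inclusive and conservative analysis datasets, the sign
# convention, and the season x process x predictor groupings.

#' Align reported correlations to the common sign convention
#'
#' Source studies report correlations on heterogeneous date axes. All effects
#' are placed on a common convention before pooling: `r` is the correlation
#' between the annual predictor and the day-of-year of reproduction, so a
#' negative `r` means earlier timing with an increasing predictor
#' (temperature or year) and a positive `r` means delayed timing.
#'
#' @param rows Data frame of raw extracted rows with columns `reported_r`
#'   (the correlation as printed in the source study) and `direction`, one of
#'   `"later_with_increase"` (a positive reported correlation means later
#'   dates; the identity case) or `"earlier_with_increase"` (a positive
#'   reported correlation means earlier dates; the sign is flipped).
#' @return The input with a column `r` holding the sign-aligned correlation.
#'   `reported_r` and `direction` are retained for auditability.
#' @examples
#' align_sign(data.frame(reported_r = 0.6, direction = "earlier_with_increase"))
#' @export
align_sign <- function(rows) {
  stopifnot(is.data.frame(rows))
  if (!all(c("reported_r", "direction") %in% names(rows))) {
    stop("`rows` must have columns `reported_r` and `direction`",
         call. = FALSE)
  }
  dir <- as.character(rows$direction)
  bad <- is.na(dir) | !dir %in% c("later_with_increase", "earlier_with_increase")
  if (any(bad)) {
    stop("missing or unknown `direction` in row(s) ",
         paste(which(bad), collapse = ", "),
         " (must be 'later_with_increase' or 'earlier_with_increase')",
         call. = FALSE)
  }
  rows$r <- ifelse(dir == "earlier_with_increase",
                   -rows$reported_r, rows$reported_r)
  rows
}

new_dataset <- function(label, records, dropped = NULL, seed = NULL) {
  structure(
    list(label = label, records = records,
         dropped = dropped %||% data.frame(effect_id = character(),
                                           reason = character(),
                                           stringsAsFactors = FALSE),
         seed = seed),
    class = "phenometa_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phenometa_dataset <- function(x, ...) {
  cat(sprintf("<phenometa %s dataset: %d effects", x$label, nrow(x$records)))
  if (!is.null(x$seed)) cat(sprintf(", seed %d", x$seed))
  cat(">\n")
  if (nrow(x$dropped) > 0) {
    cat(sprintf("  %d effect(s) excluded:\n", nrow(x$dropped)))
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("    %s: %s\n", x$dropped$effect_id[i], x$dropped$reason[i]))
    }
  }
  invisible(x)
}

# Priority for competing measurements of the same fish observations:
# water-temperature predictors beat air-temperature ones, and peak-spawning
# phenology metrics beat onset/start metrics; ties go to the first-listed row.
metric_priority <- function(predictor_metric, phenology_metric) {
  pm <- tolower(as.character(predictor_metric))
  fm <- tolower(as.character(phenology_metric))
  p <- ifelse(grepl("water", pm), 2L, ifelse(grepl("air", pm), 0L, 1L))
  f <- ifelse(grepl("peak", fm), 2L,
              ifelse(grepl("onset|start|initial|first", fm), 0L, 1L))
  p + f
}

#' Build the inclusive analysis dataset
#'
#' The inclusive dataset retains every effect except alternative measurements
#' of the same fish observations (e.g. an air-temperature and a
#' water-temperature correlation for the same population's mean spawning
#' date). Duplicates are identified by identical
#' (study, species, population, predictor, season, process); one row per
#' duplicate group is kept by metric priority (water over air temperature,
#' peak over onset dates), ties broken by the first-listed row. Every
#' exclusion is recorded in the dataset's `dropped` manifest.
#'
#' @param records Validated effect records (see [validate_effects()]).
#' @return A `phenometa_dataset` with `label = "inclusive"`.
#' @export
build_inclusive <- function(records) {
  records <- validate_effects(records)
  if (nrow(records) == 0) return(new_dataset("inclusive", records))
  key <- interaction(records$study_id, records$species, records$population,
                     records$predictor, records$season, records$process,
                     drop = TRUE)
  keep <- logical(nrow(records))
  prio <- metric_priority(records$predictor_metric, records$phenology_metric)
  for (idx in split(seq_len(nrow(records)), key)) {
    keep[idx[which.max(prio[idx])]] <- TRUE  # which.max takes first on ties
  }
  dropped <- data.frame(
    effect_id = as.character(records$effect_id[!keep]),
    reason = rep("alternative measurement of the same fish observations",
                 sum(!keep)),
    stringsAsFactors = FALSE)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  new_dataset("inclusive", kept, dropped)
}

#' Build the conservative analysis dataset
#'
#' To guard against dependency among multiple species-specific effects from
#' one publication, the conservative dataset keeps a single, randomly
#' selected effect for each (study, species) pair. Selection iterates groups
#' in sorted key order and draws from one seeded stream, so the result is
#' reproducible given (`records`, `seed`) and invariant to input row order.
#'
#' @param records Validated effect records.
#' @param seed Integer seed for the random within-group selection.
#' @return A `phenometa_dataset` with `label = "conservative"`; effects not
#'   selected are listed in the `dropped` manifest.
#' @export
build_conservative <- function(records, seed) {
  records <- validate_effects(records)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (nrow(records) == 0) {
    return(new_dataset("conservative", records, seed = as.integer(seed)))
  }
  key <- paste(records$study_id, records$species, sep = "\r")
  keep <- integer(0)
  with_local_seed(seed, {
    for (k in sort(unique(key))) {
      idx <- which(key == k)
      idx <- idx[order(as.character(records$effect_id[idx]))]
      keep <- c(keep, idx[sample.int(length(idx), 1L)])
    }
  })
  keep <- sort(keep)
  not_kept <- setdiff(seq_len(nrow(records)), keep)
  dropped <- data.frame(
    effect_id = as.character(records$effect_id[not_kept]),
    reason = rep("not selected in conservative one-effect-per-species draw",
                 length(not_kept)),
    stringsAsFactors = FALSE)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  new_dataset("conservative", kept, dropped, seed = as.integer(seed))
}

# Evaluate `code` under a temporary RNG state; the caller's state is restored.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  old <- get0(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = env)
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Partition effect records into analysis groups
#'
#' Splits a dataset into disjoint, exhaustive groups by metadata fields. The
#' canonical grouping is `c("season", "process", "predictor")`, giving the
#' spring-spawning / autumn-spawning / autumn-migration groups for each
#' predictor; adding `"system_type"` yields the lentic/lotic sub-analyses.
#'
#' @param x A `phenometa_dataset` or a data frame of effect records.
#' @param by Character vector of grouping field names.
#' @return Named list of data frames; names are the group keys joined by `.`.
#' @export
partition <- function(x, by = c("season", "process", "predictor")) {
  records <- if (inherits(x, "phenometa_dataset")) x$records else x
  stopifnot(is.data.frame(records))
  unknown <- setdiff(by, names(records))
  if (length(unknown) > 0) {
    stop("unknown grouping field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) return(structure(list(), names = character()))
  key <- interaction(records[by], drop = TRUE, sep = ".", lex.order = TRUE)
  split(records, key)
}
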