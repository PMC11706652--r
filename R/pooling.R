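# Fixed-effect (common-effect) inverse-variance pooling of Fisher's Z effects.

#' Pool Fisher's Z effects by inverse-variance weighting
#'
#' Computes the common-effect weighted mean
#' \eqn{\bar{Z} = \sum Z_i W_i / \sum W_i} with \eqn{W_i = 1/\mathrm{Var}(Z_i)},
#' its standard error \eqn{\sqrt{1/\sum W_i}}, and a normal-quantile
#' confidence interval. A group effect is flagged significant when the
#' interval excludes zero. The CI uses the standard normal quantile (1.96 at
#' 95%), the convention for fixed-effect inverse-variance pooling; users
#' comparing against t-based intervals will see slightly narrower bounds here.
#'
#' @param effects Data frame with columns `z` and `var` (see
#'   [to_z_effect()]); any metadata columns are ignored.
#' @param ci_level Confidence level as a proportion (default 0.95).
#' @return One-row data frame: `k`, `z_bar`, `se`, `ci_low`, `ci_high`,
#'   `ci_halfwidth`, `ci_level`, `r_bar` (pooled effect back-transformed to
#'   the correlation scale) and `significant`.
#' @examples
#' eff <- to_z_effect(data.frame(r = c(0.2, 0.5), n_years = c(7, 11)))
#' pool(eff)
#' @export
pool <- function(effects, ci_level = 0.95) {
  stopifnot(is.data.frame(effects))
  if (!all(c("z", "var") %in% names(effects))) {
    stop("`effects` must have columns `z` and `var`; see to_z_effect()",
         call. = FALSE)
  }
  if (nrow(effects) == 0) stop("cannot pool an empty set of effects",
                               call. = FALSE)
  if (!(is.numeric(ci_level) && length(ci_level) == 1 &&
        ci_level > 0 && ci_level < 1)) {
    stop("`ci_level` must be in (0, 1)", call. = FALSE)
  }
  if (any(effects$var <= 0)) stop("all sampling variances must be > 0",
                                  call. = FALSE)
  if (nrow(effects) == 1) {
    warning("pooling a single effect: the interval reflects only that ",
            "effect's sampling variance", call. = FALSE)
  }
  w <- 1 / effects$var
  z_bar <- sum(effects$z * w) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_low <- z_bar - q * se
  ci_high <- z_bar + q * se
  data.frame(
    k = nrow(effects), z_bar = z_bar, se = se,
    ci_low = ci_low, ci_high = ci_high, ci_halfwidth = q * se,
    ci_level = ci_level, r_bar = inverse_fisher(z_bar),
    significant = ci_low > 0 || ci_high < 0)
}

#' Pool every analysis group of a dataset
#'
#' Applies [pool()] to each non-empty group of a dataset, by default the
#' season x process x predictor partition (the spring-spawning,
#' autumn-spawning and autumn-migration groups for each predictor). Empty
#' groups are simply absent from the output.
#'
#' @param ds A `phenometa_dataset` or a data frame of validated effect
#'   records; `z`/`var` columns are computed if missing.
#' @param by Grouping fields passed to [partition()].
#' @param ci_level Confidence level for each group's interval.
#' @return Data frame with one row per group: the grouping columns, the
#'   dataset label (if `ds` is a dataset), and the [pool()] columns.
#' @export
pool_all <- function(ds, by = c("season", "process", "predictor"),
                     ci_level = 0.95) {
  records <- if (inherits(ds, "phenometa_dataset")) ds$records else ds
  label <- if (inherits(ds, "phenometa_dataset")) ds$label else NA_character_
  if (!all(c("z", "var") %in% names(records))) {
    records <- to_z_effect(records)
  }
  groups <- partition(records, by)
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    meta <- g[1, by, drop = FALSE]
    rownames(meta) <- NULL
    pooled <- suppressWarnings(pool(g, ci_level = ci_level))
    cbind(meta, dataset = label, pooled)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
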