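# Egger-type regression tests of funnel-plot asymmetry (small-study effects).

#' Egger regression test of funnel-plot asymmetry
#'
#' Tests whether effect sizes drift systematically with their own precision,
#' the funnel-plot signature of publication bias. Two classical variants are
#' provided:
#'
#' * `"se_meta_regression"` (default): a fixed-effect weighted meta-regression
#'   of each Fisher's Z on its standard error, with inverse-variance weights
#'   and the sampling variances treated as known (no residual dispersion
#'   factor). The asymmetry term is the slope on the standard error.
#' * `"precision_regression"`: the original formulation — ordinary least
#'   squares of the standardized effect \eqn{Z_i/SE_i} on precision
#'   \eqn{1/SE_i}; the asymmetry term is the intercept.
#'
#' In both variants the test statistic is coefficient / SE with a two-sided
#' standard normal reference distribution.
#'
#' @param effects Data frame with columns `z` and `var` (see [to_z_effect()]).
#' @param variant Which regression form to use; see Details.
#' @return An object of class `egger_result`: list with `coefficient`,
#'   `se_coefficient`, `z_stat`, `p_value`, `k`, `variant`.
#' @examples
#' eff <- to_z_effect(data.frame(r = c(0.1, 0.4, 0.5, 0.2, 0.6),
#'                               n_years = c(30, 8, 6, 20, 5)))
#' egger_test(eff)
#' @export
egger_test <- function(effects,
                       variant = c("se_meta_regression",
                                   "precision_regression")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(effects))
  if (!all(c("z", "var") %in% names(effects))) {
    stop("`effects` must have columns `z` and `var`; see to_z_effect()",
         call. = FALSE)
  }
  k <- nrow(effects)
  if (k < 3) {
    stop("Egger's test needs at least 3 effects (k = ", k, ")", call. = FALSE)
  }
  se <- sqrt(effects$var)
  if (max(se) - min(se) < sqrt(.Machine$double.eps)) {
    stop("all sampling variances are identical: the asymmetry predictor is ",
         "collinear with the intercept and the test is undefined",
         call. = FALSE)
  }
  z <- effects$z
  if (variant == "se_meta_regression") {
    # known-variance WLS via the normal equations; cov(beta) = (X'WX)^{-1}
    X <- cbind(1, se)
    W <- 1 / effects$var
    XtWX <- crossprod(X, W * X)
    beta <- solve(XtWX, crossprod(X, W * z))
    cov_beta <- solve(XtWX)
    coefficient <- beta[2L]
    se_coefficient <- sqrt(cov_beta[2L, 2L])
  } else {
    fit <- stats::lm(I(z / se) ~ I(1 / se))
    cf <- stats::coef(summary(fit))
    coefficient <- cf["(Intercept)", "Estimate"]
    se_coefficient <- cf["(Intercept)", "Std. Error"]
  }
  z_stat <- coefficient / se_coefficient
  structure(
    list(coefficient = unname(coefficient),
         se_coefficient = unname(se_coefficient),
         z_stat = unname(z_stat),
         p_value = 2 * stats::pnorm(-abs(z_stat)),
         k = k, variant = variant),
    class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("Egger test of funnel asymmetry (%s, k = %d)\n",
              x$variant, x$k))
  cat(sprintf("  asymmetry term = %.4f (SE %.4f), z = %.3f, p = %.4g\n",
              x$coefficient, x$se_coefficient, x$z_stat, x$p_value))
  invisible(x)
}

#' Egger tests for every analysis group of a dataset
#'
#' Runs [egger_test()] on each group of the season x process x predictor
#' partition (or any other grouping). Groups with fewer than `min_k` effects
#' are skipped with a warning — too few effects leave no residual degrees of
#' freedom worth testing.
#'
#' @param ds A `phenometa_dataset` or data frame of validated effect records.
#' @param by Grouping fields passed to [partition()].
#' @param variant Passed to [egger_test()].
#' @param min_k Minimum group size to test (default 3).
#' @return Data frame with one row per tested group: grouping columns,
#'   dataset label, `k`, `coefficient`, `se_coefficient`, `z_stat`, `p_value`.
#' @export
egger_all <- function(ds, by = c("season", "process", "predictor"),
                      variant = c("se_meta_regression",
                                  "precision_regression"),
                      min_k = 3) {
  variant <- match.arg(variant)
  records <- if (inherits(ds, "phenometa_dataset")) ds$records else ds
  label <- if (inherits(ds, "phenometa_dataset")) ds$label else NA_character_
  if (!all(c("z", "var") %in% names(records))) {
    records <- to_z_effect(records)
  }
  groups <- partition(records, by)
  rows <- list()
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (nrow(g) < min_k) {
      warning("group '", nm, "' has fewer than ", min_k,
              " effects; Egger test skipped", call. = FALSE)
      next
    }
    res <- egger_test(g, variant = variant)
    meta <- g[1, by, drop = FALSE]
    rownames(meta) <- NULL
    rows[[nm]] <- cbind(meta, dataset = label,
                        data.frame(k = res$k, coefficient = res$coefficient,
                                   se_coefficient = res$se_coefficient,
                                   z_stat = res$z_stat,
                                   p_value = res$p_value,
                                   variant = res$variant))
  }
  if (length(rows) == 0) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
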