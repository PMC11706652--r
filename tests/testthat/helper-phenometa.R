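# Shared fixtures and independent oracles for the phenometa test suite.

# Build a minimal validated effect-record table; any field can be overridden
# with a vector recycled to `n`.
make_records <- function(n = 1, ...) {
  defaults <- list(
    study_id = "S1",
    effect_id = sprintf("E%03d", seq_len(n)),
    species = "sp1",
    season = "spring",
    process = "spawning",
    system_type = "lentic",
    predictor = "temperature",
    r = 0.3,
    n_years = 10L,
    phenology_metric = "peak spawning date",
    predictor_metric = "mean water temperature")
  override <- list(...)
  for (nm in names(override)) defaults[[nm]] <- override[[nm]]
  do.call(data.frame,
          c(lapply(defaults, rep_len, n), stringsAsFactors = FALSE))
}

# ZEffect table straight from (r, n_years) pairs.
make_zeff <- function(r, n_years) {
  to_z_effect(data.frame(r = r, n_years = n_years))
}

# Independent weighted-least-squares oracle via the normal equations, with
# coefficient covariance for known variances: (X'WX)^{-1}.
wls_oracle <- function(X, w, y) {
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * y))
  list(beta = drop(beta), cov = solve(XtWX))
}

# Ordinary-least-squares oracle with the usual residual-variance covariance.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (length(y) - ncol(X))
  list(beta = drop(beta), cov = s2 * solve(XtX))
}
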