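test_that("compute_range is max minus min over observed years", {
  rng <- compute_range(c(100, 110, 95, 120))
  expect_equal(rng$range_days, 25)
  expect_equal(rng$n_years, 4)
  expect_equal(compute_range(rep(140, 6))$range_days, 0)
  # n_years counts observations, not the calendar span
  expect_equal(compute_range(c(100, 101, 99, 100, 102))$n_years, 5)
  expect_error(compute_range(c(100, 110, 95)), "at least 4")
})

test_that("winter-boundary spawning dates are unwrapped before the range", {
  expect_equal(compute_range(c(360, 5, 350, 355))$range_days, 20)
  # without unwrapping the same series would look like a 355-day range
  expect_equal(compute_range(c(360, 5, 350, 355), unwrap = FALSE)$range_days,
               355)
  # ordinary mid-year series are untouched
  expect_equal(compute_range(c(100, 110, 95, 120), unwrap = TRUE)$range_days,
               compute_range(c(100, 110, 95, 120), unwrap = FALSE)$range_days)
})

test_that("compute_ranges aggregates per population and logs exclusions", {
  series <- data.frame(
    population_id = rep(c("p1", "p2"), c(5, 3)),
    season = rep(c("spring", "autumn"), c(5, 3)),
    year = c(2001:2005, 2001:2003),
    day_of_year = c(100, 110, 95, 120, 105, 280, 285, 290))
  out <- compute_ranges(series)
  expect_equal(nrow(out), 1)
  expect_equal(out$range_days, 25)
  expect_equal(out$n_years, 5)
  excl <- attr(out, "excluded")
  expect_equal(excl$population_id, "p2")
  expect_match(excl$reason, "minimum is 4")

  # ISO dates are converted to day-of-year
  iso <- data.frame(population_id = "p1", season = "spring",
                    year = c(2001:2003, 2005),  # non-leap years only
                    date = c("2001-04-10", "2002-04-20", "2003-04-05",
                             "2005-04-30"))
  expect_equal(compute_ranges(iso)$range_days, 25)
})

test_that("iqr_screen applies the Tukey fence under the type-7 quantile", {
  recs <- data.frame(range_days = c(10, 12, 14, 16, 100))
  out <- iqr_screen(recs)
  # Q1 = 12, Q3 = 16, upper fence 22
  expect_equal(unname(out$fences), c(12 - 6, 16 + 6))
  expect_equal(out$removed$range_days, 100)
  expect_equal(nrow(out$kept), 4)

  allsame <- data.frame(range_days = rep(20, 6))
  expect_equal(nrow(iqr_screen(allsame)$removed), 0)

  # brute-force fence check on tightly clustered data
  set.seed(9)
  unif <- data.frame(range_days = runif(50, 10, 20))
  scr <- iqr_screen(unif)
  q <- quantile(unif$range_days, c(0.25, 0.75), names = FALSE)
  expect_true(all(unif$range_days <= q[2] + 1.5 * diff(q)))
  expect_equal(nrow(scr$removed), 0)

  expect_error(iqr_screen(data.frame(range_days = 1:3)), "at least 4")
})

test_that("a noiseless additive design is recovered exactly", {
  dur <- rep(c(5, 10, 20, 40), 4)
  season <- rep(c("autumn", "spring"), each = 8)
  recs <- data.frame(season = season, n_years = dur,
                     range_days = 5 + 0.5 * dur + 10 * (season == "spring"))
  res <- suppressWarnings(fit_ancova(recs))
  expect_equal(unname(res$coefficients[1:3, "Estimate"]), c(5, 0.5, 10),
               tolerance = 1e-8)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  # EMMs are model predictions at the grand-mean duration
  expect_equal(res$emm$emmean,
               5 + 0.5 * mean(dur) + 10 * (res$emm$season == "spring"),
               tolerance = 1e-10)
})

test_that("EMMs match a brute-force least-squares oracle on random designs", {
  set.seed(66)
  for (i in 1:20) {
    n <- sample(12:30, 1)
    season <- sample(c("autumn", "spring"), n, replace = TRUE)
    if (length(unique(season)) < 2) season[1:2] <- c("autumn", "spring")
    dur <- sample(5:50, n, replace = TRUE)
    y <- 8 + 0.4 * dur + 6 * (season == "spring") + rnorm(n, 0, 5)
    recs <- data.frame(season = season, n_years = dur, range_days = y)
    res <- fit_ancova(recs)
    X <- cbind(1, dur, season == "spring")
    if (!res$dropped_interaction) X <- cbind(X, dur * (season == "spring"))
    o <- ols_oracle(X, y)
    gm <- mean(dur)
    x_a <- c(1, gm, 0, if (!res$dropped_interaction) 0)
    x_s <- c(1, gm, 1, if (!res$dropped_interaction) gm)
    expect_equal(res$emm$emmean[res$emm$season == "autumn"],
                 sum(x_a * o$beta), tolerance = 1e-8)
    expect_equal(res$emm$emmean[res$emm$season == "spring"],
                 sum(x_s * o$beta), tolerance = 1e-8)
    expect_equal(res$emm$SE[res$emm$season == "spring"],
                 sqrt(drop(t(x_s) %*% o$cov %*% x_s)), tolerance = 1e-8)
  }
})

test_that("balanced designs give EMM differences equal to raw mean gaps", {
  set.seed(13)
  dur <- rep(sample(5:40, 8), 2)
  season <- rep(c("autumn", "spring"), each = 8)
  y <- 10 + 0.3 * dur + 7 * (season == "spring") + rnorm(16, 0, 3)
  res <- fit_ancova(data.frame(season = season, n_years = dur,
                               range_days = y))
  raw_gap <- mean(y[season == "spring"]) - mean(y[season == "autumn"])
  emm_gap <- diff(res$emm$emmean[order(res$emm$season)])  # spring - autumn
  expect_equal(unname(emm_gap), raw_gap, tolerance = 1e-8)
})

test_that("season encoding only flips the contrast sign", {
  set.seed(21)
  recs <- data.frame(
    season = rep(c("autumn", "spring"), each = 10),
    n_years = sample(5:40, 20, replace = TRUE))
  recs$range_days <- 10 + 0.3 * recs$n_years +
    5 * (recs$season == "spring") + rnorm(20, 0, 4)
  a <- fit_ancova(recs)
  relab <- transform(recs, season = ifelse(season == "spring", "a_spring",
                                           "z_autumn"))
  b <- fit_ancova(relab)
  expect_equal(sort(a$emm$emmean), sort(b$emm$emmean), tolerance = 1e-10)
  expect_equal(a$season_contrast_p, b$season_contrast_p, tolerance = 1e-10)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-12)
})

test_that("degenerate ANCOVA inputs fail loudly", {
  one_season <- data.frame(season = "spring", n_years = c(5, 10, 20, 30),
                           range_days = c(10, 20, 30, 40))
  expect_error(fit_ancova(one_season), "both")
  flat <- data.frame(season = rep(c("spring", "autumn"), 4),
                     n_years = 10, range_days = rnorm(8))
  expect_error(fit_ancova(flat), "distinct")
})

test_that("slope estimates are unbiased on noisy synthetic range data", {
  set.seed(44)
  true_slope <- 0.5
  slopes <- replicate(200, {
    dur <- sample(5:50, 60, replace = TRUE)
    season <- rep(c("autumn", "spring"), 30)
    y <- 5 + true_slope * dur + 8 * (season == "spring") + rnorm(60, 0, 5)
    fit_ancova(data.frame(season = season, n_years = dur,
                          range_days = y))$coefficients["n_years", "Estimate"]
  })
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - true_slope), 2 * mc_se + 1e-8)
})
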