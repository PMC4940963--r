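test_that("KM product-limit matches hand computation and handles censoring", {
  km <- km_curve(c(10, 20, 30), horizon = Inf)
  # survival after 20 = (1 - 1/3)(1 - 1/2) = 1/3
  expect_equal(km_coverage_at(km, 25), 2 / 3)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: coverage identically 0
  km0 <- km_curve(c(100, 200), observed = c(FALSE, FALSE))
  expect_equal(km_coverage_at(km0, c(50, 150, 300)), c(0, 0, 0))
  # events past the horizon are administratively censored at it
  km1 <- km_curve(c(100, 400), horizon = 365)
  expect_equal(km1$time, 100)
  expect_equal(km1$survival, 0.5)
  # censoring at an event time keeps the censored unit at risk for it
  km2 <- km_curve(c(10, 10, 20), observed = c(TRUE, FALSE, TRUE),
                  horizon = Inf)
  expect_equal(km2$n_risk, c(3L, 1L))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_error(km_curve(numeric(0)), "empty")
})

test_that("with zero censoring KM coverage equals the ECDF everywhere", {
  set.seed(91)
  for (i in 1:20) {
    x <- sample(0:365, 60, replace = TRUE)
    km <- km_curve(x, horizon = 365)
    grid <- 0:365
    expect_equal(km_coverage_at(km, grid), stats::ecdf(x)(grid))
  }
})

test_that("KM invariants hold on random censored datasets, matching survival::survfit", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    age <- sample(0:400, n, replace = TRUE)
    obs <- stats::runif(n) < 0.8
    km <- km_curve(age, obs, horizon = 365)
    expect_true(all(diff(c(1, km$survival)) <= 1e-12))
    expect_true(all(km$coverage >= 0 & km$coverage <= 1))
    expect_true(all(diff(km$coverage) >= -1e-12))
    expect_true(all(diff(km$n_risk) <= 0))
    # cross-check against the reference implementation
    a2 <- pmin(age, 365)
    o2 <- obs & age <= 365
    sf <- survival::survfit(survival::Surv(a2, o2) ~ 1)
    ref <- summary(sf, times = km$time)$surv
    expect_lt(max(abs(km$survival - ref)), 1e-10)
  }
})

test_that("log-rank test agrees with survival::survdiff and is label-invariant", {
  set.seed(23)
  for (i in 1:25) {
    g <- sample(2:3, 1)
    n <- 40 * g
    age <- sample(1:300, n, replace = TRUE)
    obs <- stats::runif(n) < 0.85
    grp <- sample(letters[1:g], n, replace = TRUE)
    while (length(unique(grp)) < g) grp <- sample(letters[1:g], n, replace = TRUE)
    res <- logrank_test(age, obs, grp)
    ref <- survival::survdiff(survival::Surv(age, obs) ~ grp)
    expect_equal(res$statistic, ref$chisq, tolerance = 1e-8)
    expect_equal(res$df, g - 1L)
    # invariant to relabeling groups
    relab <- c(a = "z", b = "y", c = "x")[grp]
    expect_equal(logrank_test(age, obs, relab)$statistic, res$statistic,
                 tolerance = 1e-8)
  }
})

test_that("log-rank degenerate and error cases", {
  # two identical groups: statistic 0, p = 1
  age <- rep(c(10, 20, 30, 40), 2)
  grp <- rep(c("a", "b"), each = 4)
  res <- logrank_test(age, rep(TRUE, 8), grp)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(logrank_test(1:5, rep(TRUE, 5), rep("a", 5)), "two groups")
  expect_error(logrank_test(1:4, rep(FALSE, 4), rep(c("a", "b"), 2)),
               "at least one event")
})

test_that("median_iqr follows the closest-ranks interpolation rule", {
  expect_equal(unname(median_iqr(c(1, 6, 14))["median"]), 6)
  expect_equal(unname(median_iqr(42)), c(42, 42, 42))
  set.seed(5)
  for (i in 1:30) {
    x <- sample(0:365, sample(1:50, 1), replace = TRUE)
    expect_equal(unname(median_iqr(x)),
                 unname(stats::quantile(x, c(0.5, 0.25, 0.75), type = 7)))
  }
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("Mood's median test: identity, closed form, degenerate input", {
  same <- list(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(suppressWarnings(mood_median_test(same))$p_value, 1)
  # fully separated groups: 2x2 closed form n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d))
  res <- suppressWarnings(mood_median_test(list(1:50, 51:100)))
  expect_equal(res$statistic, 100)
  expect_equal(res$df, 1L)
  # all pooled values identical: flagged, p = 1
  res <- mood_median_test(list(rep(7, 5), rep(7, 8)))
  expect_equal(res$p_value, 1)
  expect_match(res$note, "degenerate")
  expect_error(mood_median_test(list(1:3)), "two groups")
})

test_that("Pearson chi-square of independence: closed form and symmetries", {
  expect_equal(chisq_independence(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chisq_independence(rbind(c(10, 10), c(10, 10)))$p_value, 1)
  # 2x2 closed form: 80*(900-100)^2/40^4 = 20
  res <- chisq_independence(rbind(c(30, 10), c(10, 30)))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)
  tab <- rbind(c(12, 5, 9), c(7, 14, 3))
  res <- suppressWarnings(chisq_independence(tab))
  perm <- suppressWarnings(chisq_independence(tab[2:1, c(3, 1, 2)]))
  expect_equal(perm$statistic, res$statistic)
  expect_equal(res$statistic,
               suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic,
               ignore_attr = TRUE)
  expect_warning(chisq_independence(rbind(c(2, 3), c(4, 1))), "below 5")
  expect_error(chisq_independence(rbind(c(0, 0), c(4, 1))), "margin")
})

test_that("km_age_samples builds administrative-censoring samples", {
  cls <- data.frame(child_id = c("a", "b", "c"),
                    age_MV = c(200L, 400L, NA))
  s <- km_age_samples(cls, "MV", horizon = 365)
  expect_equal(s$age, c(200, 365, 365))
  expect_equal(s$observed, c(TRUE, FALSE, FALSE))
  expect_error(km_age_samples(cls, "BCG"), "no such dose")
})
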