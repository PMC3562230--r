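test_that("KM with no censoring equals the empirical survival function", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$curves$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$medians$median, 2)
  set.seed(31)
  t2 <- stats::rexp(200)
  km2 <- km_estimate(t2, rep(1, 200))
  emp <- vapply(km2$curves$time, function(u) mean(t2 > u), numeric(1))
  expect_equal(km2$curves$surv, emp, tolerance = 1e-12)
})

test_that("all-censored data keep survival at 1 with median not reached", {
  km <- km_estimate(c(5, 8, 12), c(0, 0, 0))
  expect_equal(nrow(km$curves), 0L)
  expect_true(is.na(km$medians$median))
  expect_equal(format_median_survival(km$medians$median), "NR")
  expect_equal(format_median_survival(24.3), "24.3")
})

test_that("the product-limit estimator matches a hand-computed worked case", {
  tm <- c(6, 6, 7, 9, 10, 12); ev <- c(1, 0, 1, 0, 1, 1)
  km <- km_estimate(tm, ev)
  oracle <- km_hand(tm, ev)
  expect_equal(km$curves$time, oracle$time)
  expect_equal(km$curves$surv, oracle$surv, tolerance = 1e-12)
  expect_equal(km$curves$surv, c(5 / 6, 0.625, 0.3125, 0), tolerance = 1e-12)
  expect_equal(km$medians$median, 10)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank is null on duplicated groups and invariant to relabeling and time shifts", {
  set.seed(8)
  tm <- stats::rexp(60); ev <- stats::rbinom(60, 1, 0.7)
  dup <- logrank_test(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 60))
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
  expect_equal(dup$p.value, 1, tolerance = 1e-9)
  g <- rep(c("a", "b"), 30)
  r1 <- logrank_test(tm, ev, g)
  r2 <- logrank_test(tm, ev, ifelse(g == "a", "z", "y"))
  r3 <- logrank_test(tm + 7, ev, g)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$statistic, r3$statistic)
  expect_error(logrank_test(tm, ev, rep("a", 60)), ">= 2 groups")
})

test_that("log-rank detects a hazard ratio of 2 at 200 per arm", {
  rejections <- sum(vapply(1:30, function(s) {
    set.seed(s)
    tm <- c(stats::rexp(200, 1), stats::rexp(200, 2))
    grp <- rep(c("a", "b"), each = 200)
    logrank_test(tm, rep(1, 400), grp)$p.value < 0.05
  }, logical(1)))
  expect_gte(rejections / 30, 0.8)
})

test_that("Cox scaling identity: per-10-unit RR is the per-unit RR to the tenth power", {
  set.seed(12)
  n <- 300
  d <- data.frame(time = stats::rexp(n), event = stats::rbinom(n, 1, 0.8),
                  age = stats::rnorm(n, 60, 12))
  d$age10 <- d$age / 10
  f1 <- cox_fit(d, "time", "event", "age", mode = "univariable")
  f10 <- cox_fit(d, "time", "event", "age10", mode = "univariable")
  expect_equal(f10$rr, f1$rr^10, tolerance = 1e-8)
})

test_that("Cox recovers a binary log-HR of 0.6 and respects the inclusion rule", {
  cover <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 500
    x <- stats::rbinom(n, 1, 0.5)
    tm <- stats::rexp(n, exp(0.6 * x))
    cens <- stats::quantile(tm, 0.6)  # ~60% events
    d <- data.frame(time = pmin(tm, cens), event = as.integer(tm <= cens), x = x)
    f <- cox_fit(d, "time", "event", "x", mode = "univariable")
    abs(f$coef - 0.6) <= 1.96 * f$se
  }, logical(1))
  expect_gte(mean(cover), 0.8)

  # multivariable mode keeps only covariates passing the univariable screen
  set.seed(77)
  n <- 400
  x <- stats::rbinom(n, 1, 0.5); z <- stats::rnorm(n)
  tm <- stats::rexp(n, exp(0.8 * x))
  d <- data.frame(time = tm, event = 1L, x = x, noise = z)
  f <- suppressWarnings(cox_fit(d, "time", "event", c("x", "noise")))
  multi <- f[f$mode == "multivariable", ]
  expect_true("x" %in% multi$covariate)
  uni_noise <- f[f$mode == "univariable" & f$covariate == "noise", ]
  if (uni_noise$p > 0.05) expect_false("noise" %in% multi$covariate)
  expect_error(cox_fit(d[1:8, ], "time", "event", "x"), "fewer than 10 events")
  expect_error(cox_fit(transform(d, x = 1), "time", "event", "x"), "constant")
})

test_that("subgroup analysis finds an effect confined to a minority subgroup", {
  set.seed(5)
  n <- 600
  sub <- stats::runif(n) < 0.18             # minority subgroup
  status <- ifelse(stats::runif(n) < 0.5, "positive", "negative")
  hr <- ifelse(sub & status == "positive", 2.8, 1)
  d <- data.frame(
    dpm_status = status,
    dpm_class = ifelse(status == "positive", "low", "negative"),
    os_months = stats::rexp(n, hr * log(2) / 30),
    os_event = 1L
  )
  inside <- suppressWarnings(
    subgroup_survival(d, "os_months", "os_event", subset = sub))
  overall <- subgroup_survival(d, "os_months", "os_event")
  expect_lt(inside$logrank$p.value, 0.05)
  expect_gt(overall$logrank$p.value, inside$logrank$p.value)
  expect_error(subgroup_survival(d, "os_months", "os_event",
                                 subset = rep(FALSE, n)), "empty subgroup")
  one_arm <- d[d$dpm_status == "positive", ]
  expect_error(subgroup_survival(one_arm, "os_months", "os_event"),
               "single dPM arm")
  expect_warning(
    subgroup_survival(d[c(which(sub & status == "positive")[1:5],
                          which(status == "negative")[1:40]), ],
                      "os_months", "os_event"),
    "too small")
})

test_that("improving every subject's time never decreases the KM median", {
  set.seed(19)
  tm <- stats::rexp(80, 1 / 20); ev <- stats::rbinom(80, 1, 0.7)
  m1 <- km_estimate(tm, ev)$medians$median
  m2 <- km_estimate(tm * 1.5 + 1, ev)$medians$median
  expect_gte(ifelse(is.na(m2), Inf, m2), ifelse(is.na(m1), Inf, m1))
})
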