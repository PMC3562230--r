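test_that("continuity-corrected chi-square reproduces the published cohort p-values", {
  npm1 <- matrix(c(90, 147, 160, 154), 2, byrow = TRUE)
  res <- association_test(npm1, "yates")
  expect_equal(res$statistic, 8.665, tolerance = 1e-3)
  expect_equal(round(res$p.value, 3), 0.003)
  tet2 <- matrix(c(10, 48, 21, 34), 2, byrow = TRUE)
  res2 <- association_test(tet2, "yates")
  expect_equal(res2$statistic, 5.211, tolerance = 1e-3)
  expect_equal(round(res2$p.value, 2), 0.02)
  # no association
  expect_equal(association_test(matrix(5, 2, 2), "yates")$p.value, 1)
})

test_that("Fisher's exact test agrees with brute-force hypergeometric enumeration", {
  set.seed(42)
  tables <- c(
    list(matrix(c(1, 9, 11, 3), 2), matrix(c(0, 10, 12, 2), 2),
         matrix(c(5, 0, 1, 4), 2), matrix(c(2, 3, 6, 4), 2)),
    replicate(30, {
      n <- sample(8:40, 1)
      a <- stats::rmultinom(1, n, stats::runif(4, 0.05, 1))
      matrix(a, 2)
    }, simplify = FALSE)
  )
  for (tab in tables) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(association_test(tab, "fisher")$p.value,
                 fisher_enumeration_p(tab), tolerance = 1e-9)
  }
})

test_that("Pearson chi-square approaches Fisher on balanced well-filled tables", {
  set.seed(9)
  for (i in 1:10) {
    # balanced near-independent tables with large, well-filled cells
    base <- sample(150:400, 1)
    d <- sample(-8:8, 4, replace = TRUE)
    tab <- matrix(base + d, 2)
    pf <- association_test(tab, "fisher")$p.value
    pp <- association_test(tab, "pearson")$p.value
    expect_lt(abs(pp - pf) / pf, 0.10)
  }
})

test_that("degenerate and symmetric table behaviour", {
  expect_warning(res <- association_test(matrix(c(0, 0, 5, 7), 2), "yates"),
                 "zero margin")
  expect_equal(res$p.value, 1)
  tab <- matrix(c(12, 5, 7, 20), 2)
  swapped <- tab[2:1, 2:1]
  for (m in c("yates", "pearson", "fisher"))
    expect_equal(association_test(tab, m)$p.value,
                 association_test(swapped, m)$p.value)
  expect_error(association_test(matrix(c(1, 2, 3, -1), 2)), "non-negative")
})

test_that("association tables use pairwise-complete denominators and published fractions", {
  # cohort reconstructed from printed frequencies: NPM1 90/237 mut in
  # dPM-positive vs 160/314 in dPM-negative
  cohort <- data.frame(
    dpm_status = c(rep("positive", 237), rep("negative", 314), rep("positive", 30)),
    dpm_class = NA_character_,
    npm1 = c(rep("mut", 90), rep("wt", 147), rep("mut", 160), rep("wt", 154),
             rep(NA, 30)),
    stringsAsFactors = FALSE
  )
  res <- build_association_table(cohort, "npm1", "status")
  expect_equal(unname(res$table), matrix(c(90, 160, 147, 154), 2))
  expect_equal(res$n, 551)  # unknowns excluded, not cohort size
  expect_equal(round(100 * unname(res$fractions), 1), c(38.0, 51.0))
  expect_equal(round(res$test$p.value, 3), 0.003)
})

test_that("low-vs-high class comparison reproduces the published NPM1 split", {
  cohort <- data.frame(
    dpm_status = "positive",
    dpm_class = c(rep("low", 143), rep("high", 94)),
    npm1 = c(rep("mut", 62), rep("wt", 81), rep("mut", 28), rep("wt", 66)),
    stringsAsFactors = FALSE
  )
  res <- build_association_table(cohort, "npm1", "class", method = "fisher")
  expect_equal(round(100 * unname(res$fractions), 1), c(43.4, 29.8))
  expect_equal(round(res$test$p.value, 2), 0.04)
})

test_that("ratio comparison recovers generator group means and separates extremes", {
  # group parameters from the published NPM1 row (zero-truncated normals)
  g <- generate_ratio_groups(n = c(301, 250), mean = c(295.4, 158.2),
                             sd = c(434.9, 295.2), seed = 21)
  cohort <- data.frame(ratio = g$ratio,
                       npm1 = ifelse(g$group == "g1", "wt", "mut"))
  res <- ratio_by_group(cohort, "npm1")
  # closed-form mean of max(0, N(mu, sigma)): mu Phi(mu/s) + s phi(mu/s)
  cens_mean <- function(mu, s) mu * stats::pnorm(mu / s) + s * stats::dnorm(mu / s)
  truth <- c(mut = cens_mean(158.2, 295.2), wt = cens_mean(295.4, 434.9))
  for (grp in c("mut", "wt")) {
    row <- res$summary[res$summary$group == grp, ]
    expect_lt(abs(row$mean - truth[[grp]]), 2 * row$sd / sqrt(row$n))
  }
  # identical groups: p near 1; complete separation: p tiny
  same <- data.frame(ratio = rep(c(100, 200, 300), 4),
                     mk = rep(c("mut", "wt"), each = 6))
  expect_gt(ratio_by_group(same, "mk")$p.value, 0.99)
  apart <- data.frame(ratio = c(rep(0, 30), rep(2400, 30)),
                      mk = rep(c("wt", "mut"), each = 30))
  for (t in c("student", "welch", "mann_whitney"))
    expect_lt(ratio_by_group(apart, "mk", t)$p.value, 1e-6)
})

test_that("clinical comparison reports medians, ranges and sensible p-values", {
  set.seed(4)
  n <- 300
  pos <- rep(c(TRUE, FALSE), length.out = n)
  cohort <- data.frame(
    dpm_status = ifelse(pos, "positive", "negative"),
    age = stats::rnorm(n, 64, 10),
    wbc = stats::rlnorm(n, log(ifelse(pos, 30, 55)), 0.6),
    sex = sample(c("male", "female"), n, TRUE)
  )
  out <- clinical_comparison(cohort)
  expect_lt(out$p[out$variable == "wbc"], 0.05)
  expect_gt(out$p[out$variable == "age"], 0.05)
  expect_true("sex" %in% out$variable)
  # identical groups: all p near 1 and identical medians
  dup <- data.frame(dpm_status = rep(c("positive", "negative"), each = 50),
                    age = rep(stats::rnorm(50, 64, 10), 2))
  out2 <- clinical_comparison(dup)
  expect_gt(out2$p[1], 0.99)
  expect_identical(out2$negative[1], out2$positive[1])
  # single-sex cohort skips the sex test with a warning
  ss <- data.frame(dpm_status = rep(c("positive", "negative"), each = 10),
                   age = stats::rnorm(20, 60, 5), sex = "male")
  expect_warning(out3 <- clinical_comparison(ss), "single-sex")
  expect_false("sex" %in% out3$variable)
})

test_that("expression normalization is a control-gene percentage", {
  expect_equal(normalize_expression(50, 100), 50)
  expect_equal(normalize_expression(134.7, 100), 134.7)
  expect_equal(normalize_expression(0, 100), 0)
  expect_error(normalize_expression(10, 0), "positive")
})

test_that("Spearman correlation handles ties, nulls and perfect inversion", {
  expect_equal(spearman_correlation(1:10, 10:1)$rho, -1)
  expect_error(spearman_correlation(1:10, rep(2, 10)), "constant")
  expect_error(spearman_correlation(1:2, 2:1), "at least 3")
  # independent pairs at n = 120 rarely exceed |rho| = 0.25
  set.seed(123)
  hits <- sum(replicate(40, {
    abs(spearman_correlation(stats::rnorm(120), stats::rnorm(120))$rho) < 0.25
  }))
  expect_gte(hits / 40, 0.95)
})

test_that("FLT3-ITD ratio grouping is strict at 0.5", {
  g <- flt3_group(c(0, 0.3, 0.5, 0.51, 1.2, NA))
  expect_equal(as.character(g),
               c("neg_or_low_ratio", "neg_or_low_ratio", "neg_or_low_ratio",
                 "high_ratio", "high_ratio", "neg_or_low_ratio"))
})
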