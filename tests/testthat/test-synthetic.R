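test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- simulation_config(seed = 17, n_cases = 60)
  a <- generate_cohort(cfg)
  b <- generate_cohort(simulation_config(seed = 17, n_cases = 60))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- generate_cohort(simulation_config(seed = 18, n_cases = 60))
  expect_false(identical(a$wbc, c_$wbc))
  # and the caller's RNG stream is left untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_cohort(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("configured dPM-positive fraction is realized", {
  st <- generate_methylation_states(simulation_config(seed = 2, n_cases = 1000))
  expect_lt(abs(mean(st$dpm_positive) - 0.429), 0.04)
  st0 <- generate_methylation_states(
    simulation_config(seed = 3, n_cases = 200, dpm_positive_fraction = 0))
  expect_true(all(st0$distal < 0.15))
  expect_false(any(st0$dpm_positive))
})

test_that("the 5'-biased propensity shows in the site frequency profile", {
  cfg <- simulation_config(seed = 6, n_cases = 400)
  st <- generate_methylation_states(cfg)
  sc <- score_cohort(100 * st$distal)
  freq <- site_frequency_profile(sc)
  expect_gt(mean(freq[1:11]), mean(freq[12:24]))
  # flat propensities flatten the profile
  cfg_flat <- simulation_config(seed = 6, n_cases = 400,
                                propensity = rep(0.4, 24))
  stf <- generate_methylation_states(cfg_flat)
  ff <- site_frequency_profile(score_cohort(100 * stf$distal))
  expect_lt(abs(mean(ff[1:11]) - mean(ff[12:24])),
            4 * stats::sd(ff) / sqrt(11))
})

test_that("peak model round-trips the latent fraction and degrades gracefully with noise", {
  cfg0 <- simulation_config(seed = 9, n_cases = 5, peak_sd = 0)
  st <- generate_methylation_states(cfg0)
  pk <- generate_peak_table(st, cfg0)
  pct <- percent_methylation(pk$peak_height_C, pk$peak_height_T)
  m <- as.vector(st$distal)
  expect_equal(pct, 100 * m, tolerance = 1e-12)
  # 5% relative noise: mean absolute percent error below 5
  cfg1 <- simulation_config(seed = 9, n_cases = 420, peak_sd = 50)
  st1 <- generate_methylation_states(cfg1)
  pk1 <- generate_peak_table(st1, cfg1)
  pct1 <- percent_methylation(pk1$peak_height_C, pk1$peak_height_T)
  expect_lt(mean(abs(pct1 - 100 * as.vector(st1$distal))), 5)
})

test_that("cohort marker frequencies follow the dPM-conditional model", {
  # pooled over seeds for stable frequencies at the published effect sizes
  pooled <- do.call(rbind, lapply(1:4, function(s) {
    coh <- generate_cohort(simulation_config(seed = s))
    data.frame(pos = attr(coh, "truth")$states$dpm_positive,
               npm1 = coh$npm1, tet2 = coh$tet2)
  }))
  expect_lt(abs(mean(pooled$npm1[pooled$pos] == "mut", na.rm = TRUE) - 0.380), 0.05)
  expect_lt(abs(mean(pooled$npm1[!pooled$pos] == "mut", na.rm = TRUE) - 0.510), 0.05)
  # TET2 measured only in a subset, as configured
  expect_lt(mean(!is.na(pooled$tet2)), 0.3)
  # the configured NPM1 contrast is detectable in most cohorts
  hits <- sum(vapply(1:25, function(s) {
    coh <- generate_cohort(simulation_config(seed = 200 + s))
    coh$dpm_status <- factor(ifelse(attr(coh, "truth")$states$dpm_positive,
                                    "positive", "negative"))
    coh$dpm_class <- factor("negative", c("negative", "low", "high"))
    build_association_table(coh, "npm1", "status")$test$p.value < 0.05
  }, logical(1)))
  expect_gte(hits / 25, 0.8)
})

test_that("null marker contrasts produce uniform-looking p-values", {
  cfg <- simulation_config(seed = 1)
  cfg$mutation_model$npm1$p_mut_pos <- 0.45
  cfg$mutation_model$npm1$p_mut_neg <- 0.45
  ps <- vapply(1:20, function(s) {
    cfg$seed <- 500L + s
    coh <- generate_cohort(cfg)
    coh$dpm_status <- factor(ifelse(attr(coh, "truth")$states$dpm_positive,
                                    "positive", "negative"))
    coh$dpm_class <- factor("negative", c("negative", "low", "high"))
    build_association_table(coh, "npm1", "status")$test$p.value
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 4)   # ~binomial(20, 0.05) upper tail
  expect_gt(mean(ps), 0.25)
})

test_that("the truth ledger exposes every latent quantity", {
  coh <- generate_cohort(simulation_config(seed = 13, n_cases = 40))
  truth <- attr(coh, "truth")
  expect_s3_class(truth$states, "methylation_truth")
  expect_named(truth, c("states", "config"))
  expect_equal(dim(truth$states$distal), c(40L, 24L))
  expect_length(truth$states$core_pm, 40L)
  expect_length(truth$states$true_ratio, 40L)
  expect_s3_class(truth$config, "simulation_config")
})

test_that("invalid configurations are rejected with named fields", {
  expect_error(simulation_config(n_cases = 0), "n_cases")
  expect_error(simulation_config(dpm_positive_fraction = 1.2),
               "dpm_positive_fraction")
  expect_error(simulation_config(propensity = rep(2, 24)), "propensities")
  bad <- default_mutation_model()
  bad$npm1$p_mut_pos <- 1.5
  expect_error(simulation_config(mutation_model = bad), "npm1")
})

test_that("the end-to-end fixture writes a self-consistent reusable bundle", {
  cfg <- simulation_config(seed = 1, n_cases = 30)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- end_to_end_fixture(cfg, d1)
  p2 <- end_to_end_fixture(cfg, d2)
  for (f in names(p1)) {
    expect_true(file.exists(p1[[f]]))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))  # seed-reproducible
  }
  p3 <- end_to_end_fixture(simulation_config(seed = 2, n_cases = 30),
                           withr::local_tempdir())
  expect_false(identical(readLines(p1$cohort), readLines(p3$cohort)))
  # the bundle feeds the pipeline unmodified
  scores <- run_score(p1$peaks)
  expect_equal(nrow(scores), 30L)
  rep <- suppressWarnings(run_analyze(scores, p1$cohort))
  expect_s3_class(rep, "dpm_report")
  expect_equal(rep$frequency$n, 30L)
  expect_equal(rep$frequency$n_low + rep$frequency$n_high,
               rep$frequency$n_positive)
})
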