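#' Simulation configuration
#'
#' All parameters of the synthetic-cohort generator. The defaults encode the
#' cohort conditions this package models: 42.9% dPM-positive cases, a
#' 5'-biased per-site methylation propensity (the first 11 distal CpGs
#' methylate more often than the last 13), called-site intensities on
#' [15%, 100%] calibrated so the positive-case mean ratio is near 541 with a
#' right-skewed distribution, mutation frequencies conditional on dPM status,
#' clinical distributions around the published medians, expression inversely
#' rank-correlated with the ratio (Spearman rho -0.2), and exponential
#' survival with subgroup-restricted dPM effects.
#'
#' @param seed Integer RNG seed; the same seed reproduces the same cohort.
#' @param n_cases Number of synthetic patients (default 555).
#' @param dpm_positive_fraction Probability a case is dPM-positive
#'   (default 0.429).
#' @param propensity Per-site methylation propensity for positive cases,
#'   length 24 (default 0.62 for sites 1-11, 0.26 for 12-24).
#' @param case_dispersion_sd SD of the case-level lognormal propensity
#'   multiplier (mean 1); drives between-case overdispersion and the
#'   right-skew of the ratio (default 0.7).
#' @param intensity_shape Beta shape parameters for called-site methylation
#'   intensity, rescaled to [0.15, 1] (default c(1.6, 1.5)).
#' @param background_max Upper bound of sub-threshold intensities (default
#'   0.15, exclusive).
#' @param peak_scale Total Sanger peak height per site (default 1000 a.u.).
#' @param peak_sd Gaussian noise SD on each peak height (default 50).
#' @param core_pm_fraction Core-promoter MSP-methylated fraction
#'   (default 0.025).
#' @param mutation_model Per-marker list: `p_mut_pos`, `p_mut_neg`
#'   (dPM-conditional mutation probabilities) and `p_known` (fraction of
#'   cases with the marker measured).
#' @param clinical Clinical distribution parameters (medians by dPM group
#'   for WBC and blasts; age/Hb/platelet parameters; male fraction).
#' @param expression Expression model: `n_measured`, target Spearman `rho`,
#'   lognormal `median` and `sdlog`.
#' @param survival_model Exponential-hazard model: reference medians for OS
#'   and EFS, covariate hazard ratios, subgroup-restricted dPM hazard
#'   ratios, censoring median and administrative cap, and the fraction of
#'   cases with follow-up.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_cases = 555L,
    dpm_positive_fraction = 0.429,
    propensity = c(rep(0.62, 11), rep(0.26, 13)),
    case_dispersion_sd = 0.7,
    intensity_shape = c(1.6, 1.5),
    background_max = 0.15,
    peak_scale = 1000,
    peak_sd = 50,
    core_pm_fraction = 0.025,
    mutation_model = default_mutation_model(),
    clinical = default_clinical_model(),
    expression = list(n_measured = 120L, rho = -0.2,
                      median = 134.7, sdlog = 0.6),
    survival_model = default_survival_model()) {
  stopifnot_scalar_number(seed, "seed", -2^31, 2^31)
  stopifnot_scalar_number(n_cases, "n_cases", 1, Inf)
  stopifnot_scalar_number(dpm_positive_fraction, "dpm_positive_fraction", 0, 1)
  stopifnot_scalar_number(core_pm_fraction, "core_pm_fraction", 0, 1)
  if (any(propensity <= 0) || any(propensity > 1))
    stop("propensities must lie in (0, 1]", call. = FALSE)
  if (any(intensity_shape <= 0)) stop("invalid Beta shape", call. = FALSE)
  for (mk in names(mutation_model)) {
    m <- mutation_model[[mk]]
    probs <- c(m$p_mut_pos, m$p_mut_neg, m$p_known)
    if (any(probs < 0) || any(probs > 1))
      stop("invalid mutation model for ", mk, call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_cases = as.integer(n_cases),
    dpm_positive_fraction = dpm_positive_fraction,
    propensity = propensity, case_dispersion_sd = case_dispersion_sd,
    intensity_shape = intensity_shape, background_max = background_max,
    peak_scale = peak_scale, peak_sd = peak_sd,
    core_pm_fraction = core_pm_fraction,
    mutation_model = mutation_model, clinical = clinical,
    expression = expression, survival_model = survival_model
  ), class = "simulation_config")
}

#' Default dPM-conditional mutation model
#'
#' Mutation probabilities conditional on dPM status and per-marker measured
#' fractions, encoding the cohort frequencies this package models (e.g.
#' NPM1 38.0% in dPM-positive vs 51.0% in dPM-negative cases; TET2 17.2%
#' vs 38.2%; IDH2 R140 26.8% vs 14.7%; FLT3-ITD high allelic ratio 13.4%
#' vs 21.0%). `p_known` reflects that some markers were measured only in a
#' subset of cases.
#'
#' @return Named list of per-marker models.
#' @export
default_mutation_model <- function() {
  list(
    npm1          = list(p_mut_pos = 0.380, p_mut_neg = 0.510, p_known = 551 / 555),
    flt3_itd_high = list(p_mut_pos = 0.134, p_mut_neg = 0.210, p_known = 552 / 555),
    flt3_tkd      = list(p_mut_pos = 0.107, p_mut_neg = 0.107, p_known = 447 / 555),
    mll_ptd       = list(p_mut_pos = 0.136, p_mut_neg = 0.136, p_known = 552 / 555),
    runx1         = list(p_mut_pos = 0.280, p_mut_neg = 0.210, p_known = 467 / 555),
    asxl1         = list(p_mut_pos = 0.160, p_mut_neg = 0.160, p_known = 420 / 555),
    tet2          = list(p_mut_pos = 0.172, p_mut_neg = 0.382, p_known = 113 / 555),
    idh1_r132     = list(p_mut_pos = 0.092, p_mut_neg = 0.092, p_known = 382 / 555),
    idh2_r140     = list(p_mut_pos = 0.268, p_mut_neg = 0.147, p_known = 344 / 555),
    idh2_r172     = list(p_mut_pos = 0.029, p_mut_neg = 0.029, p_known = 345 / 555),
    dnmt3a        = list(p_mut_pos = 0.300, p_mut_neg = 0.440, p_known = 119 / 555)
  )
}

#' Default clinical distribution model
#' @return List of clinical distribution parameters.
#' @export
default_clinical_model <- function() {
  list(
    male_fraction = 0.528,
    age = list(mean = 64, sd = 13, min = 20, max = 90),
    wbc = list(median_pos = 34.6, median_neg = 50.9, sdlog = 1.0,
               min = 0.5, max = 400),
    hb = list(mean = 9.4, sd = 1.9, min = 2.8, max = 16.5),
    platelets = list(median = 96, sdlog = 0.7, min = 3, max = 950),
    bm_blasts = list(median_pos = 58, median_neg = 68.5, sd = 18,
                     min = 3, max = 99)
  )
}

#' Default survival model
#'
#' Exponential event times whose hazard multiplies covariate effects (age
#' per 10 years, WBC per 10 x 10^9/L, FLT3-ITD high ratio, NPM1, RUNX1).
#' The dPM effect is deliberately null overall and acts only inside the
#' FLT3-low and TET2-mutated subgroups, the structure the subgroup analyses
#' probe.
#'
#' @return List of survival model parameters.
#' @export
default_survival_model <- function() {
  list(
    os = list(reference_median = 40,
              hr_age_per10 = 1.49, hr_wbc_per10 = 1.06,
              hr_flt3_high = 1.55, hr_npm1 = 0.52, hr_runx1 = 1.75,
              hr_dpm_flt3low = 1.35, hr_dpm_tet2mut = 2.2),
    efs = list(reference_median = 16,
               hr_age_per10 = 1.34, hr_wbc_per10 = 1.06,
               hr_flt3_high = 1.74, hr_npm1 = 0.72, hr_runx1 = 1.56,
               hr_dpm_flt3low = 1.25, hr_dpm_tet2mut = 2.0),
    censor_median = 60, admin_cap = 84,
    followup_fraction = 435 / 555
  )
}

#' Generate latent per-case methylation states
#'
#' dPM-positive cases draw per-site methylation indicators from the
#' 5'-biased propensity vector (scaled by a case-level lognormal dispersion
#' factor, redrawn until at least one site methylates) and Beta intensities
#' on [`background_max`, 1]; negative cases and unmethylated sites draw
#' sub-threshold intensities below `background_max`. Core-promoter states
#' are binary with prevalence `core_pm_fraction`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed`.
#' @return List of class `methylation_truth`: `distal` (n x 24 matrix of
#'   methylation fractions), `core_pm` (logical), `dpm_positive` (logical),
#'   `true_ratio` (numeric, from the latent fractions).
#' @export
generate_methylation_states <- function(config = simulation_config(),
                                        seed = NULL) {
  with_seed(seed %||% config$seed, {
    n <- config$n_cases
    k <- length(config$propensity)
    bmax <- config$background_max
    positive <- stats::runif(n) < config$dpm_positive_fraction
    # background mass sits well below the call threshold so that peak noise
    # does not push unmethylated sites across it
    m <- matrix(stats::rbeta(n * k, 1.2, 12) * (bmax - 1e-9), n, k)
    sh <- config$intensity_shape
    sdl <- config$case_dispersion_sd
    for (i in which(positive)) {
      f <- exp(stats::rnorm(1, -sdl^2 / 2, sdl))
      p <- pmin(config$propensity * f, 0.95)
      meth <- stats::runif(k) < p
      while (!any(meth)) meth <- stats::runif(k) < p
      m[i, meth] <- bmax + (1 - bmax) * stats::rbeta(sum(meth), sh[1], sh[2])
    }
    colnames(m) <- paste0("cpg_", seq_len(k))
    rownames(m) <- sprintf("case_%04d", seq_len(n))
    core_pm <- stats::runif(n) < config$core_pm_fraction
    structure(list(
      distal = m, core_pm = core_pm, dpm_positive = positive,
      true_ratio = rowSums(100 * m * (m >= bmax))
    ), class = "methylation_truth")
  })
}

#' Generate a Sanger peak-height table from methylation states
#'
#' Per site, the cytosine peak is `peak_scale * m` and the thymine peak
#' `peak_scale * (1 - m)`, each with Gaussian noise truncated at 0; the
#' percent-methylation round trip recovers `100 * m` as the noise vanishes.
#'
#' @param states A `methylation_truth` (or bare n x k matrix of fractions).
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed + 1`.
#' @return Long data.frame: `case_id`, `site_index`, `peak_height_C`,
#'   `peak_height_T`.
#' @export
generate_peak_table <- function(states, config = simulation_config(),
                                seed = NULL) {
  m <- if (inherits(states, "methylation_truth")) states$distal else as.matrix(states)
  n <- nrow(m); k <- ncol(m)
  with_seed(seed %||% (config$seed + 1L), {
    noise_c <- stats::rnorm(n * k, 0, config$peak_sd)
    noise_t <- stats::rnorm(n * k, 0, config$peak_sd)
    data.frame(
      case_id = rep(rownames(m) %||% sprintf("case_%04d", seq_len(n)), times = k),
      site_index = rep(seq_len(k), each = n),
      peak_height_C = pmax(0, config$peak_scale * as.vector(m) + noise_c),
      peak_height_T = pmax(0, config$peak_scale * (1 - as.vector(m)) + noise_t),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete synthetic clinical cohort
#'
#' Draws mutation flags conditional on dPM status, clinical variables,
#' expression rank-correlated with the methylation ratio via a Gaussian
#' copula, and exponential survival times with subgroup-restricted dPM
#' hazard effects. Every latent parameter used by recovery tests is kept in
#' the `truth` attribute.
#'
#' @param config A [simulation_config()].
#' @param states Optional pre-generated `methylation_truth`; generated from
#'   `config` when missing.
#' @return Data.frame of class `synthetic_cohort`, one row per case, with
#'   attribute `truth` (the `methylation_truth` plus the config).
#' @export
generate_cohort <- function(config = simulation_config(), states = NULL) {
  if (is.null(states)) states <- generate_methylation_states(config)
  n <- config$n_cases
  pos <- states$dpm_positive
  ratio <- states$true_ratio
  with_seed(config$seed + 2L, {
    draw_marker <- function(mm) {
      p <- ifelse(pos, mm$p_mut_pos, mm$p_mut_neg)
      val <- ifelse(stats::runif(n) < p, "mut", "wt")
      val[stats::runif(n) >= mm$p_known] <- NA_character_
      val
    }
    mk <- lapply(config$mutation_model, draw_marker)
    # FLT3-ITD allelic ratio: high group > 0.5, additional low-ratio ITDs,
    # ITD-negative cases carry ratio 0
    itd_high <- !is.na(mk$flt3_itd_high) & mk$flt3_itd_high == "mut"
    itd_low <- !itd_high & stats::runif(n) < 0.12
    flt3_itd_ratio <- ifelse(itd_high, stats::runif(n, 0.51, 1.5),
                             ifelse(itd_low, stats::runif(n, 0.05, 0.5), 0))
    flt3_itd_ratio[is.na(mk$flt3_itd_high)] <- NA
    cl <- config$clinical
    rtrunc <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    age <- rtrunc(stats::rnorm(n, cl$age$mean, cl$age$sd), cl$age$min, cl$age$max)
    wbc_med <- ifelse(pos, cl$wbc$median_pos, cl$wbc$median_neg)
    wbc <- rtrunc(stats::rlnorm(n, log(wbc_med), cl$wbc$sdlog),
                  cl$wbc$min, cl$wbc$max)
    hb <- rtrunc(stats::rnorm(n, cl$hb$mean, cl$hb$sd), cl$hb$min, cl$hb$max)
    plt <- rtrunc(stats::rlnorm(n, log(cl$platelets$median), cl$platelets$sdlog),
                  cl$platelets$min, cl$platelets$max)
    blasts_med <- ifelse(pos, cl$bm_blasts$median_pos, cl$bm_blasts$median_neg)
    blasts <- rtrunc(stats::rnorm(n, blasts_med, cl$bm_blasts$sd),
                     cl$bm_blasts$min, cl$bm_blasts$max)
    sex <- ifelse(stats::runif(n) < cl$male_fraction, "male", "female")
    # expression: Gaussian copula on the rank of the true ratio. The ratio
    # is zero-inflated (all dPM-negative cases tie at 0), which attenuates
    # the realized Spearman coefficient; compensate with the closed-form
    # attenuation factor for a bottom-tied variable so the expression-ratio
    # Spearman targets `rho` in expectation.
    ex <- config$expression
    r_pearson <- copula_r_for_spearman(ex$rho, mean(ratio == 0))
    # latent score from a continuous ordering (ties in the thresholded ratio
    # broken by the underlying methylation burden) so it is a proper normal
    # score; the tie attenuation is then exactly the inverted quantity
    ord <- order(ratio, rowSums(states$distal))
    rk <- integer(n); rk[ord] <- seq_len(n)
    z_ratio <- stats::qnorm(rk / (n + 1))
    z_expr <- r_pearson * z_ratio +
      sqrt(1 - r_pearson^2) * stats::rnorm(n)
    expression_pct <- stats::qlnorm(stats::pnorm(z_expr),
                                    log(ex$median), ex$sdlog)
    measured <- sample.int(n) <= min(ex$n_measured, n)
    expression_pct[!measured] <- NA
    # survival: exponential hazards with covariate and subgroup effects
    sv <- config$survival_model
    tet2_mut <- !is.na(mk$tet2) & mk$tet2 == "mut"
    draw_endpoint <- function(par) {
      lambda0 <- log(2) / par$reference_median
      hr <- par$hr_age_per10^((age - cl$age$mean) / 10) *
        par$hr_wbc_per10^((wbc - 44) / 10) *
        ifelse(itd_high, par$hr_flt3_high, 1) *
        ifelse(!is.na(mk$npm1) & mk$npm1 == "mut", par$hr_npm1, 1) *
        ifelse(!is.na(mk$runx1) & mk$runx1 == "mut", par$hr_runx1, 1) *
        ifelse(pos & !itd_high, par$hr_dpm_flt3low, 1) *
        ifelse(pos & tet2_mut, par$hr_dpm_tet2mut, 1)
      stats::rexp(n, lambda0 * hr)
    }
    t_os <- draw_endpoint(sv$os)
    t_efs <- pmin(draw_endpoint(sv$efs), t_os)
    censor <- pmin(stats::rexp(n, log(2) / sv$censor_median), sv$admin_cap)
    os_months <- pmin(t_os, censor); os_event <- t_os <= censor
    efs_months <- pmin(t_efs, censor); efs_event <- t_efs <= censor
    has_fu <- stats::runif(n) < sv$followup_fraction
    os_months[!has_fu] <- NA; os_event[!has_fu] <- NA
    efs_months[!has_fu] <- NA; efs_event[!has_fu] <- NA
    cohort <- data.frame(
      case_id = rownames(states$distal),
      sex = sex, age = age, bm_blasts = blasts, wbc = wbc, hb = hb,
      platelets = plt,
      npm1 = mk$npm1, flt3_tkd = mk$flt3_tkd, mll_ptd = mk$mll_ptd,
      runx1 = mk$runx1, asxl1 = mk$asxl1, tet2 = mk$tet2,
      idh1_r132 = mk$idh1_r132, idh2_r140 = mk$idh2_r140,
      idh2_r172 = mk$idh2_r172, dnmt3a = mk$dnmt3a,
      flt3_itd_ratio = flt3_itd_ratio,
      expression_pct = expression_pct,
      os_months = os_months, os_event = os_event,
      efs_months = efs_months, efs_event = efs_event,
      stringsAsFactors = FALSE
    )
    structure(cohort, truth = list(states = states, config = config),
              class = c("synthetic_cohort", "data.frame"))
  })
}

#' Realized Spearman correlation of a bottom-tied Gaussian copula
#'
#' Large-n Spearman correlation between a continuous variable and a partner
#' whose bottom fraction `f` ties at its minimum (zero-inflation), when the
#' two are joined by a Gaussian copula with latent Pearson correlation `r`.
#' With `z` the tied variable's latent normal score, its normalized midrank
#' is `U = f/2` below `qnorm(f)` and `Phi(z)` above; the partner's rank is
#' `V = Phi(y)` with `E[V | z] = Phi(r z / sqrt(2 - r^2))`. The coefficient
#' is `cov(U, V) / sqrt(var(U) var(V))` with `var(U) = (1 - f^3)/12`,
#' evaluated by numerical integration. With `f = 0` this reduces to the
#' classic `(6/pi) asin(r/2)`.
#'
#' @param r Latent copula correlation in `(-1, 1)`.
#' @param f Tied (zero) fraction in `[0, 1)`.
#' @return Realized Spearman coefficient.
#' @export
spearman_given_copula_r <- function(r, f) {
  stopifnot_scalar_number(r, "r", -1 + 1e-12, 1 - 1e-12)
  stopifnot_scalar_number(f, "f", 0, 1 - 1e-9)
  q <- if (f > 0) stats::qnorm(f) else -Inf
  u_of_z <- function(z) ifelse(z < q, f / 2, stats::pnorm(z))
  ev_of_z <- function(z) stats::pnorm(r * z / sqrt(2 - r^2))
  integrand <- function(z) u_of_z(z) * ev_of_z(z) * stats::dnorm(z)
  euv <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-10)$value
  (euv - 0.25) / sqrt((1 - f^3) / 12 * 1 / 12)
}

# invert spearman_given_copula_r over r for a target Spearman coefficient
copula_r_for_spearman <- function(rho, f) {
  if (rho == 0) return(0)
  stats::uniroot(function(r) spearman_given_copula_r(r, f) - rho,
                 interval = c(-1 + 1e-9, 1 - 1e-9), tol = 1e-9)$root
}

#' Draw zero-truncated ratio groups directly
#'
#' Shortcut generator for statistics-only tests: per-group methylation
#' ratios drawn from a normal distribution truncated at 0 (matching the
#' published per-marker group summaries), bypassing the scoring chain.
#'
#' @param n Vector of group sizes.
#' @param mean,sd Per-group normal parameters (recycled).
#' @param seed Integer seed.
#' @return Data.frame: `group` (factor by position), `ratio`.
#' @export
generate_ratio_groups <- function(n, mean, sd, seed = 1L) {
  stopifnot(length(n) == length(mean), length(mean) == length(sd))
  with_seed(seed, {
    rows <- lapply(seq_along(n), function(i) {
      data.frame(group = paste0("g", i),
                 ratio = pmax(0, stats::rnorm(n[i], mean[i], sd[i])))
    })
    out <- do.call(rbind, rows)
    out$group <- factor(out$group)
    out
  })
}

#' Write a complete, self-consistent synthetic input bundle
#'
#' Generates the synthetic promoter reference (FASTA), U/M primer table
#' (TSV), peak-height table (CSV), wide percent table (CSV) and clinical
#' cohort table (CSV) into a directory that the scoring and analysis entry
#' points consume unmodified.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly; the generated objects as
#'   attribute `objects`.
#' @export
end_to_end_fixture <- function(config = simulation_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- synthetic_promoter_reference()
  assay <- design_msp_primers(ref)
  states <- generate_methylation_states(config)
  peaks <- generate_peak_table(states, config)
  cohort <- generate_cohort(config, states)
  paths <- list(
    reference = file.path(dir, "reference.fasta"),
    primers = file.path(dir, "primers.tsv"),
    peaks = file.path(dir, "peaks.csv"),
    percent = file.path(dir, "percent.csv"),
    cohort = file.path(dir, "cohort.csv")
  )
  write_promoter_fasta(ref, paths$reference, name = "synthetic_promoter")
  write_primer_tsv(assay, paths$primers)
  utils::write.csv(peaks, paths$peaks, row.names = FALSE)
  pct <- round(100 * states$distal, 2)
  utils::write.csv(data.frame(case_id = rownames(pct), pct,
                              stringsAsFactors = FALSE),
                   paths$percent, row.names = FALSE)
  utils::write.csv(cohort, paths$cohort, row.names = FALSE, na = "")
  invisible(structure(paths, objects = list(ref = ref, assay = assay,
                                            states = states, peaks = peaks,
                                            cohort = cohort)))
}
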