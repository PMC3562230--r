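#' Scoring configuration
#'
#' Parameters controlling per-CpG methylation calling and the distal-promoter
#' methylation (dPM) ratio classification.
#'
#' @param call_threshold Percent at or above which a CpG counts as methylated
#'   (inclusive); default 15.
#' @param positivity_min_sites Minimum number of called sites for dPM-positive
#'   status; default 1.
#' @param ratio_threshold_mode `"cohort_mean_of_positives"` (threshold is the
#'   mean ratio over dPM-positive cases) or `"fixed"`.
#' @param fixed_ratio_threshold Threshold used when mode is `"fixed"`; the
#'   published cohort value is 541.
#' @param tie_rule_at_threshold Class assigned when ratio equals the
#'   threshold: `"low"` (default) or `"high"`.
#' @param min_observed_fraction Cases with fewer observed sites than this
#'   fraction of the region's sites are reported unevaluable; default 0.5.
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(call_threshold = 15,
                           positivity_min_sites = 1,
                           ratio_threshold_mode = c("cohort_mean_of_positives", "fixed"),
                           fixed_ratio_threshold = 541,
                           tie_rule_at_threshold = c("low", "high"),
                           min_observed_fraction = 0.5) {
  stopifnot_scalar_number(call_threshold, "call_threshold", 1e-9, 100)
  stopifnot_scalar_number(positivity_min_sites, "positivity_min_sites", 1, Inf)
  structure(list(
    call_threshold = call_threshold,
    positivity_min_sites = as.integer(positivity_min_sites),
    ratio_threshold_mode = match.arg(ratio_threshold_mode),
    fixed_ratio_threshold = fixed_ratio_threshold,
    tie_rule_at_threshold = match.arg(tie_rule_at_threshold),
    min_observed_fraction = min_observed_fraction
  ), class = "scoring_config")
}

#' Percent methylation from Sanger C/T peak heights
#'
#' At a CpG site read on bisulfite-converted template, the cytosine peak
#' reports the methylated fraction and the thymine peak the unmethylated
#' fraction. Percent methylation is `100 * C / (C + T)`: a single cytosine
#' is 100% methylation, a single thymine no methylation, overlapping peaks
#' partial methylation.
#'
#' @param peak_c,peak_t Non-negative peak heights (vectorized).
#' @return Percent in `[0, 100]`; `NA` (with a warning) where both heights
#'   are zero — such observations are excluded downstream.
#' @export
percent_methylation <- function(peak_c, peak_t) {
  if (any(peak_c < 0, na.rm = TRUE) || any(peak_t < 0, na.rm = TRUE))
    stop("peak heights must be non-negative", call. = FALSE)
  tot <- peak_c + peak_t
  out <- ifelse(tot > 0, pmin(pmax(100 * peak_c / tot, 0), 100), NA_real_)
  if (anyNA(out[!is.na(tot)]) && any(tot == 0, na.rm = TRUE))
    warning("observations with both peak heights zero set to NA", call. = FALSE)
  out
}

#' Call a CpG site methylated
#'
#' A site is methylated when its methylation intensity reaches the call
#' threshold (inclusive; default 15%).
#'
#' @param percent Percent methylation in `[0, 100]` (vectorized; NA passed
#'   through).
#' @param config A [scoring_config()].
#' @return Logical vector.
#' @export
call_site <- function(percent, config = scoring_config()) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE))
    stop("percent must lie in [0, 100]", call. = FALSE)
  percent >= config$call_threshold
}

#' Distal-promoter methylation ratio
#'
#' The per-case score combining methylation intensity with the number of
#' methylated cytosines: the sum of percent methylation over called sites,
#' identically `methylated_count * mean(percent among called sites)`. Zero
#' when no site is called. Missing sites are excluded.
#'
#' @param percent Numeric vector of per-site percents for one case.
#' @param config A [scoring_config()].
#' @return Non-negative score (0 to 100 * number of sites).
#' @export
methylation_ratio <- function(percent, config = scoring_config()) {
  called <- call_site(percent, config)
  sum(percent[which(called)], na.rm = TRUE)
}

#' Score a cohort of per-CpG methylation profiles
#'
#' Accepts either a wide percent matrix (one row per case, one column per
#' CpG site, the supplementary-table dialect) or a long peak-height table
#' with columns `case_id`, `site_index`, `peak_height_C`, `peak_height_T`.
#' Computes per-site percents, applies the call threshold, and derives the
#' methylated count and methylation ratio per case.
#'
#' @param x Matrix/data.frame of percents (rows = cases) or long peak table.
#' @param config A [scoring_config()].
#' @return Object of class `dpm_scores`: a data.frame with columns `case_id`,
#'   `n_observed`, `methylated_count`, `ratio`, `evaluable`, carrying the
#'   percent and call matrices as attributes `percent` and `called`.
#' @export
score_cohort <- function(x, config = scoring_config()) {
  pm <- as_percent_matrix(x)
  if (nrow(pm) == 0L) stop("no cases to score", call. = FALSE)
  called <- call_site(pm, config)
  n_obs <- rowSums(!is.na(pm))
  count <- rowSums(called, na.rm = TRUE)
  ratio <- rowSums(pm * ifelse(is.na(called), FALSE, called), na.rm = TRUE)
  evaluable <- n_obs >= config$min_observed_fraction * ncol(pm)
  if (any(!evaluable))
    warning(sprintf("%d case(s) with <%d%% of sites observed are unevaluable",
                    sum(!evaluable), round(100 * config$min_observed_fraction)),
            call. = FALSE)
  out <- data.frame(
    case_id = rownames(pm),
    n_observed = as.integer(n_obs),
    methylated_count = as.integer(count),
    ratio = as.numeric(ratio),
    evaluable = evaluable,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(out, percent = pm, called = called, config = config,
            class = c("dpm_scores", "data.frame"))
}

# normalize score_cohort() input to a percent matrix with case rownames
as_percent_matrix <- function(x) {
  if (is.data.frame(x) &&
      all(c("case_id", "site_index", "peak_height_C", "peak_height_T") %in% names(x))) {
    pct <- percent_methylation(x$peak_height_C, x$peak_height_T)
    cases <- unique(x$case_id)
    sites <- sort(unique(x$site_index))
    pm <- matrix(NA_real_, length(cases), length(sites),
                 dimnames = list(as.character(cases), paste0("cpg_", sites)))
    pm[cbind(match(x$case_id, cases), match(x$site_index, sites))] <- pct
    return(pm)
  }
  pm <- as.matrix(x)
  if (!is.numeric(pm))
    stop("percent table must be numeric or a peak-height table with columns ",
         "case_id, site_index, peak_height_C, peak_height_T", call. = FALSE)
  if (any(pm < 0 | pm > 100, na.rm = TRUE))
    stop("percent values must lie in [0, 100]", call. = FALSE)
  if (is.null(rownames(pm))) rownames(pm) <- paste0("case_", seq_len(nrow(pm)))
  pm
}

#' Cohort ratio threshold
#'
#' The dichotomization threshold between lowly and highly methylated cases:
#' the arithmetic mean of the methylation ratio over dPM-positive cases
#' (published cohort value 541), or a fixed configured value.
#'
#' @param scores A `dpm_scores` object (or numeric vector of positive-case
#'   ratios).
#' @param config A [scoring_config()].
#' @return Single numeric threshold.
#' @export
cohort_threshold <- function(scores, config = scoring_config()) {
  if (config$ratio_threshold_mode == "fixed") {
    if (is.null(config$fixed_ratio_threshold))
      stop("fixed ratio threshold requested but not set", call. = FALSE)
    return(config$fixed_ratio_threshold)
  }
  ratios <- if (inherits(scores, "dpm_scores")) {
    scores$ratio[scores$methylated_count >= config$positivity_min_sites &
                   scores$evaluable]
  } else {
    as.numeric(scores)
  }
  if (length(ratios) == 0L)
    stop("no dPM-positive cases: cannot form a cohort threshold", call. = FALSE)
  mean(ratios)
}

#' Classify cases by dPM status and class
#'
#' Status is positive when at least `positivity_min_sites` CpGs are called
#' methylated. Positive cases with ratio below the threshold are `low`,
#' above it `high`; a ratio exactly at the threshold follows the configured
#' tie rule (default `low`). Negative cases have class `negative`.
#'
#' @param scores A `dpm_scores` object from [score_cohort()].
#' @param ratio_threshold Dichotomization threshold; default computed by
#'   [cohort_threshold()].
#' @param config A [scoring_config()].
#' @return `scores` with added columns `dpm_status` (`negative`/`positive`)
#'   and `dpm_class` (`negative`/`low`/`high`), plus attribute
#'   `ratio_threshold`.
#' @export
classify_cases <- function(scores, ratio_threshold = NULL,
                           config = attr(scores, "config") %||% scoring_config()) {
  stopifnot(inherits(scores, "dpm_scores"))
  if (is.null(ratio_threshold)) ratio_threshold <- cohort_threshold(scores, config)
  positive <- scores$methylated_count >= config$positivity_min_sites
  cls <- ifelse(!positive, "negative",
         ifelse(scores$ratio < ratio_threshold, "low",
         ifelse(scores$ratio > ratio_threshold, "high",
                config$tie_rule_at_threshold)))
  scores$dpm_status <- factor(ifelse(positive, "positive", "negative"),
                              levels = c("negative", "positive"))
  scores$dpm_class <- factor(cls, levels = c("negative", "low", "high"))
  attr(scores, "ratio_threshold") <- ratio_threshold
  scores
}

#' Per-site methylation frequency profile
#'
#' For the dPM-positive cases, how often each CpG site (5'->3') is called
#' methylated — the per-site frequency bar profile of the distal promoter.
#'
#' @param scores A classified or raw `dpm_scores` object.
#' @param positives_only Count only dPM-positive cases (default TRUE).
#' @param config A [scoring_config()].
#' @return Integer vector of per-site counts, one per CpG column.
#' @export
site_frequency_profile <- function(scores, positives_only = TRUE,
                                   config = attr(scores, "config") %||% scoring_config()) {
  stopifnot(inherits(scores, "dpm_scores"))
  called <- attr(scores, "called")
  keep <- if (positives_only) {
    scores$methylated_count >= config$positivity_min_sites
  } else rep(TRUE, nrow(scores))
  counts <- colSums(called[keep, , drop = FALSE], na.rm = TRUE)
  as.integer(counts)
}

#' Summarize a scored, classified cohort
#'
#' @param object A classified `dpm_scores` object.
#' @param ... Unused.
#' @return List with `n`, `n_positive`, `positive_fraction`, `mean_ratio`
#'   (positives), `ratio_threshold`, `n_low`, `n_high`, `low_fraction`,
#'   `high_fraction`, `max_methylated_count`.
#' @export
summary.dpm_scores <- function(object, ...) {
  if (is.null(object$dpm_status)) object <- classify_cases(object)
  pos <- object$dpm_status == "positive"
  list(
    n = nrow(object),
    n_positive = sum(pos),
    positive_fraction = mean(pos),
    mean_ratio = if (any(pos)) mean(object$ratio[pos]) else NA_real_,
    ratio_threshold = attr(object, "ratio_threshold"),
    n_low = sum(object$dpm_class == "low"),
    n_high = sum(object$dpm_class == "high"),
    low_fraction = if (any(pos)) sum(object$dpm_class == "low") / sum(pos) else NA_real_,
    high_fraction = if (any(pos)) sum(object$dpm_class == "high") / sum(pos) else NA_real_,
    max_methylated_count = max(object$methylated_count)
  )
}

#' @export
print.dpm_scores <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("dPM scoring: %d cases, %d positive (%.1f%%)\n",
              s$n, s$n_positive, 100 * s$positive_fraction))
  if (!is.null(s$ratio_threshold))
    cat(sprintf("  mean ratio (positives) %.1f, threshold %.1f -> %d low / %d high\n",
                s$mean_ratio, s$ratio_threshold, s$n_low, s$n_high))
  invisible(x)
}
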