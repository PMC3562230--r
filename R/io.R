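#' Read a per-CpG methylation table, auto-detecting its dialect
#'
#' Two dialects are accepted: a long peak-height table (columns `case_id`,
#' `site_index`, `peak_height_C`, `peak_height_T`) or a wide percent table
#' (one row per case with a `case_id` column and one percent column per CpG
#' site, the supplementary-table layout). The dialect is detected from the
#' header.
#'
#' @param path CSV/TSV file path.
#' @return Either the long data.frame or a numeric percent matrix with case
#'   rownames — both accepted by [score_cohort()].
#' @export
read_methylation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty methylation table: ", path, call. = FALSE)
  if (all(c("case_id", "site_index", "peak_height_C", "peak_height_T") %in% names(df))) {
    bad <- which(is.na(df$site_index) | (is.na(df$peak_height_C) & is.na(df$peak_height_T)))
    if (length(bad))
      stop("malformed peak rows at line(s): ",
           paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
    return(df)
  }
  if ("case_id" %in% names(df)) {
    pm <- as.matrix(df[, setdiff(names(df), "case_id"), drop = FALSE])
    storage.mode(pm) <- "double"
    rownames(pm) <- as.character(df$case_id)
    return(pm)
  }
  stop("unknown methylation-table dialect in ", path,
       " (expected peak-height or wide percent columns)", call. = FALSE)
}

#' Read a clinical cohort table (CSV)
#'
#' Empty cells are missing values; marker columns use `mut`/`wt`.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector mapping user column
#'   names to canonical field names (`names` = canonical, values = as in
#'   the file).
#' @return Data.frame keyed by `case_id`.
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      user <- column_map[[canonical]]
      if (!user %in% names(df))
        stop("mapped column not found: ", user, call. = FALSE)
      names(df)[names(df) == user] <- canonical
    }
  }
  if (!"case_id" %in% names(df))
    stop("cohort table needs a case_id column", call. = FALSE)
  df
}

#' Score a methylation table end to end
#'
#' Reads (or takes) a methylation table, scores every case, derives the
#' cohort threshold and classifies cases, and optionally writes the per-case
#' scoring table and per-site frequency profile as CSV.
#'
#' @param input Path to a methylation table, or an object accepted by
#'   [score_cohort()].
#' @param config A [scoring_config()].
#' @param out Optional output path for the per-case scoring CSV (the
#'   per-site frequency table is written next to it with suffix
#'   `_site_frequency.csv`).
#' @return Classified `dpm_scores` object.
#' @export
run_score <- function(input, config = scoring_config(), out = NULL) {
  x <- if (is.character(input) && length(input) == 1L) {
    read_methylation_table(input)
  } else input
  scores <- score_cohort(x, config)
  scores <- classify_cases(scores, config = config)
  if (!is.null(out)) {
    utils::write.csv(as.data.frame(scores), out, row.names = FALSE)
    freq <- site_frequency_profile(scores, config = config)
    utils::write.csv(
      data.frame(site = seq_along(freq), n_methylated = freq),
      sub("\\.csv$", "_site_frequency.csv", out), row.names = FALSE)
  }
  scores
}

#' Run the full cohort analysis
#'
#' Joins per-case scores to the clinical table and reproduces the analysis
#' chain: methylation frequency summary, clinical comparison, mutation
#' association panel, expression-methylation rank correlation, overall and
#' subgroup survival, and uni/multivariable Cox models for OS and EFS.
#'
#' @param scores Classified `dpm_scores` (or path to a scoring CSV written
#'   by [run_score()]).
#' @param cohort Cohort data.frame (or CSV path).
#' @param association_method Default `"yates"`.
#' @param continuous_test Default `"student"`.
#' @param ratio_scale Divisor applied to the dPM ratio when entered as a
#'   continuous Cox covariate (default 100, i.e. per 100 units).
#' @return Object of class `dpm_report`: a list of result tables.
#' @export
run_analyze <- function(scores, cohort,
                        association_method = "yates",
                        continuous_test = "student",
                        ratio_scale = 100) {
  if (is.character(scores)) {
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
    scores$dpm_status <- factor(scores$dpm_status, c("negative", "positive"))
    scores$dpm_class <- factor(scores$dpm_class, c("negative", "low", "high"))
  }
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  sc <- as.data.frame(scores)[, c("case_id", "methylated_count", "ratio",
                                  "dpm_status", "dpm_class")]
  missing_ids <- setdiff(cohort$case_id, sc$case_id)
  if (length(missing_ids))
    stop("cases without scores: ", paste(utils::head(missing_ids, 5), collapse = ", "),
         call. = FALSE)
  d <- merge(cohort, sc, by = "case_id")
  if ("flt3_itd_ratio" %in% names(d)) {
    grp <- flt3_group(d$flt3_itd_ratio)
    grp[is.na(d$flt3_itd_ratio)] <- NA
    d$flt3_itd <- ifelse(grp == "high_ratio", "mut", "wt")
  }
  report <- list()
  pos <- d$dpm_status == "positive"
  report$frequency <- data.frame(
    n = nrow(d), n_positive = sum(pos),
    positive_pct = round(100 * mean(pos), 1),
    n_low = sum(d$dpm_class == "low"), n_high = sum(d$dpm_class == "high"),
    mean_ratio_positives = mean(d$ratio[pos])
  )
  report$clinical <- tryCatch(
    clinical_comparison(d, test = continuous_test, method = association_method),
    error = function(e) { warning(conditionMessage(e), call. = FALSE); NULL })
  report$mutations <- mutation_association_panel(
    d, method = association_method, test = continuous_test)
  if ("expression_pct" %in% names(d)) {
    report$expression <- tryCatch(
      spearman_correlation(d$ratio, d$expression_pct),
      error = function(e) { warning(conditionMessage(e), call. = FALSE); NULL })
  }
  if (all(c("os_months", "os_event") %in% names(d))) {
    report$survival <- analyze_survival(d, ratio_scale = ratio_scale)
  } else {
    warning("cohort lacks survival columns: survival section skipped",
            call. = FALSE)
  }
  structure(report, class = "dpm_report")
}

# overall + subgroup KM/log-rank and uni/multivariable Cox for OS and EFS
analyze_survival <- function(d, ratio_scale = 100) {
  out <- list()
  endpoints <- list(os = c("os_months", "os_event"))
  if (all(c("efs_months", "efs_event") %in% names(d)))
    endpoints$efs <- c("efs_months", "efs_event")
  flt3_low <- is.na(d$flt3_itd_ratio) | d$flt3_itd_ratio <= 0.5
  for (ep in names(endpoints)) {
    tm <- endpoints[[ep]][1]; ev <- endpoints[[ep]][2]
    res <- list()
    res$overall_status <- tryCatch(
      subgroup_survival(d, tm, ev, grouping = "status"),
      error = function(e) NULL)
    res$overall_class <- tryCatch(
      subgroup_survival(d, tm, ev, grouping = "class3"),
      error = function(e) NULL)
    res$flt3_low_status <- tryCatch(
      suppressWarnings(subgroup_survival(d, tm, ev, subset = flt3_low,
                                         grouping = "status")),
      error = function(e) NULL)
    if ("tet2" %in% names(d)) {
      res$tet2_mut_status <- tryCatch(
        suppressWarnings(subgroup_survival(
          d, tm, ev, subset = !is.na(d$tet2) & d$tet2 == "mut",
          grouping = "status")),
        error = function(e) NULL)
    }
    cd <- data.frame(
      time = d[[tm]], event = d[[ev]],
      age_per10 = d$age / 10, wbc_per10 = d$wbc / 10,
      flt3_high = as.integer(!flt3_low),
      npm1_mut = as.integer(!is.na(d$npm1) & d$npm1 == "mut"),
      runx1_mut = as.integer(!is.na(d$runx1) & d$runx1 == "mut"),
      dpm_positive = as.integer(d$dpm_status == "positive"),
      dpm_ratio = d$ratio / ratio_scale
    )
    res$cox <- tryCatch(
      suppressWarnings(cox_fit(
        cd, "time", "event",
        covariates = c("age_per10", "wbc_per10", "flt3_high", "npm1_mut",
                       "runx1_mut", "dpm_positive", "dpm_ratio"))),
      error = function(e) NULL)
    out[[ep]] <- res
  }
  out
}

#' @export
print.dpm_report <- function(x, ...) {
  cat("== dPM cohort report ==\n")
  f <- x$frequency
  cat(sprintf("cases: %d | dPM-positive: %d (%.1f%%) | low/high: %d/%d | mean ratio (pos): %.1f\n",
              f$n, f$n_positive, f$positive_pct, f$n_low, f$n_high,
              f$mean_ratio_positives))
  if (!is.null(x$clinical)) {
    cat("\n-- clinical comparison (dPM-negative vs positive) --\n")
    cl <- x$clinical; cl$p <- format_p(cl$p)
    print(cl, row.names = FALSE)
  }
  if (!is.null(x$mutations)) {
    cat("\n-- mutation associations --\n")
    mt <- x$mutations
    mt$p_status <- format_p(mt$p_status)
    mt$p_class <- format_p(mt$p_class)
    mt$p_ratio <- format_p(mt$p_ratio)
    mt$frac_mut_pos <- sprintf("%.1f%%", 100 * mt$frac_mut_pos)
    mt$frac_mut_neg <- sprintf("%.1f%%", 100 * mt$frac_mut_neg)
    print(mt[, c("marker", "n", "frac_mut_pos", "frac_mut_neg", "p_status",
                 "p_class", "p_ratio")], row.names = FALSE)
  }
  if (!is.null(x$expression)) {
    cat(sprintf("\n-- expression vs ratio: Spearman rho = %.3f, p = %s (n = %d) --\n",
                x$expression$rho, format_p(x$expression$p.value),
                x$expression$n))
  }
  if (!is.null(x$survival)) {
    for (ep in names(x$survival)) {
      cat(sprintf("\n-- %s survival --\n", toupper(ep)))
      sv <- x$survival[[ep]]
      for (an in setdiff(names(sv), "cox")) {
        a <- sv[[an]]
        if (is.null(a)) next
        meds <- paste(sprintf("%s=%s", a$km$medians$group,
                              format_median_survival(a$km$medians$median)),
                      collapse = " ")
        cat(sprintf("  %-18s n=%-4d median(months): %s  log-rank p = %s\n",
                    an, a$n, meds, format_p(a$logrank$p.value)))
      }
      if (!is.null(sv$cox)) {
        cat("  Cox model:\n")
        cx <- as.data.frame(sv$cox); cx$p <- format_p(cx$p)
        cx$rr <- sprintf("%.2f", cx$rr)
        print(cx[, c("covariate", "mode", "rr", "p")], row.names = FALSE)
      }
    }
  }
  invisible(x)
}

#' Generate a synthetic input bundle (simulate entry point)
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return File paths, invisibly (see [end_to_end_fixture()]).
#' @export
run_simulate <- function(config = simulation_config(), out_dir) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop("an output directory is required", call. = FALSE)
  end_to_end_fixture(config, out_dir)
}
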