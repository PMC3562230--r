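#' Kaplan-Meier estimate
#'
#' Product-limit estimator with the usual death-before-censor convention at
#' tied times; per-group curves when `group` is given. The median survival
#' is the smallest time with S(t) <= 0.5, or not reached (`NA`, serialized
#' as `"NR"`).
#'
#' @param time Follow-up times (months, >= 0).
#' @param event Logical/0-1 event indicator (FALSE = censored).
#' @param group Optional grouping vector.
#' @return Object of class `km_curve`: the `survfit` fit plus a `curves`
#'   data.frame of step coordinates (`group`, `time`, `surv`, `n_risk`,
#'   `n_event`) and a `medians` data.frame (`group`, `n`, `events`,
#'   `median`).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time < 0, na.rm = TRUE)) stop("negative survival time", call. = FALSE)
  keep <- !is.na(time) & !is.na(event) & (is.null(group) | !is.na(group %||% TRUE))
  time <- time[keep]; event <- as.integer(event[keep])
  if (length(time) == 0L) stop("no usable observations", call. = FALSE)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    groups <- factor(rep("all", length(time)))
  } else {
    groups <- droplevels(factor(group[keep]))
    fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  }
  sm <- summary(fit)
  # with no events every component of the summary is NULL
  times <- sm$time %||% numeric(0)
  strata <- if (is.null(sm$strata)) rep("all", length(times)) else
    sub("^groups=", "", as.character(sm$strata))
  curves <- data.frame(group = strata, time = times,
                       surv = sm$surv %||% numeric(0),
                       n_risk = sm$n.risk %||% numeric(0),
                       n_event = sm$n.event %||% numeric(0),
                       stringsAsFactors = FALSE)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, dimnames = list("all", names(tab)))
  grp_names <- sub("^groups=", "", rownames(tab))
  # median = smallest event time with S(t) <= 0.5 (not survfit's
  # interval-midpoint convention), NA when never reached
  med <- vapply(grp_names, function(g) {
    cc <- curves[curves$group == g & curves$surv <= 0.5 + 1e-12, ]
    if (nrow(cc) == 0L) NA_real_ else min(cc$time)
  }, numeric(1))
  medians <- data.frame(
    group = grp_names,
    n = as.integer(tab[, "records"]),
    events = as.integer(tab[, "events"]),
    median = unname(med),
    stringsAsFactors = FALSE
  )
  structure(list(fit = fit, curves = curves, medians = medians),
            class = "km_curve")
}

#' Serialize a median survival time
#'
#' @param median Numeric median (NA = not reached).
#' @return Character: formatted months or the `"NR"` token.
#' @export
format_median_survival <- function(median) {
  ifelse(is.na(median), "NR", sprintf("%.1f", median))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  m <- x$medians
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-16s n=%d events=%d median=%s months\n",
                m$group[i], m$n[i], m$events[i],
                format_median_survival(m$median[i])))
  invisible(x)
}

#' Two-sided log-rank test
#'
#' @param time,event As in [km_estimate()].
#' @param group Grouping with >= 2 levels.
#' @return List: `statistic` (chi-square), `df`, `p.value`, `n`, `events`.
#' @export
logrank_test <- function(time, event, group) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- as.integer(event[keep])
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2L) stop("log-rank test needs >= 2 groups", call. = FALSE)
  if (sum(event) == 0L) stop("no events", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = length(time), events = sum(event))
}

#' Cox proportional-hazards analysis
#'
#' Univariable mode fits each covariate alone; multivariable mode refits
#' jointly the covariates whose univariable p-value is at most
#' `inclusion_p` (the stepwise rule "parameters significant in univariable
#' analyses enter the multivariable model"), unless `covariates_multi`
#' overrides the selection. Continuous covariates should be pre-scaled by
#' the caller (e.g. age per 10 years, WBC per 10 x 10^9/L); the relative
#' risk is `exp(coefficient)` on that scale. Efron handling of ties.
#'
#' @param data Data.frame containing `time`, `event` and covariate columns.
#' @param time,event Column names for the endpoint.
#' @param covariates Character vector of covariate column names.
#' @param mode `"univariable"`, `"multivariable"`, or `"both"` (default).
#' @param inclusion_p Univariable p cut-off for multivariable inclusion
#'   (default 0.05).
#' @param covariates_multi Optional manual multivariable covariate list.
#' @return Object of class `cox_analysis`: data.frame with columns
#'   `covariate`, `mode`, `coef`, `rr`, `se`, `p`; attribute `fits` keeps
#'   the underlying `coxph` objects.
#' @export
cox_fit <- function(data, time, event, covariates,
                    mode = c("both", "univariable", "multivariable"),
                    inclusion_p = 0.05, covariates_multi = NULL) {
  mode <- match.arg(mode)
  keep <- stats::complete.cases(data[, c(time, event, covariates), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (sum(d[[event]]) < 10L)
    stop("fewer than 10 events: Cox fit not attempted", call. = FALSE)
  for (cv in covariates) {
    v <- d[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("constant covariate: ", cv, call. = FALSE)
  }
  surv <- survival::Surv(d[[time]], as.integer(d[[event]]))
  one_row <- function(fit, cv, mode_label) {
    s <- summary(fit)$coefficients
    r <- s[rownames(s) == cv | startsWith(rownames(s), cv), , drop = FALSE][1, ]
    if (is.na(r["coef"]) || r["se(coef)"] > 100)
      warning("possible separation / non-convergence for ", cv, call. = FALSE)
    data.frame(covariate = cv, mode = mode_label, coef = unname(r["coef"]),
               rr = unname(exp(r["coef"])), se = unname(r["se(coef)"]),
               p = unname(r["Pr(>|z|)"]), stringsAsFactors = FALSE)
  }
  fits <- list(); rows <- list()
  uni <- NULL
  if (mode %in% c("both", "univariable") || is.null(covariates_multi)) {
    uni <- do.call(rbind, lapply(covariates, function(cv) {
      fit <- survival::coxph(surv ~ ., data = d[, cv, drop = FALSE],
                             ties = "efron")
      fits[[paste0("uni_", cv)]] <<- fit
      one_row(fit, cv, "univariable")
    }))
    rows$uni <- uni
  }
  if (mode %in% c("both", "multivariable")) {
    selected <- covariates_multi %||% uni$covariate[uni$p <= inclusion_p]
    if (length(selected) == 0L) {
      warning("no covariate met the multivariable inclusion rule", call. = FALSE)
    } else {
      fit <- survival::coxph(surv ~ ., data = d[, selected, drop = FALSE],
                             ties = "efron")
      fits$multi <- fit
      rows$multi <- do.call(rbind, lapply(selected, function(cv)
        one_row(fit, cv, "multivariable")))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fits = fits, n = nrow(d), events = sum(d[[event]]),
            class = c("cox_analysis", "data.frame"))
}

#' Subgroup survival analysis
#'
#' Restricts the cohort to a subgroup (logical filter), groups it by dPM
#' status or by the three-level class (negative/low/high), and runs
#' [km_estimate()] plus [logrank_test()]. Arms with fewer than 10 cases
#' trigger a "patient numbers too small" warning.
#'
#' @param cohort Data.frame with `dpm_status`, `dpm_class` and endpoint
#'   columns.
#' @param time,event Endpoint column names (e.g. `os_months`, `os_event`).
#' @param subset Logical vector selecting the subgroup (default all).
#' @param grouping `"status"` or `"class3"`.
#' @param min_arm Small-arm warning threshold (default 10).
#' @return List: `km` (a `km_curve`), `logrank`, `n`, `grouping`.
#' @export
subgroup_survival <- function(cohort, time, event, subset = NULL,
                              grouping = c("status", "class3"),
                              min_arm = 10) {
  grouping <- match.arg(grouping)
  if (is.null(subset)) subset <- rep(TRUE, nrow(cohort))
  d <- cohort[which(subset), , drop = FALSE]
  if (nrow(d) == 0L) stop("empty subgroup", call. = FALSE)
  grp <- if (grouping == "status") factor(d$dpm_status) else factor(d$dpm_class)
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L) stop("subgroup has a single dPM arm", call. = FALSE)
  if (any(table(grp) < min_arm))
    warning("patient numbers too small in at least one arm", call. = FALSE)
  km <- km_estimate(d[[time]], d[[event]], grp)
  lr <- logrank_test(d[[time]], d[[event]], grp)
  list(km = km, logrank = lr, n = nrow(d), grouping = grouping)
}
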