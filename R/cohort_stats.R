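#' Two-sided association test on a 2x2 contingency table
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param method `"yates"` (continuity-corrected chi-square, default),
#'   `"pearson"` (uncorrected), or `"fisher"` (exact two-sided).
#' @return List: `statistic` (NA for fisher), `p.value`, `method`, `table`.
#'   A table with a zero margin returns p = 1 with a warning.
#' @export
association_test <- function(table, method = c("yates", "pearson", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) || any(table != round(table)))
    stop("`table` must be a 2x2 matrix of non-negative integer counts", call. = FALSE)
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate table (zero margin): p = 1", call. = FALSE)
    return(list(statistic = NA_real_, p.value = 1, method = method, table = table))
  }
  res <- switch(method,
    yates   = stats::chisq.test(table, correct = TRUE),
    pearson = stats::chisq.test(table, correct = FALSE),
    fisher  = stats::fisher.test(table)
  )
  list(statistic = if (method == "fisher") NA_real_ else unname(res$statistic),
       p.value = unname(res$p.value), method = method, table = table)
}

#' Build a 2x2 marker-by-methylation association table
#'
#' Cross-tabulates a mutation marker against dPM grouping with
#' pairwise-complete denominators: cases with unknown marker status are
#' dropped for that marker only, so each marker's n is the number of cases
#' actually analyzed for it.
#'
#' @param cohort Data.frame with a `dpm_status`/`dpm_class` column and a
#'   marker column coded `"mut"`/`"wt"` (NA = unknown).
#' @param marker Marker column name.
#' @param grouping `"status"` compares dPM-positive vs negative cases;
#'   `"class"` compares dPM-low vs dPM-high among positives.
#' @param method Passed to [association_test()].
#' @return List: `table` (rows = groups, cols = mut/wt), `fractions`
#'   (per-group mutated fraction), `n`, `test`.
#' @export
build_association_table <- function(cohort, marker,
                                    grouping = c("status", "class"),
                                    method = "yates") {
  grouping <- match.arg(grouping)
  if (!marker %in% names(cohort)) stop("unknown marker column: ", marker, call. = FALSE)
  if (grouping == "status") {
    grp <- factor(cohort$dpm_status, levels = c("positive", "negative"))
  } else {
    grp <- factor(cohort$dpm_class, levels = c("low", "high"))
  }
  mk <- factor(cohort[[marker]], levels = c("mut", "wt"))
  keep <- !is.na(grp) & !is.na(mk)
  if (!any(keep)) stop("no cases with known ", marker, call. = FALSE)
  tab <- table(grp[keep], mk[keep])
  if (any(rowSums(tab) == 0))
    warning(sprintf("empty group for %s under grouping '%s'", marker, grouping),
            call. = FALSE)
  m <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  fractions <- m[, "mut"] / rowSums(m)
  list(table = m, fractions = fractions, n = sum(m),
       test = association_test(m, method))
}

#' Group FLT3-ITD cases by allelic ratio
#'
#' Cases with ITD ratio above 0.5 form the adverse high-ratio group; ITD
#' ratio 0.5 or below (including ITD-negative, ratio 0) is grouped with
#' wild-type. The comparison at exactly 0.5 is strict: 0.5 goes low.
#'
#' @param flt3_itd_ratio Non-negative allelic ratios (0 or NA = ITD negative).
#' @return Factor with levels `neg_or_low_ratio`, `high_ratio`.
#' @export
flt3_group <- function(flt3_itd_ratio) {
  r <- ifelse(is.na(flt3_itd_ratio), 0, flt3_itd_ratio)
  if (any(r < 0)) stop("FLT3-ITD ratio must be non-negative", call. = FALSE)
  factor(ifelse(r > 0.5, "high_ratio", "neg_or_low_ratio"),
         levels = c("neg_or_low_ratio", "high_ratio"))
}

#' Compare methylation ratio between marker groups
#'
#' Reports n, mean and SD of the dPM ratio per marker group (dPM-negative
#' cases contribute ratio 0) and a two-sided p-value from the configured
#' two-sample test.
#'
#' @param cohort Data.frame with a numeric `ratio` column and the marker
#'   column coded `"mut"`/`"wt"` (NA = unknown).
#' @param marker Marker column name (use [flt3_group()] output for FLT3-ITD).
#' @param test `"student"` (default, equal-variance t), `"welch"`, or
#'   `"mann_whitney"`.
#' @return List: `summary` data.frame (group, n, mean, sd), `p.value`,
#'   `test`.
#' @export
ratio_by_group <- function(cohort, marker,
                           test = c("student", "welch", "mann_whitney")) {
  test <- match.arg(test)
  mk <- cohort[[marker]]
  keep <- !is.na(mk) & !is.na(cohort$ratio)
  x <- cohort$ratio[keep]
  g <- factor(mk[keep])
  if (nlevels(g) != 2L || any(table(g) < 2L))
    stop("need two groups with at least 2 cases each", call. = FALSE)
  degenerate <- all(tapply(x, g, stats::sd) == 0)
  p <- if (degenerate && test != "mann_whitney") {
    # zero within-group variance: perfect separation unless means coincide
    if (diff(tapply(x, g, mean)) == 0) 1 else 0
  } else {
    switch(test,
      student = stats::t.test(x ~ g, var.equal = TRUE)$p.value,
      welch = stats::t.test(x ~ g)$p.value,
      mann_whitney = stats::wilcox.test(x ~ g, exact = FALSE)$p.value
    )
  }
  sm <- do.call(rbind, lapply(levels(g), function(l) {
    data.frame(group = l, n = sum(g == l), mean = mean(x[g == l]),
               sd = stats::sd(x[g == l]), stringsAsFactors = FALSE)
  }))
  list(summary = sm, p.value = p, test = test)
}

#' Clinical comparison between dPM-positive and dPM-negative cases
#'
#' Medians and ranges for age, bone-marrow blasts, WBC, hemoglobin and
#' platelets per dPM group with a two-sided p-value per variable, plus the
#' sex distribution via [association_test()].
#'
#' @param cohort Data.frame with `dpm_status` and (any of) `age`,
#'   `bm_blasts`, `wbc`, `hb`, `platelets`, `sex` columns.
#' @param test Continuous test as in [ratio_by_group()]; default
#'   `"student"`.
#' @param method Association method for sex; default `"yates"`.
#' @return Data.frame: variable, per-group median and range, p.
#' @export
clinical_comparison <- function(cohort, test = "student", method = "yates") {
  grp <- factor(cohort$dpm_status, levels = c("negative", "positive"))
  if (any(table(grp) < 2L)) stop("need >= 2 cases per dPM group", call. = FALSE)
  vars <- intersect(c("age", "bm_blasts", "wbc", "hb", "platelets"), names(cohort))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    keep <- !is.na(x) & !is.na(grp)
    xt <- x[keep]; gt <- grp[keep]
    p <- tryCatch(ratio_by_group(
      data.frame(ratio = xt, mk = ifelse(gt == "positive", "mut", "wt")),
      "mk", test = test)$p.value, error = function(e) NA_real_)
    fmt <- function(g) {
      xs <- xt[gt == g]
      sprintf("%.1f (%.1f-%.1f)", stats::median(xs), min(xs), max(xs))
    }
    data.frame(variable = v,
               negative = fmt("negative"), positive = fmt("positive"),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("sex" %in% names(cohort)) {
    sx <- factor(cohort$sex)
    if (nlevels(droplevels(sx[!is.na(sx)])) < 2L) {
      warning("single-sex cohort: sex comparison skipped", call. = FALSE)
    } else {
      tab <- table(grp, sx)[, 1:2]
      tst <- association_test(matrix(as.integer(tab), 2, 2), method)
      out <- rbind(out, data.frame(
        variable = "sex",
        negative = sprintf("%d/%d", tab[1, 1], tab[1, 2]),
        positive = sprintf("%d/%d", tab[2, 1], tab[2, 2]),
        p = tst$p.value, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Normalize gene expression against a control gene
#'
#' Expression reported as a percentage of the control-gene quantity,
#' `100 * target / control` (the %CEBPA/ABL1 convention).
#'
#' @param target_quantity Target-gene quantity (vectorized, >= 0).
#' @param control_quantity Control-gene quantity (> 0).
#' @return Percent expression.
#' @export
normalize_expression <- function(target_quantity, control_quantity) {
  if (any(control_quantity <= 0, na.rm = TRUE))
    stop("control quantity must be positive", call. = FALSE)
  100 * target_quantity / control_quantity
}

#' Spearman rank correlation with two-sided p-value
#'
#' Average ranks for ties; exact permutation p for n <= 10 (no ties),
#' otherwise the t-approximation.
#'
#' @param x,y Paired numeric vectors, n >= 3 after removing missing pairs.
#' @return List: `rho`, `p.value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (n <= 10 && !ties))
  )
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = n)
}

#' Run the full marker-association panel
#'
#' For each marker column, the 2x2 status association, the low-vs-high class
#' association, and the ratio-by-group comparison, with pairwise-complete
#' denominators.
#'
#' @param cohort Cohort data.frame with `dpm_status`, `dpm_class`, `ratio`
#'   and marker columns.
#' @param markers Character vector of marker column names; default all
#'   columns coded in `"mut"`/`"wt"`.
#' @param method Association method (default `"yates"`).
#' @param test Continuous test (default `"student"`).
#' @return Data.frame, one row per marker: n, mutated fractions per status
#'   group, association p, class-association p, group means and ratio p.
#' @export
mutation_association_panel <- function(cohort, markers = NULL,
                                       method = "yates", test = "student") {
  if (is.null(markers)) {
    is_marker <- vapply(cohort, function(col) {
      all(stats::na.omit(unique(as.character(col))) %in% c("mut", "wt")) &&
        !all(is.na(col))
    }, logical(1))
    markers <- names(cohort)[is_marker]
  }
  rows <- lapply(markers, function(mk) {
    st <- tryCatch(build_association_table(cohort, mk, "status", method),
                   error = function(e) NULL)
    cl <- tryCatch(build_association_table(cohort, mk, "class", method),
                   error = function(e) NULL)
    rt <- tryCatch(ratio_by_group(cohort, mk, test), error = function(e) NULL)
    data.frame(
      marker = mk,
      n = if (!is.null(st)) st$n else NA_integer_,
      frac_mut_pos = if (!is.null(st)) st$fractions[["positive"]] else NA_real_,
      frac_mut_neg = if (!is.null(st)) st$fractions[["negative"]] else NA_real_,
      p_status = if (!is.null(st)) st$test$p.value else NA_real_,
      p_class = if (!is.null(cl)) cl$test$p.value else NA_real_,
      ratio_mean_wt = if (!is.null(rt)) rt$summary$mean[rt$summary$group == "wt"] else NA_real_,
      ratio_mean_mut = if (!is.null(rt)) rt$summary$mean[rt$summary$group == "mut"] else NA_real_,
      p_ratio = if (!is.null(rt)) rt$p.value else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
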