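#' Cardiovascular risk score from component flags
#'
#' Counts the present risk factors among hypertension, diabetes,
#' dyslipidemia, smoking and obesity (0: low risk to 5: high risk).
#'
#' @param flags named logical vector or list containing the five components.
#' @return integer in 0..5.
#' @export
compute_crs <- function(flags) {
  needed <- c("hypertension", "diabetes", "dyslipidemia", "smoking", "obesity")
  missing <- setdiff(needed, names(flags))
  if (length(missing))
    stop("missing risk flags: ", paste(missing, collapse = ", "))
  vals <- vapply(needed, function(f) isTRUE(flags[[f]]) || identical(flags[[f]], TRUE),
                 logical(1))
  if (any(vapply(needed, function(f) is.na(flags[[f]]), logical(1))))
    stop("risk flags must not be NA")
  sum(vals)
}

#' Assign the six grouping parameters to a cohort
#'
#' Adds the grouping columns used by the comparison plan: age tertiles
#' `[54,62)`, `[62,69)`, `[69,78]` (boundary ages go to the older-starting
#' group, the last interval is closed), sex, joint age-by-sex, ApoE e4
#' carrier status (at least one e4 allele), CRS score and overweight status
#' (BMI strictly greater than 25). Ages outside [54, 78] are flagged and get
#' no age group.
#'
#' @param cohort data.frame with columns age, sex, apoe, crs, bmi.
#' @return the cohort with columns age_group, age_sex, apoe_carrier,
#'   overweight, excluded added.
#' @export
assign_groups <- function(cohort) {
  br <- age_tertile_breaks()
  grp <- rep(NA_character_, nrow(cohort))
  labs <- c("54-62", "62-69", "69-78")
  grp[cohort$age >= br[1] & cohort$age < br[2]] <- labs[1]
  grp[cohort$age >= br[2] & cohort$age < br[3]] <- labs[2]
  grp[cohort$age >= br[3] & cohort$age <= br[4]] <- labs[3]
  cohort$age_group <- grp
  cohort$excluded <- is.na(grp)
  if (any(cohort$excluded))
    warning(sprintf("%d subject(s) outside the 54-78 age range were flagged",
                    sum(cohort$excluded)))
  cohort$age_sex <- ifelse(is.na(grp), NA_character_,
                           paste(cohort$sex, grp, sep = ":"))
  cohort$apoe_carrier <- grepl("e4", cohort$apoe)
  cohort$overweight <- cohort$bmi > 25
  cohort
}

#' Least-squares regression of an iron metric against age
#'
#' Ordinary least squares with the age as continuous independent variable:
#' slope, intercept, their standard errors from the residual variance and
#' the two-sided t-test p-value for a nonzero slope.
#'
#' @param ages numeric vector (at least 3, nonzero variance).
#' @param values numeric response vector of the same length.
#' @return object of class `age_regression`.
#' @examples
#' fit_age_regression(c(55, 60, 70, 75), c(10, 12, 18, 19))
#' @export
fit_age_regression <- function(ages, values) {
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  if (length(ages) < 3L) stop("at least 3 complete observations are required")
  if (stats::sd(ages) == 0) stop("zero age variance")
  fit <- stats::lm(values ~ ages)
  # summary.lm warns on zero-residual input; an exact line is a valid case
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = unname(sm["ages", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope_se = unname(sm["ages", "Std. Error"]),
                 intercept_se = unname(sm["(Intercept)", "Std. Error"]),
                 p_value = unname(sm["ages", "Pr(>|t|)"]),
                 n = length(ages)),
            class = "age_regression")
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf("Linear age model (n = %d): slope %.3f +/- %.3f per year, intercept %.2f +/- %.2f, p = %.3g\n",
              x$n, x$slope, x$slope_se, x$intercept, x$intercept_se, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test between two groups
#'
#' The U statistic is computed from rank sums with half credit for ties. The
#' two-sided p-value is exact (by enumeration of the null rank distribution)
#' when `n_a * n_b <= 400` and no ties are present, otherwise a normal
#' approximation with tie and continuity correction is used.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list with `u` (U of group a), `p_value` and `exact`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- any(duplicated(c(a, b)))
  use_exact <- (as.numeric(na) * nb <= 400) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = use_exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1   # zero-variance degenerate case
  list(u = u, p_value = min(p, 1), exact = use_exact)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value in [0, 1].
#' @param factor number of tests in the family (default 112: 16 pairwise
#'   group comparisons times 7 ROIs).
#' @return `min(1, factor * p_raw)`.
#' @export
bonferroni <- function(p_raw, factor = 112L) {
  if (factor < 1) stop("factor must be at least 1")
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) stop("p_raw must be in [0, 1]")
  pmin(1, factor * p_raw)
}

#' Enumerate the pairwise group-comparison plan
#'
#' The six grouping parameters yield 16 pairwise comparisons: the three age
#' tertile pairs, the sex pair, the three age pairs within each sex (6), the
#' ApoE carrier pair, the three pairs among observed CRS scores and the
#' overweight pair within each sex (2). Crossed with the ROIs this gives the
#' total test count per metric (112 for 7 ROIs), which is the Bonferroni
#' factor.
#'
#' @param rois character vector of ROI names.
#' @param crs_levels observed CRS scores.
#' @return object of class `comparison_plan`: a data.frame of comparisons
#'   plus attributes `n_pairs` and `n_tests`.
#' @examples
#' plan <- comparison_plan()
#' attr(plan, "n_pairs"); attr(plan, "n_tests")
#' @export
comparison_plan <- function(rois = dgm_structures(), crs_levels = 0:2) {
  pair_rows <- function(parameter, levels, subset = NA_character_) {
    cmb <- utils::combn(as.character(levels), 2)
    data.frame(parameter = parameter, subset = subset,
               level_a = cmb[1, ], level_b = cmb[2, ],
               stringsAsFactors = FALSE)
  }
  labs <- c("54-62", "62-69", "69-78")
  comparisons <- rbind(
    pair_rows("age", labs),
    data.frame(parameter = "sex", subset = NA_character_,
               level_a = "F", level_b = "M", stringsAsFactors = FALSE),
    pair_rows("age_sex", labs, subset = "F"),
    pair_rows("age_sex", labs, subset = "M"),
    data.frame(parameter = "apoe", subset = NA_character_,
               level_a = "noncarrier", level_b = "carrier",
               stringsAsFactors = FALSE),
    pair_rows("crs", crs_levels),
    data.frame(parameter = "bmi", subset = c("F", "M"),
               level_a = "normal", level_b = "overweight",
               stringsAsFactors = FALSE))
  structure(comparisons, class = c("comparison_plan", "data.frame"),
            rois = rois, n_pairs = nrow(comparisons),
            n_tests = nrow(comparisons) * length(rois))
}

#' Median-based comparison of two groups
#'
#' Medians, percent difference `100 * (median_b - median_a) / |median_a|`
#' (the absolute-value denominator keeps the sign of the difference when the
#' reference median is negative) and the Mann-Whitney test.
#'
#' @param a,b numeric value vectors for the two groups.
#' @return list with medians, percent_difference, u_statistic, p_raw.
#' @export
compare_two_groups <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  med_a <- stats::median(a); med_b <- stats::median(b)
  pct <- if (med_a == 0) NA_real_ else 100 * (med_b - med_a) / abs(med_a)
  mw <- mann_whitney(a, b)
  list(median_a = med_a, median_b = med_b, percent_difference = pct,
       u_statistic = mw$u, p_raw = mw$p_value, n_a = length(a),
       n_b = length(b))
}

# value vector of one comparison side for a given roi/metric
group_values <- function(roi_table, cohort, roi, metric, parameter, level, subset) {
  col <- switch(parameter,
                age = "age_group", sex = "sex", age_sex = "age_group",
                apoe = "apoe_carrier", crs = "crs", bmi = "overweight",
                stop(sprintf("unknown comparison parameter '%s'", parameter)))
  sel <- !cohort$excluded
  if (parameter %in% c("age_sex", "bmi") && !is.na(subset))
    sel <- sel & cohort$sex == subset
  want <- switch(parameter,
                 apoe = identical(level, "carrier"),
                 bmi = identical(level, "overweight"),
                 crs = as.numeric(level),
                 level)
  sel <- sel & !is.na(cohort[[col]]) & cohort[[col]] == want
  ids <- cohort$subject_id[sel]
  roi_table$trimmed_mean[roi_table$subject_id %in% ids &
                           roi_table$roi_name == roi &
                           roi_table$metric == metric]
}

#' Run the full group-comparison plan over an ROI table
#'
#' For every comparison in the plan, ROI and metric: group medians, percent
#' difference, Mann-Whitney U, raw and Bonferroni-corrected p-values.
#' Comparisons in which either group has fewer than 3 subjects are flagged
#' but still reported.
#'
#' @param roi_table bilateral ROI table (columns subject_id, roi_name,
#'   metric, trimmed_mean).
#' @param cohort cohort table already passed through [assign_groups()].
#' @param plan a [comparison_plan()].
#' @param factor Bonferroni factor (default: the plan's per-metric test count).
#' @return data.frame of comparison results.
#' @export
compare_groups <- function(roi_table, cohort, plan = comparison_plan(),
                           factor = attr(plan, "n_tests")) {
  if (!"age_group" %in% names(cohort)) cohort <- assign_groups(cohort)
  rois <- attr(plan, "rois")
  metrics <- unique(roi_table$metric)
  out <- list()
  for (i in seq_len(nrow(plan))) {
    for (roi in rois) {
      for (metric in metrics) {
        va <- group_values(roi_table, cohort, roi, metric,
                           plan$parameter[i], plan$level_a[i], plan$subset[i])
        vb <- group_values(roi_table, cohort, roi, metric,
                           plan$parameter[i], plan$level_b[i], plan$subset[i])
        flagged <- length(va) < 3L || length(vb) < 3L
        if (length(va) == 0 || length(vb) == 0) {
          res <- list(median_a = NA_real_, median_b = NA_real_,
                      percent_difference = NA_real_, u_statistic = NA_real_,
                      p_raw = NA_real_, n_a = length(va), n_b = length(vb))
        } else {
          res <- compare_two_groups(va, vb)
        }
        out[[length(out) + 1L]] <- data.frame(
          roi_name = roi, metric = metric, parameter = plan$parameter[i],
          subset = plan$subset[i], group_a = plan$level_a[i],
          group_b = plan$level_b[i], n_a = res$n_a, n_b = res$n_b,
          median_a = res$median_a, median_b = res$median_b,
          percent_difference = res$percent_difference,
          u_statistic = res$u_statistic, p_raw = res$p_raw,
          p_bonferroni = if (is.na(res$p_raw)) NA_real_ else bonferroni(res$p_raw, factor),
          flagged = flagged, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Sex-stratified age regressions for every ROI and metric
#'
#' Reproduces the linear-model summary table: one ordinary-least-squares age
#' regression per ROI, sex and metric.
#'
#' @param roi_table bilateral ROI table.
#' @param cohort cohort table with age and sex.
#' @return data.frame with one row per ROI, sex and metric.
#' @export
age_regression_table <- function(roi_table, cohort) {
  keys <- unique(roi_table[, c("roi_name", "metric")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    for (sx in c("F", "M")) {
      ids <- cohort$subject_id[cohort$sex == sx]
      sub <- roi_table[roi_table$roi_name == keys$roi_name[i] &
                         roi_table$metric == keys$metric[i] &
                         roi_table$subject_id %in% ids, ]
      mrg <- merge(sub, cohort[, c("subject_id", "age")], by = "subject_id")
      if (nrow(mrg) < 3L) next
      fit <- fit_age_regression(mrg$age, mrg$trimmed_mean)
      out[[length(out) + 1L]] <- data.frame(
        roi = keys$roi_name[i], sex = sx, metric = keys$metric[i],
        slope = fit$slope, slope_se = fit$slope_se,
        intercept = fit$intercept, intercept_se = fit$intercept_se,
        p_value = fit$p_value, n = fit$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
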