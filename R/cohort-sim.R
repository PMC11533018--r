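#' Published linear age models for DGM iron metrics
#'
#' The 28 sex-stratified linear regressions of QSM (ppb) and R2* (s^-1)
#' against age (years) for the seven deep-gray-matter structures, as reported
#' for the 7T healthy-aging cohort: slope and intercept with their standard
#' errors and the two-sided slope p-value. These models parameterise the
#' cohort simulator, so every printed slope can serve as a ground truth in
#' parameter-recovery experiments.
#'
#' @return data.frame with columns roi, sex (`"F"`/`"M"`), metric
#'   (`"qsm_ppb"`/`"r2star_s-1"`), slope, slope_se, intercept, intercept_se,
#'   p_value.
#' @examples
#' m <- table1_models()
#' m[m$roi == "putamen" & m$sex == "F", ]
#' @export
table1_models <- function() {
  q <- rbind(
    # roi, sex, slope, slope_se, intercept, intercept_se, p
    c("caudate", "F", 0.63, 0.26, -4.97, 17.66, 0.02),
    c("caudate", "M", 1.09, 0.47, -31.56, 30.48, 0.03),
    c("putamen", "F", 1.25, 0.33, -49.68, 22.49, 0.01),
    c("putamen", "M", 1.50, 0.54, -63.11, 34.85, 0.01),
    c("thalamus", "F", -0.09, 0.19, -10.64, 12.58, 0.62),
    c("thalamus", "M", -0.02, 0.24, -8.23, 15.21, 0.94),
    c("globus pallidus", "F", 0.06, 0.56, 85.42, 37.95, 0.92),
    c("globus pallidus", "M", 0.54, 0.59, 50.69, 38.37, 0.37),
    c("hippocampus", "F", -0.31, 0.18, 5.20, 12.41, 0.10),
    c("hippocampus", "M", -0.14, 0.20, -5.02, 12.68, 0.48),
    c("amygdala", "F", -0.51, 0.34, 17.88, 23.09, 0.14),
    c("amygdala", "M", -0.18, 0.29, -12.78, 18.51, 0.54),
    c("accumbens", "F", -1.40, 0.57, 87.74, 38.87, 0.02),
    c("accumbens", "M", -0.14, 0.54, -3.17, 35.02, 0.80))
  r <- rbind(
    c("caudate", "F", 0.36, 0.13, 21.40, 8.89, 0.01),
    c("caudate", "M", 0.43, 0.19, 20.33, 12.26, 0.03),
    c("putamen", "F", 0.69, 0.21, 11.67, 14.49, 0.01),
    c("putamen", "M", 0.72, 0.29, 13.42, 18.79, 0.02),
    c("thalamus", "F", -0.07, 0.07, 42.67, 4.67, 0.31),
    c("thalamus", "M", -0.02, 0.07, 39.83, 4.30, 0.90),
    c("globus pallidus", "F", 0.86, 0.40, 36.23, 27.06, 0.04),
    c("globus pallidus", "M", 0.00, 0.45, 88.50, 29.12, 0.99),
    c("hippocampus", "F", -0.08, 0.04, 36.17, 2.51, 0.04),
    c("hippocampus", "M", 0.03, 0.06, 29.40, 3.60, 0.58),
    c("amygdala", "F", -0.09, 0.04, 32.56, 2.94, 0.05),
    c("amygdala", "M", 0.12, 0.05, 19.23, 3.39, 0.03),
    c("accumbens", "F", 0.12, 0.08, 24.46, 5.23, 0.14),
    c("accumbens", "M", 0.26, 0.10, 17.15, 6.69, 0.02))
  build <- function(m, metric) {
    data.frame(roi = m[, 1], sex = m[, 2], metric = metric,
               slope = as.numeric(m[, 3]), slope_se = as.numeric(m[, 4]),
               intercept = as.numeric(m[, 5]),
               intercept_se = as.numeric(m[, 6]),
               p_value = as.numeric(m[, 7]), stringsAsFactors = FALSE)
  }
  rbind(build(q, "qsm_ppb"), build(r, "r2star_s-1"))
}

#' Residual standard deviation implied by a printed slope standard error
#'
#' Inverts the ordinary-least-squares identity `SE(slope) = sigma / sqrt(Sxx)`
#' with `Sxx = sum((age - mean(age))^2)`, so that cohorts simulated with
#' Gaussian residuals of this standard deviation reproduce the printed slope
#' standard error in expectation.
#'
#' @param model one row of [table1_models()] (or any list with `slope_se`).
#' @param ages numeric vector of cohort ages (at least 3 distinct values).
#' @return residual standard deviation in the units of the model's metric.
#' @export
calibrate_noise <- function(model, ages) {
  se <- if (is.numeric(model)) model else model$slope_se
  if (length(se) != 1L || !is.finite(se) || se < 0)
    stop("model must supply a single nonnegative slope_se")
  if (length(unique(ages)) < 3L) stop("at least 3 distinct ages are required")
  sxx <- sum((ages - mean(ages))^2)
  if (sxx == 0) stop("zero age variance")
  se * sqrt(sxx)
}

# Tertile age ranges and per-sex counts emulating the study demographics:
# 24/26/27 participants in [54,62), [62,69), [69,78], 37 M / 40 F overall,
# 17 females in the oldest group.
age_tertile_breaks <- function() c(54, 62, 69, 78)
female_tertile_counts <- function() c(11L, 12L, 17L)
male_tertile_counts <- function() c(13L, 14L, 10L)

# Largest-remainder allocation of n across the reference tertile proportions
allocate_counts <- function(n, ref_counts) {
  exact <- n * ref_counts / sum(ref_counts)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Sample cohort ages with the emulated tertile structure
#'
#' Ages are uniform within each tertile ([54,62), [62,69), [69,78]) with
#' per-sex group counts scaled from the emulated demographics by largest
#' remainder.
#'
#' @param n_female,n_male numbers of subjects per sex.
#' @param seed integer seed.
#' @return data.frame with columns sex, age.
#' @export
sample_cohort_ages <- function(n_female = 40L, n_male = 37L, seed = 1L) {
  set.seed(as.integer(seed))
  br <- age_tertile_breaks()
  draw <- function(n, counts, sex) {
    alloc <- allocate_counts(n, counts)
    ages <- unlist(lapply(1:3, function(t)
      stats::runif(alloc[t], br[t], br[t + 1])))
    if (length(ages) == 0) ages <- numeric(0)
    data.frame(sex = rep(sex, n), age = ages, stringsAsFactors = FALSE)
  }
  rbind(draw(n_female, female_tertile_counts(), "F"),
        draw(n_male, male_tertile_counts(), "M"))
}

#' Simulate a cohort table and its ROI iron values
#'
#' Generates subject demographics (age tertile structure, sex split, ApoE e4
#' carriers at the cohort rate of 16/77 with one homozygote, cardiovascular
#' risk scores distributed 40/20/17 over the values 0/1/2, BMI with the
#' cohort's 29/77 overweight rate) and, per subject and linear model, the ROI
#' value `intercept + slope * age + Normal(0, residual_sd)` with residual_sd
#' calibrated per sex from the printed slope standard error. Optional group
#' effects multiply the values of flagged subgroups, so percent differences
#' between group medians are directly parameterisable.
#'
#' @param models data.frame of linear age models (default [table1_models()]).
#' @param n_female,n_male subjects per sex.
#' @param group_effects optional list of effects, each a list with fields
#'   `variable` (a cohort column), `level`, `roi`, `metric`, `multiplier`.
#' @param seed integer seed; identical seeds give identical tables.
#' @param residual_sd optional fixed residual standard deviation (overrides
#'   calibration; 0 gives noiseless cohorts).
#' @param crs_probs probabilities of CRS scores 0..5.
#' @return list with `cohort` (one row per subject) and `roi` (a bilateral
#'   ROI table with one row per subject, ROI and metric).
#' @examples
#' sim <- simulate_cohort(n_female = 10, n_male = 8, seed = 7)
#' head(sim$cohort)
#' @export
simulate_cohort <- function(models = table1_models(), n_female = 40L,
                            n_male = 37L, group_effects = NULL, seed = 1L,
                            residual_sd = NULL,
                            crs_probs = c(40, 20, 17, 0, 0, 0) / 77) {
  if (n_female + n_male <= 0) stop("cohort size must be positive")
  demo <- sample_cohort_ages(n_female, n_male, seed = seed)
  n <- nrow(demo)
  set.seed(as.integer(seed) + 1L)
  demo <- demo[sample.int(n), , drop = FALSE]
  cohort <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       age = demo$age, sex = demo$sex,
                       stringsAsFactors = FALSE)

  # ApoE: carriers at the cohort rate, first carrier homozygous
  n_carrier <- round(n * 16 / 77)
  carrier_idx <- if (n_carrier > 0) sample.int(n, n_carrier) else integer(0)
  apoe <- rep("e3/e3", n)
  if (n_carrier > 0) {
    apoe[carrier_idx] <- "e3/e4"
    apoe[carrier_idx[1]] <- "e4/e4"
  }
  cohort$apoe <- apoe

  # cardiovascular risk score: exact group sizes at the cohort rates
  # (40/20/17 over scores 0/1/2 for n = 77), randomly permuted over subjects
  crs_counts <- allocate_counts(n, crs_probs)
  crs <- sample(rep(0:5, times = crs_counts))
  flag_names <- c("hypertension", "diabetes", "dyslipidemia", "smoking", "obesity")
  flags <- matrix(FALSE, n, 5, dimnames = list(NULL, flag_names))
  for (i in seq_len(n)) {
    if (crs[i] > 0) flags[i, sample.int(5, crs[i])] <- TRUE
  }
  cohort$crs <- crs
  cohort <- cbind(cohort, as.data.frame(flags))

  # BMI: overweight (> 25) at the cohort rate; obesity flag forces BMI > 30
  p_over <- 29 / 77
  overweight <- stats::runif(n) < p_over
  bmi <- ifelse(overweight, stats::runif(n, 25.5, 30), stats::runif(n, 19, 24.5))
  bmi[flags[, "obesity"]] <- stats::runif(sum(flags[, "obesity"]), 30.5, 34)
  cohort$bmi <- bmi

  # ROI values from the linear models with SE-calibrated residuals. Each
  # model draws from its own substream keyed on (seed, roi, sex, metric), so
  # ROI noise is independent across models and does not depend on which other
  # models are simulated alongside.
  roi_rows <- vector("list", nrow(models))
  for (j in seq_len(nrow(models))) {
    mod <- models[j, ]
    idx <- which(cohort$sex == mod$sex)
    if (length(idx) == 0) next
    sdj <- if (!is.null(residual_sd)) residual_sd
           else calibrate_noise(mod, cohort$age[idx])
    key <- sum(utf8ToInt(paste(mod$roi, mod$sex, mod$metric)))
    set.seed((as.numeric(seed) * 131 + key * 7919) %% 2147483647)
    vals <- mod$intercept + mod$slope * cohort$age[idx] +
      stats::rnorm(length(idx), 0, sdj)
    roi_rows[[j]] <- data.frame(subject_id = cohort$subject_id[idx],
                                roi_name = mod$roi, hemisphere = "bilateral",
                                metric = mod$metric, trimmed_mean = vals,
                                stringsAsFactors = FALSE)
  }
  roi <- do.call(rbind, roi_rows)

  if (!is.null(group_effects)) {
    for (ef in group_effects) {
      if (!ef$variable %in% names(cohort))
        stop(sprintf("group effect references unknown cohort variable '%s'", ef$variable))
      subj <- cohort$subject_id[cohort[[ef$variable]] == ef$level]
      hit <- roi$subject_id %in% subj & roi$roi_name == ef$roi &
        roi$metric == ef$metric
      roi$trimmed_mean[hit] <- roi$trimmed_mean[hit] * ef$multiplier
    }
  }

  list(cohort = cohort, roi = roi)
}
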