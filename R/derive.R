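# Subject-level derived variables: SDS transforms, midparental height,
# childhood BMI, adult height, pubertal gains and menarche-linked growth.

#' SDS reference
#'
#' A reference for transforming a measurement into a standard deviation
#' score (SDS). Either an age-dependent grid of (age, mean, sd) rows
#' (linearly interpolated between nodes, extrapolation refused) or the
#' cohort-internal mode, which standardizes by the analyzed column's own
#' mean and SD irrespective of age.
#'
#' @param grid data.frame with strictly increasing `age` and columns
#'   `mean`, `sd` (`sd > 0`), or `NULL` for cohort-internal mode.
#' @param name Variable name the reference applies to.
#' @return Object of class `sds_reference`.
#' @export
sds_reference <- function(grid = NULL, name = "variable") {
  if (!is.null(grid)) {
    stopifnot(is.data.frame(grid), all(c("age", "mean", "sd") %in% names(grid)))
    if (any(diff(grid$age) <= 0)) stop("reference ages must be strictly increasing")
    if (any(grid$sd <= 0)) stop("reference sd must be > 0 everywhere")
  }
  structure(list(grid = grid, name = name), class = "sds_reference")
}

#' Transform a value to an SDS
#'
#' @param value Measurement value(s).
#' @param age Age(s) in years (ignored in cohort-internal mode).
#' @param ref [sds_reference()]. Cohort-internal references need
#'   `cohort_mean`/`cohort_sd`.
#' @param cohort_mean,cohort_sd Mean and SD of the analyzed cohort column,
#'   used when `ref` has no grid.
#' @return SDS value(s); `NA` where the age falls outside the reference grid
#'   (extrapolation is refused).
#' @export
to_sds <- function(value, age = NULL, ref = sds_reference(),
                   cohort_mean = NULL, cohort_sd = NULL) {
  if (is.null(ref$grid)) {
    if (is.null(cohort_mean) || is.null(cohort_sd))
      stop("cohort-internal SDS needs 'cohort_mean' and 'cohort_sd'")
    if (cohort_sd <= 0) stop("'cohort_sd' must be > 0")
    return((value - cohort_mean) / cohort_sd)
  }
  g <- ref$grid
  out <- rep(NA_real_, length(value))
  ok <- !is.na(age) & age >= min(g$age) & age <= max(g$age) & !is.na(value)
  if (any(ok)) {
    mu <- stats::approx(g$age, g$mean, xout = age[ok])$y
    sd <- stats::approx(g$age, g$sd, xout = age[ok])$y
    out[ok] <- (value[ok] - mu) / sd
  }
  out
}

# cohort-internal standardization of a vector by its own mean/SD
cohort_sds <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) stop("cannot standardize: zero or undefined SD")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Midparental height in SDS
#'
#' Arithmetic mean of the mother's and father's height SDS. Missing parents
#' propagate (`NA`), excluding the subject from MPH-dependent variables.
#'
#' @param mother_sds,father_sds Parental height SDS.
#' @return MPH in SDS.
#' @export
mph_sds <- function(mother_sds, father_sds) (mother_sds + father_sds) / 2

#' Height relative to midparental height
#'
#' `DiffH-MPH`: the girl's height SDS at a milestone minus MPH SDS.
#'
#' @param height_sds Height SDS at a milestone.
#' @param mph MPH in SDS ([mph_sds()]).
#' @return Difference in SDS.
#' @export
diffh_mph <- function(height_sds, mph) height_sds - mph

#' Childhood peak BMI
#'
#' Highest BMI observed between 3.5 and 7.0 years (both ends inclusive),
#' a proxy for childhood adiposity chosen below the pubertal window.
#'
#' @param measurements data.frame with columns `age` (years), `weight` (kg)
#'   and `height` (cm).
#' @param lower,upper Age window in years (defaults 3.5 and 7.0).
#' @return Maximum BMI in kg/m2, or `NA` if no paired observation falls in
#'   the window.
#' @export
bmi_max <- function(measurements, lower = 3.5, upper = 7.0) {
  stopifnot(all(c("age", "weight", "height") %in% names(measurements)))
  m <- measurements[!is.na(measurements$weight) & !is.na(measurements$height) &
                    measurements$age >= lower & measurements$age <= upper, ]
  if (nrow(m) == 0) return(NA_real_)
  max(m$weight / (m$height / 100)^2)
}

#' Adult height
#'
#' The model-estimated adult height `Tmax`, replaced by the largest measured
#' height whenever a measurement exceeds it.
#'
#' @param tmax Model adult height (cm), e.g. `qeps_milestones(...)$Tmax`.
#' @param measured_heights Vector of measured heights (cm); may be empty.
#' @return Adult height in cm.
#' @export
adult_height <- function(tmax, measured_heights = numeric()) {
  max(c(tmax, measured_heights), na.rm = TRUE)
}

#' Pubertal gains over the AgeP5--AgeP100 window
#'
#' Total (`Tpubgain`), specific (`Ppubgain`) and basic (`QESpubgain`) height
#' gains between pubertal onset and completion, plus
#' `Deltapubgain = Ppubgain - QESpubgain`. The additive identity
#' `Tpubgain = Ppubgain + QESpubgain` holds by construction.
#'
#' @inheritParams p_fraction
#' @return One-row data.frame with the four gains.
#' @export
pubertal_gains <- function(params, consts = qeps_shape()) {
  ms <- qeps_milestones(params, consts)
  data.frame(Tpubgain = ms$Tpubgain, Ppubgain = ms$Ppubgain,
             QESpubgain = ms$QESpubgain, Deltapubgain = ms$Deltapubgain)
}

#' Menarche-linked growth quantities
#'
#' The achieved specific pubertal fraction at menarche (`P%`), the
#' T-function height at menarcheal age, the postmenarcheal gain to adult
#' height, and the durations between menarche and the pubertal milestones.
#'
#' @inheritParams p_fraction
#' @param age_menarche Imputed menarcheal age in years.
#' @param adult_height_cm Adult height in cm ([adult_height()]).
#' @return One-row data.frame: `p_percent_menarche`, `T_age_menarche`,
#'   `postmenarcheal_gain` (floored at 0 with a warning if the model height
#'   at menarche exceeds adult height), `dur_P5_to_menarche`,
#'   `dur_PPHV_to_menarche`, `dur_menarche_to_P95`, `dur_menarche_to_P99`.
#'   All `NA` when `age_menarche` is not finite.
#' @export
menarche_growth_vars <- function(params, consts = qeps_shape(), age_menarche,
                                 adult_height_cm) {
  if (!is.finite(age_menarche))
    return(data.frame(p_percent_menarche = NA_real_, T_age_menarche = NA_real_,
                      postmenarcheal_gain = NA_real_,
                      dur_P5_to_menarche = NA_real_,
                      dur_PPHV_to_menarche = NA_real_,
                      dur_menarche_to_P95 = NA_real_,
                      dur_menarche_to_P99 = NA_real_))
  ms <- qeps_milestones(params, consts)
  t_men <- qeps_components(age_menarche, params, consts)$T
  gain <- adult_height_cm - t_men
  if (gain < 0) {
    warning(sprintf("negative postmenarcheal gain (%.2f cm) floored at 0", gain))
    gain <- 0
  }
  data.frame(
    p_percent_menarche = 100 * p_fraction(age_menarche, params, consts),
    T_age_menarche = t_men,
    postmenarcheal_gain = gain,
    dur_P5_to_menarche = age_menarche - ms$ageP5,
    dur_PPHV_to_menarche = age_menarche - ms$agePPHV,
    dur_menarche_to_P95 = ms$ageP95 - age_menarche,
    dur_menarche_to_P99 = ms$ageP99 - age_menarche)
}

#' Build the subject-by-variable cohort table
#'
#' Combines fitted QEPS parameters, measurement series and subject metadata
#' into one row per subject containing every derived variable used by the
#' milestone regressions, with cohort-internal SDS columns.
#'
#' @param fits data.frame from [fit_cohort()].
#' @param measurements Long data.frame: `subject_id`, `age`, `height`, and
#'   optionally `weight` (needed for `bmi_max`).
#' @param metadata One row per subject: `subject_id`, `birth_date`,
#'   `birth_length`, `birth_weight`, `gestational_age_days`,
#'   `mother_height`, `father_height`, `menarche_mode`, `menarche_year`,
#'   `menarche_month`, `menarche_reported_age`.
#' @param consts [qeps_shape()].
#' @return data.frame, one row per subject (class `cohort_table`), with
#'   milestone-grouped derived variables (see [milestone_groups()]).
#' @export
derive_cohort <- function(fits, measurements, metadata,
                          consts = qeps_shape()) {
  stopifnot(all(c("subject_id", "AgeP50") %in% names(fits)))
  meta <- metadata[match(fits$subject_id, metadata$subject_id), ]

  n <- nrow(fits)
  ms_list <- vector("list", n)
  men_list <- vector("list", n)
  ah <- numeric(n)
  age_men <- rep(NA_real_, n)
  bmi <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    id <- fits$subject_id[i]
    sub_m <- measurements[measurements$subject_id == id, ]
    if (!is.na(fits$AgeP50[i])) {
      pars <- qeps_params(Emax = fits$Emax[i], Qmax = fits$Qmax[i],
                          Pmax = fits$Pmax[i], Etsc = fits$Etsc[i],
                          Ptsc = fits$Ptsc[i], AgeP50 = fits$AgeP50[i])
      ms_list[[i]] <- qeps_milestones(pars, consts)
      ah[i] <- adult_height(ms_list[[i]]$Tmax, sub_m$height)
      rep_i <- try(menarche_report(
        mode = meta$menarche_mode[i], birth_date = meta$birth_date[i],
        year = meta$menarche_year[i], month = meta$menarche_month[i],
        reported_age = meta$menarche_reported_age[i]), silent = TRUE)
      if (!inherits(rep_i, "try-error"))
        age_men[i] <- tryCatch(impute_menarche_age(rep_i),
                               error = function(e) NA_real_)
      men_list[[i]] <- menarche_growth_vars(pars, consts, age_men[i], ah[i])
    } else {
      ms_list[[i]] <- qeps_milestones(qeps_params(1, 1, 1, 1, 1, 12), consts)
      ms_list[[i]][] <- NA_real_
      ah[i] <- NA_real_
      men_list[[i]] <- menarche_growth_vars(qeps_params(1, 1, 1, 1, 1, 12),
                                            consts, NA_real_, NA_real_)
    }
    if ("weight" %in% names(sub_m)) bmi[i] <- bmi_max(sub_m)
  }
  ms <- do.call(rbind, ms_list)
  men <- do.call(rbind, men_list)

  mother_sds <- cohort_sds(meta$mother_height)
  father_sds <- cohort_sds(meta$father_height)
  mph <- mph_sds(mother_sds, father_sds)
  birth_length_sds <- cohort_sds(meta$birth_length)
  birth_weight_sds <- cohort_sds(meta$birth_weight)
  ga_weeks <- meta$gestational_age_days / 7

  out <- data.frame(
    subject_id = fits$subject_id,
    # birth milestone
    mother_height_sds = mother_sds, father_height_sds = father_sds,
    mph_sds = mph, ga_weeks = ga_weeks,
    birth_length_sds = birth_length_sds, birth_weight_sds = birth_weight_sds,
    diffh_mph_birth = diffh_mph(birth_length_sds, mph),
    # childhood 7 y milestone
    etsc = fits$Etsc, emax_sds = cohort_sds(fits$Emax),
    qmax_sds = cohort_sds(fits$Qmax), bmi_max = bmi,
    bmi_max_sds = cohort_sds(bmi),
    # pubertal onset milestone
    ageP5 = ms$ageP5, t_ageP5 = ms$T_ageP5,
    # midpuberty milestone
    ageP50 = ms$ageP50, t_ageP50 = ms$T_ageP50,
    agePPHV = ms$agePPHV, ageTPHV = ms$ageTPHV,
    # late/derived quantities
    ageP95 = ms$ageP95, ageP99 = ms$ageP99, ageP100 = ms$ageP100,
    pmax = ms$Pmax, tmax = ms$Tmax, adult_height = ah,
    Tpubgain = ms$Tpubgain, Ppubgain = ms$Ppubgain,
    QESpubgain = ms$QESpubgain, Deltapubgain = ms$Deltapubgain,
    p_percent_menarche = men$p_percent_menarche,
    T_age_menarche = men$T_age_menarche,
    dur_P5_to_menarche = men$dur_P5_to_menarche,
    dur_PPHV_to_menarche = men$dur_PPHV_to_menarche,
    dur_menarche_to_P95 = men$dur_menarche_to_P95,
    dur_menarche_to_P99 = men$dur_menarche_to_P99,
    # outcomes
    age_menarche = age_men,
    postmenarcheal_gain = men$postmenarcheal_gain)
  height7 <- vapply(seq_len(n), function(i) {
    if (is.na(fits$AgeP50[i])) return(NA_real_)
    pars <- qeps_params(Emax = fits$Emax[i], Qmax = fits$Qmax[i],
                        Pmax = fits$Pmax[i], Etsc = fits$Etsc[i],
                        Ptsc = fits$Ptsc[i], AgeP50 = fits$AgeP50[i])
    qeps_components(7, pars, consts)$T
  }, numeric(1))
  out$t_7y <- height7
  out$t_7y_sds <- cohort_sds(height7)
  out$diffh_mph_7y <- diffh_mph(out$t_7y_sds, mph)
  out$t_ageP5_sds <- cohort_sds(out$t_ageP5)
  out$diffh_mph_p5 <- diffh_mph(out$t_ageP5_sds, mph)
  out$t_ageP50_sds <- cohort_sds(out$t_ageP50)
  out$diffh_mph_p50 <- diffh_mph(out$t_ageP50_sds, mph)
  out$adult_height_sds <- cohort_sds(out$adult_height)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Milestone variable grouping
#'
#' The partition of explanatory variables by the clinical milestone at which
#' they become available: parental height and birth data at *birth*;
#' childhood growth and BMI at *childhood 7 years*; pubertal-onset
#' parameters at *pubertal onset*; midpubertal variables at *midpuberty*.
#' Candidate sets for the milestone regressions are cumulative over this
#' order.
#'
#' @return Named list of character vectors of column names.
#' @export
milestone_groups <- function() {
  list(
    birth = c("mph_sds", "ga_weeks", "birth_length_sds", "birth_weight_sds",
              "diffh_mph_birth"),
    childhood7y = c("etsc", "emax_sds", "qmax_sds", "bmi_max_sds",
                    "t_7y_sds", "diffh_mph_7y"),
    pubertal_onset = c("ageP5", "t_ageP5_sds", "diffh_mph_p5"),
    midpuberty = c("ageP50", "t_ageP50_sds", "diffh_mph_p50", "agePPHV",
                   "ageTPHV"))
}
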