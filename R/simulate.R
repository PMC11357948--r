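# Synthetic cohort generator calibrated to published summaries of a cohort
# of 793 healthy term-born girls. The generator provides ground truth for
# every pipeline stage: true QEPS parameters, true milestone ages, true
# menarcheal ages and degraded questionnaire reports.

#' Synthetic cohort configuration
#'
#' Defaults reproduce the published cohort's marginal summaries: parameter
#' means/SDs of the growth model, 0.3 cm measurement noise, a well-baby +
#' school visit schedule, menarche linked to the achieved fraction of the
#' specific pubertal P-function (mean 71.6%, SD 18.8%), questionnaire
#' report modes in the observed 285:38:103:367 proportions, and parental
#' heights (mother 167.19 (6.01) cm, father 181.41 (6.66) cm).
#'
#' @param n_subjects Cohort size (default 793).
#' @param seed Seed (default 1990, the cohort's birth year).
#' @param param_means,param_sds Named means/SDs of the six QEPS parameters
#'   `(Emax, Qmax, Pmax, Etsc, Ptsc, AgeP50)`.
#' @param param_corr Named 6x6 correlation matrix; the default is identity
#'   except `corr(AgeP50, Ptsc) = 0.3` and `corr(Qmax, Emax) = 0.2`
#'   (the true covariance is unpublished; these are assumptions).
#' @param noise_sd Measurement noise SD in cm (default 0.3).
#' @param menarche_mode `"p_fraction"` (default): menarche occurs when an
#'   individually drawn fraction of P is achieved, building in the
#'   P%--menarche coupling; `"age"`: menarche age drawn independently of
#'   the growth curve (null mode).
#' @param menarche_frac_mean,menarche_frac_sd Mean and SD of the achieved
#'   P-fraction at menarche (defaults 0.716, 0.188), truncated to
#'   (0.02, 0.995).
#' @param menarche_age_mean,menarche_age_sd Used by the `"age"` mode
#'   (defaults 12.96, 1.32).
#' @param report_props Proportions of the four report modes `year_month`,
#'   `year_only`, `year_age`, `age_only` (default 285:38:103:367).
#' @param mother_mean,mother_sd,father_mean,father_sd Parental height
#'   moments in cm.
#' @param mother_daughter_corr,father_daughter_corr Correlation between the
#'   parent's height SDS and the daughter's genetic height score (the
#'   standardized sum of her `Emax + Qmax` deviations); defaults 0.3, 0.2.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(
    n_subjects = 793, seed = 1990,
    param_means = c(Emax = 62.76, Qmax = 98.51, Pmax = 12.92,
                    Etsc = 0.99, Ptsc = 1.00, AgeP50 = 11.98),
    param_sds = c(Emax = 2.83, Qmax = 7.83, Pmax = 3.58,
                  Etsc = 0.09, Ptsc = 0.15, AgeP50 = 1.00),
    param_corr = NULL,
    noise_sd = 0.3,
    menarche_mode = c("p_fraction", "age"),
    menarche_frac_mean = 0.716, menarche_frac_sd = 0.188,
    menarche_age_mean = 12.96, menarche_age_sd = 1.32,
    report_props = c(year_month = 285, year_only = 38,
                     year_age = 103, age_only = 367),
    mother_mean = 167.19, mother_sd = 6.01,
    father_mean = 181.41, father_sd = 6.66,
    mother_daughter_corr = 0.3, father_daughter_corr = 0.2) {
  menarche_mode <- match.arg(menarche_mode)
  nm <- c("Emax", "Qmax", "Pmax", "Etsc", "Ptsc", "AgeP50")
  stopifnot(all(nm %in% names(param_means)), all(nm %in% names(param_sds)))
  if (is.null(param_corr)) {
    param_corr <- diag(6)
    dimnames(param_corr) <- list(nm, nm)
    param_corr["AgeP50", "Ptsc"] <- param_corr["Ptsc", "AgeP50"] <- 0.3
    param_corr["Qmax", "Emax"] <- param_corr["Emax", "Qmax"] <- 0.2
  }
  ev <- eigen(param_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("config error: 'param_corr' must be positive semi-definite")
  structure(list(
    n_subjects = n_subjects, seed = seed,
    param_means = param_means[nm], param_sds = param_sds[nm],
    param_corr = param_corr, noise_sd = noise_sd,
    menarche_mode = menarche_mode,
    menarche_frac_mean = menarche_frac_mean,
    menarche_frac_sd = menarche_frac_sd,
    menarche_age_mean = menarche_age_mean,
    menarche_age_sd = menarche_age_sd,
    report_props = report_props,
    mother_mean = mother_mean, mother_sd = mother_sd,
    father_mean = father_mean, father_sd = father_sd,
    mother_daughter_corr = mother_daughter_corr,
    father_daughter_corr = father_daughter_corr), class = "cohort_config")
}

#' Draw true QEPS parameters for a synthetic cohort
#'
#' Multivariate normal on the six parameters, truncated to the model bounds
#' (height scales >= 0, time scales in (0.5, 2), `AgeP50` in (7, 17)) by
#' redrawing out-of-bounds subjects.
#'
#' @param config [cohort_config()].
#' @return data.frame, one row per subject, columns `subject_id` and the
#'   six parameters.
#' @export
draw_parameters <- function(config = cohort_config()) {
  n <- config$n_subjects
  mu <- config$param_means
  Sigma <- diag(config$param_sds) %*% config$param_corr %*% diag(config$param_sds)
  draw <- function(m) {
    x <- MASS::mvrnorm(m, mu = mu, Sigma = Sigma)
    if (m == 1) x <- matrix(x, 1, dimnames = list(NULL, names(mu)))
    x
  }
  ok_rows <- function(x)
    x[, "Emax"] >= 0 & x[, "Qmax"] >= 0 & x[, "Pmax"] >= 0 &
    x[, "Etsc"] > 0.5 & x[, "Etsc"] < 2 &
    x[, "Ptsc"] > 0.5 & x[, "Ptsc"] < 2 &
    x[, "AgeP50"] > 7 & x[, "AgeP50"] < 17
  x <- draw(n)
  bad <- !ok_rows(x)
  guard <- 0
  while (any(bad) && guard < 100) {
    x[bad, ] <- draw(sum(bad))
    bad <- !ok_rows(x)
    guard <- guard + 1
  }
  if (any(bad)) stop("could not draw in-bounds parameters")
  data.frame(subject_id = sprintf("S%04d", seq_len(n)), as.data.frame(x))
}

# the cohort's visit schedule: dense well-baby visits, then annual school
# health measurements, jittered
visit_ages <- function(jitter_sd = 0.05) {
  infancy <- c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2)
  school <- 3:18
  ages <- c(infancy, school)
  jit <- stats::runif(length(ages), -0.15, 0.15) * c(rep(0.3, length(infancy)),
                                                     rep(1, length(school)))
  sort(pmax(ages + jit, 0.05))
}

# childhood BMI trajectory: slowly rising through 3.5-7 y with a subject
# offset; gives BMI_max marginals near the published 16.25 (1.54)
bmi_curve <- function(age, subject_offset) {
  15.3 + subject_offset + 0.18 * pmax(age - 3.5, 0)
}

#' Render noisy measurement series for a synthetic cohort
#'
#' Heights are the model curve plus i.i.d. Gaussian noise; weights are
#' generated from a childhood BMI trajectory (per-subject level shift) so
#' that `bmi_max` has realistic spread.
#'
#' @param truth data.frame from [draw_parameters()].
#' @param config [cohort_config()].
#' @param consts [qeps_shape()].
#' @return Long data.frame: `subject_id`, `age`, `height`, `weight`.
#' @export
render_measurements <- function(truth, config = cohort_config(),
                                consts = qeps_shape()) {
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    pars <- qeps_params(Emax = truth$Emax[i], Qmax = truth$Qmax[i],
                        Pmax = truth$Pmax[i], Etsc = truth$Etsc[i],
                        Ptsc = truth$Ptsc[i], AgeP50 = truth$AgeP50[i])
    ages <- visit_ages()
    h <- qeps_components(ages, pars, consts)$T +
      stats::rnorm(length(ages), 0, config$noise_sd)
    bmi <- bmi_curve(ages, stats::rnorm(1, 0.6, 1.45)) +
      stats::rnorm(length(ages), 0, 0.3)
    rows[[i]] <- data.frame(subject_id = truth$subject_id[i], age = ages,
                            height = h, weight = bmi * (h / 100)^2)
  }
  do.call(rbind, rows)
}

#' Draw true menarche ages and degraded questionnaire reports
#'
#' In the default `p_fraction` mode each girl's menarche occurs at the age
#' when her achieved P-fraction reaches an individually drawn fraction
#' (truncated normal), building in the coupling between pubertal
#' progression and menarche. Report modes are assigned in the configured
#' proportions and the report fields are degraded from the true date
#' accordingly (e.g. `age_only` reports the floored age).
#'
#' @param truth data.frame from [draw_parameters()].
#' @param config [cohort_config()].
#' @param consts [qeps_shape()].
#' @param birth_dates Vector of birth `Date`s (default: drawn uniformly
#'   over 1990).
#' @return data.frame: `subject_id`, `birth_date`, `true_age_menarche`,
#'   `true_frac`, `menarche_mode`, `menarche_year`, `menarche_month`,
#'   `menarche_reported_age`.
#' @export
draw_menarche <- function(truth, config = cohort_config(),
                          consts = qeps_shape(), birth_dates = NULL) {
  n <- nrow(truth)
  if (is.null(birth_dates))
    birth_dates <- as.Date("1990-01-01") + floor(stats::runif(n, 0, 365))
  if (config$menarche_mode == "p_fraction") {
    f <- stats::rnorm(n, config$menarche_frac_mean, config$menarche_frac_sd)
    guard <- 0
    while (any(f <= 0.02 | f >= 0.995) && guard < 100) {
      bad <- f <= 0.02 | f >= 0.995
      f[bad] <- stats::rnorm(sum(bad), config$menarche_frac_mean,
                             config$menarche_frac_sd)
      guard <- guard + 1
    }
    f <- pmin(pmax(f, 0.021), 0.994)
    age <- vapply(seq_len(n), function(i) {
      pars <- qeps_params(Emax = truth$Emax[i], Qmax = truth$Qmax[i],
                          Pmax = truth$Pmax[i], Etsc = truth$Etsc[i],
                          Ptsc = truth$Ptsc[i], AgeP50 = truth$AgeP50[i])
      age_at_p_fraction(f[i], pars, consts)
    }, numeric(1))
  } else {
    f <- rep(NA_real_, n)
    age <- stats::rnorm(n, config$menarche_age_mean, config$menarche_age_sd)
  }
  age <- pmin(pmax(age, 8.01), 19.5)   # questionnaire-plausible range

  props <- config$report_props / sum(config$report_props)
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  modes <- sample(rep(names(counts), counts))

  men_date <- birth_dates + round(age * 365.25)
  yr <- as.integer(format(men_date, "%Y"))
  mo <- as.integer(format(men_date, "%m"))
  out <- data.frame(subject_id = truth$subject_id, birth_date = birth_dates,
                    true_age_menarche = age, true_frac = f,
                    menarche_mode = modes,
                    menarche_year = ifelse(modes %in% c("year_month",
                                                        "year_only",
                                                        "year_age"),
                                           yr, NA_integer_),
                    menarche_month = ifelse(modes == "year_month", mo,
                                            NA_integer_),
                    menarche_reported_age = ifelse(
                      modes %in% c("year_age", "age_only"),
                      floor(age), NA_real_))
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs [draw_parameters()], [render_measurements()] and [draw_menarche()]
#' under one seed and assembles the subject metadata (birth data, parental
#' heights correlated with the daughter's genetic height score, menarche
#' reports).
#'
#' @param config [cohort_config()].
#' @param consts [qeps_shape()].
#' @return List of class `synthetic_cohort`: `truth` (true parameters,
#'   achieved fraction and menarche age), `measurements` (long table),
#'   `metadata` (one row per subject), `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 5, seed = 1))
#' head(coh$measurements)
#' @export
simulate_cohort <- function(config = cohort_config(), consts = qeps_shape()) {
  old <- make_rng(config$seed)
  on.exit(restore_rng(old))
  truth <- draw_parameters(config)
  n <- nrow(truth)
  meas <- render_measurements(truth, config, consts)
  men <- draw_menarche(truth, config, consts)

  # parental heights: correlated with the daughter's genetic height score
  gen <- scale(scale(truth$Emax) + scale(truth$Qmax))[, 1]
  rm_ <- config$mother_daughter_corr
  rf_ <- config$father_daughter_corr
  mother <- config$mother_mean + config$mother_sd *
    (rm_ * gen + sqrt(1 - rm_^2) * stats::rnorm(n))
  father <- config$father_mean + config$father_sd *
    (rf_ * gen + sqrt(1 - rf_^2) * stats::rnorm(n))

  ga_days <- round(stats::rnorm(n, 281, 9))
  ga_days <- pmin(pmax(ga_days, 254), 293)        # term range
  birth_len <- round(stats::rnorm(n, 50.09, 2.05), 1)
  birth_wt <- round(stats::rnorm(n, 3.53, 0.50), 2)

  metadata <- data.frame(
    subject_id = truth$subject_id, birth_date = men$birth_date,
    gestational_age_days = ga_days, birth_length = birth_len,
    birth_weight = birth_wt, mother_height = round(mother),
    father_height = round(father),
    menarche_mode = men$menarche_mode, menarche_year = men$menarche_year,
    menarche_month = men$menarche_month,
    menarche_reported_age = men$menarche_reported_age)

  truth$true_age_menarche <- men$true_age_menarche
  truth$true_frac <- men$true_frac
  truth$true_ageP5 <- vapply(seq_len(n), function(i) {
    pars <- qeps_params(Emax = truth$Emax[i], Qmax = truth$Qmax[i],
                        Pmax = truth$Pmax[i], Etsc = truth$Etsc[i],
                        Ptsc = truth$Ptsc[i], AgeP50 = truth$AgeP50[i])
    age_at_p_fraction(0.05, pars, consts)
  }, numeric(1))

  structure(list(truth = truth, measurements = meas, metadata = metadata,
                 config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, %d measurements (seed %d)\n",
              nrow(x$truth), nrow(x$measurements), x$config$seed))
  cat(sprintf("  true AgeP50 mean %.2f y, true menarche mean %.2f y\n",
              mean(x$truth$AgeP50), mean(x$truth$true_age_menarche)))
  invisible(x)
}
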