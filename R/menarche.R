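# Imputation of menarcheal age from questionnaire reports.
#
# Cohort questionnaires asked for the first period as year and/or month
# and/or age; the four observed reporting patterns are imputed to a decimal
# age with midpoint rules, and age-only reports get the empirically
# validated +0.193 year correction.

#' Construct a menarche report
#'
#' @param mode One of `"year_month"`, `"year_only"`, `"year_age"`,
#'   `"age_only"`: which fields the respondent filled in.
#' @param birth_date Date of birth (`Date` or ISO-8601 string).
#' @param year Reported calendar year (modes with a year).
#' @param month Reported month 1--12 (`year_month` only).
#' @param reported_age Reported age in whole (or fractional) years
#'   (`year_age`, `age_only`).
#' @return Object of class `menarche_report`.
#' @export
menarche_report <- function(mode, birth_date, year = NA_integer_,
                            month = NA_integer_, reported_age = NA_real_) {
  mode <- match.arg(mode, c("year_month", "year_only", "year_age", "age_only"))
  birth_date <- as.Date(birth_date)
  if (is.na(birth_date)) stop("'birth_date' must be a valid date")
  need <- switch(mode,
    year_month = c(year = !is.na(year), month = !is.na(month)),
    year_only  = c(year = !is.na(year)),
    year_age   = c(year = !is.na(year), reported_age = !is.na(reported_age)),
    age_only   = c(reported_age = !is.na(reported_age)))
  if (!all(need))
    stop(sprintf("mode '%s' requires fields: %s", mode,
                 paste(names(need)[!need], collapse = ", ")))
  if (!is.na(month) && (month < 1 || month > 12))
    stop("'month' must be in 1..12")
  if (!is.na(reported_age) && (reported_age < 8 || reported_age > 20))
    stop("'reported_age' must be in [8, 20]")
  structure(list(mode = mode, birth_date = birth_date, year = year,
                 month = month, reported_age = reported_age),
            class = "menarche_report")
}

# decimal age in years between two dates (365.25-day year)
decimal_age <- function(birth_date, date) {
  as.numeric(date - birth_date) / 365.25
}

#' Impute menarcheal age from a questionnaire report
#'
#' Imputation rules by reporting pattern:
#' * `year_month`: decimal age from birth date to the middle (day 15) of the
#'   recorded month;
#' * `year_only`: decimal age to the middle of the recorded year (July 2);
#' * `year_age`: midpoint of the overlap between the year of life at the
#'   stated age and the stated calendar year;
#' * `age_only`: reported age + 0.193 years, the correction estimated from
#'   respondents who reported year, month and age.
#'
#' @param report A [menarche_report()], or a list/data.frame row with the
#'   same fields.
#' @return Imputed menarcheal age in decimal years.
#' @examples
#' impute_menarche_age(menarche_report("age_only", "1990-06-01",
#'                                     reported_age = 13))
#' @export
impute_menarche_age <- function(report) {
  if (!inherits(report, "menarche_report"))
    report <- menarche_report(mode = report$mode,
                              birth_date = report$birth_date,
                              year = report$year, month = report$month,
                              reported_age = report$reported_age)
  bd <- report$birth_date
  birth_year <- as.integer(format(bd, "%Y"))
  if (!is.na(report$year) && report$year < birth_year)
    stop("consistency error: reported year precedes birth year")
  age <- switch(report$mode,
    year_month = decimal_age(bd, as.Date(sprintf("%04d-%02d-15",
                                                 report$year, report$month))),
    year_only = decimal_age(bd, as.Date(sprintf("%04d-07-02", report$year))),
    year_age = {
      a <- floor(report$reported_age)
      # year of life at the stated age
      lo_a <- seq(bd, by = sprintf("%d years", a), length.out = 2)[2]
      hi_a <- seq(bd, by = sprintf("%d years", a + 1), length.out = 2)[2]
      lo_y <- as.Date(sprintf("%04d-01-01", report$year))
      hi_y <- as.Date(sprintf("%04d-12-31", report$year)) + 1
      lo <- max(lo_a, lo_y)
      hi <- min(hi_a, hi_y)
      if (lo >= hi)
        stop("consistency error: stated age and year do not overlap")
      decimal_age(bd, lo + as.numeric(hi - lo) / 2)
    },
    age_only = report$reported_age + 0.193)
  if (age < 6 || age > 20)
    stop(sprintf("range error: imputed menarcheal age %.2f outside [6, 20]", age))
  age
}
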