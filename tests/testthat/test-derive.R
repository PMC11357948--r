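test_that("midparental height is the mean of parental SDS and propagates NA", {
  expect_equal(mph_sds(1.0, 0.0), 0.5)
  expect_equal(mph_sds(0, 0), 0)
  expect_equal(mph_sds(-2.86, 2.64), -0.11)
  expect_true(is.na(mph_sds(NA, 1.2)))
})

test_that("diffh_mph is a plain SDS difference", {
  expect_equal(diffh_mph(0.5, 0.5), 0)
  expect_equal(diffh_mph(1.2, 0.5), 0.7)
  set.seed(1)
  h <- rnorm(100); m <- rnorm(100)
  expect_equal(diffh_mph(h, m), h - m)
})

test_that("bmi_max takes the window maximum with inclusive bounds", {
  m1 <- data.frame(age = 5, weight = 16 * 1.1^2, height = 110)
  expect_equal(bmi_max(m1), 16)
  # observation at 3.4 y excluded by the window rule
  m2 <- data.frame(age = c(3.4, 5, 6),
                   weight = c(19, 16, 17), height = 100)
  expect_equal(bmi_max(m2), 17)
  # boundary ages are inside
  m3 <- data.frame(age = c(3.5, 7.0), weight = c(18, 15), height = 100)
  expect_equal(bmi_max(m3), 18)
  expect_true(is.na(bmi_max(data.frame(age = c(2, 8), weight = 15,
                                       height = 100))))
  # brute-force oracle on random series
  set.seed(42)
  for (i in 1:20) {
    m <- data.frame(age = runif(12, 0, 10), weight = runif(12, 12, 35),
                    height = runif(12, 80, 140))
    keep <- m$age >= 3.5 & m$age <= 7
    oracle <- if (any(keep)) max((m$weight / (m$height / 100)^2)[keep])
              else NA_real_
    expect_equal(bmi_max(m), oracle)
  }
})

test_that("to_sds standardizes against an age-interpolated reference", {
  ref <- sds_reference(data.frame(age = c(5, 10), mean = c(110, 140),
                                  sd = c(5, 6)), "height")
  expect_equal(to_sds(110, 5, ref), 0)
  expect_equal(to_sds(115, 5, ref), 1)
  expect_equal(to_sds(125, 7.5, ref), 0)       # interpolated mean
  # round trip sds -> value -> sds
  sds <- 1.3
  val <- 140 + sds * 6
  expect_equal(to_sds(val, 10, ref), sds)
  # extrapolation refused
  expect_true(is.na(to_sds(150, 12, ref)))
  # cohort-internal mode
  expect_equal(to_sds(12, ref = sds_reference(), cohort_mean = 10,
                      cohort_sd = 2), 1)
  expect_error(sds_reference(data.frame(age = c(5, 5), mean = 1, sd = 1)),
               "increasing")
  expect_error(sds_reference(data.frame(age = c(5, 6), mean = 1,
                                        sd = c(1, 0))), "sd")
})

test_that("adult height takes measured height when it exceeds the model", {
  expect_equal(adult_height(168.0, c(150, 167.2)), 168.0)
  expect_equal(adult_height(168.0, c(150, 168.9)), 168.9)
  set.seed(3)
  for (i in 1:20) {
    tmax <- runif(1, 150, 185)
    h <- runif(8, 140, 190)
    expect_equal(adult_height(tmax, h), max(c(tmax, h)))
  }
})

test_that("pubertal gains are additive and match a quadrature oracle", {
  # degenerate case: no specific pubertal growth
  p0 <- qeps_params(Emax = 60, Qmax = 95, Pmax = 0, Etsc = 1, Ptsc = 1,
                    AgeP50 = 12)
  g0 <- pubertal_gains(p0)
  expect_equal(g0$Ppubgain, 0)
  expect_equal(g0$Deltapubgain, -g0$QESpubgain)
  for (p in random_params(10, seed = 17)) {
    g <- pubertal_gains(p)
    expect_equal(g$Tpubgain, g$Ppubgain + g$QESpubgain, tolerance = 1e-12)
    expect_lte(g$Ppubgain, p$Pmax)
    expect_lt(p$Pmax - g$Ppubgain, 0.15 * p$Pmax + 1e-12)
  }
  # quadrature of component velocities over [AgeP5, AgeP100]
  ms <- qeps_milestones(pars_typical)
  for (comp in c("P", "QES", "T")) {
    qg <- integrate(function(a) qeps_velocity(a, pars_typical)[[comp]],
                    ms$ageP5, ms$ageP100, rel.tol = 1e-10)$value
    got <- switch(comp, P = ms$Ppubgain, QES = ms$QESpubgain,
                  T = ms$Tpubgain)
    expect_equal(got, qg, tolerance = 1e-3)
  }
})

test_that("menarche growth variables follow the model definitions", {
  ms <- qeps_milestones(pars_typical)
  at50 <- menarche_growth_vars(pars_typical, sh_default,
                               age_menarche = ms$ageP50,
                               adult_height_cm = ms$Tmax)
  expect_equal(at50$p_percent_menarche, 50)
  at95 <- menarche_growth_vars(pars_typical, sh_default,
                               age_menarche = ms$ageP95,
                               adult_height_cm = ms$Tmax)
  expect_equal(at95$p_percent_menarche, 95)
  # plain subtraction for postmenarcheal gain
  v <- menarche_growth_vars(pars_typical, sh_default, age_menarche = 13,
                            adult_height_cm = 168)
  t13 <- qeps_components(13, pars_typical)$T
  expect_equal(v$postmenarcheal_gain, 168 - t13)
  # negative gain floored at zero with a warning
  expect_warning(
    v2 <- menarche_growth_vars(pars_typical, sh_default, age_menarche = 20,
                               adult_height_cm = t13),
    "floored")
  expect_equal(v2$postmenarcheal_gain, 0)
  # missing menarche propagates
  v3 <- menarche_growth_vars(pars_typical, sh_default, NA_real_, 168)
  expect_true(all(is.na(v3)))
})

test_that("achieved P% increases strictly with menarcheal age", {
  ages <- seq(10, 16, by = 0.25)
  pp <- vapply(ages, function(a)
    menarche_growth_vars(pars_typical, sh_default, a,
                         180)$p_percent_menarche, numeric(1))
  expect_true(all(diff(pp) > 0))
  expect_true(all(pp >= 0 & pp <= 100))
})

test_that("derive_cohort assembles one row per subject with group columns", {
  coh <- simulate_cohort(cohort_config(n_subjects = 8, seed = 31))
  fits <- fit_cohort(coh$measurements)
  d <- derive_cohort(fits, coh$measurements, coh$metadata)
  expect_equal(nrow(d), 8)
  expect_true(all(unlist(milestone_groups()) %in% names(d)))
  expect_true(all(c("age_menarche", "postmenarcheal_gain") %in% names(d)))
  ok <- !is.na(d$ageP50)
  expect_equal(d$Tpubgain[ok], d$Ppubgain[ok] + d$QESpubgain[ok],
               tolerance = 1e-10)
  expect_true(all(d$postmenarcheal_gain[!is.na(d$postmenarcheal_gain)] >= 0))
  # cohort-internal SDS columns have mean 0, SD 1
  expect_equal(mean(d$t_7y_sds, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(d$t_7y_sds, na.rm = TRUE), 1, tolerance = 1e-10)
})
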