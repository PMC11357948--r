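test_that("p_fraction is a normalized, strictly increasing sigmoid", {
  expect_equal(p_fraction(pars_typical$AgeP50, pars_typical, sh_default), 0.5)
  # deep lower tail
  expect_lt(p_fraction(pars_typical$AgeP50 - 50 * pars_typical$Ptsc,
                       pars_typical, sh_default), 1e-6)
  grid <- seq(-0.5, 30, by = 0.01)
  pf <- p_fraction(grid, pars_typical, sh_default)
  expect_true(all(diff(pf) > 0))
  expect_true(all(pf > 0 & pf < 1))
  expect_error(p_fraction(NA_real_, pars_typical, sh_default), "finite")
  expect_error(p_fraction(Inf, pars_typical, sh_default), "finite")
})

test_that("symmetric logistic shape places 5% exactly 2.22 y before AgeP50", {
  sh1 <- qeps_shape(nu = 1)                      # symmetric special case
  p1 <- qeps_params(Emax = 60, Qmax = 95, Pmax = 12, Etsc = 1, Ptsc = 1,
                    AgeP50 = 12)
  expect_equal(p_fraction(9.78, p1, sh1), 0.05, tolerance = 1e-10)
  # bisection-style confirmation on a dense grid
  grid <- seq(8, 12, by = 1e-5)
  crossing <- grid[which.min(abs(p_fraction(grid, p1, sh1) - 0.05))]
  expect_equal(crossing, 9.78, tolerance = 2e-5)
})

test_that("components satisfy the additive decomposition and limits", {
  grid <- seq(-0.5, 30, length.out = 1000)
  cc <- qeps_components(grid, pars_typical, sh_default)
  expect_equal(cc$T, cc$QES + cc$P, tolerance = 1e-12)
  expect_true(all(cc[, c("E", "Q", "QES", "P", "T")] >= 0))
  expect_true(all(cc$P <= pars_typical$Pmax))
  # E plateau: exact limit, and >= 95% reached by age 2
  expect_equal(qeps_components(80, pars_typical, sh_default)$E,
               pars_typical$Emax, tolerance = 1e-8)
  expect_gt(qeps_components(2, pars_typical, sh_default)$E,
            0.95 * pars_typical$Emax)
  # with no specific pubertal growth, T collapses onto QES
  p0 <- qeps_params(Emax = 60, Qmax = 95, Pmax = 0, Etsc = 1, Ptsc = 1,
                    AgeP50 = 12)
  cc0 <- qeps_components(grid, p0, sh_default)
  expect_equal(cc0$T, cc0$QES, tolerance = 1e-12)
  expect_error(qeps_components(-1, pars_typical, sh_default), "t0")
})

test_that("total height is non-decreasing and plateaus after growth stops", {
  for (p in random_params(5, seed = 11)) {
    grid <- seq(-0.6, 40, by = 0.02)
    tt <- qeps_components(grid, p, sh_default)$T
    expect_true(all(diff(tt) > -1e-9))
    expect_lt(qeps_components(40, p, sh_default)$T -
              qeps_components(25, p, sh_default)$T, 1e-3)
  }
})

test_that("analytic velocities agree with numerical differentiation", {
  grid <- seq(0, 22, by = 0.25)
  h <- 1e-4
  up <- qeps_components(grid + h, pars_typical, sh_default)
  dn <- qeps_components(grid - h, pars_typical, sh_default)
  vel <- qeps_velocity(grid, pars_typical, sh_default)
  for (comp in c("E", "Q", "P", "T"))
    expect_equal(vel[[comp]], (up[[comp]] - dn[[comp]]) / (2 * h),
                 tolerance = 1e-6)
  expect_equal(vel$T, vel$QES + vel$P, tolerance = 1e-12)
})

test_that("integrated total velocity reproduces the height gain", {
  gain <- integrate(function(a) qeps_velocity(a, pars_typical, sh_default)$T,
                    0, 30, rel.tol = 1e-10, subdivisions = 2000)$value
  expect_equal(gain,
               qeps_components(30, pars_typical, sh_default)$T -
               qeps_components(0, pars_typical, sh_default)$T,
               tolerance = 1e-3)
})

test_that("with a symmetric P shape, peak P-velocity sits at AgeP50", {
  sh1 <- qeps_shape(nu = 1)
  p1 <- qeps_params(Emax = 60, Qmax = 95, Pmax = 12, Etsc = 1, Ptsc = 1,
                    AgeP50 = 12)
  grid <- seq(8, 16, by = 1e-3)
  vP <- qeps_velocity(grid, p1, sh1)$P
  expect_equal(grid[which.max(vP)], 12, tolerance = 2e-3)
})

test_that("with nu > 1 the P-function PHV falls before AgeP50", {
  for (p in random_params(5, seed = 3)) {
    ms <- qeps_milestones(p, sh_default)
    expect_lt(ms$agePPHV, p$AgeP50)
    # closed form matches a dense-grid argmax of the P velocity
    grid <- seq(ms$ageP5 - 2, ms$ageP95 + 2, by = 1e-4)
    vP <- qeps_velocity(grid, p, sh_default)$P
    expect_equal(ms$agePPHV, grid[which.max(vP)], tolerance = 2e-4)
  }
})

test_that("age_at_p_fraction inverts p_fraction", {
  expect_equal(age_at_p_fraction(0.5, pars_typical, sh_default),
               pars_typical$AgeP50)
  for (f in c(0.01, 0.05, 0.5, 0.95, 0.999)) {
    a <- age_at_p_fraction(f, pars_typical, sh_default)
    expect_equal(p_fraction(a, pars_typical, sh_default), f,
                 tolerance = 1e-6)
  }
  expect_lt(age_at_p_fraction(0.05, pars_typical, sh_default),
            age_at_p_fraction(0.95, pars_typical, sh_default))
  expect_error(age_at_p_fraction(0, pars_typical, sh_default), "inside")
  expect_error(age_at_p_fraction(1, pars_typical, sh_default), "inside")
})

test_that("milestone inversion matches a dense-grid oracle", {
  for (p in random_params(4, seed = 5)) {
    grid <- seq(p$AgeP50 - 8, p$AgeP50 + 10, by = 1e-4)
    pf <- p_fraction(grid, p, sh_default)
    for (f in c(0.05, 0.5, 0.95, 0.99)) {
      oracle <- grid[which.min(abs(pf - f))]
      expect_equal(age_at_p_fraction(f, p, sh_default), oracle,
                   tolerance = 1.01e-4)
    }
  }
})

test_that("milestones are ordered and gains are additive", {
  for (p in random_params(6, seed = 7)) {
    ms <- qeps_milestones(p, sh_default)
    expect_true(ms$ageP5 < ms$ageP50 && ms$ageP50 < ms$ageP95 &&
                ms$ageP95 < ms$ageP99 && ms$ageP99 < ms$ageP100)
    expect_equal(ms$Tpubgain, ms$Ppubgain + ms$QESpubgain, tolerance = 1e-12)
    expect_equal(ms$Deltapubgain, ms$Ppubgain - ms$QESpubgain,
                 tolerance = 1e-12)
  }
})

test_that("the dilogarithm helper matches its integral representation", {
  li2_int <- function(y)
    -integrate(function(t) log1p(t) / t, 0, y, rel.tol = 1e-12)$value
  for (y in c(0.05, 0.5, 1, 2.5, 40, 1e6))
    expect_equal(qepsgrowth:::li2neg(y), li2_int(y), tolerance = 1e-10)
})

test_that("shape constants are validated", {
  expect_error(qeps_shape(c0 = -0.1), "positive")
  expect_error(qeps_shape(pEnd = 1), "pEnd")
  expect_error(qeps_params(Emax = -1, Qmax = 90, Pmax = 10, AgeP50 = 12),
               ">= 0")
  expect_error(qeps_params(Emax = 60, Qmax = 90, Pmax = 10, Etsc = 0,
                           AgeP50 = 12), "> 0")
  expect_error(qeps_params(Emax = 60, Qmax = 90, Pmax = 10, AgeP50 = 4),
               "AgeP50")
})
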