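test_that("standardize centers and scales by the column's own SD", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40))
  s <- standardize(d)
  expect_equal(sapply(s, mean), c(a = 0, b = 0))
  expect_equal(sapply(s, sd), c(a = 1, b = 1))
  expect_equal(standardize(s)$a, s$a, tolerance = 1e-12)   # idempotent
  d$flat <- 5
  expect_error(standardize(d), "flat")
})

test_that("Holm adjustment matches the hand-computed step-down", {
  # m = 2: sorted p multiplied by (2, 1), monotone enforced
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.5)), 0.5)
  # hand-computed 4-value case with monotonicity carry-over
  p <- c(0.03, 0.01, 0.04, 0.005)
  # sorted: .005*4=.02, .01*3=.03, .03*2=.06, .04*1=.04 -> carried to .06
  expect_equal(holm_adjust(p), c(0.06, 0.03, 0.06, 0.02))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:20) {
    pv <- runif(sample(2:10, 1))
    adj <- holm_adjust(pv)
    expect_true(all(adj <= pmin(pv * length(pv), 1) + 1e-12))  # <= Bonferroni
    expect_true(all(adj >= pv))
    ord <- sample(length(pv))
    expect_equal(holm_adjust(pv[ord]), adj[ord])   # order invariance
  }
})

test_that("univariable scan recovers exact and null relations", {
  set.seed(101)
  d <- data.frame(x = rnorm(200))
  d$y <- 2 * d$x + 5
  # an exact linear relation trips lm's perfect-fit warning; expected here
  suppressWarnings(scan <- univariable_scan(d, "y", "x"))
  expect_equal(scan$beta, 1, tolerance = 1e-10)
  expect_equal(scan$r2, 1, tolerance = 1e-10)
  # independent predictor at large n
  d2 <- data.frame(x = rnorm(1e4), y = rnorm(1e4))
  scan2 <- univariable_scan(d2, "y", "x")
  expect_lt(abs(scan2$beta), 0.05)
  expect_gt(scan2$p, 0.05)
  # standardized beta equals the Pearson correlation
  d3 <- data.frame(x = rnorm(300), e = rnorm(300))
  d3$y <- 0.4 * d3$x + d3$e
  scan3 <- univariable_scan(d3, "y", "x")
  expect_equal(scan3$beta, cor(d3$x, d3$y), tolerance = 1e-10)
  expect_equal(scan3$r2, cor(d3$x, d3$y)^2, tolerance = 1e-10)
  expect_true(scan3$ci_low <= scan3$beta && scan3$beta <= scan3$ci_high)
})

test_that("variables with too few complete pairs are skipped", {
  d <- data.frame(y = rnorm(30), x1 = rnorm(30),
                  x2 = c(rnorm(5), rep(NA, 25)))
  expect_message(scan <- univariable_scan(d, "y", c("x1", "x2")),
                 "skipping")
  expect_equal(scan$variable, "x1")
})

test_that("stepwise selection finds the true predictor among noise", {
  set.seed(77)
  hits <- vapply(seq_len(100), function(i) {
    n <- 500
    d <- as.data.frame(matrix(rnorm(n * 6), n,
                              dimnames = list(NULL, paste0("x", 1:6))))
    d$y <- 0.3 * d$x1 + rnorm(n)
    sel <- stepwise_select(d, "y", paste0("x", 1:6))$selected
    "x1" %in% sel
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise handles empty candidate sets and collinearity", {
  d <- data.frame(y = rnorm(50))
  fit <- stepwise_select(d, "y", character())
  expect_equal(fit$selected, character())
  expect_equal(fit$r2, 0)
  set.seed(5)
  d2 <- data.frame(x1 = rnorm(100))
  d2$x2 <- 2 * d2$x1                       # perfect duplicate
  d2$y <- d2$x1 + rnorm(100, 0, 0.5)
  expect_warning(fit2 <- stepwise_select(d2, "y", c("x1", "x2")),
                 "collinear")
  expect_equal(fit2$selected, "x1")
})

test_that("orthogonal predictors are both selected with additive R2", {
  set.seed(19)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- residuals(lm(x2 ~ x1))             # exactly orthogonal in-sample
  d <- data.frame(x1 = x1, x2 = x2)
  d$y <- 0.5 * scale(x1)[, 1] + 0.4 * scale(x2)[, 1] + rnorm(n, 0, 0.7)
  fit <- stepwise_select(d, "y", c("x1", "x2"))
  expect_setequal(fit$selected, c("x1", "x2"))
  uni <- univariable_scan(d, "y", c("x1", "x2"))
  expect_equal(fit$r2, sum(uni$r2), tolerance = 1e-6)
  # partial R2 of each approx its marginal delta-R2 for orthogonal designs
  expect_equal(fit$table$partial_r2[fit$table$variable == "x1"],
               (fit$r2 - uni$r2[uni$variable == "x2"]) /
                 (1 - uni$r2[uni$variable == "x2"]),
               tolerance = 1e-6)
})

test_that("partial R2 reduces to model R2 for single-variable models", {
  set.seed(23)
  d <- data.frame(x = rnorm(120))
  d$y <- 0.6 * d$x + rnorm(120)
  fit <- stepwise_select(d, "y", "x")
  expect_equal(fit$table$partial_r2, fit$r2, tolerance = 1e-12)
  # bounded on random designs
  for (i in 1:10) {
    dd <- as.data.frame(matrix(rnorm(60 * 4), 60,
                               dimnames = list(NULL, c("y", "a", "b", "c"))))
    pr <- partial_r2(dd, "y", c("a", "b", "c"), "b")
    expect_gte(pr, 0)
    expect_lte(pr, 1)
  }
})

test_that("stepwise recovers a known active set with high sensitivity", {
  set.seed(311)
  sens <- vapply(seq_len(10), function(r) {
    n <- 793
    d <- as.data.frame(matrix(rnorm(n * 8), n,
                              dimnames = list(NULL, paste0("v", 1:8))))
    d$y <- 0.25 * d$v1 - 0.2 * d$v4 + 0.3 * d$v7 + rnorm(n)
    sel <- stepwise_select(d, "y", paste0("v", 1:8))$selected
    mean(c("v1", "v4", "v7") %in% sel)
  }, numeric(1))
  expect_gte(mean(sens), 0.9)
})

test_that("milestone models localize signal and have nested R2", {
  # outcome driven only by a pubertal-onset variable
  set.seed(404)
  n <- 300
  tab <- as.data.frame(matrix(rnorm(n * length(unlist(milestone_groups()))),
                              n, dimnames = list(NULL,
                                                 unlist(milestone_groups()))))
  tab$age_menarche <- 1.2 * tab$ageP5 + rnorm(n, 0, 0.6)
  mm <- milestone_models(tab, "age_menarche")
  r2 <- vapply(mm, function(x) x$r2, numeric(1))
  expect_lt(r2[["birth"]], 0.05)
  expect_lt(r2[["childhood7y"]], 0.05)
  expect_gt(r2[["pubertal_onset"]], 0.5)
  # cumulative candidate sets: R2 non-decreasing across milestones
  expect_true(all(diff(r2) > -1e-9))
  # reproducible: same input, same report
  mm2 <- milestone_models(tab, "age_menarche")
  expect_identical(r2, vapply(mm2, function(x) x$r2, numeric(1)))
  expect_error(milestone_models(tab[, -match("ageP5", names(tab))]),
               "configuration")
})

test_that("postmenarcheal-gain outcome skips the multivariable step when at
           most one association is significant", {
  set.seed(55)
  n <- 200
  tab <- as.data.frame(matrix(rnorm(n * length(unlist(milestone_groups()))),
                              n, dimnames = list(NULL,
                                                 unlist(milestone_groups()))))
  tab$postmenarcheal_gain <- rnorm(n)      # no real associations
  mm <- milestone_models(tab, "postmenarcheal_gain")
  expect_true(all(vapply(mm, function(x) is.null(x$model), logical(1))))
})
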