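# Component evaluation of the QEPS model.
#
# All closed form. The stopped Q height needs the integral of a linear
# velocity times a logistic brake, which is expressed with softplus and the
# dilogarithm (li2 below) instead of numerical quadrature, so that curve
# evaluation inside the fitting loop stays cheap and exact.

# log(1 + exp(x)) without overflow
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Dilogarithm Li2(-y) for y >= 0, vectorised.
# y <= 1: Li2(-y) = -Li2(y/(1+y)) - log(1+y)^2/2 with a fast series on [0, 1/2].
# y >  1: inversion Li2(-y) = -pi^2/6 - log(y)^2/2 - Li2(-1/y).
li2neg <- function(y) {
  stopifnot(all(y >= 0))
  out <- numeric(length(y))
  big <- y > 1
  yy <- ifelse(big, 1 / y, y)
  w <- yy / (1 + yy)                       # in [0, 1/2]
  s <- numeric(length(w))
  term <- w
  for (k in 1:60) {                        # (1/2)^60 ~ 9e-19: converged
    s <- s + term / k^2
    term <- term * w
  }
  small_val <- -s - log1p(yy)^2 / 2        # Li2(-yy)
  out[!big] <- small_val[!big]
  out[big] <- -pi^2 / 6 - log(y[big])^2 / 2 - small_val[big]
  out
}

# antiderivatives of sigma and s*sigma for the logistic brake
# sigma(s) = plogis((s - m)/w); I0' = sigma, I1' = s * sigma
brake_I0 <- function(s, m, w) w * softplus((s - m) / w)
brake_I1 <- function(s, m, w) {
  x <- (s - m) / w
  w * (m * softplus(x) + w * (x * softplus(x) + li2neg(exp(pmin(x, 700)))))
}

#' Achieved fraction of the specific pubertal P-function
#'
#' Normalized Richards-type sigmoid describing the proportion of the
#' individual's specific pubertal growth achieved by a given age. Equals
#' 0.5 at `AgeP50` by construction; strictly increasing in age.
#'
#' @param age Numeric vector of ages in decimal years since birth.
#' @param params [qeps_params()] object.
#' @param consts [qeps_shape()] object.
#' @return Numeric vector of fractions in (0, 1).
#' @seealso [age_at_p_fraction()] for the inverse.
#' @examples
#' p_fraction(12, qeps_params(60, 98, 13, 1, 1, 12), qeps_shape())
#' @export
p_fraction <- function(age, params, consts = qeps_shape()) {
  if (!all(is.finite(age))) stop("'age' must be finite")
  params <- as_qeps_params(params)
  x <- consts$k * (age - params$AgeP50) / params$Ptsc + consts$x50
  (1 + exp(-x))^(-consts$nu)
}

#' Age at which a given fraction of the P-function is achieved
#'
#' Exact inverse of [p_fraction()]; used to define the pubertal milestones
#' `AgeP5` (onset), `AgeP50` (midpuberty), `AgeP95`, `AgeP99` and the
#' operational `AgeP100` (`pEnd` of the shape constants).
#'
#' @param frac Fraction(s) strictly inside (0, 1).
#' @inheritParams p_fraction
#' @return Ages in decimal years.
#' @examples
#' pars <- qeps_params(60, 98, 13, 1, 1, 12)
#' age_at_p_fraction(c(0.05, 0.5, 0.95), pars)
#' @export
age_at_p_fraction <- function(frac, params, consts = qeps_shape()) {
  if (!all(is.finite(frac)) || any(frac <= 0) || any(frac >= 1))
    stop("'frac' must lie strictly inside (0, 1)")
  params <- as_qeps_params(params)
  xf <- -log(frac^(-1 / consts$nu) - 1)
  params$AgeP50 + params$Ptsc * (xf - consts$x50) / consts$k
}

# centre of the S stop brake: pubertal completion (95% of P)
stop_centre <- function(params, consts) {
  age_at_p_fraction(0.95, params, consts)
}

# stopped Q-function height and velocity at given ages (vectorised).
# Un-stopped Q velocity declines linearly from its value at t0 to zero at
# age tQ; heights are normalised so the un-stopped plateau equals Qmax.
# The S brake multiplies the velocity by (1 - sigma(age)).
q_stopped <- function(age, params, consts, what = c("height", "velocity")) {
  what <- match.arg(what)
  c0 <- consts$c0
  tauQ <- consts$tQ + c0
  v0 <- 2 * params$Qmax / tauQ
  m <- stop_centre(params, consts)
  w <- consts$sS
  a <- pmin(age, consts$tQ)            # velocity is zero past tQ anyway
  if (what == "velocity") {
    v <- v0 * (1 - (a + c0) / tauQ) * (1 - stats::plogis((a - m) / w))
    v[age > consts$tQ] <- 0
    return(v)
  }
  tau <- a + c0
  U <- params$Qmax * (2 * tau / tauQ - (tau / tauQ)^2)
  # correction: integral of (A + B s) * sigma(s) from -c0 to a
  A <- v0 * (1 - c0 / tauQ)
  B <- -v0 / tauQ
  C <- A * (brake_I0(a, m, w) - brake_I0(-c0, m, w)) +
       B * (brake_I1(a, m, w) - brake_I1(-c0, m, w))
  U - C
}

#' Evaluate the QEPS component heights
#'
#' Returns the E, Q-with-stop, QES, P and total T heights (cm) at the given
#' ages. `QES = E + Q` (Q already includes the S brake) and `T = QES + P`
#' exactly, by construction.
#'
#' @inheritParams p_fraction
#' @return A data.frame with columns `age`, `E`, `Q`, `QES`, `P`, `T`.
#' @examples
#' pars <- qeps_params(62.8, 98.5, 12.9, 1, 1, 12)
#' qeps_components(c(0, 7, 12, 18), pars)
#' @export
qeps_components <- function(age, params, consts = qeps_shape()) {
  if (!all(is.finite(age))) stop("'age' must be finite")
  params <- as_qeps_params(params)
  if (any(age < -consts$c0))
    stop("'age' must be >= -c0 (the model starts at t0, before birth)")
  E <- params$Emax * (1 - exp(-(age + consts$c0) / (consts$thetaE * params$Etsc)))
  Q <- q_stopped(age, params, consts, "height")
  P <- params$Pmax * p_fraction(age, params, consts)
  QES <- E + Q
  data.frame(age = age, E = E, Q = Q, QES = QES, P = P, T = QES + P)
}

#' Evaluate QEPS component velocities
#'
#' Analytic first derivatives (cm/year) of the component heights.
#'
#' @inheritParams p_fraction
#' @return A data.frame with columns `age`, `E`, `Q`, `QES`, `P`, `T`.
#' @examples
#' pars <- qeps_params(62.8, 98.5, 12.9, 1, 1, 12)
#' qeps_velocity(seq(10, 14, 0.5), pars)
#' @export
qeps_velocity <- function(age, params, consts = qeps_shape()) {
  if (!all(is.finite(age))) stop("'age' must be finite")
  params <- as_qeps_params(params)
  if (any(age < -consts$c0))
    stop("'age' must be >= -c0 (the model starts at t0, before birth)")
  thE <- consts$thetaE * params$Etsc
  vE <- params$Emax / thE * exp(-(age + consts$c0) / thE)
  vQ <- q_stopped(age, params, consts, "velocity")
  x <- consts$k * (age - params$AgeP50) / params$Ptsc + consts$x50
  # d/dage of (1+e^-x)^-nu
  vP <- params$Pmax * consts$nu * (1 + exp(-x))^(-consts$nu - 1) *
    exp(-x) * consts$k / params$Ptsc
  vQES <- vE + vQ
  data.frame(age = age, E = vE, Q = vQ, QES = vQES, P = vP, T = vQES + vP)
}

#' Pubertal milestones and gains for one parameter set
#'
#' Derives the milestone ages (`AgeP5`, `AgeP50`, `AgeP95`, `AgeP99`,
#' `AgeP100`, peak height velocity ages of the P- and T-functions), the
#' model heights at those ages, the model adult height `Tmax`, and the
#' pubertal gains over the `AgeP5`--`AgeP100` window: total (`Tpubgain`),
#' specific (`Ppubgain`), basic (`QESpubgain`) and their difference
#' (`Deltapubgain = Ppubgain - QESpubgain`).
#'
#' @inheritParams p_fraction
#' @param adult_age Age in years at which the plateaued total height is read
#'   off as `Tmax` (default 25; growth has stopped well before).
#' @return Object of class `qeps_milestones`: a one-row data.frame.
#' @details The age of peak P-velocity has the closed form
#'   `AgeP50 + Ptsc * (log(nu) - x50)/k`; for `nu > 1` it falls before
#'   `AgeP50`. The age of peak total velocity is found numerically.
#' @examples
#' qeps_milestones(qeps_params(62.8, 98.5, 12.9, 1, 1, 12))
#' @export
qeps_milestones <- function(params, consts = qeps_shape(), adult_age = 25) {
  params <- as_qeps_params(params)
  ageP5 <- age_at_p_fraction(0.05, params, consts)
  ageP50 <- params$AgeP50
  ageP95 <- age_at_p_fraction(0.95, params, consts)
  ageP99 <- age_at_p_fraction(0.99, params, consts)
  ageP100 <- age_at_p_fraction(consts$pEnd, params, consts)
  agePPHV <- ageP50 + params$Ptsc * (log(consts$nu) - consts$x50) / consts$k
  # peak total velocity: search around the pubertal window (skip infancy,
  # where velocity is monotone decreasing and much higher)
  lo <- max(2, ageP5 - 3)
  ageTPHV <- stats::optimize(function(a) qeps_velocity(a, params, consts)$T,
                             lower = lo, upper = ageP100,
                             maximum = TRUE, tol = 1e-6)$maximum
  ages <- c(ageP5, ageP50, ageP95, ageP99, ageP100, adult_age)
  comp <- qeps_components(ages, params, consts)
  Tmax <- comp$T[6]
  Tpubgain <- comp$T[5] - comp$T[1]
  Ppubgain <- comp$P[5] - comp$P[1]
  QESpubgain <- comp$QES[5] - comp$QES[1]
  out <- data.frame(
    ageP5 = ageP5, ageP50 = ageP50, ageP95 = ageP95, ageP99 = ageP99,
    ageP100 = ageP100, agePPHV = agePPHV, ageTPHV = ageTPHV,
    T_ageP5 = comp$T[1], T_ageP50 = comp$T[2], T_ageP95 = comp$T[3],
    T_ageP99 = comp$T[4], T_ageP100 = comp$T[5], Tmax = Tmax,
    Tpubgain = Tpubgain, Ppubgain = Ppubgain, QESpubgain = QESpubgain,
    Deltapubgain = Ppubgain - QESpubgain, Pmax = params$Pmax)
  class(out) <- c("qeps_milestones", "data.frame")
  out
}

#' @export
print.qeps_milestones <- function(x, ...) {
  cat("QEPS pubertal milestones\n")
  cat(sprintf("  onset AgeP5 %6.2f y  midpuberty AgeP50 %6.2f y  AgeP95 %5.2f y\n",
              x$ageP5, x$ageP50, x$ageP95))
  cat(sprintf("  PHV: P-function %5.2f y, total %5.2f y;  adult height %6.1f cm\n",
              x$agePPHV, x$ageTPHV, x$Tmax))
  cat(sprintf("  gains P5-P100: total %5.2f = P %5.2f + QES %5.2f cm\n",
              x$Tpubgain, x$Ppubgain, x$QESpubgain))
  invisible(x)
}
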