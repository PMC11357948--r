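#' Shared QEPS shape constants
#'
#' The QEPS model decomposes total height `T` into a basic part `QES`
#' (Quadratic growth from fetal life to end of growth, Exponential infancy
#' growth, stopped by a smooth `S` brake) and a specific Pubertal sigmoid `P`.
#' The shapes of the four component functions are shared across subjects;
#' only six per-subject parameters ([qeps_params()]) modify them.
#'
#' The age axis is decimal years since birth; internally the model clock
#' starts at `t0`, about six weeks after conception, i.e. `c0` years before
#' birth, where the Q and E functions take the value zero.
#'
#' @param c0 Prenatal time offset in years between `t0` and birth (default
#'   0.65, roughly 34 gestational weeks before term birth counted in whole
#'   years from conception plus six weeks).
#' @param thetaE E-function saturation time constant in years (population
#'   value; multiplied per subject by `Etsc`). The default 0.6 makes E reach
#'   over 95% of its plateau by age 2.
#' @param tQ Age in years at which the *un-stopped* Q velocity would decline
#'   linearly to zero. Default 19.55, calibrated so that cohort-mean basic
#'   growth between age 7 and adulthood matches published cohort summaries.
#' @param nu Asymmetry exponent of the Richards-type P sigmoid (> 0). `nu = 1`
#'   gives a symmetric logistic with peak P-velocity exactly at `AgeP50`;
#'   the default 1.3 places peak P-velocity slightly before `AgeP50`, as
#'   observed in cohort data.
#' @param sS Width in years of the smooth S stop brake (default 0.5).
#' @param pEnd Fraction of the P-function defining the operational "100%"
#'   age `AgeP100` (default 0.999; an asymptotic sigmoid never reaches 1).
#' @param p5_gap Calibration target in years for the population-mean gap
#'   `AgeP50 - AgeP5` at unit time scale (default 2.22). The P steepness `k`
#'   is derived from `nu` and this gap.
#'
#' @return An object of class `qeps_shape`: a list with the arguments above
#'   plus the derived P steepness `k` and the sigmoid offset `x50` placing
#'   the half-way point of P at `AgeP50`.
#'
#' @details The Richards-type pubertal fraction is
#'   \deqn{p(a) = \left(1 + e^{-x(a)}\right)^{-\nu}, \quad
#'         x(a) = k\,\frac{a - AgeP50}{Ptsc} + x_{50},}
#'   with \eqn{x_{50} = -\log(2^{1/\nu} - 1)} so that \eqn{p(AgeP50) = 1/2},
#'   and \eqn{k} solving \eqn{p(AgeP50 - p5\_gap) = 0.05} at `Ptsc = 1`.
#'
#' @examples
#' sh <- qeps_shape()
#' sh$k
#' @export
qeps_shape <- function(c0 = 0.65, thetaE = 0.6, tQ = 19.55, nu = 1.3,
                       sS = 0.5, pEnd = 0.999, p5_gap = 2.22) {
  vals <- c(c0 = c0, thetaE = thetaE, tQ = tQ, nu = nu, sS = sS,
            pEnd = pEnd, p5_gap = p5_gap)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all shape constants must be finite and strictly positive")
  if (pEnd >= 1) stop("'pEnd' must be < 1")
  # steepness: x-distance between the 5% and 50% points spans p5_gap years
  x50 <- -log(2^(1 / nu) - 1)
  x05 <- -log(0.05^(-1 / nu) - 1)
  k <- (x50 - x05) / p5_gap
  structure(list(c0 = c0, thetaE = thetaE, tQ = tQ, nu = nu, sS = sS,
                 pEnd = pEnd, p5_gap = p5_gap, k = k, x50 = x50),
            class = "qeps_shape")
}

#' @export
print.qeps_shape <- function(x, ...) {
  cat("QEPS shape constants\n")
  cat(sprintf("  c0     %6.3f y   (birth at model time c0)\n", x$c0))
  cat(sprintf("  thetaE %6.3f y   (E saturation time constant)\n", x$thetaE))
  cat(sprintf("  tQ     %6.2f y   (age of zero un-stopped Q velocity)\n", x$tQ))
  cat(sprintf("  nu     %6.3f     (P sigmoid asymmetry)\n", x$nu))
  cat(sprintf("  sS     %6.3f y   (S stop width)\n", x$sS))
  cat(sprintf("  pEnd   %6.4f    (fraction defining AgeP100)\n", x$pEnd))
  cat(sprintf("  k      %6.4f    (derived P steepness, AgeP50-AgeP5 gap %.2f y)\n",
              x$k, x$p5_gap))
  invisible(x)
}

#' Individual QEPS parameters
#'
#' The six per-subject parameters modifying the shared component shapes:
#' three height scales (cm) and two time scales (dimensionless multipliers
#' near 1) plus the age at 50% of the specific pubertal P-function.
#'
#' @param Emax Adult height gain from the E-function, cm.
#' @param Qmax Adult height gain from the *un-stopped* Q-function (its
#'   plateau before the S brake is applied), cm.
#' @param Pmax Total specific pubertal height gain, cm.
#' @param Etsc Individual E time-scale multiplier (> 0, ~1).
#' @param Ptsc Individual P time-scale multiplier (> 0, ~1).
#' @param AgeP50 Age in years at 50% of the P-function (midpuberty).
#'
#' @return Object of class `qeps_params`.
#' @examples
#' qeps_params(Emax = 62.8, Qmax = 98.5, Pmax = 12.9,
#'             Etsc = 1, Ptsc = 1, AgeP50 = 12)
#' @export
qeps_params <- function(Emax, Qmax, Pmax, Etsc = 1, Ptsc = 1, AgeP50) {
  v <- c(Emax = Emax, Qmax = Qmax, Pmax = Pmax,
         Etsc = Etsc, Ptsc = Ptsc, AgeP50 = AgeP50)
  if (!all(is.finite(v))) stop("all QEPS parameters must be finite")
  if (Emax < 0 || Qmax < 0 || Pmax < 0)
    stop("height scales Emax, Qmax, Pmax must be >= 0")
  if (Etsc <= 0 || Ptsc <= 0)
    stop("time scales Etsc, Ptsc must be > 0")
  if (AgeP50 <= 5 || AgeP50 >= 20)
    stop("'AgeP50' must lie in (5, 20) years")
  structure(as.list(v), class = "qeps_params")
}

#' @export
print.qeps_params <- function(x, ...) {
  cat("QEPS individual parameters\n")
  cat(sprintf("  Emax %7.2f cm   Qmax %7.2f cm   Pmax %6.2f cm\n",
              x$Emax, x$Qmax, x$Pmax))
  cat(sprintf("  Etsc %7.3f      Ptsc %7.3f      AgeP50 %6.2f y\n",
              x$Etsc, x$Ptsc, x$AgeP50))
  invisible(x)
}

as_qeps_params <- function(x) {
  if (inherits(x, "qeps_params")) return(x)
  x <- as.list(x)
  qeps_params(Emax = x$Emax, Qmax = x$Qmax, Pmax = x$Pmax,
              Etsc = x$Etsc, Ptsc = x$Ptsc, AgeP50 = x$AgeP50)
}
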