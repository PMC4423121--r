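#' Calibrate a density gradient with standard proteins
#'
#' Ordinary least-squares line `S = slope * volume + intercept` through the
#' peak volumes of standard proteins of known sedimentation coefficient.
#'
#' @param standards data.frame with columns `volume_ul` (peak volume from the
#'   top of the gradient) and `S` (known sedimentation coefficient, Svedberg).
#' @return list with `slope` (S per microlitre), `intercept` (S),
#'   `r_squared`, and the fitted `lm` object.
#' @export
calibrate_gradient <- function(standards) {
  if (nrow(standards) < 2 || length(unique(standards$volume_ul)) < 2) {
    stop("insufficient data: need >= 2 standards with distinct volumes")
  }
  fit <- stats::lm(S ~ volume_ul, data = standards)
  ss_tot <- sum((standards$S - mean(standards$S))^2)
  r2 <- if (ss_tot == 0) 1 else {
    1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, fit = fit)
}

#' Peak volume of a gradient fraction profile
#'
#' The signal-weighted centroid of the contiguous run of fractions around the
#' maximum whose signal is at least 50% of the peak signal — more robust to
#' the 250-ul fraction granularity than a bare argmax.
#'
#' @param profile data.frame with columns `volume_ul` (strictly increasing)
#'   and `signal` (>= 0); at least 3 fractions.
#' @return Peak volume in microlitres.
#' @export
peak_volume <- function(profile) {
  if (nrow(profile) < 3) stop("need >= 3 fractions")
  if (any(diff(profile$volume_ul) <= 0)) {
    stop("fraction volumes must be strictly increasing")
  }
  s <- profile$signal
  if (any(s < 0)) stop("signals must be >= 0")
  if (max(s) <= min(s) + 1e-12 * max(abs(s), 1)) {
    stop("no peak: profile is flat")
  }
  imax <- which.max(s)
  half <- s >= 0.5 * s[imax]
  lo <- imax
  while (lo > 1 && half[lo - 1]) lo <- lo - 1
  hi <- imax
  while (hi < length(s) && half[hi + 1]) hi <- hi + 1
  idx <- lo:hi
  sum(profile$volume_ul[idx] * s[idx]) / sum(s[idx])
}

#' Sedimentation coefficient from a fraction profile and calibration
#'
#' @param profile data.frame as for [peak_volume()].
#' @param calibration output of [calibrate_gradient()].
#' @return S in Svedberg.
#' @export
sedimentation_coefficient <- function(profile, calibration) {
  if (abs(calibration$slope) < 1e-12) {
    stop("degenerate calibration: slope is zero")
  }
  calibration$slope * peak_volume(profile) + calibration$intercept
}

#' Frictional ratio from mass and sedimentation coefficient
#'
#' `f/f_min = S_max / S` with `S_max = 0.00361 * M^(2/3)` (S_max in Svedberg
#' for a protein of mass M in Daltons): the ratio of the observed friction to
#' that of an anhydrous sphere of equal mass. Approximately 1 for a compact
#' globular protein and well above 1 for elongated or disordered proteins.
#'
#' @param mass_da molecular mass in Daltons.
#' @param S sedimentation coefficient in Svedberg.
#' @return Object of class `sedimentation_result`: list with `S`, `S_max`,
#'   `mass_da` and `f_ratio`.
#' @examples
#' frictional_ratio(99000, 3.6)  # f/f_min rounds to 2.1
#' @export
frictional_ratio <- function(mass_da, S) {
  if (!is.numeric(mass_da) || mass_da <= 0) {
    stop("invalid input: mass must be > 0")
  }
  if (!is.numeric(S) || S <= 0) stop("invalid input: S must be > 0")
  s_max <- 0.00361 * mass_da^(2 / 3)
  structure(list(S = S, S_max = s_max, mass_da = mass_da,
                 f_ratio = s_max / S),
            class = "sedimentation_result")
}

#' @export
print.sedimentation_result <- function(x, ...) {
  cat(sprintf(
    "<sedimentation_result> S = %.3g S, M = %.4g Da, S_max = %.3g S, f/f_min = %.3g\n",
    x$S, x$mass_da, x$S_max, x$f_ratio))
  invisible(x)
}
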