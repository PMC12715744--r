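#' Fit a monoexponential decay to one CPMG echo train
#'
#' Estimates the observed relaxation rate from amplitudes at times
#' `2 n tau`. The default route is weighted log-linear least squares
#' (weights proportional to amplitude squared, appropriate for additive
#' noise on an exponential) followed by a nonlinear refinement of
#' `m0 * exp(-r2obs * t)`. Trains containing non-positive amplitudes (late
#' echoes below the noise floor) skip the log stage and are fitted
#' nonlinearly from a start value derived from the positive points.
#'
#' @param series Data frame with columns `tau_s`, `echo_index`, `amplitude`
#'   for a single tau value (at least 3 echoes).
#' @param refine Run the nonlinear refinement pass (default `TRUE`).
#' @return List with `r2obs` (s^-1), `se` (standard error), `m0`, `tau_s`,
#'   `n_echoes`.
#' @export
fit_echo_decay <- function(series, refine = TRUE) {
  req <- c("tau_s", "echo_index", "amplitude")
  if (!all(req %in% names(series))) {
    stop("`series` needs columns tau_s, echo_index, amplitude")
  }
  tau <- unique(series$tau_s)
  if (length(tau) != 1L) stop("`series` must contain a single tau value")
  if (nrow(series) < 3L) stop("need at least 3 echoes")
  if (any(!is.finite(series$amplitude))) stop("amplitudes must be finite")
  tt <- 2 * series$echo_index * tau
  a <- series$amplitude
  if (max(a) == min(a)) {
    return(list(r2obs = 0, se = 0, m0 = a[1], tau_s = tau,
                n_echoes = nrow(series)))
  }
  if (all(a > 0)) {
    lf <- stats::lm(log(a) ~ tt, weights = a^2)
    r0 <- -unname(stats::coef(lf)[2])
    m0 <- exp(unname(stats::coef(lf)[1]))
  } else {
    pos <- a > 0
    lf <- stats::lm(log(a[pos]) ~ tt[pos])
    r0 <- max(-unname(stats::coef(lf)[2]), 1 / max(tt))
    m0 <- exp(unname(stats::coef(lf)[1]))
    refine <- TRUE
  }
  if (refine) {
    nf <- try(minpack.lm::nlsLM(a ~ m0 * exp(-r2 * tt),
                                start = list(m0 = m0, r2 = r0),
                                control = minpack.lm::nls.lm.control(maxiter = 200)),
              silent = TRUE)
    if (!inherits(nf, "try-error")) {
      cf <- stats::coef(nf)
      se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(nf)))[["r2"]]),
                     error = function(e) NA_real_)
      return(list(r2obs = unname(cf[["r2"]]), se = se,
                  m0 = unname(cf[["m0"]]), tau_s = tau,
                  n_echoes = nrow(series)))
    }
  }
  se <- tryCatch(suppressWarnings(summary(lf)$coefficients[2, 2]),
                 error = function(e) NA_real_)
  list(r2obs = r0, se = se, m0 = m0, tau_s = tau, n_echoes = nrow(series))
}

#' Hahn fit: R2obs against the squared echo spacing
#'
#' Ordinary least squares of \eqn{R_2^{obs} = 1/T_2 + D^{*}(2\tau)^2} over
#' the fitting window in `2 tau`. Short echo spacings (by default below
#' 40 ms, where convective and fitting artefacts inflate the apparent rate)
#' are excluded.
#'
#' @param r2obs_table Data frame with columns `tau_s` and `r2obs` (one row
#'   per echo spacing).
#' @param window Length-2 numeric, the inclusive fitting window in `2 tau`
#'   seconds (default `c(0.04, 0.4)`).
#' @return Object of class `phip_hahn_fit`: list with `t2` (s), `dstar`
#'   (s^-3), `fit_window`, `r2obs` (the rows used), `covariance` of
#'   `(1/t2, dstar)`, and `n_used`.
#' @export
fit_hahn <- function(r2obs_table, window = c(0.04, 0.4)) {
  req <- c("tau_s", "r2obs")
  if (!all(req %in% names(r2obs_table))) {
    stop("`r2obs_table` needs columns tau_s and r2obs")
  }
  two_tau <- 2 * r2obs_table$tau_s
  keep <- two_tau >= window[1] & two_tau <= window[2]
  if (sum(keep) < 3L) stop("need at least 3 tau values inside the window")
  x <- two_tau[keep]^2
  y <- r2obs_table$r2obs[keep]
  fit <- stats::lm(y ~ x)
  cf <- unname(stats::coef(fit))
  if (cf[1] <= 0) stop("nonpositive intercept: T2 not identifiable")
  structure(list(t2 = 1 / cf[1], dstar = cf[2],
                 fit_window = window,
                 r2obs = r2obs_table[keep, , drop = FALSE],
                 covariance = suppressWarnings(stats::vcov(fit)),
                 n_used = sum(keep)),
            class = "phip_hahn_fit")
}

#' @export
print.phip_hahn_fit <- function(x, ...) {
  cat(sprintf("Hahn fit (%d points, 2tau in [%g, %g] s): T2 = %.4g s, D* = %.4g s^-3\n",
              x$n_used, x$fit_window[1], x$fit_window[2], x$t2, x$dstar))
  invisible(x)
}

#' Effective T2* from a spectral line width
#'
#' `t2star = 1 / (pi * fwhm)` for a Lorentzian line.
#'
#' @param fwhm Full width at half maximum in Hz (> 0).
#' @return T2* in seconds.
#' @examples
#' t2star_from_fwhm(2.50) # 0.127 s
#' @export
t2star_from_fwhm <- function(fwhm) {
  if (any(!is.finite(fwhm) & !is.infinite(fwhm)) || any(fwhm <= 0)) {
    stop("`fwhm` must be positive")
  }
  1 / (pi * fwhm)
}

#' Convert chemical-shift offsets between ppm and Hz
#'
#' @param value Offset(s) in ppm (`ppm_to_hz`) or Hz (`hz_to_ppm`).
#' @param ref_freq Spectrometer reference frequency in Hz (> 0).
#' @return Converted offset(s).
#' @examples
#' ppm_to_hz(2.492, 18.964e6) # about 47.26 Hz
#' @export
ppm_to_hz <- function(value, ref_freq) {
  if (!is.finite(ref_freq) || ref_freq <= 0) stop("`ref_freq` must be positive")
  value * ref_freq * 1e-6
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(value, ref_freq) {
  if (!is.finite(ref_freq) || ref_freq <= 0) stop("`ref_freq` must be positive")
  value / ref_freq * 1e6
}

#' Correlation between the diffusion-homogeneity coefficient and line width
#'
#' Ordinary least squares of D* against FWHM across reactor geometries,
#' optionally with the origin appended as a data point (a sample with no
#' line broadening should show no gradient-driven excess decay). The
#' coefficient of determination is computed about the mean of the
#' (possibly origin-augmented) responses.
#'
#' @param fwhm Numeric vector of line widths (Hz).
#' @param dstar Numeric vector of D* values (s^-3), same length.
#' @param include_origin Append the point (0, 0) before fitting
#'   (default `TRUE`).
#' @param through_origin Force a zero intercept (default `FALSE`).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
correlate_dstar_fwhm <- function(fwhm, dstar, include_origin = TRUE,
                                 through_origin = FALSE) {
  if (length(fwhm) != length(dstar)) stop("length mismatch")
  if (length(fwhm) < 2L) stop("need at least 2 points")
  x <- as.numeric(fwhm); y <- as.numeric(dstar)
  if (include_origin) { x <- c(x, 0); y <- c(y, 0) }
  if (stats::sd(x) == 0) stop("degenerate x values")
  fit <- if (through_origin) stats::lm(y ~ x - 1) else stats::lm(y ~ x)
  pred <- stats::fitted(fit)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  cf <- stats::coef(fit)
  list(slope = unname(cf[["x"]]),
       intercept = if (through_origin) 0 else unname(cf[["(Intercept)"]]),
       r_squared = r2, n = length(x))
}
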