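#' Out-of-phase echo (OPE) sequence parameters
#'
#' The OPE sequence, `45x - [tau - 90x 180y 90x - tau] x n - FID`, converts
#' the antiphase PASADENA pattern into an in-phase one and is robust against
#' B0 inhomogeneity because each echo block refocuses chemical shifts. The
#' phenomenological factor `exp(-tau/td)` damps the simulated tau-dependence,
#' absorbing relaxation and couplings outside the simulated spin set.
#'
#' @param tau Inter-pulse half-delay in s (> 0).
#' @param td Damping time constant in s (> 0; `Inf` disables damping).
#' @param excitation_flip Excitation flip angle in degrees (default 45,
#'   phase +x).
#' @param n_refocus Number of echo blocks (default 3).
#' @param refocus_composite List of `c(flip, phase)` pairs (degrees) for the
#'   composite refocusing pulse; default `90x, 180y, 90x`, which acts as a
#'   broadband inversion.
#' @return Object of class `phip_ope_config`.
#' @export
ope_config <- function(tau, td = Inf, excitation_flip = 45, n_refocus = 3L,
                       refocus_composite = list(c(90, 0), c(180, 90), c(90, 0))) {
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive")
  if (is.na(td) || td <= 0) stop("`td` must be positive (or Inf)")
  n_refocus <- as.integer(n_refocus)
  if (n_refocus < 1L) stop("`n_refocus` must be >= 1")
  structure(list(tau = tau, td = td, excitation_flip = excitation_flip,
                 n_refocus = n_refocus, refocus_composite = refocus_composite),
            class = "phip_ope_config")
}

#' Run the OPE sequence and return the in-phase signal integral
#'
#' Applies the excitation pulse, then `n_refocus` blocks of
#' `[tau - composite refocus - tau]`, and detects the in-phase signal
#' integral (the real first FID point, equal to the spectrum integral),
#' multiplied by the empirical damping `exp(-tau/td)`.
#'
#' @param state A `phip_spin_state` (typically from [pasadena_state()]).
#' @param cfg A `phip_ope_config`.
#' @return Single numeric signal integral.
#' @export
run_ope <- function(state, cfg) {
  stopifnot(inherits(cfg, "phip_ope_config"))
  st <- apply_pulse(state, cfg$excitation_flip, 0)
  for (b in seq_len(cfg$n_refocus)) {
    st <- evolve_delay(st, cfg$tau)
    for (p in cfg$refocus_composite) st <- apply_pulse(st, p[1], p[2])
    st <- evolve_delay(st, cfg$tau)
  }
  signal_integral(st) * exp(-cfg$tau / cfg$td)
}

#' Scan the OPE signal over the inter-pulse delay
#'
#' Runs [run_ope()] on a fresh initial state for each tau and locates the
#' optimum by quadratic interpolation through the grid maximum and its two
#' neighbours (the interior optimum of a smooth curve is found to better
#' than the grid step).
#'
#' @param state_factory Function of no arguments returning a fresh
#'   `phip_spin_state`, or a fixed `phip_spin_state` (reused as initial
#'   state; it is never mutated).
#' @param cfg A `phip_ope_config`; its `tau` is overridden by the grid.
#' @param taus Numeric vector of positive delays in s (need not be uniform;
#'   interpolation uses the local spacing).
#' @return Object of class `phip_ope_scan`: list with `table` (data.frame
#'   `tau_s`, `integral`), `tau_opt`, `integral_opt`.
#' @export
ope_tau_scan <- function(state_factory, cfg, taus) {
  stopifnot(inherits(cfg, "phip_ope_config"))
  if (length(taus) == 0L || any(taus <= 0)) stop("`taus` must be positive")
  make_state <- if (is.function(state_factory)) {
    state_factory
  } else {
    .check_state(state_factory)
    function() state_factory
  }
  vals <- vapply(taus, function(tt) {
    c2 <- cfg; c2$tau <- tt
    run_ope(make_state(), c2)
  }, numeric(1))
  i <- which.max(vals)
  if (i == 1L || i == length(vals)) {
    tau_opt <- taus[i]; y_opt <- vals[i]
  } else {
    # parabola through the three points around the grid maximum
    x <- taus[(i - 1L):(i + 1L)]; y <- vals[(i - 1L):(i + 1L)]
    den <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / den
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / den
    tau_opt <- if (a < 0) -b / (2 * a) else taus[i]
    y_opt <- max(vals)
  }
  structure(list(table = data.frame(tau_s = taus, integral = vals),
                 tau_opt = tau_opt, integral_opt = y_opt),
            class = "phip_ope_scan")
}

#' @export
print.phip_ope_scan <- function(x, ...) {
  cat(sprintf("OPE tau scan: %d points, optimum tau = %.4g ms (integral %.4g)\n",
              nrow(x$table), x$tau_opt * 1e3, x$integral_opt))
  invisible(x)
}

#' Gaussian B1 spread description for nutation modelling
#'
#' @param period Mean nutation period T in s (> 0); the mean nutation
#'   frequency is `1/period`.
#' @param sigma_rel Relative standard deviation of the B1 field (>= 0,
#'   dimensionless), e.g. 0.0103 for 1.03 percent.
#' @return Object of class `phip_b1_distribution`.
#' @export
b1_distribution <- function(period, sigma_rel) {
  if (!is.finite(period) || period <= 0) stop("`period` must be positive")
  if (!is.finite(sigma_rel) || sigma_rel < 0) stop("`sigma_rel` must be >= 0")
  structure(list(period = period, sigma_rel = sigma_rel),
            class = "phip_b1_distribution")
}

#' Ensemble-averaged nutation curve under a Gaussian B1 distribution
#'
#' Averages `sin(2 pi nu t)` over nutation frequencies
#' `nu ~ Normal(1/period, sigma_rel/period)` by Gauss-Hermite quadrature
#' (the B1 spread scales only the nutation frequency, not the detection
#' sensitivity). The average has the closed form
#' \eqn{\sin(2\pi\nu_0 t)\exp(-2\pi^2\sigma_\nu^2 t^2)}, which the
#' quadrature reproduces to near machine precision; the quadrature route is
#' kept as the computational definition so that alternative distributions
#' remain pluggable.
#'
#' @param dist A `phip_b1_distribution`.
#' @param t Numeric vector of pulse durations in s (>= 0).
#' @param nodes Number of Gauss-Hermite nodes (default 64).
#' @return Numeric vector of ensemble-averaged signals.
#' @export
nutation_ensemble <- function(dist, t, nodes = 64L) {
  stopifnot(inherits(dist, "phip_b1_distribution"))
  if (any(t < 0)) stop("`t` must be nonnegative")
  nu0 <- 1 / dist$period
  sig <- dist$sigma_rel / dist$period
  if (sig == 0) return(sin(2 * pi * nu0 * t))
  gh <- pracma::gaussHermite(nodes)
  nu <- nu0 + sqrt(2) * sig * gh$x
  as.numeric(sin(2 * pi * outer(t, nu)) %*% gh$w) / sqrt(pi)
}

#' Signal-level CPMG decay model
#'
#' Echo amplitudes decay as \eqn{M_0 e^{-R_2^{obs}\,2n\tau}} with
#' \eqn{R_2^{obs} = 1/T_2 + D^{*}(2\tau)^2}, where `dstar` is the effective
#' diffusion-homogeneity coefficient \eqn{D^{*} = \gamma^2 G^2 D / 12}
#' (only the product is identifiable; G and D are not represented
#' separately).
#'
#' @param t2 Transverse relaxation time in s (> 0).
#' @param dstar Effective diffusion-homogeneity coefficient in s^-3 (>= 0).
#' @param m0 Initial amplitude (default 1).
#' @return Object of class `phip_cpmg_model`.
#' @export
cpmg_model <- function(t2, dstar = 0, m0 = 1) {
  if (!is.finite(t2) || t2 <= 0) stop("`t2` must be positive")
  if (!is.finite(dstar) || dstar < 0) stop("`dstar` must be >= 0")
  structure(list(t2 = t2, dstar = dstar, m0 = m0),
            class = "phip_cpmg_model")
}

#' CPMG echo-train amplitudes
#'
#' @param model A `phip_cpmg_model`.
#' @param tau Half echo spacing in s (> 0); the echo spacing is `2 tau`.
#' @param n_echoes Number of echoes (default 169).
#' @return Numeric vector of amplitudes at echoes `n = 1..n_echoes`.
#' @export
cpmg_signal <- function(model, tau, n_echoes = 169L) {
  stopifnot(inherits(model, "phip_cpmg_model"))
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive")
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 1L) stop("`n_echoes` must be >= 1")
  r2 <- 1 / model$t2 + model$dstar * (2 * tau)^2
  model$m0 * exp(-r2 * 2 * seq_len(n_echoes) * tau)
}
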