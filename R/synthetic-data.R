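# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Noise specification for the synthetic-data generators
#'
#' All generators are bit-reproducible functions of their parameters and
#' the seed. The default level, 1 percent of the maximum amplitude, is the
#' noise floor at which all recovery figures of merit are quoted.
#'
#' @param kind `"additive"` (level is a fraction of the maximum amplitude)
#'   or `"multiplicative"` (level is a relative perturbation).
#' @param level Noise level as a fraction (>= 0; default 0.01).
#' @param seed Integer RNG seed.
#' @return Object of class `phip_noise_spec`.
#' @export
noise_spec <- function(kind = c("additive", "multiplicative"),
                       level = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(level) || level < 0) stop("`level` must be >= 0")
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "phip_noise_spec")
}

.apply_noise <- function(y, noise) {
  stopifnot(inherits(noise, "phip_noise_spec"))
  if (noise$level == 0) return(y)
  .with_seed(noise$seed, {
    z <- stats::rnorm(length(y))
    switch(noise$kind,
           additive = y + noise$level * max(abs(y)) * z,
           multiplicative = y * (1 + noise$level * z))
  })
}

#' Generate a synthetic nutation curve
#'
#' Either a damped sine `a * exp(-k t) * sin(2 pi t / period)` or, when
#' `sigma_rel` is given, the Gaussian-B1 ensemble average from
#' [nutation_ensemble()]. The generating truth is attached as attribute
#' `truth` so recovery tests are self-describing.
#'
#' @param period Nutation period in s.
#' @param k Decay rate in s^-1 (damped-sine generator; ignored when
#'   `sigma_rel` is given).
#' @param sigma_rel Relative B1 spread (Gaussian-ensemble generator).
#' @param a Amplitude (default 1).
#' @param t_max Last pulse duration in s (default 1.2e-3).
#' @param dt Pulse-duration step in s (default 2e-6; must be below
#'   `period / 8` to sample the oscillation).
#' @param noise A [noise_spec()].
#' @return Data frame with columns `t_pulse_s`, `signal`; attribute
#'   `truth` holds the generator parameters.
#' @export
gen_nutation <- function(period, k = NULL, sigma_rel = NULL, a = 1,
                         t_max = 1.2e-3, dt = 2e-6,
                         noise = noise_spec()) {
  if (!is.finite(period) || period <= 0) stop("`period` must be positive")
  if (dt >= period / 8) stop("`dt` must be below period/8")
  if (is.null(k) && is.null(sigma_rel)) stop("give `k` or `sigma_rel`")
  tt <- seq(dt, t_max, by = dt)
  if (!is.null(sigma_rel)) {
    y <- a * nutation_ensemble(b1_distribution(period, sigma_rel), tt)
    truth <- list(generator = "gaussian_ensemble", period = period,
                  sigma_rel = sigma_rel, a = a)
  } else {
    y <- a * exp(-k * tt) * sin(2 * pi * tt / period)
    truth <- list(generator = "damped_sine", period = period, k = k, a = a)
  }
  out <- data.frame(t_pulse_s = tt, signal = .apply_noise(y, noise))
  attr(out, "truth") <- c(truth, list(noise = unclass(noise)))
  out
}

#' Generate synthetic CPMG echo trains
#'
#' Echo trains from [cpmg_signal()] for a set of half echo spacings, with
#' noise. Defaults reproduce the acquisition layout used for the T2 / D*
#' analysis: 10 echo spacings with `2 tau` spanning 40 to 400 ms and 169
#' echoes each.
#'
#' @param model A [cpmg_model()].
#' @param taus Half echo spacings in s (default
#'   `seq(0.02, 0.2, length.out = 10)`).
#' @param n_echoes Echoes per train (default 169).
#' @param noise A [noise_spec()]; additive noise is scaled by the maximum
#'   amplitude of each train's model curve.
#' @return Data frame with columns `tau_s`, `echo_index`, `amplitude`;
#'   attribute `truth` holds the generator parameters.
#' @export
gen_cpmg <- function(model, taus = seq(0.02, 0.2, length.out = 10),
                     n_echoes = 169L, noise = noise_spec()) {
  stopifnot(inherits(model, "phip_cpmg_model"))
  if (any(taus <= 0)) stop("`taus` must be positive")
  clean <- lapply(taus, function(tau) cpmg_signal(model, tau, n_echoes))
  amp <- .with_seed(noise$seed, {
    unlist(lapply(clean, function(y) {
      if (noise$level == 0) return(y)
      z <- stats::rnorm(length(y))
      switch(noise$kind,
             additive = y + noise$level * max(abs(y)) * z,
             multiplicative = y * (1 + noise$level * z))
    }))
  })
  out <- data.frame(
    tau_s = rep(taus, each = n_echoes),
    echo_index = rep(seq_len(n_echoes), times = length(taus)),
    amplitude = amp
  )
  attr(out, "truth") <- list(t2 = model$t2, dstar = model$dstar,
                             m0 = model$m0, n_echoes = n_echoes,
                             noise = unclass(noise))
  out
}

#' Generate synthetic injection-series signal integrals
#'
#' Normal draws `mean * (1 + cv * z)` emulating repeated automated
#' injection/ejection cycles; the default layout is 3 series of 10
#' repetitions.
#'
#' @param mean Mean signal integral.
#' @param cv Coefficient of variation as a fraction.
#' @param n Repetitions per series (default 10, >= 2).
#' @param n_series Number of series (default 3).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `series`, `rep`, `integral`; attribute
#'   `truth` holds the generator parameters.
#' @export
gen_injection_series <- function(mean, cv, n = 10L, n_series = 3L, seed = 1L) {
  n <- as.integer(n); n_series <- as.integer(n_series)
  if (n < 2L) stop("`n` must be >= 2")
  if (cv < 0) stop("`cv` must be >= 0")
  vals <- .with_seed(seed, mean * (1 + cv * stats::rnorm(n * n_series)))
  out <- data.frame(series = rep(seq_len(n_series), each = n),
                    rep = rep(seq_len(n), times = n_series),
                    integral = vals)
  attr(out, "truth") <- list(mean = mean, cv = cv, seed = seed)
  out
}

#' Generate a synthetic OPE tau-scan dataset
#'
#' Runs [ope_tau_scan()] on an ethyl acetate preset ([ea_spin_system()])
#' from the dephased PASADENA state and adds noise. The preset bundles the
#' damping constant (`Td` = 160 ms for EA-d6, 60 ms for EA-h6) used to
#' match the simulated tau-dependences to experiment.
#'
#' @param isotopologue `"EA-d6"` or `"EA-h6"`.
#' @param taus Delays in s (default 1 to 30 ms in 0.1 ms steps).
#' @param f Parahydrogen fraction (default 1).
#' @param td Damping constant in s (default: the preset value).
#' @param noise A [noise_spec()].
#' @param ... Passed to [ea_spin_system()].
#' @return Data frame with columns `tau_s`, `integral`; attributes `truth`
#'   (generator parameters incl. the noiseless `tau_opt`) and `scan` (the
#'   clean `phip_ope_scan`).
#' @export
gen_ope_dataset <- function(isotopologue = c("EA-d6", "EA-h6"),
                            taus = seq(1e-3, 30e-3, by = 1e-4),
                            f = 1, td = NULL, noise = noise_spec(), ...) {
  isotopologue <- match.arg(isotopologue)
  sys <- ea_spin_system(isotopologue, ...)
  if (is.null(td)) td <- attr(sys, "default_td")
  pair <- attr(sys, "pasadena_pair")
  cfg <- ope_config(tau = taus[1], td = td)
  scan <- ope_tau_scan(function() pasadena_state(sys, pair, f = f),
                       cfg, taus)
  out <- data.frame(tau_s = taus,
                    integral = .apply_noise(scan$table$integral, noise))
  attr(out, "truth") <- list(isotopologue = isotopologue, f = f, td = td,
                             tau_opt = scan$tau_opt,
                             noise = unclass(noise))
  attr(out, "scan") <- scan
  out
}
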