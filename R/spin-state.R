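.new_state <- function(rho, system) {
  structure(list(rho = rho, system = system), class = "phip_spin_state")
}

.check_state <- function(state) {
  if (!inherits(state, "phip_spin_state")) stop("expected a `phip_spin_state`")
  invisible(state)
}

#' PASADENA initial state after pairwise parahydrogen addition
#'
#' Builds the density operator of a spin system whose two nascent protons
#' carry parahydrogen-derived spin order while all other spins are
#' unpolarized. With `dephased = TRUE` (the default) the pair carries the
#' longitudinal two-spin order that survives a hydrogenation period long
#' compared with the inverse shift difference: the zero-quantum coherences
#' of the singlet have averaged out, leaving the deviation
#' \eqn{-s\,I_{1z}I_{2z}}. With `dephased = FALSE` the full singlet
#' projector deviation \eqn{-s\,\mathbf{I}_1\cdot\mathbf{I}_2} is kept.
#' Both are scaled by the enrichment factor \eqn{s = (4f-1)/3}.
#'
#' @param system A `phip_spin_system`.
#' @param pair Integer vector of length 2: indices of the nascent protons.
#' @param f Parahydrogen fraction in `[0, 1]` (default 1).
#' @param dephased Keep only the zz part of the pair order (default `TRUE`).
#' @return A `phip_spin_state`.
#' @examples
#' sys <- build_spin_system(c(1.26, 4.12), matrix(c(0, 7.1, 7.1, 0), 2),
#'                          b0 = 0.4454, ref_freq = 18.717e6)
#' st <- pasadena_state(sys, c(1, 2), f = 0.92)
#' @export
pasadena_state <- function(system, pair = c(1L, 2L), f = 1, dephased = TRUE) {
  stopifnot(inherits(system, "phip_spin_system"))
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1] == pair[2] ||
      any(pair < 1L) || any(pair > system$n_spins)) {
    stop("`pair` must be two distinct valid spin indices")
  }
  s <- enrichment_scale(f)$s
  n <- system$n_spins
  d <- system$dim
  i1 <- pair[1]; i2 <- pair[2]
  dev <- system$op_z[[i1]] %*% system$op_z[[i2]]
  if (!dephased) {
    dev <- dev + system$op_x[[i1]] %*% system$op_x[[i2]] +
      system$op_y[[i1]] %*% system$op_y[[i2]]
  }
  # pair deviation tensored with maximally mixed remaining spins
  rho <- diag(d) / d - s * dev / 2^(n - 2L)
  .new_state(rho, system)
}

#' Thermal-equilibrium deviation state
#'
#' Unit longitudinal deviation \eqn{\sum_i I_{iz}}: a 90-degree pulse of
#' phase +y rotates it onto +x, where it detects as a positive real signal
#' equal to the number of spins. Used as the thermal reference in sequence
#' comparisons.
#'
#' @param system A `phip_spin_system`.
#' @return A `phip_spin_state`.
#' @export
thermal_state <- function(system) {
  stopifnot(inherits(system, "phip_spin_system"))
  dev <- Reduce(`+`, system$op_z)
  .new_state(diag(system$dim) / system$dim + dev, system)
}

#' Apply an ideal (zero-duration) radio-frequency pulse
#'
#' Rotates the state by `flip` degrees about the axis at `phase` degrees in
#' the transverse plane: \eqn{U = \exp[-i\,\theta\,(F_x\cos\phi +
#' F_y\sin\phi)]} with \eqn{F_{x,y}} summed over the targeted spins.
#' Unitary, so the eigenvalues and trace of the density operator are
#' preserved exactly. B1 inhomogeneity is deliberately not modelled here;
#' it enters only at the ensemble level (see [nutation_ensemble()]).
#'
#' @param state A `phip_spin_state`.
#' @param flip Flip angle in degrees.
#' @param phase Pulse phase in degrees (0 = +x, 90 = +y).
#' @param targets Integer indices of the spins the pulse addresses
#'   (default: all).
#' @return The rotated `phip_spin_state`.
#' @export
apply_pulse <- function(state, flip, phase = 0, targets = NULL) {
  .check_state(state)
  sys <- state$system
  if (is.null(targets)) targets <- seq_len(sys$n_spins)
  targets <- as.integer(targets)
  if (any(targets < 1L) || any(targets > sys$n_spins)) {
    stop("`targets` out of range")
  }
  th <- flip * pi / 180
  ph <- phase * pi / 180
  G <- Reduce(`+`, lapply(targets, function(i) {
    cos(ph) * sys$op_x[[i]] + sin(ph) * sys$op_y[[i]]
  }))
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors %*% (exp(-1i * th * eg$values) * .herm(eg$vectors))
  .new_state(U %*% state$rho %*% .herm(U), sys)
}

# Propagator for free evolution, from the cached eigendecomposition
.delay_propagator <- function(system, t) {
  V <- system$h_vectors
  V %*% (exp(-1i * system$h_values * t) * .herm(V))
}

#' Free evolution under the rotating-frame Hamiltonian
#'
#' Propagates the density operator for time `t` using the exact matrix
#' exponential from the eigendecomposition cached in the spin system; there
#' is no integration step size.
#'
#' @param state A `phip_spin_state`.
#' @param t Delay in seconds (>= 0).
#' @return The evolved `phip_spin_state`.
#' @export
evolve_delay <- function(state, t) {
  .check_state(state)
  if (!is.finite(t) || t < 0) stop("`t` must be nonnegative")
  if (t == 0) return(state)
  U <- .delay_propagator(state$system, t)
  .new_state(U %*% state$rho %*% .herm(U), state$system)
}

# Raw complex observable Tr(rho F+), normalized so a unit I_ix deviation
# detects as 1 regardless of system size.
.detect_point <- function(state) {
  sys <- state$system
  fplus <- Reduce(`+`, sys$op_x) + 1i * Reduce(`+`, sys$op_y)
  2^(2L - sys$n_spins) * sum(diag(state$rho %*% fplus))
}

#' In-phase signal of the current state
#'
#' Real part of the normalized transverse observable
#' \eqn{2^{2-N}\,\mathrm{Tr}[\rho\,\sum_i(I_{ix} + iI_{iy})]}. The receiver
#' is aligned with +x, so +x magnetization (e.g. thermal \eqn{I_z} after a
#' 90-degree pulse of phase +y) detects as positive real; the real part is
#' the in-phase channel used for all signal integrals. By the Fourier
#' identity the first FID point carries the integral of the spectrum
#' (the trapezoidal spectrum of [fid_to_spectrum()] integrates to half the
#' first point), so this one number fixes the spectrum-integral convention
#' of the package and makes OPE tau-scans comparable across settings.
#'
#' @param state A `phip_spin_state`.
#' @return Single numeric value.
#' @export
signal_integral <- function(state) {
  Re(.detect_point(.check_state(state)))
}

#' Detect a free-induction decay
#'
#' Samples the complex observable while the state evolves freely, applying
#' an exponential apodization `exp(-pi * lw * t)` that produces a Lorentzian
#' line of full width at half maximum `lw` Hz in the spectrum.
#'
#' @param state A `phip_spin_state`.
#' @param duration Acquisition time in s (> `dwell`).
#' @param dwell Dwell time (sampling interval) in s (> 0).
#' @param lw Homogeneous line broadening in Hz (>= 0).
#' @return Object of class `phip_fid`: list with `time` (s), `signal`
#'   (complex), `dwell`, `lw`, and the source `system`.
#' @export
detect_fid <- function(state, duration, dwell, lw = 0) {
  .check_state(state)
  if (!(duration > dwell && dwell > 0)) stop("need duration > dwell > 0")
  if (lw < 0) stop("`lw` must be nonnegative")
  npts <- floor(duration / dwell)
  tgrid <- (seq_len(npts) - 1) * dwell
  U <- .delay_propagator(state$system, dwell)
  Uh <- .herm(U)
  sig <- complex(npts)
  rho <- state$rho
  st <- state
  for (k in seq_len(npts)) {
    st$rho <- rho
    sig[k] <- .detect_point(st)
    rho <- U %*% rho %*% Uh
  }
  sig <- sig * exp(-pi * lw * tgrid)
  structure(list(time = tgrid, signal = sig, dwell = dwell, lw = lw,
                 system = state$system),
            class = "phip_fid")
}

#' Fourier transform of an FID
#'
#' Discrete Fourier transform on the uniform dwell grid with the customary
#' first-point halving (trapezoidal quadrature, which removes the
#' rectangle-rule baseline offset), scaled by the dwell time so that the
#' spectrum integral (sum times frequency step) equals half the first FID
#' point. The frequency axis is returned both in Hz and in ppm (via the
#' system reference frequency); following NMR convention the rows are
#' ordered by decreasing ppm.
#'
#' @param fid A `phip_fid`.
#' @return Object of class `phip_spectrum`: list with `freq_hz`, `ppm`,
#'   `intensity` (complex), `df` (Hz per point), `ref_freq`, `lw`.
#' @export
fid_to_spectrum <- function(fid) {
  stopifnot(inherits(fid, "phip_fid"))
  n <- length(fid$signal)
  s <- fid$signal
  s[1] <- s[1] / 2
  raw <- stats::fft(s) * fid$dwell
  freq <- (seq_len(n) - 1) / (n * fid$dwell)
  fold <- freq >= 1 / (2 * fid$dwell)
  freq[fold] <- freq[fold] - 1 / fid$dwell
  ord <- order(freq, decreasing = TRUE) # high ppm on the left
  structure(list(freq_hz = freq[ord],
                 ppm = freq[ord] / fid$system$ref_freq * 1e6,
                 intensity = raw[ord],
                 df = 1 / (n * fid$dwell),
                 ref_freq = fid$system$ref_freq,
                 lw = fid$lw),
            class = "phip_spectrum")
}

#' Full width at half maximum of a spectral line
#'
#' Locates the maximum of the real part and measures the width at half
#' height by linear interpolation of the two half-height crossings.
#'
#' @param spec A `phip_spectrum`.
#' @param units `"hz"` (default) or `"ppm"`.
#' @return FWHM as a single numeric value.
#' @export
spectrum_fwhm <- function(spec, units = c("hz", "ppm")) {
  units <- match.arg(units)
  y <- Re(spec$intensity)
  x <- if (units == "hz") spec$freq_hz else spec$ppm
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- which(y[seq_len(imax)] < half)
  right <- imax - 1L + which(y[imax:length(y)] < half)
  if (length(left) == 0L || length(right) == 0L) {
    stop("line does not fall below half height inside the spectral window")
  }
  il <- max(left)
  ir <- min(right)
  xl <- x[il] + (half - y[il]) / (y[il + 1L] - y[il]) * (x[il + 1L] - x[il])
  xr <- x[ir - 1L] + (half - y[ir - 1L]) / (y[ir] - y[ir - 1L]) *
    (x[ir] - x[ir - 1L])
  abs(xr - xl)
}

#' @export
print.phip_spin_state <- function(x, ...) {
  cat(sprintf("Density operator: %d x %d (N = %d spins), trace = %.6f\n",
              nrow(x$rho), ncol(x$rho), x$system$n_spins,
              Re(sum(diag(x$rho)))))
  invisible(x)
}
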