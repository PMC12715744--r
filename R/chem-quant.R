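#' Hydrogenated product concentration after a bubbling period
#'
#' Closed-form rise-and-fall kinetics of the hyperpolarized product during
#' parahydrogen bubbling: the precursor is consumed at first-order rate
#' `k1` while the accumulated product signal decays at rate `r`, giving
#' \deqn{[PC_H] = [PC_0]\,P_0\,\frac{1}{1 - R/k_1}
#'       \left(e^{-\tau_b R} - e^{-\tau_b k_1}\right).}
#' Both exponents are decaying; at `r = k1` the removable singularity is
#' replaced by the analytic limit
#' \eqn{[PC_0] P_0 k_1 \tau_b e^{-k_1\tau_b}}. The maximum over bubbling
#' time sits at \eqn{\tau_b^{*} = \ln(k_1/R)/(k_1 - R)}.
#'
#' @param pc0 Initial precursor concentration in mM (>= 0).
#' @param p0 Reached polarization (fraction).
#' @param r Decay/reaction rate of the product term in s^-1 (>= 0).
#' @param k1 First-order hydrogenation rate constant in s^-1 (> 0).
#' @param tb Bubbling time in s (>= 0); may be a vector.
#' @return Product concentration(s) in mM.
#' @examples
#' hydrogenated_concentration(50, 0.3, r = 0.1, k1 = 0.5, tb = 4)
#' @export
hydrogenated_concentration <- function(pc0, p0, r, k1, tb) {
  if (pc0 < 0) stop("`pc0` must be >= 0")
  if (!is.finite(k1) || k1 <= 0) stop("`k1` must be positive")
  if (r < 0) stop("`r` must be >= 0")
  if (any(tb < 0)) stop("`tb` must be >= 0")
  if (isTRUE(all.equal(r, k1, tolerance = 1e-12))) {
    return(pc0 * p0 * k1 * tb * exp(-k1 * tb))
  }
  pc0 * p0 / (1 - r / k1) * (exp(-tb * r) - exp(-tb * k1))
}

#' Thermal equilibrium polarization of a spin-1/2 nucleus
#'
#' \eqn{P = \tanh[\gamma\hbar B_0 / (2 k_B T)]}; about 3.2e-5 for protons
#' at 9.4 T and 300 K, which is what makes hyperpolarization worthwhile.
#'
#' @param b0 Static field in T (>= 0).
#' @param temp Temperature in K (> 0).
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1 (default proton).
#' @return Polarization as a fraction.
#' @examples
#' thermal_polarization(9.4, 300)
#' @export
thermal_polarization <- function(b0, temp, gamma = phip_constants()$gamma_1H) {
  if (b0 < 0) stop("`b0` must be >= 0")
  if (!is.finite(temp) || temp <= 0) stop("`temp` must be positive")
  cst <- phip_constants()
  tanh(gamma * cst$hbar * b0 / (2 * cst$k_B * temp))
}

#' Maximum attainable two-proton polarization of the OPE sequence
#'
#' The sequence converts the pair spin order into at most 50 percent 1H
#' polarization per proton in the ideal case with pure parahydrogen; at
#' enrichment `f` the ceiling scales with \eqn{(4f - 1)/3}:
#' \eqn{P_{max} = 0.5\,(4f - 1)/3}.
#'
#' @param f Parahydrogen fraction in `[0.25, 1]` (sub-thermal enrichment is
#'   out of scope).
#' @return Polarization ceiling as a fraction.
#' @examples
#' max_polarization(0.92) # 0.4467
#' @export
max_polarization <- function(f) {
  if (any(!is.finite(f)) || any(f < 0.25) || any(f > 1)) {
    stop("`f` must be in [0.25, 1]")
  }
  0.5 * (4 * f - 1) / 3
}

#' Quantify hyperpolarization against a thermal reference
#'
#' The polarization reached in situ is the hyperpolarized-to-thermal signal
#' ratio, corrected for the fraction of the thermal spectrum that belongs
#' to the product (the correction coefficient, determined on a
#' high-resolution system), times the thermal polarization at the
#' polarizer's field:
#' \eqn{P = (S_{hyp}/S_{th})\,c\,P_{th}}. The molar polarization
#' `n_protons * conc * P` (mM) is reported alongside because it is
#' invariant under the choice of sequence that distributes polarization
#' over the product protons.
#'
#' @param s_hyp Hyperpolarized signal integral.
#' @param s_th Thermal reference signal integral (> 0).
#' @param correction Fraction of the thermal spectrum belonging to the
#'   product, in `(0, 1]` (default 1).
#' @param p_thermal Thermal polarization at the measurement field
#'   (fraction), e.g. from [thermal_polarization()].
#' @param conc Product concentration in mM.
#' @param n_protons Number of polarized protons per molecule (default 2).
#' @return Object of class `phip_polarization_quant`: list with the inputs
#'   plus `p` (fraction), `enhancement` and `molar_polarization` (mM).
#' @examples
#' q <- quantify_polarization(s_hyp = 2.064e5, s_th = 1, correction = 1,
#'                            p_thermal = 1.5169e-6, conc = 50)
#' q$p
#' @export
quantify_polarization <- function(s_hyp, s_th, correction = 1, p_thermal,
                                  conc, n_protons = 2) {
  if (!is.finite(s_th) || s_th <= 0) stop("`s_th` must be positive")
  if (correction <= 0 || correction > 1) stop("`correction` must be in (0, 1]")
  p <- s_hyp / s_th * correction * p_thermal
  if (abs(p) > 1) stop("computed polarization outside [-1, 1]")
  structure(list(s_hyp = s_hyp, s_th = s_th, correction = correction,
                 p_thermal = p_thermal, p = p,
                 enhancement = p / p_thermal,
                 molar_polarization = n_protons * conc * p,
                 conc = conc, n_protons = n_protons),
            class = "phip_polarization_quant")
}

#' @export
print.phip_polarization_quant <- function(x, ...) {
  cat(sprintf("Polarization: P = %.3g%% (enhancement %.3g), molar polarization %.3g mM\n",
              100 * x$p, x$enhancement, x$molar_polarization))
  invisible(x)
}

#' Fill volume of a reactor tube
#'
#' Cylinder of inner radius `inner_diameter / 2` filled to `fill_height`,
#' optionally with a hemispherical bottom of the same radius (the
#' hemisphere replaces the bottom of the cylinder, removing
#' \eqn{(1/3)\pi r^3} relative to a flat-bottomed tube of equal height).
#'
#' @param inner_diameter Inner diameter in mm (> 0).
#' @param fill_height Fill height in mm, measured from the lowest point;
#'   for a hemispherical bottom it must be at least the radius.
#' @param bottom `"hemispherical"` (default) or `"flat"`.
#' @return Volume in mL.
#' @examples
#' reactor_volume(12.5, 20) # about 2.20 mL
#' @export
reactor_volume <- function(inner_diameter, fill_height,
                           bottom = c("hemispherical", "flat")) {
  bottom <- match.arg(bottom)
  if (inner_diameter <= 0 || fill_height <= 0) stop("dimensions must be positive")
  r <- inner_diameter / 2
  if (bottom == "hemispherical" && fill_height < r) {
    stop("fill height below the hemisphere apex")
  }
  v_mm3 <- pi * r^2 * fill_height -
    if (bottom == "hemispherical") pi * r^3 / 3 else 0
  v_mm3 / 1000
}

#' Coefficient of variation of repeated measurements
#'
#' Sample standard deviation divided by the mean; the reproducibility
#' statistic used for automated injection series.
#'
#' @param values Numeric vector (length >= 2, nonzero mean).
#' @return CV as a fraction.
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 0.5
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  stats::sd(values) / m
}
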