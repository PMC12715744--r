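#' Ethyl acetate proton spin-system presets
#'
#' Models of the hydrogenation product of vinyl acetate used for OPE
#' simulations:
#' \describe{
#'   \item{`"EA-d6"`}{the deuterated isotopologue, modelled as the two
#'     nascent protons only (one methyl-side at 1.26 ppm, one
#'     methylene-side at 4.12 ppm, 3J = 7.1 Hz); deuteron couplings are
#'     absorbed into the phenomenological OPE damping `Td` rather than
#'     simulated.}
#'   \item{`"EA-h6"`}{the protonated ethyl fragment: CH3 (3 protons,
#'     1.26 ppm) and OCH2 (2 protons, 4.12 ppm) with all inter-group
#'     3J = 7.1 Hz; couplings among magnetically equivalent spins are set
#'     to zero as they do not affect the dynamics, and the uncoupled,
#'     unpolarized acetate methyl is excluded.}
#' }
#' The nascent parahydrogen pair is always one methyl proton and one
#' methylene proton (`attr(sys, "pasadena_pair")`).
#'
#' @param isotopologue `"EA-d6"` or `"EA-h6"`.
#' @param b0 Static field in T (default 0.4454).
#' @param ref_freq Reference (carrier) frequency in Hz for the 0-ppm
#'   position (default 18.717e6). This is an instrument setting and is set
#'   independently of `b0`.
#' @param j3 Vicinal coupling constant in Hz (default 7.1).
#' @return A `phip_spin_system` with attributes `pasadena_pair` and
#'   `default_td` (s; 0.160 for EA-d6, 0.060 for EA-h6).
#' @examples
#' ea_spin_system("EA-d6")
#' @export
ea_spin_system <- function(isotopologue = c("EA-d6", "EA-h6"),
                           b0 = 0.4454, ref_freq = 18.717e6, j3 = 7.1) {
  isotopologue <- match.arg(isotopologue)
  if (isotopologue == "EA-d6") {
    jm <- matrix(c(0, j3, j3, 0), 2, 2)
    sys <- build_spin_system(c(1.26, 4.12), jm, b0, ref_freq,
                             labels = c("CH3", "OCH2"))
    attr(sys, "pasadena_pair") <- c(1L, 2L)
    attr(sys, "default_td") <- 0.160
  } else {
    shifts <- c(1.26, 1.26, 1.26, 4.12, 4.12)
    jm <- matrix(0, 5, 5)
    jm[1:3, 4:5] <- j3
    jm[4:5, 1:3] <- j3
    sys <- build_spin_system(shifts, jm, b0, ref_freq,
                             labels = c("CH3a", "CH3b", "CH3c",
                                        "OCH2a", "OCH2b"))
    attr(sys, "pasadena_pair") <- c(1L, 4L)
    attr(sys, "default_td") <- 0.060
  }
  attr(sys, "isotopologue") <- isotopologue
  sys
}
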