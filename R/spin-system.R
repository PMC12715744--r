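# Single spin-1/2 Cartesian operators (2 x 2, complex)
.Ix1 <- matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i
.Iy1 <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2) # column-major: [[0, -i/2], [i/2, 0]]
.Iz1 <- diag(c(0.5, -0.5)) + 0i
.E2 <- diag(2) + 0i

# Product-basis operator for single-spin operator `op` acting on spin i of n
.op_single <- function(n, i, op) {
  out <- matrix(1 + 0i, 1, 1)
  for (k in seq_len(n)) {
    out <- kronecker(out, if (k == i) op else .E2)
  }
  out
}

.herm <- function(m) Conj(t(m))

#' Describe one spin-1/2 nucleus
#'
#' @param label Short text label (e.g. `"CH3"`).
#' @param shift Chemical shift in ppm; must be finite.
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1 (> 0); defaults to the
#'   proton value.
#' @return Object of class `phip_spin`.
#' @export
spin <- function(label, shift, gamma = phip_constants()$gamma_1H) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.finite(shift)) stop("`shift` must be finite")
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be positive")
  structure(list(label = label, shift = shift, gamma = gamma),
            class = "phip_spin")
}

#' Build a validated spin-1/2 system
#'
#' Assembles a weakly validated spin system and precomputes the rotating-frame
#' Hamiltonian together with its eigendecomposition, so that free evolution
#' uses exact matrix exponentials with no step-size parameter. The
#' Hamiltonian (in angular-frequency units, rad/s) is
#' \deqn{H = \sum_i 2\pi\,\delta_i\,10^{-6}\,\nu_{ref}\,I_{iz}
#'       + \sum_{i<j} 2\pi J_{ij}\, \mathbf{I}_i\cdot\mathbf{I}_j,}
#' i.e. full (strong) scalar coupling by default. `coupling = "weak"`
#' truncates the coupling to its secular part \eqn{2\pi J_{ij} I_{iz}I_{jz}},
#' which is useful for product-operator cross-checks.
#'
#' @param shifts Numeric vector of chemical shifts in ppm (one per spin,
#'   at most 8 spins).
#' @param j Symmetric J-coupling matrix in Hz with zero diagonal. A scalar 0
#'   or `NULL` is accepted for uncoupled systems.
#' @param b0 Static field in T (> 0).
#' @param ref_freq Spectrometer reference frequency in Hz defining the 0-ppm
#'   position (> 0). Note that the carrier is an instrument setting: it need
#'   not equal \eqn{\gamma B_0 / 2\pi}, and both are therefore explicit.
#' @param labels Optional character vector of spin labels.
#' @param coupling `"scalar"` (default, full isotropic J coupling) or
#'   `"weak"` (secular zz truncation).
#' @return Object of class `phip_spin_system`.
#' @examples
#' sys <- build_spin_system(c(1.26, 4.12), matrix(c(0, 7.1, 7.1, 0), 2),
#'                          b0 = 0.4454, ref_freq = 18.717e6)
#' sys
#' @export
build_spin_system <- function(shifts, j = NULL, b0, ref_freq,
                              labels = NULL,
                              coupling = c("scalar", "weak")) {
  coupling <- match.arg(coupling)
  n <- length(shifts)
  if (n < 1L || n > 8L) stop("between 1 and 8 spins are supported")
  if (any(!is.finite(shifts))) stop("all shifts must be finite")
  if (!is.finite(b0) || b0 <= 0) stop("`b0` must be positive")
  if (!is.finite(ref_freq) || ref_freq <= 0) stop("`ref_freq` must be positive")
  if (is.null(j) || identical(j, 0)) j <- matrix(0, n, n)
  j <- as.matrix(j)
  if (!all(dim(j) == c(n, n))) stop("`j` must be an n x n matrix")
  if (any(abs(j - t(j)) > 1e-12)) stop("`j` must be symmetric")
  if (any(abs(diag(j)) > 1e-12)) stop("`j` must have a zero diagonal")
  if (is.null(labels)) labels <- paste0("H", seq_len(n))

  dim2 <- 2L^n
  H <- matrix(0 + 0i, dim2, dim2)
  iz <- lapply(seq_len(n), function(i) .op_single(n, i, .Iz1))
  ix <- lapply(seq_len(n), function(i) .op_single(n, i, .Ix1))
  iy <- lapply(seq_len(n), function(i) .op_single(n, i, .Iy1))
  for (i in seq_len(n)) {
    H <- H + 2 * pi * shifts[i] * 1e-6 * ref_freq * iz[[i]]
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (k in (i + 1L):n) {
        if (j[i, k] != 0) {
          term <- iz[[i]] %*% iz[[k]]
          if (coupling == "scalar") {
            term <- term + ix[[i]] %*% ix[[k]] + iy[[i]] %*% iy[[k]]
          }
          H <- H + 2 * pi * j[i, k] * term
        }
      }
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  structure(
    list(
      spins = Map(spin, labels, shifts),
      shifts = as.numeric(shifts),
      j = j, b0 = b0, ref_freq = ref_freq,
      n_spins = n, dim = dim2, coupling = coupling,
      hamiltonian = H,
      h_vectors = eig$vectors, h_values = eig$values,
      op_x = ix, op_y = iy, op_z = iz
    ),
    class = "phip_spin_system"
  )
}

#' @export
print.phip_spin_system <- function(x, ...) {
  cat(sprintf("Spin system: %d spin(s), B0 = %.4f T, ref = %.6g MHz (%s coupling)\n",
              x$n_spins, x$b0, x$ref_freq / 1e6, x$coupling))
  lab <- vapply(x$spins, `[[`, "", "label")
  cat(sprintf("  %-6s %8.3f ppm\n", lab, x$shifts), sep = "")
  if (any(x$j != 0)) {
    idx <- which(upper.tri(x$j) & x$j != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      cat(sprintf("  J(%s,%s) = %.2f Hz\n",
                  lab[idx[r, 1]], lab[idx[r, 2]], x$j[idx[r, 1], idx[r, 2]]))
    }
  }
  invisible(x)
}

#' Parahydrogen enrichment scaling
#'
#' The usable singlet spin order delivered by parahydrogen at fraction `f`
#' scales as \eqn{s = (4f - 1)/3}: zero at the thermal fraction f = 1/4 and
#' one at pure parahydrogen.
#'
#' @param f Parahydrogen fraction in `[0, 1]`.
#' @return List with elements `f` and `s`.
#' @examples
#' enrichment_scale(0.92)$s # 0.8933...
#' @export
enrichment_scale <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1) {
    stop("`f` must be a single value in [0, 1]")
  }
  list(f = f, s = (4 * f - 1) / 3)
}
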