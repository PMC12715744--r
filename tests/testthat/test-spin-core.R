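test_that("spin system construction validates its inputs", {
  jm <- matrix(c(0, 7.1, 7.1, 0), 2)
  expect_s3_class(build_spin_system(c(1.26, 4.12), jm, 0.4454, 18.717e6),
                  "phip_spin_system")
  jbad <- jm; jbad[1, 2] <- 5
  expect_error(build_spin_system(c(1.26, 4.12), jbad, 0.4454, 18.717e6),
               "symmetric")
  jdiag <- jm; diag(jdiag) <- 1
  expect_error(build_spin_system(c(1.26, 4.12), jdiag, 0.4454, 18.717e6),
               "diagonal")
  expect_error(build_spin_system(c(1, 2), jm, -1, 18.717e6), "b0")
  expect_error(build_spin_system(c(1, 2), jm, 0.4454, 0), "ref_freq")
  expect_error(build_spin_system(rep(0, 9), NULL, 0.4454, 18.717e6),
               "between 1 and 8")
})

test_that("on-resonance uncoupled spin has a zero rotating-frame Hamiltonian", {
  sys <- single_spin(0)
  expect_equal(max(Mod(sys$hamiltonian)), 0)
})

test_that("pasadena state carries the expected spin order", {
  sys <- two_spin_weak()

  # thermal para-fraction: maximally mixed, silent under the sequence
  st <- pasadena_state(sys, c(1, 2), f = 0.25)
  expect_equal(st$rho, diag(4) / 4 + 0i, tolerance = 1e-14)
  expect_equal(run_ope(st, ope_config(0.01, td = 0.16)), 0, tolerance = 1e-12)

  # pure parahydrogen without dephasing: exact singlet projector
  stS <- pasadena_state(sys, c(1, 2), f = 1, dephased = FALSE)
  ev <- sort(Re(eigen(stS$rho, symmetric = TRUE)$values), decreasing = TRUE)
  expect_equal(ev, c(1, 0, 0, 0), tolerance = 1e-12)

  # state is a valid density operator
  expect_equal(Re(sum(diag(stS$rho))), 1, tolerance = 1e-12)
  expect_lt(max(Mod(stS$rho - Conj(t(stS$rho)))), 1e-12)

  # deviation amplitude scales as (4f - 1)/3
  d1 <- pasadena_state(sys, c(1, 2), f = 1)$rho - diag(4) / 4
  d92 <- pasadena_state(sys, c(1, 2), f = 0.92)$rho - diag(4) / 4
  expect_equal(d92, d1 * (4 * 0.92 - 1) / 3, tolerance = 1e-12)

  expect_error(pasadena_state(sys, c(2, 2)), "distinct")
  expect_equal(enrichment_scale(0.92)$s, 0.89333333, tolerance = 1e-8)
  expect_equal(enrichment_scale(0.25)$s, 0)
  expect_equal(enrichment_scale(1)$s, 1)
})

test_that("pulses are unitary and compose as rotations", {
  sys <- single_spin(0)
  st0 <- thermal_state(sys)

  # two 180s of the same phase return the state
  st <- apply_pulse(apply_pulse(st0, 180, 35), 180, 35)
  expect_lt(max(Mod(st$rho - st0$rho)), 1e-12)

  # composite 90x 180y 90x acts as an inversion on Iz
  st <- apply_pulse(apply_pulse(apply_pulse(st0, 90, 0), 180, 90), 90, 0)
  inverted <- deviation_state(sys, -sys$op_z[[1]])
  expect_lt(max(Mod(st$rho - inverted$rho)), 1e-12)

  # 90 degrees moves Iz fully transverse with preserved norm
  st <- apply_pulse(st0, 90, 0)
  dev <- st$rho - diag(2) / 2
  expect_lt(Mod(sum(diag(dev %*% sys$op_z[[1]]))), 1e-13)
  expect_equal(sum(Mod(dev)^2), sum(Mod(st0$rho - diag(2) / 2)^2),
               tolerance = 1e-12)
})

test_that("any pulse/delay sequence preserves the density-operator spectrum", {
  sys <- ea_spin_system("EA-d6")
  st <- pasadena_state(sys, c(1, 2), f = 0.92)
  ev0 <- sort(Re(eigen(st$rho, symmetric = TRUE)$values))
  set.seed(7)
  for (step in 1:12) {
    st <- if (stats::runif(1) < 0.5) {
      apply_pulse(st, stats::runif(1, 0, 360), stats::runif(1, 0, 360))
    } else {
      evolve_delay(st, stats::runif(1, 0, 0.02))
    }
  }
  ev1 <- sort(Re(eigen(st$rho, symmetric = TRUE)$values))
  expect_lt(max(abs(ev1 - ev0)), 1e-10)
  expect_equal(Re(sum(diag(st$rho))), 1, tolerance = 1e-12)
})

test_that("free evolution matches product-operator closed forms", {
  j <- 7.1
  sys <- two_spin_weak(j)

  # antiphase 2 I1x I2z refocuses into in-phase I1y at t = 1/(2J)
  st <- deviation_state(sys, 2 * sys$op_x[[1]] %*% sys$op_z[[2]])
  st <- evolve_delay(st, 1 / (2 * j))
  expected <- deviation_state(sys, sys$op_y[[1]])
  expect_lt(max(Mod(st$rho - expected$rho)), 1e-10)

  # t = 0 is the identity
  st0 <- pasadena_state(sys, c(1, 2))
  expect_identical(evolve_delay(st0, 0)$rho, st0$rho)
  expect_error(evolve_delay(st0, -1e-3), "nonnegative")

  # 100 Hz offset for 5 ms rotates transverse magnetization by half a turn
  off <- 100 / 18.717e6 * 1e6 # ppm giving a 100 Hz offset
  sys1 <- build_spin_system(off, NULL, 0.4454, 18.717e6)
  st <- apply_pulse(thermal_state(sys1), 90, 90) # onto +x
  st <- evolve_delay(st, 5e-3)
  expect_equal(signal_integral(st), -1, tolerance = 1e-10)
})

test_that("detection normalization, apodization and spectra behave", {
  sys <- single_spin(0)

  # maximally mixed state gives an all-zero FID
  mixed <- phiptools:::.new_state(diag(2) / 2 + 0i, sys)
  fid <- detect_fid(mixed, 0.1, 1e-3)
  expect_equal(max(Mod(fid$signal)), 0, tolerance = 1e-14)

  # unit Ix deviation detects as exactly 1 at t = 0
  st <- deviation_state(sys, sys$op_x[[1]])
  expect_equal(signal_integral(st), 1, tolerance = 1e-12)

  # 8 Hz apodization: envelope exp(-pi 8 t), spectral FWHM within 2%
  st <- apply_pulse(thermal_state(sys), 90, 90)
  fid <- detect_fid(st, 2, 2e-3, lw = 8)
  expect_equal(Mod(fid$signal), exp(-pi * 8 * fid$time), tolerance = 1e-10)
  fwhm <- spectrum_fwhm(fid_to_spectrum(fid))
  expect_lt(abs(fwhm - 8) / 8, 0.02)

  # line centred at the chemical shift: 4.12 ppm = 77.11 Hz at 18.717 MHz
  sys2 <- build_spin_system(4.12, NULL, 0.4454, 18.717e6)
  sp <- fid_to_spectrum(detect_fid(apply_pulse(thermal_state(sys2), 90, 90),
                                   2, 1e-3, lw = 2))
  pk <- which.max(Re(sp$intensity))
  expect_equal(sp$ppm[pk], 4.12, tolerance = 0.02)
  expect_equal(sp$freq_hz[pk], 4.12e-6 * 18.717e6, tolerance = 1e-2)

  # Fourier linearity: spectrum of summed FIDs = sum of spectra
  fid2 <- detect_fid(apply_pulse(thermal_state(sys2), 90, 90), 2, 1e-3, lw = 2)
  fid1 <- detect_fid(apply_pulse(thermal_state(sys2), 45, 90), 2, 1e-3, lw = 2)
  fsum <- fid1
  fsum$signal <- fid1$signal + fid2$signal
  expect_equal(fid_to_spectrum(fsum)$intensity,
               fid_to_spectrum(fid1)$intensity +
                 fid_to_spectrum(fid2)$intensity,
               tolerance = 1e-12)
})
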