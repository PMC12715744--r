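test_that("hydrogenation kinetics has the right limits and optimum", {
  # no bubbling, no product
  expect_equal(hydrogenated_concentration(50, 0.3, r = 0.1, k1 = 0.5, tb = 0), 0)

  # slow-decay limit: saturating growth pc0 p0 (1 - e^(-k1 tb))
  got <- hydrogenated_concentration(50, 0.3, r = 1e-9, k1 = 0.5, tb = 4)
  expect_equal(got, 50 * 0.3 * (1 - exp(-0.5 * 4)), tolerance = 1e-6)

  # continuity across the r = k1 removable singularity: the deviation of the
  # closed form from the analytic limit shrinks linearly with the offset
  lim <- hydrogenated_concentration(50, 0.3, r = 0.5, k1 = 0.5, tb = 4)
  for (eps in c(1e-5, 1e-7)) {
    for (side in c(-1, 1)) {
      near <- hydrogenated_concentration(50, 0.3, r = 0.5 * (1 + side * eps),
                                         k1 = 0.5, tb = 4)
      expect_lt(abs(near - lim), 10 * eps * lim)
    }
  }
  expect_equal(lim, 50 * 0.3 * 0.5 * 4 * exp(-0.5 * 4), tolerance = 1e-12)

  # maximum over bubbling time at ln(k1/r)/(k1 - r)
  r <- 0.12; k1 <- 0.55
  tb_star <- log(k1 / r) / (k1 - r)
  tb_grid <- seq(0.01, 30, by = 0.01)
  vals <- hydrogenated_concentration(50, 0.3, r, k1, tb_grid)
  expect_equal(tb_grid[which.max(vals)], tb_star, tolerance = 0.02)
})

test_that("thermal polarization matches the high-field benchmark", {
  expect_equal(thermal_polarization(9.4, 300), 3.2e-5, tolerance = 0.01)
  expect_equal(thermal_polarization(0, 300), 0)
  # low-field value scales linearly in the tanh regime
  expect_equal(thermal_polarization(0.4454, 300), 1.517e-6, tolerance = 1e-3)
})

test_that("the enrichment-scaled polarization ceiling is affine with the right anchors", {
  expect_equal(max_polarization(1), 0.5)
  expect_equal(max_polarization(0.25), 0)
  expect_equal(100 * max_polarization(0.92), 44.667, tolerance = 1e-3)
  # affine in f
  f <- c(0.3, 0.5, 0.7, 0.9)
  expect_equal(diff(max_polarization(f)) / diff(f), rep(2 / 3, 3),
               tolerance = 1e-12)
  expect_error(max_polarization(0.2), "0.25")
})

test_that("polarization accounting reproduces the reported figures of merit", {
  # achieved P = 31.3% on 50 mM with two protons: 31.3 mM molar polarization
  pth <- thermal_polarization(0.4454, 300)
  q <- quantify_polarization(s_hyp = 0.313 / pth, s_th = 1, correction = 1,
                             p_thermal = pth, conc = 50, n_protons = 2)
  expect_equal(q$p, 0.313, tolerance = 1e-12)
  expect_equal(q$molar_polarization, 31.3, tolerance = 1e-9)
  # 70% of the enrichment-scaled ceiling
  expect_equal(round(100 * q$p / max_polarization(0.92)), 70)

  # thermal signal with unit correction: enhancement 1
  q1 <- quantify_polarization(1, 1, 1, pth, conc = 50)
  expect_equal(q1$p, pth)
  expect_equal(q1$enhancement, 1)

  # linearity in s_hyp
  q2 <- quantify_polarization(2, 1, 1, pth, conc = 50)
  expect_equal(q2$p, 2 * q1$p, tolerance = 1e-14)

  # molar polarization invariant under redistributing polarization
  qa <- quantify_polarization(0.1 / pth, 1, 1, pth, conc = 50, n_protons = 2)
  qb <- quantify_polarization(0.2 / pth, 1, 1, pth, conc = 50, n_protons = 1)
  expect_equal(qa$molar_polarization, qb$molar_polarization)

  expect_error(quantify_polarization(1, 0, 1, pth, 50), "positive")
})

test_that("reactor fill volumes match the weighed sample volumes", {
  # 16 mm OD tube (ID 12.5 mm) filled to 20 mm: printed 2.215 mL
  v16 <- reactor_volume(12.5, 20)
  expect_equal(v16, 2.1987, tolerance = 1e-4)
  expect_lt(abs(v16 - 2.215) / 2.215, 0.01)
  # 5 mm OD tube (ID 4.2 mm): printed 0.265 mL
  v5 <- reactor_volume(4.2, 20)
  expect_lt(abs(v5 - 0.265) / 0.265, 0.02)
  # flat-bottom cylinder and the exact hemisphere deficit
  vf <- reactor_volume(12.5, 20, bottom = "flat")
  expect_equal(vf, pi * 6.25^2 * 20 / 1000, tolerance = 1e-12)
  expect_equal(vf - v16, pi * 6.25^3 / 3 / 1000, tolerance = 1e-12)
  expect_error(reactor_volume(12.5, 5), "apex")
})

test_that("coefficient of variation is recovered from synthetic injection series", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")

  cvs <- vapply(1:100, function(sd) {
    d <- gen_injection_series(mean = 100, cv = 0.0063, n = 30, n_series = 1,
                              seed = sd)
    coefficient_of_variation(d$integral)
  }, numeric(1))
  expect_lt(abs(mean(cvs) / 0.0063 - 1), 0.2)
})
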