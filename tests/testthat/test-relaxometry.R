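make_train <- function(model, tau, n_echoes = 169L) {
  data.frame(tau_s = tau, echo_index = seq_len(n_echoes),
             amplitude = cpmg_signal(model, tau, n_echoes))
}

test_that("echo-decay fit inverts the generator exactly on noiseless trains", {
  m <- cpmg_model(t2 = 3.91, dstar = 0.83)
  fit <- fit_echo_decay(make_train(m, tau = 0.2))
  expect_equal(fit$r2obs, 1 / 3.91 + 0.83 * 0.4^2, tolerance = 1e-10)
  expect_equal(fit$m0, 1, tolerance = 1e-8)

  # short train, arbitrary parameters: the log-linear model is exact
  m2 <- cpmg_model(t2 = 0.7, dstar = 2.4, m0 = 3)
  fit2 <- fit_echo_decay(make_train(m2, tau = 0.05, n_echoes = 12L))
  expect_equal(fit2$r2obs, 1 / 0.7 + 2.4 * 0.1^2, tolerance = 1e-10)

  # constant amplitudes: no decay
  const <- data.frame(tau_s = 0.1, echo_index = 1:10, amplitude = 2)
  expect_equal(fit_echo_decay(const)$r2obs, 0)

  expect_error(fit_echo_decay(const[1:2, ]), "3 echoes")
})

test_that("echo-decay fit survives sub-noise-floor (non-positive) echoes", {
  m <- cpmg_model(t2 = 3.91, dstar = 0.83)
  tr <- make_train(m, tau = 0.2)
  tr$amplitude[160:169] <- tr$amplitude[160:169] - 2e-6 # dip below zero
  fit <- fit_echo_decay(tr)
  expect_equal(fit$r2obs, 0.3886, tolerance = 1e-2)
})

test_that("Hahn fit recovers T2 and D* and honours the fitting window", {
  m <- cpmg_model(t2 = 3.91, dstar = 0.83)
  taus <- seq(0.02, 0.2, length.out = 10)
  tab <- data.frame(tau_s = taus,
                    r2obs = 1 / m$t2 + m$dstar * (2 * taus)^2)
  h <- fit_hahn(tab)
  expect_equal(h$t2, 3.91, tolerance = 1e-10)
  expect_equal(h$dstar, 0.83, tolerance = 1e-10)

  # short echo spacings (convection-inflated) are excluded by the window
  contaminated <- rbind(data.frame(tau_s = c(0.001, 0.005, 0.01),
                                   r2obs = c(3, 2, 1.2)), tab)
  h2 <- fit_hahn(contaminated)
  expect_equal(h2$t2, 3.91, tolerance = 1e-10)
  expect_equal(h2$n_used, 10)

  # pure-T2 decay: zero slope
  flat <- data.frame(tau_s = taus, r2obs = 1 / 3.91)
  h3 <- fit_hahn(flat)
  expect_equal(h3$dstar, 0, tolerance = 1e-12)
  expect_equal(h3$t2, 3.91, tolerance = 1e-10)

  expect_error(fit_hahn(tab[1:2, ]), "at least 3")
  expect_error(fit_hahn(tab, window = c(0.5, 0.9)), "at least 3")
})

test_that("noisy CPMG recovery has small bias across seeds", {
  m <- cpmg_model(t2 = 3.91, dstar = 0.83)
  t2s <- vapply(1:20, function(sd) {
    d <- gen_cpmg(m, noise = noise_spec(level = 0.01, seed = sd))
    r2 <- do.call(rbind, lapply(split(d, d$tau_s), function(s) {
      data.frame(tau_s = s$tau_s[1], r2obs = fit_echo_decay(s)$r2obs)
    }))
    fit_hahn(r2)$t2
  }, numeric(1))
  expect_lt(abs(mean(t2s) - 3.91) / 3.91, 0.01)
})

test_that("T2* from the line width matches the instrument summary values", {
  expect_equal(round(t2star_from_fwhm(2.50), 2), 0.13) # 16 mm tube
  expect_equal(round(t2star_from_fwhm(1.05), 2), 0.30) # 5 mm tube
  expect_equal(t2star_from_fwhm(Inf), 0)
  # strictly decreasing and scale-covariant
  expect_equal(t2star_from_fwhm(3 * 2.5), t2star_from_fwhm(2.5) / 3)
  expect_error(t2star_from_fwhm(0), "positive")
})

test_that("ppm/Hz conversion reproduces the printed line widths", {
  gamma <- phip_constants()$gamma_1H
  ref <- gamma * 0.4454 / (2 * pi) # proton frequency at the polarizer field
  expect_equal(ppm_to_hz(2.492, ref), 47.254, tolerance = 0.005 * 47.254)
  expect_equal(ppm_to_hz(1.047, ref), 19.855, tolerance = 0.005 * 19.855)
  expect_equal(ppm_to_hz(0, ref), 0)
  expect_equal(hz_to_ppm(ppm_to_hz(1.574, ref), ref), 1.574,
               tolerance = 1e-12)
})

test_that("D*-FWHM correlation computes a proper coefficient of determination", {
  # perfectly collinear: r^2 = 1
  out <- correlate_dstar_fwhm(c(1, 2, 3), c(2, 4, 6), include_origin = TRUE)
  expect_equal(out$r_squared, 1, tolerance = 1e-12)

  # published tube summary plus the origin; closed-form OLS gives 0.9848
  fw <- c(19.855, 29.847, 47.254)
  ds <- c(0.41, 0.61, 0.83)
  out2 <- correlate_dstar_fwhm(fw, ds, include_origin = TRUE)
  x <- c(fw, 0); y <- c(ds, 0)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  r2_oracle <- 1 - sum((y - alpha - beta * x)^2) / sum((y - mean(y))^2)
  expect_equal(out2$r_squared, r2_oracle, tolerance = 1e-12)
  expect_equal(out2$r_squared, 0.9848, tolerance = 1e-3)

  expect_error(correlate_dstar_fwhm(c(2, 2), c(1, 3),
                                    include_origin = FALSE), "degenerate")
})
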