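test_that("intensity calibration recovers exact and noisy lines", {
  cl <- fit_intensity_calibration(c(0, 10, 20, 40), 5 + 2 * c(0, 10, 20, 40))
  expect_equal(cl$slope, 2)
  expect_equal(cl$intercept, 5)
  expect_error(fit_intensity_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")

  set.seed(11)
  conc <- rep(seq(0, 62.5, length.out = 9), each = 50)
  d <- generate_dilution_series(seq(0, 62.5, length.out = 9), slope = 40,
                                intercept = 120, noise_sd = 60, n_rep = 50,
                                seed = 11)
  cl2 <- fit_intensity_calibration(d$concentration, d$intensity)
  expect_equal(cl2$slope, 40, tolerance = 0.05)
})

test_that("concentration conversion is definitional and round-trips", {
  cl <- fit_intensity_calibration(c(0, 10, 20), 120 + 40 * c(0, 10, 20))
  tr <- data.frame(time = c(0, 5, 10), signal = c(120, 520, 920))
  out <- to_concentration(tr, cl, biovolume = 1)
  expect_equal(out$concentration, c(0, 10, 20))
  out2 <- to_concentration(tr, cl, biovolume = 2)
  expect_equal(out2$concentration, c(0, 5, 10))  # doubling biovolume halves

  d <- generate_dilution_series(noise_sd = 0, slope = 40, intercept = 120)
  back <- to_concentration(data.frame(time = seq_len(nrow(d)),
                                      signal = d$intensity), cl, 1)
  expect_equal(back$concentration, d$concentration, tolerance = 1e-9)
})

test_that("phase segmentation finds the peak, the minimum, and applies the 45-min rule", {
  p <- kinetic_params(k = 0.0133, F0 = 100, t_peak = 90, decay_rate = 3 / 47,
                      t_dec = 47, regrow_rate = 0.0133)
  tt <- seq(0, 240, 5)
  tr <- data.frame(time = tt, signal = simulate_trace(p, tt))
  ph <- segment_phases(tr)
  expect_lte(abs(tt[ph$i_peak] - 90), 5.01)
  expect_lte(abs(tt[ph$i_min] - 137), 5.51)
  expect_true(ph$enough_pre_peak)

  # strictly increasing trace: no decay phase
  tr2 <- data.frame(time = tt, signal = 100 * exp(0.01 * tt))
  ph2 <- segment_phases(tr2)
  expect_true(is.na(ph2$i_min))

  # peak before 45 min fails the inclusion rule
  p3 <- kinetic_params(k = 0.03, F0 = 100, t_peak = 30, t_dec = 60,
                       decay_rate = 0.05, regrow_rate = 0.01)
  tr3 <- data.frame(time = tt, signal = simulate_trace(p3, tt))
  expect_false(segment_phases(tr3)$enough_pre_peak)

  expect_error(segment_phases(tr[1:3, ]), "short")
})

test_that("exponential fit is exact on clean data and rejects noise", {
  tt <- seq(0, 120, 5)
  tr <- data.frame(time = tt, signal = 3 * exp(0.02 * tt))
  fit <- fit_exponential_phase(tr)
  expect_equal(fit$k, 0.02, tolerance = 1e-9)
  expect_equal(fit$F0, 3, tolerance = 1e-9)
  expect_equal(fit$fit_r, 1, tolerance = 1e-9)
  expect_true(fit$accepted)

  set.seed(12)
  rejected <- replicate(50, {
    trn <- data.frame(time = tt, signal = pmax(rnorm(25, 100, 20), 1))
    f <- tryCatch(fit_exponential_phase(trn), error = function(e) NULL)
    is.null(f) || !f$accepted
  })
  expect_gte(mean(rejected), 0.95)

  bad <- 3 * exp(0.02 * tt); bad[1] <- -1
  expect_error(fit_exponential_phase(data.frame(time = tt, signal = bad)),
               "non-positive")
})

test_that("noisy exponentials recover k within 10% with small mean bias", {
  set.seed(13)
  tt <- seq(0, 95, 5)
  errs <- replicate(200, {
    y <- 3 * exp(0.02 * tt) * exp(rnorm(20, 0, 0.1))
    tr <- data.frame(time = tt, signal = y)
    ph <- list(i_peak = 20, i_min = NA, t_exp = 95, t_dec = NA,
               enough_pre_peak = TRUE, smoothed = y)
    fit_exponential_phase(tr, ph)$k
  })
  expect_lt(median(abs(errs - 0.02) / 0.02), 0.10)
  expect_lt(abs(mean(errs) - 0.02) / 0.02, 0.02)
})

test_that("kinetic fits are time-shift invariant and scale equivariant", {
  p <- kinetic_params(k = 0.015, F0 = 50, t_peak = 100, decay_rate = 0.06,
                      t_dec = 50, regrow_rate = 0.015)
  tt <- seq(0, 250, 5)
  y <- simulate_trace(p, tt)
  f0 <- fit_exponential_phase(data.frame(time = tt, signal = y))
  f_shift <- fit_exponential_phase(data.frame(time = tt + 60, signal = y))
  expect_equal(f_shift$k, f0$k, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f_shift$F0, f0$F0)))
  expect_equal(f_shift$t_exp, f0$t_exp)
  expect_equal(f_shift$F1 - f_shift$F2, f0$F1 - f0$F2, tolerance = 1e-9)

  f_scale <- fit_exponential_phase(data.frame(time = tt, signal = 3 * y))
  expect_equal(f_scale$k, f0$k, tolerance = 1e-9)
  expect_equal(f_scale$F0, 3 * f0$F0, tolerance = 1e-9)
  expect_equal(f_scale$F1, 3 * f0$F1, tolerance = 1e-9)
  expect_equal(f_scale$fit_r, f0$fit_r, tolerance = 1e-12)
})

test_that("acceptance fraction never increases with noise", {
  tt <- seq(0, 240, 5)
  p <- kinetic_params(k = 0.0133, F0 = 100, t_peak = 90, decay_rate = 3 / 47,
                      t_dec = 47, regrow_rate = 0.0133)
  base <- simulate_trace(p, tt)
  acc_frac <- vapply(c(0.02, 0.1, 0.3, 0.6), function(sn) {
    set.seed(14)
    mean(replicate(40, {
      tr <- data.frame(time = tt,
                       signal = pmax(base * exp(rnorm(49, 0, sn)), 1e-6))
      f <- tryCatch(fit_exponential_phase(tr), error = function(e) NULL)
      !is.null(f) && f$accepted
    }))
  }, numeric(1))
  expect_true(all(diff(acc_frac) <= 0.05 + 1e-9))
})

test_that("phase deltas follow their definitions", {
  fit <- structure(list(k = 0.01, F0 = 2, F1 = 10, F2 = 6, t_exp = 90,
                        t_dec = 47, fit_r = 0.99, accepted = TRUE),
                   class = "kinetic_fit")
  d <- phase_deltas(fit)
  expect_equal(d$delta_exp, 8)
  expect_equal(d$delta_dec, 4)
  fit$F2 <- NA_real_
  d2 <- phase_deltas(fit)
  expect_true(is.na(d2$delta_dec))
  expect_false(d2$has_decay)
  fit$F1 <- fit$F0
  expect_equal(phase_deltas(fit)$delta_exp, 0)
})

test_that("pH dependence fit recovers exact exponentials and excludes out-of-domain levels", {
  ph <- c(6.4, 6.8, 7.3, 7.8, 8.2, 8.5)
  y <- 1.1e-3 * exp(0.32 * ph)
  fit <- fit_ph_dependence(ph, y)
  expect_equal(fit$b, 0.32, tolerance = 1e-9)
  expect_equal(fit$a, 1.1e-3, tolerance = 1e-9)
  expect_equal(nrow(fit$levels), 5)  # pH 8.5 outside the 6.4-8.2 domain
  expect_equal(response_fold_change(fit), exp(0.32 * 1.8), tolerance = 1e-9)

  set.seed(15)
  ph_obs <- rep(c(6.4, 6.8, 7.3, 7.8, 8.2), each = 60)
  y_obs <- 1.1e-3 * exp(0.32 * ph_obs) * exp(rnorm(300, 0, 0.15))
  fit2 <- fit_ph_dependence(ph_obs, y_obs)
  expect_equal(fit2$b, 0.32, tolerance = 0.10)
})
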