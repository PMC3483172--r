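test_that("trace model reproduces the exponential and decay identities", {
  p <- kinetic_params(k = log(2) / 30, F0 = 3, t_peak = 90)
  expect_equal(simulate_trace(p, 0), 3)
  expect_equal(simulate_trace(p, 30), 6)  # one half-life doubles the signal
  f1 <- 3 * exp(log(2) / 30 * 90)
  # asymptotic decay approaches decay_floor * F(t_peak)
  expect_equal(simulate_trace(p, 5000), 0.5 * f1, tolerance = 1e-6)
  # continuity at the peak
  expect_equal(simulate_trace(p, 90 - 1e-9), simulate_trace(p, 90 + 1e-9),
               tolerance = 1e-6)
  # no-decay cells plateau at the peak value
  p2 <- kinetic_params(k = 0.02, F0 = 5, t_peak = 60, has_decay = FALSE)
  expect_equal(simulate_trace(p2, c(60, 120, 500)),
               rep(5 * exp(0.02 * 60), 3))
  expect_error(simulate_trace(p, c(10, 5)), "increasing")
})

test_that("finite decay phase creates a minimum and a capped regrowth", {
  p <- kinetic_params(k = 0.0133, F0 = 100, t_peak = 90, decay_rate = 3 / 47,
                      t_dec = 47, regrow_rate = 0.0133)
  tt <- seq(0, 400, 1)
  v <- simulate_trace(p, tt)
  post <- tt > 90
  i_min <- which(post)[which.min(v[post])]
  expect_equal(tt[i_min], 137, tolerance = 0.01)  # t_peak + t_dec
  f1 <- 100 * exp(0.0133 * 90)
  expect_lte(max(v), f1 + 1e-9)               # regrowth saturates at F1
  expect_gt(v[length(v)], v[i_min])           # and does regrow
})

test_that("timelapse generator conserves injected intensity and is seeded", {
  cfg <- timelapse_config(n_frames = 8, width = 96, height = 96, n_cells = 1,
                          noise_sd = 0, drift = c(0, 0), bg_level = 100,
                          bg_gradient = 0)
  g <- generate_timelapse(cfg, seed = 1)
  trace_true <- simulate_trace(g$truth$params[[1]], g$truth$times)
  ints <- vapply(seq_len(8), function(f) sum(g$stack[, , f] - 100), numeric(1))
  expect_equal(ints, trace_true, tolerance = 1e-10)

  expect_identical(g$stack, generate_timelapse(cfg, seed = 1)$stack)
  g2 <- generate_timelapse(cfg, seed = 2)
  expect_false(isTRUE(all.equal(g$truth$positions, g2$truth$positions)))
})

test_that("empty scene yields a constant-background stack", {
  cfg <- timelapse_config(n_frames = 3, width = 40, height = 40, n_cells = 0,
                          noise_sd = 0, bg_gradient = 0, bg_level = 7)
  g <- generate_timelapse(cfg, seed = 1)
  expect_true(all(g$stack == 7))
  expect_length(g$truth$cell_ids, 0)
})

test_that("impossible cell placement errors after bounded retries", {
  cfg <- timelapse_config(n_frames = 2, width = 60, height = 60, n_cells = 40,
                          cell_radius = 6)
  expect_error(generate_timelapse(cfg, seed = 1), "place")
})

test_that("valve generator puts pores on the lattice and matches pixel-count porosity", {
  vc <- valve_config(width = 256, height = 256, spacing = 24, pore_radius = 6,
                     jitter_sd = 0, noise_sd = 0)
  g <- generate_valve_image(vc, seed = 1)
  # zero jitter: centers exactly on the (margin-offset) triangular lattice
  ys <- sort(unique(g$truth$centers[, 2]))
  expect_equal(diff(ys), rep(24 * sqrt(3) / 2, length(ys) - 1),
               tolerance = 1e-9)
  # dark-pixel count as porosity oracle; generic (jittered) pore positions
  # so per-pore pixelation errors average out
  vcj <- valve_config(width = 256, height = 256, spacing = 24,
                      pore_radius = 6, jitter_sd = 0.7, noise_sd = 0)
  gj <- generate_valve_image(vcj, seed = 1)
  expect_equal(mean(gj$image < 0.5), true_porosity(gj$truth),
               tolerance = 0.02)
  # seeding contract
  expect_identical(g$image, generate_valve_image(vc, seed = 1)$image)
})

test_that("generated porosity matches the analytic sum for radii >= 4 px", {
  for (r in c(4, 6, 8)) {
    vc <- valve_config(width = 300, height = 300, spacing = 3.2 * r,
                       pore_radius = r, jitter_sd = 0.5, noise_sd = 0)
    g <- generate_valve_image(vc, seed = 2)
    expect_equal(mean(g$image < 0.5), true_porosity(g$truth),
                 tolerance = 0.02)
  }
})

test_that("dilution series is linear with the requested design", {
  d <- generate_dilution_series(slope = 2, intercept = 5, noise_sd = 0)
  expect_equal(nrow(d), 9)
  expect_equal(range(d$concentration), c(0, 62.5))
  expect_equal(d$intensity[d$concentration == 0], 5)
  # doubling c doubles (intensity - intercept)
  i1 <- d$intensity[2] - 5
  expect_equal(d$intensity[3] - 5, 2 * i1, tolerance = 1e-9)
})

test_that("ratio pair encodes the calibration ratio and round-trips pH", {
  set.seed(42)
  ph_lev <- c(6.4, 6.8, 7.3, 7.8, 8.2, 8.5)
  ratios <- 0.4 + (1.6 - 0.4) / (1 + 10^(1.5 * (7.3 - ph_lev)))
  calib <- fit_bcecf_calibration(rep(ph_lev, 3),
                                 rep(ratios, 3) + rnorm(18, 0, 0.005))
  for (ph in c(6.6, 7.4, 8.3)) {
    pair <- generate_ratio_pair(ph, calib, seed = 7)
    cr <- cell_ratios(pair$ch1, pair$ch2, radius = 5)
    expect_gt(nrow(cr), 0)
    ph_back <- ratio_to_pH(mean(cr$ratio), calib)
    expect_equal(as.numeric(ph_back), ph, tolerance = 0.05)
  }
  expect_error(generate_ratio_pair(9.5, calib), "domain")
  # background-only pair is flagged
  empty <- generate_ratio_pair(7.3, calib, seed = 1, n_cells = 0)
  expect_warning(cr0 <- cell_ratios(empty$ch1, empty$ch2), "no cells")
  expect_equal(nrow(cr0), 0)
})
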