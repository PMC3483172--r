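test_that("denoiser is a fixed point on constant images and rejects empty input", {
  expect_equal(denoise_frame(matrix(5, 20, 20)), matrix(5, 20, 20))
  expect_error(denoise_frame(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("denoiser suppresses flat-field noise >= 3x while preserving edges and mean", {
  set.seed(10)
  d <- make_disk(20, bg = 100, value = 200, n = 101)
  noisy <- d$img + matrix(rnorm(101^2, 0, 10), 101, 101)
  dn <- denoise_frame(noisy)
  # flat corner far from the disk
  expect_lte(sd(dn[1:25, 1:25]), 10 / 3)
  expect_equal(mean(dn), mean(noisy), tolerance = 0.01)
  # edge preservation: gradient across the noiseless disk boundary survives
  grad_mag <- function(M) {
    n <- nrow(M)
    gx <- (M[, c(2:n, n)] - M[, c(1, 1:(n - 1))]) / 2
    gy <- (M[c(2:n, n), ] - M[c(1, 1:(n - 1)), ]) / 2
    sqrt(gx^2 + gy^2)
  }
  dn0 <- denoise_frame(d$img, sigma = 10)
  expect_gte(max(grad_mag(dn0)), 0.9 * max(grad_mag(d$img)))
  # the TV option honors the same contract
  tv <- denoise_frame(noisy, method = "tv")
  expect_lt(sd(tv[1:25, 1:25]), 10)
  expect_equal(mean(tv), mean(noisy), tolerance = 0.01)
})

test_that("detection finds all well-separated cells within 1 px", {
  cfg <- timelapse_config(n_frames = 2, width = 256, height = 256,
                          n_cells = 10, noise_sd = 3, drift = c(0, 0),
                          F0_mean = 3000)
  g <- generate_timelapse(cfg, seed = 4)
  det <- detect_cells(g$stack[, , 1])
  expect_equal(nrow(det), 10)
  for (i in seq_len(10)) {
    dmin <- min(sqrt((det$x - g$truth$positions[i, 1, 1])^2 +
                       (det$y - g$truth$positions[i, 2, 1])^2))
    expect_lt(dmin, 1)
  }
  expect_equal(nrow(detect_cells(matrix(100, 64, 64))), 0)
})

test_that("touching cells yield one or two detections, flagged ambiguous", {
  M <- matrix(100, 80, 80)
  for (ctr in list(c(35, 40), c(46, 40))) {
    for (i in 1:80) for (j in 1:80) {
      if ((j - 1 - ctr[1])^2 + (i - 1 - ctr[2])^2 <= 36) M[i, j] <- 150
    }
  }
  M <- M + matrix(rnorm(6400, 0, 1), 80, 80)
  det <- detect_cells(M, min_area = 20)
  expect_true(nrow(det) %in% c(1, 2))
  if (nrow(det) == 1) expect_true(det$ambiguous[1])
})

test_that("tracking links a static cell and drifting cohorts", {
  # one static cell, 10 frames -> one full-length track
  det <- replicate(10, data.frame(x = 50, y = 60), simplify = FALSE)
  trks <- link_tracks(det, max_step = 5)
  expect_length(trks, 1)
  expect_equal(nrow(trks[[1]]), 10)

  # 5 cells under uniform drift (3, 0): all links correct
  cfg <- timelapse_config(n_frames = 15, width = 220, height = 220,
                          n_cells = 5, noise_sd = 3, drift = c(3, 0),
                          F0_mean = 3000)
  g <- generate_timelapse(cfg, seed = 7)
  dets <- lapply(seq_len(15), function(f) detect_cells(g$stack[, , f]))
  trks <- link_tracks(dets, max_step = 6, min_length = 15)
  expect_length(trks, 5)
  for (tr in trks) {
    errs <- vapply(seq_len(nrow(tr)), function(j) {
      min(sqrt((g$truth$positions[, 1, tr$frame[j]] - tr$x[j])^2 +
                 (g$truth$positions[, 2, tr$frame[j]] - tr$y[j])^2))
    }, numeric(1))
    expect_lt(max(errs), 1)
  }
})

test_that("tracking recovers >= 95% of links with drift below half the gate", {
  cfg <- timelapse_config(n_frames = 20, width = 300, height = 300,
                          n_cells = 8, noise_sd = 3, drift = c(2, 1),
                          F0_mean = 3000, min_separation = 4)
  g <- generate_timelapse(cfg, seed = 9)
  dets <- lapply(seq_len(20), function(f) detect_cells(g$stack[, , f]))
  trks <- link_tracks(dets, max_step = 6, min_length = 2)
  n_links <- sum(vapply(trks, nrow, integer(1)) - 1)
  good <- 0
  for (tr in trks) {
    ids <- vapply(seq_len(nrow(tr)), function(j) {
      which.min((g$truth$positions[, 1, tr$frame[j]] - tr$x[j])^2 +
                  (g$truth$positions[, 2, tr$frame[j]] - tr$y[j])^2)
    }, integer(1))
    good <- good + sum(ids[-1] == ids[-length(ids)])
  }
  expect_gte(good / (19 * 8), 0.95)
  expect_gte(n_links, 0.95 * 19 * 8)
})

test_that("crossing cells resolve by minimal displacement and are logged", {
  det <- lapply(0:8, function(f) {
    data.frame(x = c(10 + 3 * f, 34 - 3 * f), y = c(20, 20))
  })
  trks <- link_tracks(det, max_step = 8, min_length = 5)
  expect_length(trks, 2)
  amb <- attr(trks, "ambiguities")
  expect_false(is.null(amb))
  # each track keeps a consistent velocity through the crossing
  for (tr in trks) {
    steps <- diff(tr$x)
    expect_true(all(steps == steps[1]))
  }
})

test_that("local background reports annulus medians and degenerate fallback", {
  M <- matrix(40, 64, 64)
  bg <- local_background(M, c(32, 32), 9, 18)
  expect_equal(bg$value, 40)
  expect_false(bg$fallback)

  # linear gradient: annulus median equals the value at the center
  gx <- matrix(rep(seq(0, 63), each = 64), 64, 64)  # value = x (column)
  bg2 <- local_background(gx, c(30, 32), 6, 12)
  expect_equal(bg2$value, 30, tolerance = 0.01)

  # annulus fully masked -> frame-wide fallback, flagged
  mask <- matrix(TRUE, 64, 64)
  bg3 <- local_background(M, c(32, 32), 6, 12, exclude_mask = mask)
  expect_true(bg3$fallback)
  expect_equal(bg3$value, 40)
})
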