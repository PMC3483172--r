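test_that("binarization separates phases regardless of polarity", {
  M <- matrix(0.8, 60, 60); M[20:30, 20:30] <- 0.15
  mask <- binarize(M, open_radius = 0)
  expect_equal(sum(mask), 11 * 11)
  expect_identical(binarize(1 - M, dark_pores = FALSE, open_radius = 0), mask)
})

test_that("binarized generated valve matches truth pore count within 2%", {
  vc <- valve_config(noise_sd = 0, jitter_sd = 0.7)
  g <- generate_valve_image(vc, seed = 3)
  mask <- binarize(g$image)
  expect_equal(sum(mask), sum(pi * g$truth$radii^2), tolerance = 0.02)
})

test_that("pore detection measures disks and filters non-circular clutter", {
  centers <- cbind(c(30, 80, 130), c(40, 90, 40))
  mask <- make_pore_mask(centers, 10, 140, 170)
  pores <- detect_pores(mask)
  expect_equal(nrow(pores), 3)
  expect_equal(pores$radius, rep(10, 3), tolerance = 0.05)
  ord <- order(pores$x)
  expect_equal(pores$x[ord], centers[order(centers[, 1]), 1], tolerance = 0.01)

  # an elongated crack fails the circularity filter
  mask[60:63, 10:160] <- TRUE
  pores2 <- detect_pores(mask)
  expect_equal(nrow(pores2), 3)

  # border-touching components are excluded
  mask3 <- make_pore_mask(cbind(c(0, 60), c(30, 30)), 8, 64, 100)
  pores3 <- detect_pores(mask3)
  expect_equal(nrow(pores3), 1)
  expect_equal(attr(pores3, "n_excluded"), 1L)
})

test_that("pore recovery on a jittered generated valve exceeds 95%", {
  vc <- valve_config(width = 448, height = 448, spacing = 24, pore_radius = 6,
                     jitter_sd = 2.4, noise_sd = 0.03)
  g <- generate_valve_image(vc, seed = 8)
  pores <- detect_pores(binarize(g$image), min_radius = 3)
  interior_truth <- g$truth$centers[, 1] > 10 & g$truth$centers[, 1] < 437 &
    g$truth$centers[, 2] > 10 & g$truth$centers[, 2] < 437
  matched <- vapply(which(interior_truth), function(i) {
    min((pores$x - g$truth$centers[i, 1])^2 +
          (pores$y - g$truth$centers[i, 2])^2) < 9
  }, logical(1))
  expect_gte(mean(matched), 0.95)
  expect_equal(mean(pores$radius), 6, tolerance = 0.05)
})

test_that("Delaunay spacing on a perfect triangular lattice is the lattice constant", {
  vc <- valve_config(width = 320, height = 320, spacing = 30, pore_radius = 6,
                     jitter_sd = 0, noise_sd = 0)
  g <- generate_valve_image(vc, seed = 1)
  pores <- detect_pores(binarize(g$image))
  sp <- pore_spacing(pores)
  expect_gt(length(sp$d1), 50)
  # pixel-level centroids carry ~0.1 px pixelation noise
  expect_lt(max(abs(sp$d1 - 30)), 0.25)

  # on exact lattice centers the interior d1 equals the spacing exactly
  exact <- structure(
    data.frame(x = g$truth$centers[, 1], y = g$truth$centers[, 2],
               radius = g$truth$radii, area = pi * g$truth$radii^2,
               circularity = 1),
    image_dim = c(320L, 320L), class = c("pore_set", "data.frame"))
  sp_exact <- pore_spacing(exact)
  expect_lt(max(abs(sp_exact$d1 - 30)), 1e-6)

  # jittered lattice: mean d1 within 3% of the spacing
  vc2 <- valve_config(width = 320, height = 320, spacing = 30,
                      pore_radius = 6, jitter_sd = 2, noise_sd = 0.02)
  g2 <- generate_valve_image(vc2, seed = 2)
  sp2 <- pore_spacing(detect_pores(binarize(g2$image), min_radius = 3))
  expect_equal(mean(sp2$d1), 30, tolerance = 0.03)

  expect_error(pore_spacing(detect_pores(
    make_pore_mask(cbind(c(20, 50, 80, 110), rep(30, 4)), 6, 60, 140))),
    "collinear")
})

test_that("square lattice nearest-neighbor subset recovers the spacing", {
  s <- 30
  gx <- seq(20, 260, s); gy <- seq(20, 230, s)
  centers <- as.matrix(expand.grid(gx, gy))
  mask <- make_pore_mask(centers, 6, 250, 280)
  sp <- pore_spacing(detect_pores(mask))
  # edges are sides (s) or diagonals (s*sqrt(2)) of the squares
  expect_true(all(abs(sp$d1 - s) < 1 | abs(sp$d1 - s * sqrt(2)) < 1))
  nn <- sp$d1[abs(sp$d1 - s) < 1]
  expect_equal(mean(nn), s, tolerance = 0.01)
})

test_that("finger analysis measures row gaps and flags single rows", {
  # two parallel rows: d2 = gap - 2R
  centers <- rbind(cbind(seq(20, 280, 20), 40), cbind(seq(20, 280, 20), 80))
  mask <- make_pore_mask(centers, 8, 120, 300)
  fa <- finger_analysis(detect_pores(mask))
  expect_length(fa$D, 2)
  expect_equal(fa$d2, 40 - 16, tolerance = 1 / 24)
  expect_equal(fa$D, rep(16, 2), tolerance = 0.05)

  # single row: D defined, d2 flagged undefined
  one <- make_pore_mask(cbind(seq(20, 280, 20), 30), 8, 60, 300)
  fa1 <- finger_analysis(detect_pores(one))
  expect_false(fa1$d2_defined)
  expect_true(is.na(fa1$d2[1]))
  expect_equal(fa1$D, 16, tolerance = 0.05)
})

test_that("generated valve rib width is recovered within 15%", {
  vc <- valve_config(width = 384, height = 384, spacing = 24, pore_radius = 6,
                     rows_per_finger = 3, rib_width = 24, jitter_sd = 0.5,
                     noise_sd = 0.02)
  g <- generate_valve_image(vc, seed = 11)
  fa <- finger_analysis(detect_pores(binarize(g$image), min_radius = 3))
  expect_gte(length(fa$D), 3)
  expect_equal(mean(fa$d2), 24, tolerance = 0.15)
})

test_that("porosity is analytic, rotation invariant, and truth-matching", {
  centers <- cbind(rep(seq(12, 88, 19), 2), rep(c(30, 70), each = 5))
  mask <- make_pore_mask(centers, 6, 100, 100)
  pores <- detect_pores(mask)
  expect_equal(nrow(pores), 10)
  tr <- valve_traits(pores, scale = 1, region = c(0, 100, 0, 100),
                     fingers = FALSE)
  expect_equal(tr$porosity, 10 * pi * 36 / 1e4, tolerance = 0.02)

  # rotating the image by 90 degrees leaves porosity unchanged
  mask_rot <- t(mask)[nrow(t(mask)):1, ]
  tr_rot <- valve_traits(detect_pores(mask_rot), scale = 1,
                         region = c(0, 100, 0, 100), fingers = FALSE)
  expect_equal(tr_rot$porosity, tr$porosity, tolerance = 1e-6)
})

test_that("macro annotations populate the trait schema", {
  vc <- valve_config(noise_sd = 0.02, jitter_sd = 1)
  g <- generate_valve_image(vc, seed = 6)
  pores <- detect_pores(binarize(g$image), min_radius = 3)
  ann <- list(valve_width_px = 3000,
              fultoportulae = cbind(c(100, 150, 200), c(100, 160, 100)),
              rimoportulae = cbind(c(50, 300, 300, 50), c(50, 50, 300, 300)))
  tr <- valve_traits(pores, scale = 2, annotations = ann, fingers = FALSE)
  expect_equal(tr$valve_width_um, 6)          # 3000 px * 2 nm / 1000
  expect_equal(tr$n_fultoportulae, 3L)
  expect_equal(tr$cp_um, sqrt(50^2 + 60^2) * 2 / 1000)
  expect_equal(tr$rp_um, 250 * 2 / 1000)      # square of side 250 px
  expect_true(all(c("valve_width_um", "n_fultoportulae", "cp_um", "rp_um",
                    "R_nm", "d1_nm", "D_nm", "d2_nm", "porosity")
                  %in% names(tr)))
})

test_that("porosity recovery is unbiased across a porosity gradient", {
  cfg <- default_run_config()
  cfg$seed <- 2
  cfg$synthetic <- list(n = 6, porosity = c(0.05, 0.15),
                        valve = list(width = 320, height = 320, spacing = 32,
                                     jitter_sd = 1.5, noise_sd = 0.02))
  run <- run_morphometry(cfg)
  rec <- run$traits$porosity
  tru <- vapply(seq_along(run$truth), function(i) {
    sp <- pore_spacing(run$pores[[i]])
    m <- median(sp$d1)
    true_porosity(run$truth[[i]], c(m, 319 - m, m, 319 - m))
  }, numeric(1))
  expect_true(all(abs(rec - tru) < 0.01))
  sl <- coef(lm(rec ~ tru))[2]
  expect_equal(unname(sl), 1, tolerance = 0.05)
})
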