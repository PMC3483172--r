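#' Configuration of the synthetic TEM valve-image generator
#'
#' Emulates a high-magnification TEM view of the nanopore array of a centric
#' diatom valve: dark quasi-circular pores on a bright silica background,
#' arranged on a jittered triangular lattice whose rows are grouped into
#' radial "fingers" (semi-continuous cribra) separated by bright pore-free
#' ribs.
#'
#' @param width,height image size in pixels.
#' @param spacing triangular lattice spacing in pixels (must exceed twice
#'   the pore radius).
#' @param pore_radius pore radius in pixels.
#' @param radius_sd standard deviation of per-pore radius jitter, pixels.
#' @param jitter_sd positional jitter of pore centers, pixels.
#' @param rows_per_finger lattice rows per finger; `Inf` disables the
#'   finger/rib structure and fills the frame with a continuous lattice.
#' @param rib_width width of the bright pore-free rib between adjacent
#'   fingers, pixels (edge-to-edge between pore rims).
#' @param bg_value,pore_value background (silica) and pore gray levels in
#'   `[0, 1]`; pores darker than background by default.
#' @param noise_sd additive Gaussian noise sd, gray levels.
#' @param margin pore-free border, pixels.
#' @return A list of class `valve_config`.
#' @export
valve_config <- function(width = 384, height = 384, spacing = 24,
                         pore_radius = 6, radius_sd = 0, jitter_sd = 0,
                         rows_per_finger = Inf, rib_width = 24,
                         bg_value = 0.8, pore_value = 0.15, noise_sd = 0.02,
                         margin = 4) {
  stopifnot(width > 0, height > 0, spacing > 2 * pore_radius,
            pore_radius > 0, radius_sd >= 0, jitter_sd >= 0,
            rows_per_finger >= 1, rib_width >= 0, noise_sd >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "valve_config"
  cfg
}

#' Generate a synthetic TEM valve image with pore ground truth
#'
#' Pore centers sit on a perturbed triangular lattice; rows are grouped into
#' horizontal fingers when `rows_per_finger` is finite, with a pore-free rib
#' of width `rib_width` between the pore rims of adjacent fingers. Pores are
#' dark disks; the truth records exact centers and radii.
#'
#' @param config a [valve_config()].
#' @param seed integer seed.
#' @return List with `image` (numeric matrix `[height, width]`, values
#'   roughly in `[0, 1]`) and `truth`, a `pore_truth` list: `centers`
#'   (matrix x, y), `radii`, `lattice_spacing`, `finger_id` (integer per
#'   pore, `NA` without finger structure), `finger_axes` (list of horizontal
#'   axis y-positions), `rib_width`.
#' @export
generate_valve_image <- function(config, seed) {
  stopifnot(inherits(config, "valve_config"))
  s <- config$spacing
  row_dy <- s * sqrt(3) / 2
  withr::with_seed(as.integer(seed), {
    # lay rows top to bottom, inserting rib gaps between finger blocks
    y <- config$margin + config$pore_radius
    row_y <- numeric(0); row_finger <- integer(0)
    row_in_block <- 0L; finger <- 1L
    y_max <- config$height - 1 - config$margin - config$pore_radius
    while (y <= y_max) {
      row_y <- c(row_y, y); row_finger <- c(row_finger, finger)
      row_in_block <- row_in_block + 1L
      if (is.finite(config$rows_per_finger) &&
          row_in_block >= config$rows_per_finger) {
        # rib gap: rim-to-rim distance rib_width between adjacent fingers
        y <- y + config$rib_width + 2 * config$pore_radius
        row_in_block <- 0L; finger <- finger + 1L
      } else {
        y <- y + row_dy
      }
    }
    centers <- NULL; fid <- integer(0)
    x_lo <- config$margin + config$pore_radius
    x_hi <- config$width - 1 - config$margin - config$pore_radius
    for (i in seq_along(row_y)) {
      off <- if (i %% 2 == 0) s / 2 else 0
      xs <- seq(x_lo + off, x_hi, by = s)
      if (length(xs) == 0) next
      centers <- rbind(centers, cbind(xs, row_y[i]))
      fid <- c(fid, rep(row_finger[i], length(xs)))
    }
    if (is.null(centers)) stop("geometrically impossible config: no pores fit")
    if (config$jitter_sd > 0) {
      centers <- centers + matrix(rnorm(length(centers), 0, config$jitter_sd),
                                  ncol = 2)
    }
    radii <- rep(config$pore_radius, nrow(centers))
    if (config$radius_sd > 0) {
      radii <- pmax(radii + rnorm(length(radii), 0, config$radius_sd),
                    config$pore_radius / 4)
    }
    # keep pores fully inside the frame and non-overlapping with neighbors
    keep <- centers[, 1] - radii >= 0 & centers[, 1] + radii <= config$width - 1 &
      centers[, 2] - radii >= 0 & centers[, 2] + radii <= config$height - 1
    centers <- centers[keep, , drop = FALSE]
    radii <- radii[keep]; fid <- fid[keep]

    img <- matrix(config$bg_value, config$height, config$width)
    xs <- 0:(config$width - 1); ys <- 0:(config$height - 1)
    for (i in seq_len(nrow(centers))) {
      cx <- centers[i, 1]; cy <- centers[i, 2]; r <- radii[i]
      x_idx <- which(abs(xs - cx) <= r + 1)
      y_idx <- which(abs(ys - cy) <= r + 1)
      dmat <- outer((ys[y_idx] - cy)^2, (xs[x_idx] - cx)^2, "+")
      img[y_idx, x_idx][dmat <= r^2] <- config$pore_value
    }
    if (config$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, config$noise_sd),
                          nrow(img), ncol(img))
    }
    axes <- tapply(centers[, 2], fid, mean)
    truth <- structure(
      list(centers = unname(centers), radii = radii, lattice_spacing = s,
           finger_id = if (is.finite(config$rows_per_finger)) fid else
             rep(NA_integer_, length(fid)),
           finger_axes = as.numeric(axes), rib_width = config$rib_width,
           image_dim = c(height = config$height, width = config$width)),
      class = "pore_truth")
    list(image = img, truth = truth)
  })
}

#' Analytic porosity of a generated valve inside a rectangular region
#'
#' @param truth a `pore_truth` object.
#' @param region `c(x0, x1, y0, y1)` in pixel coordinates; pores are counted
#'   by their centers, each contributing its full disk area. `NULL` uses the
#'   whole image.
#' @return Porosity (pore area fraction), dimensionless.
#' @export
true_porosity <- function(truth, region = NULL) {
  stopifnot(inherits(truth, "pore_truth"))
  if (is.null(region)) {
    region <- c(0, truth$image_dim[["width"]] - 1,
                0, truth$image_dim[["height"]] - 1)
  }
  inr <- truth$centers[, 1] >= region[1] & truth$centers[, 1] <= region[2] &
    truth$centers[, 2] >= region[3] & truth$centers[, 2] <= region[4]
  area <- (region[2] - region[1]) * (region[4] - region[3])
  sum(pi * truth$radii[inr]^2) / area
}
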