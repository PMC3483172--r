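#' Generate a linear dye-dilution fluorescence series
#'
#' Emulates the intensity-vs-concentration calibration of the reporter dye
#' in the imaging device: mean intensity at concentration `c` is
#' `slope * c + intercept`, plus Gaussian noise. The default design follows
#' the calibration used for the kinetics analysis: 9 concentrations between
#' 0 and 62.5 uM.
#'
#' @param concentrations dye concentrations in uM (>= 0); default 9 levels
#'   spanning 0 to 62.5 uM.
#' @param slope,intercept linear response parameters (intensity per uM,
#'   intensity).
#' @param noise_sd Gaussian noise sd on each replicate intensity.
#' @param n_rep replicates per concentration.
#' @param seed integer seed.
#' @return data.frame with columns `concentration`, `intensity`.
#' @export
generate_dilution_series <- function(concentrations = seq(0, 62.5, length.out = 9),
                                     slope = 40, intercept = 120,
                                     noise_sd = 0, n_rep = 1, seed = 1) {
  stopifnot(all(concentrations >= 0), n_rep >= 1, noise_sd >= 0)
  withr::with_seed(as.integer(seed), {
    conc <- rep(concentrations, each = n_rep)
    intensity <- slope * conc + intercept
    if (noise_sd > 0) intensity <- intensity + rnorm(length(conc), 0, noise_sd)
    data.frame(concentration = conc, intensity = intensity)
  })
}

#' Generate a dual-excitation ratiometric image pair at a known pH
#'
#' Emulates a BCECF-type ratiometric acquisition: cells are rendered in two
#' channels such that the background-corrected channel-1/channel-2 intensity
#' ratio of every cell equals the calibration curve's ratio at the requested
#' pH, up to noise.
#'
#' @param pH intracellular pH to encode; must lie in the calibration domain.
#' @param calib a `ph_calibration` from [fit_bcecf_calibration()].
#' @param seed integer seed.
#' @param n_cells number of cells (0 gives a background-only pair).
#' @param width,height image size, pixels.
#' @param cell_radius cell radius, pixels.
#' @param cell_intensity mean channel-2 per-pixel cell intensity above
#'   background.
#' @param bg levels `c(bg1, bg2)` of the two channels.
#' @param noise_sd additive Gaussian noise sd, both channels.
#' @return List with `ch1`, `ch2` (matrices), and `truth` (centers, radius,
#'   true ratio, pH).
#' @export
generate_ratio_pair <- function(pH, calib, seed = 1, n_cells = 8,
                                width = 160, height = 160, cell_radius = 5,
                                cell_intensity = 400, bg = c(60, 80),
                                noise_sd = 2) {
  stopifnot(inherits(calib, "ph_calibration"))
  if (pH < calib$domain[1] || pH > calib$domain[2]) {
    stop("pH ", pH, " outside calibration domain [",
         calib$domain[1], ", ", calib$domain[2], "]")
  }
  ratio <- predict_ratio(calib, pH)
  withr::with_seed(as.integer(seed), {
    ch1 <- matrix(bg[1], height, width)
    ch2 <- matrix(bg[2], height, width)
    pad <- cell_radius + 2
    centers <- NULL
    if (n_cells > 0) {
      xs <- ys <- numeric(0)
      tries <- 0L
      while (length(xs) < n_cells) {
        tries <- tries + 1L
        if (tries > 1000L * n_cells) stop("could not place cells")
        x <- runif(1, pad, width - 1 - pad); y <- runif(1, pad, height - 1 - pad)
        if (length(xs) == 0 ||
            all((xs - x)^2 + (ys - y)^2 >= (4 * cell_radius)^2)) {
          xs <- c(xs, x); ys <- c(ys, y)
        }
      }
      centers <- cbind(x = xs, y = ys)
      gx <- 0:(width - 1); gy <- 0:(height - 1)
      for (i in seq_len(n_cells)) {
        x_idx <- which(abs(gx - xs[i]) <= cell_radius)
        y_idx <- which(abs(gy - ys[i]) <= cell_radius)
        dmat <- outer((gy[y_idx] - ys[i])^2, (gx[x_idx] - xs[i])^2, "+")
        disk <- dmat <= cell_radius^2
        ch2[y_idx, x_idx][disk] <- ch2[y_idx, x_idx][disk] + cell_intensity
        ch1[y_idx, x_idx][disk] <- ch1[y_idx, x_idx][disk] +
          ratio * cell_intensity
      }
    }
    if (noise_sd > 0) {
      ch1 <- ch1 + matrix(rnorm(length(ch1), 0, noise_sd), height, width)
      ch2 <- ch2 + matrix(rnorm(length(ch2), 0, noise_sd), height, width)
    }
    list(ch1 = ch1, ch2 = ch2,
         truth = list(centers = centers, radius = cell_radius,
                      ratio = ratio, pH = pH))
  })
}
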