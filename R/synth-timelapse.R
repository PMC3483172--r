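#' Configuration of the synthetic time-lapse generator
#'
#' Settings emulating a microfluidic fluorescence time-lapse acquisition:
#' drifting disk-shaped cells on a noisy, optionally tilted background, each
#' carrying a two-phase valve-formation trace (see [simulate_trace()]).
#' Defaults correspond to the acquisition the analysis was designed for:
#' one frame every 5 minutes over 8 hours, a slow advective drift from
#' medium renewal, and a decay (maturation) phase present in 75% of cells.
#'
#' Cells are rendered as uniform disks so that the level-line boundary is a
#' genuine sharp contrast; per-cell per-frame pixel values are the model
#' trace divided by the disk pixel count, so the integrated (background
#' subtracted) disk intensity equals the trace exactly before quantization.
#'
#' @param n_frames number of frames (>= 2).
#' @param width,height frame size in pixels.
#' @param n_cells number of cells (>= 0).
#' @param cell_radius cell disk radius in pixels.
#' @param frame_interval minutes between frames.
#' @param bg_level flat background level, intensity counts.
#' @param bg_gradient peak-to-peak amplitude of a linear horizontal
#'   background gradient, counts (0 disables).
#' @param noise_sd additive Gaussian noise standard deviation, counts.
#' @param drift per-frame drift `(dx, dy)` in pixels, applied to all cells.
#' @param k_mean,k_cv log-normal distribution of the accumulation rate `k`
#'   (per minute): mean and coefficient of variation.
#' @param F0_mean,F0_cv log-normal distribution of the trace origin `F0`
#'   (integrated counts above background).
#' @param t_peak_mean,t_peak_sd normal distribution of the accumulation
#'   duration (minutes), truncated to stay positive.
#' @param t_dec_mean,t_dec_sd normal distribution of the decay duration
#'   (minutes), truncated to stay positive.
#' @param decay_floor decay asymptote as a fraction of the peak value.
#' @param has_decay_frac fraction of cells with a decay phase.
#' @param regrow "k" to re-increase after the decay minimum at the cell's own
#'   accumulation rate (the sibling-valve signal), or a numeric rate per
#'   minute (0 = hold the minimum).
#' @param min_separation minimum center-to-center distance between cells, in
#'   cell radii.
#' @param margin extra empty border in pixels kept free of cells.
#' @return A list of class `timelapse_config`.
#' @export
timelapse_config <- function(n_frames = 96, width = 256, height = 256,
                             n_cells = 12, cell_radius = 6,
                             frame_interval = 5, bg_level = 100,
                             bg_gradient = 0, noise_sd = 5,
                             drift = c(0.4, 0.15),
                             k_mean = 0.0133, k_cv = 0.15,
                             F0_mean = 2000, F0_cv = 0.25,
                             t_peak_mean = 90, t_peak_sd = 39,
                             t_dec_mean = 47, t_dec_sd = 20,
                             decay_floor = 0.5, has_decay_frac = 0.75,
                             regrow = "k",
                             min_separation = 4, margin = 2) {
  stopifnot(n_frames >= 2, width > 0, height > 0, n_cells >= 0,
            cell_radius > 0, frame_interval > 0, noise_sd >= 0,
            bg_gradient >= 0, length(drift) == 2,
            has_decay_frac >= 0, has_decay_frac <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "timelapse_config"
  cfg
}

# draw per-cell kinetic parameters from the config's population distributions
sample_kinetic_params <- function(config, n) {
  if (n == 0) return(list())
  ln_pars <- function(m, cv) {
    s2 <- log(1 + cv^2); list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  kp <- ln_pars(config$k_mean, config$k_cv)
  fp <- ln_pars(config$F0_mean, config$F0_cv)
  k <- stats::rlnorm(n, kp$meanlog, kp$sdlog)
  F0 <- stats::rlnorm(n, fp$meanlog, fp$sdlog)
  t_peak <- pmax(stats::rnorm(n, config$t_peak_mean, config$t_peak_sd),
                 config$t_peak_mean / 3)
  t_dec <- pmax(stats::rnorm(n, config$t_dec_mean, config$t_dec_sd),
                config$t_dec_mean / 3)
  has_decay <- runif(n) < config$has_decay_frac
  lapply(seq_len(n), function(i) {
    rg <- if (identical(config$regrow, "k")) k[i] else as.numeric(config$regrow)
    kinetic_params(k = k[i], F0 = F0[i], t_peak = t_peak[i],
                   decay_rate = 3 / t_dec[i], has_decay = has_decay[i],
                   decay_floor = config$decay_floor, t_dec = t_dec[i],
                   regrow_rate = rg)
  })
}

# non-overlapping cell placement valid for the whole drifted trajectory
place_cells <- function(config, n) {
  r <- config$cell_radius
  pad <- r + config$margin
  dx_tot <- config$drift[1] * (config$n_frames - 1)
  dy_tot <- config$drift[2] * (config$n_frames - 1)
  x_lo <- pad + max(0, -dx_tot); x_hi <- config$width - 1 - pad - max(0, dx_tot)
  y_lo <- pad + max(0, -dy_tot); y_hi <- config$height - 1 - pad - max(0, dy_tot)
  if (n > 0 && (x_hi <= x_lo || y_hi <= y_lo)) {
    stop("frame too small for the requested drift and cell radius")
  }
  min_d <- config$min_separation * r
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 500L * max(n, 1L)) {
      stop("could not place ", n, " non-overlapping cells; ",
           "reduce n_cells or min_separation")
    }
    x <- runif(1, x_lo, x_hi); y <- runif(1, y_lo, y_hi)
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= min_d^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic fluorescence time-lapse stack with ground truth
#'
#' Renders drifting uniform-disk cells whose integrated intensity follows the
#' two-phase trace model, on a flat or linearly tilted background with
#' additive Gaussian noise. Identical `(config, seed)` pairs yield
#' bit-identical stacks.
#'
#' @param config a [timelapse_config()].
#' @param seed integer seed; all randomness derives from it.
#' @return A list with elements
#'   \describe{
#'     \item{stack}{numeric array `[height, width, n_frames]`, counts;}
#'     \item{truth}{`scene_truth` list: `cell_ids`, `positions` (array
#'       `[n_cells, 2, n_frames]` of x/y centers), `params` (list of
#'       [kinetic_params()]), `times` (minutes), `cell_radius_px`,
#'       `drift_px_per_frame`.}
#'   }
#' @export
generate_timelapse <- function(config, seed) {
  stopifnot(inherits(config, "timelapse_config"))
  withr::with_seed(as.integer(seed), {
    n <- config$n_cells
    params <- sample_kinetic_params(config, n)
    pos0 <- place_cells(config, n)
    times <- (seq_len(config$n_frames) - 1) * config$frame_interval
    h <- config$height; w <- config$width
    positions <- array(NA_real_, dim = c(n, 2, config$n_frames))
    stack <- array(0, dim = c(h, w, config$n_frames))
    bg <- matrix(config$bg_level, h, w)
    if (config$bg_gradient > 0 && w > 1) {
      bg <- bg + matrix(rep(seq(0, config$bg_gradient, length.out = w),
                            each = h), h, w)
    }
    xs <- 0:(w - 1); ys <- 0:(h - 1)
    for (f in seq_len(config$n_frames)) {
      frame <- bg
      for (i in seq_len(n)) {
        cx <- pos0[i, 1] + config$drift[1] * (f - 1)
        cy <- pos0[i, 2] + config$drift[2] * (f - 1)
        positions[i, , f] <- c(cx, cy)
        val <- simulate_trace(params[[i]], times[f])
        x_idx <- which(abs(xs - cx) <= config$cell_radius)
        y_idx <- which(abs(ys - cy) <= config$cell_radius)
        dmat <- outer((ys[y_idx] - cy)^2, (xs[x_idx] - cx)^2, "+")
        disk <- dmat <= config$cell_radius^2
        npix <- sum(disk)
        if (npix > 0) {
          frame[y_idx, x_idx][disk] <- frame[y_idx, x_idx][disk] + val / npix
        }
      }
      if (config$noise_sd > 0) {
        frame <- frame + matrix(rnorm(h * w, 0, config$noise_sd), h, w)
      }
      stack[, , f] <- frame
    }
    truth <- structure(
      list(cell_ids = seq_len(n), positions = positions, params = params,
           times = times, cell_radius_px = config$cell_radius,
           drift_px_per_frame = config$drift),
      class = "scene_truth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a cohort of noisy trace-level recordings with ground truth
#'
#' Bypasses image rendering: samples per-cell kinetic parameters from the
#' config's population distributions, evaluates the trace model on the frame
#' grid and adds proportional Gaussian noise at the given signal-to-noise
#' ratio. Used to validate the phase segmentation and exponential fitting at
#' scale.
#'
#' @param config a [timelapse_config()]; only the kinetic-population and
#'   timing fields are used.
#' @param n number of traces.
#' @param snr signal-to-noise ratio; per-sample noise sd is `value / snr`.
#' @param seed integer seed.
#' @return List with `traces` (list of data.frames `time`, `signal`),
#'   `params` (list of [kinetic_params()]).
#' @export
generate_trace_cohort <- function(config, n, snr = 10, seed = 1) {
  stopifnot(inherits(config, "timelapse_config"), n >= 1, snr > 0)
  withr::with_seed(as.integer(seed), {
    params <- sample_kinetic_params(config, n)
    times <- (seq_len(config$n_frames) - 1) * config$frame_interval
    traces <- lapply(params, function(p) {
      v <- simulate_trace(p, times)
      s <- v + rnorm(length(v), 0, v / snr)
      data.frame(time = times, signal = pmax(s, 1e-9))
    })
    list(traces = traces, params = params)
  })
}
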