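#' Default end-to-end run configuration
#'
#' Every stage parameter with its documented default. The configuration
#' round-trips through JSON unchanged (see [write_run_config()]).
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    seed = 1,
    out_dir = NULL,
    pixel_size_um = 0.65,          # 10x acquisition, camera-dependent
    cell_radius = 6,               # expected cell radius, px
    denoise = list(enabled = FALSE, method = "nlm", search_radius = 3,
                   patch_radius = 1),
    detect = list(min_area = 20, max_area = 2000, nsigma = 4),
    track = list(max_step = 10, min_length = NULL),  # NULL: ceil(45/interval)
    background = list(inner_factor = 1.5, outer_factor = 3),
    shape = list(n_levels = 96, window_factor = 4),
    kinetics = list(r_threshold = 0.95, min_pre_peak = 45,
                    smoothing_window = 3, prominence_frac = 0.1),
    calibration = list(slope = NULL, intercept = NULL),
    ph_domain = c(6.4, 8.2),
    morpho = list(scale_nm_px = 2.0, min_radius = 2, max_radius = 50,
                  min_circularity = 0.6, dark_pores = TRUE)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read and write run configurations as JSON
#'
#' @param config a `run_config` list.
#' @param path JSON file path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   returns the configuration merged over the defaults.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(unclass(default_run_config()), raw,
                           keep.null = TRUE)
  class(cfg) <- c("run_config", "list")
  cfg
}

# one tracked stack through detect -> link -> shape/background -> trace ->
# phase segmentation -> exponential fit; returns per-cell fits + exclusions
process_stack <- function(stack, times, config, pHe = NA_real_) {
  h <- dim(stack)[1]; w <- dim(stack)[2]; n_frames <- dim(stack)[3]
  interval <- if (n_frames > 1) times[2] - times[1] else 1
  min_len <- config$track$min_length
  if (is.null(min_len)) {
    min_len <- ceiling(config$kinetics$min_pre_peak / interval) + 1
  }
  r <- config$cell_radius
  frames <- lapply(seq_len(n_frames), function(i) {
    fr <- stack[, , i]
    if (isTRUE(config$denoise$enabled)) {
      fr <- denoise_frame(fr, method = config$denoise$method,
                          patch_radius = config$denoise$patch_radius,
                          search_radius = config$denoise$search_radius)
    }
    fr
  })
  detections <- lapply(frames, detect_cells,
                       min_area = config$detect$min_area,
                       max_area = config$detect$max_area,
                       nsigma = config$detect$nsigma)
  cell_masks <- lapply(frames, function(fr) {
    fr > median(fr) + config$detect$nsigma * mad(fr)
  })
  tracks <- link_tracks(detections, max_step = config$track$max_step,
                        min_length = min_len)

  exclusions <- data.frame(track_id = integer(0), reason = character(0))
  exclude <- function(id, reason) {
    exclusions <<- rbind(exclusions,
                         data.frame(track_id = id, reason = reason))
  }
  fits <- list()
  for (tr in tracks) {
    id <- attr(tr, "track_id")
    shapes <- vector("list", nrow(tr))
    bgs <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      fr <- frames[[tr$frame[i]]]
      ctr <- c(tr$x[i], tr$y[i])
      shapes[[i]] <- tryCatch(
        extract_shape(fr, ctr, n_levels = config$shape$n_levels,
                      window = config$shape$window_factor * r),
        error = function(e) NULL)
      bgs[i] <- local_background(fr, ctr,
                                 inner_radius = config$background$inner_factor * r,
                                 outer_radius = config$background$outer_factor * r,
                                 exclude_mask = cell_masks[[tr$frame[i]]])$value
    }
    ok <- !vapply(shapes, is.null, logical(1))
    if (sum(ok) < min_len) { exclude(id, "shape_extraction_failed"); next }
    trace <- integrate_fluorescence(frames, tr[ok, , drop = FALSE],
                                    shapes[ok], bgs[ok],
                                    times = times[tr$frame[ok]])
    areas <- vapply(shapes[ok], function(s) s$area, numeric(1))
    widths <- vapply(shapes[ok], function(s) s$width, numeric(1))
    bv <- biovolume(median(areas), median(widths), config$pixel_size_um)
    has_calib <- !is.null(config$calibration$slope) &&
      !is.null(config$calibration$intercept)
    if (has_calib) {
      calib <- structure(list(slope = config$calibration$slope,
                              intercept = config$calibration$intercept,
                              domain = c(0, Inf),
                              intensity_range = c(-Inf, Inf)),
                         class = "calibration_line")
      trace <- to_concentration(trace, calib, bv)
    }
    phases <- tryCatch(
      segment_phases(trace,
                     smoothing_window = config$kinetics$smoothing_window,
                     prominence_frac = config$kinetics$prominence_frac,
                     min_pre_peak = config$kinetics$min_pre_peak),
      error = function(e) NULL)
    if (is.null(phases)) { exclude(id, "no_phase_structure"); next }
    if (!phases$enough_pre_peak) exclude(id, "pre_F1_shorter_than_45min")
    fit <- tryCatch(
      fit_exponential_phase(trace, phases,
                            r_threshold = config$kinetics$r_threshold,
                            min_pre_peak = config$kinetics$min_pre_peak),
      error = function(e) NULL)
    if (is.null(fit)) { exclude(id, "exponential_fit_failed"); next }
    if (fit$fit_r <= config$kinetics$r_threshold) exclude(id, "fit_r_below_0.95")
    deltas <- phase_deltas(fit)
    fits[[length(fits) + 1]] <- data.frame(
      pHe = pHe, track_id = id, k = fit$k, F0 = fit$F0, F1 = fit$F1,
      F2 = ifelse(is.na(fit$F2), NA_real_, fit$F2),
      t_exp = fit$t_exp, t_dec = fit$t_dec, fit_r = fit$fit_r,
      accepted = fit$accepted, delta_exp = deltas$delta_exp,
      delta_dec = deltas$delta_dec, biovolume_um3 = bv,
      n_frames = nrow(trace))
  }
  list(fits = if (length(fits)) do.call(rbind, fits) else
         data.frame(pHe = numeric(0), track_id = integer(0), k = numeric(0),
                    F0 = numeric(0), F1 = numeric(0), F2 = numeric(0),
                    t_exp = numeric(0), t_dec = numeric(0), fit_r = numeric(0),
                    accepted = logical(0), delta_exp = numeric(0),
                    delta_dec = numeric(0), biovolume_um3 = numeric(0),
                    n_frames = integer(0)),
       exclusions = exclusions, tracks = tracks)
}

#' Run the time-lapse kinetics pipeline over a cohort
#'
#' Chains detection, tracking, level-line photometry, phase segmentation
#' and exponential fitting over one or more stacks, then fits the
#' exponential pH dependence of the accepted kinetic quantities. Inputs are
#' either provided stacks or a synthetic cohort specification.
#'
#' @param config a [default_run_config()]-style list. Supply either
#'   `config$inputs`, a list of entries `list(stack=, times=, pHe=)`, or
#'   `config$cohort`, a list with `ph_levels`, `n_cells`, and optional
#'   overrides of [timelapse_config()] fields plus `k_response =
#'   list(a, b)` setting the generating `k` at each pH.
#' @return List of class `timelapse_run`: `fits` (per-cell table),
#'   `responses` (named list of [fit_ph_dependence()] results for `k`,
#'   `delta_exp`, `delta_dec`, when >= 3 pH levels are present),
#'   `exclusions` (reason-coded log), `truth` (per-level ground truth for
#'   synthetic cohorts). Tables are written as CSV/JSON under
#'   `config$out_dir` when set.
#' @export
run_timelapse <- function(config) {
  stopifnot(is.list(config))
  inputs <- config$inputs
  truth <- NULL
  if (is.null(inputs) && !is.null(config$cohort)) {
    ch <- config$cohort
    ph <- ch$ph_levels
    inputs <- vector("list", length(ph))
    truth <- vector("list", length(ph))
    for (i in seq_along(ph)) {
      k_mean <- if (!is.null(ch$k_response)) {
        ch$k_response$a * exp(ch$k_response$b * ph[i])
      } else 0.0133
      tl_args <- ch$timelapse %||% list()
      tl_args$n_cells <- ch$n_cells %||% 8
      tl_args$k_mean <- k_mean
      tcfg <- do.call(timelapse_config, tl_args)
      gen <- generate_timelapse(tcfg, seed = config$seed * 1000L + i)
      inputs[[i]] <- list(stack = gen$stack, times = gen$truth$times,
                          pHe = ph[i])
      truth[[i]] <- gen$truth
    }
  }
  if (is.null(inputs)) stop("config must provide `inputs` or `cohort`")
  res <- lapply(inputs, function(inp) {
    process_stack(inp$stack, inp$times, config, pHe = inp$pHe %||% NA_real_)
  })
  fits <- do.call(rbind, lapply(res, `[[`, "fits"))
  exclusions <- do.call(rbind, lapply(seq_along(res), function(i) {
    ex <- res[[i]]$exclusions
    if (nrow(ex)) ex$stack <- i
    ex
  }))
  acc <- fits[fits$accepted, , drop = FALSE]
  responses <- list()
  if (length(unique(acc$pHe[is.finite(acc$pHe)])) >= 3) {
    dom <- config$ph_domain
    responses$k <- fit_ph_dependence(acc$pHe, acc$k, domain = dom)
    if (any(is.finite(acc$delta_exp) & acc$delta_exp > 0)) {
      responses$delta_exp <- tryCatch(
        fit_ph_dependence(acc$pHe, acc$delta_exp, domain = dom),
        error = function(e) NULL)
    }
    if (any(is.finite(acc$delta_dec) & acc$delta_dec > 0)) {
      responses$delta_dec <- tryCatch(
        fit_ph_dependence(acc$pHe, acc$delta_dec, domain = dom),
        error = function(e) NULL)
    }
  }
  out <- list(fits = fits, responses = responses, exclusions = exclusions,
              truth = truth, config = config)
  class(out) <- "timelapse_run"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(fits, file.path(config$out_dir, "kinetic_fits.csv"),
              row.names = FALSE)
    write.csv(exclusions, file.path(config$out_dir, "exclusions.csv"),
              row.names = FALSE)
    if (length(responses)) {
      jsonlite::write_json(
        lapply(responses, function(r) {
          if (is.null(r)) NULL else r[c("a", "b", "r2", "domain")]
        }),
        file.path(config$out_dir, "ph_responses.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (!is.null(inputs[[1]]$stack)) {
      overlay_tracks(inputs[[1]]$stack, res[[1]]$tracks,
                     file.path(config$out_dir, "tracks_overlay.png"))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Track overlay rendering
#'
#' Writes a PNG of the last frame with all track trajectories burnt in (red
#' points), a quick visual QC of the linking stage.
#'
#' @param stack `[h, w, t]` array.
#' @param tracks [link_tracks()] output.
#' @param path output PNG.
#' @export
overlay_tracks <- function(stack, tracks, path) {
  fr <- stack[, , dim(stack)[3]]
  fr <- (fr - min(fr)) / max(diff(range(fr)), 1e-9)
  h <- nrow(fr); w <- ncol(fr)
  rgb <- array(rep(fr, 3), dim = c(h, w, 3))
  for (tr in tracks) {
    xi <- round(tr$x) + 1; yi <- round(tr$y) + 1
    okp <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    rgb[cbind(yi[okp], xi[okp], 1)] <- 1
    rgb[cbind(yi[okp], xi[okp], 2)] <- 0
    rgb[cbind(yi[okp], xi[okp], 3)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Run the valve morphometry pipeline over a batch of images
#'
#' Binarization, circular pore detection, Voronoi spacing, finger analysis
#' and trait assembly for each image; one trait row per image. Images are
#' supplied directly or generated synthetically with known truth.
#'
#' @param config run configuration; supply either `config$images` (list of
#'   matrices, optionally with `annotations`) or `config$synthetic`, a list
#'   with `n`, `porosity` (length-2 range) and optional [valve_config()]
#'   overrides.
#' @return List of class `morphometry_run`: `traits` (data.frame, one row
#'   per image, Table-style schema plus `image`), `pores` (list of pore
#'   sets), `truth` (for synthetic batches). CSV written under
#'   `config$out_dir` when set.
#' @export
run_morphometry <- function(config) {
  stopifnot(is.list(config))
  mo <- config$morpho %||% default_run_config()$morpho
  images <- config$images
  truth <- NULL
  if (is.null(images) && !is.null(config$synthetic)) {
    sy <- config$synthetic
    n <- sy$n %||% 5
    por <- sy$porosity %||% c(0.05, 0.15)
    targets <- seq(por[1], por[2], length.out = n)
    vc_args <- sy$valve %||% list()
    images <- vector("list", n); truth <- vector("list", n)
    for (i in seq_len(n)) {
      args <- vc_args
      s <- args$spacing %||% 32
      args$spacing <- s
      # triangular-lattice fill fraction pi r^2 / (s^2 sqrt(3)/2) = target
      args$pore_radius <- sqrt(targets[i] * s^2 * sqrt(3) / 2 / pi)
      vcfg <- do.call(valve_config, args)
      gen <- generate_valve_image(vcfg, seed = (config$seed %||% 1) * 500L + i)
      images[[i]] <- gen$image
      truth[[i]] <- gen$truth
    }
  }
  if (is.null(images)) stop("config must provide `images` or `synthetic`")
  pores_list <- vector("list", length(images))
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    mask <- binarize(img, dark_pores = mo$dark_pores)
    pores <- detect_pores(mask, min_radius = mo$min_radius,
                          max_radius = mo$max_radius,
                          min_circularity = mo$min_circularity)
    pores_list[[i]] <- pores
    ann <- if (!is.null(config$annotations) &&
               length(config$annotations) >= i) config$annotations[[i]]
    tr <- valve_traits(pores, scale = mo$scale_nm_px, annotations = ann)
    tr$image <- i
    rows[[i]] <- tr
  }
  traits <- do.call(rbind, rows)
  out <- list(traits = traits, pores = pores_list, truth = truth,
              config = config)
  class(out) <- "morphometry_run"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(traits, file.path(config$out_dir, "valve_traits.csv"),
              row.names = FALSE)
  }
  out
}
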