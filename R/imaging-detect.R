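#' Detect fluorescent cells in a frame
#'
#' Segments bright connected regions above a robust background threshold and
#' returns their intensity-weighted centroids. Components whose area falls
#' outside `[min_area, max_area]` are discarded; unusually large components
#' (possible merges of touching cells) are flagged as ambiguous.
#'
#' @param frame numeric matrix, ideally denoised.
#' @param min_area,max_area component area bounds in pixels.
#' @param nsigma threshold is `median(frame) + nsigma * mad(frame)` unless
#'   `threshold` is given.
#' @param threshold absolute intensity threshold (overrides `nsigma`).
#' @param ambiguous_factor components larger than this multiple of the
#'   median retained area are flagged `ambiguous`; so are strongly elongated
#'   components (eccentricity > 0.8, e.g. two touching cells merged into one
#'   bilobed component).
#' @return data.frame with columns `x`, `y` (0-based centroid), `area`,
#'   `peak`, `ambiguous`. Zero rows when nothing is detected.
#' @export
detect_cells <- function(frame, min_area = 20, max_area = Inf, nsigma = 4,
                         threshold = NULL, ambiguous_factor = 1.7) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  bg <- median(frame)
  if (is.null(threshold)) threshold <- bg + nsigma * mad(frame)
  mask <- frame > threshold
  empty <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      peak = numeric(0), ambiguous = logical(0))
  if (!any(mask)) return(empty)
  labI <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(labI))
  mom <- EBImage::computeFeatures.moment(labI)
  nlab <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0) return(empty)
  wmat <- pmax(frame - bg, 0)
  res <- do.call(rbind, lapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    w <- wmat[idx]
    if (sum(w) <= 0) w <- rep(1, nrow(idx))
    data.frame(x = sum((idx[, 2] - 1) * w) / sum(w),
               y = sum((idx[, 1] - 1) * w) / sum(w),
               area = areas[l], peak = max(frame[idx]),
               eccentricity = mom[l, "m.eccentricity"])
  }))
  res$ambiguous <- res$area > ambiguous_factor * median(res$area) |
    res$eccentricity > 0.8
  rownames(res) <- NULL
  res
}

#' Local background level around a cell
#'
#' Median intensity over an annulus centered on the cell, excluding pixels
#' that belong to any detected cell. When too few annulus pixels survive
#' (e.g. the annulus is covered by a neighboring cell), falls back to the
#' frame-wide median and flags the fallback.
#'
#' @param frame numeric matrix.
#' @param center `c(x, y)` in 0-based pixel coordinates.
#' @param inner_radius,outer_radius annulus radii in pixels.
#' @param exclude_mask logical matrix marking pixels to ignore (detected
#'   cells), or `NULL`.
#' @param min_pixels minimum annulus sample size before falling back.
#' @return List with `value` (intensity per pixel), `n` (pixels used),
#'   `fallback` (logical).
#' @export
local_background <- function(frame, center, inner_radius, outer_radius,
                             exclude_mask = NULL, min_pixels = 10) {
  stopifnot(is.matrix(frame), length(center) == 2,
            outer_radius > inner_radius, inner_radius >= 0)
  h <- nrow(frame); w <- ncol(frame)
  x0 <- max(0, floor(center[1] - outer_radius))
  x1 <- min(w - 1, ceiling(center[1] + outer_radius))
  y0 <- max(0, floor(center[2] - outer_radius))
  y1 <- min(h - 1, ceiling(center[2] + outer_radius))
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - center[2])^2, (xs - center[1])^2, "+")
  sel <- d2 >= inner_radius^2 & d2 <= outer_radius^2
  if (!is.null(exclude_mask)) {
    sel <- sel & !exclude_mask[ys + 1, xs + 1, drop = FALSE]
  }
  vals <- frame[ys + 1, xs + 1, drop = FALSE][sel]
  if (length(vals) < min_pixels) {
    return(list(value = median(frame), n = length(vals), fallback = TRUE))
  }
  list(value = median(vals), n = length(vals), fallback = FALSE)
}
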