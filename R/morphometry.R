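#' Binarize a denoised valve image into a pore mask
#'
#' Otsu threshold on the image histogram followed by a morphological opening
#' with a 1-pixel-radius disc to remove speckle. Pores are assumed darker
#' than the silica background; set `dark_pores = FALSE` for inverted
#' polarity.
#'
#' @param img numeric matrix (grayscale, any range).
#' @param dark_pores logical polarity flag.
#' @param open_radius radius of the opening structuring element, px
#'   (0 disables).
#' @return Logical matrix, `TRUE` on the pore phase.
#' @export
binarize <- function(img, dark_pores = TRUE, open_radius = 1) {
  stopifnot(is.matrix(img), length(img) > 0)
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  norm <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(t(norm)), range = c(0, 1))
  mask <- if (dark_pores) norm < th else norm > th
  if (open_radius > 0) {
    brush <- EBImage::makeBrush(2 * open_radius + 1, shape = "diamond")
    mask <- t(EBImage::imageData(
      EBImage::opening(EBImage::Image(t(mask)), brush))) > 0.5
  }
  mask
}

#' Detect circular pores in a binary mask
#'
#' Labels connected components of the pore phase and keeps those whose
#' equivalent-circle radius `R = sqrt(A / pi)` lies within bounds and whose
#' circularity `4 pi A / P^2` reaches `min_circularity` (perimeter-based
#' circularity is clamped at 1). Components touching the image border are
#' excluded.
#'
#' @param mask logical matrix from [binarize()].
#' @param min_radius,max_radius radius bounds, px.
#' @param min_circularity circularity threshold (default 0.6).
#' @return An object of class `pore_set`: data.frame with columns `x`, `y`
#'   (0-based centroids), `radius`, `area`, `circularity`; attributes
#'   `image_dim` and `n_excluded`. May have zero rows.
#' @export
detect_pores <- function(mask, min_radius = 2, max_radius = Inf,
                         min_circularity = 0.6) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  empty <- structure(
    data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
               area = numeric(0), circularity = numeric(0)),
    image_dim = dim(mask), n_excluded = 0L,
    class = c("pore_set", "data.frame"))
  if (!any(mask)) return(empty)
  labI <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(labI))
  shp <- EBImage::computeFeatures.shape(labI)
  nlab <- nrow(shp)
  h <- nrow(mask); w <- ncol(mask)
  rows <- vector("list", nlab)
  n_excl <- 0L
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (any(idx[, 1] == 1 | idx[, 1] == h | idx[, 2] == 1 | idx[, 2] == w)) {
      n_excl <- n_excl + 1L
      next
    }
    A <- shp[l, "s.area"]; P <- shp[l, "s.perimeter"]
    r <- sqrt(A / pi)
    circ <- min(1, 4 * pi * A / max(P, 1)^2)
    if (r < min_radius || r > max_radius || circ < min_circularity) {
      n_excl <- n_excl + 1L
      next
    }
    rows[[l]] <- data.frame(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1,
                            radius = r, area = A, circularity = circ)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) { attr(empty, "n_excluded") <- n_excl; return(empty) }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, image_dim = dim(mask), n_excluded = n_excl,
            class = c("pore_set", "data.frame"))
}

# deldir tessellation of pore centers; interior = Voronoi tile not touching
# the image rectangle
pore_tessellation <- function(pores) {
  dims <- attr(pores, "image_dim")
  rw <- c(0, dims[2] - 1, 0, dims[1] - 1)
  xy <- cbind(pores$x, pores$y)
  ctr <- scale(xy, scale = FALSE)
  if (min(svd(ctr)$d) < 1e-8 * max(svd(ctr)$d, 1)) {
    stop("degenerate (collinear) pore centers: no triangulation")
  }
  dd <- deldir::deldir(pores$x, pores$y, rw = rw, suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  interior <- !vapply(tiles, function(tl) any(tl$bp), logical(1))
  list(deldir = dd, interior = interior)
}

#' Nearest-neighbor pore spacing from the Delaunay triangulation
#'
#' Builds the Voronoi diagram of the pore centers (via its Delaunay dual)
#' and measures `d1`, the center-to-center distance along Delaunay edges,
#' excluding edges incident to pores whose Voronoi cell touches the image
#' border (truncated cells bias the spacing).
#'
#' @param pores a [detect_pores()] result with >= 4 pores.
#' @return List with `d1` (numeric vector, px), `edges` (data.frame
#'   `ind1`, `ind2`, `length`, `interior`), `interior` (per-pore logical).
#' @export
pore_spacing <- function(pores) {
  stopifnot(inherits(pores, "pore_set"))
  if (nrow(pores) < 4) stop("need >= 4 pores for a tessellation")
  tess <- pore_tessellation(pores)
  seg <- tess$deldir$delsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  interior_edge <- tess$interior[seg$ind1] & tess$interior[seg$ind2]
  list(d1 = len[interior_edge],
       edges = data.frame(ind1 = seg$ind1, ind2 = seg$ind2, length = len,
                          interior = interior_edge),
       interior = tess$interior)
}

#' Finger (cribrum) structure: across-finger widths D and rib widths d2
#'
#' Groups pores into "fingers" (the elongated pore groups of the
#' semi-continuous cribra) by single-linkage clustering at a threshold of
#' `alpha` times the median nearest-neighbor spacing, fits a principal axis
#' per finger, and measures `D`, the across-finger extent of each finger's
#' pores (perpendicular to its own axis, pore rims included), and `d2`, the
#' rim-to-rim gap between adjacent fingers along the common normal
#' direction. With fewer than 2 fingers `d2` is `NA` and flagged.
#'
#' @param pores a [detect_pores()] result.
#' @param alpha clustering threshold in units of median `d1` (default 1.4).
#' @param min_finger_size smallest pore count accepted as a finger.
#' @return List with `D` (px, one per finger), `d2` (px, one per adjacent
#'   finger pair, or `NA`), `finger_id` (per pore), `d2_defined` (logical).
#' @export
finger_analysis <- function(pores, alpha = 1.4, min_finger_size = 3) {
  stopifnot(inherits(pores, "pore_set"))
  if (nrow(pores) < min_finger_size) stop("too few pores for finger analysis")
  # clustering scale: median nearest-neighbor distance (the Delaunay graph
  # contains every nearest-neighbor edge), robust to cross-rib edges;
  # collinear layouts (a single pore row) fall back to brute-force distances
  dmat <- as.matrix(dist(cbind(pores$x, pores$y)))
  diag(dmat) <- Inf
  d1_ref <- median(apply(dmat, 1, min))
  hc <- hclust(dist(cbind(pores$x, pores$y)), method = "single")
  cl <- cutree(hc, h = alpha * d1_ref)
  sizes <- table(cl)
  finger_labels <- as.integer(names(sizes)[sizes >= min_finger_size])
  if (length(finger_labels) == 0) stop("no finger-sized pore groups found")
  finger_id <- ifelse(cl %in% finger_labels, match(cl, finger_labels),
                      NA_integer_)

  axes <- lapply(finger_labels, function(fl) {
    sel <- which(cl == fl)
    pc <- prcomp(cbind(pores$x[sel], pores$y[sel]))
    list(sel = sel, center = pc$center, axis = pc$rotation[, 1],
         normal = pc$rotation[, 2])
  })
  # across-finger extent D, rims included, each finger on its own normal
  D <- vapply(axes, function(a) {
    proj <- (pores$x[a$sel] - a$center[1]) * a$normal[1] +
      (pores$y[a$sel] - a$center[2]) * a$normal[2]
    (max(proj + pores$radius[a$sel]) - min(proj - pores$radius[a$sel]))
  }, numeric(1))

  d2 <- NA_real_; d2_defined <- length(axes) >= 2
  if (d2_defined) {
    # common normal: average the per-finger normals up to sign
    ref <- axes[[1]]$normal
    nrm <- Reduce(`+`, lapply(axes, function(a) {
      if (sum(a$normal * ref) < 0) -a$normal else a$normal
    }))
    nrm <- nrm / sqrt(sum(nrm^2))
    proj_all <- pores$x * nrm[1] + pores$y * nrm[2]
    centers <- vapply(axes, function(a) mean(proj_all[a$sel]), numeric(1))
    ord <- order(centers)
    d2 <- vapply(seq_len(length(ord) - 1), function(i) {
      a <- axes[[ord[i]]]; b <- axes[[ord[i + 1]]]
      hi <- max(proj_all[a$sel] + pores$radius[a$sel])
      lo <- min(proj_all[b$sel] - pores$radius[b$sel])
      lo - hi
    }, numeric(1))
  }
  list(D = D, d2 = d2, finger_id = finger_id, d2_defined = d2_defined)
}

#' Morphometric traits of a valve image
#'
#' Assembles the nine-trait schema used to characterize a valve: the
#' nanometric traits measured from the detected pores (mean pore radius `R`,
#' mean adjacent-pore distance `d1`, mean cribrum width `D`, mean rib width
#' `d2`, porosity `r`) and the macro traits supplied as annotations (valve
#' width `W`, fultoportula count `N` and minimum spacing `cp`, adjacent
#' rimoportula spacing `rp`) -- automatic detection of the macro features is
#' out of scope, so annotations come from manual marking or ground truth.
#'
#' Porosity is the summed disk area of pores whose centers fall in the
#' analyzed region, divided by the region area; the region defaults to the
#' image inset by one median `d1` on every side, which excludes
#' border-truncated Voronoi cells from the statistics.
#'
#' @param pores a [detect_pores()] result.
#' @param scale nm per pixel (> 0).
#' @param annotations optional list with `valve_width_px`, `fultoportulae`
#'   (matrix of x, y), `rimoportulae` (matrix of x, y).
#' @param region analysis region `c(x0, x1, y0, y1)` in px; `NULL` for the
#'   default inset.
#' @param fingers optional precomputed [finger_analysis()] result; computed
#'   when `NULL` (set `FALSE` to skip).
#' @return One-row data.frame of class `morpho_traits`: `valve_width_um`,
#'   `n_fultoportulae`, `cp_um`, `rp_um`, `R_nm`, `d1_nm`, `D_nm`, `d2_nm`,
#'   `porosity`.
#' @export
valve_traits <- function(pores, scale, annotations = NULL, region = NULL,
                         fingers = NULL) {
  stopifnot(inherits(pores, "pore_set"), scale > 0)
  na_row <- data.frame(valve_width_um = NA_real_, n_fultoportulae = NA_integer_,
                       cp_um = NA_real_, rp_um = NA_real_, R_nm = NA_real_,
                       d1_nm = NA_real_, D_nm = NA_real_, d2_nm = NA_real_,
                       porosity = NA_real_)
  if (nrow(pores) < 4) {
    class(na_row) <- c("morpho_traits", "data.frame")
    return(na_row)
  }
  sp <- pore_spacing(pores)
  d1_px <- if (length(sp$d1) > 0) sp$d1 else sp$edges$length
  d1_med <- median(d1_px)
  dims <- attr(pores, "image_dim")
  if (is.null(region)) {
    region <- c(d1_med, dims[2] - 1 - d1_med, d1_med, dims[1] - 1 - d1_med)
  }
  inr <- pores$x >= region[1] & pores$x <= region[2] &
    pores$y >= region[3] & pores$y <= region[4]
  area_px <- (region[2] - region[1]) * (region[4] - region[3])
  porosity <- sum(pi * pores$radius[inr]^2) / area_px

  if (is.null(fingers)) {
    fingers <- tryCatch(finger_analysis(pores), error = function(e) NULL)
  } else if (identical(fingers, FALSE)) fingers <- NULL

  out <- na_row
  out$R_nm <- mean(pores$radius) * scale
  out$d1_nm <- mean(d1_px) * scale
  out$porosity <- porosity
  if (!is.null(fingers)) {
    out$D_nm <- mean(fingers$D) * scale
    out$d2_nm <- if (fingers$d2_defined) mean(fingers$d2) * scale else NA_real_
  }
  if (!is.null(annotations)) {
    um <- scale / 1000
    if (!is.null(annotations$valve_width_px)) {
      out$valve_width_um <- annotations$valve_width_px * um
    }
    fp <- annotations$fultoportulae
    if (!is.null(fp) && nrow(fp) >= 1) {
      out$n_fultoportulae <- nrow(fp)
      if (nrow(fp) >= 2) out$cp_um <- min(dist(fp)) * um
    }
    rp <- annotations$rimoportulae
    if (!is.null(rp) && nrow(rp) >= 2) {
      ctr <- colMeans(rp)
      ord <- order(atan2(rp[, 2] - ctr[2], rp[, 1] - ctr[1]))
      rps <- rp[ord, , drop = FALSE]
      nbr <- rbind(rps[-1, , drop = FALSE], rps[1, , drop = FALSE])
      out$rp_um <- mean(sqrt(rowSums((rps - nbr)^2))) * um
    }
  }
  class(out) <- c("morpho_traits", "data.frame")
  out
}
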