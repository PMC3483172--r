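#' Fit an exponential growth rate from a cell-density series
#'
#' `mu` is the least-squares slope of `ln(density)` on time over the
#' exponential window; the doubling time is `ln(2) / mu` (infinite and
#' flagged for non-growing cultures).
#'
#' @param times hours.
#' @param densities cells per mL (> 0).
#' @return List of class `growth_fit`: `mu` (per hour), `doubling_time`
#'   (hours), `r2`, `flagged` (TRUE when `mu <= 0`).
#' @export
fit_growth_rate <- function(times, densities) {
  stopifnot(length(times) == length(densities), all(densities > 0))
  if (length(times) < 3) stop("need >= 3 points in the exponential window")
  if (any(diff(times) <= 0)) stop("times must be increasing")
  ld <- log(densities)
  fit <- lm(ld ~ times)
  mu <- unname(coef(fit)[2])
  if (abs(mu) < 1e-10) mu <- 0  # numerically flat series
  tss <- sum((ld - mean(ld))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else NA_real_
  structure(list(mu = mu,
                 doubling_time = if (mu > 0) log(2) / mu else Inf,
                 r2 = r2,
                 flagged = mu <= 0),
            class = "growth_fit")
}

#' Element quota per cell from an extract measurement
#'
#' Unit bookkeeping from a dissolved-extract concentration to a per-cell
#' quota: `quota [pmol/cell] = conc [uM] * volume [mL] * 1000 / cells`
#' (1 uM in 1 mL is 1 nmol = 1000 pmol).
#'
#' @param concentration extract concentration, uM.
#' @param extract_volume extract volume, mL.
#' @param cell_count number of cells in the extract (> 0).
#' @return Quota in pmol per cell.
#' @export
quota_per_cell <- function(concentration, extract_volume, cell_count) {
  stopifnot(all(cell_count > 0), all(concentration >= 0),
            all(extract_volume >= 0))
  concentration * extract_volume * 1000 / cell_count
}

#' Silicon incorporation rate
#'
#' Biogenic silica quota per cell divided by the specific growth rate: the
#' silicon committed to the frustule per unit of growth.
#'
#' @param BSi_quota pmol per cell.
#' @param mu specific growth rate, per hour (> 0; non-positive rates give
#'   `Inf` with a warning).
#' @return pmol per cell per unit growth rate.
#' @export
incorporation_rate <- function(BSi_quota, mu) {
  stopifnot(all(BSi_quota >= 0))
  out <- BSi_quota / mu
  if (any(mu <= 0)) {
    warning("non-positive growth rate: incorporation rate diverges")
    out[mu <= 0] <- Inf
  }
  out
}

#' Fit the ratiometric pH calibration of a BCECF-type indicator
#'
#' Fits a monotone map from the background-corrected dual-excitation
#' fluorescence ratio to pH: a four-parameter logistic in pH
#' `ratio = r_min + (r_max - r_min) / (1 + 10^(s * (pH50 - pH)))`, with an
#' ordinary linear fit as fallback when the sigmoid is not identifiable
#' (e.g. when the data are linear over the domain). The returned object
#' carries both the forward map and its analytic inverse.
#'
#' @param pH calibration pH levels (>= 4 distinct levels spanning >= 1
#'   unit).
#' @param ratios measured ratios, same length.
#' @param tol fraction of the ratio range by which level means may
#'   decrease before the calibration is declared non-monotone.
#' @return An object of class `ph_calibration`: `model` ("logistic" or
#'   "linear"), `pars`, `domain` (pH range), `ratio_range`.
#' @export
fit_bcecf_calibration <- function(pH, ratios, tol = 0.1) {
  stopifnot(length(pH) == length(ratios))
  lev <- sort(unique(pH))
  if (length(lev) < 4) stop("need >= 4 pH levels")
  if (diff(range(lev)) < 1) stop("pH levels must span >= 1 unit")
  means <- vapply(lev, function(p) mean(ratios[pH == p]), numeric(1))
  rng <- diff(range(means))
  if (any(diff(means) < -tol * rng)) {
    stop("level means are non-monotone beyond noise tolerance")
  }
  lin <- lm(ratios ~ pH)
  rss_lin <- sum(residuals(lin)^2)
  logis <- tryCatch({
    start <- list(r_min = min(means), r_max = max(means),
                  pH50 = mean(range(lev)), s = 2 / diff(range(lev)))
    minpack.lm::nlsLM(
      ratios ~ r_min + (r_max - r_min) / (1 + 10^(s * (pH50 - pH))),
      start = start,
      lower = c(-Inf, -Inf, min(lev) - 5, 1e-3),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  }, error = function(e) NULL)
  use_logistic <- FALSE
  if (!is.null(logis)) {
    rss_log <- sum(residuals(logis)^2)
    use_logistic <- rss_log < 0.95 * rss_lin
  }
  if (use_logistic) {
    p <- as.list(coef(logis))
    obj <- list(model = "logistic", pars = p, domain = range(lev))
  } else {
    cf <- coef(lin)
    if (cf[2] <= 0) stop("calibration slope must be positive")
    obj <- list(model = "linear",
                pars = list(intercept = unname(cf[1]), slope = unname(cf[2])),
                domain = range(lev))
  }
  class(obj) <- "ph_calibration"
  obj$ratio_range <- range(predict_ratio(obj, obj$domain))
  obj
}

#' Forward calibration map: pH to expected ratio
#'
#' @param calib a [fit_bcecf_calibration()] result.
#' @param pH pH values.
#' @return Expected ratios.
#' @export
predict_ratio <- function(calib, pH) {
  stopifnot(inherits(calib, "ph_calibration"))
  if (calib$model == "logistic") {
    with(calib$pars, r_min + (r_max - r_min) / (1 + 10^(s * (pH50 - pH))))
  } else {
    calib$pars$intercept + calib$pars$slope * pH
  }
}

#' Invert the ratiometric calibration: ratio to intracellular pH
#'
#' Ratios outside the achievable calibration range are clamped to the
#' domain ends and flagged via the `"clamped"` attribute.
#'
#' @param ratio measured background-corrected ratios.
#' @param calib a [fit_bcecf_calibration()] result.
#' @return pH values with logical attribute `"clamped"`.
#' @export
ratio_to_pH <- function(ratio, calib) {
  stopifnot(inherits(calib, "ph_calibration"))
  lo <- min(calib$ratio_range); hi <- max(calib$ratio_range)
  clamped <- ratio < lo | ratio > hi
  r <- pmin(pmax(ratio, lo), hi)
  if (calib$model == "logistic") {
    p <- calib$pars
    frac <- (r - p$r_min) / (p$r_max - p$r_min)
    frac <- pmin(pmax(frac, 1e-12), 1 - 1e-12)
    out <- p$pH50 - log10(1 / frac - 1) / p$s
  } else {
    out <- (r - calib$pars$intercept) / calib$pars$slope
  }
  out <- pmin(pmax(out, calib$domain[1]), calib$domain[2])
  attr(out, "clamped") <- clamped
  out
}

#' Proton concentration fold-change for a pH difference
#'
#' `10^(delta_pH)`: a pH drop of one unit is a ten-fold proton increase.
#'
#' @param delta_pH pH difference (finite).
#' @return Dimensionless fold change.
#' @export
proton_fold <- function(delta_pH) {
  stopifnot(all(is.finite(delta_pH)))
  10^delta_pH
}

#' Per-cell dual-channel fluorescence ratios from an image pair
#'
#' Detects cells in the (brighter) second channel, then computes for each
#' cell the disk-mean intensity minus the image background median in both
#' channels and returns their ratio, the quantity the ratiometric pH
#' calibration maps to intracellular pH.
#'
#' @param ch1,ch2 channel matrices (same size).
#' @param radius integration disk radius, px.
#' @param min_area passed to [detect_cells()].
#' @return data.frame `x`, `y`, `ratio`; zero rows (with a warning) when
#'   no cells are found.
#' @export
cell_ratios <- function(ch1, ch2, radius = 5, min_area = 20) {
  stopifnot(all(dim(ch1) == dim(ch2)))
  det <- detect_cells(ch2, min_area = min_area)
  if (nrow(det) == 0) {
    warning("no cells detected: ratio undefined")
    return(data.frame(x = numeric(0), y = numeric(0), ratio = numeric(0)))
  }
  bg1 <- median(ch1); bg2 <- median(ch2)
  xs <- 0:(ncol(ch1) - 1); ys <- 0:(nrow(ch1) - 1)
  ratio <- vapply(seq_len(nrow(det)), function(i) {
    x_idx <- which(abs(xs - det$x[i]) <= radius)
    y_idx <- which(abs(ys - det$y[i]) <= radius)
    dmat <- outer((ys[y_idx] - det$y[i])^2, (xs[x_idx] - det$x[i])^2, "+")
    disk <- dmat <= radius^2
    m1 <- mean(ch1[y_idx, x_idx][disk]) - bg1
    m2 <- mean(ch2[y_idx, x_idx][disk]) - bg2
    m1 / m2
  }, numeric(1))
  data.frame(x = det$x, y = det$y, ratio = ratio)
}
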