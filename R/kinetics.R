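#' Fit the linear dye intensity-vs-concentration calibration
#'
#' Ordinary least-squares line through a dilution series of the reporter
#' dye, used to convert background-corrected intensities to concentrations.
#'
#' @param concentrations dye concentrations, uM.
#' @param intensities measured intensities (same length).
#' @return An object of class `calibration_line`: `slope` (intensity per
#'   uM), `intercept`, `domain` (concentration range), `intensity_range`
#'   (fitted-value range), `residuals`, `r2`.
#' @export
fit_intensity_calibration <- function(concentrations, intensities) {
  stopifnot(length(concentrations) == length(intensities))
  if (length(unique(concentrations)) < 3) {
    stop("need at least 3 distinct concentrations")
  }
  if (sd(concentrations) == 0) stop("zero variance in concentrations")
  fit <- lm(intensities ~ concentrations)
  tss <- sum((intensities - mean(intensities))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         domain = range(concentrations),
         intensity_range = range(fitted(fit)),
         residuals = unname(residuals(fit)),
         r2 = if (tss > 0) 1 - sum(residuals(fit)^2) / tss else NA_real_),
    class = "calibration_line")
}

#' Convert a fluorescence trace to dye concentration per biovolume
#'
#' `concentration = ((signal - intercept) / slope) / biovolume`, clipped at
#' zero. Signals outside the calibration's fitted intensity range are still
#' converted but flagged as extrapolated.
#'
#' @param trace a `fluorescence_trace` data.frame (column `signal`).
#' @param calib a [fit_intensity_calibration()] result.
#' @param biovolume cell biovolume in um^3 (> 0); see [biovolume()].
#' @return The trace with added columns `concentration` (uM per um^3 of
#'   cell) and `extrapolated`.
#' @export
to_concentration <- function(trace, calib, biovolume) {
  stopifnot(inherits(calib, "calibration_line"), biovolume > 0)
  conc <- ((trace$signal - calib$intercept) / calib$slope) / biovolume
  trace$concentration <- pmax(conc, 0)
  trace$extrapolated <- trace$signal < calib$intensity_range[1] |
    trace$signal > calib$intensity_range[2]
  trace
}

#' Cell biovolume from level-line area and width
#'
#' Approximates the volume of a centric cell lying on its girdle by
#' `V = A_L * W_L`: the in-plane area times the in-plane width, the latter
#' standing in for the cell's depth along the optical axis.
#'
#' @param area A_L in px^2.
#' @param width W_L in px.
#' @param pixel_size um per pixel.
#' @return Biovolume in um^3.
#' @export
biovolume <- function(area, width, pixel_size = 1) {
  stopifnot(area > 0, width > 0, pixel_size > 0)
  area * pixel_size^2 * width * pixel_size
}

#' Segment the two initial phases of a valve-formation trace
#'
#' Locates the end of the exponential accumulation phase (the first
#' prominent local maximum, F1) and of the decay phase (the subsequent
#' minimum before any re-increase, F2) on a median-smoothed copy of the
#' signal. Returns `i_min = NA` when the series does not decay after F1.
#' Also reports whether the trace carries at least `min_pre_peak` minutes of
#' data before F1, the inclusion rule applied to cells admitted to the
#' kinetic fit.
#'
#' @param trace `fluorescence_trace` data.frame (columns `time`, `signal`;
#'   `concentration` is used instead when present).
#' @param smoothing_window centered running-median window (odd, default 3).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   smoothed-trace range.
#' @param min_pre_peak minutes of data required before F1 (default 45).
#' @param refine logical; refine the coarse peak/minimum indices by a
#'   continuous two-segment (hinge) least-squares fit of log-signal around
#'   the candidate breakpoint. Median smoothing biases a corner peak toward
#'   its gentler side; the changepoint fit removes that bias.
#' @return List with `i_peak`, `i_min` (indices into the trace, `i_min` may
#'   be `NA`), `t_exp`, `t_dec` (minutes, `t_dec` may be `NA`),
#'   `enough_pre_peak` (logical), `smoothed`.
#' @export
segment_phases <- function(trace, smoothing_window = 3,
                           prominence_frac = 0.1, min_pre_peak = 45,
                           refine = TRUE) {
  y <- if (!is.null(trace$concentration)) trace$concentration else trace$signal
  t <- trace$time
  n <- length(y)
  if (n < 5) stop("trace too short to segment (need >= 5 samples)")
  if (n < smoothing_window) stop("trace shorter than the smoothing window")
  s <- as.numeric(runmed(y, smoothing_window))
  rng <- diff(range(s))
  if (rng <= 0) stop("flat trace: no phases to segment")

  # first local maximum with sufficient prominence
  i_peak <- NA_integer_
  for (i in 2:(n - 1)) {
    if (s[i] >= s[i - 1] && s[i] >= s[i + 1]) {
      left_min <- min(s[1:i])
      # right minimum until the series first exceeds s[i] again (or the end)
      above <- which(s[(i + 1):n] > s[i])
      j_end <- if (length(above)) i + above[1] - 1 else n
      right_min <- min(s[(i + 1):j_end])
      prominence <- s[i] - max(left_min, right_min)
      if (prominence >= prominence_frac * rng) { i_peak <- i; break }
    }
  }
  if (is.na(i_peak) && which.max(s) == n) i_peak <- n  # monotone rise
  if (is.na(i_peak)) stop("no prominent maximum found")

  # subsequent minimum before any re-increase: the post-peak series of a
  # decaying cell dips once (decay, then the sibling-valve signal rises);
  # the argmin of the smoothed series locates the dip robustly
  i_min <- NA_integer_
  if (i_peak < n) {
    j <- i_peak + which.min(s[(i_peak + 1):n])
    # accept as a decay minimum only if the drop is non-trivial
    if (s[i_peak] - s[j] > 0.02 * rng) i_min <- j
  }
  if (refine && all(y > 0)) {
    ly <- log(y)
    i_peak <- refine_breakpoint(t, ly, i_peak, w_left = 8, w_right = 4)
    if (!is.na(i_min)) {
      i_min <- refine_breakpoint(t, ly, i_min, w_left = 3, w_right = 10)
      if (i_min <= i_peak) i_min <- NA_integer_
    }
  }
  list(i_peak = i_peak, i_min = i_min,
       t_exp = t[i_peak] - t[1],
       t_dec = if (!is.na(i_min)) t[i_min] - t[i_peak] else NA_real_,
       enough_pre_peak = (t[i_peak] - t[1]) >= min_pre_peak,
       smoothed = s)
}

# Refine a phase-boundary index by a continuous two-segment least-squares
# fit: over an asymmetric window around the coarse index, log-signal is
# modeled as a line plus a slope change (hinge) at the candidate breakpoint,
# and the candidate minimizing the residual sum of squares wins. Windows are
# asymmetric because the accumulation phase is exactly log-linear while the
# decay side is only locally so.
refine_breakpoint <- function(t, ly, i0, w_left, w_right, cand_win = 4) {
  n <- length(ly)
  lo <- max(1, i0 - w_left); hi <- min(n, i0 + w_right)
  cand <- (lo + 1):(hi - 1)
  cand <- cand[abs(cand - i0) <= cand_win]
  if (length(cand) < 1 || hi - lo < 4) return(i0)
  idx <- lo:hi
  sse <- vapply(cand, function(j) {
    X <- cbind(1, t[idx], pmax(t[idx] - t[j], 0))
    sum(stats::lm.fit(X, ly[idx])$residuals^2)
  }, numeric(1))
  cand[which.min(sse)]
}

#' Fit the exponential accumulation phase of a trace
#'
#' Linear regression of `ln(signal)` on time over the accumulation window:
#' `k` is the slope, `F0` the back-transformed intercept (value at time 0),
#' and `fit_r` the absolute Pearson correlation of log-signal with time.
#' The fit is `accepted` only when `fit_r > r_threshold` (default 0.95) and
#' the trace carries at least 45 min of data before F1.
#'
#' @param trace `fluorescence_trace` data.frame.
#' @param phases a [segment_phases()] result for the same trace; computed
#'   internally when `NULL`.
#' @param r_threshold acceptance threshold on `fit_r`.
#' @param min_pre_peak minutes of pre-F1 data required for acceptance.
#' @return An object of class `kinetic_fit`: `k` (per minute), `F0`, `F1`,
#'   `F2` (`NA` without decay), `t_exp`, `t_dec`, `fit_r`, `accepted`,
#'   `n_points`.
#' @export
fit_exponential_phase <- function(trace, phases = NULL, r_threshold = 0.95,
                                  min_pre_peak = 45) {
  y <- if (!is.null(trace$concentration)) trace$concentration else trace$signal
  t <- trace$time
  if (is.null(phases)) {
    phases <- segment_phases(trace, min_pre_peak = min_pre_peak)
  }
  idx <- seq_len(phases$i_peak)
  if (length(idx) < 4) stop("need >= 4 points in the exponential window")
  if (any(y[idx] <= 0)) {
    stop("non-positive values in the exponential window; ",
         "apply background correction or an offset before fitting")
  }
  ly <- log(y[idx]); tt <- t[idx]
  fit <- lm(ly ~ tt)
  r <- abs(cor(ly, tt))
  s <- phases$smoothed
  f1 <- s[phases$i_peak]
  f2 <- if (!is.na(phases$i_min)) s[phases$i_min] else NA_real_
  structure(
    list(k = unname(coef(fit)[2]), F0 = exp(unname(coef(fit)[1])),
         F1 = f1, F2 = f2, t_exp = phases$t_exp, t_dec = phases$t_dec,
         fit_r = r,
         accepted = isTRUE(r > r_threshold) && phases$enough_pre_peak,
         n_points = length(idx)),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: k = %.4g /min, F0 = %.4g, F1 = %.4g, F2 = %s\n",
              x$k, x$F0, x$F1, ifelse(is.na(x$F2), "NA", signif(x$F2, 4))))
  cat(sprintf("  t_exp = %.4g min, t_dec = %s min, fit_r = %.4f, %s\n",
              x$t_exp, ifelse(is.na(x$t_dec), "NA", signif(x$t_dec, 4)),
              x$fit_r, if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Concentration changes over the two phases
#'
#' `delta_exp = F1 - F0` (accumulated over the exponential phase) and
#' `delta_dec = F1 - F2` (released over the decay phase; `NA` and flagged
#' when the cell has no decay phase).
#'
#' @param fit a [fit_exponential_phase()] result.
#' @return List with `delta_exp`, `delta_dec`, `has_decay`.
#' @export
phase_deltas <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  list(delta_exp = max(fit$F1 - fit$F0, 0),
       delta_dec = if (!is.na(fit$F2)) max(fit$F1 - fit$F2, 0) else NA_real_,
       has_decay = !is.na(fit$F2))
}

#' Fit the exponential pH dependence of a kinetic quantity
#'
#' Least-squares fit of `y = a * exp(b * pH)` by log-linear regression on
#' the per-level means, restricted to the stated pH domain (levels outside
#' it, such as the most basic treatment, are excluded from the fit).
#'
#' @param ph vector of external pH values (one per observation).
#' @param values positive kinetic quantity (e.g. `k`, or a phase delta).
#' @param domain pH fitting domain, default `c(6.4, 8.2)`.
#' @return An object of class `ph_response_fit`: `a`, `b` (per pH unit),
#'   `r2` (on level means), `domain`, `levels` (data.frame pH, mean, n).
#' @export
fit_ph_dependence <- function(ph, values, domain = c(6.4, 8.2)) {
  stopifnot(length(ph) == length(values))
  keep <- ph >= domain[1] & ph <= domain[2] & is.finite(values) & values > 0
  ph <- ph[keep]; values <- values[keep]
  lev <- sort(unique(ph))
  if (length(lev) < 3) stop("need >= 3 pH levels inside the domain")
  means <- vapply(lev, function(p) mean(values[ph == p]), numeric(1))
  ns <- vapply(lev, function(p) sum(ph == p), numeric(1))
  lmn <- log(means)
  fit <- lm(lmn ~ lev)
  tss <- sum((lmn - mean(lmn))^2)
  structure(
    list(a = exp(unname(coef(fit)[1])), b = unname(coef(fit)[2]),
         r2 = if (tss > 0) 1 - sum(residuals(fit)^2) / tss else NA_real_,
         domain = domain,
         levels = data.frame(pH = lev, mean = means, n = ns)),
    class = "ph_response_fit")
}

#' Fold change of a fitted pH response across a pH span
#'
#' For `y = a e^{b pH}`, the ratio between the two ends of the span is
#' `exp(b * delta_pH)`.
#'
#' @param fit a [fit_ph_dependence()] result.
#' @param delta_pH pH span (defaults to the width of the fit domain).
#' @return Dimensionless fold change.
#' @export
response_fold_change <- function(fit, delta_pH = NULL) {
  stopifnot(inherits(fit, "ph_response_fit"))
  if (is.null(delta_pH)) delta_pH <- diff(fit$domain)
  exp(fit$b * delta_pH)
}
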