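#' Weak-base enrichment of an acidic compartment
#'
#' Equilibrium enrichment of total dye inside an acidic compartment relative
#' to the outside medium, for a monoprotic weak base whose neutral form
#' diffuses freely across the membrane while the protonated form is trapped
#' (ion trapping, the mechanism by which lysosomotropic reporter dyes
#' accumulate in the silica deposition vesicle):
#' \deqn{E = \frac{1 + 10^{pKa - pH_{sdv}}}{1 + 10^{pKa - pH_{out}}}}
#'
#' @param pH_sdv compartment (SDV) pH.
#' @param pH_out outside pH (medium or cytosol).
#' @param pKa dye protonation constant.
#' @return Dimensionless enrichment factor (vectorized).
#' @export
bound_enrichment <- function(pH_sdv, pH_out, pKa = 7.5) {
  stopifnot(all(is.finite(pH_sdv)), all(is.finite(pH_out)), is.finite(pKa))
  (1 + 10^(pKa - pH_sdv)) / (1 + 10^(pKa - pH_out))
}

#' Parameters of the three-fraction SDV dye model
#'
#' The model partitions the reporter dye inside the silica deposition
#' vesicle into three fractions whose sum is the observable total:
#' `F_free`, the neutral form at diffusion equilibrium with the outside;
#' `F_bound`, the protonated form accumulated by ion trapping as a function
#' of SDV pH; and `F_fixed`, dye irreversibly entrapped in the newly formed
#' silica (no dissolution). Free and bound fractions are assumed at
#' instantaneous weak-base equilibrium with the external concentration; the
#' fixed amount grows as `d(F_fixed * V)/dt = kappa * F_bound * V`.
#'
#' `pH_sdv` and `V` may be single numbers (constant trajectories), functions
#' of time (minutes), or 2-column matrices / data.frames of (time, value)
#' knots interpolated piecewise-linearly.
#'
#' @param pH_sdv SDV pH trajectory.
#' @param V SDV volume trajectory, um^3 (> 0).
#' @param kappa silica fixation rate, per minute (>= 0).
#' @param F_ext external free-dye total concentration, uM.
#' @param pH_out external/cytosolic pH seen by the dye reservoir.
#' @param pKa dye protonation constant.
#' @param cytosol_fraction fraction of cell dye signal outside the SDV,
#'   in `[0, 1)`; the analysis assumes it negligible (0).
#' @return An object of class `sdv_params`.
#' @export
sdv_params <- function(pH_sdv = 5, V = 1, kappa = 0.02, F_ext = 1,
                       pH_out = 7.35, pKa = 7.5, cytosol_fraction = 0) {
  as_traj <- function(x, what) {
    if (is.function(x)) return(x)
    if (is.numeric(x) && length(x) == 1) return(function(t) rep(x, length(t)))
    x <- as.matrix(x)
    if (ncol(x) != 2) stop("`", what, "` must be scalar, function, or (time, value) knots")
    approxfun(x[, 1], x[, 2], rule = 2)
  }
  stopifnot(kappa >= 0, F_ext >= 0, cytosol_fraction >= 0, cytosol_fraction < 1)
  structure(list(pH_sdv = as_traj(pH_sdv, "pH_sdv"), V = as_traj(V, "V"),
                 kappa = kappa, F_ext = F_ext, pH_out = pH_out, pKa = pKa,
                 cytosol_fraction = cytosol_fraction),
            class = "sdv_params")
}

#' Exponential and logistic SDV volume trajectories
#'
#' Convenience constructors for the "non-linear kinetics" of SDV expansion:
#' exponential growth `V0 * exp(rate * t)` or logistic growth toward `Vmax`.
#'
#' @param V0 initial volume, um^3.
#' @param rate growth rate, per minute.
#' @param Vmax logistic carrying capacity, um^3.
#' @return A function of time (minutes).
#' @export
sdv_volume_exponential <- function(V0 = 0.1, rate = 0.02) {
  stopifnot(V0 > 0)
  function(t) V0 * exp(rate * t)
}

#' @rdname sdv_volume_exponential
#' @export
sdv_volume_logistic <- function(V0 = 0.1, rate = 0.05, Vmax = 10) {
  stopifnot(V0 > 0, Vmax > V0)
  function(t) Vmax / (1 + (Vmax / V0 - 1) * exp(-rate * t))
}

#' Forward-simulate the three-fraction SDV dye model
#'
#' Integrates the fixed amount `A(t) = F_fixed(t) * V(t)` with a
#' deterministic fixed-step midpoint scheme,
#' `dA/dt = kappa * F_bound(t) * V(t)`, with the free and bound fractions
#' at instantaneous weak-base equilibrium (see [bound_enrichment()]):
#' `F_free = F_ext / (1 + 10^(pKa - pH_out))` and
#' `F_bound = F_free * 10^(pKa - pH_sdv(t))`.
#'
#' @param params an [sdv_params()] object.
#' @param times output times in minutes, strictly increasing from 0.
#' @param dt integration step, minutes; must divide the output grid
#'   reasonably finely (default: 1/20 of the smallest output interval).
#' @return An `sdv_series` data.frame: `time`, `F_free`, `F_bound`,
#'   `F_fixed`, `F_total` (all uM per SDV volume), `V`.
#' @export
forward_simulate <- function(params, times, dt = NULL) {
  stopifnot(inherits(params, "sdv_params"), length(times) >= 2)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing from 0")
  }
  if (is.null(dt)) dt <- min(diff(times)) / 20
  if (params$kappa * dt > 0.5) {
    stop("integration step too large for stability (kappa * dt > 0.5); ",
         "use a smaller `dt`")
  }
  f_free <- params$F_ext / (1 + 10^(params$pKa - params$pH_out))
  bound_at <- function(t) f_free * 10^(params$pKa - params$pH_sdv(t))
  t_end <- times[length(times)]
  grid <- seq(0, t_end, by = dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  A <- numeric(length(grid))  # fixed amount, concentration x volume
  for (i in seq_along(grid)[-1]) {
    h <- grid[i] - grid[i - 1]
    tm <- grid[i - 1] + h / 2
    A[i] <- A[i - 1] + h * params$kappa * bound_at(tm) * params$V(tm)
  }
  A_out <- approxfun(grid, A)(times)
  V_out <- params$V(times)
  f_bound <- bound_at(times)
  f_fixed <- A_out / V_out
  out <- data.frame(time = times, F_free = rep(f_free, length(times)),
                    F_bound = f_bound, F_fixed = f_fixed,
                    F_total = f_free + f_bound + f_fixed, V = V_out)
  class(out) <- c("sdv_series", "data.frame")
  out
}

#' Predicted dye fold-change for a shift in SDV pH
#'
#' In the protonation-dominated regime (SDV pH well below the dye pKa) the
#' accumulated dye concentration scales as `10^(-pH_sdv)`, so a pH shift of
#' `delta_pH` changes it `10^delta_pH`-fold.
#'
#' @param delta_pH pH shift (|delta_pH| < 5).
#' @return Dimensionless fold change.
#' @export
fold_change_from_delta_pH <- function(delta_pH) {
  stopifnot(all(abs(delta_pH) < 5))
  10^delta_pH
}
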