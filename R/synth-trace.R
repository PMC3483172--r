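#' Kinetic parameters of a single-cell valve-formation trace
#'
#' Bundles the parameters of the two-phase fluorescence model used throughout
#' the package: an exponential accumulation phase \eqn{F(t) = F_0 e^{k t}} up
#' to the peak time, optionally followed by an exponential relaxation toward
#' a floor. The accumulation phase mimics reporter-dye uptake during silica
#' deposition vesicle (SDV) expansion; the decay phase mimics the maturation
#' period during which non-incorporated dye is released.
#'
#' With the defaults (`t_dec = Inf`, `regrow_rate = 0`) the post-peak trace
#' decays monotonically toward `decay_floor` times the peak value forever.
#' A finite `t_dec` truncates the decay phase after `t_dec` minutes, after
#' which the trace re-increases at `regrow_rate` (the signal of the sibling
#' valve in a dividing cell); this gives the trace a well-defined minimum at
#' `t_peak + t_dec`, which is what the phase-segmentation stage recovers.
#'
#' @param k accumulation rate, per minute (> 0).
#' @param F0 trace value at time 0, arbitrary intensity or concentration
#'   units (> 0).
#' @param t_peak end of the accumulation phase, minutes (> 0).
#' @param decay_rate relaxation rate of the decay phase, per minute (> 0).
#' @param has_decay logical; if `FALSE` the trace plateaus at its peak value.
#' @param decay_floor asymptote of the decay phase as a fraction of the peak
#'   value, in (0, 1].
#' @param t_dec duration of the decay phase in minutes (default `Inf`).
#' @param regrow_rate exponential re-increase rate after the decay minimum,
#'   per minute (default 0, i.e. the trace stays at its minimum).
#' @return An object of class `kinetic_params`.
#' @seealso [simulate_trace()]
#' @export
kinetic_params <- function(k, F0, t_peak, decay_rate = 0.064, has_decay = TRUE,
                           decay_floor = 0.5, t_dec = Inf, regrow_rate = 0) {
  stopifnot(is.numeric(k), k > 0, is.numeric(F0), F0 > 0,
            is.numeric(t_peak), t_peak > 0, is.numeric(decay_rate),
            decay_rate > 0, decay_floor > 0, decay_floor <= 1,
            t_dec > 0, regrow_rate >= 0)
  structure(list(k = k, F0 = F0, t_peak = t_peak, decay_rate = decay_rate,
                 has_decay = isTRUE(has_decay), decay_floor = decay_floor,
                 t_dec = t_dec, regrow_rate = regrow_rate),
            class = "kinetic_params")
}

#' Evaluate the two-phase trace model
#'
#' For `t <= t_peak` returns \eqn{F_0 e^{k t}}; beyond the peak, cells with a
#' decay phase relax exponentially toward `decay_floor` times the peak value,
#' and cells without one hold the peak value. The trace is continuous
#' everywhere, including at the peak and (for finite `t_dec`) at the decay
#' minimum.
#'
#' @param params a [kinetic_params()] object.
#' @param times numeric vector of times in minutes, strictly increasing.
#' @return Numeric vector of trace values at `times`.
#' @examples
#' p <- kinetic_params(k = log(2) / 30, F0 = 100, t_peak = 90)
#' simulate_trace(p, c(0, 30))  # doubles over one half-life
#' @export
simulate_trace <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(times))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing")
  }
  f1 <- params$F0 * exp(params$k * params$t_peak)
  out <- params$F0 * exp(params$k * pmin(times, params$t_peak))
  late <- times > params$t_peak
  if (any(late)) {
    if (params$has_decay) {
      floor_val <- params$decay_floor * f1
      tt <- pmin(times[late] - params$t_peak, params$t_dec)
      v <- floor_val + (f1 - floor_val) * exp(-params$decay_rate * tt)
      past_min <- (times[late] - params$t_peak) > params$t_dec
      if (any(past_min) && params$regrow_rate > 0) {
        extra <- times[late][past_min] - params$t_peak - params$t_dec
        # the sibling-valve signal saturates near the first valve's peak
        v[past_min] <- pmin(v[past_min] * exp(params$regrow_rate * extra), f1)
      }
      out[late] <- v
    } else {
      out[late] <- f1
    }
  }
  out
}

#' Time of the trace minimum (end of the decay phase)
#'
#' @param params a [kinetic_params()] object.
#' @return Minutes; `Inf` when the decay is asymptotic, `NA` when the cell
#'   has no decay phase.
#' @keywords internal
trace_minimum_time <- function(params) {
  if (!params$has_decay) return(NA_real_)
  params$t_peak + params$t_dec
}
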