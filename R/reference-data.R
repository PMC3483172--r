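# Published population-level reference values for Thalassiosira weissflogii
# grown across external pH treatments. These numbers parameterize the
# synthetic cohort defaults and serve as inputs to summary arithmetic
# (fold changes, pH spans); they are data, not fitted quantities.

#' Reference valve porosity by external pH
#'
#' Mean overall valve porosity (pore area fraction from high-magnification
#' TEM) of *T. weissflogii* valves purified from cultures grown at three
#' external pH values.
#'
#' @format data.frame with columns `pHe`, `porosity`.
#' @export
porosity_reference <- data.frame(
  pHe = c(6.8, 8.2, 8.5),
  porosity = c(0.058, 0.128, 0.100)
)

#' Reference intracellular pH by external pH
#'
#' Mean cytosolic pH (BCECF ratiometry) of *T. weissflogii* cells at
#' external pH 6.4, 7.8 and 8.2.
#'
#' @format data.frame with columns `pHe`, `pHi`.
#' @export
phi_reference <- data.frame(
  pHe = c(6.4, 7.8, 8.2),
  pHi = c(6.67, 7.35, 7.38)
)

#' Reference valve-formation kinetics
#'
#' Population means used as synthetic-cohort defaults: duration of the
#' exponential accumulation phase (90 +/- 39 min) and of the decay phase
#' (47 +/- 20 min), the fraction of cells showing a decay phase (0.75), and
#' the fitted exponential pH responses of the accumulation rate `k`
#' (y = 1.1e-3 e^{0.32 pH}) and of the phase concentration changes F1-F0
#' (y = 1e-4 e^{1.50 pH}) and F1-F2 (y = 5e-5 e^{1.47 pH}) over external
#' pH 6.4-8.2.
#'
#' @format list.
#' @export
kinetics_reference <- list(
  t_exp_min = 90, t_exp_sd = 39,
  t_dec_min = 47, t_dec_sd = 20,
  decay_fraction = 0.75,
  ph_domain = c(6.4, 8.2),
  k_response = list(a = 1.1e-3, b = 0.32),
  delta_exp_response = list(a = 1e-4, b = 1.50),
  delta_dec_response = list(a = 5e-5, b = 1.47),
  fold_exp = 13.8, fold_dec = 10.6
)
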