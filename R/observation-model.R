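#' Linear native and unfolded fluorescence baselines
#'
#' The observed fluorescence of each state drifts linearly with
#' temperature and, optionally, with denaturant concentration:
#' `B(T, D) = intercept + t_slope * T + d_slope * D`, with `T` in Kelvin
#' and `D` in molar. Intercepts are in raw signal units (extrapolated to
#' 0 K / 0 M); one baseline pair is shared across all denaturant series of
#' a variant.
#'
#' @param native_intercept,native_t_slope,native_d_slope Native-state
#'   baseline: intercept (signal units), temperature slope (signal/K) and
#'   denaturant slope (signal/M).
#' @param unfolded_intercept,unfolded_t_slope,unfolded_d_slope Same for
#'   the unfolded state.
#' @return An object of class `baseline_params`.
#' @export
baseline_params <- function(native_intercept, native_t_slope, native_d_slope = 0,
                            unfolded_intercept, unfolded_t_slope, unfolded_d_slope = 0) {
  vals <- c(native_intercept, native_t_slope, native_d_slope,
            unfolded_intercept, unfolded_t_slope, unfolded_d_slope)
  if (!is.numeric(vals) || length(vals) != 6L || any(!is.finite(vals))) {
    stop_stabfit("invalid_parameter", "baseline parameters must be finite numeric scalars")
  }
  structure(list(native_intercept = native_intercept,
                 native_t_slope = native_t_slope,
                 native_d_slope = native_d_slope,
                 unfolded_intercept = unfolded_intercept,
                 unfolded_t_slope = unfolded_t_slope,
                 unfolded_d_slope = unfolded_d_slope),
            class = "baseline_params")
}

#' Evaluate one state's baseline at given conditions
#'
#' @param baselines A [baseline_params()] object.
#' @param temperature Kelvin.
#' @param denaturant Molar.
#' @return Baseline signal, vectorised.
#' @export
native_baseline <- function(baselines, temperature, denaturant = 0) {
  baselines$native_intercept + baselines$native_t_slope * temperature +
    baselines$native_d_slope * denaturant
}

#' @rdname native_baseline
#' @export
unfolded_baseline <- function(baselines, temperature, denaturant = 0) {
  baselines$unfolded_intercept + baselines$unfolded_t_slope * temperature +
    baselines$unfolded_d_slope * denaturant
}

#' Predicted fluorescence signal of the two-state mixture
#'
#' The forward model shared by the simulator and the fitter: the signal is
#' the population-weighted mixture of the two state baselines,
#' `F = B_N (1 - f_U) + B_U f_U`, with `f_U` from [fraction_unfolded()].
#'
#' @param thermo A [thermo_params()] object.
#' @param baselines A [baseline_params()] object.
#' @param temperature Temperature(s), Kelvin.
#' @param denaturant Denaturant concentration(s), molar.
#' @return Predicted signal, vectorised over conditions.
#' @export
predicted_signal <- function(thermo, baselines, temperature, denaturant = 0) {
  fu <- fraction_unfolded(thermo, temperature, denaturant)
  bn <- native_baseline(baselines, temperature, denaturant)
  bu <- unfolded_baseline(baselines, temperature, denaturant)
  bn * (1 - fu) + bu * fu
}

#' Convert a raw signal to an apparent fraction unfolded
#'
#' Inverts the fitted baselines at each measurement condition,
#' `(B_N - F) / (B_N - B_U)`, so that curves from different variants can be
#' overlaid on a common degree-of-unfolding axis. Noisy points may fall
#' slightly outside [0, 1]; they are not clipped.
#'
#' @param signal Observed signal(s).
#' @inheritParams predicted_signal
#' @param min_separation Smallest admissible |B_N - B_U|; below this the
#'   transition is unidentifiable and a `degenerate_baseline` error is
#'   raised.
#' @return Apparent fraction unfolded, vectorised.
#' @export
normalize_signal <- function(signal, baselines, temperature, denaturant = 0,
                             min_separation = 1e-6) {
  check_condition(temperature, denaturant)
  bn <- native_baseline(baselines, temperature, denaturant)
  bu <- unfolded_baseline(baselines, temperature, denaturant)
  if (any(abs(bn - bu) < min_separation)) {
    stop_stabfit("degenerate_baseline",
      "native and unfolded baselines coincide at a measured condition; transition unidentifiable")
  }
  (bn - signal) / (bn - bu)
}
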