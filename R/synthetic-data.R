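#' Experimental design of a simulated unfolding experiment
#'
#' Mirrors the standard nanoDSF design: a temperature ramp from 15 to
#' 95 degrees C recorded at a ladder of GuHCl concentrations (default 13
#' levels evenly spaced over 0-5 M), with additive Gaussian noise on the
#' fluorescence signal. The noise level is given either absolutely
#' (`noise_sd`, signal units) or as a fraction of the native-to-unfolded
#' amplitude at mid-range conditions (`noise_frac`, default 1%).
#'
#' @param denaturant_levels GuHCl concentrations, molar (>= 5 levels).
#' @param temp_start,temp_stop,temp_step Ramp in degrees C.
#' @param noise_sd Absolute noise SD in signal units, or `NULL` to use
#'   `noise_frac`.
#' @param noise_frac Noise SD as a fraction of the transition amplitude.
#' @param seed Integer master seed; every series draws its own substream.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(denaturant_levels = seq(0, 5, length.out = 13),
                              temp_start = 15, temp_stop = 95, temp_step = 0.5,
                              noise_sd = NULL, noise_frac = 0.01, seed = 1L) {
  if (length(denaturant_levels) < 5L || any(denaturant_levels < 0)) {
    stop_stabfit("design_error", "need >= 5 non-negative denaturant levels")
  }
  if (temp_step <= 0 || temp_stop <= temp_start) {
    stop_stabfit("design_error", "temperature ramp must be increasing with step > 0")
  }
  if ((!is.null(noise_sd) && noise_sd < 0) || noise_frac < 0) {
    stop_stabfit("design_error", "noise must be >= 0")
  }
  structure(list(denaturant_levels = sort(denaturant_levels),
                 temp_start = temp_start, temp_stop = temp_stop,
                 temp_step = temp_step, noise_sd = noise_sd,
                 noise_frac = noise_frac, seed = as.integer(seed)),
            class = "experiment_design")
}

#' Default synthetic baseline truth
#'
#' A well-separated, realistically sloped baseline pair used throughout
#' the examples and tests: native (1000, -2, 0), unfolded (600, -1, 20)
#' in signal units.
#'
#' @return A [baseline_params()] object.
#' @export
default_baselines <- function() {
  baseline_params(1000, -2, 0, 600, -1, 20)
}

design_noise_sd <- function(baselines, design) {
  if (!is.null(design$noise_sd)) return(design$noise_sd)
  tmid <- mean(c(design$temp_start, design$temp_stop)) + 273.15
  dmid <- mean(range(design$denaturant_levels))
  amp <- abs(native_baseline(baselines, tmid, dmid) -
             unfolded_baseline(baselines, tmid, dmid))
  design$noise_frac * amp
}

#' Simulate one variant's unfolding dataset
#'
#' Forward-simulates the fluorescence surface with [predicted_signal()]
#' (the identical model the fitter minimises against) and adds i.i.d.
#' Gaussian noise. Each denaturant series uses its own RNG substream
#' derived deterministically from the design's master seed, so the same
#' (truth, design, seed) always yields a bit-identical dataset.
#'
#' @param thermo True [thermo_params()].
#' @param baselines True [baseline_params()].
#' @param design An [experiment_design()].
#' @param variant_label,replicate_id Labels for the resulting dataset.
#' @return An [unfolding_dataset()].
#' @export
simulate_dataset <- function(thermo, baselines, design = experiment_design(),
                             variant_label = "synthetic", replicate_id = 1L) {
  if (!inherits(design, "experiment_design")) {
    stop_stabfit("design_error", "design must be an experiment_design object")
  }
  temps_c <- seq(design$temp_start, design$temp_stop, by = design$temp_step)
  temps_k <- temps_c + 273.15
  sd <- design_noise_sd(baselines, design)

  set.seed(design$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(design$denaturant_levels))
  series <- Map(function(d, s) {
    mu <- predicted_signal(thermo, baselines, temps_k, d)
    set.seed(s)
    unfolding_series(d, temps_k, mu + rnorm(length(mu), sd = sd))
  }, design$denaturant_levels, sub_seeds)
  unfolding_dataset(variant_label, unname(series), replicate_id)
}

#' Simulate the four corners of a double-mutant cycle
#'
#' Generates one dataset per corner (wild type, two single mutants,
#' double mutant) with independent noise streams derived from the master
#' seed, for end-to-end exercises of the fit-then-cycle pipeline.
#'
#' @param truths Named list of four [thermo_params()] (distinct labels).
#' @param baselines True [baseline_params()] shared by the four.
#' @param design An [experiment_design()]; its seed is the master seed.
#' @return A named list of four [unfolding_dataset()]s.
#' @export
simulate_cycle <- function(truths, baselines = default_baselines(),
                           design = experiment_design()) {
  if (length(truths) != 4L || is.null(names(truths)) ||
      anyDuplicated(names(truths))) {
    stop_stabfit("design_error", "truths must be a named list of four distinct variants")
  }
  set.seed(design$seed)
  corner_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  out <- Map(function(lbl, th, s) {
    d <- design; d$seed <- s
    simulate_dataset(th, baselines, d, variant_label = lbl)
  }, names(truths), truths, corner_seeds)
  out
}

table1_env <- new.env(parent = emptyenv())

table1_df <- function() {
  if (is.null(table1_env$df)) {
    path <- system.file("extdata", "table1_thermo_params.csv", package = "stabfit")
    table1_env$df <- read.csv(path, stringsAsFactors = FALSE)
  }
  table1_env$df
}

#' Published thermodynamic parameters of the CI2 variant panel
#'
#' `table1_data()` returns the packaged table of globally fitted
#' thermodynamic parameters for the 26 purified CI2 variants (melting
#' temperature, folding enthalpy, heat-capacity change, m-value, folding
#' free energy and unfolding midpoint at 298 K, each with its standard
#' error, plus the common-m stability changes for the six variants of the
#' two double-mutant cycles). `table1_parameters()` looks up one variant
#' and returns its [thermo_params()], with the remaining columns attached
#' as the `"published"` attribute.
#'
#' @param variant_label Variant name as printed, e.g. `"wild-type"`,
#'   `"I57A"`, `"L49I/I57V"`.
#' @return `table1_data()`: a data frame; `table1_parameters()`: a
#'   `thermo_params` object.
#' @export
table1_data <- function() table1_df()

#' @rdname table1_data
#' @export
table1_parameters <- function(variant_label) {
  df <- table1_df()
  i <- match(variant_label, df$variant)
  if (is.na(i)) {
    stop_stabfit("lookup_error",
      sprintf("unknown variant '%s'; see table1_data()$variant for the %d available labels",
              variant_label, nrow(df)))
  }
  row <- df[i, ]
  out <- thermo_params(row$t_m, row$dh_m, row$dcp, row$m_value)
  attr(out, "published") <- row
  out
}
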