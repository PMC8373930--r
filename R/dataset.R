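#' One denaturant series of a melting experiment
#'
#' A single temperature ramp recorded at a fixed GuHCl concentration.
#'
#' @param denaturant GuHCl concentration, molar (scalar, >= 0).
#' @param temperature Temperatures, Kelvin, strictly increasing.
#' @param signal Fluorescence signal, same length as `temperature`.
#' @param mask Optional logical vector; `TRUE` marks points excluded from
#'   fitting (e.g. aggregation artefacts at high temperature).
#' @return An object of class `unfolding_series`.
#' @export
unfolding_series <- function(denaturant, temperature, signal, mask = NULL) {
  stopifnot(length(denaturant) == 1L, denaturant >= 0,
            length(temperature) == length(signal))
  if (any(diff(temperature) <= 0)) {
    stop_stabfit("invalid_series", "temperatures must be strictly increasing within a series")
  }
  if (is.null(mask)) mask <- rep(FALSE, length(temperature))
  stopifnot(is.logical(mask), length(mask) == length(temperature))
  if (sum(!mask) < 10L) {
    stop_stabfit("invalid_series", "a series needs at least 10 unmasked points")
  }
  structure(list(denaturant = denaturant, temperature = temperature,
                 signal = signal, mask = mask),
            class = "unfolding_series")
}

#' A variant's complete unfolding dataset
#'
#' All denaturant series of one replicate experiment for one variant. At
#' least five distinct denaturant levels are required for a reliable
#' two-dimensional fit.
#'
#' @param variant_label Variant name, e.g. `"wild-type"` or `"L49I/I57V"`.
#' @param series List of [unfolding_series()] objects.
#' @param replicate_id Integer replicate index (default 1).
#' @return An object of class `unfolding_dataset`.
#' @export
unfolding_dataset <- function(variant_label, series, replicate_id = 1L) {
  stopifnot(is.character(variant_label), length(variant_label) == 1L,
            is.list(series), length(series) > 0L)
  if (!all(vapply(series, inherits, logical(1), "unfolding_series"))) {
    stop_stabfit("invalid_dataset", "series must be a list of unfolding_series objects")
  }
  lev <- vapply(series, `[[`, numeric(1), "denaturant")
  if (length(unique(lev)) < 5L) {
    stop_stabfit("invalid_dataset", "at least 5 distinct denaturant levels are required")
  }
  series <- series[order(lev)]
  structure(list(variant_label = variant_label, series = series,
                 replicate_id = as.integer(replicate_id)),
            class = "unfolding_dataset")
}

#' @export
print.unfolding_dataset <- function(x, ...) {
  n <- sum(vapply(x$series, function(s) length(s$temperature), integer(1)))
  cat(sprintf("<unfolding_dataset> %s (replicate %d): %d series, %d points, [GuHCl] %.2g-%.2g M\n",
              x$variant_label, x$replicate_id, length(x$series), n,
              min(vapply(x$series, `[[`, numeric(1), "denaturant")),
              max(vapply(x$series, `[[`, numeric(1), "denaturant"))))
  invisible(x)
}

#' Mask points of a dataset inside a temperature/denaturant window
#'
#' Marks observations for exclusion from fitting, e.g. aggregation-prone
#' regions (a variant that aggregates above 50 degrees C at low GuHCl can
#' be handled with `temperature_range = c(323.15, Inf),
#' denaturant_range = c(0, 2)`).
#'
#' @param dataset An [unfolding_dataset()].
#' @param temperature_range Kelvin window `c(lo, hi)` to mask.
#' @param denaturant_range Molar window `c(lo, hi)`; only series whose
#'   concentration falls inside it are touched.
#' @return The dataset with updated masks.
#' @export
mask_dataset <- function(dataset, temperature_range = c(-Inf, Inf),
                         denaturant_range = c(-Inf, Inf)) {
  dataset$series <- lapply(dataset$series, function(s) {
    if (s$denaturant >= denaturant_range[1] && s$denaturant <= denaturant_range[2]) {
      hit <- s$temperature >= temperature_range[1] & s$temperature <= temperature_range[2]
      s$mask <- s$mask | hit
      if (sum(!s$mask) < 10L) {
        stop_stabfit("invalid_series", "masking left fewer than 10 points in a series")
      }
    }
    s
  })
  dataset
}
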