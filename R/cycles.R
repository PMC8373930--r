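#' A variant's stability (or stability change) with its uncertainty
#'
#' Carries one free-energy value at a reference temperature together with
#' its standard error and provenance, the unit of account for
#' double-mutant-cycle arithmetic. `source` distinguishes values from
#' independent per-variant fits (`"free-fit"`), re-fits with a consensus
#' m-value (`"common-m"`), and external predictor tables
#' (`"external-prediction"`, e.g. FoldX/Rosetta output read as input);
#' records from different sources must never be mixed in one cycle.
#'
#' @param variant_label Variant name.
#' @param dg Folding free energy (or difference), kJ/mol.
#' @param se Standard error, kJ/mol (>= 0).
#' @param source One of `"free-fit"`, `"common-m"`, `"external-prediction"`.
#' @param reference_temperature Kelvin; default 298.
#' @return An object of class `stability_record`.
#' @export
stability_record <- function(variant_label, dg, se = 0,
                             source = c("free-fit", "common-m", "external-prediction"),
                             reference_temperature = 298) {
  source <- match.arg(source)
  if (!is.finite(se) || se < 0) stop_stabfit("invalid_parameter", "se must be >= 0")
  structure(list(variant_label = variant_label, dg = dg, se = se,
                 source = source, reference_temperature = reference_temperature),
            class = "stability_record")
}

check_compatible <- function(...) {
  recs <- list(...)
  src <- unique(vapply(recs, `[[`, character(1), "source"))
  tref <- unique(vapply(recs, `[[`, numeric(1), "reference_temperature"))
  if (length(src) > 1L || length(tref) > 1L) {
    stop_stabfit("incompatible_records",
      "stability records must share source and reference temperature")
  }
  invisible(TRUE)
}

#' Stability change relative to a reference variant
#'
#' `ddG_f = dG_f(variant) - dG_f(reference)`, negative when the variant is
#' more stable than the reference. Errors combine in quadrature by
#' default; if the two values come from one joint fit and their estimated
#' covariance is known, pass it to account for the correlation.
#'
#' @param variant,reference [stability_record()] objects with the same
#'   source and reference temperature.
#' @param covariance Covariance between the two dG estimates, kJ^2/mol^2
#'   (default 0 = independent errors).
#' @return A `stability_record` holding the ddG_f.
#' @export
ddg <- function(variant, reference, covariance = 0) {
  check_compatible(variant, reference)
  stability_record(variant$variant_label,
                   dg = variant$dg - reference$dg,
                   se = sqrt(variant$se^2 + reference$se^2 - 2 * covariance),
                   source = variant$source,
                   reference_temperature = variant$reference_temperature)
}

#' Coupling energy of a double-mutant cycle
#'
#' The deviation of the double mutant's stability change from additivity
#' of its single mutants,
#' `dddG_f = ddG_f(double) - (ddG_f(single1) + ddG_f(single2))`.
#' A nonzero coupling energy indicates thermodynamic interaction between
#' the two substitutions (negative = synergistic stabilisation). The
#' standard error is the quadrature sum of the three inputs.
#'
#' @param ddg1,ddg2 [stability_record()] objects with the single-mutant
#'   ddG_f values.
#' @param ddg12 The double mutant's ddG_f record.
#' @return An object of class `cycle_result` with fields `ddg_single_1`,
#'   `ddg_single_2`, `ddg_double`, `dddg`, `dddg_se`.
#' @export
coupling_energy <- function(ddg1, ddg2, ddg12) {
  check_compatible(ddg1, ddg2, ddg12)
  structure(list(ddg_single_1 = ddg1, ddg_single_2 = ddg2, ddg_double = ddg12,
                 dddg = ddg12$dg - (ddg1$dg + ddg2$dg),
                 dddg_se = sqrt(ddg1$se^2 + ddg2$se^2 + ddg12$se^2)),
            class = "cycle_result")
}

#' Full double-mutant cycle from the four corner stabilities
#'
#' Convenience wrapper building the three ddG_f records against wild type
#' and the coupling energy from the four corners (wild type, both single
#' mutants, double mutant).
#'
#' @param wt,single1,single2,double [stability_record()] objects holding
#'   absolute dG_f values of the four corners.
#' @return A `cycle_result`.
#' @export
double_mutant_cycle <- function(wt, single1, single2, double) {
  coupling_energy(ddg(single1, wt), ddg(single2, wt), ddg(double, wt))
}

#' @export
print.cycle_result <- function(x, ...) {
  f <- function(r) sprintf("%s: %.1f +/- %.1f", r$variant_label,
                           round_half_away(r$dg), round_half_away(r$se))
  cat("<double-mutant cycle> (ddG_f, kJ/mol)\n",
      " ", f(x$ddg_single_1), "\n  ", f(x$ddg_single_2), "\n  ",
      f(x$ddg_double), "\n",
      sprintf("  coupling dddG_f = %.1f +/- %.1f kJ/mol\n",
              round_half_away(x$dddg), round_half_away(x$dddg_se)), sep = "")
  invisible(x)
}

records_to_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("variant_label", "dg") %in% names(x)))
    return(x[, intersect(c("variant_label", "dg", "se"), names(x))])
  }
  data.frame(variant_label = vapply(x, `[[`, character(1), "variant_label"),
             dg = vapply(x, `[[`, numeric(1), "dg"),
             se = vapply(x, `[[`, numeric(1), "se"),
             stringsAsFactors = FALSE)
}

#' Compare experimental stability changes with predicted ones
#'
#' Matches records by variant label and summarises the agreement with the
#' Pearson correlation coefficient and a least-squares line
#' (`predicted ~ experimental`). Predictor tables (e.g. FoldX, Rosetta, or
#' unitless sequence-model scores) are supplied in the same record shape.
#'
#' @param experimental,predicted Lists of [stability_record()]s, or data
#'   frames with columns `variant_label`, `dg` (and optionally `se`).
#' @return A list with `r`, `slope`, `intercept`, `n`, and the unmatched
#'   labels of both tables.
#' @export
compare_predictions <- function(experimental, predicted) {
  e <- records_to_df(experimental)
  p <- records_to_df(predicted)
  mm <- merge(e, p, by = "variant_label", suffixes = c("_exp", "_pred"))
  if (nrow(mm) < 3L) {
    stop_stabfit("insufficient_overlap",
      sprintf("only %d matched variant label(s); need at least 3", nrow(mm)))
  }
  fit <- lm(dg_pred ~ dg_exp, data = mm)
  list(r = cor(mm$dg_exp, mm$dg_pred),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       n = nrow(mm),
       unmatched_experimental = setdiff(e$variant_label, mm$variant_label),
       unmatched_predicted = setdiff(p$variant_label, mm$variant_label))
}
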