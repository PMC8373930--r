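#' Read unfolding datasets from tidy CSV
#'
#' The canonical on-disk dialect is long/tidy, one observation per row,
#' with header `variant,replicate,denaturant_M,temperature_C,signal` and
#' an optional `mask` column (0/1). Temperatures are degrees C on disk
#' (instrument convention) and converted to Kelvin on read. Rows are
#' grouped into one [unfolding_dataset()] per (variant, replicate) and
#' series are sorted by temperature.
#'
#' @param path CSV file path.
#' @return A list of [unfolding_dataset()]s, named `variant#replicate`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_stabfit("parse_error", paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("variant", "replicate", "denaturant_M", "temperature_C", "signal")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_stabfit("parse_error",
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("replicate", "denaturant_M", "temperature_C", "signal")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) || anyNA(v)) {
      lines <- if (length(bad)) bad + 1L else which(is.na(v)) + 1L
      stop_stabfit("parse_error",
        sprintf("non-numeric value(s) in column '%s' at line(s) %s", col,
                paste(head(lines, 5L), collapse = ", ")))
    }
    df[[col]] <- v
  }
  key <- paste(df$variant, df$replicate, df$denaturant_M, df$temperature_C, sep = "\r")
  if (anyDuplicated(key)) {
    stop_stabfit("parse_error",
      sprintf("duplicate (variant, replicate, denaturant, temperature) key(s) at line(s) %s",
              paste(head(which(duplicated(key)) + 1L, 5L), collapse = ", ")))
  }
  mask <- if ("mask" %in% names(df)) as.logical(as.numeric(df$mask)) else rep(FALSE, nrow(df))

  out <- list()
  for (v in unique(df$variant)) {
    for (r in unique(df$replicate[df$variant == v])) {
      sel <- df$variant == v & df$replicate == r
      sub <- df[sel, ]; msk <- mask[sel]
      series <- lapply(sort(unique(sub$denaturant_M)), function(d) {
        i <- which(sub$denaturant_M == d)
        i <- i[order(sub$temperature_C[i])]
        unfolding_series(d, sub$temperature_C[i] + 273.15, sub$signal[i], msk[i])
      })
      out[[paste0(v, "#", r)]] <- unfolding_dataset(v, series, as.integer(r))
    }
  }
  out
}

#' Write unfolding datasets to tidy CSV
#'
#' Inverse of [read_dataset()]: Kelvin is converted back to degrees C; a
#' `mask` column is written only when any point is masked.
#'
#' @param datasets A single [unfolding_dataset()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(datasets, path) {
  if (inherits(datasets, "unfolding_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(ds) {
    do.call(rbind, lapply(ds$series, function(s) {
      data.frame(variant = ds$variant_label, replicate = ds$replicate_id,
                 denaturant_M = s$denaturant,
                 temperature_C = s$temperature - 273.15,
                 signal = s$signal, mask = as.integer(s$mask),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!any(rows$mask == 1L)) rows$mask <- NULL
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_pm <- function(value, se, digits) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          round_half_away(value, digits), round_half_away(se, digits))
}

#' Summary table of fitted thermodynamic parameters
#'
#' Collates fits into a publication-style table: one row per variant with
#' `value +/- SE` strings for the melting temperature, folding enthalpy,
#' heat-capacity change, m-value, and the derived folding free energy and
#' denaturant midpoint at the reference temperature. Rows are sorted by
#' dG_f descending (least to most stable). Numeric values are attached as
#' the `"numeric"` attribute; rounding is half-away-from-zero at the
#' customary precision (T_m/dCp/m/dG/[D]50: 1 decimal, dH_m: integer).
#'
#' @param fits A `fit_result` or list of them.
#' @param cycles Optional list of `cycle_result`s appended as a coupling
#'   block attribute `"cycles"`.
#' @param reference_temperature Kelvin, default 298.
#' @return A data frame of formatted strings.
#' @export
report_table <- function(fits, cycles = NULL, reference_temperature = 298) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  if (!length(fits)) stop_stabfit("empty_input", "no fits supplied")
  num <- do.call(rbind, lapply(fits, function(f) {
    se <- f$standard_errors
    pick_se <- function(p) {
      i <- grep(paste0("^", p, "(\\[|$)"), names(se))
      if (length(i)) unname(se[i[1]]) else 0
    }
    dg <- gibbs_free_energy(f$thermo, reference_temperature, 0)
    data.frame(variant = f$variant_label,
               t_m = f$thermo$t_m, t_m_se = pick_se("t_m"),
               dh_m = f$thermo$dh_m, dh_m_se = pick_se("dh_m"),
               dcp = f$thermo$dcp, dcp_se = pick_se("dcp"),
               m_value = f$thermo$m_value, m_se = pick_se("m_value"),
               dg_f = dg,
               dg_f_se = derived_quantity_error(f, "dg", reference_temperature),
               d50 = -dg / f$thermo$m_value,
               d50_se = derived_quantity_error(f, "d50", reference_temperature),
               stringsAsFactors = FALSE)
  }))
  num <- num[order(num$dg_f, decreasing = TRUE), , drop = FALSE]
  rownames(num) <- NULL
  out <- data.frame(
    variant = num$variant,
    t_m_K = fmt_pm(num$t_m, num$t_m_se, 1),
    dh_m_kJ_mol = fmt_pm(num$dh_m, num$dh_m_se, 0),
    dcp_kJ_mol_K = fmt_pm(num$dcp, num$dcp_se, 1),
    m_kJ_mol_M = fmt_pm(num$m_value, num$m_se, 1),
    dg_f_kJ_mol = fmt_pm(num$dg_f, num$dg_f_se, 1),
    d50_M = fmt_pm(num$d50, num$d50_se, 1),
    stringsAsFactors = FALSE)
  attr(out, "numeric") <- num
  if (length(cycles)) {
    attr(out, "cycles") <- data.frame(
      double = vapply(cycles, function(cy) cy$ddg_double$variant_label, character(1)),
      dddg_kJ_mol = vapply(cycles, function(cy)
        fmt_pm(cy$dddg, cy$dddg_se, 1), character(1)),
      stringsAsFactors = FALSE)
  }
  out
}
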