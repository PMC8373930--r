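#' Thermodynamic parameters of a two-state folder
#'
#' Bundles the four parameters that determine the folding free energy
#' surface of one protein variant over temperature and denaturant
#' concentration: the melting temperature in water, the folding enthalpy at
#' that temperature, the heat-capacity change of folding, and the
#' denaturant m-value of the linear extrapolation method.
#'
#' @param t_m Melting temperature at zero denaturant, Kelvin (> 0).
#' @param dh_m Enthalpy change for folding at `t_m`, kJ/mol (< 0 for a
#'   cooperative folder, the only case supported).
#' @param dcp Heat-capacity change for folding, kJ/mol/K.
#' @param m_value Denaturant m-value for GuHCl unfolding, kJ/mol/M (> 0).
#' @return An object of class `thermo_params`.
#' @examples
#' wt <- thermo_params(t_m = 352.3, dh_m = -322, dcp = -4.3, m_value = 8.2)
#' gibbs_free_energy(wt, temperature = 298)
#' @export
thermo_params <- function(t_m, dh_m, dcp, m_value) {
  for (v in list(t_m, dh_m, dcp, m_value)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_stabfit("invalid_parameter", "thermodynamic parameters must be finite numeric scalars")
    }
  }
  if (t_m <= 0) stop_stabfit("invalid_parameter", "t_m must be positive (Kelvin)")
  if (m_value <= 0) stop_stabfit("invalid_parameter", "m_value must be positive")
  if (dh_m >= 0) {
    stop_stabfit("invalid_parameter",
      "dh_m must be negative under the folding sign convention (cooperative folder)")
  }
  structure(list(t_m = t_m, dh_m = dh_m, dcp = dcp, m_value = m_value),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "<thermo_params> T_m = %.1f K, dH_m = %.0f kJ/mol, dCp = %.2f kJ/mol/K, m = %.2f kJ/mol/M\n",
    x$t_m, x$dh_m, x$dcp, x$m_value))
  invisible(x)
}

check_condition <- function(temperature, denaturant) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop_stabfit("invalid_condition", "temperature must be positive (Kelvin)")
  }
  if (any(!is.finite(denaturant)) || any(denaturant < 0)) {
    stop_stabfit("invalid_condition", "denaturant concentration must be >= 0 (molar)")
  }
  invisible(TRUE)
}

#' Folding free energy at a temperature and denaturant concentration
#'
#' Evaluates the two-state folding free energy
#' \deqn{\Delta G_f(T, D) = \Delta H_m (1 - T/T_m) +
#'   \Delta C_p (T - T_m - T \ln(T/T_m)) + m D,}
#' i.e. the Gibbs-Helmholtz relation in temperature combined with the
#' linear extrapolation method in denaturant. Negative values mean the
#' folded state is favoured; the function is zero at `(T = t_m, D = 0)` by
#' construction and increases linearly in `D` with slope `m_value`.
#'
#' @param params A [thermo_params()] object.
#' @param temperature Temperature(s), Kelvin.
#' @param denaturant Denaturant concentration(s), molar. Default 0.
#' @return Folding free energy in kJ/mol, vectorised over conditions.
#' @export
gibbs_free_energy <- function(params, temperature, denaturant = 0) {
  check_condition(temperature, denaturant)
  t_r <- temperature / params$t_m
  params$dh_m * (1 - t_r) +
    params$dcp * (temperature - params$t_m - temperature * log(t_r)) +
    params$m_value * denaturant
}

#' Equilibrium fraction of unfolded protein
#'
#' Two-state population of the unfolded state,
#' `f_U = 1 / (1 + exp(-dG_f / (R T)))`, a logistic function of the folding
#' free energy. Equals 0.5 exactly where `dG_f = 0` (the transition
#' midpoint) and approaches 0/1 for strongly stable/unstable conditions.
#'
#' @inheritParams gibbs_free_energy
#' @return Fraction unfolded in (0, 1), vectorised.
#' @export
fraction_unfolded <- function(params, temperature, denaturant = 0) {
  dg <- gibbs_free_energy(params, temperature, denaturant)
  plogis(dg / (R_GAS * temperature))
}

#' Denaturant unfolding midpoint at a fixed temperature
#'
#' The GuHCl concentration at which folded and unfolded populations are
#' equal, `[D]50% = -dG_f(T, 0) / m`. For variants already unfolded in
#' water at the chosen temperature the midpoint is negative; it is returned
#' as-is with a message.
#'
#' @inheritParams gibbs_free_energy
#' @return Midpoint concentration, molar.
#' @export
midpoint_denaturant <- function(params, temperature) {
  if (params$m_value <= 0) stop_stabfit("invalid_parameter", "m_value must be positive")
  d50 <- -gibbs_free_energy(params, temperature, 0) / params$m_value
  if (any(d50 < 0)) {
    message("midpoint_denaturant: negative midpoint (variant unfolded in water at this temperature)")
  }
  d50
}

#' Apparent melting temperature at a denaturant concentration
#'
#' Solves `dG_f(T, D) = 0` for the temperature at which half the protein is
#' unfolded at a fixed denaturant concentration, on the heat-unfolding
#' branch (above the temperature of maximum stability, where dG_f rises
#' monotonically; the cold-denaturation root of the Gibbs-Helmholtz curve
#' is ignored). Root bracketing plus Newton polishing; at `D = 0` this is
#' `t_m` by definition and is returned exactly.
#'
#' @param params A [thermo_params()] object.
#' @param denaturant Denaturant concentration, molar (scalar).
#' @param bracket Search interval in Kelvin.
#' @return Apparent melting temperature, Kelvin.
#' @export
melting_temperature_at <- function(params, denaturant, bracket = c(250, 400)) {
  stopifnot(length(denaturant) == 1L)
  if (denaturant == 0) return(params$t_m)
  f <- function(tt) gibbs_free_energy(params, tt, denaturant)
  # temperature of maximum stability: d(dG)/dT = 0
  t_s <- params$t_m * exp(-params$dh_m / (params$t_m * params$dcp))
  bracket[1] <- min(max(bracket[1], t_s), bracket[2] - 1e-6)
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop_stabfit("no_transition",
      sprintf("no unfolding transition of dG_f in [%g, %g] K at %g M", bracket[1], bracket[2], denaturant))
  }
  tt <- uniroot(f, bracket, tol = 1e-10)$root
  # Newton polish to drive |dG| below 1e-9 kJ/mol
  for (i in 1:5) {
    g <- f(tt)
    if (abs(g) < 1e-12) break
    slope <- -params$dh_m / params$t_m - params$dcp * log(tt / params$t_m)
    tt <- tt - g / slope
  }
  tt
}
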