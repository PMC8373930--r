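# shared fixtures: truths and a reduced design for fast fitting tests
wt_truth <- function() thermo_params(t_m = 352.3, dh_m = -322, dcp = -4.3, m_value = 8.2)

# coarser grid than the full instrument ramp; keeps fit tests quick
small_design <- function(...) {
  experiment_design(denaturant_levels = seq(0, 5, length.out = 7),
                    temp_step = 1, ...)
}

# independent Gibbs-Helmholtz oracle: integrate the van 't Hoff relation
# d(dG/T)/dT = -dH(T)/T^2 with dH(T) = dH_m + dCp (T - T_m), from T_m
# (where dG = 0) to T, then add the linear denaturant term
vant_hoff_dg <- function(p, temperature, denaturant = 0) {
  integral <- integrate(function(x) (p$dh_m + p$dcp * (x - p$t_m)) / x^2,
                        p$t_m, temperature, rel.tol = 1e-12)$value
  temperature * (-integral) + p$m_value * denaturant
}

random_thermo <- function() {
  thermo_params(t_m = runif(1, 310, 380), dh_m = runif(1, -450, -100),
                dcp = runif(1, -7, -0.5), m_value = runif(1, 4, 12))
}
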