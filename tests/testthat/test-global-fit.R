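test_that("initial guess locates the thermal transition and rejects flat data", {
  wt <- wt_truth()
  ds <- simulate_dataset(wt, default_baselines(),
                         small_design(noise_frac = 0, seed = 1), "wild-type")
  g <- initial_guess(ds)
  expect_lt(abs(g$thermo$t_m - 352.3), 2)

  # pure baseline data: no transition anywhere in the ramp
  temps <- seq(288.15, 368.15, by = 1)
  bl <- default_baselines()
  set.seed(4)
  flat <- unfolding_dataset("flat", lapply(seq(0, 5, length.out = 6), function(d) {
    unfolding_series(d, temps, native_baseline(bl, temps, d) + rnorm(length(temps), sd = 2))
  }))
  expect_error(initial_guess(flat), class = "no_transition")

  # guessed t_m ordering follows the true stability ordering
  g_d55g <- initial_guess(simulate_dataset(thermo_params(361.1, -378, -4.7, 8.5),
                                           default_baselines(), small_design(seed = 3), "D55G"))
  g_i57a <- initial_guess(simulate_dataset(thermo_params(333.1, -269, -5.4, 11.6),
                                           default_baselines(), small_design(seed = 3), "I57A"))
  expect_gt(g_d55g$thermo$t_m, g_i57a$thermo$t_m)
})

test_that("noise-free data are recovered exactly by the global fit", {
  wt <- wt_truth()
  ds <- simulate_dataset(wt, default_baselines(),
                         small_design(noise_frac = 0, seed = 1), "wild-type")
  fit <- fit_variant(ds, fit_options(n_starts = 2))
  expect_true(fit$converged)
  expect_lt(abs(fit$thermo$t_m - wt$t_m), 1e-4)
  expect_lt(abs(fit$thermo$dh_m - wt$dh_m), 1e-4)
  expect_lt(abs(fit$thermo$dcp - wt$dcp), 1e-4)
  expect_lt(abs(fit$thermo$m_value - wt$m_value), 1e-4)
  expect_lt(abs(fit$baselines[[1]]$unfolded_d_slope - 20), 1e-3)
  # refitting from the fitted point is a fixed point of the optimiser
  refit <- fit_variant(ds, fit_options(n_starts = 1,
                                       start = list(thermo = fit$thermo,
                                                    baselines = fit$baselines[[1]])))
  expect_lt(abs(refit$thermo$t_m - fit$thermo$t_m), 1e-6)
  expect_lte(refit$ssr, fit$ssr * (1 + 1e-8))
})

test_that("noisy fits recover dG_f within the pooled experimental reproducibility", {
  wt <- wt_truth()
  ds <- simulate_dataset(wt, default_baselines(), small_design(seed = 1), "wild-type")
  fit <- fit_variant(ds)
  expect_true(fit$converged)
  dg_truth <- gibbs_free_energy(wt, 298)
  expect_lt(abs(gibbs_free_energy(fit$thermo, 298) - dg_truth), 1.2)
})

test_that("fixing m at the generating value leaves the other estimates unchanged", {
  wt <- wt_truth()
  truth <- thermo_params(wt$t_m, wt$dh_m, wt$dcp, 8.4)
  ds <- simulate_dataset(truth, default_baselines(), small_design(seed = 5), "wt84")
  free_fit <- fit_variant(ds)
  fixed_fit <- fit_variant(ds, fit_options(fixed = list(m_value = 8.4)))
  expect_identical(fixed_fit$thermo$m_value, 8.4)
  expect_identical(fixed_fit$standard_errors[["m_value[wt84]"]], 0)
  for (p in c("t_m", "dh_m", "dcp")) {
    se <- free_fit$standard_errors[[paste0(p, "[wt84]")]]
    expect_lt(abs(fixed_fit$thermo[[p]] - free_fit$thermo[[p]]), se)
  }
})

test_that("replicates share thermodynamics but keep their own baselines", {
  wt <- wt_truth()
  bl2 <- baseline_params(900, -1.8, 0, 550, -0.9, 15)
  d1 <- simulate_dataset(wt, default_baselines(), small_design(seed = 21), "wt", 1L)
  d2 <- simulate_dataset(wt, bl2, small_design(seed = 22), "wt", 2L)
  fit <- fit_variant(list(d1, d2))
  expect_length(fit$baselines, 2L)
  expect_lt(abs(fit$baselines[[1]]$native_intercept - 1000), 30)
  expect_lt(abs(fit$baselines[[2]]$native_intercept - 900), 30)
  expect_lt(abs(gibbs_free_energy(fit$thermo, 298) - gibbs_free_energy(wt, 298)), 1.2)
})

test_that("joint fits share or fix a common m-value and shrink standard errors", {
  a <- thermo_params(352.3, -322, -4.3, 8.4)
  b <- thermo_params(356.2, -332, -4.2, 8.4)
  ds <- list(simulate_dataset(a, default_baselines(), small_design(seed = 31), "A"),
             simulate_dataset(b, default_baselines(), small_design(seed = 32), "B"))
  joint <- fit_joint(ds, fit_options(share_m = TRUE))
  m_hat <- joint[["A"]]$thermo$m_value
  m_se <- joint[["A"]]$standard_errors[["m_value"]]
  expect_identical(joint[["B"]]$thermo$m_value, m_hat)
  expect_lt(abs(m_hat - 8.4), 2 * m_se)

  free_a <- fit_variant(ds[[1]])
  fixed <- fit_joint(ds, fit_options(fixed = list(m_value = 8.4)))
  se_free <- derived_quantity_error(free_a, "dg", 298)
  se_fixed <- derived_quantity_error(fixed[["A"]], "dg", 298)
  expect_lte(se_fixed, se_free)

  # degenerate case: a single-variant joint fit equals fit_variant
  single <- fit_joint(ds[1], fit_options(seed = 9))
  direct <- fit_variant(ds[[1]], fit_options(seed = 9))
  expect_equal(single[["A"]]$thermo, direct$thermo, tolerance = 1e-8)
})

test_that("average m-value reproduces the consensus arithmetic", {
  expect_equal(average_m(c(8.2, 8.7, 8.5, 8.3, 8.5, 7.9)), 8.35)
  expect_equal(average_m(7.7), 7.7)
  expect_equal(average_m(c(8, 8, 8)), 8)
  expect_error(average_m(numeric(0)), class = "empty_input")
})

test_that("delta-method errors agree with parametric Monte Carlo", {
  skip_if_not_installed("MASS")
  wt <- wt_truth()
  ds <- simulate_dataset(wt, default_baselines(), small_design(seed = 41), "wt")
  fit <- fit_variant(ds)
  th <- unlist(fit$thermo)
  cov <- fit$thermo_covariance
  set.seed(42)
  draws <- MASS::mvrnorm(2000, mu = th, Sigma = cov)
  mc <- apply(draws, 1, function(x) {
    p <- thermo_params(x[1], x[2], x[3], x[4])
    gibbs_free_energy(p, 298)
  })
  se_mc <- stats::sd(mc)
  se_delta <- derived_quantity_error(fit, "dg", 298)
  expect_lt(abs(se_delta - se_mc) / se_mc, 0.15)

  # a fit without covariance cannot propagate
  broken <- fit; broken$thermo_covariance <- NULL
  expect_error(derived_quantity_error(broken, "dg"), class = "unavailable_error")
  # zero parameter uncertainty propagates to zero derived uncertainty
  null_fit <- fit; null_fit$thermo_covariance <- matrix(0, 4, 4)
  expect_identical(derived_quantity_error(null_fit, "d50"), 0)
})

test_that("derived-quantity gradients are analytically correct", {
  wt <- wt_truth()
  ds <- simulate_dataset(wt, default_baselines(), small_design(seed = 43), "wt")
  fit <- fit_variant(ds)
  # check d50 and tm_app delta errors against finite-difference gradients
  for (q in list(list(name = "d50", fn = function(p) -gibbs_free_energy(p, 298, 0) / p$m_value),
                 list(name = "tm_app", fn = function(p) melting_temperature_at(p, 2)))) {
    th <- unlist(fit$thermo)
    g <- vapply(1:4, function(j) {
      h <- max(1e-6, 1e-6 * abs(th[j]))
      up <- th; up[j] <- th[j] + h
      dn <- th; dn[j] <- th[j] - h
      (q$fn(thermo_params(up[1], up[2], up[3], up[4])) -
         q$fn(thermo_params(dn[1], dn[2], dn[3], dn[4]))) / (2 * h)
    }, numeric(1))
    se_fd <- sqrt(drop(t(g) %*% fit$thermo_covariance %*% g))
    se_an <- derived_quantity_error(fit, q$name, temperature = 298, denaturant = 2)
    expect_equal(se_an, se_fd, tolerance = 1e-4)
  }
})
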