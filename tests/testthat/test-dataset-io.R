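test_that("dataset containers enforce the experimental-design invariants", {
  temps <- seq(288, 368, by = 1)
  sig <- rnorm(length(temps))
  expect_error(unfolding_series(0, rev(temps), sig), class = "invalid_series")
  expect_error(unfolding_series(0, temps[1:5], sig[1:5]), class = "invalid_series")
  s <- unfolding_series(0, temps, sig)
  expect_error(unfolding_dataset("x", list(s, s, s, s)), class = "invalid_dataset")

  ds <- simulate_dataset(wt_truth(), default_baselines(), small_design(seed = 1), "wt")
  masked <- mask_dataset(ds, temperature_range = c(323.15, Inf),
                         denaturant_range = c(0, 2))
  low_d <- vapply(masked$series, `[[`, numeric(1), "denaturant") <= 2
  for (i in which(low_d)) {
    expect_true(all(masked$series[[i]]$mask[masked$series[[i]]$temperature >= 323.15]))
  }
  for (i in which(!low_d)) expect_false(any(masked$series[[i]]$mask))
})

test_that("masked points are excluded from the fit objective", {
  wt <- wt_truth()
  ds <- simulate_dataset(wt, default_baselines(), small_design(noise_frac = 0, seed = 1), "wt")
  # corrupt a high-temperature window of the lowest-GuHCl series, then mask it
  bad <- ds
  hit <- bad$series[[1]]$temperature > 360
  bad$series[[1]]$signal[hit] <- bad$series[[1]]$signal[hit] + 300
  corrupt_fit <- fit_variant(bad, fit_options(n_starts = 2))
  masked <- mask_dataset(bad, temperature_range = c(360, Inf), denaturant_range = c(0, 0))
  clean_fit <- fit_variant(masked, fit_options(n_starts = 2))
  expect_lt(abs(clean_fit$thermo$t_m - wt$t_m), 1e-3)
  expect_lt(abs(clean_fit$thermo$t_m - wt$t_m), abs(corrupt_fit$thermo$t_m - wt$t_m))
})

test_that("the tidy CSV dialect round-trips datasets exactly", {
  wt <- wt_truth()
  ds <- simulate_dataset(wt, default_baselines(),
                         experiment_design(seed = 8), "wild-type")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_length(back, 1L)
  rt <- back[[1]]
  expect_identical(rt$variant_label, "wild-type")
  expect_length(rt$series, 13L)
  for (i in seq_along(ds$series)) {
    expect_equal(rt$series[[i]]$temperature, ds$series[[i]]$temperature, tolerance = 1e-9)
    expect_equal(rt$series[[i]]$signal, ds$series[[i]]$signal, tolerance = 1e-9)
    expect_equal(range(rt$series[[i]]$temperature - 273.15), c(15, 95))
  }
})

test_that("malformed CSV input fails with located parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(variant = "x", replicate = 1,
                   denaturant_M = rep(0:5, each = 12),
                   temperature_C = rep(seq(15, 70, by = 5), 6),
                   signal = rnorm(72))
  ok <- df
  write.csv(ok[, -3], path, row.names = FALSE)
  err <- tryCatch(read_dataset(path), error = identity)
  expect_s3_class(err, "parse_error")
  expect_match(conditionMessage(err), "denaturant_M")

  bad <- df; bad$signal <- as.character(bad$signal); bad$signal[5] <- "oops"
  write.csv(bad, path, row.names = FALSE)
  err <- tryCatch(read_dataset(path), error = identity)
  expect_s3_class(err, "parse_error")
  expect_match(conditionMessage(err), "signal")
  expect_match(conditionMessage(err), "6")  # header + 5th data row

  dup <- rbind(df, df[1, ])
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_dataset(path), class = "parse_error")
})

test_that("the report table formats and orders variants like the published table", {
  truths <- list("wild-type" = wt_truth(),
                 "I57A" = thermo_params(333.1, -269, -5.4, 11.6))
  fits <- lapply(names(truths), function(v) {
    fit_variant(simulate_dataset(truths[[v]], default_baselines(),
                                 small_design(noise_frac = 0, seed = 3), v),
                fit_options(n_starts = 1))
  })
  tab <- report_table(fits)
  # least stable first (dG_f descending)
  expect_identical(tab$variant, c("I57A", "wild-type"))
  expect_match(tab$t_m_K[tab$variant == "wild-type"], "^352\\.3 ± 0\\.0")
  expect_match(tab$dg_f_kJ_mol[tab$variant == "wild-type"], "^-30\\.6")
  expect_match(tab$d50_M[tab$variant == "I57A"], "^1\\.6")
  num <- attr(tab, "numeric")
  expect_equal(num$m_value[num$variant == "I57A"], 11.6, tolerance = 1e-3)

  cyc <- coupling_energy(stability_record("a", -6.9, 0.3, "common-m"),
                         stability_record("b", -2.2, 0.1, "common-m"),
                         stability_record("a/b", -6.5, 0.2, "common-m"))
  tab2 <- report_table(fits, cycles = list(cyc))
  expect_identical(attr(tab2, "cycles")$dddg_kJ_mol, "2.6 ± 0.4")
  expect_null(attr(tab, "cycles"))
})
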