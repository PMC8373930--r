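#' Options controlling the global fit
#'
#' @param fixed Named list of thermodynamic parameters held fixed at the
#'   given values for all variants, e.g. `list(m_value = 8.4)` to fix the
#'   m-value at a consensus average.
#' @param share_m If `TRUE`, joint fits estimate a single m-value common to
#'   all variants instead of one per variant.
#' @param denaturant_baselines If `FALSE`, the baseline denaturant slopes
#'   are fixed at zero.
#' @param n_starts Number of multi-start optimisations; the first uses the
#'   initial guess unperturbed, the rest seeded jitters around it. The
#'   lowest sum of squares wins (ties by first index).
#' @param seed Integer seed for the multi-start jitter.
#' @param maxit Maximum Levenberg-Marquardt iterations per start.
#' @param ftol Relative sum-of-squares convergence tolerance.
#' @param start Optional list(thermo=, baselines=) overriding the automatic
#'   initial guess (single-variant fits only).
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(fixed = list(), share_m = FALSE,
                        denaturant_baselines = TRUE,
                        n_starts = 5L, seed = 1L, maxit = 500L,
                        ftol = 1e-12, start = NULL) {
  if (length(fixed) && is.null(names(fixed))) {
    stop_stabfit("invalid_parameter", "`fixed` must be a named list")
  }
  bad <- setdiff(names(fixed), c("t_m", "dh_m", "dcp", "m_value"))
  if (length(bad)) {
    stop_stabfit("invalid_parameter",
                 paste0("unknown fixed parameter(s): ", paste(bad, collapse = ", ")))
  }
  if (share_m && "m_value" %in% names(fixed)) {
    stop_stabfit("invalid_parameter", "m_value cannot be both shared and fixed")
  }
  structure(list(fixed = fixed, share_m = share_m,
                 denaturant_baselines = denaturant_baselines,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 maxit = as.integer(maxit), ftol = ftol, start = start),
            class = "fit_options")
}

THERMO_PARS <- c("t_m", "dh_m", "dcp", "m_value")
BASELINE_PARS <- c("native_intercept", "native_t_slope", "native_d_slope",
                   "unfolded_intercept", "unfolded_t_slope", "unfolded_d_slope")
THERMO_LOWER <- c(t_m = 220, dh_m = -2000, dcp = -100, m_value = 1e-3)
THERMO_UPPER <- c(t_m = 430, dh_m = -0.1, dcp = 0, m_value = 100)

#' Data-driven starting values for a global fit
#'
#' Locates the thermal transition of the lowest-denaturant series as the
#' extremum of the smoothed temperature derivative of the signal (the t_m
#' guess), and estimates baselines from straight-line fits to the first and
#' last 15% of each series, regressing per-series intercepts on denaturant
#' for the baseline denaturant slopes. The remaining thermodynamic
#' parameters start from generic values typical of a small single-domain
#' protein (dH_m -300 kJ/mol, dCp -4 kJ/mol/K, m 8 kJ/mol/M).
#'
#' @param data An [unfolding_dataset()] or list of replicate datasets of
#'   one variant.
#' @return A list with elements `thermo` and `baselines`.
#' @export
initial_guess <- function(data) {
  reps <- if (inherits(data, "unfolding_dataset")) list(data) else data
  ds <- reps[[1]]
  lev <- vapply(ds$series, `[[`, numeric(1), "denaturant")
  s0 <- ds$series[[which.min(lev)]]

  keep <- !s0$mask
  tt <- s0$temperature[keep]; yy <- s0$signal[keep]
  k <- max(7L, 2L * (length(yy) %/% 16L) + 1L)      # odd window
  sm <- stats::filter(yy, rep(1 / k, k), sides = 2)
  dv <- diff(as.numeric(sm)) / diff(tt)
  dv <- dv[is.finite(dv)]
  tmid <- (tt[-1] + tt[-length(tt)]) / 2
  tmid <- tmid[is.finite(diff(as.numeric(sm)))]
  if (!length(dv)) stop_stabfit("no_transition", "series too short to locate a transition")
  # the transition shows as a derivative excursion from the baseline slope;
  # compare the largest excursion to the noise floor of the smoothed
  # derivative (point noise estimated from second differences of the raw
  # signal, robust to broad transitions)
  dc <- abs(dv - median(dv))
  noise_hat <- sqrt(mean(diff(yy, differences = 2)^2) / 6)
  step <- median(diff(tt))
  deriv_noise <- noise_hat * sqrt(2) / (k * step)
  detected <- max(dc) > 5 * deriv_noise + 1e-8
  if (!detected) {
    stop_stabfit("no_transition",
      "no detectable unfolding transition (flat signal derivative) in the lowest-denaturant series")
  }
  t_m_guess <- tmid[which.max(dc)]

  edge_fit <- function(s, tail_end) {
    keep <- which(!s$mask)
    n <- length(keep)
    m <- max(3L, ceiling(0.15 * n))
    idx <- if (tail_end) keep[(n - m + 1L):n] else keep[1:m]
    coef(lm(s$signal[idx] ~ s$temperature[idx]))
  }
  guess_state <- function(tail_end) {
    per_rep <- lapply(reps, function(d) {
      cc <- t(vapply(d$series, edge_fit, numeric(2), tail_end = tail_end))
      dd <- vapply(d$series, `[[`, numeric(1), "denaturant")
      list(ic = cc[, 1], sl = cc[, 2], d = dd)
    })
    ic <- unlist(lapply(per_rep, `[[`, "ic"))
    sl <- unlist(lapply(per_rep, `[[`, "sl"))
    dd <- unlist(lapply(per_rep, `[[`, "d"))
    dslope <- 0
    if (length(unique(dd)) >= 2) {
      fit <- lm(ic ~ dd)
      dslope <- unname(coef(fit)[2])
      ic0 <- unname(coef(fit)[1])
    } else ic0 <- mean(ic)
    c(ic0, mean(sl), dslope)
  }
  nat <- guess_state(tail_end = FALSE)
  unf <- guess_state(tail_end = TRUE)

  list(thermo = thermo_params(t_m = min(max(t_m_guess, THERMO_LOWER["t_m"] + 1),
                                        THERMO_UPPER["t_m"] - 1),
                              dh_m = -300, dcp = -4, m_value = 8),
       baselines = baseline_params(nat[1], nat[2], nat[3], unf[1], unf[2], unf[3]))
}

# ---- internal problem assembly ---------------------------------------------

# groups: named list variant_label -> list of unfolding_dataset (replicates)
build_problem <- function(groups, options) {
  guesses <- lapply(names(groups), function(v) {
    if (!is.null(options$start) && length(groups) == 1L) options$start
    else initial_guess(groups[[v]])
  })
  names(guesses) <- names(groups)

  rows <- list()
  add <- function(par, variant, replicate, init, lower, upper) {
    rows[[length(rows) + 1L]] <<- data.frame(
      par = par, variant = variant, replicate = replicate,
      init = init, lower = lower, upper = upper, stringsAsFactors = FALSE)
  }
  if (options$share_m) {
    add("m_value", NA_character_, NA_integer_, guesses[[1]]$thermo$m_value,
        THERMO_LOWER["m_value"], THERMO_UPPER["m_value"])
  }
  for (v in names(groups)) {
    th <- guesses[[v]]$thermo
    for (p in c("t_m", "dh_m", "dcp", if (!options$share_m) "m_value")) {
      add(p, v, NA_integer_, th[[p]], THERMO_LOWER[p], THERMO_UPPER[p])
    }
    for (r in seq_along(groups[[v]])) {
      bl <- guesses[[v]]$baselines
      for (p in BASELINE_PARS) add(p, v, r, bl[[p]], -Inf, Inf)
    }
  }
  reg <- do.call(rbind, rows)
  reg$value <- reg$init
  reg$fixed <- FALSE
  for (nm in names(options$fixed)) {
    hit <- reg$par == nm
    reg$fixed[hit] <- TRUE
    reg$value[hit] <- reg$init[hit] <- options$fixed[[nm]]
  }
  if (!options$denaturant_baselines) {
    hit <- reg$par %in% c("native_d_slope", "unfolded_d_slope")
    reg$fixed[hit] <- TRUE
    reg$value[hit] <- reg$init[hit] <- 0
  }
  reg$id <- paste0(reg$par,
                   ifelse(is.na(reg$variant), "", paste0("[", reg$variant, "]")),
                   ifelse(is.na(reg$replicate), "", paste0("#", reg$replicate)))

  # flattened data blocks, one per (variant, replicate)
  blocks <- list()
  for (v in names(groups)) {
    for (r in seq_along(groups[[v]])) {
      ds <- groups[[v]][[r]]
      keep <- lapply(ds$series, function(s) !s$mask)
      blocks[[length(blocks) + 1L]] <- list(
        variant = v, replicate = r,
        temperature = unlist(Map(function(s, k) s$temperature[k], ds$series, keep)),
        denaturant = unlist(Map(function(s, k) rep(s$denaturant, sum(k)), ds$series, keep)),
        signal = unlist(Map(function(s, k) s$signal[k], ds$series, keep)))
    }
  }

  free <- which(!reg$fixed)
  thermo_at <- function(values, v) {
    pick <- function(p) {
      i <- which(reg$par == p & !is.na(reg$variant) & reg$variant == v & is.na(reg$replicate))
      if (!length(i) && p == "m_value") i <- which(reg$par == "m_value" & is.na(reg$variant))
      values[i]
    }
    structure(list(t_m = pick("t_m"), dh_m = pick("dh_m"),
                   dcp = pick("dcp"), m_value = pick("m_value")),
              class = "thermo_params")
  }
  baselines_at <- function(values, v, r) {
    out <- lapply(BASELINE_PARS, function(p) {
      values[which(reg$par == p & reg$variant == v & reg$replicate == r)]
    })
    names(out) <- BASELINE_PARS
    structure(out, class = "baseline_params")
  }
  residuals_fn <- function(theta) {
    values <- reg$value
    values[free] <- theta
    unlist(lapply(blocks, function(b) {
      th <- thermo_at(values, b$variant)
      bl <- baselines_at(values, b$variant, b$replicate)
      b$signal - predicted_signal(th, bl, b$temperature, b$denaturant)
    }))
  }
  list(reg = reg, free = free, blocks = blocks, residuals_fn = residuals_fn,
       thermo_at = thermo_at, baselines_at = baselines_at,
       n_points = sum(vapply(blocks, function(b) length(b$signal), integer(1))))
}

fit_core <- function(groups, options) {
  prob <- build_problem(groups, options)
  reg <- prob$reg
  free <- prob$free
  if (!length(free)) stop_stabfit("degenerate_fit", "no free parameters")
  theta0 <- reg$init[free]
  lower <- reg$lower[free]; upper <- reg$upper[free]

  ctrl <- minpack.lm::nls.lm.control(ftol = options$ftol, ptol = 1e-12,
                                     gtol = 0, maxiter = options$maxit)
  set.seed(options$seed)
  best <- NULL
  for (s in seq_len(max(1L, options$n_starts))) {
    th <- theta0
    if (s > 1L) {
      jit <- rnorm(length(th))
      scale <- ifelse(reg$par[free] == "t_m", 2, pmax(abs(th) * 0.05, 1e-3))
      th <- pmin(pmax(th + jit * scale, lower), upper)
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = th, lower = lower, upper = upper,
                         fn = prob$residuals_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop_stabfit("degenerate_fit", "all optimisation starts failed")

  theta_hat <- best$par
  converged <- best$info %in% c(1, 2, 3, 4, 6, 7)
  ssr <- best$deviance
  dof <- prob$n_points - length(free)
  if (dof <= 0) stop_stabfit("degenerate_fit", "fewer data points than free parameters")
  sigma2 <- ssr / dof

  J <- fd_jacobian(prob$residuals_fn, theta_hat)
  JtJ <- crossprod(J)
  cov_free <- tryCatch({
    R <- chol(JtJ)
    if (rcond(JtJ) < 1e-14) stop("near-singular")
    chol2inv(R) * sigma2
  }, error = function(e) {
    stop_stabfit("degenerate_fit",
      "singular Jacobian: baselines and transition are not jointly identifiable")
  })
  dimnames(cov_free) <- list(reg$id[free], reg$id[free])

  values <- reg$value
  values[free] <- theta_hat
  se_all <- setNames(rep(0, nrow(reg)), reg$id)
  se_all[reg$id[free]] <- sqrt(pmax(0, diag(cov_free)))

  results <- list()
  for (v in names(groups)) {
    th <- prob$thermo_at(values, v)
    bls <- lapply(seq_along(groups[[v]]), function(r) prob$baselines_at(values, v, r))
    names(bls) <- vapply(groups[[v]], function(d) as.character(d$replicate_id), character(1))

    # 4x4 thermo covariance in THERMO_PARS order; zero rows for fixed pars
    ids <- vapply(THERMO_PARS, function(p) {
      i <- which(reg$par == p & !is.na(reg$variant) & reg$variant == v & is.na(reg$replicate))
      if (!length(i)) i <- which(reg$par == p & is.na(reg$variant))
      reg$id[i]
    }, character(1))
    tc <- matrix(0, 4, 4, dimnames = list(THERMO_PARS, THERMO_PARS))
    present <- ids %in% rownames(cov_free)
    tc[present, present] <- cov_free[ids[present], ids[present], drop = FALSE]

    own <- reg$id[!is.na(reg$variant) & reg$variant == v]
    shared <- reg$id[is.na(reg$variant)]
    results[[v]] <- structure(list(
      variant_label = v,
      thermo = th,
      baselines = bls,
      standard_errors = se_all[c(shared, own)],
      thermo_covariance = tc,
      covariance = cov_free,
      residual_sd = sqrt(sigma2),
      ssr = ssr,
      dof = dof,
      n_points = prob$n_points,
      n_series = sum(vapply(groups[[v]], function(d) length(d$series), integer(1))),
      converged = converged,
      optimizer_info = best$info),
      class = "fit_result")
  }
  attr(results, "parameter_values") <- setNames(values, reg$id)
  results
}

normalize_groups <- function(data) {
  if (inherits(data, "unfolding_dataset")) data <- list(data)
  if (inherits(data[[1]], "unfolding_dataset")) {
    labs <- vapply(data, `[[`, character(1), "variant_label")
    groups <- split(data, labs)[unique(labs)]
  } else {
    groups <- data  # already a named list of replicate lists
  }
  lapply(groups, function(g) if (inherits(g, "unfolding_dataset")) list(g) else g)
}

#' Global fit of one variant's unfolding surface
#'
#' Estimates the four thermodynamic parameters and the state baselines by
#' minimising the sum of squared signal residuals over all (unmasked)
#' points of all denaturant series jointly, with Levenberg-Marquardt and
#' seeded multi-start. Replicate datasets of the same variant share the
#' thermodynamic parameters and get their own baselines. Parameter
#' covariance is `(J'J)^-1 * SSR/dof` at the optimum.
#'
#' @param data An [unfolding_dataset()], or a list of replicate datasets of
#'   one variant.
#' @param options A [fit_options()] object.
#' @return A `fit_result` with elements `thermo`, `baselines` (per
#'   replicate), `standard_errors`, `thermo_covariance` (4x4, zero
#'   rows/columns for fixed parameters), `covariance` (all free
#'   parameters), `residual_sd`, `dof`, `converged` and bookkeeping counts.
#' @examples
#' \donttest{
#' truth <- table1_parameters("wild-type")
#' ds <- simulate_dataset(truth, default_baselines(),
#'                        experiment_design(noise_frac = 0, seed = 1))
#' fit <- fit_variant(ds)
#' fit$thermo
#' }
#' @export
fit_variant <- function(data, options = fit_options()) {
  groups <- normalize_groups(data)
  if (length(groups) != 1L) {
    stop_stabfit("invalid_dataset", "fit_variant expects data from a single variant; use fit_joint")
  }
  fit_core(groups, options)[[1]]
}

#' Joint global fit of several variants, optionally with a common m-value
#'
#' All variants are fitted simultaneously. With `share_m = TRUE` in the
#' options a single m-value is estimated jointly for every variant; with
#' `fixed = list(m_value = ...)` the m-value is held at a supplied
#' consensus (e.g. the average of individually fitted m-values). Fixing or
#' sharing m removes it from the per-variant parameter count, which
#' shrinks the standard errors of the remaining parameters.
#'
#' @param data A list of [unfolding_dataset()] objects (one or more per
#'   variant; replicates are pooled by `variant_label`).
#' @param options A [fit_options()] object.
#' @return A named list of `fit_result` objects, one per variant.
#' @export
fit_joint <- function(data, options = fit_options()) {
  groups <- normalize_groups(data)
  fit_core(groups, options)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (%d series, %d points, residual SD %.3g)%s\n",
              x$variant_label, x$n_series, x$n_points, x$residual_sd,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$thermo)
  invisible(x)
}

#' Average m-value across fits
#'
#' Arithmetic mean of the denaturant m-values, used to define a consensus
#' m for re-analysis of variants whose solvent-exposed surface change is
#' assumed equal.
#'
#' @param fits A numeric vector of m-values, or a list of `fit_result`
#'   objects.
#' @return Mean m-value, kJ/mol/M.
#' @export
average_m <- function(fits) {
  if (is.list(fits)) {
    fits <- vapply(fits, function(f) {
      if (inherits(f, "fit_result")) f$thermo$m_value
      else if (is.numeric(f) && length(f) == 1L) f
      else stop_stabfit("invalid_parameter", "elements must be fit_result or numeric")
    }, numeric(1))
  }
  if (!length(fits)) stop_stabfit("empty_input", "no m-values supplied")
  mean(fits)
}

# analytic gradient of dG_f(T, D) in (t_m, dh_m, dcp, m_value)
dg_gradient <- function(thermo, temperature, denaturant) {
  tt <- temperature; tm <- thermo$t_m
  c(t_m = thermo$dh_m * tt / tm^2 + thermo$dcp * (tt / tm - 1),
    dh_m = 1 - tt / tm,
    dcp = tt - tm - tt * log(tt / tm),
    m_value = denaturant)
}

#' Delta-method standard error of a derived quantity
#'
#' First-order error propagation from the fitted parameter covariance to a
#' quantity derived from the thermodynamic parameters: the folding free
#' energy at a condition (`"dg"`), the denaturant midpoint at a
#' temperature (`"d50"`), or the apparent melting temperature at a
#' denaturant concentration (`"tm_app"`, via the implicit-function
#' theorem). Gradients are analytic.
#'
#' @param fit A `fit_result`.
#' @param quantity One of `"dg"`, `"d50"`, `"tm_app"`.
#' @param temperature Temperature (K) at which `"dg"`/`"d50"` are
#'   evaluated. Default 298 K.
#' @param denaturant Denaturant (M) for `"dg"`/`"tm_app"`. Default 0.
#' @return Standard error in the quantity's units.
#' @export
derived_quantity_error <- function(fit, quantity = c("dg", "d50", "tm_app"),
                                   temperature = 298, denaturant = 0) {
  quantity <- match.arg(quantity)
  if (is.null(fit$thermo_covariance)) {
    stop_stabfit("unavailable_error", "fit carries no parameter covariance")
  }
  th <- fit$thermo
  g <- switch(quantity,
    dg = dg_gradient(th, temperature, denaturant),
    d50 = {
      gd <- dg_gradient(th, temperature, 0)
      out <- -gd / th$m_value
      out["m_value"] <- gibbs_free_energy(th, temperature, 0) / th$m_value^2
      out
    },
    tm_app = {
      # implicit function theorem on dG(T*, D) = 0: dT*/dp = -(ddG/dp)/(ddG/dT)
      tt <- melting_temperature_at(th, denaturant)
      gd <- dg_gradient(th, tt, denaturant)
      slope <- -th$dh_m / th$t_m - th$dcp * log(tt / th$t_m)
      -gd / slope
    })
  sqrt(max(0, drop(t(g) %*% fit$thermo_covariance %*% g)))
}

#' Folding stability of a fitted variant at a reference temperature
#'
#' Evaluates the Gibbs-Helmholtz expression at the reference temperature in
#' water and propagates the fit covariance to a standard error, returning a
#' [stability_record()] ready for double-mutant-cycle arithmetic.
#'
#' @param fit A `fit_result`.
#' @param temperature Reference temperature, Kelvin (default 298).
#' @param source Provenance tag, see [stability_record()].
#' @return A `stability_record`.
#' @export
stability_from_fit <- function(fit, temperature = 298, source = "free-fit") {
  stability_record(fit$variant_label,
                   dg = gibbs_free_energy(fit$thermo, temperature, 0),
                   se = derived_quantity_error(fit, "dg", temperature = temperature),
                   source = source,
                   reference_temperature = temperature)
}
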