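#' Assemble a fitting dataset
#'
#' Bundles the observed total central-concentration series and the
#' attribute fraction series with the known dose and initial modified
#' fraction, plus the error-model scales. Pre-dose rows (time 0, drawn
#' before the bolus) and missing values are dropped.
#'
#' @param concentration Tibble (`subject`, `time_days`, `concentration`).
#' @param fractions Tibble (`subject`, `time_days`, `fraction`).
#' @param dose Administered amount, mg (known, fixes the dose/V scale).
#' @param f Initial modified fraction; a batch observable, fixed during
#'   fitting rather than estimated.
#' @param sigma_prop Proportional error SD on concentrations.
#' @param sigma_add Additive error SD on fractions.
#' @return An object of class `fit_dataset`.
#' @export
fit_dataset <- function(concentration, fractions, dose, f,
                        sigma_prop = 0.1, sigma_add = 0.02) {
  conc <- concentration %>%
    filter(.data$time_days > 0, is.finite(.data$concentration),
           .data$concentration > 0)
  frac <- fractions %>%
    filter(.data$time_days > 0, is.finite(.data$fraction))
  if (nrow(conc) == 0 && nrow(frac) == 0)
    abort("Empty fitting dataset: no usable post-dose observations.")
  if (length(unique(conc$time_days)) < 6)
    abort("A fit needs >= 6 post-dose concentration time points.")
  if (any(frac$fraction < 0 | frac$fraction > 1))
    abort("Fractions must lie in [0, 1].")
  if (!is.numeric(dose) || dose <= 0) abort("`dose` must be positive.")
  if (f < 0 || f > 1) abort("`f` must lie in [0, 1].")
  structure(list(conc = conc, frac = frac, dose = dose, f = f,
                 sigma_prop = sigma_prop, sigma_add = sigma_add),
            class = "fit_dataset")
}

# Model predictions at the union of observation times, via the spectral
# fast path (matrix form; deSolve fallback for near-defective matrices).
predict_observables <- function(params, data) {
  times <- sort(unique(c(0, data$conc$time_days, data$frac$time_days)))
  states <- solve_analytic(params, times)
  if (is.null(states)) {
    traj <- simulate_attribute(params, times, method = "lsoda")
    states <- cbind(AC0 = traj$AC0, AP0 = traj$AP0,
                    ACmod = traj$ACmod, APmod = traj$APmod)
  }
  central <- states[, "AC0"] + states[, "ACmod"]
  list(times = times, total = central / params$V,
       fraction = states[, "ACmod"] / central)
}

#' Negative log-likelihood of a parameter set
#'
#' Gaussian likelihood with proportional error on total central
#' concentrations and additive error on attribute fractions:
#' `sd = sigma_prop * observation` and `sd = sigma_add` respectively. The
#' error scales are fixed (taken from the dataset) and the proportional
#' weight is anchored on the observation (the usual 1/y^2 weighting), so
#' the objective stays finite on noise-free data and its minimum sits at
#' the truth when residuals vanish. Non-finite or non-positive
#' concentration predictions yield `+Inf` (a rejected step).
#'
#' @param params An [attribute_params()] object (already constrained).
#' @param data A [fit_dataset()].
#' @return Scalar negative log-likelihood.
#' @export
pk_objective <- function(params, data) {
  stopifnot(inherits(data, "fit_dataset"))
  pred <- tryCatch(predict_observables(params, data),
                   error = function(e) NULL)
  if (is.null(pred)) return(Inf)
  idx_c <- match(data$conc$time_days, pred$times)
  idx_f <- match(data$frac$time_days, pred$times)
  mu_c <- pred$total[idx_c]
  mu_f <- pred$fraction[idx_f]
  if (any(!is.finite(mu_c)) || any(mu_c <= 0) || any(!is.finite(mu_f)))
    return(Inf)
  sd_c <- data$sigma_prop * data$conc$concentration
  nll_c <- sum(log(sd_c) + 0.5 * ((data$conc$concentration - mu_c) / sd_c)^2 +
                 0.5 * log(2 * pi))
  nll_f <- sum(log(data$sigma_add) +
                 0.5 * ((data$frac$fraction - mu_f) / data$sigma_add)^2 +
                 0.5 * log(2 * pi))
  nll_c + nll_f
}

# theta (log scale, free parameters) -> constrained attribute_params
theta_to_params <- function(theta, attribute_kind, data) {
  free <- free_param_names(attribute_kind)
  vals <- setNames(exp(theta), free)
  p <- list(kCP = vals[["kCP"]], kPC = vals[["kPC"]],
            ktr = if ("ktr" %in% free) vals[["ktr"]] else 0,
            kcl0 = vals[["kcl0"]],
            kclmod = if ("kclmod" %in% free) vals[["kclmod"]] else
              vals[["kcl0"]],
            V = vals[["V"]], dose = data$dose, f = data$f)
  structure(p, class = "attribute_params")
}

nll_theta <- function(theta, attribute_kind, data) {
  if (any(!is.finite(theta)) || any(abs(theta) > 30)) return(Inf)
  pk_objective(theta_to_params(theta, attribute_kind, data), data)
}

#' Fit an attribute model by maximum likelihood
#'
#' Minimizes [pk_objective()] under the attribute-specific constraints
#' ([apply_constraints()]), optimizing free rates and the central volume
#' in log space (which enforces positivity). A seeded multi-start
#' Nelder-Mead search is followed by a quasi-Newton (BFGS) polish of the
#' best start; per-parameter CVs come from the inverse observed
#' information at the optimum.
#'
#' @param data A [fit_dataset()].
#' @param attribute_kind `"deamidation-like"` (ties `kclmod = kcl0`) or
#'   `"man5-like"` (forces `ktr = 0`).
#' @param n_starts Number of multi-start initializations.
#' @param seed Seed for the start dispersion.
#' @return An object of class `attr_fit`: `params` (full constrained
#'   parameter set), `estimates`, `cv_pct`, `objective`, `converged`,
#'   `attribute_kind`, `n_obs`, plus optimizer detail.
#' @export
fit_attribute <- function(data, attribute_kind = c("deamidation-like",
                                                   "man5-like"),
                          n_starts = 20, seed = 1) {
  attribute_kind <- match.arg(attribute_kind)
  stopifnot(inherits(data, "fit_dataset"))
  free <- free_param_names(attribute_kind)

  # heuristic centre: generic antibody rates; V from the earliest
  # post-dose concentration (C(0+) ~ dose / V)
  c_early <- data$conc$concentration[which.min(data$conc$time_days)]
  v0 <- max(data$dose / c_early, 1e-6)
  centre <- log(setNames(c(rep(0.1, length(free) - 1), v0),
                         free))

  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    if (i == 1) centre else centre + rnorm(length(free), sd = 0.7)
  })

  runs <- lapply(starts, function(th0) {
    tryCatch(
      optim(th0, nll_theta, attribute_kind = attribute_kind, data = data,
            method = "Nelder-Mead",
            control = list(maxit = 800, reltol = 1e-12)),
      error = function(e) NULL
    )
  })
  runs <- Filter(function(r) !is.null(r) && is.finite(r$value), runs)
  if (length(runs) == 0)
    abort(paste0("No start converged for the ", attribute_kind,
                 " fit; check the dataset and error scales."))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  polish <- tryCatch(
    optim(best$par, nll_theta, attribute_kind = attribute_kind,
          data = data, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) best
  )
  if (is.finite(polish$value) && polish$value <= best$value) best <- polish

  params <- theta_to_params(best$par, attribute_kind, data)
  estimates <- setNames(exp(best$par), free)
  fit <- structure(list(
    params = params,
    estimates = estimates,
    free_names = free,
    theta = best$par,
    objective = best$value,
    converged = best$convergence == 0,
    attribute_kind = attribute_kind,
    n_obs = nrow(data$conc) + nrow(data$frac),
    n_starts = n_starts,
    cv_pct = NULL
  ), class = "attr_fit")
  fit$cv_pct <- parameter_cv(fit, data)
  fit
}

#' Coefficients of variation of fitted parameters
#'
#' Asymptotic CVs from the inverse observed information: the Hessian of
#' the negative log-likelihood at the optimum, computed in log-parameter
#' space, gives the covariance of log-estimates; the square root of its
#' diagonal is (to first order) the relative standard deviation of each
#' estimate, reported as a percent (sd / estimate x 100). Parameters fixed
#' by constraint carry no CV of their own.
#'
#' @param fit An `attr_fit` object.
#' @param data The [fit_dataset()] it was fitted to.
#' @return Named numeric vector of CV percentages for the free parameters
#'   (`NA` with a warning when the information matrix is singular).
#' @export
parameter_cv <- function(fit, data) {
  stopifnot(inherits(fit, "attr_fit"))
  H <- tryCatch(
    optimHess(fit$theta, nll_theta, attribute_kind = fit$attribute_kind,
              data = data),
    error = function(e) NULL
  )
  bad <- setNames(rep(NA_real_, length(fit$free_names)), fit$free_names)
  if (is.null(H)) {
    warn("Hessian evaluation failed; CVs undefined.")
    return(bad)
  }
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) < 0)) {
    warn(paste0("Observed information is singular or indefinite ",
                "(condition issues at the optimum); CVs undefined."))
    return(bad)
  }
  setNames(100 * sqrt(diag(cov)), fit$free_names)
}

#' Bootstrap coefficients of variation
#'
#' Parametric-bootstrap alternative to the asymptotic CVs: synthetic
#' datasets are resimulated from the fitted model under the dataset's
#' error scales, refitted, and `sd / mean * 100` is reported per free
#' parameter.
#'
#' @param fit An `attr_fit`.
#' @param data Its [fit_dataset()].
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed.
#' @param n_starts Starts per refit (fewer than the primary fit; each
#'   refit starts near the estimate).
#' @return Named numeric vector of CV percentages.
#' @export
bootstrap_cv <- function(fit, data, n_boot = 20, seed = 1, n_starts = 3) {
  stopifnot(inherits(fit, "attr_fit"))
  pred <- predict_observables(fit$params, data)
  idx_c <- match(data$conc$time_days, pred$times)
  idx_f <- match(data$frac$time_days, pred$times)
  set.seed(seed)
  boots <- purrr::map(seq_len(n_boot), function(b) {
    d <- data
    mu_c <- pred$total[idx_c]
    d$conc$concentration <- pmax(
      mu_c * (1 + rnorm(length(mu_c), sd = data$sigma_prop)), 1e-12)
    mu_f <- pred$fraction[idx_f]
    d$frac$fraction <- pmin(pmax(
      mu_f + rnorm(length(mu_f), sd = data$sigma_add), 0), 1)
    refit <- tryCatch(
      fit_attribute(d, fit$attribute_kind, n_starts = n_starts,
                    seed = seed + b),
      error = function(e) NULL
    )
    if (is.null(refit)) NULL else refit$estimates
  })
  boots <- Filter(Negate(is.null), boots)
  if (length(boots) < 2) {
    warn("Too few successful bootstrap refits; CVs undefined.")
    return(setNames(rep(NA_real_, length(fit$free_names)),
                    fit$free_names))
  }
  mat <- do.call(rbind, boots)
  apply(mat, 2, function(x) 100 * sd(x) / mean(x))
}

#' @export
print.attr_fit <- function(x, ...) {
  cat("<attr_fit> ", x$attribute_kind, "\n", sep = "")
  tab <- tidy(x)
  cat(sprintf("  %-8s %10s %12s\n", "param", "estimate", "CV%"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-8s %10.4g %12s\n", tab$term[i], tab$estimate[i],
                ifelse(tab$constrained[i], "(fixed)",
                       ifelse(is.na(tab$cv_pct[i]), "NA",
                              sprintf("%.1f", tab$cv_pct[i])))))
  }
  cat(sprintf("  -logLik %.4f, %s, %d obs\n", x$objective,
              ifelse(x$converged, "converged", "NOT converged"), x$n_obs))
  invisible(x)
}

#' Tidy a fitted attribute model
#'
#' One row per model parameter (free and constraint-tied), with the point
#' estimate and asymptotic CV percent; constrained parameters carry no CV.
#'
#' @param x An `attr_fit`.
#' @param ... Unused.
#' @return A tibble (`term`, `estimate`, `cv_pct`, `constrained`).
#' @export
tidy.attr_fit <- function(x, ...) {
  all_names <- c("kCP", "kPC", "ktr", "kcl0", "kclmod", "V")
  tibble(
    term = all_names,
    estimate = vapply(all_names, function(nm) x$params[[nm]], numeric(1)),
    cv_pct = vapply(all_names, function(nm) {
      if (nm %in% x$free_names) x$cv_pct[[nm]] else NA_real_
    }, numeric(1)),
    constrained = !all_names %in% x$free_names
  )
}

#' One-line summary of a fitted attribute model
#'
#' @param x An `attr_fit`.
#' @param ... Unused.
#' @return A one-row tibble (`attribute_kind`, `objective`, `converged`,
#'   `n_obs`, `n_starts`, `n_free`).
#' @export
glance.attr_fit <- function(x, ...) {
  tibble(attribute_kind = x$attribute_kind, objective = x$objective,
         converged = x$converged, n_obs = x$n_obs,
         n_starts = x$n_starts, n_free = length(x$free_names))
}
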