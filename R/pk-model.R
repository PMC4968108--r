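#' Parameter set for the two-compartment original/modified-form model
#'
#' The model tracks a therapeutic antibody as two molecular forms — the
#' original form and a form carrying one quality attribute (e.g., a
#' deamidated Fc site or the Man5 glycoform) — each distributed over a
#' central (plasma) and a peripheral (tissue) compartment. All transitions
#' are first order.
#'
#' @param kCP Central-to-peripheral distribution rate, 1/day.
#' @param kPC Peripheral-to-central distribution rate, 1/day (shared by both
#'   forms, as is `kCP`).
#' @param ktr In-circulation conversion rate from the original to the
#'   modified form, 1/day. Acts in both compartments.
#' @param kcl0 Clearance rate of the original form from the central
#'   compartment, 1/day.
#' @param kclmod Clearance rate of the modified form, 1/day.
#' @param V Central distribution volume, L.
#' @param dose Administered amount (IV bolus), mg. With `V` in litres the
#'   central concentrations come out in µg/mL numerically.
#' @param f Initial modified fraction of the dose, in `[0, 1]`. `100 * f` is
#'   the attribute's "initial level" in percent.
#'
#' @return An object of class `attribute_params` (a named list).
#' @examples
#' attribute_params(kCP = 0.17, kPC = 0.093, ktr = 0.01,
#'                  kcl0 = 0.13, kclmod = 0.13, V = 3.34, f = 0.056)
#' @export
attribute_params <- function(kCP, kPC, ktr, kcl0, kclmod, V, dose = 1, f = 0) {
  p <- list(kCP = kCP, kPC = kPC, ktr = ktr, kcl0 = kcl0,
            kclmod = kclmod, V = V, dose = dose, f = f)
  for (nm in c("kCP", "kPC", "ktr", "kcl0", "kclmod")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort(paste0("`", nm, "` must be a single non-negative finite number."))
  }
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V) || V <= 0)
    abort("`V` must be a single positive number.")
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    abort("`dose` must be a single non-negative number.")
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    abort("`f` must lie in [0, 1].")
  structure(p, class = "attribute_params")
}

#' @export
print.attribute_params <- function(x, ...) {
  cat("<attribute_params>\n")
  cat(sprintf("  kCP=%.4g kPC=%.4g ktr=%.4g kcl0=%.4g kclmod=%.4g 1/d\n",
              x$kCP, x$kPC, x$ktr, x$kcl0, x$kclmod))
  cat(sprintf("  V=%.4g L, dose=%.4g mg, initial level=%.3g%%\n",
              x$V, x$dose, 100 * x$f))
  invisible(x)
}

#' Reference parameter sets for the two modeled attributes
#'
#' Best-fit rate constants and central volume for the Fc deamidation and
#' Man5 glycoform models of the MAB2 clinical study. The deamidation model
#' assumes equal clearance of both forms; the Man5 model assumes no
#' in-circulation formation (`ktr = 0`) and faster clearance of the
#' glycoform.
#'
#' @param attribute `"deamidation"` or `"man5"`.
#' @param dose,f Passed through to [attribute_params()].
#' @return An `attribute_params` object.
#' @examples
#' reference_params("man5", f = 0.03)
#' @export
reference_params <- function(attribute = c("deamidation", "man5"),
                             dose = 1, f = 0) {
  attribute <- match.arg(attribute)
  if (attribute == "deamidation") {
    attribute_params(kCP = 0.17, kPC = 0.093, ktr = 0.01,
                     kcl0 = 0.13, kclmod = 0.13, V = 3.34,
                     dose = dose, f = f)
  } else {
    attribute_params(kCP = 0.18, kPC = 0.096, ktr = 0,
                     kcl0 = 0.127, kclmod = 0.295, V = 3.32,
                     dose = dose, f = f)
  }
}

#' Time derivatives of the four model amounts
#'
#' Pure right-hand side of the coupled ODE system. State order is
#' `(AC0, AP0, ACmod, APmod)`: original form central/peripheral, then
#' modified form central/peripheral. Conversion (`ktr`) drains the original
#' form in both compartments and feeds the modified form in the matching
#' compartment; clearance acts only on the central compartment.
#'
#' @param state Numeric 4-vector of amounts.
#' @param params An [attribute_params()] object.
#' @return Numeric 4-vector of d(amount)/dt, 1/day scaled.
#' @examples
#' p <- reference_params("deamidation")
#' pk_rhs(c(1, 0, 0, 0), p)  # first component is -(kCP + ktr + kcl0)
#' @export
pk_rhs <- function(state, params) {
  stopifnot(length(state) == 4L, all(is.finite(state)))
  AC0 <- state[[1]]; AP0 <- state[[2]]
  ACmod <- state[[3]]; APmod <- state[[4]]
  with(params, c(
    -(kCP + ktr + kcl0) * AC0 + kPC * AP0,
    -(kPC + ktr) * AP0 + kCP * AC0,
    -(kCP + kclmod) * ACmod + ktr * AC0 + kPC * APmod,
    -kPC * APmod + ktr * AP0 + kCP * ACmod
  ))
}

# 4x4 rate matrix of the linear system, state order (AC0, AP0, ACmod, APmod)
pk_rate_matrix <- function(params) {
  with(params, matrix(c(
    -(kCP + ktr + kcl0), kPC,          0,               0,
    kCP,                -(kPC + ktr),  0,               0,
    ktr,                 0,           -(kCP + kclmod),  kPC,
    0,                   ktr,          kCP,            -kPC
  ), nrow = 4, byrow = TRUE))
}

pk_initial_state <- function(params) {
  c(AC0 = (1 - params$f) * params$dose, AP0 = 0,
    ACmod = params$f * params$dose, APmod = 0)
}

# Analytic solution by eigen-decomposition; NULL if the matrix is too close
# to defective for a reliable spectral solve.
solve_analytic <- function(params, times) {
  A <- pk_rate_matrix(params)
  eg <- eigen(A)
  if (any(abs(Im(eg$values)) > 1e-12)) return(NULL)
  Vm <- Re(eg$vectors)
  lam <- Re(eg$values)
  x0 <- pk_initial_state(params)
  cf <- tryCatch(solve(Vm, x0), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  # reconstruction check guards near-defective cases
  if (max(abs(Vm %*% cf - x0)) > 1e-8 * max(1, sum(abs(x0)))) return(NULL)
  E <- exp(outer(times, lam))           # n_times x 4
  out <- t(Vm %*% (t(E) * cf))          # n_times x 4 states
  colnames(out) <- c("AC0", "AP0", "ACmod", "APmod")
  out
}

#' Simulate the model over a time grid
#'
#' Integrates the four coupled amount equations from the IV-bolus initial
#' condition `AC0(0) = (1 - f) * dose`, `ACmod(0) = f * dose`,
#' `AP0(0) = APmod(0) = 0` and derives central concentrations
#' `C0 = AC0 / V`, `Cmod = ACmod / V`.
#'
#' The default route is `deSolve::lsoda` at rtol `1e-8` /
#' atol `1e-12 * dose`. Because the system is linear and time-invariant an
#' exact spectral solution is also available (`method = "analytic"`); it is
#' used internally where many evaluations are needed and falls back to the
#' integrator if the rate matrix is nearly defective.
#'
#' @param params An [attribute_params()] object.
#' @param times Increasing numeric vector of times in days, starting at 0.
#' @param method `"lsoda"` (default) or `"analytic"`.
#' @return A tibble of class `pk_trajectory` with columns `time_days`,
#'   `AC0`, `AP0`, `ACmod`, `APmod`, `C0`, `Cmod`.
#' @examples
#' traj <- simulate_attribute(reference_params("deamidation", f = 0.056),
#'                            times = 0:42)
#' head(traj)
#' @export
simulate_attribute <- function(params, times,
                               method = c("lsoda", "analytic")) {
  method <- match.arg(method)
  if (!inherits(params, "attribute_params"))
    abort("`params` must be an `attribute_params` object.")
  if (length(times) < 1L || any(diff(times) <= 0))
    abort("`times` must be strictly increasing.")
  if (times[[1]] != 0)
    abort("`times` must start at 0 (time of the IV bolus).")

  states <- if (method == "analytic") solve_analytic(params, times) else NULL
  if (is.null(states)) {
    x0 <- pk_initial_state(params)
    sol <- tryCatch(
      deSolve::lsoda(
        y = x0, times = times,
        func = function(t, y, p) list(pk_rhs(y, p)),
        parms = params,
        rtol = 1e-8, atol = 1e-12 * max(params$dose, 1)
      ),
      error = function(e) abort(paste0(
        "ODE solver failed: ", conditionMessage(e),
        "\nparams: ", paste(sprintf("%s=%.4g", names(unclass(params)),
                                    unlist(params)), collapse = ", ")))
    )
    states <- sol[, c("AC0", "AP0", "ACmod", "APmod"), drop = FALSE]
  }
  out <- tibble(
    time_days = times,
    AC0 = states[, "AC0"], AP0 = states[, "AP0"],
    ACmod = states[, "ACmod"], APmod = states[, "APmod"]
  ) %>%
    mutate(C0 = .data$AC0 / params$V, Cmod = .data$ACmod / params$V)
  class(out) <- c("pk_trajectory", class(out))
  attr(out, "params") <- params
  out
}

#' Eigen-rates and amplitudes of the two-compartment submodel
#'
#' With no in-circulation conversion a single form follows the standard
#' two-compartment bolus model; its central unit-bolus profile is the
#' biexponential `A * exp(-lambda1 * t) + B * exp(-lambda2 * t)`. This
#' closed form serves as an independent oracle for the integrator.
#'
#' @param kCP,kPC,kcl Non-negative first-order rates, 1/day.
#' @return A list with `lambda1 > lambda2` (1/day), amplitudes `A`, `B`
#'   (`A + B = 1`), and `degenerate` flag set when the two eigen-rates
#'   coincide (the biexponential form then breaks down).
#' @examples
#' biexp_coefficients(kCP = 0.18, kPC = 0.096, kcl = 0.127)
#' @export
biexp_coefficients <- function(kCP, kPC, kcl) {
  stopifnot(kCP >= 0, kPC >= 0, kcl >= 0)
  a <- kCP + kcl
  b <- kPC
  disc <- (a + b)^2 - 4 * b * kcl
  if (abs(disc) < 1e-14) {
    warn("Repeated eigen-rate: biexponential form is degenerate.")
    lam <- (a + b) / 2
    return(list(lambda1 = lam, lambda2 = lam, A = NA_real_, B = NA_real_,
                degenerate = TRUE))
  }
  s <- sqrt(disc)
  lambda1 <- (a + b + s) / 2
  lambda2 <- (a + b - s) / 2
  A <- (lambda1 - kPC) / (lambda1 - lambda2)
  list(lambda1 = lambda1, lambda2 = lambda2, A = A, B = 1 - A,
       degenerate = FALSE)
}

#' Central unit-bolus concentration profile from biexponential coefficients
#'
#' @param bx Result of [biexp_coefficients()].
#' @param times Numeric vector of times, days.
#' @return Central amounts for a unit bolus (dimensionless fractions).
#' @export
biexp_profile <- function(bx, times) {
  if (isTRUE(bx$degenerate))
    abort("Degenerate (repeated eigen-rate) profile not representable.")
  bx$A * exp(-bx$lambda1 * times) + bx$B * exp(-bx$lambda2 * times)
}

# Windowed AUC of the unit-bolus central biexponential, in day units.
biexp_auc <- function(bx, t_end, t_start = 0) {
  seg <- function(amp, lam) {
    if (lam == 0) amp * (t_end - t_start)
    else amp * (exp(-lam * t_start) - exp(-lam * t_end)) / lam
  }
  seg(bx$A, bx$lambda1) + seg(bx$B, bx$lambda2)
}

#' Closed-form central modified fraction under equal clearance
#'
#' When the modified form clears at the same rate as the original
#' (`kclmod = kcl0`, the deamidation assumption), the modified share of the
#' central amount follows `1 - (1 - f) * exp(-ktr * t)` exactly, independent
#' of the distribution and clearance rates.
#'
#' @param f Initial modified fraction.
#' @param ktr Conversion rate, 1/day.
#' @param times Times in days.
#' @return Modified fraction at each time.
#' @examples
#' equal_clearance_fraction(f = 0, ktr = 0.01, times = 42)  # 0.34297
#' @export
equal_clearance_fraction <- function(f, ktr, times) {
  1 - (1 - f) * exp(-ktr * times)
}

#' Apply attribute-specific model constraints
#'
#' Two attribute kinds are supported. `"deamidation-like"`: the modification
#' does not alter clearance, so `kclmod` is tied to `kcl0`. `"man5-like"`:
#' the modification does not form in circulation, so `ktr` is forced to 0.
#' Distribution rates `kCP`/`kPC` are shared between forms in both kinds.
#'
#' @param params An [attribute_params()] object.
#' @param attribute_kind `"deamidation-like"` or `"man5-like"`.
#' @return A constrained `attribute_params` object.
#' @examples
#' p <- attribute_params(0.17, 0.093, 0.01, 0.13, kclmod = 0.2, V = 3.34)
#' apply_constraints(p, "deamidation-like")$kclmod  # 0.13
#' @export
apply_constraints <- function(params,
                              attribute_kind = c("deamidation-like",
                                                 "man5-like")) {
  attribute_kind <- match.arg(attribute_kind)
  if (attribute_kind == "deamidation-like") {
    params$kclmod <- params$kcl0
  } else {
    params$ktr <- 0
  }
  params
}

# Free (estimated) parameter names under each constraint set.
free_param_names <- function(attribute_kind) {
  switch(attribute_kind,
    "deamidation-like" = c("kCP", "kPC", "ktr", "kcl0", "V"),
    "man5-like" = c("kCP", "kPC", "kcl0", "kclmod", "V"),
    abort(paste0("Unknown attribute kind: ", attribute_kind))
  )
}
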