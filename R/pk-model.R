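#' Structural one-compartment oral PK parameters
#'
#' Bundles the three apparent parameters of the one-compartment model with
#' first-order absorption and elimination: absorption rate constant `ka`
#' (1/h), apparent volume of distribution `v` (Vd/F, L) and apparent
#' clearance `cl` (CL/F, L/h). Oral bioavailability F is unidentifiable
#' after oral dosing and is folded into `v` and `cl`.
#'
#' @param ka Absorption rate constant (1/h), > 0.
#' @param v Apparent volume of distribution Vd/F (L), > 0.
#' @param cl Apparent clearance CL/F (L/h), > 0.
#'
#' @return An object of class `structural_params` with fields `ka`, `v`,
#'   `cl` and the derived elimination rate constant `ke = cl/v` (1/h) and
#'   half-life `t_half = log(2)/ke` (h).
#' @examples
#' p <- structural_params(ka = 0.8, v = 386.35, cl = 5.316)
#' p$t_half
#' @export
structural_params <- function(ka, v, cl) {
  for (nm in c("ka", "v", "cl")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("'%s' must be a single finite positive number", nm))
    }
  }
  ke <- cl / v
  structure(
    list(ka = ka, v = v, cl = cl, ke = ke, t_half = log(2) / ke),
    class = "structural_params"
  )
}

#' @export
print.structural_params <- function(x, ...) {
  cat("One-compartment oral PK parameters\n")
  cat(sprintf("  ka   %.4g 1/h\n  Vd/F %.4g L\n  CL/F %.4g L/h\n", x$ka, x$v, x$cl))
  cat(sprintf("  ke   %.4g 1/h (t1/2 = %.3g h)\n", x$ke, x$t_half))
  invisible(x)
}

#' Dosing regimen
#'
#' @param dose Amount per administration (mg), >= 0.
#' @param tau Dosing interval (h), > 0. Once-daily dosing is `tau = 24`.
#' @param n_doses Number of administrations, or `Inf` for steady state.
#'
#' @return An object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(300, 24)          # 300 mg once daily, at steady state
#' dosing_regimen(300, 24, n_doses = 5)
#' @export
dosing_regimen <- function(dose, tau = 24, n_doses = Inf) {
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0) {
    stop("'dose' must be a single finite number >= 0")
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("'tau' must be a single finite positive number")
  }
  if (!is.numeric(n_doses) || length(n_doses) != 1L || is.na(n_doses) ||
      (is.finite(n_doses) && (n_doses < 1 || n_doses != floor(n_doses)))) {
    stop("'n_doses' must be a positive integer or Inf (steady state)")
  }
  structure(list(dose = dose, tau = tau, n_doses = n_doses),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  ss <- if (is.infinite(x$n_doses)) "steady state" else sprintf("%d doses", x$n_doses)
  cat(sprintf("%g mg every %g h (%s)\n", x$dose, x$tau, ss))
  invisible(x)
}

## Bateman terms, vectorised over t and over parameters.  The ka ~= ke
## degeneracy is handled by the analytic limit D*ka*t*exp(-ka*t)/V, switched
## on a relative gap of 1e-6 to avoid catastrophic cancellation.
.bateman <- function(t, dose, ka, v, cl) {
  n <- max(length(t), length(dose), length(ka), length(v), length(cl))
  t <- rep_len(t, n); dose <- rep_len(dose, n)
  ka <- rep_len(ka, n); v <- rep_len(v, n); cl <- rep_len(cl, n)
  ke <- cl / v
  degen <- abs(ka - ke) / ke < 1e-6
  out <- numeric(n)
  reg <- !degen
  out[reg] <- dose[reg] * ka[reg] / (v[reg] * (ka[reg] - ke[reg])) *
    (exp(-ke[reg] * t[reg]) - exp(-ka[reg] * t[reg]))
  out[degen] <- dose[degen] * ka[degen] * t[degen] *
    exp(-ka[degen] * t[degen]) / v[degen]
  pmax(out, 0)
}

#' Concentration after a single oral dose
#'
#' Bateman solution of the two-state linear system gut depot -> central
#' compartment: `C(t) = D*ka / (V*(ka - ke)) * (exp(-ke*t) - exp(-ka*t))`.
#' When `ka` is numerically equal to `ke` the analytic limit
#' `D*ka*t*exp(-ka*t)/V` is used instead.
#'
#' @param t Time since the dose (h), vectorised, >= 0.
#' @param dose Dose amount (mg).
#' @param p A [structural_params()] object.
#'
#' @return Concentration (mg/L), same length as `t`.
#' @examples
#' p <- structural_params(0.8, 386.35, 5.316)
#' conc_single_dose(24, 300, p)
#' @export
conc_single_dose <- function(t, dose, p) {
  stopifnot(inherits(p, "structural_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be finite and >= 0")
  }
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0) {
    stop("'dose' must be a single finite number >= 0")
  }
  .bateman(t, dose, p$ka, p$v, p$cl)
}

## Geometric accumulation sums for n doses at interval tau, evaluated at
## time-since-last-dose tsld:  sum_{k=0}^{n-1} exp(-r*(tsld + k*tau))
##   = exp(-r*tsld) * (1 - exp(-n*r*tau)) / (1 - exp(-r*tau))
## with n = Inf giving the steady-state factor 1/(1 - exp(-r*tau)).
.accum <- function(r, tsld, tau, n) {
  acc <- ifelse(is.infinite(n), 1 / (1 - exp(-r * tau)),
                (1 - exp(-n * r * tau)) / (1 - exp(-r * tau)))
  exp(-r * tsld) * acc
}

#' Concentration under repeated dosing (superposition)
#'
#' Sum of the single-dose solution over administrations at `0, tau, 2*tau,
#' ...`. For a steady-state regimen (`n_doses = Inf`) the geometric-series
#' accumulation is evaluated in closed form, which is exact.
#'
#' @param t Time since the first dose (h), vectorised. For steady-state
#'   regimens `t` is interpreted modulo `tau` within the dosing interval.
#' @param regimen A [dosing_regimen()].
#' @param p A [structural_params()].
#'
#' @return Concentration (mg/L).
#' @export
conc_multidose <- function(t, regimen, p) {
  stopifnot(inherits(regimen, "dosing_regimen"), inherits(p, "structural_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be finite and >= 0")
  }
  tau <- regimen$tau
  ke <- p$ke
  if (is.infinite(regimen$n_doses)) {
    tsld <- t %% tau
    n_given <- Inf
  } else {
    # doses at k*tau for k = 0 .. n_doses-1; only doses at or before t count
    n_given <- pmin(floor(t / tau) + 1, regimen$n_doses)
    tsld <- t - (n_given - 1) * tau
  }
  if (abs(p$ka - ke) / ke < 1e-6) {
    # limit form: superpose explicitly (finite windows only matter over
    # ~10 half-lives; cap the sum there for steady state)
    n_eff <- if (is.infinite(regimen$n_doses)) ceiling(10 * p$t_half / tau) else NA
    return(vapply(seq_along(t), function(i) {
      ni <- if (is.infinite(n_given)) n_eff else n_given[i]
      tt <- tsld[i] + tau * (seq_len(ni) - 1)
      sum(.bateman(tt, regimen$dose, p$ka, p$v, p$cl))
    }, numeric(1)))
  }
  amp <- regimen$dose * p$ka / (p$v * (p$ka - ke))
  pmax(amp * (.accum(ke, tsld, tau, n_given) - .accum(p$ka, tsld, tau, n_given)), 0)
}

#' Steady-state trough concentration
#'
#' Concentration immediately before the next administration at steady
#' state, computed from the analytic accumulation factor (exact, not a
#' truncated superposition).
#'
#' @param regimen A [dosing_regimen()]; `n_doses` is ignored (steady state
#'   is assumed).
#' @param p A [structural_params()].
#'
#' @return Trough concentration (mg/L).
#' @examples
#' ss_trough(dosing_regimen(300, 24), structural_params(0.8, 386.35, 5.316))
#' @export
ss_trough <- function(regimen, p) {
  stopifnot(inherits(regimen, "dosing_regimen"), inherits(p, "structural_params"))
  ss <- dosing_regimen(regimen$dose, regimen$tau, Inf)
  conc_multidose(regimen$tau, ss, p)
}

#' Steady-state 24-h AUC
#'
#' Area under the concentration-time curve over one dosing interval at
#' steady state. For a linear model this equals `dose / cl` exactly,
#' independent of `ka` and `v`.
#'
#' @param dose Dose per 24-h interval (mg).
#' @param p A [structural_params()].
#'
#' @return AUC over one interval (mg*h/L).
#' @export
ss_auc24 <- function(dose, p) {
  stopifnot(inherits(p, "structural_params"))
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0)) {
    stop("'dose' must be finite and >= 0")
  }
  dose / p$cl
}

#' Solve the absorption rate constant from t_max and half-life
#'
#' Inverts the time-to-peak relation of the one-compartment oral model,
#' `t_max = (log(ka) - log(ke)) / (ka - ke)` with `ke = log(2)/t_half`,
#' for `ka` on the branch `ka > ke`. This is how a fixed absorption
#' constant can be derived from summary kinetics (half-life and t_max)
#' when absorption-phase samples are unavailable.
#'
#' On the `ka > ke` branch, `t_max` decreases from its supremum `1/ke`
#' (attained in the limit `ka -> ke`) towards 0 as `ka` grows, so a root
#' exists iff `0 < t_max < 1/ke`.
#'
#' @param t_half Elimination half-life (h), > 0.
#' @param t_max Time of maximum concentration (h), > 0.
#' @param ka_max Upper cap for the root search (1/h); values of `t_max`
#'   small enough to push `ka` above the cap are rejected.
#'
#' @return The absorption rate constant `ka` (1/h), with `ka > ke`.
#' @examples
#' solve_ka(t_half = 30, t_max = 4.5626)  # ~0.8 1/h
#' @export
solve_ka <- function(t_half, t_max, ka_max = 100) {
  if (!is.numeric(t_half) || length(t_half) != 1L || !is.finite(t_half) || t_half <= 0) {
    stop("'t_half' must be a single finite positive number")
  }
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) || t_max <= 0) {
    stop("'t_max' must be a single finite positive number")
  }
  ke <- log(2) / t_half
  tmax_fun <- function(ka) (log(ka) - log(ke)) / (ka - ke)
  sup <- 1 / ke                      # t_max as ka -> ke+
  lo <- ke * (1 + 1e-9)
  floor_tmax <- tmax_fun(ka_max)
  if (t_max >= sup || t_max <= floor_tmax) {
    stop(sprintf(
      "no root with ka in (ke, %g]: feasible t_max range is (%.4g, %.4g) h for t_half = %g h",
      ka_max, floor_tmax, sup, t_half
    ))
  }
  root <- stats::uniroot(function(ka) tmax_fun(ka) - t_max,
                         lower = lo, upper = ka_max, tol = 1e-12)
  ka <- root$root
  # polish: the relation must be reproduced to <= 1e-8 relative
  if (abs(tmax_fun(ka) - t_max) / t_max > 1e-8) {
    stop("root refinement failed to reach 1e-8 relative accuracy")
  }
  ka
}
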