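#' Population PK parameters of the final posaconazole model
#'
#' Fixed effects, the age covariate coefficient on apparent clearance,
#' inter-individual variability (IIV) standard deviations and the
#' proportional residual-error magnitude of the one-compartment
#' posaconazole model in lung-transplant recipients. Defaults are the
#' final-model estimates: `ka_pop` 0.8 1/h (fixed, derived from summary
#' kinetics), `v_pop` 386.35 L, `cl_pop` 8.8 L/h at the covariate
#' reference (age 0, uncentered), `beta_cl_age` -0.009 per year on
#' log CL/F, IIV SDs 3.43 / 0.45 / 0.36 for ka / Vd/F / CL/F, and
#' proportional error 0.29.
#'
#' The individual-parameter link is log-normal:
#' \deqn{\log ka_i = \log ka_{pop} + \eta_{ka,i}}
#' \deqn{\log V_i  = \log V_{pop}  + \eta_{V,i}}
#' \deqn{\log CL_i = \log CL_{pop} + \beta_{age} \cdot age_i + \eta_{CL,i}}
#' with independent \eqn{\eta \sim N(0, \omega^2)}. Age enters uncentered,
#' so `cl_pop` is the intercept at age 0 and the typical 56-year-old has
#' CL/F of about 5.3 L/h.
#'
#' @param ka_pop Typical absorption rate constant (1/h).
#' @param v_pop Typical apparent volume Vd/F (L).
#' @param cl_pop Typical apparent clearance CL/F (L/h) at age 0.
#' @param beta_cl_age Age coefficient on log CL/F (1/year).
#' @param omega_ka,omega_v,omega_cl IIV standard deviations (log scale).
#' @param b_prop Proportional residual error magnitude.
#'
#' @return An object of class `population_parameters`.
#' @examples
#' population_parameters()
#' @export
population_parameters <- function(ka_pop = 0.8, v_pop = 386.35, cl_pop = 8.8,
                                  beta_cl_age = -0.009,
                                  omega_ka = 3.43, omega_v = 0.45,
                                  omega_cl = 0.36, b_prop = 0.29) {
  for (nm in c("ka_pop", "v_pop", "cl_pop")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("'%s' must be a single finite positive number", nm))
    }
  }
  for (nm in c("omega_ka", "omega_v", "omega_cl", "b_prop")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
      stop(sprintf("'%s' must be a single finite number >= 0", nm))
    }
  }
  if (!is.numeric(beta_cl_age) || length(beta_cl_age) != 1L || !is.finite(beta_cl_age)) {
    stop("'beta_cl_age' must be a single finite number")
  }
  structure(
    list(ka_pop = ka_pop, v_pop = v_pop, cl_pop = cl_pop,
         beta_cl_age = beta_cl_age,
         omega_ka = omega_ka, omega_v = omega_v, omega_cl = omega_cl,
         b_prop = b_prop),
    class = "population_parameters"
  )
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("Population PK parameters (one-compartment oral, log-normal IIV)\n")
  cat("Fixed effects\n")
  cat(sprintf("  ka_pop       %8.4g 1/h\n", x$ka_pop))
  cat(sprintf("  Vd/F_pop     %8.4g L\n", x$v_pop))
  cat(sprintf("  CL/F_pop     %8.4g L/h (at age 0)\n", x$cl_pop))
  cat(sprintf("  beta_CL,age  %8.4g per year (log scale)\n", x$beta_cl_age))
  cat("Random-effect SDs\n")
  cat(sprintf("  omega_ka %.4g   omega_V %.4g   omega_CL %.4g\n",
              x$omega_ka, x$omega_v, x$omega_cl))
  cat(sprintf("Proportional residual error  %.4g\n", x$b_prop))
  invisible(x)
}

#' Load or save population parameters as a YAML/JSON-style config
#'
#' The config maps parameter names (as in [population_parameters()]) to
#' values; missing keys keep the default-model values.
#'
#' @param path Path to a YAML file.
#' @return For `read_population_parameters`, a `population_parameters`
#'   object; for `write_population_parameters`, `path` invisibly.
#' @export
read_population_parameters <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(population_parameters))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown population parameter(s) in config: ", paste(extra, collapse = ", "))
  }
  do.call(population_parameters, cfg)
}

#' @rdname read_population_parameters
#' @param pop A `population_parameters` object.
#' @export
write_population_parameters <- function(pop, path) {
  stopifnot(inherits(pop, "population_parameters"))
  yaml::write_yaml(unclass(pop), path)
  invisible(path)
}

#' Map population parameters and covariates to individual PK parameters
#'
#' Applies the log-normal link: `ka = ka_pop*exp(eta_ka)`,
#' `v = v_pop*exp(eta_v)`, `cl = cl_pop*exp(beta_cl_age*age + eta_cl)`.
#'
#' @param pop A [population_parameters()] object.
#' @param covariates A list or one-row data frame with at least `age`
#'   (years).
#' @param eta Named numeric vector or list with `eta_ka`, `eta_v`,
#'   `eta_cl` (log-scale deviations; default all 0 gives the typical
#'   individual).
#'
#' @return A [structural_params()] object with attributes `covariates`
#'   and `eta` recording its provenance.
#' @examples
#' pop <- population_parameters()
#' individual_params(pop, list(age = 56))  # typical 56-year-old
#' @export
individual_params <- function(pop, covariates,
                              eta = c(eta_ka = 0, eta_v = 0, eta_cl = 0)) {
  stopifnot(inherits(pop, "population_parameters"))
  age <- covariates$age
  if (is.null(age) || !is.finite(age)) stop("'covariates$age' (years) is required")
  eta <- as.list(eta)
  for (nm in c("eta_ka", "eta_v", "eta_cl")) {
    if (is.null(eta[[nm]])) eta[[nm]] <- 0
    if (!is.finite(eta[[nm]])) stop(sprintf("'%s' must be finite", nm))
  }
  p <- structural_params(
    ka = pop$ka_pop * exp(eta$eta_ka),
    v  = pop$v_pop * exp(eta$eta_v),
    cl = pop$cl_pop * exp(pop$beta_cl_age * age + eta$eta_cl)
  )
  attr(p, "covariates") <- covariates
  attr(p, "eta") <- eta
  p
}

#' Draw an individual from the population
#'
#' Samples independent random effects `eta ~ N(0, omega^2)` for each
#' parameter and applies [individual_params()]. With all `omega` equal to
#' 0 this reduces to the typical individual.
#'
#' @inheritParams individual_params
#' @param eta_cap If finite, truncate each `|eta|` at `eta_cap * omega`
#'   (rejection-free clamping). Default `Inf` (no cap), matching the
#'   reported model.
#'
#' @return A [structural_params()] object (see [individual_params()]).
#' @export
sample_individual <- function(pop, covariates, eta_cap = Inf) {
  stopifnot(inherits(pop, "population_parameters"))
  om <- c(pop$omega_ka, pop$omega_v, pop$omega_cl)
  eta <- stats::rnorm(3, 0, om)
  if (is.finite(eta_cap)) eta <- pmin(pmax(eta, -eta_cap * om), eta_cap * om)
  individual_params(pop, covariates,
                    eta = c(eta_ka = eta[1], eta_v = eta[2], eta_cl = eta[3]))
}

#' Apply the proportional residual-error model
#'
#' Observation model `y = c_pred * (1 + b_prop * eps)` with standard
#' normal `eps`, floored at 0 since concentrations are physical
#' quantities.
#'
#' @param c_pred Model-predicted concentration(s), mg/L, >= 0.
#' @param b_prop Proportional error magnitude.
#' @param eps Standard normal draw(s); defaults to fresh draws.
#'
#' @return Simulated observed concentration(s), mg/L.
#' @export
apply_residual_error <- function(c_pred, b_prop,
                                 eps = stats::rnorm(length(c_pred))) {
  if (any(!is.finite(c_pred)) || any(c_pred < 0)) {
    stop("'c_pred' must be finite and >= 0")
  }
  pmax(c_pred * (1 + b_prop * eps), 0)
}
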