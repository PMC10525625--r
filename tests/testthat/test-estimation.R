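test_that("OFV equals the closed-form density when all IIV is zero", {
  pop0 <- population_parameters(omega_ka = 0, omega_v = 0, omega_cl = 0,
                                beta_cl_age = 0, b_prop = 0.29)
  ds <- tdm_dataset(data.frame(
    ID = 1, TIME = c(0, 10), EVID = c(1L, 0L), AMT = c(300, NA),
    DV = c(NA, 0.6), BLQ = 0L, age = 56))
  f <- conc_single_dose(10, 300, structural_params(0.8, 386.35, 8.8))
  expected <- -2 * dnorm(0.6, f, 0.29 * f, log = TRUE)
  res <- compute_ofv(ds, pop0)
  expect_equal(res$ofv, expected, tolerance = 1e-8)
  expect_identical(res$se, 0)

  # a subject contributing no observations leaves the OFV unchanged
  ds2 <- tdm_dataset(rbind(as.data.frame(ds), data.frame(
    ID = 2, TIME = 0, EVID = 1L, AMT = 300, DV = NA, BLQ = 0L, age = 40)))
  expect_equal(suppressWarnings(compute_ofv(ds2, pop0))$ofv, expected,
               tolerance = 1e-8)
})

test_that("importance-sampling OFV agrees with Gauss-Hermite quadrature", {
  # one subject, one active random effect (CL/F): the marginal likelihood
  # is a 1-D integral an adaptive-free quadrature can nail
  pop1 <- population_parameters(omega_ka = 0, omega_v = 0, omega_cl = 0.36,
                                beta_cl_age = 0)
  p_typ <- structural_params(0.8, 386.35, 8.8)
  tt <- c(8, 30, 54)
  set.seed(61)
  f_true <- vapply(tt, function(x) {
    sum(conc_single_dose(x - c(0, 24)[c(0, 24) <= x], 300, p_typ))
  }, numeric(1))
  y <- f_true * (1 + 0.29 * rnorm(3))
  ds <- tdm_dataset(data.frame(
    ID = 1, TIME = c(0, 8, 24, 30, 54), EVID = c(1L, 0L, 1L, 0L, 0L),
    AMT = c(300, NA, 300, NA, NA), DV = c(NA, y[1], NA, y[2], y[3]),
    BLQ = 0L, age = 56))

  gh <- pracma::gaussHermite(60)
  loglik_eta <- function(eta) {
    cl <- 8.8 * exp(eta)
    p <- structural_params(0.8, 386.35, cl)
    f <- vapply(tt, function(x) {
      sum(conc_single_dose(x - c(0, 24)[c(0, 24) <= x], 300, p))
    }, numeric(1))
    sum(dnorm(y, f, 0.29 * f, log = TRUE))
  }
  vals <- vapply(sqrt(2) * 0.36 * gh$x, loglik_eta, numeric(1))
  ll_gh <- log(sum(gh$w * exp(vals)) / sqrt(pi))
  ofv_gh <- -2 * ll_gh

  res_is <- compute_ofv(ds, pop1, estimation_settings(ofv_mc = 4000, seed = 62))
  expect_lt(abs(res_is$ofv - ofv_gh), 0.1)
  # the Laplace backend is a coarser but close approximation
  res_lp <- compute_ofv(ds, pop1, estimation_settings(ofv_method = "laplace"))
  expect_lt(abs(res_lp$ofv - ofv_gh), 1)
})

test_that("empirical Bayes estimates: prior mode, recovery, shrinkage", {
  pop <- population_parameters()
  # subject 2 has doses but no observations: posterior mode is the prior mode
  ds <- tdm_dataset(data.frame(
    ID = c(1, 1, 2), TIME = c(0, 30, 0), EVID = c(1L, 0L, 1L),
    AMT = c(300, NA, 300), DV = c(NA, 1.4, NA), BLQ = 0L, age = 50))
  eb <- suppressWarnings(estimate_ebes(ds, pop))
  expect_identical(nrow(eb$ebes), 2L)
  expect_identical(unname(unlist(eb$ebes[2, c("eta_ka", "eta_v", "eta_cl")])),
                   c(0, 0, 0))

  # dense low-noise design including the absorption phase recovers the
  # generating random effects (error magnitude matching the assay)
  pop_rich <- population_parameters(b_prop = 0.02)
  eta_true <- c(eta_ka = 0.5, eta_v = 0.3, eta_cl = -0.4)
  p_i <- individual_params(pop_rich, list(age = 50), eta = eta_true)
  ds_rich <- dense_dataset(list(p_i),
                           times = c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 18, 24,
                                     36, 48, 72, 96, 120, 144, 168, 192, 216,
                                     220, 224, 228, 232, 236),
                           n_days = 10, b = 0.02, seed = 63)
  eb_rich <- estimate_ebes(ds_rich, pop_rich)
  got <- unlist(eb_rich$ebes[1, c("eta_ka", "eta_v", "eta_cl")])
  expect_lt(max(abs(got - eta_true) / abs(eta_true)), 0.05)

  # sparse data shrink the MAP estimates towards zero on average
  cov <- generate_covariates(cohort_spec(), n = 150, seed = 64)
  des <- sampling_design(samples_range = c(1L, 2L), samples_mean = 1.5)
  ds_sparse <- suppressWarnings(generate_tdm_dataset(cov, des, pop, seed = 65))
  truth <- attr(ds_sparse, "truth")
  eb_sp <- suppressWarnings(estimate_ebes(ds_sparse, pop))
  m <- merge(eb_sp$ebes, truth, by = "id", suffixes = c("_map", "_true"))
  for (comp in c("eta_v", "eta_cl")) {
    expect_lt(mean(abs(m[[paste0(comp, "_map")]])),
              mean(abs(m[[paste0(comp, "_true")]])))
  }
  expect_true(all(eb_sp$shrinkage > 0))

  # conditional samples distribute around the MAP modes
  eb_cond <- suppressWarnings(estimate_ebes(ds_sparse, pop, n_samples = 40,
                                            seed = 66))
  expect_identical(dim(eb_cond$samples), c(nrow(eb_cond$ebes), 40L, 3L))
})

test_that("SAEM matches weighted nonlinear least squares without IIV", {
  # no random effects in the generating model: the NLME likelihood reduces
  # to proportionally-weighted least squares over the pooled observations
  pop_t <- population_parameters(v_pop = 320, cl_pop = 7.5, beta_cl_age = 0,
                                 omega_ka = 0, omega_v = 0, omega_cl = 0,
                                 b_prop = 0.02)
  p_typ <- structural_params(0.8, 320, 7.5)
  ds <- dense_dataset(rep(list(p_typ), 40),
                      times = c(2, 5, 12, 24, 50, 98, 146, 194, 221),
                      b = 0.02, seed = 71)
  fit <- fit_popmodel(ds, covariate_model = list(),
                      init = population_parameters(omega_ka = 0.3,
                                                   omega_v = 0.3,
                                                   omega_cl = 0.3),
                      settings = estimation_settings(n_explore = 200,
                                                     n_smooth = 200,
                                                     ofv_mc = 200, seed = 72))
  # independent oracle: weighted NLS on the superposed closed form
  obs <- as.data.frame(ds[ds$EVID == 0, ])
  dose_t <- seq(0, by = 24, length.out = 10)
  predfun <- function(lv, lcl, tt) {
    ke <- exp(lcl - lv)
    vapply(tt, function(x) {
      td <- x - dose_t[dose_t <= x]
      sum(300 * 0.8 / (exp(lv) * (0.8 - ke)) * (exp(-ke * td) - exp(-0.8 * td)))
    }, numeric(1))
  }
  w <- rep(1, nrow(obs))
  for (it in 1:3) {
    nls_fit <- nls(DV ~ predfun(lv, lcl, TIME), data = obs,
                   start = list(lv = log(380), lcl = log(8.8)), weights = w)
    w <- 1 / predfun(coef(nls_fit)[["lv"]], coef(nls_fit)[["lcl"]], obs$TIME)^2
  }
  v_nls <- exp(coef(nls_fit)[["lv"]])
  cl_nls <- exp(coef(nls_fit)[["lcl"]])
  expect_lt(abs(fit$pop$v_pop - v_nls) / v_nls, 0.01)
  expect_lt(abs(fit$pop$cl_pop - cl_nls) / cl_nls, 0.01)
  # and both sit within a percent of the generating truth
  expect_lt(abs(fit$pop$v_pop - 320) / 320, 0.01)
  expect_lt(abs(fit$pop$cl_pop - 7.5) / 7.5, 0.01)
  # estimated IIV collapses towards zero on IIV-free data
  expect_lt(fit$theta$omega[["v"]], 0.02)
  expect_lt(fit$theta$omega[["cl"]], 0.02)
})

test_that("fitting improves the objective function and is deterministic", {
  cov <- generate_covariates(cohort_spec(), n = 40, seed = 81)
  des <- sampling_design(samples_range = c(3L, 5L), samples_mean = 4,
                         max_day = 12)
  ds <- suppressWarnings(generate_tdm_dataset(cov, des, seed = 82))
  init <- population_parameters(v_pop = 200, cl_pop = 5, beta_cl_age = 0,
                                omega_ka = 1, omega_v = 1, omega_cl = 1,
                                b_prop = 0.5)
  settings <- fast_settings(seed = 83)
  fit <- suppressWarnings(fit_popmodel(ds, init = init, settings = settings))
  ofv_init <- suppressWarnings(compute_ofv(ds, init, settings))$ofv
  # descent: allow the importance-sampling Monte Carlo wiggle
  expect_lt(fit$ofv, ofv_init - 3 * (fit$ofv_se + 1))

  fit2 <- suppressWarnings(fit_popmodel(ds, init = init, settings = settings))
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$ofv, fit2$ofv)
  expect_identical(fit$ebes, fit2$ebes)
  expect_identical(fit$trace, fit2$trace)

  # frozen fixed effect stays at its initial value
  expect_identical(fit$pop$ka_pop, init$ka_pop)
})
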