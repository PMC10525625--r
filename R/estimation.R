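#' SAEM estimation settings
#'
#' Tuning knobs for the stochastic-approximation EM fit and the
#' importance-sampling likelihood. Defaults follow the usual two-phase
#' scheme: an exploratory phase with step size 1 and simulated-annealing
#' variance inflation, then a smoothing phase with decreasing step size
#' `1/(k - K1)`.
#'
#' @param n_explore Exploratory-phase iterations (step size 1).
#' @param n_smooth Smoothing-phase iterations.
#' @param n_kernel Random-walk Metropolis sweeps per subject per
#'   iteration (each sweep updates each random-effect component once; an
#'   additional independent-proposal step runs every iteration).
#' @param ofv_mc Importance-sampling size per subject for the objective
#'   function value.
#' @param ofv_method `"is"` (importance sampling, reference) or
#'   `"laplace"` (fast Laplace approximation).
#' @param anneal Simulated-annealing retention factor in the exploratory
#'   phase: variances may not shrink faster than this factor per
#'   iteration.
#' @param rw_target Target acceptance rate for the adaptive random-walk
#'   scales.
#' @param freeze Character vector of frozen fixed effects; default
#'   `"ka_pop"`, since sparse elimination-phase sampling cannot inform
#'   the absorption constant.
#' @param freeze_omega Character vector of IIV SDs held at their initial
#'   value (e.g. `"omega_ka"`); default none.
#' @param seed Integer seed; every stochastic step of the fit flows from
#'   it, so identical settings and data give identical results.
#'
#' @return An object of class `estimation_settings`.
#' @export
estimation_settings <- function(n_explore = 300, n_smooth = 100, n_kernel = 2,
                                ofv_mc = 1000, ofv_method = c("is", "laplace"),
                                anneal = 0.95, rw_target = 0.4,
                                freeze = "ka_pop", freeze_omega = character(0),
                                seed = 1234) {
  stopifnot(n_explore >= 1, n_smooth >= 1, n_kernel >= 1, ofv_mc >= 10,
            anneal > 0, anneal < 1, rw_target > 0, rw_target < 1)
  structure(
    list(n_explore = as.integer(n_explore), n_smooth = as.integer(n_smooth),
         n_kernel = as.integer(n_kernel), ofv_mc = as.integer(ofv_mc),
         ofv_method = match.arg(ofv_method), anneal = anneal,
         rw_target = rw_target, freeze = freeze, freeze_omega = freeze_omega,
         seed = as.integer(seed)),
    class = "estimation_settings"
  )
}

## ---- internal model representation -------------------------------------
## theta: list(beta = list(ka, v, cl), omega = c(ka, v, cl), b)
## beta vectors are on the log-parameter scale; first element is the
## intercept (log of the typical value), remaining elements are covariate
## coefficients in the order of covariate_model[[p]].

.PARAMS <- c("ka", "v", "cl")

## Build per-parameter design matrices from the covariate table.
## Continuous covariates enter as-is; logical as 0/1; character/factor as
## 0/1 dummies per non-reference level (named covariate.level).
.model_matrices <- function(covariates, covariate_model) {
  n <- nrow(covariates)
  lapply(stats::setNames(.PARAMS, .PARAMS), function(p) {
    vars <- covariate_model[[p]]
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    for (v in vars) {
      x <- covariates[[v]]
      if (is.null(x)) stop(sprintf("covariate '%s' not found in dataset", v))
      if (is.numeric(x)) {
        X <- cbind(X, stats::setNames(data.frame(x), v))
      } else if (is.logical(x)) {
        X <- cbind(X, stats::setNames(data.frame(as.numeric(x)), v))
      } else {
        f <- factor(x)
        if (nlevels(f) < 2) stop(sprintf("covariate '%s' is constant", v))
        d <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(d) <- paste(v, levels(f)[-1], sep = ".")
        X <- cbind(X, d)
      }
    }
    as.matrix(X)
  })
}

.pop_to_theta <- function(pop) {
  list(beta = list(ka = c("(Intercept)" = log(pop$ka_pop)),
                   v  = c("(Intercept)" = log(pop$v_pop)),
                   cl = c("(Intercept)" = log(pop$cl_pop), age = pop$beta_cl_age)),
       omega = c(ka = pop$omega_ka, v = pop$omega_v, cl = pop$omega_cl),
       b = pop$b_prop)
}

.theta_to_pop <- function(theta) {
  bcl <- theta$beta$cl
  extra <- setdiff(names(bcl), c("(Intercept)", "age"))
  if (length(extra) || length(theta$beta$ka) > 1 || length(theta$beta$v) > 1) {
    stop("fitted covariate model is not the canonical age-on-CL/F form")
  }
  population_parameters(
    ka_pop = exp(theta$beta$ka[["(Intercept)"]]),
    v_pop = exp(theta$beta$v[["(Intercept)"]]),
    cl_pop = exp(bcl[["(Intercept)"]]),
    beta_cl_age = if ("age" %in% names(bcl)) bcl[["age"]] else 0,
    omega_ka = theta$omega[["ka"]], omega_v = theta$omega[["v"]],
    omega_cl = theta$omega[["cl"]], b_prop = theta$b
  )
}

## Align a theta init with the design matrices (zero-fill new coefficients).
.align_theta <- function(theta, Xs) {
  for (p in .PARAMS) {
    nm <- colnames(Xs[[p]])
    b <- stats::setNames(numeric(length(nm)), nm)
    common <- intersect(nm, names(theta$beta[[p]]))
    b[common] <- theta$beta[[p]][common]
    theta$beta[[p]] <- b
  }
  theta
}

## Per-subject log-likelihood of the observations given log-parameters phi
## (n x 3 matrix, columns ka/v/cl). Returns a length-n vector.
.subject_loglik <- function(prep, phi, b) {
  phi <- pmin(pmax(phi, -40), 40)    # overflow guard on extreme proposals
  f <- .pred_conc(prep, exp(phi[, 1]), exp(phi[, 2]), exp(phi[, 3]))
  sd <- b * pmax(f, 1e-12)
  ll <- stats::dnorm(prep$y, f, sd, log = TRUE)
  out <- numeric(prep$n)
  rs <- rowsum(ll, group = prep$subj, reorder = TRUE)
  out[as.integer(rownames(rs))] <- rs
  out
}

.mean_matrix <- function(Xs, theta) {
  cbind(ka = as.numeric(Xs$ka %*% theta$beta$ka),
        v  = as.numeric(Xs$v %*% theta$beta$v),
        cl = as.numeric(Xs$cl %*% theta$beta$cl))
}

## ---- SAEM --------------------------------------------------------------

#' Fit the population model by SAEM
#'
#' Maximum-likelihood estimation of the nonlinear mixed-effects model by
#' stochastic-approximation EM: a Metropolis kernel samples each
#' subject's random effects from their conditional distribution, the
#' sufficient statistics of the (linear-Gaussian) complete-data model are
#' smoothed by stochastic approximation, and closed-form M-steps update
#' the fixed effects (a weighted regression of sampled log-parameters on
#' the covariate design), the IIV variances and the proportional error.
#' The exploratory phase uses simulated-annealing variance retention to
#' avoid premature collapse of the random effects.
#'
#' Relative standard errors are obtained from a stochastic approximation
#' of the Fisher information (Louis' identity with analytic complete-data
#' scores), accumulated over the smoothing phase.
#'
#' @param dataset A [tdm_dataset()].
#' @param covariate_model Named list with elements `ka`, `v`, `cl` (any
#'   may be absent) giving covariate column names that enter linearly on
#'   the log scale of that parameter. Default: age on CL/F.
#' @param init A [population_parameters()] used as the starting point
#'   (and source of frozen values).
#' @param settings An [estimation_settings()].
#'
#' @return An object of class `popfit`: estimates (`pop` when the model
#'   is the canonical form, else `NULL`), `theta` (internal
#'   coefficients), `rse` (percent), `ofv` and its Monte Carlo SE,
#'   empirical Bayes estimates `ebes`, `shrinkage` (percent per
#'   random effect), the iteration `trace`, and `converged`.
#' @export
fit_popmodel <- function(dataset, covariate_model = list(cl = "age"),
                         init = population_parameters(),
                         settings = estimation_settings()) {
  stopifnot(inherits(settings, "estimation_settings"),
            inherits(init, "population_parameters"))
  set.seed(settings$seed)
  prep <- .prepare_dataset(dataset)
  n <- prep$n
  Xs <- .model_matrices(prep$covariates, covariate_model)
  theta <- .align_theta(.pop_to_theta(init), Xs)

  freeze_beta <- list(ka = colnames(Xs$ka) == "(Intercept)" & "ka_pop" %in% settings$freeze,
                      v  = colnames(Xs$v) == "(Intercept)" & "v_pop" %in% settings$freeze,
                      cl = colnames(Xs$cl) == "(Intercept)" & "cl_pop" %in% settings$freeze)
  freeze_om <- stats::setNames(paste0("omega_", .PARAMS) %in% settings$freeze_omega, .PARAMS)

  XtX <- lapply(Xs, crossprod)
  n_iter <- settings$n_explore + settings$n_smooth
  omega <- pmax(theta$omega, 1e-3)
  b <- max(theta$b, 1e-3)

  mu <- .mean_matrix(Xs, theta)
  eta <- matrix(0, n, 3, dimnames = list(NULL, .PARAMS))
  ll_cur <- .subject_loglik(prep, mu + eta, b)
  rw_sd <- omega                       # adaptive RW scales per component

  # sufficient statistics
  s_xy <- lapply(Xs, function(X) numeric(ncol(X)))
  s_phi2 <- c(ka = 0, v = 0, cl = 0)
  s_err <- 0
  trace <- matrix(NA_real_, n_iter,
                  length(unlist(theta$beta)) + 4,
                  dimnames = list(NULL, c(
                    paste0("beta_", rep(.PARAMS, lengths(theta$beta)), ".",
                           unlist(lapply(theta$beta, names))),
                    paste0("omega_", .PARAMS), "b")))
  # Fisher accumulation (smoothing phase)
  free_idx <- NULL; fi_D <- NULL; fi_G <- NULL; fi_count <- 0

  for (k in seq_len(n_iter)) {
    explor <- k <= settings$n_explore
    gamma <- if (explor) 1 else 1 / (k - settings$n_explore)

    ## -- MCMC kernel -----------------------------------------------------
    # (a) independent proposal from the prior: prior terms cancel
    eta_prop <- matrix(stats::rnorm(n * 3), n, 3) * rep(omega, each = n)
    eta_prop[, freeze_om & omega == 0] <- 0
    ll_prop <- .subject_loglik(prep, mu + eta_prop, b)
    acc <- log(stats::runif(n)) < (ll_prop - ll_cur)
    eta[acc, ] <- eta_prop[acc, ]
    ll_cur[acc] <- ll_prop[acc]
    # (b) componentwise random walks with prior ratio
    for (sweep in seq_len(settings$n_kernel)) {
      for (c_i in 1:3) {
        if (omega[c_i] <= 0) next
        step <- stats::rnorm(n, 0, rw_sd[c_i])
        eta_prop <- eta
        eta_prop[, c_i] <- eta[, c_i] + step
        ll_prop <- .subject_loglik(prep, mu + eta_prop, b)
        lprior <- (eta[, c_i]^2 - eta_prop[, c_i]^2) / (2 * omega[c_i]^2)
        acc <- log(stats::runif(n)) < (ll_prop - ll_cur + lprior)
        eta[acc, c_i] <- eta_prop[acc, c_i]
        ll_cur[acc] <- ll_prop[acc]
        rate <- mean(acc)
        rw_sd[c_i] <- min(rw_sd[c_i] * exp(0.4 * (rate - settings$rw_target)),
                          10 * max(omega[c_i], 0.1))
      }
    }

    phi <- mu + eta
    f <- .pred_conc(prep, exp(phi[, 1]), exp(phi[, 2]), exp(phi[, 3]))

    ## -- stochastic approximation of sufficient statistics ---------------
    for (p in .PARAMS) {
      j <- match(p, .PARAMS)
      s_xy[[p]] <- (1 - gamma) * s_xy[[p]] + gamma * as.numeric(crossprod(Xs[[p]], phi[, j]))
      s_phi2[p] <- (1 - gamma) * s_phi2[p] + gamma * sum(phi[, j]^2)
    }
    s_err <- (1 - gamma) * s_err + gamma * sum(((prep$y - f) / pmax(f, 1e-12))^2)

    ## -- M-step ----------------------------------------------------------
    for (p in .PARAMS) {
      j <- match(p, .PARAMS)
      frz <- freeze_beta[[p]]
      beta <- theta$beta[[p]]
      if (!all(frz)) {
        rhs <- s_xy[[p]][!frz]
        if (any(frz)) rhs <- rhs - XtX[[p]][!frz, frz, drop = FALSE] %*% beta[frz]
        beta[!frz] <- solve(XtX[[p]][!frz, !frz, drop = FALSE], rhs)
      }
      theta$beta[[p]] <- beta
      if (!freeze_om[p]) {
        rss <- s_phi2[p] - 2 * sum(beta * s_xy[[p]]) +
          as.numeric(t(beta) %*% XtX[[p]] %*% beta)
        om2_hat <- max(rss / n, 1e-10)
        omega[j] <- sqrt(if (explor) max(settings$anneal * omega[j]^2, om2_hat) else om2_hat)
      }
    }
    b_hat <- sqrt(max(s_err / prep$n_obs, 1e-10))
    b <- if (explor) max(sqrt(settings$anneal) * b, b_hat) else b_hat

    # conditional log-lik changes with theta: refresh
    mu <- .mean_matrix(Xs, theta)
    ll_cur <- .subject_loglik(prep, mu + eta, b)

    trace[k, ] <- c(unlist(theta$beta), omega, b)

    ## -- Fisher information accumulation (smoothing phase) ---------------
    if (!explor) {
      sc <- .complete_score(prep, Xs, theta, omega, b, eta, freeze_beta, freeze_om)
      if (is.null(fi_D)) {
        fi_D <- sc$score * 0; fi_G <- matrix(0, length(sc$score), length(sc$score))
        free_idx <- sc$names
      }
      fi_count <- fi_count + 1
      w <- 1 / fi_count
      fi_D <- (1 - w) * fi_D + w * sc$score
      fi_G <- (1 - w) * fi_G + w * (sc$neg_hess + tcrossprod(sc$score))
    }
  }
  theta$omega <- stats::setNames(omega, .PARAMS)
  theta$b <- b

  ## RSEs from Louis' identity: I = E[-Hc] - E[Sc Sc'] + E[Sc]E[Sc]'
  rse <- NULL
  info <- NULL
  if (!is.null(fi_D)) {
    info <- fi_G - tcrossprod(fi_D)
    info <- (info + t(info)) / 2
    dimnames(info) <- list(free_idx, free_idx)
    est <- .theta_free_values(theta, freeze_beta, freeze_om)
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      se <- sqrt(diag(vc))
      # intercepts are log-scale: SE(log) is already the relative SE
      denom <- ifelse(grepl("^beta_.*Intercept", free_idx), 1, abs(est))
      rse <- stats::setNames(100 * se / denom, free_idx)
    }
  }

  ## convergence heuristic: drift over the last half of the smoothing
  ## phase small relative to the estimate (the early smoothing iterations
  ## legitimately move while the 1/k averaging settles)
  sm <- trace[(settings$n_explore + 1):n_iter, , drop = FALSE]
  half <- sm[seq(ceiling(nrow(sm) / 2), nrow(sm)), , drop = FALSE]
  drift <- abs(half[nrow(half), ] - half[1, ])
  converged <- all(drift < pmax(0.05, 0.1 * abs(half[nrow(half), ])))

  pop <- tryCatch(.theta_to_pop(theta), error = function(e) NULL)

  ebes <- .map_ebes(prep, Xs, theta)
  shr <- 100 * (1 - apply(ebes, 2, stats::sd) / pmax(theta$omega, 1e-12))

  ofv <- .ofv_internal(prep, Xs, theta, settings)

  structure(
    list(pop = pop, theta = theta, covariate_model = covariate_model,
         rse = rse, ofv = ofv$ofv, ofv_se = ofv$se,
         ebes = as.data.frame(cbind(id = prep$ids, ebes)),
         shrinkage = stats::setNames(shr, paste0("eta_", .PARAMS)),
         trace = trace, converged = converged, fisher = info, n_subjects = n,
         n_obs = prep$n_obs, settings = settings),
    class = "popfit"
  )
}

#' @export
print.popfit <- function(x, ...) {
  cat(sprintf("Population PK fit (SAEM): %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("OFV %.2f (MC SE %.3f)%s\n", x$ofv, x$ofv_se,
              if (x$converged) "" else "  [convergence flag raised]"))
  est <- c(unlist(x$theta$beta), x$theta$omega, x$theta$b)
  keys <- c(paste0("beta_", rep(.PARAMS, lengths(x$theta$beta)), ".",
                   unlist(lapply(x$theta$beta, names))),
            paste0("omega_", .PARAMS), "b")
  nat <- est
  ints <- grepl("Intercept", keys)
  nat[ints] <- exp(est[ints])
  tab <- data.frame(estimate = signif(nat, 4))
  rownames(tab) <- sub("^beta_(ka|v|cl)\\.\\(Intercept\\)$", "\\1_pop",
                       sub("^b$", "b_prop", keys))
  if (!is.null(x$rse)) {
    tab$rse_pct <- signif(x$rse[match(keys, names(x$rse))], 3)
  }
  print(tab)
  cat("eta-shrinkage (%):", paste(sprintf("%s %.1f", names(x$shrinkage), x$shrinkage),
                                  collapse = ", "), "\n")
  invisible(x)
}

## Free-parameter bookkeeping ------------------------------------------------

.theta_free_names <- function(theta, freeze_beta, freeze_om) {
  nm <- c()
  for (p in .PARAMS) {
    keep <- !freeze_beta[[p]]
    nm <- c(nm, paste0("beta_", p, ".", names(theta$beta[[p]]))[keep])
  }
  nm <- c(nm, paste0("omega_", .PARAMS)[!freeze_om], "b")
  nm
}

.theta_free_values <- function(theta, freeze_beta, freeze_om) {
  v <- c()
  for (p in .PARAMS) v <- c(v, theta$beta[[p]][!freeze_beta[[p]]])
  c(v, theta$omega[!freeze_om], theta$b)
}

## Complete-data score and negative Hessian for the free parameters, given
## the current random-effect draws. All blocks are analytic because the
## complete-data model is linear-Gaussian in the log-parameters and the
## error part depends on theta only through b.
.complete_score <- function(prep, Xs, theta, omega, b, eta, freeze_beta, freeze_om) {
  nms <- .theta_free_names(theta, freeze_beta, freeze_om)
  q <- length(nms)
  score <- stats::setNames(numeric(q), nms)
  neg_hess <- matrix(0, q, q, dimnames = list(nms, nms))
  pos <- 1
  om_pos <- list()
  for (p in .PARAMS) {
    j <- match(p, .PARAMS)
    X <- Xs[[p]]; e <- eta[, j]; om <- omega[j]
    keep <- !freeze_beta[[p]]
    nk <- sum(keep)
    if (nk) {
      idx <- pos:(pos + nk - 1)
      score[idx] <- as.numeric(crossprod(X[, keep, drop = FALSE], e)) / om^2
      neg_hess[idx, idx] <- crossprod(X[, keep, drop = FALSE]) / om^2
      om_pos[[p]] <- list(beta_idx = idx, Xe = as.numeric(crossprod(X[, keep, drop = FALSE], e)))
      pos <- pos + nk
    } else {
      om_pos[[p]] <- list(beta_idx = integer(0), Xe = numeric(0))
    }
  }
  for (p in .PARAMS[!freeze_om]) {
    j <- match(p, .PARAMS)
    e <- eta[, j]; om <- omega[j]; n <- length(e)
    score[pos] <- sum(e^2) / om^3 - n / om
    neg_hess[pos, pos] <- 3 * sum(e^2) / om^4 - n / om^2
    bi <- om_pos[[p]]$beta_idx
    if (length(bi)) {
      cross <- 2 * om_pos[[p]]$Xe / om^3
      neg_hess[pos, bi] <- cross
      neg_hess[bi, pos] <- cross
    }
    pos <- pos + 1
  }
  # error magnitude
  mu <- .mean_matrix(Xs, theta)
  phi <- mu + eta
  f <- .pred_conc(prep, exp(phi[, 1]), exp(phi[, 2]), exp(phi[, 3]))
  r <- (prep$y - f) / pmax(f, 1e-12)
  N <- prep$n_obs
  score[pos] <- sum(r^2) / b^3 - N / b
  neg_hess[pos, pos] <- 3 * sum(r^2) / b^4 - N / b^2
  list(names = nms, score = score, neg_hess = neg_hess)
}

## ---- empirical Bayes estimates ------------------------------------------

.neg_logpost_one <- function(eta_i, prep_i, mu_i, omega, b, active) {
  if (any(!is.finite(eta_i)) || any(abs(eta_i) > 40)) return(1e10)
  eta_full <- numeric(3)
  eta_full[active] <- eta_i
  phi <- mu_i + eta_full
  f_pair <- .bateman(prep_i$tdiff, prep_i$amt, exp(phi[1]), exp(phi[2]), exp(phi[3]))
  f <- as.numeric(rowsum(f_pair, group = prep_i$obs_of_pair, reorder = TRUE))
  sd <- b * pmax(f, 1e-12)
  -sum(stats::dnorm(prep_i$y, f, sd, log = TRUE)) +
    sum(eta_i^2 / (2 * omega[active]^2))
}

.subject_slices <- function(prep) {
  lapply(seq_len(prep$n), function(i) {
    oi <- which(prep$subj == i)
    pi <- which(prep$pair_subj == i)
    list(y = prep$y[oi], tdiff = prep$pair_tdiff[pi], amt = prep$pair_amt[pi],
         obs_of_pair = match(prep$pair_obs[pi], oi))
  })
}

.map_ebes <- function(prep, Xs, theta) {
  omega <- theta$omega; b <- theta$b
  mu <- .mean_matrix(Xs, theta)
  active <- which(omega > 1e-8)
  slices <- .subject_slices(prep)
  eta <- matrix(0, prep$n, 3, dimnames = list(NULL, paste0("eta_", .PARAMS)))
  if (!length(active)) return(eta)
  for (i in seq_len(prep$n)) {
    if (!length(slices[[i]]$y)) next   # no observations: prior mode 0
    opt <- stats::optim(numeric(length(active)), .neg_logpost_one,
                        prep_i = slices[[i]], mu_i = mu[i, ], omega = omega,
                        b = b, active = active, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    eta[i, active] <- opt$par
  }
  eta
}

#' Empirical Bayes estimates of individual random effects
#'
#' MAP (posterior-mode) estimates of each subject's random effects given
#' population parameters, with optional Markov-chain samples from the
#' conditional distribution for use in covariate screening when
#' shrinkage is high. A subject with no usable observations gets the
#' prior mode, eta = 0.
#'
#' @param dataset A [tdm_dataset()].
#' @param pop A [population_parameters()] or a [fit_popmodel()] result.
#' @param n_samples Conditional-distribution samples per subject
#'   (0 = MAP only).
#' @param seed Integer seed for the conditional sampler.
#'
#' @return A list: `ebes` (data frame of `id`, `eta_ka`, `eta_v`,
#'   `eta_cl`, and the implied individual `ka`, `v`, `cl`), `shrinkage`
#'   (percent), and `samples` (array subject x draw x component, or
#'   `NULL`).
#' @export
estimate_ebes <- function(dataset, pop, n_samples = 0, seed = 1234) {
  th <- .as_theta(pop)
  set.seed(seed)
  prep <- .prepare_dataset(dataset, keep_empty = TRUE)
  Xs <- .model_matrices(prep$covariates, .covariate_model_of(pop))
  theta <- .align_theta(th, Xs)
  eta <- .map_ebes(prep, Xs, theta)
  mu <- .mean_matrix(Xs, theta)
  phi <- mu + eta
  ebes <- data.frame(id = prep$ids, eta, ka = exp(phi[, 1]), v = exp(phi[, 2]),
                     cl = exp(phi[, 3]))
  shr <- 100 * (1 - apply(eta, 2, stats::sd) / pmax(theta$omega, 1e-12))
  samples <- NULL
  if (n_samples > 0) {
    samples <- .conditional_samples(prep, Xs, theta, eta, n_samples)
  }
  list(ebes = ebes, shrinkage = stats::setNames(shr, paste0("eta_", .PARAMS)),
       samples = samples)
}

## RW Metropolis chain per subject started at the MAP; returns
## n x n_samples x 3 array of eta draws (thinned).
.conditional_samples <- function(prep, Xs, theta, eta_start, n_samples,
                                 thin = 5, burn = 50) {
  omega <- theta$omega; b <- theta$b
  mu <- .mean_matrix(Xs, theta)
  n <- prep$n
  eta <- eta_start
  ll <- .subject_loglik(prep, mu + eta, b)
  rw <- pmax(omega, 1e-3) / 2
  total <- burn + thin * n_samples
  out <- array(NA_real_, c(n, n_samples, 3),
               dimnames = list(NULL, NULL, paste0("eta_", .PARAMS)))
  s <- 0
  for (it in seq_len(total)) {
    for (c_i in which(omega > 1e-8)) {
      eta_prop <- eta
      eta_prop[, c_i] <- eta[, c_i] + stats::rnorm(n, 0, rw[c_i])
      ll_prop <- .subject_loglik(prep, mu + eta_prop, b)
      lprior <- (eta[, c_i]^2 - eta_prop[, c_i]^2) / (2 * omega[c_i]^2)
      acc <- log(stats::runif(n)) < (ll_prop - ll + lprior)
      eta[acc, c_i] <- eta_prop[acc, c_i]
      ll[acc] <- ll_prop[acc]
      rw[c_i] <- rw[c_i] * exp(0.3 * (mean(acc) - 0.4))
    }
    if (it > burn && (it - burn) %% thin == 0) {
      s <- s + 1
      out[, s, ] <- eta
    }
  }
  out
}

## ---- objective function value -------------------------------------------

.as_theta <- function(pop) {
  if (inherits(pop, "popfit")) pop$theta
  else if (inherits(pop, "population_parameters")) .pop_to_theta(pop)
  else stop("'pop' must be population_parameters or a popfit")
}

.covariate_model_of <- function(pop) {
  if (inherits(pop, "popfit")) return(pop$covariate_model)
  if (pop$beta_cl_age == 0) list() else list(cl = "age")
}

#' Objective function value (-2 log-likelihood)
#'
#' Marginal -2 log-likelihood of a dataset under given population
#' parameters, by importance sampling around each subject's MAP random
#' effects (default) or by the Laplace approximation. Dimensions with
#' zero IIV are collapsed analytically (the random effect is fixed at
#' its mean), so `omega = 0` is exact, not degenerate.
#'
#' @inheritParams estimate_ebes
#' @param settings An [estimation_settings()]; `ofv_mc` controls the
#'   importance-sampling size and `ofv_method` the backend. The
#'   computation is deterministic given `settings$seed`.
#'
#' @return A list with `ofv`, `se` (Monte Carlo standard error of the
#'   log-likelihood; 0 for Laplace) and per-subject log-likelihood
#'   contributions `ll_i`.
#' @export
compute_ofv <- function(dataset, pop, settings = estimation_settings()) {
  theta <- .as_theta(pop)
  set.seed(settings$seed)
  prep <- .prepare_dataset(dataset)
  Xs <- .model_matrices(prep$covariates, .covariate_model_of(pop))
  theta <- .align_theta(theta, Xs)
  .ofv_internal(prep, Xs, theta, settings)
}

.ofv_internal <- function(prep, Xs, theta, settings) {
  omega <- theta$omega; b <- theta$b
  mu <- .mean_matrix(Xs, theta)
  active <- which(omega > 1e-8)
  slices <- .subject_slices(prep)
  d <- length(active)
  ll_i <- numeric(prep$n)
  var_i <- numeric(prep$n)
  M <- settings$ofv_mc
  for (i in seq_len(prep$n)) {
    sl <- slices[[i]]
    if (!length(sl$y)) { ll_i[i] <- 0; next }
    if (d == 0) {
      ll_i[i] <- -.neg_logpost_one(numeric(0), sl, mu[i, ], omega, b, integer(0))
      next
    }
    # MAP and curvature for the proposal
    opt <- stats::optim(numeric(d), .neg_logpost_one, prep_i = sl, mu_i = mu[i, ],
                        omega = omega, b = b, active = active, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10), hessian = TRUE)
    H <- (opt$hessian + t(opt$hessian)) / 2
    ev <- eigen(H, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-6)
    if (settings$ofv_method == "laplace") {
      # -opt$value carries the eta prior quadratic form; add its
      # normalising constant and the Gaussian volume around the mode
      # (the (2*pi)^{d/2} factors cancel)
      ll_i[i] <- -opt$value - sum(log(omega[active])) - 0.5 * sum(log(lam))
      next
    }
    Sig_half <- ev$vectors %*% diag(sqrt(1 / lam), d) %*% t(ev$vectors)
    Z <- matrix(stats::rnorm(M * d), M, d)
    props <- sweep(Z %*% (1.2 * Sig_half), 2, opt$par, `+`)
    # log proposal density
    Zq <- rowSums(Z^2)
    log_q <- -Zq / 2 - d / 2 * log(2 * pi) - 0.5 * sum(log((1.2)^2 / lam))
    log_p <- -apply(props, 1, .neg_logpost_one, prep_i = sl, mu_i = mu[i, ],
                    omega = omega, b = b, active = active) -
      sum(log(omega[active])) - d / 2 * log(2 * pi)
    lw <- log_p - log_q
    m <- max(lw)
    w <- exp(lw - m)
    ll_i[i] <- m + log(mean(w))
    var_i[i] <- stats::var(w) / (M * mean(w)^2)
  }
  list(ofv = -2 * sum(ll_i), se = sqrt(sum(var_i)), ll_i = ll_i)
}
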