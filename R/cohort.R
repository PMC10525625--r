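#' Cohort specification for the synthetic lung-transplant population
#'
#' Describes the covariate structure of the study cohort as marginal
#' summaries: per continuous covariate a (median, IQR, range) triple, plus
#' category frequencies for sex, transplant indication and co-medication.
#' Defaults reproduce the demographic and laboratory characteristics of
#' the 32-patient lung-transplant TDM cohort (median age 56 years, IQR
#' 48-61, range 22-71, and so on), the 10:22 female:male ratio, the
#' indication counts 3/7/13/7/1/1 (cystic fibrosis / pulmonary fibrosis /
#' interstitial lung disease / COPD / asthma / chronic aspergillosis), and
#' co-medication frequencies (calcineurin inhibitor 32/32, mycophenolate
#' mofetil 31/32, acid suppressants 29/32).
#'
#' @param n_subjects Number of subjects to generate by default.
#' @param continuous Named list; each element `list(median=, iqr=c(lo,hi),
#'   range=c(min,max))`.
#' @param p_female Probability of female sex.
#' @param indication_freq Named numeric vector of indication probabilities
#'   (will be normalised).
#' @param comed_freq Named numeric vector of co-medication probabilities
#'   (`calcineurin`, `mmf`, `acid_suppressant`).
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 32,
                        continuous = list(
                          age        = list(median = 56,   iqr = c(48, 61),     range = c(22, 71)),
                          height     = list(median = 170,  iqr = c(170, 175),   range = c(151, 185)),
                          weight     = list(median = 69,   iqr = c(60, 83),     range = c(38, 100)),
                          bmi        = list(median = 24.4, iqr = c(20.7, 27.0), range = c(13.1, 32.4)),
                          bsa        = list(median = 1.81, iqr = c(1.68, 2.00), range = c(1.40, 2.20)),
                          creatinine = list(median = 110,  iqr = c(69, 124),    range = c(53, 301)),
                          egfr       = list(median = 0.98, iqr = c(0.82, 1.60), range = c(0.32, 2.16)),
                          alt        = list(median = 0.72, iqr = c(0.42, 1.03), range = c(0.24, 4.97)),
                          ast        = list(median = 0.35, iqr = c(0.31, 0.52), range = c(0.15, 1.68)),
                          ggt        = list(median = 0.63, iqr = c(0.34, 1.31), range = c(0.20, 3.30)),
                          therapy_duration = list(median = 40, iqr = c(20, 97), range = c(10, 1123))
                        ),
                        p_female = 10 / 32,
                        indication_freq = c(cystic_fibrosis = 3, pulmonary_fibrosis = 7,
                                            interstitial_lung_disease = 13, copd = 7,
                                            asthma = 1, chronic_aspergillosis = 1),
                        comed_freq = c(calcineurin = 32 / 32, mmf = 31 / 32,
                                       acid_suppressant = 29 / 32)) {
  if (!is.numeric(n_subjects) || n_subjects < 1) stop("'n_subjects' must be >= 1")
  for (nm in names(continuous)) {
    s <- continuous[[nm]]
    if (!all(c("median", "iqr", "range") %in% names(s))) {
      stop(sprintf("continuous covariate '%s' needs median, iqr and range", nm))
    }
    ok <- s$range[1] <= s$iqr[1] && s$iqr[1] <= s$median &&
      s$median <= s$iqr[2] && s$iqr[2] <= s$range[2] && s$range[1] < s$range[2]
    if (!ok) {
      stop(sprintf("infeasible summary for '%s': need range <= IQR <= median ordering", nm))
    }
  }
  if (p_female < 0 || p_female > 1) stop("'p_female' must be in [0,1]")
  structure(
    list(n_subjects = as.integer(n_subjects), continuous = continuous,
         p_female = p_female,
         indication_freq = indication_freq / sum(indication_freq),
         comed_freq = comed_freq),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d subjects, %d continuous covariates, %.0f%% female\n",
              x$n_subjects, length(x$continuous), 100 * x$p_female))
  invisible(x)
}

## Continuous distribution matching a (median, IQR, range) summary: the
## quantile function is a monotone (Hyman-filtered) cubic spline through
## the five known quantiles (min, q25, median, q75, max), so the
## quartiles are reproduced exactly and the support is bounded by the
## stated range. A two-parameter family (e.g. a scaled Beta) cannot in
## general satisfy three quartile constraints, which matters for the
## strongly skewed laboratory covariates.
.fit_quantile_spline <- function(median, iqr, range) {
  p <- c(0, 0.25, 0.5, 0.75, 1)
  q <- c(range[1], iqr[1], median, iqr[2], range[2])
  # strictly increasing knots required; nudge ties (e.g. q25 == median)
  eps <- 1e-9 * max(abs(q), 1)
  for (i in 2:5) if (q[i] <= q[i - 1]) q[i] <- q[i - 1] + eps
  stats::splinefun(p, q, method = "hyman")
}

#' Generate a virtual covariate table
#'
#' Draws `n` covariate vectors from the marginal summaries of a
#' [cohort_spec()]: each continuous covariate from a bounded distribution
#' whose quantile function is a monotone cubic spline through the
#' reported (min, q25, median, q75, max), so the published quartiles are
#' matched exactly and draws stay inside the reported range; categorical
#' covariates from the stated frequencies. Covariates are drawn
#' independently (only marginal summaries are available); the
#' cystic-fibrosis flag is derived from the sampled indication so the two
#' stay consistent.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of subjects (default `spec$n_subjects`).
#' @param method `"random"` draws every covariate independently at
#'   random; `"quantile"` places the `n` values of each continuous
#'   covariate at the systematic quantile positions `(i - 0.5)/n`
#'   (independently shuffled across covariates) and assigns categories
#'   at their expected counts. Use `"quantile"` to reconstruct a fixed
#'   study cohort whose summary statistics should match the published
#'   ones exactly rather than up to sampling noise.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A data frame with one row per subject: `id`, `sex`,
#'   `indication`, `cystic_fibrosis`, the continuous covariates, and
#'   co-medication flags.
#' @examples
#' head(generate_covariates(cohort_spec(), n = 5, seed = 1))
#' @export
generate_covariates <- function(spec = cohort_spec(), n = spec$n_subjects,
                                method = c("random", "quantile"), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(id = seq_len(n))
  expected_counts <- function(p) {
    # deterministic category assignment at expected frequencies
    k <- floor(p * n)
    rem <- p * n - k
    k[order(rem, decreasing = TRUE)[seq_len(n - sum(k))]] <-
      k[order(rem, decreasing = TRUE)[seq_len(n - sum(k))]] + 1
    k
  }
  if (method == "random") {
    out$sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
    out$indication <- sample(names(spec$indication_freq), n, replace = TRUE,
                             prob = spec$indication_freq)
  } else {
    kf <- expected_counts(c(spec$p_female, 1 - spec$p_female))
    out$sex <- sample(rep(c("female", "male"), kf))
    ki <- expected_counts(spec$indication_freq)
    out$indication <- sample(rep(names(spec$indication_freq), ki))
  }
  out$cystic_fibrosis <- out$indication == "cystic_fibrosis"
  for (nm in names(spec$continuous)) {
    s <- spec$continuous[[nm]]
    qfun <- .fit_quantile_spline(s$median, s$iqr, s$range)
    out[[nm]] <- if (method == "random") {
      qfun(stats::runif(n))
    } else {
      sample(qfun((seq_len(n) - 0.5) / n))   # shuffled to keep covariates unlinked
    }
  }
  for (nm in names(spec$comed_freq)) {
    p <- spec$comed_freq[[nm]]
    out[[paste0("comed_", nm)]] <- if (method == "random") {
      stats::runif(n) < p
    } else {
      sample(rep(c(TRUE, FALSE), expected_counts(c(p, 1 - p))))
    }
  }
  out
}

#' Sparse TDM sampling design
#'
#' Describes when serum concentrations are drawn: number of samples per
#' subject (1 + truncated Poisson, matching a sparse-TDM average of 2.5
#' samples per patient with mode 2), an elimination-phase window in hours
#' after the last dose (its start must exceed the expected time to peak,
#' about 4.6 h at ka 0.8 1/h), a first sampling day (day 4, the expected
#' approach to steady state), and the assay's lower limit of
#' quantification.
#'
#' @param samples_range Integer range of samples per subject.
#' @param samples_mean Mean samples per subject (of the 1 + Poisson law).
#' @param window Hours after the most recent dose within which samples are
#'   drawn, `c(start, end)` with `end <= tau`.
#' @param start_day First day of treatment (1-based) on which sampling may
#'   occur.
#' @param max_day Last day on which sampling may occur.
#' @param expected_tmax Expected time to peak (h); the window must start
#'   after it so samples are in the elimination phase.
#' @param lloq Lower limit of quantification (mg/L).
#'
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(samples_range = c(1L, 12L), samples_mean = 2.5,
                            window = c(5, 24), start_day = 4, max_day = 40,
                            expected_tmax = 4.6, lloq = 0.1) {
  if (samples_range[1] < 1 || samples_range[2] < samples_range[1]) {
    stop("'samples_range' must satisfy 1 <= min <= max")
  }
  if (samples_mean < samples_range[1] || samples_mean > samples_range[2]) {
    stop("'samples_mean' must lie inside 'samples_range'")
  }
  if (window[1] <= expected_tmax) {
    stop("sampling window must start after the expected t_max (elimination phase)")
  }
  if (window[2] <= window[1]) stop("'window' must be increasing")
  if (start_day < 1 || max_day < start_day) stop("need 1 <= start_day <= max_day")
  if (lloq <= 0) stop("'lloq' must be positive")
  structure(
    list(samples_range = as.integer(samples_range), samples_mean = samples_mean,
         window = window, start_day = as.integer(start_day),
         max_day = as.integer(max_day), expected_tmax = expected_tmax,
         lloq = lloq),
    class = "sampling_design"
  )
}

## samples per subject: 1 + Poisson(mean-1), clamped to the design range
.draw_n_samples <- function(n, design) {
  k <- 1L + stats::rpois(n, design$samples_mean - 1)
  pmin(pmax(k, design$samples_range[1]), design$samples_range[2])
}

#' Simulate a sparse TDM dataset from a virtual cohort
#'
#' For each subject: draws true individual parameters from the population
#' model, lays down once-daily dosing from time 0, draws a sparse set of
#' elimination-phase sampling times on days `start_day..max_day`, computes
#' the true concentrations by superposition, perturbs them with the
#' proportional residual error, and flags values below the LLOQ (stored
#' with `DV = lloq`, `BLQ = 1`).
#'
#' @param cohort Covariate table from [generate_covariates()].
#' @param design A [sampling_design()].
#' @param pop A [population_parameters()].
#' @param regimen A [dosing_regimen()]; its `dose` is the starting (and,
#'   without an adjustment rule, constant) daily dose.
#' @param adjust_rule Optional `function(observed_conc, current_dose)`
#'   returning the dose used from the day after a measurement; `NULL`
#'   (default) keeps the dose constant, since the study's TDM adjustments
#'   followed no published rule.
#' @param seed Optional integer seed.
#'
#' @return A [tdm_dataset()] with one dose row per administration and one
#'   observation row per sample, covariates repeated on each row. The true
#'   generating parameters are attached as `attr(, "truth")` (data frame
#'   of per-subject `ka`, `v`, `cl` and etas).
#' @export
generate_tdm_dataset <- function(cohort, design = sampling_design(),
                                 pop = population_parameters(),
                                 regimen = dosing_regimen(300, 24),
                                 adjust_rule = NULL, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"),
            inherits(pop, "population_parameters"),
            inherits(regimen, "dosing_regimen"))
  if (!is.null(seed)) set.seed(seed)
  tau <- regimen$tau
  rows <- vector("list", nrow(cohort))
  truth <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    cov_i <- cohort[i, , drop = FALSE]
    p_i <- sample_individual(pop, cov_i)
    eta <- attr(p_i, "eta")
    truth[[i]] <- data.frame(id = cov_i$id, ka = p_i$ka, v = p_i$v, cl = p_i$cl,
                             eta_ka = eta$eta_ka, eta_v = eta$eta_v,
                             eta_cl = eta$eta_cl)
    n_obs <- .draw_n_samples(1L, design)
    obs_day <- sort(sample(seq(design$start_day, design$max_day), n_obs,
                           replace = TRUE))
    tsld <- stats::runif(n_obs, design$window[1], design$window[2])
    t_obs <- (obs_day - 1) * tau + tsld
    # dosing from day 1 through the last sampled day
    dose_t <- seq(0, by = tau, length.out = max(obs_day))
    dose_amt <- rep(regimen$dose, length(dose_t))
    if (!is.null(adjust_rule)) {
      # sequential pass: observations seen so far set later doses
      c_true_seq <- numeric(n_obs)
      for (j in seq_len(n_obs)) {
        on <- dose_t <= t_obs[j]
        c_true_seq[j] <- sum(.bateman(t_obs[j] - dose_t[on], dose_amt[on],
                                      p_i$ka, p_i$v, p_i$cl))
        y_j <- apply_residual_error(c_true_seq[j], pop$b_prop)
        later <- dose_t > t_obs[j]
        if (any(later)) dose_amt[later] <- adjust_rule(y_j, dose_amt[later][1])
      }
    }
    c_true <- vapply(t_obs, function(tt) {
      on <- dose_t <= tt
      sum(.bateman(tt - dose_t[on], dose_amt[on], p_i$ka, p_i$v, p_i$cl))
    }, numeric(1))
    y <- apply_residual_error(c_true, pop$b_prop)
    blq <- y < design$lloq
    dv <- ifelse(blq, design$lloq, y)
    sub <- data.frame(
      ID = cov_i$id,
      TIME = c(dose_t, t_obs),
      EVID = c(rep(1L, length(dose_t)), rep(0L, n_obs)),
      AMT = c(dose_amt, rep(NA_real_, n_obs)),
      DV = c(rep(NA_real_, length(dose_t)), dv),
      BLQ = c(rep(0L, length(dose_t)), as.integer(blq))
    )
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    cov_rep <- cov_i[rep(1L, nrow(sub)), setdiff(names(cov_i), "id"), drop = FALSE]
    rows[[i]] <- cbind(sub, cov_rep)
  }
  out <- tdm_dataset(do.call(rbind, rows))
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "lloq") <- design$lloq
  out
}
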