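#' Univariate covariate screening
#'
#' Screens candidate covariates against the individual-parameter
#' distributions: for each PK parameter (ka, Vd/F, CL/F) and each
#' candidate, a two-sided Pearson correlation test of the subject-level
#' random-effect estimate against a continuous covariate, or a one-way
#' ANOVA F test across levels of a categorical covariate. Candidates
#' with p < 0.05 are flagged for the stepwise model building.
#'
#' When MAP empirical Bayes estimates are strongly shrunk (sparse data),
#' pass conditional-distribution samples (see [estimate_ebes()] with
#' `n_samples > 0`): the per-subject conditional means are used instead
#' of the modes, which preserves screening power.
#'
#' @param ebes Either the list returned by [estimate_ebes()], a
#'   [fit_popmodel()] result, or a data frame with columns `eta_ka`,
#'   `eta_v`, `eta_cl` (one row per subject).
#' @param covariates Data frame of subject-level covariates, one row per
#'   subject in the same order.
#' @param candidates Covariate columns to screen (default: all except
#'   `id`).
#' @param shrinkage_switch Shrinkage percentage above which conditional
#'   means (if samples are available) replace MAP modes.
#'
#' @return An object of class `screening_table`: a candidates x 3 matrix
#'   of p-values with attribute `flagged` (p < 0.05). No multiplicity
#'   correction is applied.
#' @export
screen_covariates <- function(ebes, covariates,
                              candidates = setdiff(names(covariates), "id"),
                              shrinkage_switch = 30) {
  samples <- NULL
  shrink <- NULL
  if (inherits(ebes, "popfit")) {
    eta <- as.matrix(ebes$ebes[, paste0("eta_", .PARAMS)])
    shrink <- ebes$shrinkage
  } else if (is.list(ebes) && !is.null(ebes$ebes)) {
    eta <- as.matrix(ebes$ebes[, paste0("eta_", .PARAMS)])
    samples <- ebes$samples
    shrink <- ebes$shrinkage
  } else {
    eta <- as.matrix(ebes[, paste0("eta_", .PARAMS)])
  }
  if (nrow(eta) != nrow(covariates)) {
    stop("'covariates' must have one row per subject in 'ebes'")
  }
  if (!is.null(samples) && !is.null(shrink) && any(shrink > shrinkage_switch)) {
    cond_mean <- apply(samples, c(1, 3), mean)
    high <- which(shrink > shrinkage_switch)
    eta[, high] <- cond_mean[, high]
  }
  pv <- matrix(NA_real_, length(candidates), 3,
               dimnames = list(candidates, c("ka", "v", "cl")))
  for (cand in candidates) {
    x <- covariates[[cand]]
    if (is.null(x)) stop(sprintf("candidate '%s' not in covariates", cand))
    constant <- if (is.numeric(x)) stats::sd(x) == 0 else nlevels(factor(x)) < 2
    if (constant) {
      warning(sprintf("'%s' is constant; p-value undefined", cand))
      next
    }
    for (j in 1:3) {
      e <- eta[, j]
      pv[cand, j] <- if (is.numeric(x)) {
        if (stats::sd(e) == 0) NA_real_ else stats::cor.test(e, x)$p.value
      } else {
        stats::anova(stats::aov(e ~ factor(x)))[["Pr(>F)"]][1]
      }
    }
  }
  structure(pv, class = c("screening_table", "matrix"),
            flagged = !is.na(pv) & pv < 0.05)
}

#' @export
print.screening_table <- function(x, ...) {
  cat("Covariate screening p-values (parameter random effects)\n")
  m <- unclass(x)
  star <- ifelse(attr(x, "flagged"), " *", "  ")
  body <- matrix(paste0(formatC(m, digits = 3, format = "f"), star),
                 nrow(m), dimnames = dimnames(m))
  body[is.na(m)] <- "   NA"
  colnames(body) <- c("Ka", "Vd/F", "CL/F")
  print(body, quote = FALSE)
  cat("* p < 0.05\n")
  invisible(x)
}

#' Flagged (covariate, parameter) pairs from a screening table
#'
#' @param table A [screen_covariates()] result.
#' @return Data frame `covariate`, `parameter`, `p`, sorted by ascending
#'   p-value.
#' @export
screening_candidates <- function(table) {
  stopifnot(inherits(table, "screening_table"))
  fl <- attr(table, "flagged")
  idx <- which(fl, arr.ind = TRUE)
  out <- data.frame(covariate = rownames(table)[idx[, 1]],
                    parameter = colnames(table)[idx[, 2]],
                    p = table[fl])
  out[order(out$p), , drop = FALSE]
}

#' Stepwise covariate model building
#'
#' Forward inclusion of screened candidates in ascending screening-p
#' order, each kept iff the objective function value drops by more than
#' `dofv` (3.84 for one added parameter at p < 0.05 under the chi-square
#' approximation), followed by a backward elimination pass at the same
#' threshold. Covariates enter linearly on the log-parameter scale.
#'
#' @param dataset A [tdm_dataset()].
#' @param base_fit A [fit_popmodel()] result for the base model.
#' @param candidates Data frame as from [screening_candidates()] (may be
#'   empty: the base model is returned with an empty trace).
#' @param dofv OFV drop required for inclusion.
#' @param settings [estimation_settings()] used for the refits and for
#'   the (seed-matched) OFV evaluations.
#'
#' @return A list: `fit` (final model), `trace` (class `stepwise_trace`:
#'   one row per tested move with OFVs, the drop, and the decision).
#' @export
stepwise_build <- function(dataset, base_fit, candidates, dofv = 3.84,
                           settings = base_fit$settings) {
  stopifnot(inherits(base_fit, "popfit"))
  trace <- data.frame(step = integer(0), action = character(0),
                      covariate = character(0), parameter = character(0),
                      ofv_base = numeric(0), ofv_extended = numeric(0),
                      delta_ofv = numeric(0), accepted = logical(0))
  current <- base_fit
  model <- base_fit$covariate_model
  step <- 0L
  if (nrow(candidates)) {
    for (i in seq_len(nrow(candidates))) {
      cand <- candidates[i, ]
      if (cand$covariate %in% model[[cand$parameter]]) next
      trial <- model
      trial[[cand$parameter]] <- c(trial[[cand$parameter]], cand$covariate)
      fit_ext <- tryCatch(
        fit_popmodel(dataset, covariate_model = trial,
                     init = if (!is.null(current$pop)) current$pop else population_parameters(),
                     settings = settings),
        error = function(e) {
          message(sprintf("refit with %s on %s failed: %s; candidate skipped",
                          cand$covariate, cand$parameter, conditionMessage(e)))
          NULL
        })
      if (is.null(fit_ext)) next
      step <- step + 1L
      delta <- current$ofv - fit_ext$ofv
      accepted <- is.finite(delta) && delta > dofv
      trace[step, ] <- list(step, "forward", cand$covariate, cand$parameter,
                            current$ofv, fit_ext$ofv, delta, accepted)
      if (accepted) {
        current <- fit_ext
        model <- trial
      }
    }
    ## backward elimination over everything added beyond the base model
    added <- setdiff(unlist(lapply(.PARAMS, function(p) {
      paste(p, setdiff(model[[p]], base_fit$covariate_model[[p]]), sep = ":")
    })), character(0))
    for (tag in added) {
      parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
      trial <- model
      trial[[parts[1]]] <- setdiff(trial[[parts[1]]], parts[2])
      fit_red <- tryCatch(
        fit_popmodel(dataset, covariate_model = trial,
                     init = population_parameters(), settings = settings),
        error = function(e) NULL)
      if (is.null(fit_red)) next
      step <- step + 1L
      delta <- fit_red$ofv - current$ofv   # increase on removal
      keep <- is.finite(delta) && delta > dofv
      trace[step, ] <- list(step, "backward", parts[2], parts[1],
                            current$ofv, fit_red$ofv, delta, !keep)
      if (!keep) {
        current <- fit_red
        model <- trial
      }
    }
  }
  class(trace) <- c("stepwise_trace", "data.frame")
  list(fit = current, trace = trace)
}

#' @export
print.stepwise_trace <- function(x, ...) {
  if (!nrow(x)) {
    cat("Stepwise trace: no candidates tested (base model retained)\n")
  } else {
    cat("Stepwise covariate search\n")
    print(as.data.frame(x))
  }
  invisible(x)
}
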