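## Simulate K replicates of the dataset's observations under the model:
## fresh random effects per subject per replicate, proportional error on
## the predictions. Returns an n_obs x K matrix.
.simulate_replicates <- function(prep, Xs, theta, K) {
  omega <- theta$omega; b <- theta$b
  mu <- .mean_matrix(Xs, theta)
  n <- prep$n
  out <- matrix(NA_real_, prep$n_obs, K)
  for (k in seq_len(K)) {
    eta <- matrix(stats::rnorm(n * 3), n, 3) * rep(omega, each = n)
    phi <- mu + eta
    f <- .pred_conc(prep, exp(phi[, 1]), exp(phi[, 2]), exp(phi[, 3]))
    out[, k] <- pmax(f * (1 + b * stats::rnorm(prep$n_obs)), 0)
  }
  out
}

#' Normalized prediction distribution errors
#'
#' Simulation-based standardized residuals: `K` replicates of every
#' subject's design are simulated from the model; within each subject the
#' observed and simulated vectors are decorrelated with the Cholesky
#' factor of the empirical simulated covariance; each decorrelated
#' observation is ranked among its simulated counterparts and the rank
#' (with uniform jitter on ties, and the extremes mapped to `1/(2K)` and
#' `1 - 1/(2K)`) is pushed through the standard normal quantile. Under a
#' correct model the result is approximately standard normal.
#'
#' @param dataset A [tdm_dataset()].
#' @param pop A [population_parameters()] or [fit_popmodel()] result.
#' @param K Number of simulated replicates (>= 100; 1000 is the
#'   conventional choice).
#' @param seed Integer seed.
#'
#' @return Numeric vector of NPDE values, one per non-BLQ observation,
#'   with attributes `id` and `time`.
#' @export
compute_npde <- function(dataset, pop, K = 1000, seed = 1234) {
  if (K < 100) stop("'K' must be at least 100 replicates")
  theta <- .as_theta(pop)
  set.seed(seed)
  prep <- .prepare_dataset(dataset)
  Xs <- .model_matrices(prep$covariates, .covariate_model_of(pop))
  theta <- .align_theta(theta, Xs)
  sims <- .simulate_replicates(prep, Xs, theta, K)
  npde <- numeric(prep$n_obs)
  for (i in seq_len(prep$n)) {
    idx <- which(prep$subj == i)
    S <- sims[idx, , drop = FALSE]              # n_i x K
    m <- rowMeans(S)
    V <- stats::cov(t(S))
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      warning(sprintf("singular simulated covariance for subject %s; ridge added",
                      prep$ids[i]))
      L <- chol(V + diag(1e-8 * max(diag(V)), nrow(V)))
    }
    y_dec <- backsolve(L, prep$y[idx] - m, transpose = TRUE)
    S_dec <- backsolve(L, S - m, transpose = TRUE)
    for (j in seq_along(idx)) {
      cmp <- S_dec[j, ]
      r <- sum(cmp < y_dec[j]) + sum(cmp == y_dec[j]) * stats::runif(1)
      u <- min(max(r / K, 1 / (2 * K)), 1 - 1 / (2 * K))
      npde[idx[j]] <- stats::qnorm(u)
    }
  }
  structure(npde, id = prep$ids[prep$subj], time = prep$time)
}

#' Goodness-of-fit table
#'
#' One row per non-BLQ observation: the observed concentration, the
#' population prediction (random effects at zero), the individual
#' prediction (MAP random effects), and the NPDE.
#'
#' @inheritParams compute_npde
#' @return A data frame `id`, `time`, `observed`, `pred_population`,
#'   `pred_individual`, `npde`.
#' @export
gof_table <- function(dataset, pop, K = 1000, seed = 1234) {
  theta <- .as_theta(pop)
  prep <- .prepare_dataset(dataset)
  Xs <- .model_matrices(prep$covariates, .covariate_model_of(pop))
  theta <- .align_theta(theta, Xs)
  mu <- .mean_matrix(Xs, theta)
  pred_pop <- .pred_conc(prep, exp(mu[, 1]), exp(mu[, 2]), exp(mu[, 3]))
  eta <- .map_ebes(prep, Xs, theta)
  phi <- mu + eta
  pred_ind <- .pred_conc(prep, exp(phi[, 1]), exp(phi[, 2]), exp(phi[, 3]))
  npde <- compute_npde(dataset, pop, K = K, seed = seed)
  data.frame(id = prep$ids[prep$subj], time = prep$time, observed = prep$y,
             pred_population = pred_pop, pred_individual = pred_ind,
             npde = as.numeric(npde))
}

#' Visual predictive check
#'
#' Compares the observed 10th/50th/90th percentiles of concentration,
#' binned on time after the most recent dose, with the 90% prediction
#' interval of the same percentiles across `K` simulated replicates of
#' the dataset. Bins are quantile-based; bins with fewer than 5
#' observations are merged with their neighbour. Optional prediction
#' correction (Bergstrand) rescales each observation and simulation by
#' the ratio of the bin-median population prediction to its own
#' population prediction, which removes dose- and covariate-driven
#' spread; it is off by default.
#'
#' @inheritParams compute_npde
#' @param bins Target number of time-after-dose bins.
#' @param pred_correct Apply prediction correction.
#'
#' @return An object of class `vpc_result`: a data frame with one row per
#'   bin x percentile: bin midpoint, number of observations, the observed
#'   percentile, and the simulated 90% interval bounds; `K` is attached
#'   as an attribute.
#' @export
vpc <- function(dataset, pop, K = 1000, bins = 6, pred_correct = FALSE,
                seed = 1234) {
  if (K < 100) stop("'K' must be at least 100 replicates")
  theta <- .as_theta(pop)
  set.seed(seed)
  prep <- .prepare_dataset(dataset)
  Xs <- .model_matrices(prep$covariates, .covariate_model_of(pop))
  theta <- .align_theta(theta, Xs)
  ## time after most recent dose, per observation
  tad <- as.numeric(tapply(prep$pair_tdiff, prep$pair_obs, min))
  y <- prep$y
  sims <- .simulate_replicates(prep, Xs, theta, K)
  if (pred_correct) {
    mu <- .mean_matrix(Xs, theta)
    pred <- .pred_conc(prep, exp(mu[, 1]), exp(mu[, 2]), exp(mu[, 3]))
  }
  ## quantile bins on TAD, merging small bins with their left neighbour
  edges <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(tad, edges, include.lowest = TRUE, labels = FALSE)
  repeat {
    counts <- table(factor(bin, levels = seq_len(max(bin))))
    small <- which(counts < 5)
    if (!length(small) || length(counts) == 1) break
    s <- small[1]
    message(sprintf("VPC bin %d has <5 observations; merged with neighbour", s))
    into <- if (s == 1) 2 else s - 1
    bin[bin == s] <- into
    bin <- match(bin, sort(unique(bin)))
  }
  if (pred_correct) {
    med_pred <- stats::ave(pred, bin, FUN = stats::median)
    scale <- med_pred / pmax(pred, 1e-12)
    y <- y * scale
    sims <- sims * scale
  }
  probs <- c(0.1, 0.5, 0.9)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(bnum) {
    idx <- bin == bnum
    obs_q <- stats::quantile(y[idx], probs, names = FALSE)
    sim_q <- apply(sims[idx, , drop = FALSE], 2, stats::quantile,
                   probs = probs, names = FALSE)   # 3 x K
    pi_lo <- apply(sim_q, 1, stats::quantile, probs = 0.05, names = FALSE)
    pi_hi <- apply(sim_q, 1, stats::quantile, probs = 0.95, names = FALSE)
    data.frame(bin = bnum, tad_mid = stats::median(tad[idx]), n_obs = sum(idx),
               percentile = c(10, 50, 90), observed = obs_q,
               sim_lower = pi_lo, sim_upper = pi_hi)
  }))
  rownames(out) <- NULL
  structure(out, class = c("vpc_result", "data.frame"), K = K,
            pred_correct = pred_correct)
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d bins, %d replicates%s\n", length(unique(x$bin)),
              attr(x, "K"), if (isTRUE(attr(x, "pred_correct"))) " (prediction-corrected)" else ""))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}
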