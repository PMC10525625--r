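# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms.

# Numerical ODE solution of gut -> central with first-order transfer.
ode_conc <- function(t, dose, ka, v, cl) {
  ke <- cl / v
  deriv <- function(tt, y, parms) {
    list(c(-ka * y[1], ka * y[1] - ke * y[2]))
  }
  times <- sort(unique(c(0, t)))
  sol <- deSolve::lsoda(c(gut = dose, cent = 0), times, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  unname(sol[match(t, sol[, "time"]), "cent"] / v)
}

# Two-sided Fisher exact p-value by full hypergeometric enumeration over
# all tables with the observed margins.
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ])          # row 1 total
  n2 <- sum(tab[2, ])         # row 2 total
  k <- sum(tab[, 1])          # column 1 total
  x <- tab[1, 1]
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(x, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand-built dense-design dataset for one or more subjects with known
# individual parameters: doses daily up to n_days, observations at the
# given times after the first dose.
dense_dataset <- function(params, times, n_days = 10, dose = 300, b = 0.02,
                          ages = rep(50, length(params)), seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(params), function(i) {
    p <- params[[i]]
    dose_t <- seq(0, by = 24, length.out = n_days)
    f <- vapply(times, function(tt) {
      on <- dose_t <= tt
      sum(conc_single_dose(tt - dose_t[on], dose, p))
    }, numeric(1))
    y <- f * (1 + b * stats::rnorm(length(times)))
    data.frame(
      ID = i,
      TIME = c(dose_t, times),
      EVID = c(rep(1L, n_days), rep(0L, length(times))),
      AMT = c(rep(dose, n_days), rep(NA_real_, length(times))),
      DV = c(rep(NA_real_, n_days), y),
      BLQ = 0L,
      age = ages[i]
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$ID, df$TIME, -df$EVID), ]
  tdm_dataset(df)
}

# Quick small settings for fits inside tests.
fast_settings <- function(seed = 1, ...) {
  estimation_settings(n_explore = 80, n_smooth = 40, ofv_mc = 200,
                      seed = seed, ...)
}
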