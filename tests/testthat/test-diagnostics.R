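test_that("NPDE is calibrated to a standard normal under the true model", {
  pop <- population_parameters()
  cov <- generate_covariates(cohort_spec(), n = 100, seed = 121)
  des <- sampling_design(samples_range = c(5L, 5L), samples_mean = 5,
                         max_day = 20)
  ds <- suppressWarnings(generate_tdm_dataset(cov, des, pop, seed = 122))
  npde <- suppressWarnings(compute_npde(ds, pop, K = 200, seed = 123))
  expect_gte(length(npde), 450)
  expect_lt(abs(mean(npde)), 0.1)
  expect_gt(var(npde), 0.85)
  expect_lt(var(npde), 1.15)
})

test_that("an observation at the simulated median has NPDE near zero", {
  pop0 <- population_parameters(omega_ka = 0, omega_v = 0, omega_cl = 0,
                                b_prop = 0.05)
  # observations equal to the model prediction: the centre of a symmetric
  # simulated distribution
  p_typ <- individual_params(pop0, list(age = 50))
  dose_t <- seq(0, by = 24, length.out = 6)
  tt <- c(100, 124)
  f <- vapply(tt, function(x)
    sum(conc_single_dose(x - dose_t[dose_t <= x], 300, p_typ)), numeric(1))
  df <- data.frame(
    ID = 1, TIME = c(dose_t, tt), EVID = c(rep(1L, 6), 0L, 0L),
    AMT = c(rep(300, 6), NA, NA), DV = c(rep(NA, 6), f), BLQ = 0L, age = 50)
  ds <- tdm_dataset(df[order(df$TIME, -df$EVID), ])
  npde <- compute_npde(ds, pop0, K = 1000, seed = 124)
  expect_lt(max(abs(npde)), 0.3)
})

test_that("NPDE detects a misspecified clearance", {
  pop <- population_parameters()
  cov <- generate_covariates(cohort_spec(), n = 60, seed = 125)
  des <- sampling_design(samples_range = c(4L, 4L), samples_mean = 4,
                         max_day = 15)
  ds <- suppressWarnings(generate_tdm_dataset(cov, des, pop, seed = 126))
  wrong <- population_parameters(cl_pop = pop$cl_pop / 2)
  npde <- suppressWarnings(compute_npde(ds, wrong, K = 200, seed = 127))
  # model clearance too low -> predictions too high -> NPDE shifted down
  tt <- t.test(as.numeric(npde))
  expect_lt(tt$p.value, 0.01)
  expect_lt(mean(npde), 0)
})

test_that("GOF table pairs observations with both prediction levels", {
  pop <- population_parameters()
  cov <- generate_covariates(cohort_spec(), n = 20, seed = 128)
  ds <- suppressWarnings(generate_tdm_dataset(cov, pop = pop, seed = 129))
  gof <- suppressWarnings(gof_table(ds, pop, K = 150, seed = 130))
  expect_identical(nrow(gof), sum(ds$EVID == 0 & ds$BLQ == 0))
  expect_true(all(gof$pred_population > 0))
  expect_true(all(is.finite(gof$npde)))
  # individual predictions track the data more closely than population ones
  expect_lt(median(abs(gof$observed - gof$pred_individual)),
            median(abs(gof$observed - gof$pred_population)))
})

test_that("VPC validates inputs, is deterministic, and orders its bands", {
  pop <- population_parameters()
  cov <- generate_covariates(cohort_spec(), n = 50, seed = 131)
  des <- sampling_design(samples_range = c(3L, 4L), samples_mean = 3.5)
  ds <- suppressWarnings(generate_tdm_dataset(cov, des, pop, seed = 132))
  expect_error(vpc(ds, pop, K = 2), "at least 100")
  v1 <- suppressWarnings(vpc(ds, pop, K = 150, seed = 133))
  v2 <- suppressWarnings(vpc(ds, pop, K = 150, seed = 133))
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_true(all(v1$sim_lower <= v1$sim_upper))
  for (bn in unique(v1$bin)) {
    obs_q <- v1$observed[v1$bin == bn][order(v1$percentile[v1$bin == bn])]
    expect_true(all(diff(obs_q) >= 0))
  }
  # small bins are merged with a message
  tiny <- suppressWarnings(generate_tdm_dataset(
    generate_covariates(cohort_spec(), n = 8, seed = 134), des, pop, seed = 135))
  expect_message(suppressWarnings(vpc(tiny, pop, K = 120, bins = 6, seed = 136)),
                 "merged")
})

test_that("VPC bands cover the observed median under the true model", {
  pop <- population_parameters()
  des <- sampling_design(samples_range = c(3L, 4L), samples_mean = 3.5,
                         max_day = 15)
  hits <- 0; total <- 0
  for (r in seq_len(20)) {
    cov <- generate_covariates(cohort_spec(), n = 40, seed = 140 + r)
    ds <- suppressWarnings(generate_tdm_dataset(cov, des, pop, seed = 160 + r))
    v <- suppressWarnings(vpc(ds, pop, K = 150, bins = 4, seed = 180 + r))
    med <- v[v$percentile == 50, ]
    hits <- hits + sum(med$observed >= med$sim_lower &
                         med$observed <= med$sim_upper)
    total <- total + nrow(med)
  }
  expect_gte(hits / total, 0.9)
})
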