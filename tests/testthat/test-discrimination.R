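test_that("Harrell's C matches exhaustive pair enumeration", {
  expect_equal(harrells_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(harrells_c(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0.0)
  ## usable pairs {(1,2),(1,3)}, concordant {(1,2)}
  expect_equal(harrells_c(c(2, 1, 3), c(1, 2, 3), c(1, 0, 1)), 0.5)
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    risk <- sample(n, n, replace = TRUE)    # with risk ties
    time <- round(rexp(n), 2)
    event <- rbinom(n, 1, 0.7)
    if (!any(event)) next
    got <- tryCatch(harrells_c(risk, time, event), error = function(e) NULL)
    want <- tryCatch(oracle_c_index(risk, time, event), error = function(e) NULL)
    expect_equal(got, want)
  }
  ## antisymmetry without risk ties
  set.seed(62)
  risk <- rnorm(20); time <- rexp(20); event <- rbinom(20, 1, 0.6)
  expect_equal(harrells_c(risk, time, event) + harrells_c(-risk, time, event), 1)
  expect_error(harrells_c(1, 2, 0), "usable")
})

test_that("cumulative/dynamic AUC reduces to Mann-Whitney without censoring", {
  expect_equal(cumulative_dynamic_auc(c(4, 3, 2, 1), c(1, 2, 3, 4),
                                      rep(1, 4), 2.5), 1.0)
  expect_equal(cumulative_dynamic_auc(rep(1, 6), 1:6, rep(1, 6), 3.5), 0.5)
  set.seed(63)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    time <- rexp(n) + 0.01
    risk <- sample(5, n, replace = TRUE)
    horizon <- median(time)
    lab <- as.integer(time <= horizon)
    if (length(unique(lab)) < 2) next
    expect_equal(cumulative_dynamic_auc(risk, time, rep(1, n), horizon),
                 oracle_auc(risk, lab))
  }
  expect_error(cumulative_dynamic_auc(1:4, c(5, 6, 7, 8), rep(1, 4), 2),
               "no cases")
  expect_error(cumulative_dynamic_auc(1:4, c(1, 2, 3, 4), rep(1, 4), 9),
               "no controls")
})

test_that("censored AUC estimate approaches the uncensored truth", {
  beta <- 1
  horizon <- 2
  set.seed(64)
  ## truth from a large uncensored draw of the same generating model
  x0 <- rnorm(2e4)
  t0 <- rexp(2e4, 0.3 * exp(beta * x0))
  truth <- auc_binary(x0[1:8000], (t0 <= horizon)[1:8000])
  ## heavily censored sample
  n <- 4000
  x <- rnorm(n)
  t_ev <- rexp(n, 0.3 * exp(beta * x))
  cens <- runif(n, 0, 4)
  est <- cumulative_dynamic_auc(x, pmin(t_ev, cens), t_ev <= cens, horizon)
  expect_equal(est, truth, tolerance = 0.03)
})

test_that("metrics are invariant under strictly monotone risk transforms", {
  set.seed(65)
  risk <- rnorm(40); time <- rexp(40); event <- rbinom(40, 1, 0.6)
  event[1] <- 1
  h <- median(time)
  expect_equal(harrells_c(exp(risk), time, event), harrells_c(risk, time, event))
  expect_equal(cumulative_dynamic_auc(2 * risk + 5, time, event, h),
               cumulative_dynamic_auc(risk, time, event, h))
  lab <- rbinom(40, 1, 0.5); lab[1:2] <- c(0, 1)
  expect_equal(auc_binary(plogis(risk), lab), auc_binary(risk, lab))
})

test_that("discrimination slope and IDI follow their definitions", {
  p_new <- c(0.8, 0.6, 0.2)
  p_old <- c(0.6, 0.4, 0.4)
  labels <- c(1, 1, 0)
  expect_equal(discrimination_slope(p_new, labels), 0.5)
  expect_equal(discrimination_slope(p_old, labels), 0.1)
  expect_equal(idi(p_new, p_old, labels), 0.4)
  expect_equal(idi(p_new, p_new, labels), 0)
  ## adding a constant leaves a slope unchanged
  expect_equal(discrimination_slope(p_new + 0.1, labels),
               discrimination_slope(p_new, labels))
  expect_error(discrimination_slope(p_new, c(1, 1, 1)), "both")
})

test_that("model-pair discrimination report is internally consistent", {
  sim <- simulate_cohort(generator_config(n_patients = 500), seed = 66)
  rec <- sim$cohort
  rec$stage <- factor(rec$stage)
  f3 <- suppressMessages(fit_cox(rec, c("age", "sex", "stage", "bmi", "crp_gt10")))
  f2 <- suppressMessages(fit_cox(rec, c("age", "sex", "stage")))
  rep <- compare_discrimination(f3, f2, rec, horizon = 5)
  expect_equal(rep$idi, unname(rep$slopes["new"] - rep$slopes["reference"]),
               tolerance = 1e-12)
  expect_true(all(rep$harrells_c > 0.5 & rep$harrells_c < 1))
  expect_true(all(rep$auc_t > 0.5 & rep$auc_t < 1))
})
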