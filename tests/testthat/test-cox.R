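test_that("Cox fit matches brute-force partial-likelihood maximisation", {
  ## binary covariate, event times (1,3) in group 1 and (2,4) in group 0,
  ## interleaved so the partial-likelihood maximum is interior
  dat <- data.frame(time = c(1, 3, 2, 4), event_all = TRUE,
                    x = c(1, 1, 0, 0))
  fit <- fit_cox(dat, "x")
  oracle <- oracle_cox_coef(dat$time, rep(1, 4), dat$x)
  expect_lt(abs(unname(fit$coefficients["x"]) - oracle), 1e-6)

  set.seed(41)
  compared <- 0
  while (compared < 5) {
    d <- random_survival(7)
    d$event_all <- d$event == 1
    f <- tryCatch(
      withCallingHandlers(suppressMessages(fit_cox(d, "x")),
                          warning = function(w) stop("not converged")),
      error = function(e) NULL)
    if (is.null(f)) next
    ll <- vapply(c(-2, 0, 2), cox_partial_loglik, 0,
                 time = d$time, event = d$event, x = d$x)
    if (diff(range(ll)) < 1e-9) next
    oc <- oracle_cox_coef(d$time, d$event, d$x)
    if (abs(oc) > 9) next
    expect_lt(abs(unname(f$coefficients["x"]) - oc), 1e-5)
    compared <- compared + 1
  }
})

test_that("degenerate inputs raise informative errors", {
  dat <- data.frame(time = 1:6, event_all = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                    x = 0, y = rnorm(6))
  expect_error(fit_cox(dat, "x"), "constant")
  dat$event_all <- FALSE
  expect_error(fit_cox(dat, "y"), "no events")
  ## monotone likelihood: covariate perfectly orders the failures
  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12, 13, 14),
                    event_all = TRUE,
                    x = c(1, 1, 1, 0, 0, 0, 0, 0))
  expect_error(suppressWarnings(fit_cox(sep, "x")), "separation")
})

test_that("duplicating every record keeps the coefficient and shrinks the SE by sqrt(2)", {
  set.seed(42)
  d <- random_survival(200)
  d$event_all <- d$event == 1
  ## Breslow ties: duplication shifts the partial likelihood by a constant,
  ## so the maximiser is exactly invariant
  f1 <- fit_cox(d, "x", ties = "breslow")
  f2 <- fit_cox(rbind(d, d), "x", ties = "breslow")
  expect_equal(unname(f2$coefficients), unname(f1$coefficients), tolerance = 1e-6)
  expect_equal(unname(f1$se / f2$se), sqrt(2), tolerance = 0.05)
})

test_that("the CRC outcome view censors non-CRC deaths", {
  rec <- data.frame(sample_id = c("a", "b", "c"), time = c(2, 3, 4),
                    event_all = c(TRUE, TRUE, FALSE),
                    event_crc = c(FALSE, TRUE, FALSE))
  v <- crc_outcome_view(rec)
  expect_equal(v$event, c(FALSE, TRUE, FALSE))
  expect_equal(v$time, rec$time)         # censored at the death time
  bad <- rec; bad$event_crc[3] <- TRUE
  expect_error(crc_outcome_view(bad), "implies")
})

test_that("predicted horizon risk behaves like the survival function", {
  set.seed(7)
  lambda <- 0.25
  n <- 2000
  d <- data.frame(t_ev = rexp(n, lambda), cens = runif(n, 0, 8))
  d$time <- pmin(d$t_ev, d$cens)
  d$event_all <- d$t_ev <= d$cens
  null_fit <- fit_cox(d, character(0))
  p <- predict_risk(null_fit, d, horizon = 3)
  expect_lt(diff(range(p)), 1e-12)       # no covariates: identical risk
  lambda_hat <- sum(d$event_all) / sum(d$time)
  expect_equal(p[1], 1 - exp(-lambda_hat * 3), tolerance = 0.02)

  ## strictly increasing in the linear predictor
  d$x <- rnorm(n)
  fx <- fit_cox(d, "x")
  px <- predict_risk(fx, d, horizon = 3)
  lp <- unname(fx$coefficients["x"]) * d$x
  expect_true(all(diff(px[order(lp)]) >= 0))
})

test_that("proportional-hazards diagnostics calibrate under PH and detect violations", {
  set.seed(77)
  pvals <- replicate(120, {
    n <- 150
    x <- rbinom(n, 1, 0.5)
    t_ev <- rweibull(n, 1.3, 8) * exp(-0.5 * x / 1.3)
    cens <- runif(n, 2, 15)
    d <- data.frame(time = pmin(t_ev, cens), event_all = t_ev <= cens, x = x)
    ph_diagnostics(fit_cox(d, "x"))$ph$p[1]
  })
  expect_gte(mean(pvals < 0.05), 0.01)
  expect_lte(mean(pvals < 0.05), 0.12)

  ## crossing hazards: shape 0.5 vs 2 with matched medians
  set.seed(78)
  hits <- replicate(10, {
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    t_ev <- ifelse(x == 1,
                   rweibull(n, 0.5, 5 / log(2)^2),
                   rweibull(n, 2, 5 / sqrt(log(2))))
    d <- data.frame(time = t_ev, event_all = TRUE, x = x)
    ph_diagnostics(fit_cox(d, "x"))$ph$p[1] < 0.05
  })
  expect_gt(mean(hits), 0.5)

  ## single event with an interior coefficient (event covariate between the
  ## censored ones): the fit succeeds but diagnostics are undefined
  one <- data.frame(time = c(1, 2, 3), event_all = c(TRUE, FALSE, FALSE),
                    x = c(0, 1, -1))
  expect_error(ph_diagnostics(fit_cox(one, "x")), "fewer than 2")
})

test_that("linearity screen flags a strongly non-linear covariate", {
  set.seed(79)
  n <- 800
  x <- rnorm(n)
  t_ev <- rexp(n, exp(1.2 * x^2 - 1))
  d <- data.frame(time = t_ev, event_all = TRUE, x = x)
  diag <- ph_diagnostics(fit_cox(d, "x"))
  expect_lt(diag$linearity$p[diag$linearity$covariate == "x"], 0.01)
})
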