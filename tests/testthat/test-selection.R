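make_selection_data <- function(n = 500, n_null = 10, beta = 0.5, seed = 81) {
  set.seed(seed)
  u <- rnorm(n)
  nulls <- matrix(rnorm(n * n_null), n, dimnames = list(NULL, paste0("null", seq_len(n_null))))
  t_ev <- rexp(n, 0.15 * exp(beta * u))
  cens <- runif(n, 2, 12)
  records <- data.frame(sample_id = sprintf("S%04d", 1:n),
                        time = pmin(t_ev, cens), event_all = t_ev <= cens,
                        event_crc = t_ev <= cens,
                        age = rnorm(n, 60, 8), sex = factor(rbinom(n, 1, 0.5)),
                        crp_gt10 = rbinom(n, 1, 0.1) > 0)
  traits <- data.frame(sample_id = records$sample_id, planted = u, nulls,
                       check.names = FALSE)
  list(records = records, traits = traits)
}

test_that("bootstrap importance puts a planted trait first", {
  d <- make_selection_data()
  rk <- bootstrap_importance(d$traits, d$records, n_boot = 25, seed = 2,
                             eta = 0.1, nrounds = 150)
  expect_equal(rk$table$trait[1], "planted")
  expect_gt(rk$table$frequency[1], 0.9)
  expect_equal(sum(rk$table$importance > 0), nrow(rk$table) -
                 sum(rk$table$importance == 0))
  expect_error(bootstrap_importance(d$traits, d$records, n_boot = 0), "n_boot")
})

test_that("duplicated trait columns share boosting credit", {
  d <- make_selection_data(n = 400, n_null = 5)
  single <- bootstrap_importance(d$traits, d$records, n_boot = 40, seed = 3,
                                 eta = 0.1, nrounds = 120)
  dup <- d$traits
  dup$planted_copy <- dup$planted
  both <- bootstrap_importance(dup, d$records, n_boot = 40, seed = 3,
                               eta = 0.1, nrounds = 120)
  imp_single <- single$table$importance[single$table$trait == "planted"]
  imp_pair <- sum(both$table$importance[both$table$trait %in%
                                          c("planted", "planted_copy")])
  expect_equal(imp_pair, imp_single, tolerance = 0.3)
})

test_that("ranking is invariant to trait column order under one seed", {
  d <- make_selection_data(n = 300, n_null = 4)
  r1 <- bootstrap_importance(d$traits, d$records, n_boot = 10, seed = 5,
                             eta = 0.1, nrounds = 80)
  shuffled <- d$traits[, c("sample_id", "null3", "planted", "null1", "null2",
                           "null4")]
  r2 <- bootstrap_importance(shuffled, d$records, n_boot = 10, seed = 5,
                             eta = 0.1, nrounds = 80)
  expect_equal(r1$table$trait, r2$table$trait)
  expect_equal(r1$table$importance, r2$table$importance, tolerance = 1e-10)
})

test_that("forward LLR selection adds true signal and respects its base model", {
  d <- make_selection_data(n = 800, n_null = 6, seed = 82)
  base <- c("age", "sex")
  ## empty candidate list returns the base model
  sel0 <- forward_llr_select(character(0), d$traits[, "sample_id", drop = FALSE],
                             d$records, base)
  expect_equal(sel0$selected, character(0))
  expect_equal(sel0$fit$covariates, base)

  ## a copy of a base covariate is never selected
  tr <- d$traits
  tr$age_copy <- d$records$age
  sel1 <- forward_llr_select(c("age_copy"), tr, d$records, base)
  expect_false("age_copy" %in% sel1$selected)

  rk <- bootstrap_importance(d$traits, d$records, n_boot = 15, seed = 6,
                             eta = 0.1, nrounds = 120)
  sel <- forward_llr_select(rk, d$traits, d$records, base, alpha = 0.05)
  expect_true("planted" %in% sel$selected)
  expect_lte(length(setdiff(sel$selected, "planted")), 1)
  ## in-sample log-likelihood never decreases along accepted steps
  added <- sel$steps[sel$steps$added, ]
  expect_true(all(added$llr >= 0))
})

test_that("penalised Cox reduces to the clinical model in the strong-penalty limit", {
  d <- make_selection_data(n = 300, n_null = 5, seed = 83)
  clin <- cbind(age = d$records$age)
  gly <- as.matrix(d$traits[, -1])
  x <- cbind(clin, gly)
  y <- survival::Surv(d$records$time, as.numeric(d$records$event_all))
  pf <- c(0, rep(1, ncol(gly)))
  fit <- glmnet::glmnet(x, y, family = "cox", penalty.factor = pf,
                        lambda = c(50, 10), thresh = 1e-12)
  cf <- as.numeric(coef(fit, s = 50))
  expect_true(all(cf[-1] == 0))           # glycans fully shrunk
  clin_fit <- survival::coxph(y ~ clin, ties = "breslow")
  expect_equal(cf[1], unname(coef(clin_fit)), tolerance = 1e-3)
})

test_that("unpenalised limit matches the Cox fit", {
  d <- make_selection_data(n = 120, n_null = 2, seed = 84)
  x <- as.matrix(d$traits[, -1])
  y <- survival::Surv(d$records$time, as.numeric(d$records$event_all))
  lam <- exp(seq(log(1), log(1e-8), length.out = 30))
  fit <- glmnet::glmnet(x, y, family = "cox", lambda = lam, thresh = 1e-14)
  dat <- cbind(d$records, d$traits[, -1])
  ref <- fit_cox(dat, colnames(x), ties = "breslow")
  expect_equal(as.numeric(coef(fit, s = 1e-8)), unname(ref$coefficients),
               tolerance = 1e-4)
})

test_that("validation deviance comparison is calibrated under null glycans", {
  covered <- vapply(1:5, function(i) {
    set.seed(90 + i)
    n <- 350
    records <- data.frame(sample_id = sprintf("S%03d", 1:n),
                          age = rnorm(n, 60, 8))
    t_ev <- rexp(n, 0.1 * exp(0.03 * (records$age - 60)))
    cens <- runif(n, 2, 15)
    records$time <- pmin(t_ev, cens)
    records$event_all <- t_ev <= cens
    records$event_crc <- records$event_all
    traits <- data.frame(sample_id = records$sample_id,
                         matrix(rnorm(n * 6), n,
                                dimnames = list(NULL, paste0("g", 1:6))))
    cmp <- l1_cox_deviance_compare(records, "age", traits, folds = 4,
                                   inner_folds = 4, seed = i)
    cmp$ci95[1] <= 0 && cmp$ci95[2] >= 0
  }, TRUE)
  expect_gte(sum(covered), 3)
})
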