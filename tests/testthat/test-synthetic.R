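test_that("identical seeds give bit-identical cohorts", {
  a <- simulate_cohort(generator_config(n_patients = 150), seed = 9)
  b <- simulate_cohort(generator_config(n_patients = 150), seed = 9)
  expect_identical(a$peak_table, b$peak_table)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$glycan_score, b$truth$glycan_score)
  c <- simulate_cohort(generator_config(n_patients = 150), seed = 10)
  expect_false(identical(a$cohort$time, c$cohort$time))
})

test_that("clinical marginals follow the configured study conditions", {
  cfg <- generator_config()
  set.seed(21)
  rec <- generate_clinical(cfg)
  expect_equal(nrow(rec), 1229L)
  ## stage counts within the binomial 99% envelope of (249, 421, 413, 146)
  counts <- tabulate(rec$stage, 4)
  for (s in 1:4) {
    lo <- qbinom(0.005, 1229, cfg$stage_probs[s])
    hi <- qbinom(0.995, 1229, cfg$stage_probs[s])
    expect_gte(counts[s], lo)
    expect_lte(counts[s], hi)
  }
  expect_true(all(rec$age >= 30 & rec$age <= 90))
  expect_true(all(rec$bmi > 0, na.rm = TRUE))
  expect_equal(mean(is.na(rec$bmi)), 172 / 1229, tolerance = 0.35)
  expect_equal(mean(rec$crp > 10), 130 / 1229, tolerance = 0.35)
  expect_equal(median(rec$op_to_sample), 5.4, tolerance = 0.2)

  cfg1 <- generator_config(stage_probs = c(1, 0, 0, 0))
  set.seed(1)
  expect_true(all(generate_clinical(cfg1)$stage == 1))
  expect_error(generator_config(n_patients = 0), "positive")
  expect_error(generator_config(stage_probs = c(0.5, 0.5, 0.5, -0.5)))
})

test_that("plate standards reflect technical noise only", {
  cfg <- generator_config(n_patients = 200, technical_sd = 0)
  sim <- simulate_cohort(cfg, seed = 3)
  std <- normalize_total_area(sim$peak_table)
  std <- std[std$is_standard, paste0("GP", 1:24)]
  expect_gt(nrow(std), 2)
  expect_lt(max(abs(sweep(as.matrix(std), 2, as.matrix(std)[1, ]))), 1e-9)

  ## positive areas, closed after normalisation
  sim2 <- simulate_cohort(generator_config(n_patients = 120), seed = 4)
  areas <- as.matrix(sim2$peak_table[paste0("GP", 1:24)])
  expect_true(all(areas > 0))
  norm <- normalize_total_area(sim2$peak_table)
  expect_lt(max(abs(rowSums(norm[paste0("GP", 1:24)]) - 100)), 1e-9)
  ## every plate of a cohort sample carries standards
  plates <- unique(sim2$peak_table$plate_id[!sim2$peak_table$is_standard])
  for (p in plates)
    expect_gte(sum(sim2$peak_table$is_standard & sim2$peak_table$plate_id == p),
               cfg$standards_per_plate)
})

test_that("robustness worsens as technical noise grows", {
  mean_rob <- vapply(c(0.02, 0.08, 0.2), function(ts) {
    sim <- simulate_cohort(generator_config(n_patients = 950, technical_sd = ts),
                           seed = 17)
    tm <- compute_robustness(derive_traits(normalize_total_area(sim$peak_table)))
    mean(tm$robustness, na.rm = TRUE)
  }, 0)
  expect_true(all(is.finite(mean_rob)))
  expect_true(all(diff(mean_rob) > 0))
})

test_that("survival times follow the Weibull baseline when all effects are null", {
  cfg <- generator_config(n_patients = 5000, log_hr_stage = c(0, 0, 0),
                          log_hr_glycan = 0, log_hr_age = 0, log_hr_crp = 0,
                          admin_censor_years = 1e6,
                          recruitment_window_years = 1e-9)
  sim <- simulate_cohort(cfg, seed = 31)
  expect_true(all(sim$cohort$event_all))
  ks <- suppressWarnings(
    ks.test(sim$cohort$time, pweibull, shape = cfg$baseline_hazard_shape,
            scale = cfg$baseline_hazard_scale))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero administrative censor window yields zero events", {
  sim <- simulate_cohort(generator_config(n_patients = 100,
                                          admin_censor_years = 0), seed = 6)
  expect_false(any(sim$cohort$event_all))
  expect_true(all(sim$cohort$time == 0))
})

test_that("cause labels respect the event hierarchy and stage fractions", {
  sim <- simulate_cohort(generator_config(n_patients = 2000), seed = 13)
  expect_true(all(!sim$cohort$event_crc | sim$cohort$event_all))
  ## CRC fraction among stage-4 deaths near the configured 128/134
  d4 <- sim$cohort[sim$cohort$stage == 4 & sim$cohort$event_all, ]
  expect_gt(mean(d4$event_crc), 0.8)
})
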