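test_that("total-area normalisation matches hand values and is idempotent and scale invariant", {
  areas <- c(25, 25, 50, rep(0, 21))
  pt <- toy_peak_table(areas, paste0("GP", 1:24))
  norm <- normalize_total_area(pt)
  expect_equal(unlist(norm[paste0("GP", 1:24)], use.names = FALSE), areas)

  pt2 <- toy_peak_table(c(2, 3, 5, rep(0, 21)), paste0("GP", 1:24))
  norm2 <- normalize_total_area(pt2)
  expect_equal(unlist(norm2[paste0("GP", 1:3)], use.names = FALSE), c(20, 30, 50))

  set.seed(11)
  for (i in 1:10) {
    raw <- toy_peak_table(runif(24, 1, 100), paste0("GP", 1:24))
    n1 <- normalize_total_area(raw)
    expect_equal(sum(unlist(n1[paste0("GP", 1:24)])), 100)
    ## idempotence
    expect_equal(normalize_total_area(n1), n1)
    ## scale invariance
    scaled <- raw
    scaled[paste0("GP", 1:24)] <- scaled[paste0("GP", 1:24)] * 7.3
    expect_equal(normalize_total_area(scaled)[paste0("GP", 1:24)],
                 n1[paste0("GP", 1:24)])
  }
})

test_that("zero-total rows are excluded with a warning", {
  df <- rbind(toy_peak_table(runif(24, 1, 10), paste0("GP", 1:24)),
              toy_peak_table(rep(0, 24), paste0("GP", 1:24)))
  df$sample_id <- c("A", "B")
  expect_warning(norm <- normalize_total_area(validate_peak_table(df)),
                 "zero total area")
  expect_equal(nrow(norm), 1L)
  expect_equal(norm$sample_id, "A")
})

test_that("derived traits equal hand-computed ratios on a toy annotation", {
  ann <- toy_annotation()
  defs <- default_trait_definitions(ann)
  pt <- normalize_total_area(toy_peak_table(c(40, 30, 20, 10)))
  tm <- derive_traits(pt, defs = defs, annotation = ann)
  v <- tm$values[1, ]
  expect_equal(unname(v["G0n"]), 100 * 40 / 90)
  expect_equal(unname(v["G1n"]), 100 * 30 / 90)
  expect_equal(unname(v["G2n"]), 100 * 20 / 90)
  expect_equal(unname(v["FGS/(F+FG+FGS)"]), 10)
  expect_equal(unname(v["FGS/(FG+FGS)"]), 100 * 10 / 60)
  expect_equal(unname(v["Fn"]), 100)
  expect_equal(unname(v["P1"]), 40)   # measured percentages pass through
  expect_equal(unname(v["P1n"]), 100 * 40 / 90)
})

test_that("neutral galactosylation partition sums to 100 and ratio identities hold", {
  sim <- simulate_cohort(generator_config(n_patients = 120), seed = 5)
  tm <- derive_traits(normalize_total_area(sim$peak_table))
  v <- tm$values
  expect_lt(max(abs(rowSums(v[, c("G0n", "G1n", "G2n")]) - 100)), 1e-9)
  expect_true(all(v[, c("G0n", "G1n", "G2n", "Fn", "FBn")] >= 0))
  expect_true(all(v[, c("G0n", "G1n", "G2n", "Fn", "FBn")] <= 100))
  r <- v[, "FBS1/FS1"]
  expect_equal(v[, "FBS1/(FS1+FBS1)"], r / (1 + r), tolerance = 1e-12)
})

test_that("robustness follows the variance-ratio definition and is shift invariant", {
  ## Var(stand) = 1, Var(cohort) = 20 -> 5%
  std <- c(-1, 1) / sqrt(2) * sqrt(2)        # sample var exactly 1
  expect_equal(stats::var(std), 2 * std[2]^2)
  std <- c(-1, 1) * sqrt(1 / 2)
  coh <- c(-1, 1, -3, 3) * sqrt(20 / stats::var(c(-1, 1, -3, 3)))
  expect_equal(robustness(std, coh), 5.0)
  ## identical spread -> 100%
  expect_equal(robustness(c(1, 2, 3), c(4, 5, 6)), 100.0)
  ## invariance to adding a constant
  expect_equal(robustness(std + 11, coh - 3), robustness(std, coh))
  expect_error(robustness(1, c(1, 2)), "at least 2")
})

test_that("robustness filter is strictly below threshold", {
  ## planted variance ratios 19.9% and 20.1% against the 20% rule
  set.seed(2)
  coh <- rnorm(200)
  coh <- (coh - mean(coh)) / stats::sd(coh)           # cohort var exactly 1
  make_std <- function(ratio) c(-1, 1) * sqrt(ratio / 2)
  vals <- cbind(ok = c(coh, make_std(0.199)),
                borderline = c(coh, make_std(0.201)))
  rownames(vals) <- c(sprintf("S%03d", 1:200), "STD1", "STD2")
  tm <- manual_trait_matrix(vals, is_standard = c(rep(FALSE, 200), TRUE, TRUE))
  tm <- filter_robust(compute_robustness(tm), threshold = 20)
  expect_true(tm$retained[["ok"]])
  expect_false(tm$retained[["borderline"]])

  ## strictness on exact boundary values
  vals2 <- matrix(0, 2, 4, dimnames = list(c("a", "b"), c("t1", "t2", "t3", "t4")))
  tm2 <- manual_trait_matrix(vals2, is_standard = c(FALSE, FALSE),
                             robustness = c(t1 = 5, t2 = 19.99, t3 = 20, t4 = 25))
  tm2 <- filter_robust(tm2, threshold = 20)
  expect_equal(sum(tm2$retained), 2L)
  expect_true(all(tm2$retained[c("t1", "t2")]))
  ## threshold 100 keeps everything finite below it
  expect_equal(sum(filter_robust(tm2, 100)$retained), 4L)
  ## empty matrix
  tm0 <- manual_trait_matrix(matrix(0, 2, 0, dimnames = list(c("a", "b"), NULL)),
                             is_standard = c(FALSE, FALSE))
  expect_equal(length(filter_robust(tm0)$retained), 0L)
})

test_that("Blom rank-normal transform matches the quantile formula", {
  got <- rank_normal_transform(c(3, 1, 2))
  expected <- qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4))
  expect_equal(got, expected)
  expect_equal(got[3], 0)
  expect_equal(got[1], -got[2])

  ## order/sign preservation and monotone invariance
  x <- c(-1, 0, 1)
  expect_equal(order(rank_normal_transform(x)), order(x))
  set.seed(4)
  y <- rnorm(50)
  expect_equal(rank_normal_transform(exp(y)), rank_normal_transform(y))
  expect_lt(abs(mean(rank_normal_transform(y))), 1e-10)
  expect_error(rank_normal_transform(rep(2, 10)), "identical")
  ## missing values propagate
  z <- c(5, NA, 1, 3)
  tz <- rank_normal_transform(z)
  expect_true(is.na(tz[2]))
  expect_equal(sum(is.na(tz)), 1L)
})
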