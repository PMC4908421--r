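## Independent brute-force oracles used by the unit and acceptance tests.
## These deliberately avoid the code paths they check.

## Efron partial log-likelihood for a single numeric covariate.
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(beta * x[D]))
    sumR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in 0:(d - 1)) ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

## Grid + golden-section maximisation of the partial likelihood.
oracle_cox_coef <- function(time, event, x, lower = -10, upper = 10) {
  stats::optimize(function(b) cox_partial_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

## Exhaustive pairwise concordance (Harrell), ties in risk counted half.
oracle_c_index <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no usable pairs")
  num / den
}

## Mann-Whitney AUC by full pair enumeration.
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}

## Benjamini-Hochberg step-up by its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

## Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  min(1, 2 * min(p_ge, p_le))
}

## Small random survival dataset.
random_survival <- function(n, censor_frac = 0.3) {
  time <- round(rexp(n, 0.5), 2) + 0.05
  event <- as.integer(runif(n) > censor_frac)
  x <- rnorm(n)
  data.frame(time = time, event = event, x = x)
}

## Toy 4-peak annotation used for forced-arithmetic trait checks.
toy_annotation <- function() {
  validate_annotation(data.frame(
    peak = c("P1", "P2", "P3", "P4"),
    structure = c("FA2", "FA2G1", "FA2G2", "FA2G2S1"),
    galactose_count = c(0, 1, 2, 2),
    sialic_acid_count = c(0, 0, 0, 1),
    core_fucose = c(TRUE, TRUE, TRUE, TRUE),
    bisecting_glcnac = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE))
}

toy_peak_table <- function(areas, peaks = paste0("P", seq_along(areas))) {
  df <- data.frame(sample_id = "S1", plate_id = "PL1", is_standard = FALSE,
                   stringsAsFactors = FALSE)
  df[peaks] <- as.list(areas)
  validate_peak_table(df, peaks)
}

## Hand-built trait_matrix with chosen values / robustness for filter tests.
manual_trait_matrix <- function(values, is_standard,
                                robustness = NULL) {
  tm <- structure(list(
    values = values,
    sample_id = rownames(values),
    plate_id = rep("PL1", nrow(values)),
    is_standard = is_standard,
    definitions = NULL, robustness = robustness, retained = NULL),
    class = "trait_matrix")
  tm
}

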