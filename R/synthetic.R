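#' Synthetic cohort generator configuration
#'
#' Defines the study conditions emulated by the generator: a colorectal-cancer
#' cohort of 1229 patients with the published stage distribution, a 24-peak
#' IgG glycome measured on 96-well plates carrying 3 biologically identical
#' technical standards each, and Weibull proportional-hazards survival with
#' stage effects at the published univariate hazard ratios. All effect sizes
#' are planted, recorded in the returned truth, and recoverable downstream.
#'
#' @param n_patients Number of patients.
#' @param stage_probs Probabilities of AJCC stages 1-4 (default the published
#'   stage counts 249/421/413/146 out of 1229).
#' @param plate_size Wells per plate, cohort samples plus standards.
#' @param standards_per_plate Technical-standard wells per plate.
#' @param peak_concentration Dispersion of the logistic-normal compositional
#'   noise; the biological log-ratio SD is \code{1/sqrt(peak_concentration)}.
#' @param technical_sd SD of plate-level shifts and per-well technical noise on
#'   the log-ratio scale.
#' @param glycan_axis_sd SD of the latent glycan score's shift along the
#'   galactosylation/sialylation axis, on the log-ratio scale.
#' @param mean_profile 24-vector of mean peak percentages (must sum to 100);
#'   the default is calibrated so derived neutral-trait means sit near the
#'   survivor column of the published trait table (G0n about 38, G1n about 44,
#'   G2n about 17.5).
#' @param log_hr_stage Log hazard ratios of stages 2-4 versus stage 1
#'   (default \code{log(c(1.35, 2.65, 14.32))}).
#' @param log_hr_glycan Log hazard ratio per SD of the latent glycan score.
#' @param log_hr_age Log hazard ratio per year of age (centred at 59).
#' @param log_hr_crp Log hazard ratio for CRP above 10 mg/l.
#' @param crc_death_fraction_by_stage Probability that a death is CRC-caused,
#'   per stage (defaults from the published stage-specific death counts).
#' @param baseline_hazard_shape,baseline_hazard_scale Weibull baseline (years).
#' @param recruitment_window_years Accrual window; diagnosis dates are uniform
#'   over it.
#' @param admin_censor_years Administrative censor date, years after study
#'   start; censoring duration is \code{max(0, admin_censor_years - offset)}.
#' @param female_prob,rectum_prob,bmi_mean,bmi_sd,bmi_missing_frac,
#'   crp_gt10_frac,crp_sdlog,op_to_sample_median_months,op_to_sample_sdlog,
#'   emergency_op_prob Clinical marginals (defaults near the published
#'   summary table).
#' @param seed Integer seed used by \code{\link{simulate_cohort}}.
#' @return A validated \code{generator_config} list.
#' @export
generator_config <- function(n_patients = 1229,
                             stage_probs = c(249, 421, 413, 146) / 1229,
                             plate_size = 96,
                             standards_per_plate = 3,
                             peak_concentration = 16,
                             technical_sd = 0.05,
                             glycan_axis_sd = 0.3,
                             mean_profile = default_mean_profile(),
                             log_hr_stage = log(c(1.35, 2.65, 14.32)),
                             log_hr_glycan = 0.3,
                             log_hr_age = 0.02,
                             log_hr_crp = log(2.13),
                             crc_death_fraction_by_stage = c(22 / 54, 76 / 115, 159 / 186, 128 / 134),
                             baseline_hazard_shape = 1.2,
                             baseline_hazard_scale = 29,
                             recruitment_window_years = 7,
                             admin_censor_years = 14,
                             female_prob = 0.43,
                             rectum_prob = 0.41,
                             bmi_mean = 26.6, bmi_sd = 4.4,
                             bmi_missing_frac = 172 / 1229,
                             crp_gt10_frac = 130 / 1229,
                             crp_sdlog = 1.4,
                             op_to_sample_median_months = 5.4,
                             op_to_sample_sdlog = 0.706,
                             emergency_op_prob = 0.15,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (n_patients < 1) stop("n_patients must be positive")
  if (length(stage_probs) != 4 || any(stage_probs < 0) || any(stage_probs > 1))
    stop("stage_probs must be 4 probabilities in [0, 1]")
  if (abs(sum(stage_probs) - 1) > 1e-12)
    stop("stage_probs must sum to 1")
  if (plate_size <= standards_per_plate || standards_per_plate < 1)
    stop("need plate_size > standards_per_plate >= 1")
  if (baseline_hazard_shape <= 0 || baseline_hazard_scale <= 0)
    stop("Weibull baseline parameters must be positive")
  if (length(mean_profile) != 24 || any(mean_profile <= 0))
    stop("mean_profile must be 24 positive percentages")
  if (abs(sum(mean_profile) - 100) > 1e-6)
    stop("mean_profile must sum to 100")
  if (length(log_hr_stage) != 3)
    stop("log_hr_stage must give stages 2-4 versus 1")
  if (length(crc_death_fraction_by_stage) != 4 ||
      any(crc_death_fraction_by_stage < 0) || any(crc_death_fraction_by_stage > 1))
    stop("crc_death_fraction_by_stage must be 4 probabilities")
  structure(cfg, class = "generator_config")
}

#' Default mean peak-percentage profile
#'
#' Calibrated against the survivor column of the published trait table:
#' about 80\% neutral glycome split 38.5/44/17.5 across G0/G1/G2, neutral
#' fucosylation near 79\% with 17.5\% bisected, and sialylation of fucosylated
#' structures near 26\%.
#'
#' @return Named 24-vector of percentages summing to 100.
#' @export
default_mean_profile <- function() {
  p <- c(GP1 = 0.2, GP2 = 0.6, GP3 = 0.1, GP4 = 24.0, GP5 = 0.3, GP6 = 5.6,
         GP7 = 0.6, GP8 = 18.8, GP9 = 9.5, GP10 = 4.0, GP11 = 2.3,
         GP12 = 0.8, GP13 = 0.1, GP14 = 11.0, GP15 = 2.1,
         GP16 = 1.4, GP17 = 0.6, GP18 = 8.5, GP19 = 0.4, GP20 = 1.7,
         GP21 = 0.6, GP22 = 4.2, GP23 = 1.8, GP24 = 0.8)
  stopifnot(abs(sum(p) - 100) < 1e-9)
  p
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate clinical covariates
#'
#' Draws patient covariates from marginals matching the published cohort
#' summary: age normal(59, 10) truncated to [30, 90], 43\% female, AJCC stage
#' from \code{stage_probs}, 41\% rectal site, BMI normal(26.6, 4.4) truncated
#' positive with missing-completely-at-random dropout, log-normal CRP
#' calibrated so the configured fraction exceeds 10 mg/l, log-normal
#' operation-to-sampling time with median 5.4 months, and a two-level
#' operation type.
#'
#' Call inside a seeded context (\code{\link{simulate_cohort}} does this).
#'
#' @param config A \code{generator_config}.
#' @return data.frame of covariate-only cohort records.
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  crp_meanlog <- log(10) - config$crp_sdlog * stats::qnorm(1 - config$crp_gt10_frac)
  crp <- stats::rlnorm(n, crp_meanlog, config$crp_sdlog)
  bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd, lower = 0)
  bmi[stats::runif(n) < config$bmi_missing_frac] <- NA_real_
  data.frame(
    sample_id = sprintf("P%04d", seq_len(n)),
    age = rtruncnorm(n, 59, 10, 30, 90),
    sex = factor(ifelse(stats::runif(n) < config$female_prob, "F", "M"),
                 levels = c("M", "F")),
    stage = sample.int(4, n, replace = TRUE, prob = config$stage_probs),
    site = factor(ifelse(stats::runif(n) < config$rectum_prob, "rectum", "colon"),
                  levels = c("colon", "rectum")),
    bmi = bmi,
    crp = crp,
    crp_gt10 = crp > 10,
    op_type = factor(ifelse(stats::runif(n) < config$emergency_op_prob,
                            "emergency", "elective"),
                     levels = c("elective", "emergency")),
    op_to_sample = stats::rlnorm(n, log(config$op_to_sample_median_months),
                                 config$op_to_sample_sdlog),
    stringsAsFactors = FALSE)
}

## Per-peak loadings of the latent glycan score: raises agalactosylated and
## lowers digalactosylated / sialylated peaks, so a high score means the
## pro-inflammatory glycome shift (G0n up, G2n and sialylation down).
glycan_axis_loadings <- function(annotation = gp_annotation()) {
  l <- (annotation$galactose_count == 0) - (annotation$galactose_count == 2) -
    0.5 * (annotation$sialic_acid_count >= 1)
  names(l) <- annotation$peak
  l
}

#' Generate a glycan peak table with plate structure
#'
#' Draws per-sample 24-part compositions from a logistic-normal model centred
#' on \code{mean_profile}: biological log-ratio noise with SD
#' \code{1/sqrt(peak_concentration)}, a latent per-patient glycan score
#' shifting the galactosylation/sialylation axis (stored in the truth), a
#' plate-level technical shift and per-well technical noise (both SD
#' \code{technical_sd}). Samples fill plates of \code{plate_size} wells;
#' each plate carries \code{standards_per_plate} technical replicates of one
#' fixed reference composition perturbed only by technical noise. Raw areas
#' carry an arbitrary per-well chromatogram intensity, removed by total-area
#' normalisation.
#'
#' @param records Clinical records (covariates only).
#' @param config A \code{generator_config}.
#' @param annotation Peak annotation (for the axis loadings).
#' @return list with \code{peak_table} and \code{truth} (per-patient
#'   \code{glycan_score} plus the loading vector).
#' @export
generate_peak_table <- function(records, config, annotation = gp_annotation()) {
  stopifnot(inherits(config, "generator_config"))
  n <- nrow(records)
  if (n < 1) stop("records must be non-empty")
  peaks <- names(config$mean_profile)
  k <- length(peaks)
  sigma_bio <- 1 / sqrt(config$peak_concentration)
  loadings <- glycan_axis_loadings(annotation)[peaks]
  mu <- log(config$mean_profile)

  per_plate <- config$plate_size - config$standards_per_plate
  plate_of <- ceiling(seq_len(n) / per_plate)
  n_plates <- max(plate_of)
  plate_shift <- matrix(stats::rnorm(n_plates * k, 0, config$technical_sd),
                        n_plates, k)
  u <- stats::rnorm(n)

  z_cohort <- matrix(mu, n, k, byrow = TRUE) +
    matrix(stats::rnorm(n * k, 0, sigma_bio), n, k) +
    config$glycan_axis_sd * outer(u, loadings) +
    plate_shift[plate_of, , drop = FALSE] +
    matrix(stats::rnorm(n * k, 0, config$technical_sd), n, k)

  n_std <- n_plates * config$standards_per_plate
  std_plate <- rep(seq_len(n_plates), each = config$standards_per_plate)
  z_std <- matrix(mu, n_std, k, byrow = TRUE) +
    plate_shift[std_plate, , drop = FALSE] +
    matrix(stats::rnorm(n_std * k, 0, config$technical_sd), n_std, k)

  intensity <- stats::rlnorm(n + n_std, log(1e5), 0.2)
  areas <- exp(rbind(z_cohort, z_std)) * intensity
  colnames(areas) <- peaks

  tab <- data.frame(
    sample_id = c(records$sample_id,
                  sprintf("STD_%03d_%d", std_plate,
                          rep(seq_len(config$standards_per_plate), n_plates))),
    plate_id = sprintf("PL%03d", c(plate_of, std_plate)),
    is_standard = rep(c(FALSE, TRUE), c(n, n_std)),
    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(areas))
  tab <- validate_peak_table(tab, peaks)
  list(peak_table = tab,
       truth = list(glycan_score = stats::setNames(u, records$sample_id),
                    loadings = loadings, sigma_bio = sigma_bio))
}

#' Generate survival outcomes under a Weibull proportional-hazards model
#'
#' The all-cause linear predictor is the stage effect plus the configured age,
#' CRP and latent-glycan-score effects; event times follow a Weibull baseline,
#' so the proportional-hazards assumption holds exactly. Deaths are labelled
#' CRC-caused by a stage-dependent Bernoulli draw; censoring is administrative
#' at a fixed calendar date with uniform accrual.
#'
#' @param records Clinical records (covariates present).
#' @param truth Truth list from \code{\link{generate_peak_table}} (uses the
#'   latent glycan score).
#' @param config A \code{generator_config}.
#' @return The records with \code{time} (years), \code{event_all},
#'   \code{event_crc} filled in, plus a \code{linear_predictor} attribute on
#'   the truth returned alongside.
#' @export
generate_survival <- function(records, truth, config) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(records$stage) || any(is.na(records$stage)))
    stop("records must carry a complete stage variable")
  n <- nrow(records)
  u <- truth$glycan_score[records$sample_id]
  lp <- c(0, config$log_hr_stage)[records$stage] +
    config$log_hr_age * (records$age - 59) +
    config$log_hr_crp * as.numeric(records$crp_gt10) +
    config$log_hr_glycan * u
  shape <- config$baseline_hazard_shape
  scale <- config$baseline_hazard_scale
  t_event <- scale * (-log(stats::runif(n)) / exp(lp))^(1 / shape)
  offset <- stats::runif(n, 0, config$recruitment_window_years)
  t_censor <- pmax(0, config$admin_censor_years - offset)
  event <- t_event <= t_censor
  crc_cause <- stats::runif(n) < config$crc_death_fraction_by_stage[records$stage]
  records$time <- pmin(t_event, t_censor)
  records$event_all <- event
  records$event_crc <- event & crc_cause
  attr(records, "linear_predictor") <- lp
  records
}

#' Simulate a complete synthetic study dataset
#'
#' Runs \code{\link{generate_clinical}}, \code{\link{generate_peak_table}} and
#' \code{\link{generate_survival}} under one seed. Identical seeds produce
#' bit-identical cohorts.
#'
#' @param config A \code{generator_config}.
#' @param seed Overrides \code{config$seed} when given.
#' @param annotation Peak annotation.
#' @return A \code{synthetic_cohort}: list with \code{peak_table},
#'   \code{cohort} (records with outcomes) and \code{truth} (latent glycan
#'   scores, loadings, linear predictor, and the full config).
#' @export
simulate_cohort <- function(config = generator_config(), seed = NULL,
                            annotation = gp_annotation()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) config$seed <- seed
  set.seed(config$seed)
  records <- generate_clinical(config)
  pk <- generate_peak_table(records, config, annotation)
  cohort <- generate_survival(records, pk$truth, config)
  truth <- pk$truth
  truth$linear_predictor <- attr(cohort, "linear_predictor")
  attr(cohort, "linear_predictor") <- NULL
  truth$config <- config
  structure(list(peak_table = pk$peak_table, cohort = cohort, truth = truth),
            class = "synthetic_cohort")
}

#' Stage-4-like classification benchmark
#'
#' Generates the feature/label structure of the stage-stratified
#' rapid-progressor task at desk scale: a latent glycan score that raises the
#' progression odds, several glycan traits measuring that score with noise,
#' and clinical covariates with a modest effect of their own. With
#' \code{glycan_logodds = 0} the glycans are pure noise (the null benchmark
#' for type-I-error checks of the comparison protocol).
#'
#' Call inside a seeded context.
#'
#' @param n Patients (the study's stage-4 stratum holds about 150).
#' @param n_glycans Number of glycan features.
#' @param glycan_logodds Log odds of rapid progression per SD of the latent
#'   score.
#' @param clinical_logodds Log odds per SD of the informative clinical
#'   covariate.
#' @param noise_sd Measurement noise SD of each glycan feature.
#' @param intercept Logistic intercept controlling the progression rate.
#' @return list with \code{clinical} (matrix), \code{glycans} (matrix),
#'   \code{u} (latent score) and binary \code{labels}.
#' @export
simulate_progression_features <- function(n = 150, n_glycans = 5,
                                          glycan_logodds = 1.5,
                                          clinical_logodds = 0.3,
                                          noise_sd = 0.7, intercept = -1) {
  u <- stats::rnorm(n)
  clinical <- cbind(age = stats::rnorm(n), sex = stats::rbinom(n, 1, 0.43),
                    crp = stats::rnorm(n))
  glycans <- vapply(seq_len(n_glycans),
                    function(i) u + stats::rnorm(n, 0, noise_sd), numeric(n))
  colnames(glycans) <- paste0("g", seq_len(n_glycans))
  prob <- stats::plogis(intercept + glycan_logodds * u +
                          clinical_logodds * clinical[, "age"])
  list(clinical = clinical, glycans = glycans, u = u,
       labels = stats::rbinom(n, 1, prob))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$cohort), "patients,",
      sum(x$cohort$event_all), "deaths (", sum(x$cohort$event_crc),
      "CRC ), seed", x$truth$config$seed, "\n")
  invisible(x)
}
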