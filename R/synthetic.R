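# Synthetic cohort generator with a known linear ground-truth outcome model.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the demographic profile of a large commercial
#' mobile weight-loss cohort: age mean 43.2 (SD 10.8) years, 92.2% female,
#' height mean 166.4 (SD 7.5) cm, BMI mean 33.7 (SD 5.8) truncated at 25
#' (initial weight is derived as BMI x height^2, giving a mean near 93.4 kg).
#' Truncated samplers are internally calibrated so the post-truncation mean
#' equals the configured marginal.
#'
#' The outcome model is linear by construction: week-16 weight equals initial
#' weight, plus the archetype's configured endpoint effect (kg), plus the sum
#' over the 7 behaviors of `true_effects` (kg per SD) times the user's
#' standardized 16-week behavior aggregate, plus Gaussian noise of SD
#' `noise_sd`. Weekly behaviors are drawn around a per-user propensity
#' (between-user SD `behavior_user_sd`) with independent week-to-week
#' variation (`behavior_week_sd`); setting the latter to zero makes behaviors
#' constant within user.
#'
#' @param n_users Number of users to simulate.
#' @param seed Integer seed; the generator is byte-deterministic given the
#'   full config.
#' @param archetype_mix Probabilities of the five weight-trajectory
#'   archetypes (sharp decrease, moderate decrease, yo-yo, increase, other);
#'   must sum to 1.
#' @param behavior_means,behavior_user_sd,behavior_week_sd Named numeric
#'   vectors over the 7 weekly behavior variables.
#' @param true_effects List with `behaviors` (kg per SD of the standardized
#'   16-week aggregate, signed) and `archetypes` (kg endpoint effect at week
#'   16 for each archetype shape).
#' @param noise_sd SD (kg) of the outcome noise on week-16 weight.
#' @param measurement_sd SD (kg) of measurement noise on weekly weight logs
#'   (weeks 1-15; the week-16 log is the outcome itself).
#' @param yoyo_dip_kg Depth (kg) of the yo-yo archetype's week-8 trough.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_users = 2000L,
                             seed = 1L,
                             archetype_mix = c(0.15, 0.40, 0.15, 0.10, 0.20),
                             behavior_means = c(weight_input_freq = 4.5,
                                                meal_input_adherence = 75,
                                                exercise_input_freq = 3,
                                                calorie_intake = 1600,
                                                steps_k = 6,
                                                alcohol_drinks = 2,
                                                over_calorie_events = 1.5),
                             behavior_user_sd = c(weight_input_freq = 1.2,
                                                  meal_input_adherence = 12,
                                                  exercise_input_freq = 1.6,
                                                  calorie_intake = 240,
                                                  steps_k = 2,
                                                  alcohol_drinks = 1.6,
                                                  over_calorie_events = 1.2),
                             behavior_week_sd = c(weight_input_freq = 0.9,
                                                  meal_input_adherence = 9,
                                                  exercise_input_freq = 1.2,
                                                  calorie_intake = 180,
                                                  steps_k = 1.5,
                                                  alcohol_drinks = 1.2,
                                                  over_calorie_events = 0.9),
                             true_effects = list(
                               behaviors = c(weight_input_freq = -0.6,
                                             meal_input_adherence = -0.8,
                                             exercise_input_freq = -0.4,
                                             calorie_intake = 1.2,
                                             steps_k = -0.3,
                                             alcohol_drinks = 0.4,
                                             over_calorie_events = 0.5),
                               archetypes = c("sharp decrease" = -11.2,
                                              "moderate decrease" = -4.7,
                                              "yo-yo" = -1.0,
                                              "increase" = 2.8,
                                              "other" = -0.9)),
                             noise_sd = 2.0,
                             measurement_sd = 0.5,
                             yoyo_dip_kg = 7.5,
                             age_mean = 43.2, age_sd = 10.8,
                             height_mean = 166.4, height_sd = 7.5,
                             bmi_mean = 33.7, bmi_sd = 5.8,
                             female_share = 0.922) {
  if (!is.numeric(n_users) || n_users < 1)
    stop("n_users must be a positive integer", call. = FALSE)
  if (length(archetype_mix) != 5 || any(archetype_mix < 0) ||
      abs(sum(archetype_mix) - 1) > 1e-9)
    stop("archetype_mix must be 5 non-negative probabilities summing to 1",
         call. = FALSE)
  if (noise_sd < 0 || measurement_sd < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  stopifnot(setequal(names(behavior_means), BEHAVIOR_VARS),
            setequal(names(true_effects$behaviors), BEHAVIOR_VARS),
            setequal(names(true_effects$archetypes), ARCHETYPES))
  names(archetype_mix) <- ARCHETYPES
  structure(list(n_users = as.integer(n_users), seed = as.integer(seed),
                 archetype_mix = archetype_mix,
                 behavior_means = behavior_means[BEHAVIOR_VARS],
                 behavior_user_sd = behavior_user_sd[BEHAVIOR_VARS],
                 behavior_week_sd = behavior_week_sd[BEHAVIOR_VARS],
                 true_effects = true_effects,
                 noise_sd = noise_sd, measurement_sd = measurement_sd,
                 yoyo_dip_kg = yoyo_dip_kg,
                 age_mean = age_mean, age_sd = age_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 female_share = female_share),
            class = "generator_config")
}

#' Noise-free variant of the generator configuration
#'
#' Zero outcome noise, zero weight-measurement noise, and zero week-to-week
#' behavior variation (behaviors reduce to the per-user propensity), so the
#' outcome is an exact deterministic linear function of features observable
#' from week 1. Useful for realizability checks: a correctly trained model
#' should reach near-zero error.
#'
#' @param ... Passed to [generator_config()].
#' @return A `generator_config`.
#' @export
noiseless_config <- function(...) {
  cfg <- generator_config(...)
  cfg$noise_sd <- 0
  cfg$measurement_sd <- 0
  cfg$behavior_week_sd[] <- 0
  cfg
}

# Archetype weekly offset curve in kg; endpoint (t = 16) equals `effect`.
archetype_offset <- function(archetype, effect, weeks = 1:N_WEEKS,
                             yoyo_dip = 7.5) {
  t <- weeks
  switch(archetype,
    "sharp decrease"    = effect * (1 - exp(-t / 2)) / (1 - exp(-8)),
    "moderate decrease" = effect * t / 16,
    "increase"          = effect * t / 16,
    # yo-yo: fast early loss bottoming out at week 8, then rebound (the
    # curved decline is what distinguishes a rebounder from a steady loser
    # before the trough is reached)
    "yo-yo"             = ifelse(t <= 8,
                                 -yoyo_dip * (1 - exp(-t / 3)) / (1 - exp(-8 / 3)),
                                 -yoyo_dip + (yoyo_dip + effect) * (t - 8) / 8),
    # "other": none-of-the-above catchall with a distinctive inverted-U
    # (small mid-program gain that resolves to the configured endpoint)
    "other"             = 2.5 * sin(pi * t / 16) + effect * t / 16,
    stop("unknown archetype: ", archetype))
}

# Truncation bounds for the behavior variables (eligibility requires >= 1
# weight input and > 0 meal adherence every week; adherence is a percentage).
behavior_bounds <- function() {
  list(lower = c(weight_input_freq = 1, meal_input_adherence = 1,
                 exercise_input_freq = 0, calorie_intake = 500,
                 steps_k = 0, alcohol_drinks = 0, over_calorie_events = 0),
       upper = c(weight_input_freq = Inf, meal_input_adherence = 100,
                 exercise_input_freq = Inf, calorie_intake = Inf,
                 steps_k = Inf, alcohol_drinks = Inf,
                 over_calorie_events = Inf))
}

#' Generate a synthetic cohort
#'
#' Draws user profiles, 16 weeks of lifelog records per user, and week-16
#' outcome weights from the linear ground-truth model described in
#' [generator_config()]. Fully reproducible given the config (including its
#' seed).
#'
#' @param config A [generator_config()].
#' @return A `synthetic_cohort` list with `profiles`, `logs`,
#'   `archetype_labels` (named by user), `truth` (the effect maps used), and
#'   the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_users
  with_local_seed(config$seed, {
    user_id <- sprintf("u%05d", seq_len(n))
    archetype <- sample(ARCHETYPES, n, replace = TRUE,
                        prob = config$archetype_mix)
    gender <- ifelse(stats::runif(n) < config$female_share, "female", "male")
    age <- rtrunc_norm(n, calibrate_trunc_mean(config$age_mean, config$age_sd,
                                               18, 65),
                       config$age_sd, 18, 65)
    height <- rtrunc_norm(n, calibrate_trunc_mean(config$height_mean,
                                                  config$height_sd, 125, 230),
                          config$height_sd, 125, 230)
    bmi <- rtrunc_norm(n, calibrate_trunc_mean(config$bmi_mean, config$bmi_sd,
                                               25 + 1e-6, Inf),
                       config$bmi_sd, 25 + 1e-6, Inf)
    initial <- bmi * (height / 100)^2
    target <- initial * (1 - rtrunc_norm(n, 0.12, 0.05, 0.02, 0.30))

    # Weekly behaviors: per-user propensity + independent weekly variation,
    # truncated to each variable's support.
    bounds <- behavior_bounds()
    behaviors <- array(NA_real_, c(n, N_WEEKS, length(BEHAVIOR_VARS)),
                       dimnames = list(user_id, NULL, BEHAVIOR_VARS))
    delta <- numeric(n)
    for (j in seq_along(BEHAVIOR_VARS)) {
      v <- BEHAVIOR_VARS[j]
      prop <- stats::rnorm(n, 0, config$behavior_user_sd[[v]])
      mu <- config$behavior_means[[v]] + prop
      draws <- rtrunc_norm(n * N_WEEKS, rep(mu, N_WEEKS),
                           config$behavior_week_sd[[v]],
                           bounds$lower[[v]], bounds$upper[[v]])
      behaviors[, , j] <- draws
      agg <- rowMeans(matrix(behaviors[, , j], nrow = n))
      sd_agg <- sqrt(config$behavior_user_sd[[v]]^2 +
                       config$behavior_week_sd[[v]]^2 / N_WEEKS)
      std <- if (sd_agg > 0) (agg - config$behavior_means[[v]]) / sd_agg
             else rep(0, n)
      delta <- delta + config$true_effects$behaviors[[v]] * std
    }

    eta <- stats::rnorm(n, 0, config$noise_sd)
    arch_eff <- config$true_effects$archetypes[archetype]
    final <- initial + arch_eff + delta + eta

    # Weekly weight path: archetype shape plus measurement noise for weeks
    # 1-15; the behavioral displacement and outcome noise materialize in the
    # week-16 outcome, which is the last logged weight.
    weight <- matrix(NA_real_, n, N_WEEKS)
    for (i in seq_len(n)) {
      off <- archetype_offset(archetype[i], arch_eff[i], 1:N_WEEKS,
                              config$yoyo_dip_kg)
      path <- initial[i] + off
      path[1:(N_WEEKS - 1)] <- path[1:(N_WEEKS - 1)] +
        stats::rnorm(N_WEEKS - 1, 0, config$measurement_sd)
      path[N_WEEKS] <- final[i]
      weight[i, ] <- path
    }
    if (any(weight <= 0)) stop("generated non-positive weight; check config")

    logs <- data.frame(
      user_id = rep(user_id, each = N_WEEKS),
      week = rep(1:N_WEEKS, n),
      weight_input_freq = as.vector(t(behaviors[, , "weight_input_freq"])),
      meal_input_adherence = as.vector(t(behaviors[, , "meal_input_adherence"])),
      exercise_input_freq = as.vector(t(behaviors[, , "exercise_input_freq"])),
      calorie_intake = as.vector(t(behaviors[, , "calorie_intake"])),
      steps_k = as.vector(t(behaviors[, , "steps_k"])),
      alcohol_drinks = as.vector(t(behaviors[, , "alcohol_drinks"])),
      over_calorie_events = as.vector(t(behaviors[, , "over_calorie_events"])),
      weight_kg = as.vector(t(weight)),
      stringsAsFactors = FALSE)

    profiles <- data.frame(user_id = user_id, gender = gender, age = age,
                           height_cm = height, initial_weight_kg = initial,
                           target_weight_kg = target,
                           stringsAsFactors = FALSE)
    names(archetype) <- user_id
    structure(list(profiles = profiles, logs = logs,
                   archetype_labels = archetype,
                   truth = config$true_effects, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$profiles), "users x", N_WEEKS, "weeks\n")
  print(round(100 * prop.table(table(x$archetype_labels)), 1))
  invisible(x)
}

#' Ground-truth effect map of a generator configuration
#'
#' Returns the signed effects (kg) the generator applies, for
#' parameter-recovery assertions against fitted contribution coefficients.
#'
#' @param config A [generator_config()].
#' @return List with `behaviors` (kg per SD of the standardized aggregate)
#'   and `archetypes` (kg endpoint effects).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  config$true_effects
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes `profiles.csv`, `logs.csv` (the schemas read back by
#' [read_profiles()] / [read_logs()]) and `truth.txt` (key = value lines of
#' the ground-truth effects).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_profiles(cohort$profiles, file.path(dir, "profiles.csv"))
  write_logs(cohort$logs, file.path(dir, "logs.csv"))
  tr <- c(
    sprintf("behavior\t%s\t%.10g", names(cohort$truth$behaviors),
            cohort$truth$behaviors),
    sprintf("archetype\t%s\t%.10g", names(cohort$truth$archetypes),
            cohort$truth$archetypes))
  writeLines(tr, file.path(dir, "truth.txt"))
  invisible(dir)
}
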