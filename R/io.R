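# Delimited-text schemas, validation, and the end-to-end pipeline.

LOG_COLUMNS <- c("user_id", "week", BEHAVIOR_VARS, "weight_kg")
PROFILE_COLUMNS <- c("user_id", "gender", "age", "height_cm",
                     "initial_weight_kg", "target_weight_kg")

validate_numeric <- function(df, cols, file, errors) {
  for (cn in cols) {
    bad <- which(!is.na(df[[paste0(".raw.", cn)]]) & is.na(df[[cn]]))
    if (length(bad))
      errors <- c(errors, sprintf("%s line %d: non-numeric value '%s' in %s",
                                  file, bad + 1L, df[[paste0(".raw.", cn)]][bad],
                                  cn))
  }
  errors
}

read_delim_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  errors <- character(0)
  for (cn in numeric_cols) {
    raw <- df[[cn]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad))
      errors <- c(errors,
                  sprintf("%s line %d: non-numeric '%s' in column %s",
                          basename(path), bad + 1L, raw[bad], cn))
    df[[cn]] <- val
  }
  list(data = df[required], errors = errors)
}

#' Read weekly lifelog records
#'
#' Expects a UTF-8 CSV with header columns `user_id, week,
#' weight_input_freq, meal_input_adherence, exercise_input_freq,
#' calorie_intake, steps_k, alcohol_drinks, over_calorie_events, weight_kg`
#' (weeks 1-based). Row-level problems are reported with line numbers.
#'
#' @param path CSV file path.
#' @return Validated data frame of weekly logs.
#' @export
read_logs <- function(path) {
  res <- read_delim_checked(path, LOG_COLUMNS, setdiff(LOG_COLUMNS, "user_id"))
  df <- res$data
  errors <- res$errors
  dup <- duplicated(df[c("user_id", "week")])
  if (any(dup))
    errors <- c(errors, sprintf("%s line %d: duplicate (user_id, week) = (%s, %s)",
                                basename(path), which(dup) + 1L,
                                df$user_id[dup], df$week[dup]))
  bad_week <- which(!is.na(df$week) & (df$week < 1 | df$week > 16 |
                                         df$week != floor(df$week)))
  if (length(bad_week))
    errors <- c(errors, sprintf("%s line %d: week outside 1..16",
                                basename(path), bad_week + 1L))
  if (length(errors)) stop(paste(errors, collapse = "\n"), call. = FALSE)
  df$week <- as.integer(df$week)
  df
}

#' Read user profile records
#'
#' Expects a UTF-8 CSV with header columns `user_id, gender, age, height_cm,
#' initial_weight_kg, target_weight_kg`; `gender` is `female` or `male`.
#'
#' @param path CSV file path.
#' @return Validated data frame of profiles.
#' @export
read_profiles <- function(path) {
  res <- read_delim_checked(path, PROFILE_COLUMNS,
                            setdiff(PROFILE_COLUMNS, c("user_id", "gender")))
  df <- res$data
  errors <- res$errors
  dup <- duplicated(df$user_id)
  if (any(dup))
    errors <- c(errors, sprintf("%s line %d: duplicate user_id %s",
                                basename(path), which(dup) + 1L,
                                df$user_id[dup]))
  bad_g <- which(!df$gender %in% c("female", "male"))
  if (length(bad_g))
    errors <- c(errors, sprintf("%s line %d: gender must be female/male",
                                basename(path), bad_g + 1L))
  if (length(errors)) stop(paste(errors, collapse = "\n"), call. = FALSE)
  df
}

#' Write weekly logs / profiles in the package schema
#'
#' @param logs,profiles Data frames in the package schemas.
#' @param path Output CSV path.
#' @name write_schemas
#' @export
write_logs <- function(logs, path) {
  utils::write.csv(logs[LOG_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schemas
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles[PROFILE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param profiles_path,logs_path Input CSVs; ignored when `simulate` is a
#'   [generator_config()], in which case the cohort is generated and written
#'   to `out_dir`.
#' @param simulate `NULL`, or a [generator_config()] to generate the cohort.
#' @param cluster_k Number of trajectory clusters.
#' @param model_config A [retain_config()].
#' @param n_replicates Cross-validation replicates.
#' @param train_fraction Training share per replicate.
#' @param seed Base seed for splits/clustering.
#' @param verbose Log stage progress.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, profiles_path = NULL, logs_path = NULL,
                            simulate = NULL, cluster_k = 5L,
                            model_config = retain_config(),
                            n_replicates = 5L, train_fraction = 0.7,
                            seed = 1L, verbose = TRUE) {
  structure(list(out_dir = out_dir, profiles_path = profiles_path,
                 logs_path = logs_path, simulate = simulate,
                 cluster_k = as.integer(cluster_k),
                 model_config = model_config,
                 n_replicates = as.integer(n_replicates),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: (optional) simulate, filter, cluster, featurize, train, evaluate,
#' explain. Artifacts written under `config$out_dir`: the exclusion report,
#' trajectory barycenters, the cross-validation report (JSON + text), the
#' global attention/coefficient pattern, and a per-sample contribution table
#' example. Every artifact is reproducible from the config and seeds alone.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the eval report, global pattern, and file
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    say("[simulate] generating %d users", config$simulate$n_users)
    cohort <- generate_cohort(config$simulate)
    write_cohort(cohort, config$out_dir)
    profiles <- cohort$profiles
    logs <- cohort$logs
  } else {
    say("[load] reading %s, %s", config$profiles_path, config$logs_path)
    profiles <- read_profiles(config$profiles_path)
    logs <- read_logs(config$logs_path)
  }

  say("[filter] applying eligibility filters")
  flt <- filter_eligible(profiles, logs)
  write_exclusion_report(flt$report,
                         file.path(config$out_dir, "exclusion_report.txt"))
  if (nrow(flt$profiles) < 10)
    stop("fewer than 10 eligible users after filtering", call. = FALSE)

  say("[evaluate] %d-replicate cross-validation", config$n_replicates)
  report <- cross_validate(flt$profiles, flt$logs,
                           model_config = config$model_config,
                           n_replicates = config$n_replicates,
                           train_fraction = config$train_fraction,
                           cluster_k = config$cluster_k, seed = config$seed)
  write_eval_report(report, file.path(config$out_dir, "eval_report.json"))

  say("[explain] refitting on a single split for the global pattern")
  users <- flt$profiles$user_id
  n_train <- max(1L, min(length(users) - 1L,
                         round(config$train_fraction * length(users))))
  train_users <- with_local_seed(config$seed, sample(users, n_train))
  cfg <- config$model_config
  cfg$seed <- config$seed
  res <- fit_and_evaluate(flt$profiles, flt$logs, train_users, cfg,
                          cluster_k = config$cluster_k,
                          cluster_seed = config$seed)
  utils::write.csv(
    data.frame(cluster = seq_len(res$traj_model$k),
               label = res$traj_model$labels,
               res$traj_model$barycenters),
    file.path(config$out_dir, "trajectory_barycenters.csv"),
    row.names = FALSE)
  gp <- global_pattern(res$fit, res$test_tensor)
  write_global_pattern(gp, file.path(config$out_dir, "global_pattern.csv"))
  ct <- decompose_prediction(res$fit, res$test_tensor,
                             which(res$test_tensor$sample_index$prefix_week ==
                                     N_WEEKS)[1])
  utils::write.csv(ct$variant,
                   file.path(config$out_dir, "contributions_example.csv"),
                   row.names = FALSE)

  meta <- list(fingerprint = config_fingerprint(
                 list(cluster_k = config$cluster_k,
                      model = unclass(config$model_config),
                      n_replicates = config$n_replicates,
                      train_fraction = config$train_fraction,
                      seed = config$seed)),
               seed = config$seed,
               cv_seeds = report$seeds)
  jsonlite::write_json(meta, file.path(config$out_dir, "run_meta.json"),
                       auto_unbox = TRUE)
  say("[done] artifacts in %s", config$out_dir)
  invisible(list(eval_report = report, global_pattern = gp,
                 exclusion_report = flt$report, fit = res$fit,
                 out_dir = config$out_dir))
}
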