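#' Body mass index from weight and height
#'
#' @param weight_kg Body weight in kilograms.
#' @param height_cm Standing height in centimetres.
#' @return BMI in kg/m^2 (vectorized).
#' @examples
#' compute_bmi(93.4, 166.4)  # 33.7 to one decimal
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive and finite", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

#' CDC obesity class from BMI
#'
#' Bands are lower-bound inclusive: overweight \[25, 30), obese class I
#' \[30, 35), class II \[35, 40), class III >= 40. BMI below 25 gets `NA`
#' (no class assigned; such users are not eligible for the program).
#'
#' @param bmi BMI in kg/m^2 (vectorized).
#' @return Factor with levels `overweight`, `obese I`, `obese II`, `obese III`.
#' @export
obesity_class <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("bmi must be positive and finite", call. = FALSE)
  cut(bmi, breaks = c(25, 30, 35, 40, Inf), right = FALSE,
      labels = c("overweight", "obese I", "obese II", "obese III"))
}

#' Categorize 16-week weight outcome
#'
#' Percent change p = 100 * (initial - final) / initial is mapped to the
#' program's outcome bands. Loss bands are lower-bound inclusive
#' (\[2,5), \[5,10), \[10,15), >= 15); "stable" covers gains up to 2% and
#' losses below 2%; larger gains fall in "gained >2%".
#'
#' @param initial_kg,final_kg Initial and final weight in kg (vectorized).
#' @return Factor with the six outcome band labels.
#' @export
outcome_category <- function(initial_kg, final_kg) {
  if (any(initial_kg <= 0) || any(final_kg <= 0))
    stop("weights must be positive", call. = FALSE)
  p <- 100 * (initial_kg - final_kg) / initial_kg
  cut(p, breaks = c(-Inf, -2, 2, 5, 10, 15, Inf), right = FALSE,
      labels = c("gained >2%", "stable", "loss 2-5%", "loss 5-10%",
                 "loss 10-15%", "loss >15%"))
}

#' Apply program eligibility filters
#'
#' Keeps users who completed the 16-week program with at least one weight
#' entry and one meal entry every week, who aim to lose weight
#' (target < initial), with height in \[125, 230\] cm, age in \[18, 65\]
#' years, and BMI >= 25. Filters are applied in that order and the exclusion
#' report counts users removed by each filter (a user is counted once, at the
#' first filter that removes them).
#'
#' @param profiles Data frame with columns `user_id`, `gender`, `age`,
#'   `height_cm`, `initial_weight_kg`, `target_weight_kg`.
#' @param logs Data frame of weekly records with at least `user_id`, `week`,
#'   `weight_input_freq`, `meal_input_adherence` (see [read_logs()] for the
#'   full schema).
#' @return List with `profiles` (eligible rows, plus derived `bmi` and
#'   `obesity_class`), `logs` (restricted to eligible users), and `report`
#'   (an `exclusion_report`).
#' @export
filter_eligible <- function(profiles, logs) {
  if (anyDuplicated(profiles$user_id))
    stop("duplicate user_id in profiles", call. = FALSE)
  n_in <- nrow(profiles)
  alive <- rep(TRUE, n_in)
  counts <- integer(0)

  weeks_by_user <- split(logs$week, logs$user_id)
  complete16 <- vapply(profiles$user_id, function(u) {
    w <- weeks_by_user[[as.character(u)]]
    !is.null(w) && length(unique(w)) == 16L && all(sort(unique(w)) == 1:16)
  }, logical(1))

  rec_ok <- vapply(seq_len(n_in), function(i) {
    u <- profiles$user_id[i]
    rows <- logs[logs$user_id == u, , drop = FALSE]
    if (nrow(rows) == 0) return(FALSE)
    all(rows$weight_input_freq >= 1, na.rm = FALSE) &&
      all(rows$meal_input_adherence > 0, na.rm = FALSE) &&
      !anyNA(rows$weight_input_freq) && !anyNA(rows$meal_input_adherence)
  }, logical(1))

  apply_filter <- function(keep, name) {
    removed <- sum(alive & !keep)
    counts[[name]] <<- removed
    alive <<- alive & keep
  }

  apply_filter(complete16, "incomplete 16-week program")
  apply_filter(rec_ok, "missing weekly weight/meal records")
  apply_filter(profiles$target_weight_kg < profiles$initial_weight_kg,
               "target weight not below initial")
  apply_filter(profiles$height_cm >= 125 & profiles$height_cm <= 230,
               "height outside 125-230 cm")
  apply_filter(profiles$age >= 18 & profiles$age <= 65,
               "age outside 18-65 years")
  bmi <- profiles$initial_weight_kg / (profiles$height_cm / 100)^2
  apply_filter(bmi >= 25, "BMI below 25")

  keep <- profiles[alive, , drop = FALSE]
  keep$bmi <- compute_bmi(keep$initial_weight_kg, keep$height_cm)
  keep$obesity_class <- obesity_class(keep$bmi)
  report <- structure(
    list(filters = data.frame(filter = names(counts),
                              excluded = unlist(counts, use.names = FALSE)),
         n_in = n_in, n_out = sum(alive)),
    class = "exclusion_report")
  list(profiles = keep,
       logs = logs[logs$user_id %in% keep$user_id, , drop = FALSE],
       report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Eligibility filtering:", x$n_in, "users in,", x$n_out, "retained\n")
  for (i in seq_len(nrow(x$filters)))
    cat(sprintf("  - %-40s %d excluded\n",
                x$filters$filter[i], x$filters$excluded[i]))
  invisible(x)
}

#' Write an exclusion report as plain text
#'
#' @param report An `exclusion_report` from [filter_eligible()].
#' @param path Output file path.
#' @export
write_exclusion_report <- function(report, path) {
  lines <- c(sprintf("n_in\t%d", report$n_in),
             sprintf("%s\t%d", report$filters$filter, report$filters$excluded),
             sprintf("n_out\t%d", report$n_out))
  writeLines(lines, path)
  invisible(path)
}
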