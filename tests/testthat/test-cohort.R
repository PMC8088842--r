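test_that("BMI computation matches hand arithmetic", {
  expect_equal(round(compute_bmi(93.4, 166.4), 1), 33.7)
  expect_equal(compute_bmi(100, 200), 25.0)
  expect_equal(compute_bmi(88.8, 166.4), 88.8 / 1.664^2, tolerance = 1e-12)
  expect_error(compute_bmi(-1, 170), "positive")
  expect_error(compute_bmi(80, 0), "positive")
})

test_that("obesity classes follow lower-inclusive CDC bands", {
  expect_equal(as.character(obesity_class(33.7)), "obese I")
  expect_equal(as.character(obesity_class(25.0)), "overweight")
  expect_true(is.na(obesity_class(24.99)))
  expect_equal(as.character(obesity_class(c(29.99, 30, 35, 40, 55))),
               c("overweight", "obese I", "obese II", "obese III",
                 "obese III"))
})

test_that("outcome bands partition percent change with chosen boundaries", {
  # Table-1-style means: 93.4 -> 88.8 is a 4.92% loss
  expect_equal(as.character(outcome_category(93.4, 88.8)), "loss 2-5%")
  expect_equal(as.character(outcome_category(100, 100)), "stable")
  expect_equal(as.character(outcome_category(100, 84)), "loss >15%")
  expect_equal(as.character(outcome_category(100, 102)), "stable")       # gain of exactly 2%
  expect_equal(as.character(outcome_category(100, 102.01)), "gained >2%")
  expect_equal(as.character(outcome_category(100, 98)), "loss 2-5%")     # loss of exactly 2%
  expect_equal(as.character(outcome_category(100, 85)), "loss >15%")
  # every input gets exactly one band
  p <- seq(80, 110, by = 0.37)
  expect_false(anyNA(outcome_category(rep(100, length(p)), p)))
})

make_profile <- function(user_id, gender = "female", age = 40,
                         height_cm = 165, initial = 90, target = 80) {
  data.frame(user_id = user_id, gender = gender, age = age,
             height_cm = height_cm, initial_weight_kg = initial,
             target_weight_kg = target, stringsAsFactors = FALSE)
}

make_logs <- function(user_id, weeks = 1:16, wif = 5, mia = 80) {
  data.frame(user_id = user_id, week = weeks,
             weight_input_freq = wif, meal_input_adherence = mia,
             exercise_input_freq = 3, calorie_intake = 1600, steps_k = 6,
             alcohol_drinks = 1, over_calorie_events = 1,
             weight_kg = 90 - 0.1 * weeks, stringsAsFactors = FALSE)
}

test_that("each eligibility filter excludes its violator, counts reconcile", {
  profiles <- rbind(
    make_profile("ok"),
    make_profile("short", height_cm = 124),
    make_profile("old", age = 66),
    make_profile("young", age = 17),
    make_profile("lean", initial = 60, target = 55),     # BMI 22
    make_profile("gainer", initial = 90, target = 95),
    make_profile("dropout"),
    make_profile("no_meals"))
  logs <- rbind(
    make_logs("ok"), make_logs("short"), make_logs("old"),
    make_logs("young"), make_logs("lean"), make_logs("gainer"),
    make_logs("dropout", weeks = 1:12),
    make_logs("no_meals", mia = c(rep(80, 15), 0)))
  res <- filter_eligible(profiles, logs)
  expect_equal(res$profiles$user_id, "ok")
  rep <- res$report
  expect_equal(rep$n_in, 8)
  expect_equal(rep$n_out, 1)
  expect_equal(rep$n_out + sum(rep$filters$excluded), rep$n_in)
  cnt <- setNames(rep$filters$excluded, rep$filters$filter)
  expect_equal(unname(cnt["incomplete 16-week program"]), 1)
  expect_equal(unname(cnt["missing weekly weight/meal records"]), 1)
  expect_equal(unname(cnt["target weight not below initial"]), 1)
  expect_equal(unname(cnt["height outside 125-230 cm"]), 1)
  expect_equal(unname(cnt["age outside 18-65 years"]), 2)
  expect_equal(unname(cnt["BMI below 25"]), 1)
  # derived fields on the survivors
  expect_equal(res$profiles$bmi, compute_bmi(90, 165))
})

test_that("filtering is idempotent and monotone", {
  cohort <- generate_cohort(generator_config(n_users = 50, seed = 77))
  once <- filter_eligible(cohort$profiles, cohort$logs)
  twice <- filter_eligible(once$profiles[names(cohort$profiles)], once$logs)
  expect_equal(twice$profiles$user_id, once$profiles$user_id)
  expect_true(all(twice$report$filters$excluded == 0))
  expect_lte(nrow(once$profiles), nrow(cohort$profiles))
})

test_that("duplicate user ids are rejected", {
  profiles <- rbind(make_profile("a"), make_profile("a"))
  expect_error(filter_eligible(profiles, make_logs("a")), "duplicate")
})
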