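test_that("bmi and classification follow the WPRO cut-offs", {
  expect_equal(bmi(57.5, 1.60), 57.5 / 2.56)
  expect_equal(bmi(1.7^2, 1.7), 1)
  expect_error(bmi(60, 0), "> 0")

  expect_equal(as.character(classify_bmi(23.0)), "overweight")
  expect_equal(as.character(classify_bmi(25.0)), "obesity1")
  expect_equal(as.character(classify_bmi(30.0)), "obesity2")
  expect_equal(as.character(classify_bmi(22.99)), "below")
  expect_equal(as.character(classify_bmi(24.999)), "overweight")
  expect_equal(as.character(classify_bmi(29.999)), "obesity1")
  expect_error(classify_bmi(-1), "> 0")
})

test_that("weight changes apply by sex without mutating the input", {
  cohort <- make_fixed_cohort(bmi_male = c(60 / 2.56), bmi_female = c(55 / 2.56))
  before <- cohort$weight_kg
  out <- apply_weight_change(cohort, c(male = 0.59, female = 0.76))
  expect_equal(out$weight_kg, c(60 - 0.59, 55 - 0.76))
  expect_equal(cohort$weight_kg, before) # input untouched
  expect_equal(out$height_m, cohort$height_m)

  # zero change is the identity, and changes invert
  expect_equal(apply_weight_change(cohort, c(male = 0, female = 0)), cohort)
  fwd <- apply_weight_change(cohort, c(male = 0.15, female = 0.19))
  back <- apply_weight_change(fwd, c(male = -0.15, female = -0.19))
  expect_equal(back$weight_kg, cohort$weight_kg)

  expect_error(apply_weight_change(cohort, c(male = 100, female = 100)),
               "non-positive")
  expect_error(apply_weight_change(cohort[0, ], c(male = 0, female = 0)), "empty")
})

test_that("weighted prevalence reduces to known closed forms", {
  # every member in class -> estimate 1, se 0
  allin <- make_fixed_cohort(bmi_male = c(23.5, 24, 24.9), bmi_female = c(23.1, 24.5))
  p <- weighted_prevalence(allin, "overweight")
  expect_equal(p$estimate, 1)
  expect_equal(p$se, 0)

  # equal weights: k of n in class
  mixed <- make_fixed_cohort(bmi_male = c(24, 26, 20, 31), bmi_female = c(24, 22))
  expect_equal(weighted_prevalence(mixed, "overweight")$estimate, 2 / 6)
  expect_equal(weighted_prevalence(mixed, "obesity2")$estimate, 1 / 6)
  expect_equal(weighted_prevalence(mixed, "overweight", "male")$estimate, 1 / 4)

  # weights shift the estimate as the weighted ratio
  wtd <- make_fixed_cohort(bmi_male = c(24, 20), bmi_female = numeric(0),
                           weights = c(3, 1))
  expect_equal(weighted_prevalence(wtd, "overweight")$estimate, 0.75)
  expect_equal(weighted_prevalence(wtd, "overweight")$se,
               sqrt(9 * 0.0625 + 1 * 0.5625) / 4)

  expect_error(weighted_prevalence(make_fixed_cohort(24, numeric(0)),
                                   "overweight", "female"),
               "empty")
})

test_that("weighted class shares always sum to one", {
  for (seed in 1:3) {
    cohort <- generate_adult_cohort(cohort_spec(n = 800, seed = seed))
    prev <- weighted_prevalence(cohort)
    expect_equal(sum(prev$estimate), 1)
  }
})

test_that("mean BMI reduction is the weighted mean of dw over height squared", {
  cohort <- make_fixed_cohort(bmi_male = c(22, 25), bmi_female = c(21, 24))
  res <- mean_bmi_reduction(cohort, c(male = 0.59, female = 0.59))
  expect_equal(res$dbmi[res$stratum == "both"], 0.59 / 2.56)
  res0 <- mean_bmi_reduction(cohort, c(male = 0, female = 0))
  expect_equal(res0$dbmi, c(0, 0, 0))
  # exact linearity in dw
  r1 <- mean_bmi_reduction(cohort, c(male = 0.1, female = 0.2))
  r3 <- mean_bmi_reduction(cohort, c(male = 0.3, female = 0.6))
  expect_equal(r3$dbmi, 3 * r1$dbmi)
})

test_that("a bigger price increase never raises overweight-or-obesity prevalence", {
  cohort <- default_test_cohort(n = 6000, seed = 33)
  wc <- weight_change_table(market_impact())
  adults <- wc[wc$group %in% c("male", "female"), ]
  combined <- vapply(paste0("s", 1:5), function(sid) {
    dw <- adults[adults$scenario_id == sid, ]
    shifted <- apply_weight_change(
      cohort, stats::setNames(dw$weight_reduction_kg, dw$group))
    prev <- weighted_prevalence(shifted)
    sum(prev$estimate[prev$class != "below"])
  }, numeric(1))
  # scenarios are ordered by price increase (5, 11, 19, 20, 20%)
  expect_true(all(diff(combined) <= 1e-12))
  baseline <- sum(weighted_prevalence(cohort)$estimate[-1])
  expect_true(all(combined <= baseline))
})

test_that("the topmost class can only shrink under a weight reduction", {
  for (seed in c(7, 8)) {
    cohort <- generate_adult_cohort(cohort_spec(n = 4000, seed = seed))
    before <- weighted_prevalence(cohort, "obesity2")$estimate
    shifted <- apply_weight_change(cohort, c(male = 0.59, female = 0.76))
    after <- weighted_prevalence(shifted, "obesity2")$estimate
    expect_lte(after, before)
  }
})

test_that("prevalence table spans baseline and scenarios by stratum", {
  cohort <- default_test_cohort(n = 3000, seed = 44)
  wc <- weight_change_table(market_impact())
  tab <- prevalence_table(cohort, wc)
  expect_setequal(unique(tab$scenario_id), c("baseline", paste0("s", 1:5)))
  expect_setequal(unique(tab$stratum), c("both", "male", "female"))
  expect_equal(nrow(tab), 6 * 3 * 4)
  expect_true(all(tab$estimate >= 0 & tab$estimate <= 1))
  expect_true(all(tab$se >= 0))
})
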