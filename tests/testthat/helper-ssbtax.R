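# Shared fixtures, built in code.

# A small deterministic cohort with known composition: n_male + n_female
# adults, fixed heights, BMI values supplied directly.
make_fixed_cohort <- function(bmi_male, bmi_female,
                              height_male = 1.60, height_female = 1.60,
                              weights = NULL) {
  n <- length(bmi_male) + length(bmi_female)
  height <- c(rep(height_male, length(bmi_male)),
              rep(height_female, length(bmi_female)))
  bmi_all <- c(bmi_male, bmi_female)
  tibble::tibble(
    id = seq_len(n),
    age = rep(30, n),
    sex = c(rep("male", length(bmi_male)), rep("female", length(bmi_female))),
    weight_kg = bmi_all * height^2,
    height_m = height,
    survey_weight = weights %||% rep(1, n)
  )
}

default_test_cohort <- function(n = 20000, seed = 101) {
  generate_adult_cohort(cohort_spec(n = n, seed = seed))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
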