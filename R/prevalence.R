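#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(57.5, 1.60)
bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0)) rlang::abort("height must be > 0")
  weight_kg / height_m^2
}

bmi_class_levels <- c("below", "overweight", "obesity1", "obesity2")

#' Classify BMI under the WPRO (Asian) cut-offs
#'
#' Half-open intervals, closed on the left: below (< 23), overweight
#' (23 <= BMI < 25), obesity class I (25 <= BMI < 30), obesity class II
#' (BMI >= 30).
#'
#' @param x BMI values (> 0).
#' @return A factor with levels `below`, `overweight`, `obesity1`,
#'   `obesity2`.
#' @export
#' @examples
#' classify_bmi(c(22.99, 23, 25, 30))
classify_bmi <- function(x) {
  if (any(x <= 0)) rlang::abort("BMI must be > 0")
  cut(x, breaks = c(-Inf, 23, 25, 30, Inf), right = FALSE,
      labels = bmi_class_levels)
}

#' Apply sex-specific weight reductions to a cohort
#'
#' Subtracts each person's sex-specific weight reduction from their weight,
#' leaving heights unchanged (the model assumes no height change over the
#' projection horizon). The input cohort is not modified.
#'
#' @param cohort A cohort tibble.
#' @param dweight_by_sex Named numeric, kg, e.g. `c(male = 0.59, female =
#'   0.76)`; positive values are weight reductions.
#' @return The cohort with updated `weight_kg`.
#' @export
#' @examples
#' cohort <- generate_adult_cohort(cohort_spec(n = 500, seed = 1))
#' taxed <- apply_weight_change(cohort, c(male = 0.59, female = 0.76))
apply_weight_change <- function(cohort, dweight_by_sex) {
  if (nrow(cohort) == 0) rlang::abort("cohort is empty")
  if (!all(c("male", "female") %in% names(dweight_by_sex))) {
    rlang::abort("dweight_by_sex needs named 'male' and 'female' entries")
  }
  new_weight <- cohort$weight_kg - unname(dweight_by_sex[cohort$sex])
  if (any(new_weight <= 0)) {
    rlang::abort("weight change would produce non-positive body weights")
  }
  out <- cohort
  out$weight_kg <- new_weight
  out
}

stratum_filter <- function(cohort, stratum) {
  stratum <- match.arg(stratum, c("both", "male", "female"))
  out <- if (stratum == "both") cohort else cohort[cohort$sex == stratum, ]
  if (nrow(out) == 0) rlang::abort(paste0("stratum '", stratum, "' is empty"))
  out
}

#' Survey-weighted BMI class prevalence
#'
#' Estimates the weighted share of a BMI class in a stratum,
#' `sum(w * 1[class]) / sum(w)`, with a linearised (Taylor) standard error
#' for the weighted ratio: `sqrt(sum(w^2 (y - p)^2)) / sum(w)`. No
#' cluster/stratum design terms are included, so these SEs approximate - and
#' will typically undershoot - those of a complex survey design.
#'
#' @param cohort A cohort tibble.
#' @param class One of `below`, `overweight`, `obesity1`, `obesity2`, or
#'   `NULL` for all four classes.
#' @param stratum `"both"`, `"male"` or `"female"`.
#' @return A tibble with columns `class`, `stratum`, `estimate`, `se`.
#' @export
#' @examples
#' cohort <- generate_adult_cohort(cohort_spec(n = 2000, seed = 1))
#' weighted_prevalence(cohort, "overweight")
weighted_prevalence <- function(cohort, class = NULL, stratum = "both") {
  sub <- stratum_filter(cohort, stratum)
  classes <- if (is.null(class)) bmi_class_levels else {
    match.arg(class, bmi_class_levels, several.ok = TRUE)
  }
  cls <- classify_bmi(bmi(sub$weight_kg, sub$height_m))
  w <- sub$survey_weight
  sw <- sum(w)
  purrr::map_dfr(classes, function(cl) {
    y <- as.numeric(cls == cl)
    p <- sum(w * y) / sw
    se <- sqrt(sum(w^2 * (y - p)^2)) / sw
    tibble::tibble(class = cl, stratum = stratum, estimate = p, se = se)
  })
}

#' Survey-weighted mean BMI
#'
#' @param cohort A cohort tibble.
#' @param stratum `"both"`, `"male"` or `"female"`.
#' @return A tibble with columns `stratum`, `estimate`, `se` (linearised).
#' @export
weighted_mean_bmi <- function(cohort, stratum = "both") {
  sub <- stratum_filter(cohort, stratum)
  x <- bmi(sub$weight_kg, sub$height_m)
  w <- sub$survey_weight
  m <- sum(w * x) / sum(w)
  se <- sqrt(sum(w^2 * (x - m)^2)) / sum(w)
  tibble::tibble(stratum = stratum, estimate = m, se = se)
}

#' Survey-weighted mean BMI reduction from sex-specific weight reductions
#'
#' With heights fixed, a weight reduction `dw` changes a person's BMI by
#' `dw / height^2`; the stratum mean BMI reduction is the survey-weighted
#' mean of that quantity, and is exactly linear in `dw`.
#'
#' @param cohort A cohort tibble.
#' @param dweight_by_sex Named numeric, kg (positive = reduction).
#' @param strata Strata to report.
#' @return A tibble with columns `stratum` and `dbmi` (kg/m^2).
#' @export
#' @examples
#' cohort <- generate_adult_cohort(cohort_spec(n = 2000, seed = 1))
#' mean_bmi_reduction(cohort, c(male = 0.59, female = 0.76))
mean_bmi_reduction <- function(cohort, dweight_by_sex,
                               strata = c("both", "male", "female")) {
  if (!all(c("male", "female") %in% names(dweight_by_sex))) {
    rlang::abort("dweight_by_sex needs named 'male' and 'female' entries")
  }
  purrr::map_dfr(strata, function(st) {
    sub <- stratum_filter(cohort, st)
    dbmi_i <- unname(dweight_by_sex[sub$sex]) / sub$height_m^2
    tibble::tibble(
      stratum = st,
      dbmi = sum(sub$survey_weight * dbmi_i) / sum(sub$survey_weight)
    )
  })
}

#' Prevalence table across scenarios
#'
#' Recomputes the weighted BMI-class prevalences (and the mean BMI) for the
#' baseline cohort and after each scenario's adult weight reductions, by
#' stratum. `"both"` estimates pool the strata with survey weights rather
#' than averaging the sex-specific estimates.
#'
#' @param cohort A cohort tibble.
#' @param weight_changes A tibble with columns `scenario_id`, `group`
#'   (`male`/`female`) and `weight_reduction_kg`, as the adult rows of
#'   [weight_change_table()].
#' @return A tibble of class `ssb_prevalence` with columns `scenario_id`
#'   (`baseline` first), `class`, `stratum`, `estimate`, `se`.
#' @export
prevalence_table <- function(cohort, weight_changes) {
  adults <- weight_changes[weight_changes$group %in% c("male", "female"), ]
  strata <- c("both", "male", "female")
  base <- purrr::map_dfr(strata, function(st) weighted_prevalence(cohort, NULL, st))
  base <- dplyr::mutate(base, scenario_id = "baseline", .before = 1)
  proj <- purrr::map_dfr(unique(adults$scenario_id), function(sid) {
    dw <- adults[adults$scenario_id == sid, ]
    dvec <- stats::setNames(dw$weight_reduction_kg, dw$group)
    shifted <- apply_weight_change(cohort, dvec)
    purrr::map_dfr(strata, function(st) weighted_prevalence(shifted, NULL, st)) |>
      dplyr::mutate(scenario_id = sid, .before = 1)
  })
  out <- dplyr::bind_rows(base, proj)
  class(out) <- c("ssb_prevalence", class(out))
  out
}
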