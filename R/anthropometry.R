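#' Energy-to-weight conversion parameters
#'
#' Equilibrium energy-balance coefficients translating a sustained change in
#' daily energy intake into steady-state body-weight change. Adults use
#' sex-specific equilibrium coefficients (93.0 kJ/day per kg for men, 72.3
#' for women). Children aged 2-5 use fixed coefficients (216 kJ/day per kg
#' for boys, 204 for girls); ages 6-17 use age- and sex-specific linear
#' equations in kcal/day/kg: `68 - 2.5*age` for boys and `62 - 2.2*age` for
#' girls. About 50% of the equilibrium change is attained after one year and
#' 95% after three; `maturity_fraction` scales the reported equilibrium
#' change (1.0 reports the full equilibrium value at the 3-year horizon,
#' 0.95 the attained fraction).
#'
#' @param adult Named vector, kJ/day per kg, for `male` and `female` adults.
#' @param child25 Named vector, kJ/day per kg, for children aged 2-5.
#' @param hall_intercept,hall_slope Coefficients of the linear kcal/day/kg
#'   equations for ages 6-17 (intercept minus slope times age).
#' @param kcal_to_kj Conversion factor, kJ per kcal.
#' @param maturity_fraction Fraction of the equilibrium change reported.
#' @return A list of class `ssb_energy_weight_params`.
#' @export
energy_weight_params <- function(adult = c(male = 93.0, female = 72.3),
                                 child25 = c(male = 216, female = 204),
                                 hall_intercept = c(male = 68, female = 62),
                                 hall_slope = c(male = 2.5, female = 2.2),
                                 kcal_to_kj = 4.184,
                                 maturity_fraction = 1.0) {
  coefs <- c(adult, child25, hall_intercept, hall_slope, kcal_to_kj)
  if (any(coefs <= 0)) rlang::abort("all energy-weight coefficients must be > 0")
  if (maturity_fraction <= 0 || maturity_fraction > 1) {
    rlang::abort("maturity_fraction must lie in (0, 1]")
  }
  for (v in list(adult, child25, hall_intercept, hall_slope)) {
    if (!all(c("male", "female") %in% names(v))) {
      rlang::abort("sex-specific coefficients need 'male' and 'female' entries")
    }
  }
  # the linear child equations must stay positive over the supported ages
  if (hall_intercept[["male"]] - hall_slope[["male"]] * 17 <= 0 ||
      hall_intercept[["female"]] - hall_slope[["female"]] * 17 <= 0) {
    rlang::abort("child energy equations must be positive for ages up to 17")
  }
  structure(
    list(
      adult = adult, child25 = child25,
      hall_intercept = hall_intercept, hall_slope = hall_slope,
      kcal_to_kj = kcal_to_kj, maturity_fraction = maturity_fraction
    ),
    class = "ssb_energy_weight_params"
  )
}

normalize_sex <- function(sex) {
  out <- c(
    male = "male", female = "female",
    boys = "male", girls = "female", boy = "male", girl = "female"
  )[as.character(sex)]
  if (any(is.na(out))) {
    rlang::abort(paste0(
      "unknown sex value(s): ",
      paste(unique(sex[is.na(out)]), collapse = ", ")
    ))
  }
  unname(out)
}

#' Equilibrium adult weight change from an energy-intake change
#'
#' Divides the sustained daily energy change by the sex-specific equilibrium
#' coefficient. Sign is preserved: a positive energy decrease expressed as a
#' positive number yields a positive weight reduction.
#'
#' @param denergy Change in daily energy intake, kJ/person/day (vectorised).
#' @param sex `"male"` or `"female"` (vectorised, recycled against `denergy`).
#' @param params An [energy_weight_params()] object.
#' @return Equilibrium weight change, kg.
#' @export
#' @examples
#' adult_weight_change(13.7, "male")
adult_weight_change <- function(denergy, sex, params = energy_weight_params()) {
  sex <- normalize_sex(sex)
  unname(params$maturity_fraction * denergy / params$adult[sex])
}

#' Equilibrium child weight change from an energy-intake change
#'
#' Ages 2-5 use the fixed per-kg coefficients (216/204 kJ/day per kg); ages
#' 6-17 use the sex-specific linear kcal/day/kg equations, converting the
#' energy change to kcal first. Ages outside 2-17 are an error (adults are
#' handled by [adult_weight_change()]).
#'
#' @param denergy Change in daily energy intake, kJ/person/day.
#' @param age Age in completed years, 2-17 (vectorised).
#' @param sex `"male"`/`"boys"` or `"female"`/`"girls"`.
#' @param params An [energy_weight_params()] object.
#' @return Equilibrium weight change, kg.
#' @export
#' @examples
#' child_weight_change(13.7, 10, "boys")
child_weight_change <- function(denergy, age, sex, params = energy_weight_params()) {
  if (any(age < 2 | age > 17)) {
    rlang::abort("child ages must lie in [2, 17]; use adult_weight_change() for adults")
  }
  sex <- normalize_sex(sex)
  n <- max(length(denergy), length(age), length(sex))
  denergy <- rep_len(denergy, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  coef_young <- params$child25[sex]
  kcal_per_kg <- params$hall_intercept[sex] - params$hall_slope[sex] * age
  out <- ifelse(
    age <= 5,
    denergy / coef_young,
    (denergy / params$kcal_to_kj) / kcal_per_kg
  )
  params$maturity_fraction * unname(out)
}

#' Population-average child weight change
#'
#' Averages [child_weight_change()] over single-year ages 2-17 with the given
#' age weights (the child population age structure). Weights that do not sum
#' to one are normalised with a warning.
#'
#' @param denergy Change in daily energy intake, kJ/person/day.
#' @param age_weights A tibble with columns `age` (covering 2-17) and
#'   `weight`, as from [child_age_weights()], or a named numeric vector.
#' @param sex `"boys"` or `"girls"` (or `"male"`/`"female"`).
#' @param params An [energy_weight_params()] object.
#' @return The age-weighted mean equilibrium weight change, kg.
#' @export
#' @examples
#' population_average_child_change(13.7, child_age_weights(), "boys")
population_average_child_change <- function(denergy, age_weights, sex,
                                            params = energy_weight_params()) {
  if (!is.data.frame(age_weights)) {
    age_weights <- tibble::tibble(
      age = as.numeric(names(age_weights)),
      weight = as.numeric(age_weights)
    )
  }
  if (any(age_weights$weight < 0)) rlang::abort("age weights must be >= 0")
  total <- sum(age_weights$weight)
  if (total <= 0) rlang::abort("age weights must have positive mass")
  if (abs(total - 1) > 1e-8) {
    rlang::warn("age weights did not sum to 1; normalising")
    age_weights$weight <- age_weights$weight / total
  }
  changes <- child_weight_change(denergy, age_weights$age, sex, params)
  sum(age_weights$weight * changes)
}

#' Weight-change table across scenarios
#'
#' Applies the energy-to-weight conversion to every scenario's per-capita
#' energy decrease, for adult men and women and for boys and girls aged 2-17
#' (averaged over the child age structure). Reported as positive weight
#' reductions, matching the sign convention of the published tables.
#'
#' @param impact An `ssb_market_impact` tibble from [market_impact()].
#' @param age_weights Child age weights, as from [child_age_weights()].
#' @param params An [energy_weight_params()] object.
#' @return A tibble with columns `scenario_id`, `group` (`boys`, `girls`,
#'   `male`, `female`), `age_band` (`2-17` or `18+`) and
#'   `weight_reduction_kg`.
#' @export
weight_change_table <- function(impact, age_weights = child_age_weights(),
                                params = energy_weight_params()) {
  purrr::map_dfr(seq_len(nrow(impact)), function(i) {
    energy_decrease <- -impact$denergy_per_capita[i]
    tibble::tibble(
      scenario_id = impact$scenario_id[i],
      group = c("boys", "girls", "male", "female"),
      age_band = c("2-17", "2-17", "18+", "18+"),
      weight_reduction_kg = c(
        population_average_child_change(energy_decrease, age_weights, "boys", params),
        population_average_child_change(energy_decrease, age_weights, "girls", params),
        adult_weight_change(energy_decrease, "male", params),
        adult_weight_change(energy_decrease, "female", params)
      )
    )
  })
}
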