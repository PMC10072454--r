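#' Type-2-diabetes burden parameters
#'
#' Parameters of the comparative risk assessment step: the relative risk
#' reduction of type 2 diabetes per 2-unit BMI decrease (27%, 95% CI
#' 23-30%), the baseline diabetes prevalence among adults aged 18-69 (4.1%),
#' the adult population the relative reduction is scaled to, and treatment
#' costs. The two unit costs are synthetic placeholders calibrated so that
#' the blended cost per case equals 7,656,142 VND (the value implied by the
#' published cost-savings-to-avoided-cases ratio); replace them with claims
#' data when available. Sex-specific baseline prevalences are not published;
#' optional overrides are provided for users who have them.
#'
#' @param rrr_per_2_bmi Relative risk reduction per 2 kg/m^2 BMI decrease.
#' @param rrr_ci Length-2 vector, 95% CI of `rrr_per_2_bmi`.
#' @param baseline_prevalence Overall diabetes prevalence among adults.
#' @param baseline_prevalence_by_sex Optional named vector of per-sex
#'   baseline prevalences (`male`, `female`); defaults to the overall value.
#' @param adult_population Number of adults aged 18-69 the burden is scaled
#'   to.
#' @param complication_share Share of diabetes cases with complications.
#' @param cost_with_complications,cost_without_complications Annualised
#'   direct treatment cost per case, VND.
#' @param vnd_per_usd Exchange rate, VND per USD.
#' @param dose_response `"linear"` (RRR scales proportionally with
#'   `dbmi / 2`) or `"multiplicative"` (`1 - (1 - rrr)^(dbmi/2)`); the two
#'   differ by under 0.7% relative for the BMI changes this model produces.
#' @return A list of class `ssb_diabetes_params`.
#' @export
diabetes_params <- function(rrr_per_2_bmi = 0.27,
                            rrr_ci = c(0.23, 0.30),
                            baseline_prevalence = 0.041,
                            baseline_prevalence_by_sex = NULL,
                            adult_population = 67e6,
                            complication_share = 0.5,
                            cost_with_complications = 10312284,
                            cost_without_complications = 5e6,
                            vnd_per_usd = 22370,
                            dose_response = c("linear", "multiplicative")) {
  if (rrr_per_2_bmi <= 0 || rrr_per_2_bmi >= 1) {
    rlang::abort("rrr_per_2_bmi must lie in (0, 1)")
  }
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    rlang::abort("baseline_prevalence must lie in (0, 1)")
  }
  if (adult_population <= 0) rlang::abort("adult_population must be > 0")
  if (complication_share < 0 || complication_share > 1) {
    rlang::abort("complication_share must lie in [0, 1]")
  }
  if (cost_with_complications < 0 || cost_without_complications < 0) {
    rlang::abort("treatment costs must be >= 0")
  }
  structure(
    list(
      rrr_per_2_bmi = rrr_per_2_bmi,
      rrr_ci = rrr_ci,
      baseline_prevalence = baseline_prevalence,
      baseline_prevalence_by_sex = baseline_prevalence_by_sex,
      adult_population = adult_population,
      complication_share = complication_share,
      cost_with_complications = cost_with_complications,
      cost_without_complications = cost_without_complications,
      vnd_per_usd = vnd_per_usd,
      dose_response = match.arg(dose_response)
    ),
    class = "ssb_diabetes_params"
  )
}

blended_cost_per_case <- function(params) {
  params$complication_share * params$cost_with_complications +
    (1 - params$complication_share) * params$cost_without_complications
}

#' Relative risk reduction of diabetes from a BMI decrease
#'
#' Scales the 27%-per-2-unit relative risk reduction to the achieved mean
#' BMI decrease. The default dose-response is linear proportional scaling
#' (`rrr * dbmi / 2`); a multiplicative alternative
#' (`1 - (1 - rrr)^(dbmi/2)`) is available via `diabetes_params()`.
#'
#' @param dbmi Mean BMI decrease, kg/m^2 (>= 0, vectorised).
#' @param params A [diabetes_params()] object.
#' @return The relative risk reduction (fraction).
#' @export
#' @examples
#' diabetes_rrr(2.0)
diabetes_rrr <- function(dbmi, params = diabetes_params()) {
  if (any(dbmi < 0)) rlang::abort("BMI decrease must be >= 0")
  rrr <- if (params$dose_response == "linear") {
    params$rrr_per_2_bmi * dbmi / 2
  } else {
    1 - (1 - params$rrr_per_2_bmi)^(dbmi / 2)
  }
  if (any(rrr >= 1)) {
    rlang::abort("relative risk reduction >= 1: unphysical BMI decrease")
  }
  rrr
}

#' Absolute reduction in diabetes prevalence
#'
#' @param baseline_prev Baseline diabetes prevalence (fraction in (0, 1)).
#' @param rrr Relative risk reduction (fraction).
#' @return Prevalence reduction in percentage points.
#' @export
#' @examples
#' prevalence_reduction(0.041, diabetes_rrr(2.0))
prevalence_reduction <- function(baseline_prev, rrr) {
  if (any(baseline_prev <= 0) || any(baseline_prev >= 1)) {
    rlang::abort("baseline prevalence must lie in (0, 1)")
  }
  baseline_prev * rrr * 100
}

#' Avoided diabetes cases
#'
#' @param prevalence_reduction_pp Prevalence reduction, percentage points.
#' @param adult_population Adults the reduction applies to.
#' @return Number of avoided cases, rounded to the nearest integer.
#' @export
#' @examples
#' avoided_cases(0.03, 67e6)
avoided_cases <- function(prevalence_reduction_pp, adult_population) {
  if (any(adult_population <= 0)) rlang::abort("adult population must be > 0")
  round(prevalence_reduction_pp / 100 * adult_population)
}

#' Treatment-cost savings from avoided diabetes cases
#'
#' Multiplies avoided cases by the complication-share-blended cost per case
#' and converts to USD at the configured exchange rate.
#'
#' @param avoided Number of avoided cases (vectorised).
#' @param params A [diabetes_params()] object.
#' @return A tibble with columns `avoided`, `cost_bn_vnd` (billion VND) and
#'   `cost_m_usd` (million USD).
#' @export
#' @examples
#' cost_saving(20270)
cost_saving <- function(avoided, params = diabetes_params()) {
  if (is.null(params$cost_with_complications) ||
      is.null(params$cost_without_complications) ||
      is.null(params$complication_share)) {
    rlang::abort("cost parameters are not set")
  }
  vnd <- avoided * blended_cost_per_case(params)
  tibble::tibble(
    avoided = avoided,
    cost_bn_vnd = vnd / 1e9,
    cost_m_usd = vnd / params$vnd_per_usd / 1e6
  )
}

#' Diabetes burden table across scenarios
#'
#' Runs the full comparative-risk-assessment chain for each scenario's mean
#' BMI reductions: relative risk reduction, absolute prevalence reduction by
#' stratum, avoided cases in the adult population (from the both-sexes
#' estimate) and treatment-cost savings.
#'
#' @param dbmi_table A tibble with columns `scenario_id`, `stratum`
#'   (`both`/`male`/`female`) and `dbmi`, as from stacking
#'   [mean_bmi_reduction()] over scenarios.
#' @param params A [diabetes_params()] object.
#' @return A tibble of class `ssb_burden` with columns `scenario_id`,
#'   `stratum`, `dbmi`, `prevalence_reduction_pp`, `avoided_cases`,
#'   `cost_bn_vnd`, `cost_m_usd` (the last three populated on the `both`
#'   rows).
#' @export
burden_table <- function(dbmi_table, params = diabetes_params()) {
  prev_for <- function(stratum) {
    by_sex <- params$baseline_prevalence_by_sex
    if (stratum %in% c("male", "female") && !is.null(by_sex)) {
      by_sex[[stratum]]
    } else {
      params$baseline_prevalence
    }
  }
  out <- dplyr::mutate(
    dbmi_table,
    rrr = diabetes_rrr(.data$dbmi, params),
    prevalence_reduction_pp = prevalence_reduction(
      unname(vapply(.data$stratum, prev_for, numeric(1))), .data$rrr
    )
  )
  out <- dplyr::mutate(
    out,
    avoided_cases = ifelse(
      .data$stratum == "both",
      avoided_cases(.data$prevalence_reduction_pp, params$adult_population),
      NA_real_
    )
  )
  costs <- cost_saving(ifelse(is.na(out$avoided_cases), 0, out$avoided_cases), params)
  out$cost_bn_vnd <- ifelse(is.na(out$avoided_cases), NA_real_, costs$cost_bn_vnd)
  out$cost_m_usd <- ifelse(is.na(out$avoided_cases), NA_real_, costs$cost_m_usd)
  out$rrr <- NULL
  class(out) <- c("ssb_burden", class(out))
  out
}
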