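#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Monte Carlo result
#'
#' @param x An `ssb_mc` object from [run_mc()].
#' @param ... Unused.
#' @return A tibble with one row per scenario, output and stratum, with the
#'   Monte Carlo `mean` and `sd` and the matching `deterministic` value.
#' @export
tidy.ssb_mc <- function(x, ...) {
  det <- attr(x, "deterministic")
  dplyr::left_join(
    tibble::as_tibble(x),
    dplyr::rename(det, deterministic = "value"),
    by = c("scenario_id", "output", "stratum")
  )
}

#' Summarise a Monte Carlo run
#'
#' @param x An `ssb_mc` object.
#' @param ... Unused.
#' @return A one-row tibble with the model, iteration count, seed, number of
#'   rejected (non-positive) conversion-factor draws and scenario count.
#' @export
glance.ssb_mc <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    model = cfg$model,
    iterations = cfg$iterations,
    seed = cfg$seed,
    rejected_draws = attr(x, "rejected_draws"),
    n_scenarios = length(unique(x$scenario_id))
  )
}

#' Tidy a synthetic cohort's calibration
#'
#' @param x An `ssb_cohort` from [generate_adult_cohort()].
#' @param ... Unused.
#' @return A tibble of achieved weighted prevalences and mean BMI per
#'   stratum, next to the calibration targets.
#' @export
tidy.ssb_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  targets <- spec$targets |>
    tidyr::pivot_longer(c("overweight", "obesity1", "obesity2", "mean_bmi"),
                        names_to = "quantity", values_to = "target")
  achieved <- purrr::map_dfr(c("male", "female"), function(sx) {
    prev <- weighted_prevalence(x, stratum = sx)
    dplyr::bind_rows(
      tibble::tibble(sex = sx, quantity = prev$class, achieved = prev$estimate),
      tibble::tibble(sex = sx, quantity = "mean_bmi",
                     achieved = weighted_mean_bmi(x, sx)$estimate)
    )
  })
  dplyr::inner_join(targets, achieved, by = c("sex", "quantity"))
}

#' Summarise a synthetic cohort
#'
#' @param x An `ssb_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: size, seed, fraction male, weighted mean BMI
#'   and weighted overweight-or-obesity prevalence.
#' @export
glance.ssb_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  prev <- weighted_prevalence(x)
  tibble::tibble(
    n = nrow(x),
    seed = if (!is.null(spec)) spec$seed else NA_integer_,
    frac_male = mean(x$sex == "male"),
    mean_bmi = weighted_mean_bmi(x)$estimate,
    prev_overweight_plus = sum(prev$estimate[prev$class != "below"])
  )
}
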