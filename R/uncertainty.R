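#' Fit a beta distribution to a mean and 95% interval
#'
#' Finds beta shape parameters whose mean equals `mean` exactly (the shapes
#' are parameterised as `mean * k` and `(1 - mean) * k`) and whose central
#' 95% interval matches `(lo, hi)` in least squares, by a 1-D search over the
#' concentration `k`. With `method = "moments"` the concentration is instead
#' chosen so the SD equals the normal-approximation width `(hi - lo) / 3.92`.
#'
#' @param mean Target mean, in (0, 1).
#' @param lo,hi Target central 95% interval bounds.
#' @param method `"ci"` (least-squares on the interval) or `"moments"`.
#' @return A list of class `ssb_beta_fit`: `shape1`, `shape2`, `mean`,
#'   `ci` (achieved 2.5/97.5% quantiles) and `residual`.
#' @export
#' @examples
#' fit_beta_from_ci(0.27, 0.23, 0.30)
fit_beta_from_ci <- function(mean = 0.27, lo = 0.23, hi = 0.30,
                             method = c("ci", "moments")) {
  method <- match.arg(method)
  if (mean <= 0 || mean >= 1 || lo <= 0 || hi >= 1) {
    rlang::abort("mean and interval bounds must lie in (0, 1)")
  }
  if (lo >= mean || hi <= mean) {
    rlang::abort("interval bounds must bracket the mean (lo < mean < hi)")
  }
  if (method == "moments") {
    sd <- (hi - lo) / 3.92
    k <- mean * (1 - mean) / sd^2 - 1
    if (k <= 0) rlang::abort("interval too wide for a valid beta fit")
  } else {
    obj <- function(log_k) {
      k <- exp(log_k)
      q <- stats::qbeta(c(0.025, 0.975), mean * k, (1 - mean) * k)
      (q[1] - lo)^2 + (q[2] - hi)^2
    }
    opt <- stats::optimize(obj, interval = c(log(2), log(1e8)), tol = 1e-12)
    k <- exp(opt$minimum)
  }
  shape1 <- mean * k
  shape2 <- (1 - mean) * k
  ci <- stats::qbeta(c(0.025, 0.975), shape1, shape2)
  structure(
    list(
      shape1 = shape1, shape2 = shape2,
      mean = shape1 / (shape1 + shape2),
      ci = ci,
      residual = sqrt((ci[1] - lo)^2 + (ci[2] - hi)^2)
    ),
    class = "ssb_beta_fit"
  )
}

#' Monte Carlo configuration for probabilistic sensitivity analysis
#'
#' Model 1 resamples only the per-sex adult energy-to-weight conversion
#' factors (normal, parameter-level draws per iteration). Model 2
#' additionally resamples the diabetes relative risk reduction from a beta
#' distribution matched to its published mean and 95% CI. Conversion-factor
#' SDs are not published; the default 5% coefficient of variation is a
#' calibration chosen so simulated weight-change SDs approximate the
#' published Monte Carlo SDs, and is user-overridable.
#'
#' @param iterations Number of Monte Carlo iterations.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param model `"model1"` or `"model2"`.
#' @param cf_mean Named per-sex means of the adult conversion factor,
#'   kJ/day per kg.
#' @param cf_sd Named per-sex SDs (defaults to 5% of the means).
#' @param rrr_mean,rrr_ci Mean and 95% CI of the diabetes relative risk
#'   reduction per 2 BMI units (model 2 only).
#' @param beta_method Passed to [fit_beta_from_ci()]: `"ci"` or `"moments"`.
#' @return A list of class `ssb_mc_config`.
#' @export
mc_config <- function(iterations = 10000, seed = 1L,
                      model = c("model1", "model2"),
                      cf_mean = c(male = 93.0, female = 72.3),
                      cf_sd = 0.05 * cf_mean,
                      rrr_mean = 0.27, rrr_ci = c(0.23, 0.30),
                      beta_method = c("ci", "moments")) {
  if (iterations < 1) rlang::abort("iterations must be >= 1")
  if (any(cf_mean <= 0) || any(cf_sd < 0)) {
    rlang::abort("conversion-factor means must be > 0 and SDs >= 0")
  }
  structure(
    list(
      iterations = as.integer(iterations), seed = as.integer(seed),
      model = match.arg(model),
      cf_mean = cf_mean, cf_sd = cf_sd,
      rrr_mean = rrr_mean, rrr_ci = rrr_ci,
      beta_method = match.arg(beta_method)
    ),
    class = "ssb_mc_config"
  )
}

# Survey-weighted sums used to turn per-sex weight reductions into stratum
# mean BMI reductions without touching the microdata per iteration.
cohort_mc_stats <- function(cohort) {
  w <- cohort$survey_weight
  invh2w <- w / cohort$height_m^2
  male <- cohort$sex == "male"
  list(
    sw = c(male = sum(w[male]), female = sum(w[!male]), both = sum(w)),
    sinvh2w = c(male = sum(invh2w[male]), female = sum(invh2w[!male]))
  )
}

# The downstream chain, vectorised over parameter draws. `energy_decrease`
# is the positive per-capita energy-intake decrease (kJ/day); `cf_m`, `cf_f`
# and `rrr2` are equal-length draw vectors (or scalars for the
# deterministic evaluation).
burden_chain <- function(energy_decrease, cf_m, cf_f, rrr2, stats, params) {
  dw_m <- energy_decrease / cf_m
  dw_f <- energy_decrease / cf_f
  dbmi_male <- dw_m * stats$sinvh2w[["male"]] / stats$sw[["male"]]
  dbmi_female <- dw_f * stats$sinvh2w[["female"]] / stats$sw[["female"]]
  dbmi_both <- (dw_m * stats$sinvh2w[["male"]] + dw_f * stats$sinvh2w[["female"]]) /
    stats$sw[["both"]]
  rrr_of <- function(dbmi) {
    if (params$dose_response == "linear") rrr2 * dbmi / 2 else 1 - (1 - rrr2)^(dbmi / 2)
  }
  prev_for <- function(stratum) {
    by_sex <- params$baseline_prevalence_by_sex
    if (stratum %in% c("male", "female") && !is.null(by_sex)) by_sex[[stratum]]
    else params$baseline_prevalence
  }
  pp_both <- prev_for("both") * rrr_of(dbmi_both) * 100
  pp_male <- prev_for("male") * rrr_of(dbmi_male) * 100
  pp_female <- prev_for("female") * rrr_of(dbmi_female) * 100
  cases <- round(pp_both / 100 * params$adult_population)
  vnd <- cases * blended_cost_per_case(params)
  list(
    weight_change_male = dw_m, weight_change_female = dw_f,
    bmi_reduction_both = dbmi_both, bmi_reduction_male = dbmi_male,
    bmi_reduction_female = dbmi_female,
    prevalence_reduction_pp_both = pp_both,
    prevalence_reduction_pp_male = pp_male,
    prevalence_reduction_pp_female = pp_female,
    avoided_cases_both = cases,
    cost_bn_vnd_both = vnd / 1e9,
    cost_m_usd_both = vnd / params$vnd_per_usd / 1e6
  )
}

chain_to_tibble <- function(values, f) {
  nm <- names(values)
  stratum <- sub(".*_(both|male|female)$", "\\1", nm)
  output <- sub("_(both|male|female)$", "", nm)
  tibble::tibble(
    output = output, stratum = stratum,
    value = unname(vapply(values, f, numeric(1)))
  )
}

draw_positive_normal <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  rejected <- 0L
  while (any(x <= 0)) {
    bad <- x <= 0
    rejected <- rejected + sum(bad)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  list(draws = x, rejected = rejected)
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the weight-to-burden chain for
#' every scenario. Parameters are drawn once per iteration (parameter-level
#' resampling): the per-sex conversion factors from truncated-positive
#' normals (model 1 and 2), and the diabetes relative risk reduction from the
#' fitted beta (model 2 only; model 1 holds it at its point value). All
#' conversion-factor draws are made before any risk draws, so models 1 and 2
#' share identical weight-change draws for the same seed. Means and SDs over
#' iterations are reported per output.
#'
#' @param impact An `ssb_market_impact` tibble from [market_impact()].
#' @param cohort A cohort tibble (supplies the survey-weighted height
#'   structure that converts weight change into BMI change).
#' @param config An [mc_config()].
#' @param params A [diabetes_params()] object.
#' @return An object of class `ssb_mc`: a tibble with columns `scenario_id`,
#'   `model`, `output`, `stratum`, `mean`, `sd`, with the matching
#'   deterministic (point-parameter) values as attribute `"deterministic"`
#'   and the configuration as attribute `"config"`.
#' @export
#' @examples
#' cohort <- generate_adult_cohort(cohort_spec(n = 1000, seed = 1))
#' mc <- run_mc(market_impact(), cohort, mc_config(iterations = 200, seed = 2))
#' tidy(mc)
run_mc <- function(impact, cohort, config = mc_config(),
                   params = diabetes_params()) {
  stopifnot(inherits(config, "ssb_mc_config"))
  stats_ <- cohort_mc_stats(cohort)
  n <- config$iterations
  set.seed(config$seed)
  d_m <- draw_positive_normal(n, config$cf_mean[["male"]], config$cf_sd[["male"]])
  d_f <- draw_positive_normal(n, config$cf_mean[["female"]], config$cf_sd[["female"]])
  if (config$model == "model2") {
    fit <- fit_beta_from_ci(config$rrr_mean, config$rrr_ci[1], config$rrr_ci[2],
                            method = config$beta_method)
    rrr2 <- stats::rbeta(n, fit$shape1, fit$shape2)
  } else {
    rrr2 <- rep(params$rrr_per_2_bmi, n)
  }
  res <- purrr::map_dfr(seq_len(nrow(impact)), function(i) {
    energy_decrease <- -impact$denergy_per_capita[i]
    sim <- burden_chain(energy_decrease, d_m$draws, d_f$draws, rrr2,
                        stats_, params)
    means <- chain_to_tibble(sim, mean)
    sds <- chain_to_tibble(sim, stats::sd)
    dplyr::mutate(
      dplyr::rename(means, mean = "value"),
      sd = sds$value,
      scenario_id = impact$scenario_id[i],
      model = config$model,
      .before = 1
    ) |>
      dplyr::relocate("scenario_id", "model", "output", "stratum")
  })
  det <- purrr::map_dfr(seq_len(nrow(impact)), function(i) {
    sim <- burden_chain(-impact$denergy_per_capita[i],
                        config$cf_mean[["male"]], config$cf_mean[["female"]],
                        params$rrr_per_2_bmi, stats_, params)
    dplyr::mutate(chain_to_tibble(sim, identity),
                  scenario_id = impact$scenario_id[i], .before = 1)
  })
  attr(res, "deterministic") <- det
  attr(res, "config") <- config
  attr(res, "rejected_draws") <- d_m$rejected + d_f$rejected
  class(res) <- c("ssb_mc", class(res))
  res
}

#' One-way deterministic sensitivity analysis on the price elasticity
#'
#' Re-runs the deterministic pipeline for each elasticity value. The market
#' calibration (baseline volume, population, mean sugar density) is held
#' fixed at its base-case inversion; only the demand response is varied, so
#' every consumption decrease scales by `elasticity / base`. When a cohort
#' is supplied the downstream weight, BMI and diabetes-burden outputs are
#' appended.
#'
#' @param elasticities Negative elasticity values to evaluate.
#' @param scenarios Scenario tibble.
#' @param market Market calibration from [calibrate_market()].
#' @param cohort Optional cohort for downstream outputs.
#' @param ew_params,d_params Anthropometry and diabetes parameter objects.
#' @return A tibble of class `ssb_sa` keyed by `elasticity` and
#'   `scenario_id`.
#' @export
#' @examples
#' one_way_sa(c(-1.14, -1.0, -0.8))
one_way_sa <- function(elasticities = c(-1.14, -1.0, -0.8),
                       scenarios = tax_scenarios(),
                       market = calibrate_market(),
                       cohort = NULL,
                       ew_params = energy_weight_params(),
                       d_params = diabetes_params()) {
  if (any(elasticities >= 0)) rlang::abort("elasticities must be negative")
  out <- purrr::map_dfr(elasticities, function(e) {
    imp <- market_impact(scenarios, market, elasticity = e)
    tab <- dplyr::mutate(tibble::as_tibble(imp), elasticity = e, .before = 1)
    if (!is.null(cohort)) {
      stats_ <- cohort_mc_stats(cohort)
      extra <- purrr::map_dfr(seq_len(nrow(imp)), function(i) {
        sim <- burden_chain(-imp$denergy_per_capita[i],
                            ew_params$adult[["male"]], ew_params$adult[["female"]],
                            d_params$rrr_per_2_bmi, stats_, d_params)
        tibble::tibble(
          scenario_id = imp$scenario_id[i],
          weight_change_male = sim$weight_change_male,
          weight_change_female = sim$weight_change_female,
          bmi_reduction_both = sim$bmi_reduction_both,
          avoided_cases = sim$avoided_cases_both,
          cost_bn_vnd = sim$cost_bn_vnd_both
        )
      })
      tab <- dplyr::left_join(tab, extra, by = "scenario_id")
    }
    tab
  })
  class(out) <- c("ssb_sa", class(out))
  out
}
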