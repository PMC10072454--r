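#' Default run configuration
#'
#' The configuration that reproduces the base-case analysis: the five
#' shipped tax scenarios, the market calibration inverted from the published
#' 10%-ad-valorem scenario, a synthetic cohort of 3,856 adults, Monte Carlo
#' models 1 and 2 at 10,000 iterations, and the one-way elasticity
#' sensitivity analysis at -1.14, -1.0 and -0.8. A YAML copy ships at
#' `system.file("config", "baseline.yaml", package = "ssbtax")`.
#'
#' @return A list of class `ssb_run_config`.
#' @export
default_config <- function() {
  validate_config(list(
    seed = 42L,
    outputs = "ssbtax-out",
    elasticity = -1.14,
    scenarios = purrr::transpose(as.list(tax_scenarios())),
    market = list(
      decrease_s1 = 171.3, price_increase_s1 = 0.05,
      per_capita_decrease_s1 = 2.6, sugar_decrease_s1 = 0.8
    ),
    cohort = list(n = 3856),
    energy_weight = list(),
    diabetes = list(),
    mc = list(enabled = TRUE, iterations = 10000,
              models = list("model1", "model2")),
    sa = list(elasticities = list(-1.14, -1.0, -0.8))
  ))
}

#' Read and validate a run configuration from YAML
#'
#' @param path Path to a YAML configuration file with the structure of
#'   [default_config()] (see the shipped `config/baseline.yaml`).
#' @return A validated list of class `ssb_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("config file not found: ", path))
  validate_config(yaml::read_yaml(path))
}

as_num_vec <- function(x) {
  if (is.list(x)) unlist(x) else x
}

validate_config <- function(config) {
  if (!is.list(config)) rlang::abort("config must be a list")
  for (field in c("seed", "scenarios")) {
    if (is.null(config[[field]])) {
      rlang::abort(paste0("config is missing required field: ", field))
    }
  }
  if (length(config$scenarios) == 0) rlang::abort("config has an empty scenario list")
  for (sc in config$scenarios) {
    for (field in c("id", "tax_type", "rate")) {
      if (is.null(sc[[field]])) {
        rlang::abort(paste0("every scenario needs '", field, "'"))
      }
    }
    if (!sc$tax_type %in% c("ad_valorem", "specific_volume", "specific_sugar")) {
      rlang::abort(paste0("unknown tax_type in scenario ", sc$id, ": ", sc$tax_type))
    }
    if (sc$rate < 0) rlang::abort(paste0("negative rate in scenario ", sc$id))
  }
  config$seed <- as.integer(config$seed)
  config$elasticity <- config$elasticity %||% -1.14
  config$outputs <- config$outputs %||% "ssbtax-out"
  config$market <- config$market %||% list()
  config$cohort <- config$cohort %||% list(n = 3856)
  config$energy_weight <- config$energy_weight %||% list()
  config$diabetes <- config$diabetes %||% list()
  config$mc <- config$mc %||% list(enabled = FALSE)
  config$sa <- config$sa %||% list()
  structure(config, class = c("ssb_run_config", "list"))
}

config_scenarios <- function(config) {
  purrr::map_dfr(config$scenarios, function(sc) {
    tibble::tibble(
      id = sc$id, tax_type = sc$tax_type, rate = sc$rate,
      avg_price_increase = sc$avg_price_increase %||% NA_real_
    )
  })
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("pipeline stage '", stage, "' failed: ",
                        conditionMessage(e)))
  })
}

#' Run the full scenario pipeline
#'
#' Executes every modelling step for every scenario in the configuration -
#' tax to price, price to consumption, sugar and energy accounting, energy to
#' weight, cohort BMI reclassification, diabetes burden, Monte Carlo
#' uncertainty and the elasticity sensitivity analysis - and writes one CSV
#' per result table plus a JSON manifest recording the configuration, its
#' hash, the seed and the package version. Re-running with the same
#' configuration and seed writes byte-identical CSVs.
#'
#' @param config A configuration list from [default_config()] /
#'   [read_run_config()], or a path to a YAML file.
#' @param out_dir Output directory (overrides `config$outputs`).
#' @param quiet Suppress progress and parameter-echo messages.
#' @return Invisibly, a named list of the result tibbles plus `paths`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$cohort$n <- 500
#' cfg$mc <- list(enabled = TRUE, iterations = 50, models = list("model1"))
#' res <- run_pipeline(cfg, out_dir = tempfile("ssbtax"))
#' res$market_impact
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  out_dir <- out_dir %||% config$outputs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) rlang::inform(paste0(...))

  scenarios <- config_scenarios(config)
  market <- run_stage("market calibration",
    do.call(calibrate_market, config$market))
  ew_params <- run_stage("energy-weight parameters",
    do.call(energy_weight_params, lapply(config$energy_weight, as_num_vec)))
  d_params <- run_stage("diabetes parameters",
    do.call(diabetes_params, lapply(config$diabetes, as_num_vec)))
  say("elasticity = ", config$elasticity,
      "; baseline volume = ", round(market$baseline_volume, 1),
      " ML/yr; population = ", round(market$population / 1e6, 2),
      " M; mean sugar density = ", round(market$sugar_density, 2), " g/100ml")

  cohort <- run_stage("cohort", {
    if (!is.null(config$cohort$path)) {
      read_cohort(config$cohort$path)
    } else {
      spec_args <- config$cohort
      spec_args$seed <- spec_args$seed %||% config$seed
      spec_args <- lapply(spec_args, as_num_vec)
      generate_adult_cohort(do.call(cohort_spec, spec_args))
    }
  })
  say("cohort: ", nrow(cohort), " adults")

  impact <- run_stage("market impact",
    market_impact(scenarios, market, elasticity = config$elasticity))
  weights <- run_stage("weight change",
    weight_change_table(impact, child_age_weights(), ew_params))
  prevalence <- run_stage("prevalence", prevalence_table(cohort, weights))
  dbmi <- run_stage("BMI reduction", {
    adults <- weights[weights$group %in% c("male", "female"), ]
    purrr::map_dfr(unique(adults$scenario_id), function(sid) {
      dw <- adults[adults$scenario_id == sid, ]
      mean_bmi_reduction(
        cohort, stats::setNames(dw$weight_reduction_kg, dw$group)
      ) |>
        dplyr::mutate(scenario_id = sid, .before = 1)
    })
  })
  burden <- run_stage("diabetes burden", burden_table(dbmi, d_params))

  mc <- NULL
  if (isTRUE(config$mc$enabled)) {
    mc <- run_stage("Monte Carlo", {
      models <- unlist(config$mc$models %||% list("model1"))
      purrr::map_dfr(models, function(m) {
        run_mc(impact, cohort,
               mc_config(iterations = config$mc$iterations %||% 10000,
                         seed = config$seed, model = m),
               d_params)
      })
    })
  }
  sa <- NULL
  if (length(config$sa$elasticities %||% list()) > 0) {
    sa <- run_stage("sensitivity analysis",
      one_way_sa(unlist(config$sa$elasticities), scenarios, market, cohort,
                 ew_params, d_params))
  }

  tables <- list(
    market_impact = tibble::as_tibble(impact),
    weight_change = weights,
    prevalence = tibble::as_tibble(prevalence),
    burden = tibble::as_tibble(burden),
    mc_summary = if (!is.null(mc)) tibble::as_tibble(mc) else NULL,
    sa_elasticity = if (!is.null(sa)) tibble::as_tibble(sa) else NULL
  )
  paths <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths[nm] <- p
  }
  manifest <- list(
    package = "ssbtax",
    version = as.character(utils::packageVersion("ssbtax")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths["manifest"] <- manifest_path
  say("wrote ", length(paths), " files to ", out_dir)
  invisible(c(tables[!vapply(tables, is.null, logical(1))],
              list(paths = paths)))
}
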