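#' Default SSB market categories
#'
#' The four beverage categories the Vietnamese SSB market is modelled with:
#' carbonates, juices, ready-to-drink tea/coffee, and energy/sport drinks.
#' Category sugar densities are fixed model constants (11, 7, 9 and 16 g per
#' 100 ml). Baseline volumes and retail prices come from a proprietary market
#' database and are therefore `NA` by default; supply your own via
#' [read_categories()] or by editing the returned tibble when you want
#' per-category price computations instead of the shipped average price
#' increases.
#'
#' @return A tibble with columns `name`, `baseline_volume_ml_per_year`
#'   (million litres/year), `retail_price_vnd_per_litre` and
#'   `sugar_density_g_per_100ml`.
#' @export
#' @examples
#' ssb_categories()
ssb_categories <- function() {
  tibble::tibble(
    name = c("carbonates", "juices", "rtd_tea_coffee", "energy_sport"),
    baseline_volume_ml_per_year = NA_real_,
    retail_price_vnd_per_litre = NA_real_,
    sugar_density_g_per_100ml = c(11, 7, 9, 16)
  )
}

#' Read a beverage-category table from CSV
#'
#' @param path Path to a CSV with columns `name`,
#'   `baseline_volume_ml_per_year`, `retail_price_vnd_per_litre`,
#'   `sugar_density_g_per_100ml`.
#' @return A validated tibble of beverage categories.
#' @export
read_categories <- function(path) {
  cats <- readr::read_csv(path, show_col_types = FALSE)
  required <- c(
    "name", "baseline_volume_ml_per_year",
    "retail_price_vnd_per_litre", "sugar_density_g_per_100ml"
  )
  missing <- setdiff(required, names(cats))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "category table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  validate_categories(cats)
  cats
}

validate_categories <- function(cats) {
  ok_vol <- is.na(cats$baseline_volume_ml_per_year) |
    cats$baseline_volume_ml_per_year >= 0
  ok_price <- is.na(cats$retail_price_vnd_per_litre) |
    cats$retail_price_vnd_per_litre > 0
  ok_sugar <- cats$sugar_density_g_per_100ml >= 0 &
    cats$sugar_density_g_per_100ml <= 30
  if (!all(ok_vol)) rlang::abort("baseline volumes must be >= 0")
  if (!all(ok_price)) rlang::abort("retail prices must be > 0")
  if (!all(ok_sugar)) rlang::abort("sugar densities must lie in [0, 30] g/100 ml")
  invisible(cats)
}

#' The five modelled tax scenarios
#'
#' The default scenario set: a 10% and a 40% ad valorem excise on the
#' ex-factory price, volumetric specific taxes of 3,500 and 7,000 VND per
#' litre, and a sugar-based specific tax of 60 VND per gram of sugar per
#' litre. Each scenario carries the average retail price increase produced by
#' the external tax-incidence model (5%, 11%, 19%, 20%, 20%) as
#' `avg_price_increase`; these are used directly by [market_impact()], while
#' per-category computation from prices remains available through
#' [retail_price_increase()] when a price table is supplied.
#'
#' @return A tibble with columns `id`, `tax_type` (one of `ad_valorem`,
#'   `specific_volume`, `specific_sugar`), `rate` (fraction of factory price
#'   for ad valorem, VND/litre for volumetric, VND per gram of sugar per litre
#'   for sugar-based) and `avg_price_increase` (fraction).
#' @export
#' @examples
#' tax_scenarios()
tax_scenarios <- function() {
  tibble::tibble(
    id = paste0("s", 1:5),
    tax_type = c(
      "ad_valorem", "specific_volume", "specific_sugar",
      "specific_volume", "ad_valorem"
    ),
    rate = c(0.10, 3500, 60, 7000, 0.40),
    avg_price_increase = c(0.05, 0.11, 0.19, 0.20, 0.20)
  )
}

#' Published per-scenario market impacts
#'
#' The published per-scenario consumption, sugar and energy impacts, as
#' model reference inputs: total and per-capita consumption decreases, sugar
#' decrease and energy-intake decrease for the five shipped scenarios. These
#' are the printed values the market calibration inverts and downstream
#' steps consume (all positive magnitudes of decreases).
#'
#' @return A tibble with columns `scenario_id`, `price_increase`,
#'   `decrease_total` (million litres/year), `decrease_per_capita`
#'   (litres/person/year), `sugar_decrease` (g/person/day) and
#'   `energy_decrease` (kJ/person/day).
#' @export
#' @examples
#' published_market_impacts()
published_market_impacts <- function() {
  tibble::tibble(
    scenario_id = paste0("s", 1:5),
    price_increase = c(0.05, 0.11, 0.19, 0.20, 0.20),
    decrease_total = c(171.3, 334.0, 641.0, 668.0, 684.9),
    decrease_per_capita = c(2.6, 5.1, 9.8, 10.2, 10.5),
    sugar_decrease = c(0.8, 1.6, 3.2, 3.1, 3.3),
    energy_decrease = c(13.7, 26.2, 54.0, 52.4, 54.9)
  )
}

#' Tax pass-through assumptions
#'
#' The excise applies to the ex-factory price. A 100% pass-through of the tax
#' to the factory price corresponds to roughly a 50% pass-through of the tax
#' amount to the retail price, which is the default used for specific-tax
#' price computations.
#'
#' @param factory_rate Fraction of the tax passed to the factory price.
#' @param retail_rate Fraction of the tax amount reaching the retail price.
#' @return A named list with class `ssb_pass_through`.
#' @export
pass_through <- function(factory_rate = 1.0, retail_rate = 0.5) {
  stopifnot(is.numeric(factory_rate), is.numeric(retail_rate))
  if (factory_rate < 0 || factory_rate > 1.5 || retail_rate < 0 || retail_rate > 1.5) {
    rlang::abort("pass-through rates must lie in [0, 1.5]")
  }
  structure(
    list(factory_rate = factory_rate, retail_rate = retail_rate),
    class = "ssb_pass_through"
  )
}

#' Retail price increase implied by a tax scenario
#'
#' Converts a tax design into the fractional retail price increase for a
#' beverage category. When the scenario carries an `avg_price_increase`
#' override (the shipped scenarios do, taken from the external tax-incidence
#' model), that value is returned. Otherwise specific taxes are converted
#' using the retail pass-through and the category's retail price:
#' volumetric taxes add `rate * retail_rate / price` and sugar-based taxes
#' add `rate * (sugar_density * 10) * retail_rate / price` (density in
#' g/100 ml, so `density * 10` is grams of sugar per litre). Ad valorem
#' scenarios without an override cannot be priced here because the factory
#' price basis is external to this model.
#'
#' @param scenario A one-row tibble or list with `tax_type`, `rate` and
#'   optionally `avg_price_increase`.
#' @param category A one-row tibble or list with `retail_price_vnd_per_litre`
#'   and `sugar_density_g_per_100ml`; required when no override is present.
#' @param pass_through A [pass_through()] object.
#' @return The fractional retail price increase.
#' @export
#' @examples
#' retail_price_increase(list(tax_type = "specific_volume", rate = 7000),
#'   category = list(retail_price_vnd_per_litre = 17500))
retail_price_increase <- function(scenario, category = NULL,
                                  pass_through = ssbtax::pass_through()) {
  tax_type <- scenario$tax_type
  rate <- scenario$rate
  if (is.null(tax_type) || !tax_type %in% c("ad_valorem", "specific_volume", "specific_sugar")) {
    rlang::abort(paste0("unknown tax_type: ", format(tax_type)))
  }
  if (rate < 0) rlang::abort("tax rate must be >= 0")
  override <- scenario$avg_price_increase
  if (!is.null(override) && length(override) == 1 && !is.na(override)) {
    if (override < 0 || override > 1) {
      rlang::abort("avg_price_increase override must lie in [0, 1]")
    }
    return(override)
  }
  if (rate == 0) return(0)
  if (tax_type == "ad_valorem") {
    rlang::abort(paste0(
      "ad valorem scenarios need an avg_price_increase override: ",
      "the factory-price basis is not part of this model"
    ))
  }
  if (is.null(category) || is.null(category$retail_price_vnd_per_litre)) {
    rlang::abort("specific-tax price computation needs a category with a retail price")
  }
  price <- category$retail_price_vnd_per_litre
  if (any(is.na(price)) || any(price <= 0)) {
    rlang::abort("retail price must be > 0")
  }
  if (tax_type == "specific_volume") {
    return(rate * pass_through$retail_rate / price)
  }
  # specific_sugar: rate is VND per gram of sugar contained, per litre
  density <- category$sugar_density_g_per_100ml
  if (is.null(density) || any(is.na(density))) {
    rlang::abort("sugar-based tax needs the category sugar density")
  }
  rate * (density * 10) * pass_through$retail_rate / price
}

#' Consumption response to a price increase
#'
#' Applies the own-price elasticity of demand as a linear point-elasticity
#' approximation: the change in volume is `elasticity * price_increase *
#' baseline_volume`. With the default elasticity of -1.14, a 1% price rise
#' reduces consumption by 1.14%. The result is negative for a price increase
#' (a consumption decrease) and scales linearly in both arguments.
#'
#' @param price_increase Fractional retail price increase (vectorised).
#' @param elasticity Own-price elasticity (dimensionless, negative).
#' @param baseline_volume Baseline consumption, million litres/year.
#' @return Change in consumption, million litres/year (negative = decrease).
#' @export
#' @examples
#' consumption_change(0.05, -1.14, 3005.3)
consumption_change <- function(price_increase, elasticity = -1.14,
                               baseline_volume) {
  stopifnot(is.numeric(price_increase), is.numeric(elasticity), is.numeric(baseline_volume))
  if (any(elasticity >= 0)) rlang::abort("own-price elasticity must be negative")
  if (any(baseline_volume < 0)) rlang::abort("baseline volume must be >= 0")
  elasticity * price_increase * baseline_volume
}

#' Calibrate the aggregate SSB market from one published scenario
#'
#' The proprietary market-volume database behind the baseline consumption is
#' not public, but the published scenario-1 impacts pin down the aggregate
#' market under the linear elasticity model. Inverting the 10% ad-valorem
#' scenario (5% price rise, elasticity -1.14, total decrease 171.3 million
#' litres/year, per-capita decrease 2.6 litres/year, sugar decrease 0.8
#' g/day) yields the aggregate baseline volume, the implied population, and
#' the consumption-weighted mean sugar density used for all scenarios.
#'
#' @param decrease_s1 Published total consumption decrease in the calibration
#'   scenario, million litres/year (positive magnitude).
#' @param price_increase_s1 Fractional price increase in that scenario.
#' @param elasticity Own-price elasticity used in the calibration.
#' @param per_capita_decrease_s1 Published per-capita decrease, litres/person/year.
#' @param sugar_decrease_s1 Published sugar decrease, g/person/day.
#' @return A list of class `ssb_market` with `baseline_volume` (million
#'   litres/year), `population` (persons) and `sugar_density` (g/100 ml).
#' @export
#' @examples
#' calibrate_market()
calibrate_market <- function(decrease_s1 = 171.3, price_increase_s1 = 0.05,
                             elasticity = -1.14,
                             per_capita_decrease_s1 = 2.6,
                             sugar_decrease_s1 = 0.8) {
  inputs <- c(decrease_s1, price_increase_s1, abs(elasticity),
              per_capita_decrease_s1, sugar_decrease_s1)
  if (any(!is.finite(inputs)) || any(inputs == 0)) {
    rlang::abort("market calibration needs non-zero decrease, price increase, elasticity, per-capita and sugar inputs")
  }
  baseline_volume <- decrease_s1 / (price_increase_s1 * abs(elasticity))
  population <- decrease_s1 * 1e6 / per_capita_decrease_s1
  daily_ml <- per_capita_decrease_s1 * 1000 / 365
  sugar_density <- sugar_decrease_s1 / daily_ml * 100
  structure(
    list(
      baseline_volume = baseline_volume,
      population = population,
      sugar_density = sugar_density
    ),
    class = "ssb_market"
  )
}

#' Sugar change implied by a volume change
#'
#' Multiplies a per-capita daily volume change by the sugar density. Given a
#' vector of category densities (with per-category volume changes), returns
#' the sum over categories, i.e. the net change in sugar consumed.
#'
#' @param dvolume Volume change, ml/person/day (vector allowed).
#' @param sugar_density Sugar density, g/100 ml (scalar or per-category vector).
#' @return Sugar change, g/person/day. Scalar when `sugar_density` has
#'   length > 1 (category sum), elementwise otherwise.
#' @export
#' @examples
#' sugar_change(100, 16)
sugar_change <- function(dvolume, sugar_density) {
  if (any(sugar_density < 0)) rlang::abort("sugar density must be >= 0")
  x <- dvolume * sugar_density / 100
  if (length(sugar_density) > 1L) sum(x) else x
}

#' Energy change implied by a sugar change
#'
#' One gram of sugar provides 4 kcal, i.e. 16.7 kJ.
#'
#' @param dsugar Sugar change, g/person/day.
#' @param kj_per_gram Energy density of sugar, kJ/g.
#' @return Energy change, kJ/person/day.
#' @export
#' @examples
#' energy_change(1)
energy_change <- function(dsugar, kj_per_gram = 16.7) {
  kj_per_gram * dsugar
}

#' Per-scenario market impacts of SSB taxation
#'
#' Runs the tax-to-price and price-to-consumption steps for every scenario and
#' converts the volume response into per-capita sugar and energy-intake
#' changes: retail price increase (scenario override or computed from a price
#' table), linear elasticity volume response on the aggregate market,
#' per-capita volume via the calibrated population, sugar via the mean sugar
#' density, and energy at 16.7 kJ per gram of sugar. All deltas are negative
#' for a price increase (decreases).
#'
#' @param scenarios A scenario tibble, as from [tax_scenarios()].
#' @param market An `ssb_market` calibration, as from [calibrate_market()].
#' @param elasticity Own-price elasticity applied to the demand response.
#' @param categories Optional category price table for scenarios without a
#'   price-increase override.
#' @param pass_through A [pass_through()] object for specific-tax pricing.
#' @return A tibble of class `ssb_market_impact` with one row per scenario:
#'   `scenario_id`, `tax_type`, `rate`, `price_increase`, `dvolume_total`
#'   (million litres/year), `dvolume_per_capita` (litres/person/year),
#'   `dsugar_per_capita` (g/person/day), `denergy_per_capita` (kJ/person/day).
#' @export
#' @examples
#' market_impact()
market_impact <- function(scenarios = tax_scenarios(),
                          market = calibrate_market(),
                          elasticity = -1.14,
                          categories = NULL,
                          pass_through = ssbtax::pass_through()) {
  if (nrow(scenarios) == 0) rlang::abort("scenario list is empty")
  out <- purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    p <- retail_price_increase(sc, category = categories, pass_through = pass_through)
    dvol_total <- consumption_change(p, elasticity, market$baseline_volume)
    dvol_pc <- dvol_total * 1e6 / market$population
    dvol_pc_ml_day <- dvol_pc * 1000 / 365
    dsugar <- sugar_change(dvol_pc_ml_day, market$sugar_density)
    tibble::tibble(
      scenario_id = sc$id,
      tax_type = sc$tax_type,
      rate = sc$rate,
      price_increase = p,
      dvolume_total = dvol_total,
      dvolume_per_capita = dvol_pc,
      dsugar_per_capita = dsugar,
      denergy_per_capita = energy_change(dsugar)
    )
  })
  attr(out, "elasticity") <- elasticity
  attr(out, "market") <- market
  class(out) <- c("ssb_market_impact", class(out))
  out
}
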