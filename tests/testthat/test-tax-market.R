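test_that("retail price increase handles the three tax designs", {
  # shipped scenarios return their average-price-increase overrides
  sc <- tax_scenarios()
  expect_equal(retail_price_increase(sc[1, ]), 0.05)
  expect_equal(retail_price_increase(sc[5, ]), 0.20)

  # specific taxes computed from a retail price at 50% retail pass-through
  cat17500 <- list(retail_price_vnd_per_litre = 17500,
                   sugar_density_g_per_100ml = 11)
  expect_equal(
    retail_price_increase(list(tax_type = "specific_volume", rate = 7000),
                          cat17500),
    7000 * 0.5 / 17500
  )
  # sugar-based: rate applies per gram of sugar contained per litre
  expect_equal(
    retail_price_increase(list(tax_type = "specific_sugar", rate = 60),
                          cat17500),
    60 * 110 * 0.5 / 17500
  )
  # at the same retail price, the 60 VND/g sugar tax on an 11 g/100ml
  # product lands close to the 7,000 VND/L volumetric design (19% vs 20%)
  p_sugar <- retail_price_increase(list(tax_type = "specific_sugar", rate = 60), cat17500)
  p_vol <- retail_price_increase(list(tax_type = "specific_volume", rate = 7000), cat17500)
  expect_lt(abs(p_sugar / p_vol - 0.19 / 0.20), 0.06)

  # no tax, no price change
  expect_equal(retail_price_increase(list(tax_type = "ad_valorem", rate = 0)), 0)
  expect_equal(retail_price_increase(list(tax_type = "specific_volume", rate = 0)), 0)

  expect_error(retail_price_increase(list(tax_type = "flat_fee", rate = 1)),
               "unknown tax_type")
  expect_error(
    retail_price_increase(list(tax_type = "specific_volume", rate = 100),
                          list(retail_price_vnd_per_litre = 0)),
    "price"
  )
  expect_error(
    retail_price_increase(list(tax_type = "ad_valorem", rate = 0.1)),
    "override"
  )
})

test_that("consumption response is linear in price increase and volume", {
  expect_equal(consumption_change(0.05, -1.14, 3005.3), -171.3, tolerance = 1e-4)
  expect_equal(consumption_change(0, -1.14, 5000), 0)
  # 4x the price increase gives exactly 4x the response
  base <- consumption_change(0.05, -1.14, 3005.3)
  for (k in c(0, 0.5, 2, 4, 10)) {
    expect_equal(consumption_change(0.05 * k, -1.14, 3005.3), k * base)
  }
  expect_equal(consumption_change(0.20, -1.14, 3005.3), -685.2, tolerance = 1e-3)
  expect_error(consumption_change(0.05, 1.14, 100), "negative")
  expect_error(consumption_change(0.05, -1.14, -5), ">= 0")
})

test_that("market calibration inverts the published calibration scenario", {
  m <- calibrate_market()
  expect_s3_class(m, "ssb_market")
  expect_equal(m$baseline_volume, 171.3 / 0.057, tolerance = 1e-10)
  expect_equal(m$baseline_volume, 3005.3, tolerance = 1e-4)
  expect_equal(m$population, 171.3e6 / 2.6)
  expect_equal(m$sugar_density, 0.8 / (2.6 * 1000 / 365) * 100, tolerance = 1e-10)
  expect_equal(m$sugar_density, 11.23, tolerance = 1e-3)
  expect_error(calibrate_market(price_increase_s1 = 0), "calibration")
  expect_error(calibrate_market(elasticity = 0), "calibration")
})

test_that("calibration round-trips the published consumption decrease", {
  m <- calibrate_market()
  dec <- -consumption_change(0.05, -1.14, m$baseline_volume)
  expect_equal(dec, 171.3, tolerance = 1e-12)
})

test_that("sugar and energy accounting follow the densities", {
  expect_equal(sugar_change(100, 16), 16)
  expect_equal(sugar_change(0, 9), 0)
  expect_equal(sugar_change(7.12, 11.2), 0.797, tolerance = 1e-2)
  # category vector sums over categories
  expect_equal(sugar_change(c(10, 20), c(11, 16)), 10 * 0.11 + 20 * 0.16)
  expect_error(sugar_change(10, -1), ">= 0")

  expect_equal(energy_change(1), 16.7)
  expect_equal(energy_change(0), 0)
  expect_equal(energy_change(3.3), 55.11)
  # monotone non-decreasing in both volume and density
  grid <- expand.grid(v = seq(0, 100, by = 20), d = seq(0, 16, by = 4))
  e <- energy_change(sugar_change(grid$v, 1) * grid$d)
  expect_true(all(diff(sort(e)) >= 0))
  for (d in c(4, 8, 16)) {
    expect_true(all(diff(energy_change(sugar_change(seq(0, 50, 10), d))) >= 0))
  }
})

test_that("market impact table is sign-coherent and internally consistent", {
  imp <- market_impact()
  expect_s3_class(imp, "ssb_market_impact")
  expect_equal(nrow(imp), 5)
  # price increase > 0 => every delta is a decrease
  expect_true(all(imp$dvolume_total < 0))
  expect_true(all(imp$dvolume_per_capita < 0))
  expect_true(all(imp$dsugar_per_capita < 0))
  expect_true(all(imp$denergy_per_capita < 0))
  # energy is exactly 16.7 x sugar
  expect_equal(imp$denergy_per_capita, 16.7 * imp$dsugar_per_capita)
  # scenario 1 reproduces the calibration decrease to 4 significant figures
  expect_equal(-imp$dvolume_total[1], 171.3, tolerance = 5e-5)
  # the 40% ad valorem scenario is exactly 4x the 10% scenario
  expect_equal(imp$dvolume_total[5], 4 * imp$dvolume_total[1])
  expect_error(market_impact(tax_scenarios()[0, ]), "empty")
})

test_that("published impact table carries the five scenarios", {
  pub <- published_market_impacts()
  expect_equal(nrow(pub), 5)
  expect_equal(pub$energy_decrease[1], 13.7)
})

test_that("category tables validate on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ssb_categories(), path)
  cats <- read_categories(path)
  expect_equal(cats$sugar_density_g_per_100ml, c(11, 7, 9, 16))
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(ssb_categories(), -"sugar_density_g_per_100ml"), bad)
  expect_error(read_categories(bad), "missing column")
})

test_that("pass-through rates are validated", {
  pt <- pass_through()
  expect_equal(pt$retail_rate, 0.5)
  expect_error(pass_through(retail_rate = 2), "0, 1.5")
})
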