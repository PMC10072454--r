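test_that("beta fit reproduces the mean exactly and the interval closely", {
  fit <- fit_beta_from_ci(0.27, 0.23, 0.30)
  expect_equal(fit$mean, 0.27, tolerance = 1e-9)
  # the published interval is asymmetric the opposite way from a beta with
  # this mean, so the least-squares fit carries a small residual
  expect_lt(abs(fit$ci[1] - 0.23), 0.01)
  expect_lt(abs(fit$ci[2] - 0.30), 0.01)
  expect_lt(fit$residual, 0.015)

  # a vanishingly narrow interval drives the variance to zero
  tight <- fit_beta_from_ci(0.27, 0.2699, 0.2701)
  v <- with(tight, shape1 * shape2 / ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  expect_lt(v, 1e-6)

  expect_error(fit_beta_from_ci(0.27, 0.28, 0.30), "bracket")
  expect_error(fit_beta_from_ci(0.27, 0.23, 0.26), "bracket")
  expect_error(fit_beta_from_ci(1.2, 0.2, 0.3), "\\(0, 1\\)")

  mom <- fit_beta_from_ci(0.27, 0.23, 0.30, method = "moments")
  sd_mom <- sqrt(with(mom, shape1 * shape2 /
                        ((shape1 + shape2)^2 * (shape1 + shape2 + 1))))
  expect_equal(sd_mom, (0.30 - 0.23) / 3.92, tolerance = 1e-6)
})

test_that("degenerate distributions collapse the MC onto the deterministic chain", {
  cohort <- default_test_cohort(n = 2000, seed = 55)
  imp <- market_impact()
  cfg <- mc_config(iterations = 5, seed = 9, model = "model1",
                   cf_sd = c(male = 0, female = 0))
  mc <- run_mc(imp, cohort, cfg)
  det <- attr(mc, "deterministic")
  joined <- dplyr::left_join(tibble::as_tibble(mc), det,
                             by = c("scenario_id", "output", "stratum"))
  expect_identical(joined$mean, joined$value)
  expect_true(all(joined$sd == 0))
})

test_that("the deterministic MC chain agrees with the table pipeline", {
  cohort <- default_test_cohort(n = 2000, seed = 55)
  imp <- market_impact()
  mc <- run_mc(imp, cohort, mc_config(iterations = 1, seed = 1,
                                      cf_sd = c(male = 0, female = 0)))
  det <- attr(mc, "deterministic")
  # same quantities via the tidyverse table route
  wc <- weight_change_table(imp)
  adults <- wc[wc$group %in% c("male", "female") & wc$scenario_id == "s3", ]
  dbmi <- mean_bmi_reduction(
    cohort, stats::setNames(adults$weight_reduction_kg, adults$group))
  expect_equal(
    det$value[det$scenario_id == "s3" & det$output == "bmi_reduction" &
                det$stratum == "both"],
    dbmi$dbmi[dbmi$stratum == "both"]
  )
  burden <- burden_table(dplyr::mutate(dbmi, scenario_id = "s3", .before = 1))
  expect_equal(
    det$value[det$scenario_id == "s3" & det$output == "avoided_cases" &
                det$stratum == "both"],
    burden$avoided_cases[burden$stratum == "both"]
  )
})

test_that("MC is seed-deterministic and converges to the deterministic value", {
  cohort <- default_test_cohort(n = 2000, seed = 55)
  imp <- market_impact()
  cfg <- mc_config(iterations = 2000, seed = 99, model = "model2")
  mc_a <- run_mc(imp, cohort, cfg)
  mc_b <- run_mc(imp, cohort, cfg)
  expect_identical(tibble::as_tibble(mc_a), tibble::as_tibble(mc_b))

  # |mean - deterministic| < 4 * SD / sqrt(iterations) for every output,
  # with an allowance for the integer rounding of avoided cases (which
  # propagates into the cost figures)
  joined <- tidy(mc_a)
  nonzero <- joined[joined$sd > 0, ]
  blend <- 0.5 * 7656142
  rounding <- c(avoided_cases = 0.51, cost_bn_vnd = 1.02 * blend / 1e9,
                cost_m_usd = 1.02 * blend / 22370 / 1e6)
  slack <- unname(rounding[nonzero$output])
  slack[is.na(slack)] <- 0
  expect_true(all(
    abs(nonzero$mean - nonzero$deterministic) <
      4 * nonzero$sd / sqrt(cfg$iterations) + slack
  ))
})

test_that("model 2 adds diabetes-parameter variance on top of model 1", {
  cohort <- default_test_cohort(n = 2000, seed = 55)
  imp <- market_impact()
  m1 <- run_mc(imp, cohort, mc_config(iterations = 1500, seed = 7, model = "model1"))
  m2 <- run_mc(imp, cohort, mc_config(iterations = 1500, seed = 7, model = "model2"))
  t1 <- tibble::as_tibble(m1)
  t2 <- tibble::as_tibble(m2)
  # identical weight-change draws => identical weight outputs
  w1 <- t1[t1$output == "weight_change", ]
  w2 <- t2[t2$output == "weight_change", ]
  expect_identical(w1$mean, w2$mean)
  expect_identical(w1$sd, w2$sd)
  # diabetes outputs gain variance
  a1 <- t1[t1$output == "avoided_cases", ]
  a2 <- t2[t2$output == "avoided_cases", ]
  expect_true(all(a2$sd >= a1$sd))
})

test_that("one-way elasticity SA scales the linear chain exactly", {
  sa <- one_way_sa(c(-1.14, -1.0, -0.8))
  base <- sa[sa$elasticity == -1.14, ]
  # the base elasticity row equals the base analysis
  imp <- market_impact()
  expect_equal(base$dvolume_total, imp$dvolume_total)
  for (e in c(-1.0, -0.8)) {
    sub <- sa[sa$elasticity == e, ]
    expect_equal(sub$dvolume_total, base$dvolume_total * e / -1.14)
    expect_equal(sub$denergy_per_capita, base$denergy_per_capita * e / -1.14)
  }
  # scenario 1 at elasticity -1.0: 171.3 / 1.14
  expect_equal(-sa$dvolume_total[sa$elasticity == -1.0 & sa$scenario_id == "s1"],
               150.3, tolerance = 1e-3)
  expect_error(one_way_sa(c(-1, 0.5)), "negative")
})

test_that("SA appends downstream outputs when a cohort is supplied", {
  cohort <- default_test_cohort(n = 1000, seed = 3)
  sa <- one_way_sa(c(-1.14, -0.8), cohort = cohort)
  expect_true(all(c("weight_change_male", "bmi_reduction_both",
                    "avoided_cases") %in% names(sa)))
  base <- sa[sa$elasticity == -1.14, ]
  low <- sa[sa$elasticity == -0.8, ]
  expect_equal(low$weight_change_male, base$weight_change_male * 0.8 / 1.14)
})
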