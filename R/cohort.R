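#' Per-sex BMI calibration targets for the synthetic cohort
#'
#' Baseline weighted prevalences of overweight (23 <= BMI < 25), obesity
#' class I (25 <= BMI < 30) and obesity class II (BMI >= 30) by sex, plus the
#' per-sex mean BMI the generator calibrates to. With the default 50/50 sex
#' split these imply overall prevalences of 17.9%, 13.6% and 3.4% and an
#' overall mean BMI of 21.96 kg/m^2.
#'
#' @return A tibble with columns `sex`, `overweight`, `obesity1`, `obesity2`,
#'   `mean_bmi`.
#' @export
cohort_targets <- function() {
  tibble::tibble(
    sex = c("male", "female"),
    overweight = c(0.192, 0.165),
    obesity1 = c(0.131, 0.142),
    obesity2 = c(0.017, 0.051),
    mean_bmi = c(21.98, 21.94)
  )
}

#' Specification for the synthetic adult cohort
#'
#' Describes the cohort the generator emulates: a nationally sampled adult
#' population aged 18-69 with survey weights, whose weighted BMI class
#' prevalences and mean BMI match the published baseline. The default sample
#' size mirrors the source survey (3,856 respondents); calibration checks use
#' larger `n` to shrink sampling noise.
#'
#' @param n Number of adults to generate (>= 100).
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @param sex_split Fraction male.
#' @param targets Per-sex calibration targets, as [cohort_targets()].
#' @param height_mean Named vector of mean heights (m) by sex. These are
#'   synthetic plausible values for a Vietnamese adult population, not survey
#'   estimates; heights are auxiliary because calibration is on BMI.
#' @param height_sd Height standard deviation (m).
#' @param weight_shape Gamma shape for the i.i.d. survey weights (mean 1).
#' @return A list of class `ssb_cohort_spec`.
#' @export
cohort_spec <- function(n = 3856, seed = 1L, sex_split = 0.5,
                        targets = cohort_targets(),
                        height_mean = c(male = 1.62, female = 1.53),
                        height_sd = 0.06,
                        weight_shape = 10) {
  if (n < 100) rlang::abort("cohort size must be at least 100")
  if (sex_split < 0 || sex_split > 1) rlang::abort("sex_split must lie in [0, 1]")
  prev <- as.matrix(targets[, c("overweight", "obesity1", "obesity2")])
  if (any(prev < 0) || any(prev > 1) || any(rowSums(prev) >= 1)) {
    rlang::abort("class prevalences must lie in [0, 1] and sum to < 1 per sex")
  }
  if (height_sd <= 0 || weight_shape <= 0) {
    rlang::abort("height_sd and weight_shape must be > 0")
  }
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed), sex_split = sex_split,
      targets = targets, height_mean = height_mean, height_sd = height_sd,
      weight_shape = weight_shape
    ),
    class = "ssb_cohort_spec"
  )
}

# Mean of a log-normal truncated to (lo, hi).
trunc_lnorm_mean <- function(mu, sigma, lo, hi) {
  mass <- stats::plnorm(hi, mu, sigma) - stats::plnorm(lo, mu, sigma)
  z_hi <- if (is.finite(hi)) (log(hi) - mu - sigma^2) / sigma else Inf
  z_lo <- if (lo > 0) (log(lo) - mu - sigma^2) / sigma else -Inf
  exp(mu + sigma^2 / 2) * (stats::pnorm(z_hi) - stats::pnorm(z_lo)) / mass
}

# Least-squares fit of a base log-normal to the three upper-tail
# probabilities P(BMI >= 23), P(BMI >= 25), P(BMI >= 30).
fit_base_lognormal <- function(p_ow, p_o1, p_o2) {
  tails <- c(p_ow + p_o1 + p_o2, p_o1 + p_o2, p_o2)
  cuts <- c(23, 25, 30)
  # closed-form init from the outer two tails
  z <- stats::qnorm(1 - tails[c(1, 3)])
  sigma0 <- (log(30) - log(23)) / (z[2] - z[1])
  mu0 <- log(23) - sigma0 * z[1]
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    sum((stats::plnorm(cuts, mu, sigma, lower.tail = FALSE) - tails)^2)
  }
  fit <- stats::optim(c(mu0, log(sigma0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), residual = fit$value)
}

# Location parameter of the below-23 log-normal component so that the
# overall mean BMI hits the target, given the upper-class mixture.
calibrate_below <- function(base, probs, target_mean) {
  class_means <- c(
    trunc_lnorm_mean(base$mu, base$sigma, 23, 25),
    trunc_lnorm_mean(base$mu, base$sigma, 25, 30),
    trunc_lnorm_mean(base$mu, base$sigma, 30, Inf)
  )
  p_below <- 1 - sum(probs)
  m_below <- (target_mean - sum(probs * class_means)) / p_below
  if (!is.finite(m_below) || m_below <= 12 || m_below >= 23) {
    rlang::abort(paste0(
      "infeasible cohort calibration: implied below-overweight mean BMI ",
      sprintf("%.2f", m_below),
      " is outside (12, 23); check target prevalences and mean_bmi"
    ))
  }
  f <- function(mu_b) trunc_lnorm_mean(mu_b, base$sigma, 0, 23) - m_below
  sol <- stats::uniroot(f, lower = log(10), upper = log(23) + 2,
                        tol = 1e-12)
  list(mu = sol$root, sigma = base$sigma, mean = m_below,
       class_means = class_means)
}

# Inverse-CDF draw from a log-normal truncated to (lo, hi).
rtrunc_lnorm <- function(n, mu, sigma, lo, hi) {
  u <- stats::runif(n, stats::plnorm(lo, mu, sigma), stats::plnorm(hi, mu, sigma))
  stats::qlnorm(u, mu, sigma)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic adult cohort
#'
#' Draws a survey-like adult microdata table (age, sex, weight, height,
#' survey weight) whose weighted BMI class shares match the calibration
#' targets. Per sex, BMI is drawn from a four-component mixture: class
#' membership (below / overweight / obesity I / obesity II) allocated by
#' deterministic largest-remainder counts matching the target shares, with
#' within-class BMI from a base log-normal -
#' least-squares fitted to the three target tail probabilities - truncated to
#' the class interval. The below-23 component keeps the fitted scale but its
#' location is root-found so the per-sex mean BMI hits its target. Heights
#' are truncated normal per sex, weight is `BMI * height^2`, and survey
#' weights are i.i.d. gamma with mean 1.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `ssb_cohort` with columns `id`, `age`, `sex`,
#'   `weight_kg`, `height_m`, `survey_weight`, carrying the per-sex
#'   calibration (fitted mixture parameters) as attribute `"calibration"`.
#' @export
#' @examples
#' cohort <- generate_adult_cohort(cohort_spec(n = 1000, seed = 7))
#' dplyr::count(cohort, sex)
generate_adult_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "ssb_cohort_spec"))
  set.seed(spec$seed)
  bounds <- c(23, 25, 30, Inf)
  sexes <- c("male", "female")
  n_male <- round(spec$n * spec$sex_split)
  n_by_sex <- c(male = n_male, female = spec$n - n_male)

  calibration <- list()
  rows <- purrr::map(sexes, function(sx) {
    tg <- spec$targets[spec$targets$sex == sx, ]
    if (nrow(tg) != 1) rlang::abort(paste0("targets must contain one row for sex ", sx))
    probs <- c(tg$overweight, tg$obesity1, tg$obesity2)
    base <- fit_base_lognormal(probs[1], probs[2], probs[3])
    below <- calibrate_below(base, probs, tg$mean_bmi)
    calibration[[sx]] <<- list(base = base, below = below, probs = probs)

    n <- n_by_sex[[sx]]
    if (n == 0) return(NULL)
    # deterministic largest-remainder allocation: class counts match the
    # target shares as closely as integer counts allow
    p4 <- c(1 - sum(probs), probs)
    counts <- floor(n * p4)
    short <- n - sum(counts)
    if (short > 0) {
      extra <- order(n * p4 - counts, decreasing = TRUE)[seq_len(short)]
      counts[extra] <- counts[extra] + 1
    }
    cls <- rep.int(1:4, counts)
    bmi_val <- numeric(n)
    idx <- cls == 1
    bmi_val[idx] <- rtrunc_lnorm(sum(idx), below$mu, below$sigma, 0, 23)
    for (k in 2:4) {
      idx <- cls == k
      bmi_val[idx] <- rtrunc_lnorm(sum(idx), base$mu, base$sigma,
                                   bounds[k - 1], bounds[k])
    }
    height <- rtrunc_norm(n, spec$height_mean[[sx]], spec$height_sd, 1.30, 1.95)
    tibble::tibble(
      age = sample(18:69, n, replace = TRUE),
      sex = sx,
      weight_kg = bmi_val * height^2,
      height_m = height,
      survey_weight = stats::rgamma(n, shape = spec$weight_shape,
                                    rate = spec$weight_shape)
    )
  })
  cohort <- dplyr::bind_rows(rows)
  cohort <- dplyr::mutate(cohort, id = dplyr::row_number(), .before = 1)
  attr(cohort, "calibration") <- calibration
  attr(cohort, "spec") <- spec
  class(cohort) <- c("ssb_cohort", class(cohort))
  cohort
}

#' Child population age weights
#'
#' Single-year age shares for children aged 2-17, used to average child
#' weight changes over the age structure. `"uniform"` gives each of the 16
#' ages a share of 1/16 (the census age structure behind the published child
#' averages is not public; uniform weights reproduce them to the printed
#' precision). `"custom"` normalises a user table; ages not listed get zero.
#'
#' @param mode `"uniform"` or `"custom"`.
#' @param table For `"custom"`: a tibble with columns `age` and `weight`, or
#'   a numeric vector named by age.
#' @return A tibble with columns `age` (2-17) and `weight` summing to 1.
#' @export
#' @examples
#' child_age_weights()
child_age_weights <- function(mode = c("uniform", "custom"), table = NULL) {
  mode <- match.arg(mode)
  ages <- 2:17
  if (mode == "uniform") {
    return(tibble::tibble(age = ages, weight = rep(1 / 16, 16)))
  }
  if (is.null(table)) rlang::abort("custom age weights need a table")
  if (!is.data.frame(table)) {
    table <- tibble::tibble(age = as.numeric(names(table)),
                            weight = as.numeric(table))
  }
  if (any(!table$age %in% ages)) rlang::abort("custom ages must lie in 2-17")
  if (any(table$weight < 0)) rlang::abort("age weights must be >= 0")
  out <- tibble::tibble(age = ages) |>
    dplyr::left_join(table, by = "age") |>
    dplyr::mutate(weight = dplyr::coalesce(.data$weight, 0))
  if (sum(out$weight) <= 0) rlang::abort("age weights must have positive mass")
  out$weight <- out$weight / sum(out$weight)
  out
}

cohort_columns <- c("id", "age", "sex", "weight_kg", "height_m", "survey_weight")

validate_cohort <- function(cohort, adult = TRUE) {
  missing <- setdiff(cohort_columns, names(cohort))
  if (length(missing) > 0) {
    rlang::abort(paste0("cohort is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(cohort) == 0) rlang::abort("cohort is empty")
  bad <- which(
    !(cohort$weight_kg > 10 & cohort$weight_kg < 250) |
      !(cohort$survey_weight > 0) |
      !(cohort$sex %in% c("male", "female")) |
      (adult & !(cohort$height_m > 1.2 & cohort$height_m < 2.1))
  )
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "invalid anthropometry in cohort row(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else ""
    ))
  }
  invisible(cohort)
}

#' Write / read a cohort as CSV
#'
#' Lossless CSV round-trip of the cohort microdata, with schema and
#' anthropometry validation on read.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the validated cohort tibble;
#'   `write_cohort()` returns the input invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort[, cohort_columns], path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_integer(), age = readr::col_double(),
      sex = readr::col_character(), weight_kg = readr::col_double(),
      height_m = readr::col_double(), survey_weight = readr::col_double()
    )
  )
  validate_cohort(cohort)
  class(cohort) <- c("ssb_cohort", class(cohort))
  cohort
}
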