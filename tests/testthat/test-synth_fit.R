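test_that("predictor matrices are standardized and prune constant columns", {
  study <- make_toy_study()
  pm <- build_predictors(study, "R2", c("R1", "R3"), 2003L)
  # pre-period of R2 is 2001-2002 with losses (2, 4): mean 3 before scaling
  raw_pre <- pm$x_treated["pre_loss_mean"] * pm$scale$scale["pre_loss_mean"] +
    pm$scale$center["pre_loss_mean"]
  expect_equal(unname(raw_pre), 3)
  # standardized columns: mean 0, variance 1 over treated + donors
  Z <- cbind(pm$x_treated, pm$x_donors)
  expect_equal(unname(rowMeans(Z)), rep(0, nrow(Z)), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 1, var)), rep(1, nrow(Z)), tolerance = 1e-12)

  # a constant covariate is dropped with a warning, k reduced by one
  study2 <- make_toy_study()
  study2$covariates$slope <- 7
  expect_warning(pm2 <- build_predictors(study2, "R2", c("R1", "R3"), 2003L),
                 "slope")
  expect_equal(length(pm2$predictor_names), length(pm$predictor_names) - 1)

  expect_error(build_predictors(study, "R2", "R1", 2003L), "insufficient")
})

test_that("an exact clone in the donor pool drives the fit to zero error", {
  sim <- small_sim()
  study <- sim$study
  id <- treated_ids(study)[1]
  # clone the treated unit as a new donor: same outcomes and covariates
  clone_id <- "ZZ_clone"
  oc <- study$outcomes[study$outcomes$reserve_id == id, ]
  oc$reserve_id <- clone_id
  cv <- study$covariates[study$covariates$reserve_id == id, ]
  cv$reserve_id <- clone_id
  study$outcomes <- dplyr::bind_rows(study$outcomes, oc)
  study$covariates <- dplyr::bind_rows(study$covariates, cv)
  study$treatments <- dplyr::bind_rows(
    study$treatments,
    tibble::tibble(reserve_id = clone_id, intervention_year = NA_integer_,
                   excluded_reason = NA_character_))
  study$groups <- split(study$covariates$reserve_id, study$covariates$group)

  # few donors relative to predictors so the exact match is unique
  pool <- c(clone_id, donor_ids(sim$study)[1:4])
  fit <- fit_synthetic(study, id, pool, config = fast_cfg())
  expect_lt(fit$mspe_pre, 1e-6)
  expect_lt(max(abs(fit$effect_series)), 1e-2)
})

test_that("two-donor fits compose the convex interpolation of the inner problem", {
  # treated trajectory exactly halfway between two donors, identical covariates
  years <- 2001:2010
  mk <- function(id, slope) tibble::tibble(
    reserve_id = id, year = years, cumulative_loss_ha = slope * seq_along(years))
  outcomes <- dplyr::bind_rows(mk("T", 2), mk("A", 1), mk("B", 4))
  covariates <- tibble::tibble(
    reserve_id = c("T", "A", "B"), pop_density = 10, road_length = 5,
    precipitation = 1000, elevation = 100, slope = 5, aspect = 180,
    agb_baseline = 100, ppp = 1000, age = 10, travel_time = 100,
    area_ha = 1000, group = "G1")
  treatments <- tibble::tibble(reserve_id = c("T", "A", "B"),
                               intervention_year = c(2006L, NA, NA))
  suppressWarnings(study <- study_dataset(outcomes, covariates, treatments))
  suppressWarnings(
    fit <- fit_synthetic(study, "T", c("A", "B"), config = fast_cfg()))
  # w = (2/3, 1/3) on (A, B) reproduces the treated series exactly
  expect_equal(unname(fit$weights$w[c("A", "B")]), c(2 / 3, 1 / 3),
               tolerance = 1e-6)
  expect_equal(fit$counterfactual, fit$observed, tolerance = 1e-6)
})

test_that("counterfactuals stay inside the donor envelope and improve on uniform v", {
  sim <- small_sim()
  study <- sim$study
  for (id in treated_ids(study)) {
    fit <- fit_synthetic(study, id, config = fast_cfg())
    Y0 <- forestsynth:::outcome_matrix(study, fit$donor_ids)
    expect_true(all(fit$counterfactual >= apply(Y0, 1, min) - 1e-8))
    expect_true(all(fit$counterfactual <= apply(Y0, 1, max) + 1e-8))
    expect_true(all(fit$weights$w >= 0))
    expect_equal(sum(fit$weights$w), 1, tolerance = 1e-8)
    expect_equal(sum(fit$weights$v), 1, tolerance = 1e-8)
    expect_equal(fit$effect_final, fit$effect_series[length(fit$effect_series)])

    # monotone improvement over the uniform-v starting point
    pm <- build_predictors(study, id, fit$donor_ids, fit$intervention_year)
    k <- length(pm$x_treated)
    w_u <- inner_weights(pm, rep(1 / k, k))$w
    yrs <- fit$years
    pre <- yrs < fit$intervention_year
    y1 <- fit$observed
    cf_u <- drop(Y0 %*% w_u)
    expect_lte(fit$mspe_pre, mean((y1[pre] - cf_u[pre])^2) + 1e-9)
  }
})

test_that("rescaling all outcomes rescales effects linearly and MSPEs quadratically", {
  sim <- small_sim()
  study <- sim$study
  id <- treated_ids(study)[1]
  fit1 <- fit_synthetic(study, id, config = fast_cfg())
  cc <- 3.7
  study2 <- study
  study2$outcomes$cumulative_loss_ha <- cc * study2$outcomes$cumulative_loss_ha
  fit2 <- fit_synthetic(study2, id, config = fast_cfg())
  expect_equal(fit2$effect_final, cc * fit1$effect_final, tolerance = 1e-4)
  expect_equal(fit2$mspe_pre, cc^2 * fit1$mspe_pre, tolerance = 1e-4)
  expect_equal(fit2$mspe_post, cc^2 * fit1$mspe_post, tolerance = 1e-4)
})

test_that("donor-pool and pre-period guards fire", {
  sim <- small_sim()
  study <- sim$study
  id <- treated_ids(study)[1]
  expect_error(fit_synthetic(study, id, donor_ids(study)[1:5]),
               "more than 20")
  expect_error(
    fit_synthetic(study, id, intervention_year = 2003L,
                  config = fast_cfg(min_pre_years = 5)),
    "pre-intervention period")
})

test_that("fits serialize to JSON with small weights omitted", {
  sim <- small_sim()
  fit <- fit_synthetic(sim$study, treated_ids(sim$study)[1],
                       config = fast_cfg())
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$treated_id, fit$treated_id)
  expect_true(all(unlist(js$donor_weights) >= 1e-4))
  expect_equal(js$mspe_pre, fit$mspe_pre, tolerance = 1e-12)
})
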