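test_that("area trimming keeps donors at or above the threshold, monotonically", {
  study <- make_toy_study()
  # treated R2 has area 2000; rescale donors to 50/100/400 vs treated 1000
  study$covariates$area_ha <- c(50, 1000, 100)
  study$outcomes <- dplyr::bind_rows(
    study$outcomes,
    tibble::tibble(reserve_id = "R4", year = 2001:2005,
                   cumulative_loss_ha = 1:5))
  study$covariates <- dplyr::bind_rows(
    study$covariates,
    dplyr::mutate(study$covariates[1, ], reserve_id = "R4", area_ha = 400))
  study$treatments <- dplyr::bind_rows(
    study$treatments,
    tibble::tibble(reserve_id = "R4", intervention_year = NA_integer_,
                   excluded_reason = NA_character_))
  study$groups <- split(study$covariates$reserve_id, study$covariates$group)

  expect_setequal(trim_donor_pool(study, "R2", 0.1), c("R3", "R4"))  # 100 in (>=)
  expect_setequal(trim_donor_pool(study, "R2", 0.25), "R4")
  expect_setequal(trim_donor_pool(study, "R2", 0), c("R1", "R3", "R4"))

  # monotone: larger factor => nested pool
  sim <- small_sim()
  id <- treated_ids(sim$study)[1]
  fs <- sort(runif(6))
  pools <- lapply(fs, function(f) trim_donor_pool(sim$study, id, f))
  for (i in seq_len(length(fs) - 1)) {
    expect_true(all(pools[[i + 1]] %in% pools[[i]]))
  }
})

test_that("concordance scores direction, magnitude band and significance", {
  full <- structure(list(treated_id = "X", effect_final = 100,
                         intervention_year = 2007L), class = "synth_fit")
  mk <- function(eff) structure(list(treated_id = "X", effect_final = eff),
                                class = "synth_fit")
  v <- concordance(full, 0.02, list(
    list(factor = 0.1, fit = mk(115), p_value = 0.03, n_donors = 30),
    list(factor = 0.25, fit = mk(-10), p_value = 0.03, n_donors = 30),
    list(factor = 0.5, fit = mk(121), p_value = 0.2, n_donors = 30),
    list(factor = 0.9, fit = mk(90), p_value = 0.01, n_donors = 15)))
  r <- v$trim_results
  expect_equal(r$direction_match, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(r$within_20pct, c(TRUE, FALSE, FALSE, TRUE))
  # <= 20 donors: significance not assessable rather than FALSE
  expect_equal(r$still_significant, c(TRUE, TRUE, FALSE, NA))

  # zero full effect: within_20pct is recorded FALSE, sign(0) matches only 0
  v0 <- concordance(structure(list(treated_id = "X", effect_final = 0),
                              class = "synth_fit"), 0.5,
                    list(list(factor = 0.1, fit = mk(5), p_value = 0.5,
                              n_donors = 30)))
  expect_false(v0$trim_results$direction_match)
  expect_false(v0$trim_results$within_20pct)
})

test_that("anticipation preconditions and skip rules hold", {
  sim <- small_sim()
  study <- sim$study
  id <- treated_ids(study)[1]
  expect_error(anticipation_check(study, id, pseudo_year = 2007L),
               "must precede")
  expect_error(anticipation_check(study, id, pseudo_year = 2010L),
               "must precede")
  # only one year before the pseudo-intervention: skipped, not excluded
  res <- NULL
  expect_warning(
    res <- anticipation_check(study, id, pseudo_year = 2002L,
                              config = fast_cfg()),
    "skipped")
  expect_false(res$excluded)
  expect_true(res$skipped)
  expect_true(is.na(res$p_value))
})

test_that("backdating detects built-in anticipation but spares clean reserves", {
  scfg <- fast_cfg()
  seeds <- 1:4
  p_var <- p_null <- numeric(length(seeds))
  excl <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- sim_config(n_groups = 1, donors_per_group = 40,
                      treated_per_group = 1, years = c(1998, 2014),
                      intervention_years = 2010, effect_rho = 0.7,
                      seed = seeds[i])
    sim <- simulate_study(cfg)
    variant <- make_anticipation_variant(sim$study, sim$truth, 2005)
    id <- treated_ids(sim$study)[1]
    chk_v <- suppressWarnings(
      anticipation_check(variant$study, id, 2005, config = scfg))
    chk_0 <- suppressWarnings(
      anticipation_check(sim$study, id, 2005, config = scfg))
    p_var[i] <- chk_v$p_value
    p_null[i] <- chk_0$p_value
    excl[i] <- chk_v$excluded
  }
  # power: the screen catches built-in anticipation in at least half the
  # replicates and always ranks the variant as more suspicious than the null
  expect_gte(sum(excl), 2)
  expect_lt(mean(p_var), mean(p_null))
  # specificity: clean reserves are never excluded here
  expect_true(all(p_null >= 0.05))
})

test_that("anticipation variants update the truth and reject bad pseudo-years", {
  cfg <- sim_config(n_groups = 1, donors_per_group = 21, treated_per_group = 1,
                    years = c(2001, 2014), intervention_years = 2010,
                    effect_rho = 0.4, seed = 9)
  sim <- simulate_study(cfg)
  expect_error(make_anticipation_variant(sim$study, sim$truth, 2010), "precede")

  v <- make_anticipation_variant(sim$study, sim$truth, 2005)
  expect_silent(validate_study(v$study))
  # effect now covers more years, so the injected truth must grow
  expect_gt(v$truth$treated$true_averted_final[1],
            sim$truth$treated$true_averted_final[1])
  avert <- v$truth$treated$averted_by_year[[1]]
  expect_true(all(avert[as.character(2001:2004)] == 0))
  expect_true(all(avert[as.character(2005:2014)] > 0))
})
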