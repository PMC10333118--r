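#' Anticipation (backdating) check
#'
#' Tests whether a reserve's loss trajectory already diverged from its donors
#' before the official intervention — e.g. in 2005, when the national tiger
#' conservation authority was constituted, two years before the first
#' gazettements. The pre-intervention period is split into a training window
#' (years before `pseudo_year`) and a testing window (`pseudo_year` up to,
#' but excluding, the true intervention year): the panel is truncated at the
#' last true pre-intervention year and a full synthetic-control + placebo
#' analysis is run with `pseudo_year` as the intervention. A significant
#' pseudo-effect (p < `alpha`) marks the reserve as excluded for anticipation.
#'
#' @inheritParams fit_synthetic
#' @param pseudo_year Backdated hypothetical intervention year (default 2005);
#'   must precede the true intervention year.
#' @param alpha Significance level for exclusion (default 0.05).
#' @return List with `p_value` (NA if skipped), `excluded`, `skipped`,
#'   `ensemble` (the placebo ensemble or NULL).
#' @export
anticipation_check <- function(study, treated_id, pseudo_year = 2005L,
                               donor_ids = NULL, config = synth_config(),
                               alpha = 0.05) {
  true_year <- intervention_year_of(study, treated_id)
  if (is.na(true_year)) stop("reserve is not treated", call. = FALSE)
  if (pseudo_year >= true_year) {
    stop("pseudo_year must precede the true intervention year", call. = FALSE)
  }
  if (is.null(donor_ids)) {
    donor_ids <- donor_ids(study, group = reserve_group(study, treated_id))
  }
  n_pre_pseudo <- pseudo_year - study$years[1]
  if (n_pre_pseudo < config$min_pre_years) {
    warning(sprintf("anticipation check skipped for %s: only %d year(s) before pseudo_year",
                    treated_id, n_pre_pseudo), call. = FALSE)
    return(list(p_value = NA_real_, excluded = FALSE, skipped = TRUE,
                ensemble = NULL))
  }
  sub <- truncate_panel(study, true_year - 1L)
  ens <- placebo_distribution(sub, treated_id, donor_ids,
                              intervention_year = pseudo_year, config = config)
  list(p_value = ens$p_value, excluded = ens$p_value < alpha, skipped = FALSE,
       ensemble = ens)
}

#' Area-based donor-pool trimming
#'
#' Returns the donors (within the treated reserve's landscape grouping by
#' default) whose area is at least `factor` times the treated reserve's area.
#' The study uses factors 0.1 (donors at least a tenth of the treated area)
#' and 0.25 (at least a quarter); the boundary is inclusive. Monotone:
#' a larger factor can only shrink the pool.
#'
#' @param study A `study_dataset`.
#' @param treated_id Treated reserve id.
#' @param factor Trim factor in `[0, 1]`.
#' @param donor_ids Candidate donors (defaults to the treated reserve's
#'   grouping).
#' @return Character vector of retained donor ids (possibly empty).
#' @export
trim_donor_pool <- function(study, treated_id, factor, donor_ids = NULL) {
  stopifnot(factor >= 0, factor <= 1)
  if (is.null(donor_ids)) {
    donor_ids <- donor_ids(study, group = reserve_group(study, treated_id))
  }
  areas <- study$covariates$area_ha[
    match(donor_ids, study$covariates$reserve_id)]
  a_treated <- study$covariates$area_ha[
    match(treated_id, study$covariates$reserve_id)]
  sort(donor_ids[areas >= factor * a_treated])
}

#' Concordance of trimmed refits with the full-pool result
#'
#' Scores each trimmed refit against the full-pool fit on three robustness
#' properties used in the study: same effect direction, effect magnitude
#' within +/-20% of the full-pool `effect_final` (hectares), and retained
#' placebo significance. When a trimmed pool has 20 or fewer donors the
#' significance column is reported as not assessable (`NA`) rather than
#' `FALSE`, because the placebo test cannot reach 0.05 there.
#'
#' @param full_fit `synth_fit` on the untrimmed pool.
#' @param full_p p-value of the untrimmed placebo test.
#' @param trimmed List of per-threshold results; each element a list with
#'   `factor`, `fit` (`synth_fit` or NULL if the pool was unusable),
#'   `p_value`, `n_donors`.
#' @param alpha Significance level (default 0.05).
#' @return A `robustness_verdict`: `treated_id`, `effect_full`, tibble
#'   `trim_results` with columns `factor`, `n_donors`, `effect_final`,
#'   `p_value`, `direction_match`, `within_20pct`, `still_significant`.
#' @export
concordance <- function(full_fit, full_p, trimmed, alpha = 0.05) {
  eff_full <- full_fit$effect_final
  rows <- purrr::map_dfr(trimmed, function(tr) {
    if (is.null(tr$fit)) {
      return(tibble::tibble(factor = tr$factor, n_donors = tr$n_donors,
                            effect_final = NA_real_, p_value = NA_real_,
                            direction_match = NA, within_20pct = NA,
                            still_significant = NA))
    }
    eff <- tr$fit$effect_final
    dir_match <- if (eff_full == 0) eff == 0 else sign(eff) == sign(eff_full)
    within <- if (eff_full == 0) FALSE else
      abs(eff - eff_full) <= 0.2 * abs(eff_full)
    sig <- if (tr$n_donors <= 20) NA else tr$p_value < alpha
    tibble::tibble(factor = tr$factor, n_donors = tr$n_donors,
                   effect_final = eff, p_value = tr$p_value,
                   direction_match = dir_match, within_20pct = within,
                   still_significant = sig)
  })
  structure(list(treated_id = full_fit$treated_id, effect_full = eff_full,
                 p_full = full_p, trim_results = rows),
            class = "robustness_verdict")
}

#' @export
print.robustness_verdict <- function(x, ...) {
  cat(sprintf("<robustness_verdict> %s (effect %.1f ha):\n", x$treated_id,
              x$effect_full))
  print(x$trim_results)
  invisible(x)
}

#' Run the full trimming battery for one reserve
#'
#' Convenience wrapper: refits the synthetic control and placebo test on each
#' trimmed donor pool and scores concordance against the full-pool result.
#'
#' @inheritParams fit_synthetic
#' @param full_fit,full_p Full-pool fit and p-value.
#' @param factors Trim factors (default `c(0.1, 0.25)`).
#' @param alpha Significance level.
#' @return A `robustness_verdict`.
#' @export
trimmed_refits <- function(study, treated_id, full_fit, full_p,
                           factors = c(0.1, 0.25), donor_ids = NULL,
                           config = synth_config(), alpha = 0.05) {
  if (is.null(donor_ids)) {
    donor_ids <- donor_ids(study, group = reserve_group(study, treated_id))
  }
  iy <- full_fit$intervention_year
  trimmed <- lapply(factors, function(f) {
    pool <- trim_donor_pool(study, treated_id, f, donor_ids)
    if (length(pool) < 2) {
      return(list(factor = f, fit = NULL, p_value = NA_real_,
                  n_donors = length(pool)))
    }
    cfg <- config
    cfg$allow_small_donor_pool <- TRUE
    fit <- fit_synthetic(study, treated_id, pool, iy, cfg)
    ens <- suppressWarnings(
      placebo_distribution(study, treated_id, pool, iy, cfg, treated_fit = fit))
    list(factor = f, fit = fit, p_value = ens$p_value, n_donors = length(pool))
  })
  concordance(full_fit, full_p, trimmed, alpha = alpha)
}
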