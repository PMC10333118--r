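#' Pipeline configuration
#'
#' Bundles all study-level constants: the 2007-2015 treatment window, the
#' more-than-20-placebo requirement, the 0.05 significance level, donor trim
#' factors of 0.1 and 0.25, 9,999 bootstrap iterations, the 2005 backdated
#' pseudo-intervention, and the carbon prices.
#'
#' @param window Inclusive intervention-year window (default `c(2007, 2015)`).
#' @param alpha Significance level (default 0.05).
#' @param trim_factors Donor trim factors (default `c(0.1, 0.25)`).
#' @param bootstrap_iterations Iterations for [bootstrap_group_test()]
#'   (default 9999).
#' @param pseudo_year Backdated intervention year (default 2005).
#' @param prices A [price_config()].
#' @param synth A [synth_config()].
#' @param seed Integer seed for all stochastic steps.
#' @param run_robustness,run_anticipation Toggle the robustness stages.
#' @return A `run_config` list.
#' @export
run_config <- function(window = c(2007L, 2015L), alpha = 0.05,
                       trim_factors = c(0.1, 0.25),
                       bootstrap_iterations = 9999L, pseudo_year = 2005L,
                       prices = price_config(), synth = synth_config(),
                       seed = 1L, run_robustness = TRUE,
                       run_anticipation = TRUE) {
  structure(list(window = as.integer(window), alpha = alpha,
                 trim_factors = trim_factors,
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 pseudo_year = as.integer(pseudo_year), prices = prices,
                 synth = synth, seed = as.integer(seed),
                 run_robustness = isTRUE(run_robustness),
                 run_anticipation = isTRUE(run_anticipation)),
            class = "run_config")
}

#' Descriptive forest-loss summary
#'
#' Totals and per-reserve means of terminal cumulative forest loss for the
#' whole study and for the treated and donor groups, with per-year averages
#' (total divided by the number of panel years) and group shares. The 95%
#' confidence interval of the group mean uses t-distribution quantiles.
#'
#' @param study A `study_dataset`.
#' @return List with `n_years`, `total_ha`, `per_year_ha` and a tibble
#'   `by_group` (group, n, total_ha, share_pct, mean_ha, ci_lo, ci_hi).
#' @export
summarize_losses <- function(study) {
  validate_study(study)
  n_years <- diff(study$years) + 1
  final <- study$outcomes |>
    dplyr::filter(.data$year == study$years[2]) |>
    dplyr::select("reserve_id", "cumulative_loss_ha")
  tr <- study$treatments
  final$status <- ifelse(
    final$reserve_id %in% tr$reserve_id[!is.na(tr$intervention_year)],
    "treated", "donor")
  total <- sum(final$cumulative_loss_ha)
  grp <- function(x) {
    n <- length(x)
    m <- if (n > 0) mean(x) else NA_real_
    if (n >= 2 && sd(x) > 0) {
      half <- stats::qt(0.975, n - 1) * sd(x) / sqrt(n)
      ci <- m + c(-half, half)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    tibble::tibble(n = n, total_ha = sum(x),
                   share_pct = if (total > 0) 100 * sum(x) / total else NA_real_,
                   mean_ha = m, ci_lo = ci[1], ci_hi = ci[2])
  }
  by_group <- dplyr::bind_rows(
    dplyr::mutate(grp(final$cumulative_loss_ha[final$status == "treated"]),
                  group = "treated", .before = 1),
    dplyr::mutate(grp(final$cumulative_loss_ha[final$status == "donor"]),
                  group = "donor", .before = 1)
  )
  list(n_years = n_years, total_ha = total, per_year_ha = total / n_years,
       by_group = by_group)
}

#' Run the full evaluation pipeline
#'
#' Composes the stages in study order: validate, treatment-window filter,
#' per-reserve synthetic-control fit, placebo inference, anticipation
#' exclusion (for significant reserves), donor-pool trimming with
#' concordance scoring, carbon accounting for significant reserves, and
#' portfolio aggregation. When `out_dir` is given, writes `report.json`,
#' `effects.csv`, `carbon.csv` and `robustness.csv`.
#'
#' @param study A `study_dataset` (e.g. from [load_study()] or
#'   [simulate_study()]).
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory.
#' @return A `study_report` list: `effects` (per-reserve tibble), `accounts`,
#'   `portfolio`, `robustness`, `losses`, `fit_quality_test`, `config_echo`.
#' @export
run_pipeline <- function(study, cfg = run_config(), out_dir = NULL) {
  validate_study(study)
  study <- filter_treatment_window(study, cfg$window[1], cfg$window[2])
  eval_year <- study$years[2]
  treated <- treated_ids(study)

  fits <- list()
  ensembles <- list()
  rows <- vector("list", length(treated))
  for (i in seq_along(treated)) {
    id <- treated[i]
    message(sprintf("[%d/%d] fitting %s", i, length(treated), id))
    pool <- donor_ids(study, group = reserve_group(study, id))
    res <- tryCatch({
      fit <- fit_synthetic(study, id, pool, config = cfg$synth)
      ens <- placebo_distribution(study, id, pool, config = cfg$synth,
                                  treated_fit = fit)
      fits[[id]] <- fit
      ensembles[[id]] <- ens
      tibble::tibble(
        reserve_id = id, intervention_year = fit$intervention_year,
        effect_final = fit$effect_final, mspe_pre = fit$mspe_pre,
        mspe_post = fit$mspe_post, ratio = ens$treated_ratio,
        p_value = ens$p_value, n_placebos = ens$n_placebos,
        cannot_reach_alpha = ens$cannot_reach_alpha,
        excluded_reason = NA_character_)
    }, error = function(e) {
      tibble::tibble(reserve_id = id, intervention_year = NA_integer_,
                     effect_final = NA_real_, mspe_pre = NA_real_,
                     mspe_post = NA_real_, ratio = NA_real_,
                     p_value = NA_real_, n_placebos = NA_integer_,
                     cannot_reach_alpha = NA,
                     excluded_reason = paste("fit error:", conditionMessage(e)))
    })
    rows[[i]] <- res
  }
  effects <- dplyr::bind_rows(rows)

  # anticipation check on significant reserves only
  if (cfg$run_anticipation && nrow(effects) > 0) {
    sig <- !is.na(effects$p_value) & effects$p_value < cfg$alpha
    for (id in effects$reserve_id[sig]) {
      chk <- tryCatch(
        suppressWarnings(
          anticipation_check(study, id, cfg$pseudo_year,
                             config = cfg$synth, alpha = cfg$alpha)),
        error = function(e) list(excluded = FALSE, skipped = TRUE))
      if (isTRUE(chk$excluded)) {
        effects$excluded_reason[effects$reserve_id == id] <-
          sprintf("anticipation effect (backdated %d, p = %.3f)",
                  cfg$pseudo_year, chk$p_value)
      }
    }
  }
  effects$significant <- !is.na(effects$p_value) &
    effects$p_value < cfg$alpha & is.na(effects$excluded_reason)

  # robustness battery for significant reserves
  robustness <- NULL
  if (cfg$run_robustness && any(effects$significant)) {
    rob_rows <- lapply(effects$reserve_id[effects$significant], function(id) {
      v <- trimmed_refits(study, id, fits[[id]],
                          effects$p_value[effects$reserve_id == id],
                          factors = cfg$trim_factors, config = cfg$synth,
                          alpha = cfg$alpha)
      dplyr::mutate(v$trim_results, reserve_id = id,
                    effect_full = v$effect_full, .before = 1)
    })
    robustness <- dplyr::bind_rows(rob_rows)
  }

  # fit-quality comparison: significant vs non-significant pre-MSPE
  fit_quality <- NULL
  ok <- !is.na(effects$mspe_pre)
  if (any(effects$significant[ok]) && any(!effects$significant[ok])) {
    fit_quality <- bootstrap_group_test(
      effects$mspe_pre[ok & effects$significant],
      effects$mspe_pre[ok & !effects$significant],
      iterations = cfg$bootstrap_iterations, seed = cfg$seed)
  }

  # carbon accounting for significant reserves
  accounts <- NULL
  portfolio <- NULL
  if (!is.null(study$carbon) && any(effects$significant)) {
    acc_rows <- lapply(effects$reserve_id[effects$significant], function(id) {
      fit <- fits[[id]]
      cr <- study$carbon[study$carbon$reserve_id == id, ]
      if (nrow(cr) == 0) return(NULL)
      inc <- diff(c(0, fit$effect_series))
      names(inc) <- fit$years
      post <- fit$years >= fit$intervention_year
      carbon_account(id, effect_series = inc[post], carbon_record = cr,
                     intervention_year = fit$intervention_year,
                     eval_year = eval_year, prices = cfg$prices)
    })
    accounts <- dplyr::bind_rows(acc_rows)
    if (nrow(accounts) > 0) portfolio <- aggregate_portfolio(accounts)
  }

  report <- structure(
    list(effects = effects, accounts = accounts, portfolio = portfolio,
         robustness = robustness, losses = summarize_losses(study),
         fit_quality_test = fit_quality,
         config_echo = cfg, fits = fits, ensembles = ensembles),
    class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  n_sig <- sum(x$effects$significant, na.rm = TRUE)
  cat(sprintf("<study_report> %d treated reserves, %d significant\n",
              nrow(x$effects), n_sig))
  if (!is.null(x$portfolio)) {
    cat(sprintf("  net averted loss %.0f ha, net avoided %.2f ktCO2e, SCC %.2f kUSD\n",
                x$portfolio$net_ha, x$portfolio$net_tco2e / 1000,
                x$portfolio$net_scc_kusd))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(report$effects, file.path(out_dir, "effects.csv"))
  if (!is.null(report$accounts)) {
    readr::write_csv(report$accounts, file.path(out_dir, "carbon.csv"))
  }
  if (!is.null(report$robustness)) {
    readr::write_csv(report$robustness, file.path(out_dir, "robustness.csv"))
  }
  cfg <- report$config_echo
  obj <- list(
    config = list(window = cfg$window, alpha = cfg$alpha,
                  trim_factors = cfg$trim_factors,
                  bootstrap_iterations = cfg$bootstrap_iterations,
                  pseudo_year = cfg$pseudo_year, seed = cfg$seed,
                  prices = unclass(cfg$prices)),
    losses = list(total_ha = report$losses$total_ha,
                  per_year_ha = report$losses$per_year_ha,
                  by_group = report$losses$by_group),
    effects = report$effects,
    portfolio = report$portfolio,
    fit_quality_test = report$fit_quality_test
  )
  jsonlite::write_json(obj, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
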