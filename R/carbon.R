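#' Carbon pricing and conversion constants
#'
#' Defaults are the study constants: a social cost of carbon of US$86 per
#' tCO2e for India, a voluntary-carbon-market offset price of US$5.8 per
#' tCO2e, the IPCC carbon-to-CO2e emissions factor of 3.67 (44/12), and a
#' 10-year linear decay for belowground carbon released after forest loss.
#'
#' @param scc_price US$ per tCO2e (default 86).
#' @param offset_price US$ per tCO2e (default 5.8).
#' @param emissions_factor tCO2e per tC (default 3.67).
#' @param bgb_decay_years Years over which belowground carbon is released
#'   linearly after loss (default 10).
#' @return A `price_config` list.
#' @export
price_config <- function(scc_price = 86, offset_price = 5.8,
                         emissions_factor = 3.67, bgb_decay_years = 10) {
  stopifnot(scc_price > 0, offset_price > 0, emissions_factor > 0,
            bgb_decay_years > 0)
  structure(list(scc_price = scc_price, offset_price = offset_price,
                 emissions_factor = emissions_factor,
                 bgb_decay_years = bgb_decay_years),
            class = "price_config")
}

#' Rescale a 2010 carbon density to the intervention year
#'
#' Carbon-density maps reference 2010; the density applied at the
#' intervention year is scaled proportionally to the forest-cover ratio
#' between the intervention year and 2010.
#'
#' @param density_2010 Carbon density (tC/ha) in 2010.
#' @param cover_2010,cover_interv Forest cover (ha) in 2010 and at the
#'   intervention year; both must be positive.
#' @return Scaled density (tC/ha).
#' @export
scale_density <- function(density_2010, cover_2010, cover_interv) {
  if (any(cover_2010 <= 0) || any(cover_interv <= 0)) {
    stop("forest covers must be > 0", call. = FALSE)
  }
  stopifnot(all(density_2010 >= 0))
  density_2010 * cover_interv / cover_2010
}

#' Convert an averted-loss series into avoided CO2e emissions
#'
#' The aboveground component counts each averted hectare at the full
#' aboveground carbon density times the emissions factor. The belowground
#' component applies a linear decay: soil/root carbon from a hectare lost in
#' year `t` is only fractionally released by `eval_year`, with fraction
#' `min(1, (eval_year - t) / bgb_decay_years)`.
#'
#' @param effect_series Named numeric vector of *annual* averted hectares
#'   (increments of counterfactual minus observed), names = calendar years.
#' @param agb_density,bgb_density Carbon densities (tC/ha) at the
#'   intervention year.
#' @param eval_year Evaluation year (the last panel year, 2020 in the study).
#' @param prices A [price_config()].
#' @return List with `agb_tco2e`, `bgb_tco2e`, `total_tco2e`.
#' @export
avoided_emissions <- function(effect_series, agb_density, bgb_density,
                              eval_year, prices = price_config()) {
  yrs <- as.integer(names(effect_series))
  if (is.null(names(effect_series)) || anyNA(yrs)) {
    stop("effect_series must be named by calendar year", call. = FALSE)
  }
  if (eval_year < min(yrs)) {
    stop("eval_year precedes the first effect year", call. = FALSE)
  }
  ef <- prices$emissions_factor
  agb <- sum(effect_series * agb_density * ef)
  frac <- pmin(1, pmax(0, (eval_year - yrs) / prices$bgb_decay_years))
  bgb <- sum(effect_series * bgb_density * ef * frac)
  list(agb_tco2e = agb, bgb_tco2e = bgb, total_tco2e = agb + bgb)
}

#' Uncertainty of avoided emissions
#'
#' Propagates the carbon-density prediction standard errors additively:
#' `|averted_ha| * emissions_factor * (agb_se + bgb_se)` (tCO2e), matching
#' the additive decomposition of the net uncertainty into above- and
#' belowground parts.
#'
#' @param averted_ha Net averted hectares (absolute value used).
#' @param agb_se,bgb_se Density standard errors (tC/ha).
#' @param emissions_factor tCO2e per tC (default 3.67).
#' @return Uncertainty in tCO2e (>= 0).
#' @export
emissions_uncertainty <- function(averted_ha, agb_se, bgb_se,
                                  emissions_factor = 3.67) {
  stopifnot(all(agb_se >= 0), all(bgb_se >= 0), emissions_factor > 0)
  abs(averted_ha) * emissions_factor * (agb_se + bgb_se)
}

#' Monetary value of avoided emissions
#'
#' @param avoided_tco2e Avoided emissions (tCO2e; may be negative for
#'   reserves that underperformed their counterfactual).
#' @param price_per_t US$ per tCO2e (> 0).
#' @return Value in thousand US$.
#' @export
value_emissions <- function(avoided_tco2e, price_per_t) {
  stopifnot(price_per_t > 0)
  avoided_tco2e * price_per_t / 1000
}

#' Build the full carbon account for one reserve
#'
#' Composes [scale_density()], [avoided_emissions()],
#' [emissions_uncertainty()] and [value_emissions()] into the per-reserve
#' account. When only a terminal averted-hectares figure is available
#' (`effect_series = NULL`), increments are distributed uniformly over the
#' post-intervention years.
#'
#' @param reserve_id Reserve id.
#' @param effect_series Named annual averted-hectares increments, or `NULL`.
#' @param averted_ha Terminal net averted hectares (required if
#'   `effect_series` is `NULL`; otherwise derived as its sum).
#' @param carbon_record One-row slice of the carbon table for this reserve.
#' @param intervention_year,eval_year Calendar years.
#' @param prices A [price_config()].
#' @return A `carbon_account` tibble row: averted_ha, avoided_tco2e and its
#'   agb/bgb components, uncertainty, and SCC / offset values (thousand US$)
#'   with uncertainties.
#' @export
carbon_account <- function(reserve_id, effect_series = NULL, averted_ha = NULL,
                           carbon_record, intervention_year, eval_year,
                           prices = price_config()) {
  if (is.null(effect_series)) {
    stopifnot(!is.null(averted_ha))
    post_years <- seq(intervention_year, eval_year)
    effect_series <- setNames(rep(averted_ha / length(post_years),
                                  length(post_years)), post_years)
  }
  averted_ha <- sum(effect_series)
  agb_d <- scale_density(carbon_record$agb_c_density,
                         carbon_record$forest_cover_2010,
                         carbon_record$forest_cover_interv)
  bgb_d <- scale_density(carbon_record$bgb_c_density,
                         carbon_record$forest_cover_2010,
                         carbon_record$forest_cover_interv)
  em <- avoided_emissions(effect_series, agb_d, bgb_d, eval_year, prices)
  unc <- emissions_uncertainty(averted_ha, carbon_record$agb_c_se,
                               carbon_record$bgb_c_se,
                               prices$emissions_factor)
  tibble::tibble(
    reserve_id = reserve_id,
    intervention_year = intervention_year,
    averted_ha = averted_ha,
    avoided_tco2e = em$total_tco2e,
    agb_component_tco2e = em$agb_tco2e,
    bgb_component_tco2e = em$bgb_tco2e,
    avoided_tco2e_uncertainty = unc,
    scc_value_kusd = value_emissions(em$total_tco2e, prices$scc_price),
    offset_value_kusd = value_emissions(em$total_tco2e, prices$offset_price),
    scc_value_uncertainty_kusd = value_emissions(unc, prices$scc_price),
    offset_value_uncertainty_kusd = value_emissions(unc, prices$offset_price)
  )
}

#' Aggregate reserve accounts into a portfolio summary
#'
#' Splits significant reserves into gains (positive averted loss) and losses
#' (negative, i.e. more deforestation than the counterfactual), and reports
#' gains, losses and nets for hectares, tCO2e and both monetary valuations.
#' Net = sum of gains minus sum of absolute losses; uncertainties aggregate
#' additively.
#'
#' @param accounts Tibble of `carbon_account` rows.
#' @param significant Logical vector (default all `TRUE`): which accounts
#'   enter the portfolio.
#' @return A one-row tibble with columns `gain_*`, `loss_*` (absolute
#'   magnitudes), `net_*` for `ha`, `tco2e`, `scc_kusd`, `offset_kusd`,
#'   plus additively aggregated uncertainties.
#' @export
aggregate_portfolio <- function(accounts, significant = NULL) {
  if (is.null(significant)) significant <- rep(TRUE, nrow(accounts))
  acc <- accounts[significant, , drop = FALSE]
  if (nrow(acc) == 0) {
    acc <- accounts[0, ]
  }
  pos <- acc$averted_ha > 0
  sum0 <- function(x) if (length(x) == 0) 0 else sum(x)
  g <- function(col) sum0(acc[[col]][pos])
  l <- function(col) abs(sum0(acc[[col]][!pos]))
  tibble::tibble(
    n_reserves = nrow(acc), n_gain = sum(pos), n_loss = sum(!pos),
    gain_ha = g("averted_ha"), loss_ha = l("averted_ha"),
    net_ha = g("averted_ha") - l("averted_ha"),
    gain_tco2e = g("avoided_tco2e"), loss_tco2e = l("avoided_tco2e"),
    net_tco2e = g("avoided_tco2e") - l("avoided_tco2e"),
    gain_scc_kusd = g("scc_value_kusd"), loss_scc_kusd = l("scc_value_kusd"),
    net_scc_kusd = g("scc_value_kusd") - l("scc_value_kusd"),
    gain_offset_kusd = g("offset_value_kusd"),
    loss_offset_kusd = l("offset_value_kusd"),
    net_offset_kusd = g("offset_value_kusd") - l("offset_value_kusd"),
    tco2e_uncertainty = sum0(acc$avoided_tco2e_uncertainty),
    scc_uncertainty_kusd = sum0(acc$scc_value_uncertainty_kusd),
    offset_uncertainty_kusd = sum0(acc$offset_value_uncertainty_kusd)
  )
}

#' Published co-benefit estimates for 11 Indian tiger reserves
#'
#' Returns the packaged table of published per-reserve estimates (2007-2015
#' interventions, evaluated at 2020) for the 11 reserves with significant
#' avoided deforestation: averted hectares, avoided emissions (ktCO2e, with
#' uncertainty), and their valuation at US$86 (social cost) and US$5.8
#' (offset market) per tCO2e, in thousand US$. Used as a regression fixture
#' for the valuation arithmetic.
#'
#' @return A tibble with columns `reserve_id`, `treatment_year`,
#'   `averted_ha`, `avoided_ktco2e`, `avoided_ktco2e_unc`, `scc_kusd`,
#'   `scc_kusd_unc`, `offset_kusd`, `offset_kusd_unc`.
#' @export
published_cobenefits <- function() {
  path <- system.file("extdata", "tiger_cobenefits_published.csv",
                      package = "forestsynth", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
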