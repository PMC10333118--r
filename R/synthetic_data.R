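#' Simulation configuration
#'
#' Describes a synthetic study: landscape groups of donor and treated
#' reserves observed over a 20-year panel, covariate-driven annual loss
#' rates with serially correlated log-normal shocks, and a proportional
#' post-intervention reduction of the treated units' loss rate.
#'
#' The default configuration mirrors the structure of the Indian
#' tiger-reserve evaluation: 3 regional groupings with 44, 29 and 44 donors,
#' 45 treated reserves in total, a 2001-2020 panel, interventions between
#' 2007 and 2015 with about half of treated reserves entering in 2007.
#' Annual losses follow
#' `area * base_rate * exp(beta' z + gamma_gt + eps_it)` with standardized
#' covariates `z` (roughly an order of magnitude of between-reserve rate
#' heterogeneity under the default coefficients), group-level year shocks
#' `gamma_gt` shared by all reserves of a landscape (regional rainfall,
#' enforcement and market drivers — the common structure that makes a
#' donor-based counterfactual informative), and reserve-level AR(1)
#' log-noise `eps_it` for serially correlated idiosyncratic shocks.
#'
#' @param n_groups Number of landscape groups.
#' @param donors_per_group Donors per group (scalar or vector of length
#'   `n_groups`); each must exceed 20 so the placebo test can reject at 0.05.
#' @param treated_per_group Treated reserves per group (scalar or vector).
#' @param years Panel `c(start, end)` (default 2001-2020).
#' @param intervention_years Candidate intervention years (treated reserves
#'   are assigned years from this set; with more than one candidate, 2007
#'   receives about half the reserves as in the study window).
#' @param effect_rho Fractional reduction of the annual loss rate after
#'   intervention, in `[0, 1)` (0 = null study).
#' @param covariate_effects Named log-linear coefficients on standardized
#'   covariates.
#' @param base_rate Expected annual loss as a fraction of reserve area.
#' @param noise_sd Stationary SD of the reserve-level (idiosyncratic)
#'   log-scale shocks.
#' @param ar1_phi AR(1) coefficient of the idiosyncratic shocks.
#' @param year_shock_sd SD of the group-level year shocks shared by all
#'   reserves in a landscape group.
#' @param agb_c_mean,agb_c_sd Mean/SD of reserve aboveground carbon density
#'   (tC/ha, 2010 reference).
#' @param bgb_ratio Belowground:aboveground carbon ratio.
#' @param carbon_se_frac Density SE as a fraction of the density.
#' @param seed Integer seed; everything is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_groups = 3L,
                       donors_per_group = c(44L, 29L, 44L),
                       treated_per_group = c(22L, 8L, 15L),
                       years = c(2001L, 2020L),
                       intervention_years = 2007:2015,
                       effect_rho = 0.3,
                       covariate_effects = c(pop_density = 0.25,
                                             road_length = 0.2,
                                             elevation = -0.2,
                                             travel_time = -0.2,
                                             slope = -0.12),
                       base_rate = 0.001,
                       noise_sd = 0.15,
                       ar1_phi = 0.5,
                       year_shock_sd = 0.25,
                       agb_c_mean = 60, agb_c_sd = 15,
                       bgb_ratio = 0.26,
                       carbon_se_frac = 0.15,
                       seed = 1L) {
  donors_per_group <- rep_len(as.integer(donors_per_group), n_groups)
  treated_per_group <- rep_len(as.integer(treated_per_group), n_groups)
  stopifnot(all(donors_per_group >= 21L),
            diff(years) >= 10,
            effect_rho >= 0, effect_rho < 1,
            abs(ar1_phi) < 1, base_rate > 0, noise_sd >= 0,
            year_shock_sd >= 0,
            all(intervention_years > years[1]),
            all(intervention_years <= years[2]))
  structure(list(n_groups = as.integer(n_groups),
                 donors_per_group = donors_per_group,
                 treated_per_group = treated_per_group,
                 years = as.integer(years),
                 intervention_years = as.integer(intervention_years),
                 effect_rho = effect_rho,
                 covariate_effects = covariate_effects,
                 base_rate = base_rate, noise_sd = noise_sd,
                 ar1_phi = ar1_phi, year_shock_sd = year_shock_sd,
                 agb_c_mean = agb_c_mean, agb_c_sd = agb_c_sd,
                 bgb_ratio = bgb_ratio, carbon_se_frac = carbon_se_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# AR(1) log-noise with stationary SD `sd`.
.ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  for (t in seq_len(n - 1)) e[t + 1] <- phi * e[t] + rnorm(1, 0, innov_sd)
  e
}

#' Simulate a study with known ground truth
#'
#' Draws reserve covariates (log-normal population density, road length,
#' purchasing power and area; normal climate and topography; uniform age and
#' travel time), generates annual forest-loss increments from the
#' covariate-driven log-linear rate model with AR(1) shocks, reduces treated
#' units' rates by `effect_rho` from their intervention year onward, and
#' accumulates losses into a monotone cumulative panel. The no-effect
#' counterfactual of every treated unit is simulated with the *same* shock
#' sequence, so the injected effect (true averted hectares, per year and
#' terminal) is known exactly.
#'
#' @param cfg A [sim_config()].
#' @return List with `study` (a validated `study_dataset`) and `truth`
#'   (`sim_truth`: per-treated tibble of terminal truth plus per-year averted
#'   increments, and the generating config).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_study_impl(cfg))
}

.simulate_study_impl <- function(cfg) {
  yrs <- seq(cfg$years[1], cfg$years[2])
  n_yr <- length(yrs)
  groups <- sprintf("G%d", seq_len(cfg$n_groups))

  units <- purrr::map_dfr(seq_len(cfg$n_groups), function(g) {
    n_d <- cfg$donors_per_group[g]
    n_t <- cfg$treated_per_group[g]
    tibble::tibble(
      reserve_id = c(sprintf("%s_T%02d", groups[g], seq_len(n_t)),
                     sprintf("%s_D%03d", groups[g], seq_len(n_d))),
      group = groups[g],
      treated = rep(c(TRUE, FALSE), c(n_t, n_d))
    )
  })
  n <- nrow(units)

  covariates <- tibble::tibble(
    reserve_id = units$reserve_id,
    pop_density = rlnorm(n, log(50), 1),
    road_length = rlnorm(n, log(100), 0.8),
    precipitation = rnorm(n, 1200, 300),
    elevation = pmax(0, rnorm(n, 600, 300)),
    slope = pmax(0, rnorm(n, 10, 4)),
    aspect = runif(n, 0, 360),
    agb_baseline = pmax(10, rnorm(n, 120, 30)),
    ppp = rlnorm(n, log(2000), 0.5),
    age = runif(n, 5, 70),
    travel_time = runif(n, 60, 600),
    # treated and donor areas share one distribution so treated units are
    # generically inside the donor convex hull (see vignette for the
    # real-data caveat: actual tiger reserves tend to be larger)
    area_ha = rlnorm(n, log(50000), 0.5),
    group = units$group
  )

  # log-linear loss-rate index on standardized covariates
  beta <- cfg$covariate_effects
  Z <- scale(as.matrix(covariates[, names(beta)]))
  idx <- drop(Z %*% beta)

  # intervention years: with several candidates, ~half of treated enter at
  # the earliest year (as in the study), the rest spread uniformly
  n_treated <- sum(units$treated)
  iy_pool <- cfg$intervention_years
  if (length(iy_pool) == 1) {
    iys <- rep(iy_pool, n_treated)
  } else {
    later <- iy_pool[-1]
    early <- rbinom(n_treated, 1, 0.5) == 1
    iys <- ifelse(early, iy_pool[1],
                  later[sample.int(length(later), n_treated, replace = TRUE)])
  }
  treatments <- tibble::tibble(
    reserve_id = units$reserve_id,
    intervention_year = NA_integer_
  )
  treatments$intervention_year[units$treated] <- as.integer(iys)

  # group-level year shocks: common drivers shared within a landscape
  year_shocks <- matrix(rnorm(n_yr * cfg$n_groups, 0, cfg$year_shock_sd),
                        nrow = n_yr, dimnames = list(yrs, groups))

  outcomes <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    eps <- .ar1_noise(n_yr, cfg$ar1_phi, cfg$noise_sd)
    gamma_g <- year_shocks[, units$group[i]]
    annual_cf <- covariates$area_ha[i] * cfg$base_rate *
      exp(idx[i] + gamma_g + eps)
    annual <- annual_cf
    if (units$treated[i]) {
      iy <- treatments$intervention_year[treatments$reserve_id == units$reserve_id[i]]
      post <- yrs >= iy
      annual[post] <- annual_cf[post] * (1 - cfg$effect_rho)
      averted <- annual_cf - annual
      truth_rows[[i]] <- tibble::tibble(
        reserve_id = units$reserve_id[i],
        intervention_year = iy,
        true_averted_final = sum(averted),
        averted_by_year = list(setNames(averted, yrs))
      )
    }
    outcomes[[i]] <- tibble::tibble(
      reserve_id = units$reserve_id[i], year = yrs,
      cumulative_loss_ha = cumsum(annual)
    )
  }

  agb <- pmax(1, rnorm(n, cfg$agb_c_mean, cfg$agb_c_sd))
  cover2010 <- 0.8 * covariates$area_ha
  carbon <- tibble::tibble(
    reserve_id = units$reserve_id,
    agb_c_density = agb,
    bgb_c_density = cfg$bgb_ratio * agb,
    agb_c_se = cfg$carbon_se_frac * agb,
    bgb_c_se = cfg$carbon_se_frac * cfg$bgb_ratio * agb,
    forest_cover_2010 = cover2010,
    forest_cover_interv = cover2010 * runif(n, 0.95, 1.02)
  )

  study <- study_dataset(dplyr::bind_rows(outcomes), covariates, treatments,
                         carbon)
  truth <- structure(
    list(treated = dplyr::bind_rows(truth_rows), config = cfg),
    class = "sim_truth"
  )
  list(study = study, truth = truth)
}

#' Build an anticipation variant of a simulated study
#'
#' Returns a copy of the simulated study in which every treated reserve's
#' loss-rate reduction begins at `pseudo_year` instead of its official
#' intervention year, while the recorded intervention years are unchanged.
#' Used as a positive control for [anticipation_check()]: the backdated
#' pseudo-intervention should now detect a real pre-intervention divergence.
#'
#' @param study,truth Output of [simulate_study()].
#' @param pseudo_year Year the (hidden) effect actually starts; must precede
#'   every official intervention year.
#' @return List with modified `study` and `truth`.
#' @export
make_anticipation_variant <- function(study, truth, pseudo_year) {
  cfg <- truth$config
  if (any(pseudo_year >= truth$treated$intervention_year)) {
    stop("pseudo_year must precede every true intervention year", call. = FALSE)
  }
  yrs <- seq(study$years[1], study$years[2])
  new_truth <- truth$treated
  for (i in seq_len(nrow(truth$treated))) {
    id <- truth$treated$reserve_id[i]
    iy <- truth$treated$intervention_year[i]
    averted <- truth$treated$averted_by_year[[i]]
    # reconstruct the no-effect annual series, then re-apply the reduction
    # from pseudo_year onward
    obs <- outcome_series(study, id)
    annual_obs <- diff(c(0, obs))
    annual_cf <- annual_obs + averted
    sel <- yrs >= pseudo_year
    annual_new <- annual_cf
    annual_new[sel] <- annual_cf[sel] * (1 - cfg$effect_rho)
    study$outcomes$cumulative_loss_ha[study$outcomes$reserve_id == id] <-
      cumsum(annual_new)
    new_averted <- annual_cf - annual_new
    new_truth$true_averted_final[i] <- sum(new_averted)
    new_truth$averted_by_year[[i]] <- setNames(new_averted, yrs)
  }
  validate_study(study)
  truth$treated <- new_truth
  list(study = study, truth = truth)
}
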