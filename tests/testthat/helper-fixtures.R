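# Shared fixtures: all built in code, no files.

# Small deterministic 3-reserve, 5-year study (1 treated, 2 donors).
make_toy_study <- function(loss_r2 = c(2, 4, 6, 8, 10),
                           intervention_year = 2003L) {
  years <- 2001:2005
  outcomes <- tibble::tibble(
    reserve_id = rep(c("R1", "R2", "R3"), each = 5),
    year = rep(years, 3),
    cumulative_loss_ha = c(1, 2, 3, 4, 5, loss_r2, 3, 6, 9, 12, 15)
  )
  covariates <- tibble::tibble(
    reserve_id = c("R1", "R2", "R3"),
    pop_density = c(10, 20, 30), road_length = c(5, 6, 7),
    precipitation = c(1000, 1100, 1200), elevation = c(300, 400, 500),
    slope = c(5, 10, 15), aspect = c(90, 180, 270),
    agb_baseline = c(100, 120, 140), ppp = c(1500, 2000, 2500),
    age = c(10, 20, 30), travel_time = c(100, 200, 300),
    area_ha = c(1000, 2000, 3000), group = "G1"
  )
  treatments <- tibble::tibble(
    reserve_id = c("R1", "R2", "R3"),
    intervention_year = c(NA_integer_, intervention_year, NA_integer_)
  )
  carbon <- tibble::tibble(
    reserve_id = c("R1", "R2", "R3"),
    agb_c_density = c(50, 60, 70), bgb_c_density = c(13, 15, 18),
    agb_c_se = c(5, 6, 7), bgb_c_se = c(1.3, 1.5, 1.8),
    forest_cover_2010 = c(800, 1600, 2400),
    forest_cover_interv = c(780, 1550, 2350)
  )
  study_dataset(outcomes, covariates, treatments, carbon)
}

# Fast estimator config for small simulated studies.
fast_cfg <- function(...) {
  synth_config(allow_small_donor_pool = TRUE, ...)
}

# One small simulated study, memoized across tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(
        n_groups = 1, donors_per_group = 22, treated_per_group = 2,
        years = c(2001, 2014), intervention_years = 2007, effect_rho = 0.3,
        seed = 7))
    }
    cache
  }
})

# Exhaustive simplex grids at step 0.005 (shared across QP oracle tests).
simplex_grid <- local({
  cache <- list()
  function(J, step = 0.005) {
    key <- as.character(J)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n <- round(1 / step)
    W <- switch(key,
      "2" = cbind(0:n, n - (0:n)),
      "3" = do.call(rbind, lapply(0:n, function(a) {
        b <- 0:(n - a)
        cbind(a, b, n - a - b)
      })),
      "4" = do.call(rbind, lapply(0:n, function(a) {
        do.call(rbind, lapply(0:(n - a), function(b) {
          cc <- 0:(n - a - b)
          cbind(a, b, cc, n - a - b - cc)
        }))
      })),
      stop("unsupported J"))
    cache[[key]] <<- W / n
    cache[[key]]
  }
})

# Best objective on the grid for a given instance.
grid_best_objective <- function(x1, X0, v, step = 0.005) {
  W <- simplex_grid(ncol(X0), step)
  R <- x1 - X0 %*% t(W)              # k x N residual matrix
  min(colSums(v * R^2))
}

# Build a deterministic panel whose group totals are prescribed exactly.
make_totals_study <- function(n_treated, treated_total, n_donor, donor_total,
                              years = 2001:2020) {
  n <- n_treated + n_donor
  ids <- sprintf("R%03d", seq_len(n))
  per_treated <- treated_total / n_treated
  per_donor <- donor_total / n_donor
  finals <- c(rep(per_treated, n_treated), rep(per_donor, n_donor))
  outcomes <- tibble::tibble(
    reserve_id = rep(ids, each = length(years)),
    year = rep(years, n),
    cumulative_loss_ha = as.vector(vapply(
      finals, function(f) f * seq_along(years) / length(years),
      numeric(length(years)))))
  covariates <- tibble::tibble(
    reserve_id = ids, pop_density = seq_len(n), road_length = 1,
    precipitation = 1000, elevation = 100, slope = 5, aspect = 180,
    agb_baseline = 100, ppp = 1000, age = 10, travel_time = 100,
    area_ha = 1000, group = "G1")
  treatments <- tibble::tibble(
    reserve_id = ids,
    intervention_year = c(rep(2007L, n_treated), rep(NA_integer_, n_donor)))
  study_dataset(outcomes, covariates, treatments)
}
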