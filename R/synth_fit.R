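#' Estimator configuration
#'
#' Collects the numerical settings of the nested synthetic-control
#' optimization. The outer search over predictor weights `v` is a
#' derivative-free Nelder-Mead run on a softmax reparameterization of the
#' (k-1)-dimensional simplex, started at uniform `v`, so the reported
#' pre-intervention MSPE never exceeds the uniform-v value.
#'
#' @param outer_maxit Maximum outer iterations (default 500).
#' @param outer_tol Relative convergence tolerance on the outer objective
#'   (default 1e-8).
#' @param min_pre_years Minimum number of pre-intervention years required to
#'   fit (default 3).
#' @param allow_small_donor_pool If `FALSE` (default), fitting with 20 or
#'   fewer donors is an error; the placebo test needs more than 20 donors to
#'   be able to reject at the 0.05 level.
#' @param min_placebos Minimum placebo count below which p-values are flagged
#'   as unable to reach 0.05 (default 20).
#' @param mspe_floor_factor Relative floor applied to a degenerate (zero)
#'   pre-intervention MSPE when used as a ratio denominator: the floor is
#'   `mspe_floor_factor * var(treated pre-period series)` (default 1e-8).
#' @return A `synth_config` list.
#' @export
synth_config <- function(outer_maxit = 500L, outer_tol = 1e-8,
                         min_pre_years = 3L, allow_small_donor_pool = FALSE,
                         min_placebos = 20L, mspe_floor_factor = 1e-8) {
  structure(list(outer_maxit = as.integer(outer_maxit), outer_tol = outer_tol,
                 min_pre_years = as.integer(min_pre_years),
                 allow_small_donor_pool = isTRUE(allow_small_donor_pool),
                 min_placebos = as.integer(min_placebos),
                 mspe_floor_factor = mspe_floor_factor),
            class = "synth_config")
}

#' Build the standardized predictor matrix for one treated unit
#'
#' Predictors are the reserve-level structural deforestation drivers
#' (population density, road length, precipitation, elevation, slope, aspect,
#' baseline aboveground biomass, purchasing power parity, reserve age, travel
#' time to city, and total area) plus the mean pre-intervention cumulative
#' forest loss. Each predictor is centred and scaled to unit variance over
#' the pooled treated + donor units; predictors with no spread are dropped
#' with a warning.
#'
#' @param study A `study_dataset`.
#' @param unit_id Treated (or pseudo-treated) reserve id.
#' @param donor_ids Donor reserve ids (at least 2).
#' @param intervention_year First year of the post period; the pre period is
#'   all years strictly before it.
#' @return A `predictor_matrix` list: `predictor_names`, `x_treated` (k),
#'   `x_donors` (k x J, columns sorted by donor id), `scale` (centre/scale
#'   used).
#' @export
build_predictors <- function(study, unit_id, donor_ids, intervention_year) {
  donor_ids <- sort(donor_ids)
  if (length(donor_ids) < 2) {
    stop("insufficient donors: need at least 2", call. = FALSE)
  }
  yrs <- seq(study$years[1], study$years[2])
  if (!(intervention_year > study$years[1] && intervention_year <= study$years[2])) {
    stop("intervention_year must lie inside the panel", call. = FALSE)
  }
  pre_years <- yrs[yrs < intervention_year]
  ids <- c(unit_id, donor_ids)
  cov <- study$covariates[match(ids, study$covariates$reserve_id), ]
  if (anyNA(cov$reserve_id)) {
    stop("covariates missing for some unit(s)", call. = FALSE)
  }
  X <- as.matrix(cov[, .fs_predictor_covariates])
  pre_loss <- vapply(ids, function(id) {
    mean(outcome_series(study, id)[as.character(pre_years)])
  }, numeric(1))
  X <- cbind(X, pre_loss_mean = pre_loss)
  rownames(X) <- ids

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 0 & is.finite(scl)
  if (any(!keep)) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(colnames(X)[!keep], collapse = ", ")), call. = FALSE)
  }
  X <- X[, keep, drop = FALSE]
  Z <- scale(X, center = ctr[keep], scale = scl[keep])
  structure(
    list(predictor_names = colnames(X),
         x_treated = Z[1, ],
         x_donors = t(Z[-1, , drop = FALSE]),
         scale = list(center = ctr[keep], scale = scl[keep])),
    class = "predictor_matrix"
  )
}

# Softmax with the last coordinate's logit pinned at 0.
.softmax_v <- function(theta) {
  z <- c(theta, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Fit a synthetic control for one treated reserve
#'
#' Nested optimization in the standard synthetic-control form: the outer
#' search chooses predictor weights `v` on the simplex to minimize the
#' pre-intervention mean squared prediction error (MSPE) of the implied
#' counterfactual; for each candidate `v` the inner quadratic program
#' ([inner_weights()]) picks donor weights `w` on the simplex that best match
#' the treated unit's predictors in the metric `diag(v)`. The counterfactual
#' is the `w`-weighted combination of donor outcome series, a convex
#' combination bounded by the donor envelope in every year. Deterministic:
#' fixed uniform-`v` start, sorted donor order, no randomness.
#'
#' @inheritParams build_predictors
#' @param config A [synth_config()].
#' @return A `synth_fit` object: `treated_id`, `intervention_year`,
#'   `donor_ids`, `weights` (list `v`, `w`), `years`, `observed`,
#'   `counterfactual`, `effect_series` (counterfactual - observed),
#'   `effect_final` (at the last panel year, hectares), `mspe_pre`,
#'   `mspe_post` (ha^2), `converged`.
#' @export
fit_synthetic <- function(study, treated_id, donor_ids = NULL,
                          intervention_year = NULL, config = synth_config()) {
  if (is.null(intervention_year)) {
    intervention_year <- intervention_year_of(study, treated_id)
  }
  if (is.null(donor_ids)) {
    donor_ids <- donor_ids(study, group = reserve_group(study, treated_id))
  }
  donor_ids <- sort(setdiff(donor_ids, treated_id))
  if (length(donor_ids) <= 20 && !config$allow_small_donor_pool) {
    stop(sprintf("donor pool has %d donors; more than 20 are required (set allow_small_donor_pool to override)",
                 length(donor_ids)), call. = FALSE)
  }
  yrs <- seq(study$years[1], study$years[2])
  pre_years <- yrs[yrs < intervention_year]
  if (length(pre_years) < config$min_pre_years) {
    stop(sprintf("pre-intervention period has %d year(s); config requires >= %d",
                 length(pre_years), config$min_pre_years), call. = FALSE)
  }

  pm <- build_predictors(study, treated_id, donor_ids, intervention_year)
  k <- length(pm$x_treated)
  y1 <- outcome_series(study, treated_id)
  Y0 <- outcome_matrix(study, donor_ids)
  pre_idx <- which(yrs < intervention_year)

  pre_mspe_of <- function(v) {
    w <- inner_weights(pm, v)$w
    cf_pre <- drop(Y0[pre_idx, , drop = FALSE] %*% w)
    mean((y1[pre_idx] - cf_pre)^2)
  }

  converged <- TRUE
  if (k == 1) {
    v <- 1
  } else {
    obj <- function(theta) pre_mspe_of(.softmax_v(theta))
    theta0 <- rep(0, k - 1)
    if (k == 2) {
      opt <- optimize(obj, interval = c(-15, 15))
      theta <- opt$minimum
      # keep the monotone-improvement guarantee of the uniform start
      if (opt$objective > obj(theta0)) theta <- theta0
      best_theta <- theta
    } else {
      run_nm <- function(start) {
        optim(start, obj, method = "Nelder-Mead",
              control = list(maxit = config$outer_maxit,
                             reltol = config$outer_tol))
      }
      opt <- run_nm(theta0)
      converged <- opt$convergence == 0
      best_theta <- opt$par
      best_obj <- opt$value
      # simplex vertices (all weight on one predictor) are frequent optima
      # that the softmax parameterization only reaches asymptotically:
      # evaluate them as candidates and restart from the best if it wins
      for (i in seq_len(k)) {
        theta_i <- rep(-20, k - 1)
        if (i < k) theta_i[i] <- 20  # i == k: all -20 puts weight on vertex k
        o_i <- obj(theta_i)
        if (o_i < best_obj) {
          opt_i <- run_nm(theta_i)
          if (opt_i$value < min(best_obj, o_i)) {
            best_theta <- opt_i$par
            best_obj <- opt_i$value
          } else {
            best_theta <- theta_i
            best_obj <- o_i
          }
        }
      }
    }
    v <- .softmax_v(best_theta)
  }

  iw <- inner_weights(pm, v)
  w <- iw$w
  cf <- drop(Y0 %*% w)
  post_idx <- which(yrs >= intervention_year)
  mspe_pre <- mean((y1[pre_idx] - cf[pre_idx])^2)
  mspe_post <- mean((y1[post_idx] - cf[post_idx])^2)
  effect <- cf - y1

  structure(
    list(treated_id = treated_id, intervention_year = intervention_year,
         donor_ids = donor_ids,
         weights = list(v = setNames(v, pm$predictor_names), w = w),
         predictor_names = pm$predictor_names,
         years = yrs, observed = unname(y1), counterfactual = unname(cf),
         effect_series = unname(effect),
         effect_final = unname(effect[length(effect)]),
         mspe_pre = mspe_pre, mspe_post = mspe_post,
         pre_variance = var(y1[pre_idx]),
         converged = converged),
    class = "synth_fit"
  )
}

#' @export
print.synth_fit <- function(x, ...) {
  cat(sprintf("<synth_fit> %s (intervention %d): effect_final %.1f ha, MSPE pre %.3g / post %.3g\n",
              x$treated_id, x$intervention_year, x$effect_final,
              x$mspe_pre, x$mspe_post))
  top <- sort(x$weights$w[x$weights$w > 1e-4], decreasing = TRUE)
  cat("  donor weights:", paste(sprintf("%s=%.3f", names(top), top),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit A `synth_fit`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file). Donor weights below
#'   1e-4 are omitted.
#' @export
fit_to_json <- function(fit, path = NULL) {
  w <- fit$weights$w[fit$weights$w >= 1e-4]
  obj <- list(
    treated_id = fit$treated_id,
    intervention_year = fit$intervention_year,
    donor_weights = as.list(w),
    v = as.list(fit$weights$v),
    years = fit$years, observed = fit$observed,
    counterfactual = fit$counterfactual, effect = fit$effect_series,
    mspe_pre = fit$mspe_pre, mspe_post = fit$mspe_post,
    effect_final = fit$effect_final
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Plot observed versus counterfactual trajectories
#'
#' @param x A `synth_fit`.
#' @param ... Ignored.
#' @return A ggplot object: observed and synthetic cumulative forest loss
#'   with a dashed line at the intervention year.
#' @export
plot.synth_fit <- function(x, ...) {
  d <- tibble::tibble(
    year = rep(x$years, 2),
    loss = c(x$observed, x$counterfactual),
    series = rep(c("observed", "synthetic"), each = length(x$years))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = x$intervention_year, linetype = "dashed") +
    ggplot2::labs(x = "year", y = "cumulative forest loss (ha)",
                  title = x$treated_id) +
    ggplot2::theme_minimal()
}
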