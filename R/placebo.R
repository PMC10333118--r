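#' Post/pre MSPE ratio of a fit
#'
#' The test statistic of the placebo analysis: the post-intervention MSPE of
#' the counterfactual divided by its pre-intervention MSPE. A unit genuinely
#' affected by the intervention has a large ratio (good pre fit, big post
#' divergence). A degenerate zero pre-MSPE denominator is floored at
#' `mspe_floor_factor * var(treated pre-period series)` and flagged.
#'
#' @param fit A `synth_fit`.
#' @param config A [synth_config()] (supplies the floor factor).
#' @return Numeric ratio with attribute `floored` (logical).
#' @export
mspe_ratio <- function(fit, config = synth_config()) {
  floor_val <- config$mspe_floor_factor * max(fit$pre_variance, 0)
  if (floor_val <= 0) floor_val <- .Machine$double.eps
  floored <- fit$mspe_pre < floor_val
  r <- fit$mspe_post / max(fit$mspe_pre, floor_val)
  attr(r, "floored") <- floored
  r
}

#' Smallest placebo count able to reject at a given level
#'
#' The rank-based placebo test over `n` placebos plus the treated unit has
#' attainable p-value floor `1/(n+1)`; this returns the smallest `n` for
#' which that floor is strictly below `alpha`. At `alpha = 0.05` this is 20,
#' i.e. more than 20 donors are needed per grouping to be able to declare
#' significance at the 5% level.
#'
#' @param alpha Significance level in (0, 1).
#' @return Integer `n`.
#' @export
minimum_donors_for_alpha <- function(alpha) {
  stopifnot(alpha > 0, alpha < 1)
  n <- max(1L, as.integer(ceiling(1 / alpha) - 1))
  while (1 / (n + 1) >= alpha) n <- n + 1L
  n
}

#' Placebo distribution and permutation p-value for one treated reserve
#'
#' Fits one synthetic control per donor, treating that donor as the
#' pseudo-treated unit with the true treated unit added to its donor pool
#' (same intervention year and configuration). The p-value is the descending
#' rank of the treated unit's post/pre MSPE ratio among all treated + placebo
#' ratios, divided by the total count; ties are given the worst (largest)
#' rank for the treated unit. Placebo fits that fail are recorded and
#' excluded from the rank with a warning.
#'
#' @inheritParams fit_synthetic
#' @param treated_fit Optional pre-computed `synth_fit` for the treated unit
#'   (refitted if `NULL`).
#' @return A `placebo_ensemble`: `treated_id`, `unit_ratios` (named, one per
#'   unit including the treated), `treated_ratio`, `p_value`, `n_placebos`,
#'   `cannot_reach_alpha` flag, `failed_placebos`.
#' @export
placebo_distribution <- function(study, treated_id, donor_ids = NULL,
                                 intervention_year = NULL,
                                 config = synth_config(),
                                 treated_fit = NULL) {
  if (is.null(intervention_year)) {
    intervention_year <- intervention_year_of(study, treated_id)
  }
  if (is.null(donor_ids)) {
    donor_ids <- donor_ids(study, group = reserve_group(study, treated_id))
  }
  donor_ids <- sort(setdiff(donor_ids, treated_id))
  if (is.null(treated_fit)) {
    treated_fit <- fit_synthetic(study, treated_id, donor_ids,
                                 intervention_year, config)
  }
  treated_ratio <- as.numeric(mspe_ratio(treated_fit, config))

  ratios <- numeric(0)
  failed <- character(0)
  for (d in donor_ids) {
    pool <- sort(c(setdiff(donor_ids, d), treated_id))
    fit_d <- tryCatch(
      fit_synthetic(study, d, pool, intervention_year, config),
      error = function(e) NULL
    )
    if (is.null(fit_d)) {
      failed <- c(failed, d)
    } else {
      ratios[d] <- as.numeric(mspe_ratio(fit_d, config))
    }
  }
  if (length(failed) > 0) {
    warning(sprintf("%d placebo fit(s) failed and were excluded: %s",
                    length(failed), paste(failed, collapse = ", ")),
            call. = FALSE)
  }
  n_placebos <- length(ratios)
  rank_treated <- 1L + sum(ratios >= treated_ratio)  # worst rank under ties
  p_value <- rank_treated / (n_placebos + 1)
  cannot <- n_placebos < config$min_placebos
  if (cannot) {
    warning(sprintf("only %d placebos: attainable p-value floor %.3f cannot reach 0.05",
                    n_placebos, 1 / (n_placebos + 1)), call. = FALSE)
  }
  structure(
    list(treated_id = treated_id,
         unit_ratios = c(setNames(treated_ratio, treated_id), ratios),
         treated_ratio = treated_ratio,
         p_value = p_value, n_placebos = n_placebos,
         cannot_reach_alpha = cannot, failed_placebos = failed),
    class = "placebo_ensemble"
  )
}

#' @export
print.placebo_ensemble <- function(x, ...) {
  cat(sprintf("<placebo_ensemble> %s: ratio %.2f, p = %.4f (%d placebos%s)\n",
              x$treated_id, x$treated_ratio, x$p_value, x$n_placebos,
              if (x$cannot_reach_alpha) ", cannot reach 0.05" else ""))
  invisible(x)
}

#' Serialize a placebo ensemble to JSON
#'
#' @param ens A `placebo_ensemble`.
#' @param path Optional file path.
#' @return JSON string.
#' @export
ensemble_to_json <- function(ens, path = NULL) {
  obj <- list(treated_id = ens$treated_id,
              unit_ratios = as.list(ens$unit_ratios),
              treated_ratio = ens$treated_ratio, p_value = ens$p_value,
              n_placebos = ens$n_placebos,
              cannot_reach_alpha = ens$cannot_reach_alpha,
              failed_placebos = ens$failed_placebos)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Two-sample bootstrap test of equal means
#'
#' Bootstrap hypothesis test for two independent samples: both groups are
#' shifted to the pooled mean (imposing the null), resampled with
#' replacement, and the absolute difference of resampled means is compared
#' against the observed absolute difference. Used to compare pre-intervention
#' MSPE between groups of reserves (e.g. significant vs non-significant
#' fits), with the study default of 9,999 iterations.
#'
#' @param mspe_group_a,mspe_group_b Numeric vectors (non-empty).
#' @param iterations Bootstrap iterations (default 9999).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return List with `p_value`, `observed_diff`, `iterations`, `seed`.
#' @export
bootstrap_group_test <- function(mspe_group_a, mspe_group_b,
                                 iterations = 9999L, seed = 1L) {
  stopifnot(length(mspe_group_a) > 0, length(mspe_group_b) > 0,
            iterations >= 1)
  na <- length(mspe_group_a)
  nb <- length(mspe_group_b)
  obs <- abs(mean(mspe_group_a) - mean(mspe_group_b))
  pooled_mean <- mean(c(mspe_group_a, mspe_group_b))
  a0 <- mspe_group_a - mean(mspe_group_a) + pooled_mean
  b0 <- mspe_group_b - mean(mspe_group_b) + pooled_mean
  null_stats <- withr::with_seed(seed, {
    sa <- matrix(sample(a0, na * iterations, replace = TRUE), nrow = iterations)
    sb <- matrix(sample(b0, nb * iterations, replace = TRUE), nrow = iterations)
    abs(rowMeans(sa) - rowMeans(sb))
  })
  p <- (1 + sum(null_stats >= obs)) / (iterations + 1)
  list(p_value = p, observed_diff = obs, iterations = iterations, seed = seed)
}

#' Covariate balance and collinearity diagnostics
#'
#' Computes the pairwise Pearson correlation matrix of the numeric matching
#' covariates over all supplied units (flagging pairs at or above the
#' collinearity threshold, 0.8 by default as used for predictor screening)
#' and an analysis of similarities (ANOSIM) permutation test on Euclidean
#' distances of the standardized covariates between the treated and donor
#' groups. ANOSIM R near 0 with a non-significant p indicates no structural
#' difference between groups.
#'
#' @param covariates Covariate table (as in a `study_dataset`).
#' @param treated_ids,donor_ids Reserve ids of the two groups (>= 2 each).
#' @param pearson_threshold Absolute correlation at or above which a pair is
#'   flagged (default 0.8).
#' @param permutations ANOSIM permutations (default 999).
#' @param seed Integer seed for the permutation test.
#' @return A `balance_report`: `pearson_matrix`, `flagged_pairs` (tibble),
#'   `anosim_R`, `anosim_p`, `seed`.
#' @export
balance_report <- function(covariates, treated_ids, donor_ids,
                           pearson_threshold = 0.8, permutations = 999L,
                           seed = 1L) {
  stopifnot(length(treated_ids) >= 2, length(donor_ids) >= 2)
  ids <- c(treated_ids, donor_ids)
  cov <- covariates[match(ids, covariates$reserve_id), ]
  if (anyNA(cov$reserve_id)) stop("covariates missing for some unit(s)", call. = FALSE)
  X <- as.matrix(cov[, .fs_predictor_covariates])
  spread <- apply(X, 2, sd)
  if (any(spread == 0)) {
    warning(sprintf("excluding zero-variance covariate(s) from correlations: %s",
                    paste(colnames(X)[spread == 0], collapse = ", ")),
            call. = FALSE)
    X <- X[, spread > 0, drop = FALSE]
  }
  R <- cor(X)
  flag_idx <- which(abs(R) >= pearson_threshold & upper.tri(R), arr.ind = TRUE)
  flagged <- tibble::tibble(
    var1 = rownames(R)[flag_idx[, 1]],
    var2 = colnames(R)[flag_idx[, 2]],
    r = R[flag_idx]
  )
  Z <- scale(X)
  grouping <- factor(rep(c("treated", "donor"), c(length(treated_ids),
                                                  length(donor_ids))))
  an <- withr::with_seed(seed, vegan::anosim(dist(Z), grouping,
                                             permutations = permutations))
  structure(
    list(pearson_matrix = R, flagged_pairs = flagged,
         anosim_R = unname(an$statistic), anosim_p = an$signif, seed = seed),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> ANOSIM R = %.3f (p = %.3f); %d collinear pair(s) flagged\n",
              x$anosim_R, x$anosim_p, nrow(x$flagged_pairs)))
  invisible(x)
}
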