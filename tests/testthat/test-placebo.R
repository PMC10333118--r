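test_that("MSPE ratios follow hand arithmetic and floor degenerate denominators", {
  fit <- structure(list(mspe_pre = 4, mspe_post = 4, pre_variance = 1),
                   class = "synth_fit")
  expect_equal(as.numeric(mspe_ratio(fit)), 1)
  expect_false(attr(mspe_ratio(fit), "floored"))

  # hand-computed 3-pre/3-post toy: pre errors (1,2,3), post errors (2,4,6)
  fit2 <- structure(list(mspe_pre = mean(c(1, 4, 9)),
                         mspe_post = mean(c(4, 16, 36)), pre_variance = 1),
                    class = "synth_fit")
  expect_equal(as.numeric(mspe_ratio(fit2)), mean(c(4, 16, 36)) / mean(c(1, 4, 9)))

  fit3 <- structure(list(mspe_pre = 0, mspe_post = 2, pre_variance = 1),
                    class = "synth_fit")
  r <- mspe_ratio(fit3)
  expect_true(attr(r, "floored"))
  expect_equal(as.numeric(r), 2 / 1e-8)
})

test_that("the placebo-count floor for rejection matches brute force", {
  expect_identical(minimum_donors_for_alpha(0.05), 20L)
  expect_identical(minimum_donors_for_alpha(0.5), 2L)
  # brute-force oracle over n
  brute <- function(alpha) {
    n <- 1L
    while (1 / (n + 1) >= alpha) n <- n + 1L
    n
  }
  for (alpha in c(0.01, 0.05, 0.1, 0.2, 0.33)) {
    expect_identical(minimum_donors_for_alpha(alpha), brute(alpha))
  }
  expect_identical(minimum_donors_for_alpha(0.01), 100L)
})

test_that("placebo p-values use descending ranks and respect the attainable floor", {
  sim <- small_sim()
  study <- sim$study
  id <- treated_ids(study)[1]
  ens <- suppressWarnings(
    placebo_distribution(study, id, config = fast_cfg(outer_maxit = 60)))
  n <- ens$n_placebos
  expect_equal(n, 22)
  rank <- 1 + sum(ens$unit_ratios[names(ens$unit_ratios) != id] >=
                    ens$treated_ratio)
  expect_equal(ens$p_value, rank / (n + 1))
  expect_gte(ens$p_value, 1 / (n + 1))
  expect_lte(ens$p_value, 1)

  # permutation symmetry: donor order must not matter
  ens2 <- suppressWarnings(
    placebo_distribution(study, id, donor_ids = rev(donor_ids(study, "G1")),
                         config = fast_cfg(outer_maxit = 60)))
  expect_equal(ens2$p_value, ens$p_value)

  # too few placebos: flagged, p still returned
  ens3 <- suppressWarnings(
    placebo_distribution(study, id, donor_ids = donor_ids(study)[1:6],
                         config = fast_cfg(outer_maxit = 30)))
  expect_true(ens3$cannot_reach_alpha)
  expect_equal(ens3$n_placebos, 6)
})

test_that("bootstrap two-sample test is exact for identical groups and powerful at 10 SD", {
  a <- c(1, 2, 3, 4, 5)
  res <- bootstrap_group_test(a, a, iterations = 499, seed = 3)
  expect_gte(res$p_value, 0.9)

  set.seed(11)
  g1 <- rnorm(15)
  g2 <- rnorm(15) + 10
  res2 <- bootstrap_group_test(g1, g2, iterations = 9999, seed = 5)
  expect_lte(res2$p_value, 0.001)

  # deterministic given the seed
  res3 <- bootstrap_group_test(g1, g2, iterations = 9999, seed = 5)
  expect_identical(res2$p_value, res3$p_value)
})

test_that("balance reports flag perfect collinearity and separate disjoint clusters", {
  sim <- small_sim()
  cov <- sim$study$covariates
  cov$aspect <- cov$elevation        # duplicated column
  ids <- cov$reserve_id
  rep1 <- suppressWarnings(
    balance_report(cov, ids[1:2], ids[-(1:2)], seed = 1))
  expect_true(any(rep1$flagged_pairs$var1 == "elevation" &
                    rep1$flagged_pairs$var2 == "aspect" |
                  rep1$flagged_pairs$var1 == "aspect" &
                    rep1$flagged_pairs$var2 == "elevation"))
  expect_equal(max(abs(rep1$flagged_pairs$r)), 1, tolerance = 1e-12)
  expect_true(isSymmetric(rep1$pearson_matrix))
  expect_equal(unname(diag(rep1$pearson_matrix)), rep(1, ncol(rep1$pearson_matrix)))

  # two clusters 10 SD apart: R near 1, p at the permutation floor
  cov2 <- sim$study$covariates
  tr <- ids[1:6]
  num <- setdiff(names(cov2), c("reserve_id", "group"))
  for (cl in num) {
    cov2[[cl]][cov2$reserve_id %in% tr] <-
      cov2[[cl]][cov2$reserve_id %in% tr] + 10 * sd(cov2[[cl]])
  }
  rep2 <- balance_report(cov2, tr, setdiff(ids, tr), permutations = 199,
                         seed = 2)
  expect_gt(rep2$anosim_R, 0.9)
  expect_lte(rep2$anosim_p, 1 / (199 + 1) + 1e-9)

  # homogeneous data with arbitrary labels: R near 0, not significant
  rep3 <- balance_report(sim$study$covariates, ids[1:8], ids[9:24],
                         permutations = 199, seed = 3)
  expect_lt(abs(rep3$anosim_R), 0.35)
  expect_gt(rep3$anosim_p, 0.05)
})

test_that("ANOSIM statistic equals the rank-dissimilarity formula", {
  # tiny case recomputed from first principles
  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  grp <- factor(c("a", "a", "a", "b", "b", "b"))
  d <- dist(X)
  rk <- rank(d)
  between <- as.vector(outer(grp, grp, "!=")[lower.tri(diag(6))])
  n <- 6
  R_manual <- (mean(rk[between]) - mean(rk[!between])) / (n * (n - 1) / 4)
  an <- withr::with_seed(1, vegan::anosim(d, grp, permutations = 99))
  expect_equal(unname(an$statistic), R_manual, tolerance = 1e-12)
})
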