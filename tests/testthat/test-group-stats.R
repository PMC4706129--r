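test_that("omnibus ANOVA with gated post hocs handles identical and shifted groups", {
  g <- rep(c("A", "B", "C"), each = 5)
  v <- rep(c(1, 2, 3, 4, 5), 3)
  res <- anova_with_posthoc(v, g)
  expect_equal(res$F, 0)
  expect_false(any(res$pairs$significant))

  set.seed(20)
  v2 <- c(rnorm(20), rnorm(20), rnorm(20, 5))
  g2 <- rep(c("A", "B", "C"), each = 20)
  res2 <- anova_with_posthoc(v2, g2)
  expect_lt(res2$p, 1e-6)
  flags <- res2$pairs$significant
  involves_c <- res2$pairs$group1 == "C" | res2$pairs$group2 == "C"
  expect_true(all(flags[involves_c]))
  expect_false(any(flags[!involves_c]))

  # gate closed: a pairwise p below the corrected level is not flagged
  # when the omnibus misses alpha, unless gating is turned off
  set.seed(22)
  v3 <- c(rnorm(8), rnorm(8), rnorm(8, 1.1))
  g3 <- rep(c("A", "B", "C"), each = 8)
  res3 <- anova_with_posthoc(v3, g3)
  expect_gt(res3$p, 0.05)
  expect_lt(min(res3$pairs$p), 0.05 / 3)
  expect_false(any(res3$pairs$significant))
  res4 <- anova_with_posthoc(v3, g3, gate = FALSE)
  expect_true(any(res4$pairs$significant))

  # degenerate: zero variance everywhere, equal means -> no difference
  res5 <- anova_with_posthoc(rep(1, 9), rep(c("A", "B", "C"), each = 3))
  expect_false(any(res5$pairs$significant))
  expect_error(anova_with_posthoc(1:4, c("A", "A", "B", "C")), ">= 2 subjects")
})

test_that("integration averages across the full density grid only", {
  expect_equal(integrate_measure(rep(0.7, 41)), 0.7)
  expect_equal(integrate_measure(1:41), 21)
  expect_error(integrate_measure(c(1, NA, 3)), "every grid density")
  expect_error(integrate_measure(numeric(0)), "every grid density")
})

test_that("integrated t test matches the textbook formula", {
  res <- ttest_integrated(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
  rev <- ttest_integrated(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p, res$p)
  same <- ttest_integrated(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(ttest_integrated(1, c(1, 2)), ">= 2 subjects")
})

test_that("nodal consistency counts significant densities per node", {
  set.seed(30)
  n_a <- 10; n_b <- 10; n_nodes <- 6; n_dens <- 12
  a <- array(rnorm(n_a * n_nodes * n_dens), c(n_a, n_nodes, n_dens))
  b <- array(rnorm(n_b * n_nodes * n_dens), c(n_b, n_nodes, n_dens))
  # huge injected effect at node 3, all densities
  b[, 3, ] <- b[, 3, ] + 50
  S <- nodal_consistency(a, b)
  expect_equal(unname(S[3]), n_dens)
  expect_lte(max(S[-3]), 3)
  expect_true(all(S >= 0 & S <= n_dens))

  # null: mean S near alpha * n_densities
  set.seed(31)
  S_null <- replicate(20, {
    a0 <- array(rnorm(n_a * n_nodes * n_dens), c(n_a, n_nodes, n_dens))
    b0 <- array(rnorm(n_b * n_nodes * n_dens), c(n_b, n_nodes, n_dens))
    mean(nodal_consistency(a0, b0))
  })
  expect_lt(mean(S_null), 0.12 * n_dens)

  # invariant to affine rescaling of the metric
  S_aff <- nodal_consistency(a * 3 + 7, b * 3 + 7)
  expect_identical(S, S_aff)
})

test_that("spearman correlations use average ranks and a computed family size", {
  clin <- data.frame(MMSE = c(1, 2, 3, 4, 5), CAMCOG = c(2, 4, 6, 8, 10),
                     CAF = c(5, 4, 3, 2, 1), NPI_hall = c(1, 1, 2, 2, 3),
                     UPDRS = c(2, 3, 1, 5, 4))
  integ <- data.frame(C = c(1, 2, 3, 4, 5), L = c(5, 6, 7, 8, 7),
                      E = c(2, 1, 4, 3, 5), Q = c(1, 3, 2, 5, 4),
                      C_norm = c(9, 7, 8, 6, 5), L_norm = c(1, 2, 4, 3, 5),
                      sigma = c(2, 4, 1, 3, 5))
  res <- spearman_clinical(clin, integ)
  expect_equal(attr(res, "family_size"), 35L)
  expect_equal(nrow(res), 35L)
  expect_equal(res$rho[res$score == "MMSE" & res$measure == "C"], 1)
  # tie-corrected rank formula, oracle value 8 / sqrt(10 * 9.5)
  rho_tie <- res$rho[res$score == "MMSE" & res$measure == "L"]
  expect_equal(rho_tie, 8 / sqrt(10 * 9.5), tolerance = 1e-10)
  expect_equal(rho_tie,
               unname(suppressWarnings(cor.test(clin$MMSE, integ$L,
                                                method = "spearman",
                                                exact = FALSE)$estimate)))
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_error(spearman_clinical(clin[1:3, ], integ[1:3, ]), "4 subjects")
})

test_that("kruskal-wallis motion test separates shifted groups only", {
  g <- rep(c("A", "B", "C"), each = 5)
  flat <- kruskal_wallis_motion(rep(1:5, 3), g)
  expect_equal(flat$H, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1, tolerance = 1e-9)

  set.seed(40)
  v <- c(rnorm(17), rnorm(17), rnorm(17, 10))
  g2 <- rep(c("A", "B", "C"), each = 17)
  res <- kruskal_wallis_motion(v, g2)
  expect_lt(res$p, 0.01)
  expect_error(kruskal_wallis_motion(1:3, c("A", "B", "C")), ">= 2 subjects")
})

test_that("group-level directional findings recover from default synthetic cohorts", {
  res <- recovery_results()
  # DLB regularization: higher sigma and E than the AD-like group, lower C
  # than controls, in the majority of cohort seeds
  expect_gte(count_seeds_greater(res, "sigma", "DLB", "AD"), 6L)
  expect_gte(count_seeds_greater(res, "E", "DLB", "AD"), 6L)
  expect_gte(count_seeds_greater(res, "C", "HC", "DLB"), 6L)
  # edge displacement: attenuated long-range coupling surfaces as extra
  # short-range edges at fixed density
  expect_gte(count_seeds_greater(res, "short_edges_d19", "DLB", "HC"), 8L)
})
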