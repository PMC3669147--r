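test_that("area-corrected estimator matches the closed form", {
  d <- counts_from_totals("ctrl", M = 360, S = 1)
  est <- estimate_probability(d)
  expect_equal(unname(est$per_treatment), 0.9)     # 360 / (360 + 40*1)
  expect_equal(estimate_probability(d, estimator = "literal")$per_observation$P,
               360 / 361)

  # boundaries: S = 0 -> P = 1; M = 0 -> P = 0, both estimators
  expect_equal(estimate_probability(counts_from_totals("t", 5, 0))$per_observation$P, 1)
  expect_equal(estimate_probability(counts_from_totals("t", 0, 3))$per_observation$P, 0)
  expect_equal(estimate_probability(counts_from_totals("t", 5, 0),
                                    estimator = "literal")$per_observation$P, 1)
  expect_equal(estimate_probability(counts_from_totals("t", 0, 3),
                                    estimator = "literal")$per_observation$P, 0)
})

test_that("fields are aggregated per replicate before estimation", {
  d <- data.frame(treatment = "t", replicate = 1, field = c(1:3, 1:2),
                  compartment = c(rep("migrated", 3), rep("non_migrated", 2)),
                  count = c(100, 150, 110, 3, 6))
  est <- estimate_probability(d)
  expect_equal(est$per_observation$M, 360)
  expect_equal(est$per_observation$S, 9)
  expect_equal(est$per_observation$P, 360 / (360 + 40 * 9))
})

test_that("scaling all counts leaves the literal estimator unchanged", {
  set.seed(71)
  d <- gen_migration_counts(c(A = 0.8, B = 0.6), 400, n_replicates = 3,
                            seed = 71)
  d2 <- d; d2$count <- d2$count * 7L
  expect_equal(estimate_probability(d, estimator = "literal")$per_treatment,
               estimate_probability(d2, estimator = "literal")$per_treatment)
})

test_that("uninformative observations are excluded with a warning", {
  d <- rbind(counts_from_totals("t", c(10, 0), c(2, 0)))
  expect_warning(est <- estimate_probability(d), "excluding 1")
  expect_equal(nrow(est$per_observation), 1)
  d0 <- counts_from_totals("t", 0, 0)
  expect_warning(expect_error(estimate_probability(d0), "no informative"))
  # a replicate missing one compartment entirely is a design error
  dbad <- data.frame(treatment = "t", replicate = 1, field = 1,
                     compartment = "migrated", count = 5)
  expect_error(estimate_probability(dbad), "compartment")
})

test_that("per-field mode spreads the non-migrated total over fields", {
  d <- data.frame(treatment = "t", replicate = 1, field = c(1:2, 1),
                  compartment = c("migrated", "migrated", "non_migrated"),
                  count = c(90, 110, 2))
  est <- estimate_probability(d, unit = "field")
  expect_equal(nrow(est$per_observation), 2)
  expect_equal(est$per_observation$P,
               c(90 / (90 + 40 * 1), 110 / (110 + 40 * 1)))
})

test_that("permutation p-value equals exhaustive enumeration on 3-vs-3", {
  d <- rbind(counts_from_totals("A", M = c(1, 1, 1), S = c(9, 9, 9)),
             counts_from_totals("B", M = c(9, 9, 9), S = c(1, 1, 1)))
  res <- permutation_test(d, estimator = "literal", n_permutations = 1000)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_permutations, 20)        # C(6,3) assignments
  expect_equal(res$p_value, 2 / 20)           # the two extreme labelings
  expect_equal(abs(res$observed_diff), 0.8)

  # identical constant groups: zero difference, p = 1
  d0 <- rbind(counts_from_totals("A", c(5, 5, 5), c(5, 5, 5)),
              counts_from_totals("B", c(5, 5, 5), c(5, 5, 5)))
  res0 <- permutation_test(d0, estimator = "literal")
  expect_equal(res0$observed_diff, 0)
  expect_equal(res0$p_value, 1)
})

test_that("exhaustive p-value matches an independent enumeration oracle", {
  set.seed(72)
  for (i in 1:10) {
    MA <- sample(5:50, 3); SA <- sample(0:5, 3, replace = TRUE)
    MB <- sample(5:50, 4); SB <- sample(0:5, 4, replace = TRUE)
    d <- rbind(counts_from_totals("A", MA, SA),
               counts_from_totals("B", MB, SB))
    res <- permutation_test(d, n_permutations = 1000)
    PA <- MA / (MA + 40 * SA); PB <- MB / (MB + 40 * SB)
    expect_equal(res$p_value, oracle_exhaustive_perm_p(PA, PB))
  }
})

test_that("permutation test is seed-reproducible and label-invariant", {
  d <- gen_migration_counts(c(A = 0.85, B = 0.9), 500, n_replicates = 10,
                            seed = 73)
  r1 <- permutation_test(d, n_permutations = 500, seed = 99)
  r2 <- permutation_test(d, n_permutations = 500, seed = 99)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$method, "monte_carlo")
  expect_gte(r1$p_value, 1 / 501)

  # relabel treatments and shuffle rows: same p-value
  d_swap <- d
  d_swap$treatment <- ifelse(d$treatment == "A", "B", "A")
  d_swap <- d_swap[sample(nrow(d_swap)), ]
  r3 <- permutation_test(d_swap, n_permutations = 500, seed = 99)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$observed_diff, -r1$observed_diff)

  expect_error(permutation_test(counts_from_totals("A", c(3, 3), c(1, 1))),
               "two treatments")
})

test_that("bootstrap CIs bracket the estimate and are seed-stable", {
  d <- counts_from_totals("t", M = c(9, 9, 9), S = c(1, 1, 1))
  ci_const <- bootstrap_ci(d, estimator = "literal", n_bootstrap = 200,
                           seed = 1)
  expect_equal(ci_const$lower, ci_const$upper)   # identical observations

  set.seed(74)
  d2 <- gen_migration_counts(c(t = 0.9), 800, n_replicates = 8, seed = 74)
  ci1 <- bootstrap_ci(d2, n_bootstrap = 500, seed = 7)
  ci2 <- bootstrap_ci(d2, n_bootstrap = 500, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$estimate)
  expect_gte(ci1$upper, ci1$estimate)
  expect_equal(ci1$level, 0.95)

  d1 <- counts_from_totals("t", 9, 1)
  expect_warning(ci_deg <- bootstrap_ci(d1), "single observation")
  expect_equal(ci_deg$lower, ci_deg$upper)
})

test_that("migration_inference bundles the three analyses reproducibly", {
  d <- gen_migration_counts(c(A = 0.85, B = 0.92), 600, n_replicates = 6,
                            seed = 75)
  inf1 <- migration_inference(d, n_permutations = 300, n_bootstrap = 300,
                              seed = 42)
  inf2 <- migration_inference(d, n_permutations = 300, n_bootstrap = 300,
                              seed = 42)
  expect_identical(inf1$permutation$p_value, inf2$permutation$p_value)
  expect_identical(inf1$bootstrap, inf2$bootstrap)
  expect_named(inf1$estimate$per_treatment, c("A", "B"))
})

test_that("per-field permutation detects a 0.02 probability separation more often than not", {
  # Directional power check in the per-field mode (the mode that mirrors
  # per-observation dot plots): with ~0.02 separation at U=1000 the test
  # should reject more often than not. Replicate-level inference is much
  # less powerful here because Poisson noise in A*S dominates.
  set.seed(76)
  rej <- vapply(1:40, function(i) {
    d <- gen_migration_counts(c(ctrl = 0.918, trt = 0.898), 1000,
                              n_replicates = 8, seed = 7600 + i)
    permutation_test(d, n_permutations = 400, seed = 7700 + i,
                     unit = "field")$p_value <= 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.5)
})
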