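make_wells <- function(cond_ratios, ref = 500) {
  do.call(rbind, lapply(names(cond_ratios), function(cond) {
    r <- cond_ratios[[cond]]
    data.frame(condition = cond, replicate = seq_along(r),
               firefly = r * ref, renilla = ref)
  }))
}

test_that("normalization maps the control to 1 and divides by its mean", {
  wells <- make_wells(list(ctrl = c(2, 2, 2)))
  norm <- normalize_wells(wells, "firefly_over_renilla", "ctrl")
  expect_equal(norm$normalized_activity, 1)

  wells2 <- make_wells(list(A = c(2, 2, 2), ctrl = c(4, 4, 4)))
  norm2 <- normalize_wells(wells2, "firefly_over_renilla", "ctrl")
  expect_equal(norm2$normalized_activity[norm2$condition == "A"], 0.5)
  expect_equal(norm2$normalized_activity[norm2$condition == "ctrl"], 1)

  # control maps to exactly 1 whatever the data
  set.seed(61)
  wells3 <- make_wells(list(A = runif(3, 1, 3), B = runif(3, 1, 3),
                            ctrl = runif(3, 1, 3)))
  norm3 <- normalize_wells(wells3, "firefly_over_renilla", "ctrl")
  expect_equal(norm3$normalized_activity[norm3$condition == "ctrl"], 1)
})

test_that("orientation swap inverts the per-well ratio", {
  wells <- make_wells(list(A = c(2, 2, 2), ctrl = c(4, 4, 4)))
  fr <- normalize_wells(wells, "firefly_over_renilla", "ctrl")
  rf <- normalize_wells(wells, "renilla_over_firefly", "ctrl")
  expect_equal(fr$mean_ratio * rf$mean_ratio, rep(1, 2))
  # with constant within-condition ratios, normalized activities invert too
  expect_equal(rf$normalized_activity[rf$condition == "A"], 2)
})

test_that("normalization rejects bad wells and missing controls", {
  wells <- make_wells(list(A = c(2, 2), ctrl = c(4, 4)))
  expect_error(normalize_wells(wells, "firefly_over_renilla", "nope"),
               "control condition")
  wells$firefly[1] <- 0
  expect_error(normalize_wells(wells, "firefly_over_renilla", "ctrl"),
               "condition 'A', replicate 1")
})

test_that("baseline is the mean of the negative controls", {
  norm <- tibble::tibble(condition = c("n1", "n2", "x"),
                         normalized_activity = c(0.15, 0.20, 0.5))
  bl <- unrepressed_baseline(norm, c("n1", "n2"))
  expect_equal(bl$value, 0.175)
  expect_equal(unrepressed_baseline(norm, c("n1", "n1"))$value, 0.15)
  expect_warning(unrepressed_baseline(norm, "n2"), "single negative control")
  expect_error(unrepressed_baseline(norm, "missing"), "unknown")
})

test_that("repression percent reproduces the sign conventions", {
  bl <- structure(list(value = 0.2, source_conditions = "n"),
                  class = "reporter_baseline")
  expect_equal(repression_percent(0.56 * 0.2, bl), 44)
  expect_equal(repression_percent(0.2, bl), 0)
  expect_equal(repression_percent(0.3, bl), -50)  # de-repression
  expect_error(repression_percent(0.1, 0), "baseline")
})

test_that("synergy calls follow the independence expectation", {
  expect_equal(synergy_call(0.44, 0, 0.44)$expected_additive, 0.44)
  sc <- synergy_call(0.44, 0.17, 0.5352)
  expect_equal(sc$expected_additive, 1 - 0.56 * 0.83)
  expect_equal(sc$verdict, "additive")

  # no single effect + strong combined effect = synergy
  expect_equal(synergy_call(0, 0.05, 0.78, tolerance = 0.05)$verdict,
               "synergistic")
  expect_equal(synergy_call(0.4, 0.4, 0.3)$verdict, "sub-additive")
  expect_error(synergy_call(1.2, 0, 0.5), "exceed 1")

  # symmetry and the lower bound max(a, b) on [0,1]
  set.seed(62)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    expect_equal(synergy_call(a, b, 0.5)$expected_additive,
                 synergy_call(b, a, 0.5)$expected_additive)
    expect_gte(synergy_call(a, b, 0.5)$expected_additive, max(a, b) - 1e-12)
  }
})

test_that("t-test reproduces the pooled-variance closed form", {
  res <- two_sided_t_test(c(1, 2, 3), c(2, 3, 4), variant = "student")
  expect_equal(res$t_statistic, -sqrt(3) / sqrt(2), tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.287865, tolerance = 1e-4)

  same <- two_sided_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # antisymmetry
  swap <- two_sided_t_test(c(2, 3, 4), c(1, 2, 3), variant = "student")
  expect_equal(swap$t_statistic, -res$t_statistic)
  expect_equal(swap$p_value, res$p_value)

  # degenerate samples
  expect_equal(two_sided_t_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(two_sided_t_test(c(2, 2), c(3, 3)), "zero variance")
  expect_error(two_sided_t_test(1, c(1, 2)), "n >= 2")

  w <- two_sided_t_test(c(1, 2, 3), c(2, 3, 4, 10), variant = "welch")
  expect_lt(w$df, 5)  # Welch df is fractional and below pooled df
})

test_that("relative quantities follow the efficiency-2 formulas", {
  expect_equal(relative_quantity(list(target_ct = 25, reference_ct = 20),
                                 "delta_ct"), 2^-5)
  cal <- list(target_ct = 22, reference_ct = 20)
  m0 <- list(target_ct = 22, reference_ct = 20)       # ddCt = 0
  expect_equal(relative_quantity(m0, "delta_delta_ct", cal), 1)
  m2 <- list(target_ct = 24, reference_ct = 20)       # ddCt = 2
  expect_equal(relative_quantity(m2, "delta_delta_ct", cal), 0.25)
  expect_error(relative_quantity(m2, "delta_delta_ct"), "calibrator")
  expect_error(relative_quantity(list(target_ct = 50, reference_ct = 20),
                                 "delta_ct"), "0, 45")

  # strictly decreasing in delta-delta-Ct; one fewer cycle doubles RQ
  rqs <- vapply(20:26, function(ct) {
    relative_quantity(list(target_ct = ct, reference_ct = 20),
                      "delta_delta_ct", cal)
  }, 1.0)
  expect_true(all(diff(rqs) < 0))
  expect_equal(rqs[1:6] / rqs[2:7], rep(2, 6))
})

test_that("qpcr_quantify handles tables with a calibrator sample", {
  tab <- tibble::tibble(sample = c("calibrator", "kd"),
                        target_ct = c(20, 22), reference_ct = c(18, 18))
  rq <- qpcr_quantify(tab, "delta_delta_ct", calibrator = "calibrator")
  expect_equal(rq$rq, c(1, 0.25))
  expect_error(qpcr_quantify(tab, "delta_delta_ct", calibrator = "zz"),
               "not found")
})

test_that("planted repression is recovered from noisy synthetic plates", {
  set.seed(63)
  reps <- vapply(1:200, function(i) {
    wells <- gen_luciferase_plate(
      c("miR-x" = 0.44, "neg1" = 0, "neg2" = 0),
      noise_cv = 0.1, seed = 6000 + i)
    norm <- normalize_wells(wells, "firefly_over_renilla", "empty_vector")
    bl <- unrepressed_baseline(norm, c("neg1", "neg2"))
    repression_percent(
      norm$normalized_activity[norm$condition == "miR-x"], bl)
  }, 1.0)
  expect_lt(abs(mean(reps) - 44), 1)
})
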