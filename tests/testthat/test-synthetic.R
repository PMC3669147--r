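test_that("migration count generator hits the model expectations", {
  # E(total migrated) = p*U = 459; E(total non-migrated) = (1-p)*U/A = 1.025
  n <- 10000
  d <- gen_migration_counts(c(t = 0.918), 500, n_replicates = n, seed = 81)
  agg <- estimate_probability(d)$per_observation
  expect_equal(nrow(agg), n)
  expect_lt(abs(mean(agg$M) - 459) / 459, 0.01)           # within 1%
  expect_lt(abs(mean(agg$M) - 459), 4 * sqrt(459 / n))    # CLT band
  expect_lt(abs(mean(agg$S) - 1.025), 4 * sqrt(1.025 / n))

  # p -> 1 limit: the non-migrated expectation vanishes
  d1 <- gen_migration_counts(c(t = 0.999), 500, n_replicates = 200, seed = 82)
  s_tot <- sum(d1$count[d1$compartment == "non_migrated"])
  expect_lt(s_tot / 200, 0.1)
})

test_that("generators are pure functions of their seed", {
  a <- gen_migration_counts(c(A = 0.9, B = 0.8), 500, n_replicates = 3,
                            seed = 83)
  b <- gen_migration_counts(c(A = 0.9, B = 0.8), 500, n_replicates = 3,
                            seed = 83)
  expect_identical(a, b)
  c <- gen_migration_counts(c(A = 0.9, B = 0.8), 500, n_replicates = 3,
                            seed = 84)
  expect_false(identical(a, c))

  p1 <- gen_luciferase_plate(c(x = 0.4, neg = 0), seed = 85)
  p2 <- gen_luciferase_plate(c(x = 0.4, neg = 0), seed = 85)
  expect_identical(p1, p2)

  q1 <- gen_ct_table(c(kd = 0.25), noise_sd = 0.2, seed = 86)
  q2 <- gen_ct_table(c(kd = 0.25), noise_sd = 0.2, seed = 86)
  expect_identical(q1, q2)

  g1 <- gen_utr(100, seed = 87)
  g2 <- gen_utr(100, seed = 87)
  expect_identical(g1$record$residues, g2$record$residues)
})

test_that("per-treatment and per-replicate U specifications are honored", {
  d <- gen_migration_counts(c(A = 0.5, B = 0.5),
                            U = c(A = 200, B = 2000),
                            n_replicates = 50, seed = 88)
  agg <- estimate_probability(d)$per_observation
  expect_lt(mean(agg$M[agg$treatment == "A"]), 200)
  expect_gt(mean(agg$M[agg$treatment == "B"]), 500)

  dl <- gen_migration_counts(c(A = 0.5), U = list(A = c(100, 4000)),
                             n_replicates = 2, seed = 89)
  aggl <- estimate_probability(dl)$per_observation
  expect_gt(aggl$M[aggl$replicate == 2], aggl$M[aggl$replicate == 1])
})

test_that("noiseless plates are exact and the control recovers zero repression", {
  wells <- gen_luciferase_plate(c("miR-x" = 0.44, neg = 0), noise_cv = 0,
                                seed = 91)
  ratios <- wells$firefly / wells$renilla
  expect_equal(ratios[wells$condition == "miR-x"],
               rep(0.176 * 0.56, 3))
  expect_equal(ratios[wells$condition == "empty_vector"], rep(1, 3))
  norm <- normalize_wells(wells, "firefly_over_renilla", "empty_vector")
  bl <- unrepressed_baseline(norm, "neg") |> suppressWarnings()
  expect_equal(repression_percent(
    norm$normalized_activity[norm$condition == "miR-x"], bl), 44)
  expect_equal(repression_percent(
    norm$normalized_activity[norm$condition == "neg"], bl), 0)

  # orientation flag swaps the channels
  w2 <- gen_luciferase_plate(c(neg = 0), noise_cv = 0,
                             orientation = "renilla_over_firefly", seed = 92)
  expect_equal(unique(w2$firefly[w2$condition == "empty_vector"]), 1e5)
  expect_equal(w2$renilla[w2$condition == "neg"] / w2$firefly[w2$condition == "neg"],
               rep(0.176, 3))
})

test_that("planted UTR truth tables are recovered exactly by the scanner", {
  mirA <- mature_mirna("mirA", "UAGCAGCACGUAAAUAUUGGCG")
  mirB <- mature_mirna("mirB", "UCGAGGAGCUCACAGUCUAGUA")
  patA <- seed_site_patterns(mirA)[["8mer"]]    # length 8
  patB <- seed_site_patterns(mirB)[["7mer-m8"]] # length 7
  gu <- gen_utr(120, planted = list(
    list(kind = "seed_site", mirna = mirA, class = "8mer", start = 30L),
    list(kind = "seed_site", mirna = mirB, class = "7mer-m8", start = 44L),
    list(kind = "polyA_signal", pattern = "AATAAA", start = 100L)),
    mirnas = list(mirA, mirB), seed = 93)
  sites <- scan_seed_sites(gu$record, list(mirA, mirB))
  truth <- gu$truth[gu$truth$kind == "seed_site", ]
  expect_identical(
    sort(paste(sites$mirna, sites$site_class, sites$start)),
    sort(paste(truth$label, truth$site_class, truth$start)))
  # planted gap: site ends at 38, next begins at 44 -> 6 nt apart
  pairs <- cooperative_pairs(sites)
  expect_equal(pairs$gap_nt, 6L)
  expect_true(pairs$within_optimum)
  motifs <- find_motifs(gu$record, "polyA_signal")
  expect_true(any(motifs$start == 100L))
})

test_that("a 394 nt planted gap falls outside the cooperative window", {
  mirA <- mature_mirna("mirA", "UAGCAGCACGUAAAUAUUGGCG")
  mirB <- mature_mirna("mirB", "UCGAGGAGCUCACAGUCUAGUA")
  gu <- gen_utr(500, planted = list(
    list(kind = "seed_site", mirna = mirA, class = "8mer", start = 10L),
    list(kind = "seed_site", mirna = mirB, class = "7mer-m8", start = 412L)),
    mirnas = list(mirA, mirB), seed = 94)
  sites <- scan_seed_sites(gu$record, list(mirA, mirB))
  pairs <- cooperative_pairs(sites, all = TRUE)
  expect_equal(pairs$gap_nt, 394L)
  expect_false(pairs$within_optimum)
})

test_that("backgrounds without planted sites carry no accidental sites", {
  set.seed(95)
  mirs <- lapply(1:3, function(i) mature_mirna(paste0("m", i),
                                               random_mirna_seq()))
  for (i in 1:100) {
    gu <- gen_utr(500, planted = list(), mirnas = mirs, seed = 9500 + i)
    expect_equal(nrow(scan_seed_sites(gu$record, mirs)), 0)
  }
})

test_that("planted spans are validated", {
  mir <- mature_mirna("m", "UAGCAGCACGUAAAUAUUGGCG")
  expect_error(gen_utr(20, planted = list(
    list(kind = "seed_site", mirna = mir, class = "8mer", start = 15L)),
    seed = 1), "out of bounds")
  expect_error(gen_utr(60, planted = list(
    list(kind = "seed_site", mirna = mir, class = "8mer", start = 10L),
    list(kind = "seed_site", mirna = mir, class = "8mer", start = 14L)),
    seed = 1), "overlap")
})

test_that("Ct tables recover fold changes through the ddCt pipeline", {
  tab0 <- gen_ct_table(c(up = 4, down = 0.25), noise_sd = 0, seed = 96)
  rq0 <- qpcr_quantify(tab0, "delta_delta_ct", calibrator = "calibrator")
  expect_equal(rq0$rq[rq0$sample == "calibrator"], 1)
  expect_equal(rq0$rq[rq0$sample == "up"], 4)
  expect_equal(rq0$rq[rq0$sample == "down"], 0.25)

  # noisy recovery: geometric mean over repeats within 5% of truth
  set.seed(97)
  rqs <- vapply(1:200, function(i) {
    tab <- gen_ct_table(c(kd = 0.25), noise_sd = 0.2, seed = 9700 + i)
    qpcr_quantify(tab, "delta_delta_ct",
                  calibrator = "calibrator")$rq[tab$sample == "kd"]
  }, 1.0)
  expect_lt(abs(exp(mean(log(rqs))) / 0.25 - 1), 0.05)
})

test_that("estimates recover generator truth across both stages", {
  # parameter recovery: estimator mean close to truth at moderate scale
  d <- gen_migration_counts(c(A = 0.9, B = 0.5), 1000, n_replicates = 300,
                            seed = 98)
  p_hat <- estimate_probability(d)$per_treatment
  expect_lt(abs(p_hat[["A"]] - 0.9), 0.015)
  expect_lt(abs(p_hat[["B"]] - 0.5), 0.02)
})
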