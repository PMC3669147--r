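# Two-compartment transwell migration statistics.
#
# In a transwell assay, migrated cells (filter underside) and non-migrated
# cells (topside) are counted in separate microscopic fields that sample
# macroscopic areas of different size. With M and S the migrated and
# non-migrated counts of a replicate, p the migration probability and U the
# expected number of cells loaded, the count model is
#
#     E(M) = p * U,       E(S) = (1 - p) * U / A,
#
# where A is the area factor between the two sampled regions (A = 40 for
# the 10x/5x field layout this model was built for). The method-of-moments
# estimator consistent with those expectations rescales the non-migrated
# count by A before forming the migrated fraction:
#
#     P = M / (M + A * S)        ("area_corrected", default)
#
# so that E(P) ~ p to first order. The "literal" estimator P = M / (M + S)
# is also available for data whose S column has already been area-scaled
# upstream. Significance of a two-treatment difference is assessed by Monte
# Carlo permutation of treatment labels over replicate-level observations,
# and uncertainty by a non-parametric percentile bootstrap.

#' Transwell design constants
#'
#' @param area_factor Ratio A of the macroscopic areas sampled for
#'   non-migrated versus migrated counts (default 40).
#' @param fields_migrated Microscopic fields counted on the migrated side
#'   per insert (default 10).
#' @param fields_nonmigrated Fields counted on the non-migrated side
#'   (default 5).
#' @return An object of class `migration_design`.
#' @export
migration_design <- function(area_factor = 40, fields_migrated = 10,
                             fields_nonmigrated = 5) {
  if (!(area_factor > 0)) stopf("`area_factor` must be > 0")
  if (fields_migrated < 1 || fields_nonmigrated < 1) {
    stopf("field counts must be >= 1")
  }
  structure(list(area_factor = area_factor,
                 fields_migrated = as.integer(fields_migrated),
                 fields_nonmigrated = as.integer(fields_nonmigrated)),
            class = "migration_design")
}

validate_migration_counts <- function(counts) {
  req <- c("treatment", "replicate", "field", "compartment", "count")
  if (!all(req %in% names(counts))) {
    stopf("`counts` must have columns %s", paste(req, collapse = ", "))
  }
  if (!all(counts$compartment %in% c("migrated", "non_migrated"))) {
    stopf("`compartment` must be 'migrated' or 'non_migrated'")
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stopf("counts must be non-negative integers")
  }
  invisible(counts)
}

#' Estimate per-treatment migration probabilities from field counts
#'
#' Field counts are aggregated to the replicate (insert-pair) level: M is
#' the sum of migrated-field counts and S the sum of non-migrated-field
#' counts of a replicate. The area-corrected estimator forms
#' `P = M / (M + A * S)` per replicate (the literal estimator omits A), and
#' the per-treatment estimate is the mean of its replicates' P values.
#' Replicates with M = S = 0 carry no information and are excluded with a
#' warning. With `unit = "field"` each migrated field becomes its own
#' observation, paired with its replicate's area-corrected non-migrated
#' total spread evenly over the migrated fields
#' (`P_m = M_m / (M_m + A * S / n_fields)`); this reproduces
#' per-observation dot-plots but the observations share S within a
#' replicate and are therefore correlated -- use replicate-level
#' observations for inference.
#'
#' @param counts Data frame of field counts with columns `treatment`,
#'   `replicate`, `field`, `compartment` (`"migrated"`/`"non_migrated"`),
#'   `count`.
#' @param design A [migration_design].
#' @param estimator `"area_corrected"` (default) or `"literal"`.
#' @param unit Observation unit: `"replicate"` (default) or `"field"`.
#' @return An object of class `migration_estimate`: `per_observation`
#'   tibble (`treatment`, `replicate`, `M`, `S`, `P`) and `per_treatment`
#'   named vector of p-hat values.
#' @examples
#' d <- data.frame(treatment = "ctrl", replicate = 1, field = 1:2,
#'                 compartment = c("migrated", "non_migrated"),
#'                 count = c(360, 1))
#' estimate_probability(d)$per_treatment  # 360 / (360 + 40) = 0.9
#' @export
estimate_probability <- function(counts, design = migration_design(),
                                 estimator = c("area_corrected", "literal"),
                                 unit = c("replicate", "field")) {
  estimator <- match.arg(estimator)
  unit <- match.arg(unit)
  stopifnot(inherits(design, "migration_design"))
  validate_migration_counts(counts)
  A <- if (estimator == "area_corrected") design$area_factor else 1

  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(counts), treatment, replicate),
    M = sum(count[compartment == "migrated"]),
    S = sum(count[compartment == "non_migrated"]),
    n_mig_fields = sum(compartment == "migrated"),
    n_non_fields = sum(compartment == "non_migrated"),
    .groups = "drop")
  if (any(agg$n_mig_fields == 0) || any(agg$n_non_fields == 0)) {
    stopf("every (treatment, replicate) needs at least one field per compartment")
  }
  agg <- agg[order(agg$treatment, agg$replicate), ]

  if (unit == "replicate") {
    empty <- agg$M + agg$S == 0
    if (any(empty)) {
      warnf("excluding %d observation(s) with no cells counted", sum(empty))
      agg <- agg[!empty, , drop = FALSE]
    }
    if (nrow(agg) == 0) stopf("no informative observations left")
    per_obs <- tibble::tibble(treatment = agg$treatment,
                              replicate = agg$replicate,
                              M = agg$M, S = agg$S,
                              P = agg$M / (agg$M + A * agg$S))
  } else {
    mig <- counts[counts$compartment == "migrated", , drop = FALSE]
    key <- paste(mig$treatment, mig$replicate, sep = "\r")
    akey <- paste(agg$treatment, agg$replicate, sep = "\r")
    S_tot <- unname(setNames(agg$S, akey)[key])
    n_fld <- unname(setNames(agg$n_mig_fields, akey)[key])
    S_share <- S_tot / n_fld
    denom <- mig$count + A * S_share
    empty <- denom == 0
    if (any(empty)) {
      warnf("excluding %d field observation(s) with no cells counted",
            sum(empty))
    }
    per_obs <- tibble::tibble(treatment = mig$treatment[!empty],
                              replicate = mig$replicate[!empty],
                              M = mig$count[!empty], S = S_share[!empty],
                              P = mig$count[!empty] / denom[!empty])
    if (nrow(per_obs) == 0) stopf("no informative observations left")
    per_obs <- per_obs[order(per_obs$treatment, per_obs$replicate), ]
  }
  p_hat <- tapply(per_obs$P, per_obs$treatment, mean)
  structure(list(per_observation = per_obs,
                 per_treatment = setNames(as.numeric(p_hat), names(p_hat)),
                 estimator = estimator, unit = unit, design = design),
            class = "migration_estimate")
}

#' @export
print.migration_estimate <- function(x, ...) {
  cat(sprintf("<migration_estimate> (%s, per-%s) %d observations\n",
              x$estimator, x$unit, nrow(x$per_observation)))
  for (t in names(x$per_treatment)) {
    cat(sprintf("  %s: p-hat = %.4f\n", t, x$per_treatment[[t]]))
  }
  invisible(x)
}

perm_diffs_exhaustive <- function(P, nA) {
  n <- length(P)
  tot <- sum(P)
  cmb <- combn(n, nA)
  sums <- colSums(matrix(P[cmb], nrow = nA))
  sums / nA - (tot - sums) / (n - nA)
}

#' Monte Carlo permutation test for a two-treatment migration difference
#'
#' The statistic is the difference of per-treatment mean migration
#' probabilities over observation-level P values. Treatment labels are
#' permuted across observations, preserving group sizes; the two-sided
#' p-value uses add-one smoothing, `p = (1 + #{|d*| >= |d_obs|}) /
#' (1 + n_permutations)`, so it is never 0. When the number of distinct
#' label assignments is at most `n_permutations` the test switches to
#' exhaustive enumeration automatically and the p-value is exact
#' (`#{|d*| >= |d_obs|} / n_assignments`, the identity assignment
#' included).
#'
#' @inheritParams estimate_probability
#' @param n_permutations Number of random permutations (default 10000).
#' @param seed Integer seed making the Monte Carlo draw reproducible;
#'   `NULL` leaves the RNG state alone.
#' @return Object of class `migration_permutation`: `observed_diff`
#'   (first treatment in sorted label order minus the second), `p_value`,
#'   `n_permutations` (number actually evaluated), `method`
#'   (`"exhaustive"` or `"monte_carlo"`), `treatments`, `estimate`.
#' @export
permutation_test <- function(counts, design = migration_design(),
                             estimator = "area_corrected",
                             n_permutations = 10000, seed = NULL,
                             unit = "replicate") {
  est <- estimate_probability(counts, design = design, estimator = estimator,
                              unit = unit)
  treatments <- sort(names(est$per_treatment))
  if (length(treatments) != 2) {
    stopf("permutation test requires exactly two treatments (got %d)",
          length(treatments))
  }
  obs <- est$per_observation
  PA <- obs$P[obs$treatment == treatments[[1]]]
  PB <- obs$P[obs$treatment == treatments[[2]]]
  if (length(PA) < 2 || length(PB) < 2) {
    stopf("need at least two observations per treatment")
  }
  observed <- mean(PA) - mean(PB)
  # Canonical pool: sorted values, subsets drawn at the smaller group size.
  # |diff| is invariant under complementing the subset, so this makes the
  # p-value bit-identical under treatment relabeling and input row order.
  P <- sort(c(PA, PB))
  n <- length(P)
  k <- min(length(PA), length(PB))
  tol <- 1e-12
  n_assign <- choose(n, k)
  if (n_assign <= n_permutations) {
    diffs <- perm_diffs_exhaustive(P, k)
    p <- sum(abs(diffs) >= abs(observed) - tol) / length(diffs)
    method <- "exhaustive"
    n_done <- length(diffs)
  } else {
    tot <- sum(P)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(i) {
        s <- sum(P[sample.int(n, k)])
        abs(s / k - (tot - s) / (n - k)) >= abs(observed) - tol
      }, TRUE))
    })
    p <- (1 + hits) / (1 + n_permutations)
    method <- "monte_carlo"
    n_done <- n_permutations
  }
  structure(list(observed_diff = observed, p_value = p,
                 n_permutations = n_done, method = method,
                 treatments = treatments, seed = seed, estimate = est),
            class = "migration_permutation")
}

#' @export
print.migration_permutation <- function(x, ...) {
  cat(sprintf(
    "<migration_permutation> %s - %s = %.5f; p = %.6g (%s, %d permutations)\n",
    x$treatments[[1]], x$treatments[[2]], x$observed_diff, x$p_value,
    x$method, x$n_permutations))
  invisible(x)
}

#' Non-parametric bootstrap confidence intervals for migration probabilities
#'
#' Observations (replicate-level P values) are resampled with replacement
#' within each treatment; the per-treatment estimate is recomputed on each
#' resample and the percentile interval at the requested level is reported.
#' Deterministic given `seed`. A treatment with a single observation yields
#' a degenerate interval with a warning.
#'
#' @inheritParams permutation_test
#' @param level Confidence level (default 0.95).
#' @param n_bootstrap Number of bootstrap resamples (default 10000).
#' @return Tibble with columns `treatment`, `estimate`, `lower`, `upper`,
#'   `level`, `n_bootstrap`.
#' @export
bootstrap_ci <- function(counts, design = migration_design(),
                         estimator = "area_corrected", level = 0.95,
                         n_bootstrap = 10000, seed = NULL,
                         unit = "replicate") {
  stopifnot(level > 0, level < 1)
  est <- estimate_probability(counts, design = design, estimator = estimator,
                              unit = unit)
  obs <- est$per_observation
  treatments <- sort(names(est$per_treatment))
  alpha <- (1 - level) / 2
  rows <- with_seed(seed, {
    lapply(treatments, function(t) {
      P <- obs$P[obs$treatment == t]
      point <- mean(P)
      if (length(P) == 1) {
        warnf("treatment '%s' has a single observation; CI is degenerate", t)
        lo <- hi <- point
      } else {
        idx <- matrix(sample.int(length(P), length(P) * n_bootstrap,
                                 replace = TRUE), nrow = n_bootstrap)
        means <- rowMeans(matrix(P[idx], nrow = n_bootstrap))
        qs <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
        lo <- qs[[1]]; hi <- qs[[2]]
      }
      tibble::tibble(treatment = t, estimate = point, lower = lo, upper = hi,
                     level = level, n_bootstrap = n_bootstrap)
    })
  })
  dplyr::bind_rows(rows)
}

#' Full migration inference: estimates, permutation test, bootstrap CIs
#'
#' @inheritParams permutation_test
#' @param level,n_bootstrap Passed to [bootstrap_ci()].
#' @return Object of class `migration_inference` bundling the
#'   [estimate_probability()], [permutation_test()] and [bootstrap_ci()]
#'   results, plus the seed used.
#' @export
migration_inference <- function(counts, design = migration_design(),
                                estimator = "area_corrected",
                                n_permutations = 10000, n_bootstrap = 10000,
                                level = 0.95, seed = NULL,
                                unit = "replicate") {
  perm <- permutation_test(counts, design = design, estimator = estimator,
                           n_permutations = n_permutations, seed = seed,
                           unit = unit)
  ci <- bootstrap_ci(counts, design = design, estimator = estimator,
                     level = level, n_bootstrap = n_bootstrap,
                     seed = derive_seed(seed, 1), unit = unit)
  structure(list(estimate = perm$estimate, permutation = perm,
                 bootstrap = ci, seed = seed),
            class = "migration_inference")
}

#' @export
print.migration_inference <- function(x, ...) {
  print(x$estimate)
  print(x$permutation)
  for (i in seq_len(nrow(x$bootstrap))) {
    cat(sprintf("  %s: %d%% CI [%.4f, %.4f]\n", x$bootstrap$treatment[[i]],
                round(100 * x$bootstrap$level[[i]]), x$bootstrap$lower[[i]],
                x$bootstrap$upper[[i]]))
  }
  invisible(x)
}

#' Dot/box plot of per-observation migration probabilities
#'
#' Minimal visual companion to [estimate_probability()]: one dot per
#' observation (use `unit = "field"` for the per-field view), superposed on
#' a box plot per treatment. Requires ggplot2.
#'
#' @param est A `migration_estimate`.
#' @return A ggplot object.
#' @export
plot_migration <- function(est) {
  stopifnot(inherits(est, "migration_estimate"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_migration requires the ggplot2 package")
  }
  df <- est$per_observation
  ggplot2::ggplot(df, ggplot2::aes(x = treatment, y = P,
                                   colour = treatment)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = NULL, y = "estimated migration probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
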