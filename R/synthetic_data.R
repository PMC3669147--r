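# Synthetic-data generators with known ground truth.
#
# Every generator is a pure function of its parameters including the seed,
# and emits exactly the tables/records the analysis functions consume, so
# the whole pipeline can be exercised end to end with recoverable truth.
# Count data use the Poisson distribution -- the minimal count model
# consistent with the migration model's expectation statements -- and
# luminescence uses multiplicative lognormal noise (strictly positive,
# scale-free) parameterized by its coefficient of variation.

#' Simulate transwell field counts
#'
#' For each treatment and replicate, migrated-field counts are drawn as
#' `Poisson(p * U / fields_migrated)` per field and non-migrated-field
#' counts as `Poisson((1 - p) * U / (A * fields_nonmigrated))` per field,
#' so replicate totals have the expectations `E(M) = p * U` and
#' `E(S) = (1 - p) * U / A` that define the migration model.
#'
#' @param p Named numeric vector of true migration probabilities, one per
#'   treatment (values in (0, 1); names are the treatment labels).
#' @param U Expected number of cells loaded per replicate: a single
#'   number, a vector named like `p` (per treatment), or a list of
#'   per-replicate vectors named like `p`.
#' @param design A [migration_design].
#' @param n_replicates Replicates (insert pairs) per treatment.
#' @param seed Integer seed; the output is a pure function of the
#'   arguments including this seed.
#' @return A migration-counts tibble (`treatment`, `replicate`, `field`,
#'   `compartment`, `count`).
#' @export
gen_migration_counts <- function(p, U, design = migration_design(),
                                 n_replicates = 2, seed = NULL) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stopf("`p` must be a named vector (names = treatment labels)")
  }
  if (any(p <= 0) || any(p >= 1)) stopf("probabilities must lie in (0, 1)")
  u_for <- function(t, r) {
    if (is.list(U)) return(U[[t]][[min(r, length(U[[t]]))]])
    if (!is.null(names(U))) return(U[[t]])
    U[[1]]
  }
  fm <- design$fields_migrated
  fs <- design$fields_nonmigrated
  A <- design$area_factor
  with_seed(seed, {
    rows <- lapply(names(p), function(t) {
      lapply(seq_len(n_replicates), function(r) {
        u <- u_for(t, r)
        if (!(u > 0)) stopf("U must be > 0")
        m_counts <- rpois(fm, p[[t]] * u / fm)
        s_counts <- rpois(fs, (1 - p[[t]]) * u / (A * fs))
        tibble::tibble(
          treatment = t, replicate = r,
          field = c(seq_len(fm), seq_len(fs)),
          compartment = c(rep("migrated", fm), rep("non_migrated", fs)),
          count = c(m_counts, s_counts))
      })
    })
    dplyr::bind_rows(unlist(rows, recursive = FALSE))
  })
}

# Lognormal factor with mean exactly 1 and coefficient of variation cv.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a dual-luciferase reporter plate
#'
#' Each UTR-reporter condition `c` is generated with expected test/reference
#' ratio `baseline_ratio * (1 - repression[c])`, multiplied per well by a
#' mean-1 lognormal factor with the given CV; the normalization control
#' condition (the empty-vector analogue) is generated at unit ratio, so the
#' negative-control conditions (repression 0) land at `baseline_ratio`
#' after control normalization.
#'
#' @param repression Named numeric vector of true repression fractions per
#'   condition (include negative controls with value 0).
#' @param baseline_ratio Expected normalized activity of an unrepressed UTR
#'   reporter relative to the control (default 0.176).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   luminescence noise (default 0.1).
#' @param n_replicates Wells per condition (default 3, i.e. triplicates).
#' @param control_condition Label of the unit-ratio normalization control
#'   added to the plate.
#' @param orientation Which channel carries the test signal (matches
#'   [normalize_wells()]).
#' @param reference_level Raw luminescence of the reference channel.
#' @param seed Integer seed.
#' @return Tibble of wells (`condition`, `replicate`, `firefly`,
#'   `renilla`).
#' @export
gen_luciferase_plate <- function(repression, baseline_ratio = 0.176,
                                 noise_cv = 0.1, n_replicates = 3,
                                 control_condition = "empty_vector",
                                 orientation = c("firefly_over_renilla",
                                                 "renilla_over_firefly"),
                                 reference_level = 1e5, seed = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(names(repression))) stopf("`repression` must be named")
  if (any(repression > 1)) stopf("repression fractions cannot exceed 1")
  if (noise_cv < 0) stopf("`noise_cv` must be >= 0")
  if (control_condition %in% names(repression)) {
    stopf("'%s' is reserved for the normalization control", control_condition)
  }
  exp_ratio <- c(setNames(1, control_condition),
                 baseline_ratio * (1 - repression))
  with_seed(seed, {
    rows <- lapply(names(exp_ratio), function(cond) {
      ratio <- exp_ratio[[cond]] * lognormal_factor(n_replicates, noise_cv)
      test <- ratio * reference_level
      ref <- rep(reference_level, n_replicates)
      if (orientation == "firefly_over_renilla") {
        tibble::tibble(condition = cond, replicate = seq_len(n_replicates),
                       firefly = test, renilla = ref)
      } else {
        tibble::tibble(condition = cond, replicate = seq_len(n_replicates),
                       firefly = ref, renilla = test)
      }
    })
    dplyr::bind_rows(rows)
  })
}

resolve_planted <- function(spec, mirnas_by_name) {
  if (!is.list(spec) || is.null(spec$kind) || is.null(spec$start)) {
    stopf("each planted spec needs `kind` and `start`")
  }
  start <- as.integer(spec$start)
  if (spec$kind == "seed_site") {
    mir <- if (inherits(spec$mirna, "mature_mirna")) {
      spec$mirna
    } else {
      mirnas_by_name[[as.character(spec$mirna)]]
    }
    if (is.null(mir)) stopf("planted site references unknown miRNA '%s'",
                            spec$mirna)
    cls <- match.arg(spec$class, SITE_CLASSES)
    pattern <- seed_site_patterns(mir)[[cls]]
    list(kind = "seed_site", label = mir$name, class = cls,
         pattern = pattern, start = start, end = start + nchar(pattern))
  } else if (spec$kind %in% c("polyA_signal", "CPE", "AU_rich")) {
    pattern <- toupper(spec$pattern %||% motif_consensus_default()[[spec$kind]][[1]])
    list(kind = spec$kind, label = spec$kind, class = NA_character_,
         pattern = pattern, start = start, end = start + nchar(pattern))
  } else {
    stopf("unknown planted kind '%s'", spec$kind)
  }
}

#' Generate a synthetic UTR with planted sites and motifs
#'
#' Builds an i.i.d. background sequence with the requested GC content,
#' writes the planted seed sites / motifs verbatim at their coordinates,
#' and rejection-samples the background until scanning the sequence with
#' the guarded miRNAs returns exactly the planted truth (no accidental
#' sites, no class promotion of a planted site by flanking bases). Fails
#' after `max_attempts` redraws.
#'
#' @param length UTR length in nt.
#' @param planted List of plant specs: `list(kind = "seed_site",
#'   mirna = <mature_mirna>, class = "8mer", start = <0-based>)` or
#'   `list(kind = "polyA_signal", pattern = "AATAAA", start = ...)`.
#' @param mirnas miRNAs whose absence outside the truth table is
#'   guaranteed (defaults to the miRNAs of the planted sites).
#' @param background_gc Background GC fraction (default 0.5).
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap (default 10000).
#' @return List with `record` (a [seq_record]) and `truth` (tibble of
#'   `kind`, `label`, `site_class`, `start`, `end`, `pattern`).
#' @export
gen_utr <- function(length, planted = list(), mirnas = list(),
                    background_gc = 0.5, seed = NULL, max_attempts = 10000) {
  if (inherits(mirnas, "mature_mirna")) mirnas <- list(mirnas)
  mirnas_by_name <- setNames(mirnas, vapply(mirnas, `[[`, "", "name"))
  plants <- lapply(planted, resolve_planted, mirnas_by_name = mirnas_by_name)
  guard <- mirnas
  for (k in seq_along(plants)) {
    if (plants[[k]]$kind == "seed_site" &&
        inherits(planted[[k]]$mirna, "mature_mirna") &&
        !plants[[k]]$label %in% vapply(guard, `[[`, "", "name")) {
      guard <- c(guard, list(planted[[k]]$mirna))
    }
  }
  if (length(plants) > 0) {
    spans <- do.call(rbind, lapply(plants, function(p) c(p$start, p$end)))
    if (any(spans[, 1] < 0) || any(spans[, 2] > length)) {
      stopf("planted span out of bounds")
    }
    o <- order(spans[, 1])
    spans <- spans[o, , drop = FALSE]
    if (nrow(spans) > 1 && any(spans[-1, 1] < spans[-nrow(spans), 2])) {
      stopf("planted spans overlap")
    }
  }
  truth <- tibble::tibble(kind = character(), label = character(),
                          site_class = character(), start = integer(),
                          end = integer(), pattern = character())
  if (length(plants) > 0) {
    truth <- dplyr::bind_rows(lapply(plants, function(p) {
      tibble::tibble(kind = p$kind, label = p$label, site_class = p$class,
                     start = p$start, end = p$end, pattern = p$pattern)
    }))
  }
  site_truth <- truth[truth$kind == "seed_site", , drop = FALSE]
  probs <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
             G = background_gc / 2, T = (1 - background_gc) / 2)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      chars <- sample(names(probs), length, replace = TRUE, prob = probs)
      for (p in plants) {
        chars[(p$start + 1):p$end] <- strsplit(p$pattern, "", fixed = TRUE)[[1]]
      }
      residues <- paste(chars, collapse = "")
      found <- scan_seed_sites(residues, guard)
      ok <- nrow(found) == nrow(site_truth) &&
        (nrow(found) == 0 ||
           setequal(paste(found$mirna, found$site_class, found$start),
                    paste(site_truth$label, site_truth$site_class,
                          site_truth$start)))
      if (ok) {
        rec <- seq_record(sprintf("synthetic_utr_%dnt", length), residues)
        return(list(record = rec, truth = truth))
      }
    }
    stopf("could not place planted elements without accidental sites in %d attempts",
          max_attempts)
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Target Ct values follow `reference_ct - log2(fold_change) + N(0, sd)`
#' under fixed efficiency-2 amplification, so the delta-delta-Ct pipeline
#' (calibrated on a fold-1 sample) recovers the planted fold changes.
#'
#' @param fold_changes Named positive vector of true fold changes per
#'   sample.
#' @param reference_ct Reference-gene Ct (cycles; default 15).
#' @param noise_sd Standard deviation of the Ct noise (cycles).
#' @param calibrator Name of the fold-1 calibrator sample; prepended
#'   automatically when absent from `fold_changes`.
#' @param seed Integer seed.
#' @return Tibble with columns `sample`, `target_ct`, `reference_ct`.
#' @export
gen_ct_table <- function(fold_changes, reference_ct = 15, noise_sd = 0,
                         calibrator = "calibrator", seed = NULL) {
  if (is.null(names(fold_changes))) stopf("`fold_changes` must be named")
  if (any(fold_changes <= 0)) stopf("fold changes must be > 0")
  if (!calibrator %in% names(fold_changes)) {
    fold_changes <- c(setNames(1, calibrator), fold_changes)
  }
  with_seed(seed, {
    ct <- reference_ct - log2(fold_changes) +
      rnorm(length(fold_changes), 0, noise_sd)
    tibble::tibble(sample = names(fold_changes), target_ct = as.numeric(ct),
                   reference_ct = reference_ct)
  })
}
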