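# Dual-luciferase reporter quantification, miRNA synergy classification and
# qPCR relative quantification.
#
# Two normalization orientations are first-class because the two common
# reporter vectors put the test UTR behind different luciferases: in a
# pGL3-style screen the Firefly channel is the test signal (divide Firefly
# by Renilla), in a psiCheck2-style assay it is the Renilla channel. The
# orientation is a required, explicit choice -- it is never inferred from
# the data.

#' Normalize dual-luciferase well measurements
#'
#' Computes per-well test/reference ratios under the chosen orientation,
#' averages replicate wells per condition, and divides every condition by
#' the control condition's mean, so the control maps to exactly 1.
#' `per_well = TRUE` instead pairs each well with the control well of the
#' same replicate index before averaging (paired-by-plate reading).
#'
#' @param wells Data frame with columns `condition`, `replicate`,
#'   `firefly`, `renilla` (raw luminescence, all > 0).
#' @param orientation `"firefly_over_renilla"` or `"renilla_over_firefly"`.
#' @param control_condition Label of the normalization control; must be
#'   present in `wells`.
#' @param per_well Pair wells by replicate index instead of dividing by the
#'   control mean.
#' @return Tibble with columns `condition`, `n_wells`, `mean_ratio` and
#'   `normalized_activity`, in order of first appearance.
#' @export
normalize_wells <- function(wells,
                            orientation = c("firefly_over_renilla",
                                            "renilla_over_firefly"),
                            control_condition, per_well = FALSE) {
  orientation <- match.arg(orientation)
  req <- c("condition", "replicate", "firefly", "renilla")
  if (!all(req %in% names(wells))) {
    stopf("`wells` must have columns %s", paste(req, collapse = ", "))
  }
  bad <- which(!(wells$firefly > 0) | !(wells$renilla > 0))
  if (length(bad) > 0) {
    stopf("non-positive luminescence in well (condition '%s', replicate %s)",
          wells$condition[[bad[[1]]]], wells$replicate[[bad[[1]]]])
  }
  if (!control_condition %in% wells$condition) {
    stopf("control condition '%s' not present", control_condition)
  }
  ratio <- if (orientation == "firefly_over_renilla") {
    wells$firefly / wells$renilla
  } else {
    wells$renilla / wells$firefly
  }
  conds <- unique(wells$condition)
  if (per_well) {
    ctrl_idx <- wells$condition == control_condition
    ctrl_ratio <- setNames(ratio[ctrl_idx], wells$replicate[ctrl_idx])
    rep_key <- as.character(wells$replicate)
    if (any(!rep_key %in% names(ctrl_ratio))) {
      stopf("per-well pairing: control has no well for replicate %s",
            rep_key[!rep_key %in% names(ctrl_ratio)][[1]])
    }
    norm <- ratio / ctrl_ratio[rep_key]
    mean_ratio <- tapply(ratio, wells$condition, mean)[conds]
    activity <- tapply(norm, wells$condition, mean)[conds]
  } else {
    mean_ratio <- tapply(ratio, wells$condition, mean)[conds]
    activity <- mean_ratio / mean_ratio[[control_condition]]
  }
  n_wells <- as.integer(table(wells$condition)[conds])
  tibble::tibble(condition = conds, n_wells = n_wells,
                 mean_ratio = as.numeric(mean_ratio),
                 normalized_activity = as.numeric(activity))
}

#' Unrepressed baseline from negative-control conditions
#'
#' The unrepressed expression level of a UTR reporter is estimated as the
#' arithmetic mean of the normalized activities of conditions transfected
#' with miRNAs that have no target site in the UTR.
#'
#' @param normalized Output of [normalize_wells()], or a named numeric
#'   vector of normalized activities.
#' @param negative_controls Labels of the negative-control conditions.
#' @return An object of class `reporter_baseline` with fields `value` and
#'   `source_conditions`.
#' @export
unrepressed_baseline <- function(normalized, negative_controls) {
  if (is.data.frame(normalized)) {
    vals <- setNames(normalized$normalized_activity, normalized$condition)
  } else {
    vals <- normalized
  }
  missing <- setdiff(negative_controls, names(vals))
  if (length(missing) > 0) {
    stopf("unknown negative control condition '%s'", missing[[1]])
  }
  if (length(negative_controls) < 1) stopf("need at least one negative control")
  if (length(negative_controls) == 1) {
    warnf("baseline estimated from a single negative control ('%s')",
          negative_controls)
  }
  structure(list(value = mean(vals[negative_controls]),
                 source_conditions = negative_controls),
            class = "reporter_baseline")
}

#' @export
print.reporter_baseline <- function(x, ...) {
  cat(sprintf("<reporter_baseline> %.4g (mean of %s)\n", x$value,
              paste(x$source_conditions, collapse = ", ")))
  invisible(x)
}

#' Repression relative to the unrepressed baseline, in percent
#'
#' `100 * (1 - activity / baseline)`. Negative values indicate
#' de-repression (activity above baseline), as seen when an endogenous
#' miRNA is sequestered by an antisense inhibitor.
#'
#' @param activity Normalized activity (vectorized).
#' @param baseline A `reporter_baseline` or a positive number.
#' @return Percentage(s); 0 means activity equals the baseline.
#' @export
repression_percent <- function(activity, baseline) {
  b <- if (inherits(baseline, "reporter_baseline")) baseline$value else baseline
  if (!(b > 0)) stopf("baseline must be > 0")
  100 * (1 - activity / b)
}

#' Classify a miRNA combination as additive or synergistic
#'
#' Under independent action, two miRNAs with single-miRNA repression
#' fractions a and b are expected to jointly repress by
#' `1 - (1 - a)(1 - b)`. The combination is called synergistic when the
#' observed combined repression exceeds that expectation by more than
#' `tolerance`, sub-additive when it falls short by more than `tolerance`,
#' and additive otherwise. The tolerance (default 0.05 absolute) is this
#' package's formalization of a qualitative judgement.
#'
#' @param single_a,single_b Repression fractions of the single miRNAs
#'   (at most 1; negative values = de-repression are allowed).
#' @param combined Observed repression fraction of the combination.
#' @param tolerance Absolute tolerance band around the additive expectation.
#' @return An object of class `synergy_call` with fields `single_a`,
#'   `single_b`, `combined`, `expected_additive`, `tolerance`, `verdict`.
#' @examples
#' synergy_call(0.0, 0.05, combined = 0.78)  # synergistic
#' @export
synergy_call <- function(single_a, single_b, combined, tolerance = 0.05) {
  if (any(c(single_a, single_b, combined) > 1)) {
    stopf("repression fractions cannot exceed 1")
  }
  expected <- 1 - (1 - single_a) * (1 - single_b)
  verdict <- if (combined > expected + tolerance) {
    "synergistic"
  } else if (combined < expected - tolerance) {
    "sub-additive"
  } else {
    "additive"
  }
  structure(list(single_a = single_a, single_b = single_b,
                 combined = combined, expected_additive = expected,
                 tolerance = tolerance, verdict = verdict),
            class = "synergy_call")
}

#' @export
print.synergy_call <- function(x, ...) {
  cat(sprintf(
    "<synergy_call> singles %.3f + %.3f -> expected additive %.3f; observed %.3f: %s\n",
    x$single_a, x$single_b, x$expected_additive, x$combined, x$verdict))
  invisible(x)
}

#' Two-sided t-test (Student or Welch)
#'
#' Classical two-sample t statistic with two-sided p-value. The Student
#' (pooled-variance) variant is the default; Welch is available. Degenerate
#' samples with zero pooled variance return p = 1 when the means are equal
#' and raise an error otherwise.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return List with `t_statistic`, `df`, `p_value`, `variant`.
#' @export
two_sided_t_test <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs n >= 2")
  if (var(x) + var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t_statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1, variant = variant))
    }
    stopf("zero variance with unequal means: t statistic is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"),
                      alternative = "two.sided")
  list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, variant = variant)
}

#' Relative quantity from qPCR cycle thresholds
#'
#' With amplification efficiency fixed at 2: `delta_ct` returns
#' `2^-(Ct_target - Ct_reference)` (relative to the reference gene only);
#' `delta_delta_ct` additionally normalizes to a calibrator sample,
#' `2^-(dCt_sample - dCt_calibrator)`.
#'
#' @param m A measurement: list or one-row data frame with `target_ct` and
#'   `reference_ct` (cycles, in (0, 45)).
#' @param method `"delta_ct"` or `"delta_delta_ct"`.
#' @param calibrator Calibrator measurement (same shape as `m`); required
#'   for `delta_delta_ct`.
#' @return Relative quantity (positive real; 1 means no change).
#' @examples
#' relative_quantity(list(target_ct = 25, reference_ct = 20),
#'                   method = "delta_ct")  # 2^-5
#' @export
relative_quantity <- function(m, method = c("delta_ct", "delta_delta_ct"),
                              calibrator = NULL) {
  method <- match.arg(method)
  check_ct <- function(v, what) {
    if (!is.numeric(v) || any(v <= 0) || any(v >= 45)) {
      stopf("%s Ct values must lie in (0, 45)", what)
    }
  }
  check_ct(m$target_ct, "target"); check_ct(m$reference_ct, "reference")
  dct <- m$target_ct - m$reference_ct
  if (method == "delta_ct") return(2^(-dct))
  if (is.null(calibrator)) stopf("delta_delta_ct requires a calibrator")
  check_ct(calibrator$target_ct, "calibrator target")
  check_ct(calibrator$reference_ct, "calibrator reference")
  dct_cal <- calibrator$target_ct - calibrator$reference_ct
  2^(-(dct - dct_cal))
}

#' Relative quantities for a table of qPCR measurements
#'
#' @param ct_table Data frame with columns `sample`, `target_ct`,
#'   `reference_ct`.
#' @param method Passed to [relative_quantity()].
#' @param calibrator Sample label used as calibrator (required for
#'   `delta_delta_ct`).
#' @return Tibble with columns `sample` and `rq`.
#' @export
qpcr_quantify <- function(ct_table, method = c("delta_ct", "delta_delta_ct"),
                          calibrator = NULL) {
  method <- match.arg(method)
  cal <- NULL
  if (method == "delta_delta_ct") {
    if (is.null(calibrator)) stopf("delta_delta_ct requires a calibrator sample")
    idx <- which(ct_table$sample == calibrator)
    if (length(idx) == 0) stopf("calibrator sample '%s' not found", calibrator)
    cal <- list(target_ct = mean(ct_table$target_ct[idx]),
                reference_ct = mean(ct_table$reference_ct[idx]))
  }
  rq <- vapply(seq_len(nrow(ct_table)), function(i) {
    relative_quantity(list(target_ct = ct_table$target_ct[[i]],
                           reference_ct = ct_table$reference_ct[[i]]),
                      method = method, calibrator = cal)
  }, 1.0)
  tibble::tibble(sample = ct_table$sample, rq = rq)
}
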