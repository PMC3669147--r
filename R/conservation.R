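# Pairwise global alignment with affine gap costs, percent identity, and
# multi-sequence conserved-position masks.
#
# The alignment model follows the workbench convention used for UTR/CDS
# identity tables: global alignment with gap open cost 10 and gap extension
# cost 1 (a gap run of length L costs open + L*ext). Match/mismatch rewards
# are not standardized by that convention, so they are explicit parameters
# with defaults match = +1, mismatch = -2. The definition of "% identity" is
# equally tool-dependent, so the denominator is a choice: all alignment
# columns (default), the shorter sequence, or only ungapped columns.

#' Scoring scheme for affine-gap alignment
#'
#' @param match Positive reward for an identical column.
#' @param mismatch Score (usually negative) for a substituted column.
#' @param gap_open Positive cost charged once when a gap run opens.
#' @param gap_extend Positive cost charged for every gap column (including
#'   the first); must not exceed `gap_open`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = 10,
                           gap_extend = 1) {
  if (!(match > 0)) stopf("`match` must be > 0")
  if (!(gap_extend > 0)) stopf("`gap_extend` must be > 0")
  if (!(gap_open >= gap_extend)) stopf("`gap_open` must be >= `gap_extend`")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

as_residues <- function(x, arg = "sequence") {
  if (inherits(x, "seq_record")) return(x$residues)
  if (is.character(x) && length(x) == 1L) {
    x <- toupper(x)
    if (grepl("[^ACGTUN]", x)) stopf("illegal residue in %s", arg)
    return(chartr("U", "T", x))
  }
  stopf("%s must be a seq_record or a single string", arg)
}

record_id <- function(x, default) if (inherits(x, "seq_record")) x$id else default

identity_count <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  sum(ca == cb & ca != "-" & ca != "N")
}

#' Optimal global alignment under affine gap costs
#'
#' Needleman-Wunsch/Gotoh dynamic programming over three layers (diagonal,
#' gap-in-b, gap-in-a). Traceback tie-breaking is fixed (prefer diagonal,
#' then gap-in-b, then gap-in-a), so the reported alignment is deterministic.
#' Terminal gaps are penalized by default (true global alignment); set
#' `free_end_gaps = TRUE` for the semi-global variant in which leading and
#' trailing gaps are free, useful when calibrating identity values against
#' tools whose end-gap treatment is unpublished.
#'
#' @param a,b Sequences ([seq_record] or plain strings), same moltype.
#' @param scheme A [scoring_scheme].
#' @param free_end_gaps If `TRUE`, end gaps cost nothing.
#' @param identity_denominator Denominator used for the percent identity
#'   stored on the result; see [percent_identity()].
#' @return An object of class `alignment_result` with fields `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `n_identities`,
#'   `percent_identity` and `identity_denominator`.
#' @examples
#' aln <- global_align("ACGT", "AGGT")
#' aln$score            # 3 matches - one mismatch penalty
#' aln$percent_identity # 75
#' @export
global_align <- function(a, b, scheme = scoring_scheme(),
                         free_end_gaps = FALSE,
                         identity_denominator = c("alignment_length",
                                                  "shorter_sequence",
                                                  "ungapped_columns")) {
  identity_denominator <- match.arg(identity_denominator)
  stopifnot(inherits(scheme, "scoring_scheme"))
  ra <- as_residues(a, "a"); rb <- as_residues(b, "b")
  if (!nzchar(ra) || !nzchar(rb)) stopf("cannot align an empty sequence")
  res <- .gotoh_align_cpp(ra, rb, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend, free_end_gaps)
  out <- structure(
    list(id_a = record_id(a, "a"), id_b = record_id(b, "b"),
         aligned_a = res$aligned_a, aligned_b = res$aligned_b,
         score = res$score,
         n_identities = identity_count(res$aligned_a, res$aligned_b),
         length_a = nchar(ra), length_b = nchar(rb),
         percent_identity = NA_real_,
         identity_denominator = identity_denominator,
         scheme = scheme, free_end_gaps = free_end_gaps),
    class = "alignment_result"
  )
  out$percent_identity <- percent_identity(out, identity_denominator)
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s vs %s\n  score %.6g, identity %.2f%% (%s)\n",
              x$id_a, x$id_b, x$score, x$percent_identity,
              x$identity_denominator))
  if (nchar(x$aligned_a) <= 80) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' Percent identity of an alignment
#'
#' 100 times the number of identical (non-gap, non-N) columns divided by the
#' chosen denominator. Symmetric in the two sequences.
#'
#' @param aln An `alignment_result`.
#' @param denominator `"alignment_length"` (all columns including gaps,
#'   default), `"shorter_sequence"`, or `"ungapped_columns"`.
#' @return A percentage in \[0, 100\].
#' @export
percent_identity <- function(aln, denominator = c("alignment_length",
                                                  "shorter_sequence",
                                                  "ungapped_columns")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(aln, "alignment_result"))
  ids <- aln$n_identities
  den <- switch(denominator,
    alignment_length = nchar(aln$aligned_a),
    shorter_sequence = min(aln$length_a, aln$length_b),
    ungapped_columns = {
      ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
      cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
      sum(ca != "-" & cb != "-")
    })
  if (den == 0) return(0)
  100 * ids / den
}

#' Pairwise identity matrix for a set of sequences
#'
#' Convenience wrapper reproducing the familiar cross-species identity table:
#' every sequence is aligned against every other and the percent identity is
#' tabulated (100 on the diagonal).
#'
#' @param records List of [seq_record] objects.
#' @inheritParams global_align
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
identity_matrix <- function(records, scheme = scoring_scheme(),
                            free_end_gaps = FALSE,
                            identity_denominator = "alignment_length") {
  ids <- vapply(records, `[[`, "", "id")
  n <- length(records)
  mat <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(mat)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      aln <- global_align(records[[i]], records[[j]], scheme = scheme,
                          free_end_gaps = free_end_gaps,
                          identity_denominator = identity_denominator)
      mat[i, j] <- mat[j, i] <- aln$percent_identity
    }
  }
  mat
}

#' Positions of a reference conserved across several sequences
#'
#' Aligns the reference against each other sequence (reference-anchored
#' pairwise alignments) and flags a reference position as conserved only if
#' the aligned column is identical in every comparison; a reference base
#' aligned to a gap, a substitution, or an N all count as non-identical.
#'
#' @param reference A [seq_record] (or string) whose positions are flagged.
#' @param others List of sequences to compare against (at least one).
#' @inheritParams global_align
#' @return An object of class `conservation_mask`: `reference_id` plus a
#'   logical vector `flags`, one per ungapped reference position.
#' @export
conserved_positions <- function(reference, others, scheme = scoring_scheme(),
                                free_end_gaps = FALSE) {
  if (inherits(others, "seq_record") || is.character(others)) others <- list(others)
  if (length(others) < 1) stopf("need at least one sequence to compare against")
  ref_res <- as_residues(reference, "reference")
  flags <- rep(TRUE, nchar(ref_res))
  for (other in others) {
    aln <- global_align(reference, other, scheme = scheme,
                        free_end_gaps = free_end_gaps)
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    refpos <- cumsum(ca != "-")
    keep_cols <- ca != "-"
    ok <- ca == cb & ca != "-" & ca != "N"
    flags[refpos[keep_cols]] <- flags[refpos[keep_cols]] & ok[keep_cols]
  }
  structure(list(reference_id = record_id(reference, "reference"),
                 flags = flags),
            class = "conservation_mask")
}

#' @export
print.conservation_mask <- function(x, ...) {
  cat(sprintf("<conservation_mask> %s: %d/%d positions conserved (%.1f%%)\n",
              x$reference_id, sum(x$flags), length(x$flags),
              100 * mean(x$flags)))
  invisible(x)
}

#' Conserved runs of a conservation mask as BED-style intervals
#'
#' @param mask A `conservation_mask`.
#' @return A tibble with columns `seq_id`, `start` (0-based), `end`
#'   (exclusive), one row per maximal conserved run.
#' @export
conserved_runs <- function(mask) {
  stopifnot(inherits(mask, "conservation_mask"))
  r <- rle(mask$flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(seq_id = mask$reference_id,
                 start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

# Exhaustive-search optimum over every global alignment; oracle for tests.
# Exported for the acceptance procedure; not part of the analysis surface.
#' Exhaustive-search alignment score (test oracle)
#'
#' Enumerates every global alignment of two short sequences (length <= 12)
#' and returns the optimal affine-gap score. Independent of the dynamic
#' programming implementation; used to verify it.
#'
#' @inheritParams global_align
#' @return The optimal score.
#' @export
exhaustive_align_score <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  ra <- as_residues(a, "a"); rb <- as_residues(b, "b")
  .exhaustive_align_score_cpp(ra, rb, scheme$match, scheme$mismatch,
                              scheme$gap_open, scheme$gap_extend)
}
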