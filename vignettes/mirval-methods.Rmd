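---
title: "Methods and design notes for mirval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mirval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mirval` covers the analysis chain of a miRNA target-validation study:
annotating a 3'UTR with candidate regulatory elements, scoring their
cross-species conservation, quantifying the reporter and qPCR experiments
that test them, and performing resampling inference on a transwell
migration assay. This vignette explains the models behind each stage, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data validation does and does not show.

## Seed-site scanning

Canonical miRNA target sites are defined by perfect Watson–Crick pairing
of the miRNA seed. Writing the mature miRNA 5'→3' with position 1 at the
5' end, the site on the UTR (always the sense strand — these are mRNA
sequences) is:

* **8mer** — reverse complement of positions 2–8, followed by A,
* **7mer-m8** — reverse complement of positions 2–8,
* **7mer-A1** — reverse complement of positions 2–7, followed by A,
* **6mer** — reverse complement of positions 2–7.

The trailing A is an adenosine opposite miRNA position 1 on the target,
a feature of high-efficacy sites independent of position-1 pairing.
Scanning is literal string matching: G:U wobble pairs are not accepted,
and `N` never matches anything. All overlapping occurrences are reported,
but a span is labeled with its highest class only, ranked
8mer > 7mer-m8 > 7mer-A1 > 6mer; a lower-class hit is suppressed exactly
when a higher-class hit's span contains it. This matching is intentionally
the reproducible core of what target-prediction servers do; context
scoring, 3'-supplementary pairing and thermodynamics are out of scope.

Motif annotation uses configurable consensus sets, by default
polyadenylation signals {AATAAA, ATTAAA}, cytoplasmic polyadenylation
elements {TTTTAT, TTTTAAT, TTTTTAT} and the AU-rich pentamer {ATTTA}.
Published UTR annotations are often only graphical, so these sets are
configuration, not constants; overlapping hits (e.g. two overlapping
polyadenylation hexamers) are always representable.

Inter-site spacing defaults to the between-site convention
(`downstream.start − upstream.end`, the number of nucleotides strictly
between the sites), with start-to-start and end-to-end alternatives
because published distances rarely say which convention they use. Two
sites are flagged as candidates for cooperative action when their gap
lies in the experimentally established 6–40 nt window.

Site-ablating mutations replace part of a seed match with a 6-nt
restriction recognition sequence (SacI `GAGCTC`, AgeI `ACCGGT`, SalI
`GTCGAC`), right-aligned to the seed-match core (the 7-nt match of
8mer/7mer-m8 sites, the 6-nt match otherwise) so the seed is maximally
disrupted while nothing outside the site span changes. The edit is
verified by re-scanning: any surviving or newly created site for the same
miRNA near the span is an error, not a silent success.

## Conservation scoring

Pairwise global alignment uses affine gap costs in the convention of the
sequence-analysis workbenches used for published UTR/CDS identity tables:
a gap run of length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$, with
defaults open = 10, ext = 1. Match/mismatch rewards are not standardized
by that convention and default to +1/−2, fully configurable. The
dynamic programming (Gotoh's three-layer recursion) uses a fixed traceback
tie-break — diagonal, then gap in the second sequence, then gap in the
first — so the reported alignment is deterministic. Terminal gaps are
penalized by default; a free-end-gap mode exists because the end-gap
treatment of the original workbench is unpublished and identity values
can only be calibrated by trying both.

"Percent identity" is likewise tool-dependent, so the denominator is
explicit: all alignment columns (default), the shorter sequence, or only
ungapped columns. Reproducing a published identity table therefore means
reporting the parameter set (match/mismatch, end-gap mode, denominator)
alongside the numbers; small residual deviations of a point or two can
remain attributable to unpublished tool internals. The implementation is
validated two independent ways: exhaustive enumeration of every alignment
of short pairs, and score agreement with an independently implemented
alignment library on longer pairs.

Conservation masks are reference-anchored: the reference is aligned
pairwise against each other sequence and a reference position is flagged
conserved only if its column is identical in every comparison (gaps and
`N` count as non-identical). This is deliberately not a multiple sequence
alignment; positional shading of a reference UTR is the goal.

## Reporter quantification

Dual-luciferase vectors differ in which luciferase carries the test UTR,
so both normalization orientations are first-class and the orientation is
a required argument, never inferred. Per-well test/reference ratios are
averaged per condition and divided by the control condition's mean, which
maps the control to exactly 1; a paired per-well mode (each well divided
by the control well of the same replicate index) is available for designs
where each mutant is compared against its own matched control.

The unrepressed baseline is the arithmetic mean of the normalized
activities of negative-control conditions (miRNAs with no site in the
UTR), and repression is $100(1 - \mathrm{activity}/\mathrm{baseline})$;
negative values mean de-repression, as produced by antisense inhibition
of an endogenous miRNA. Significance uses the classical two-sided
Student t-test (Welch available); raw p-values are reported by default,
with Bonferroni available but off, matching how such screens are usually
reported.

For two miRNAs with single repressions $r_1, r_2$, independent action
predicts a combined repression $1-(1-r_1)(1-r_2)$. The package calls a
combination synergistic when the observed combined repression exceeds
this by more than an absolute tolerance, sub-additive when it falls short
by more, and additive otherwise. The tolerance (default 0.05) is this
package's formalization of a qualitative judgement; it is a classification
band, not a significance test, and should be read alongside the t-tests.

qPCR relative quantities assume fixed efficiency-2 amplification:
$\Delta C_t = C_t^{target} - C_t^{ref}$, RQ $=2^{-\Delta C_t}$ for the
ΔCt method and $2^{-(\Delta C_t^{sample}-\Delta C_t^{calibrator})}$ for
ΔΔCt. No standard-curve efficiency correction is applied.

## Migration model

A transwell assay counts migrated cells on the filter underside and
non-migrated cells on the top, in microscopic fields that sample
macroscopic areas differing by a factor $A$ (default 40 for the
10-field/5-field layout at different magnifications). With $p_t$ the
migration probability under treatment $t$ and $U_{rt}$ the expected
number of cells loaded into replicate $r$, the count model is

$$E(M) = p_t U_{rt}, \qquad E(S) = (1-p_t) U_{rt} / A .$$

Counts are aggregated to the replicate (insert-pair) level — migrated and
non-migrated fields cannot be paired one-to-one, and the replicate is the
independent experimental unit. The default estimator is the
method-of-moments form consistent with the expectations above,

$$P = \frac{M}{M + A\,S},$$

whose first-order Taylor expectation is $p_t$; the per-treatment estimate
is the mean of its replicates' $P$ values. A `literal` estimator
$M/(M+S)$ is provided for data whose non-migrated counts were already
area-scaled upstream; which convention a published dataset used is often
impossible to tell from the printed formula alone, so both ship and the
area factor is data ($A$ is an argument), not code.

Two properties of this estimator deserve attention.

*Small-sample bias.* $P$ is only first-order unbiased. Because
$M/(M+A S)$ is convex in $S$ and $A S$ amplifies the Poisson noise of a
small count, the second-order bias is approximately $(A-1)p(1-p)/U$
upward. At $U = 1000$ and $A = 40$ this is about $+0.01$ at $p = 0.5$
and $+0.003$ at $p = 0.9$ — negligible relative to between-replicate
noise in realistic designs, but visible when averaging many thousands of
observations, and the validation suite measures it directly. Larger $U$
shrinks it linearly.

*Observation unit.* A per-field mode exists
($P_m = M_m/(M_m + A S/n_{fields})$, the replicate's area-corrected
non-migrated total spread evenly over its migrated fields) and reproduces
per-observation dot plots. But fields within a replicate share the same
$S$, so per-field observations are correlated: permuting them as if
exchangeable badly inflates the false-positive rate. Inference in this
package therefore defaults to replicate-level observations; the per-field
mode is for visualization and effect-direction checks.

The treatment difference is tested by permuting treatment labels across
observations: statistic $\hat p_A - \hat p_B$, two-sided Monte Carlo
p-value with add-one smoothing $(1 + \#\{|d^*| \ge |d_{obs}|\})/(1+B)$,
which can never be zero. When the number of distinct label assignments is
at most the permutation budget, the test switches automatically to
exhaustive enumeration and the p-value is exact. The Monte Carlo draw
samples subsets from the sorted pooled values at the smaller group size,
which makes the p-value bit-identical under treatment relabeling and row
reordering given the same seed.

Uncertainty per treatment uses the non-parametric percentile bootstrap:
resample replicate-level $P$ values with replacement, recompute the mean,
take the percentile interval. The percentile interval was chosen for
transparency and because it is the method named in the study designs this
package targets; with very few replicates (around ten) and the skewed,
discrete-$S$-driven distribution of $P$, percentile intervals of a mean
undercover somewhat — the validation suite quantifies this — and BCa or
studentized intervals would be the upgrade path if calibrated coverage at
small $n$ is required.

## Synthetic data

The generators emit exactly the tables the analysis consumes, as pure
functions of their parameters including the seed.

* **Migration counts**: per migrated field $\mathrm{Pois}(pU/n_{mig})$,
  per non-migrated field $\mathrm{Pois}((1-p)U/(A\,n_{non}))$, so
  replicate totals match the model expectations. Poisson is the minimal
  count model consistent with the stated means; real counts may be
  overdispersed (clumped cells, field-to-field heterogeneity), which the
  generator does not emulate.
* **Luciferase plates**: the test/reference ratio of a UTR-reporter
  condition is `baseline_ratio × (1 − repression)` times a mean-1
  lognormal factor with the requested CV (default 10%, a realistic
  plate-to-plate scale); the normalization control is generated at unit
  ratio. The default `baseline_ratio` of 0.176 puts unrepressed UTR
  reporters at a realistic fraction of the control vector's signal.
  Transfection-efficiency drift and plate-position effects are not
  simulated.
* **UTRs**: i.i.d. background at a requested GC content with planted
  sites/motifs written verbatim, rejection-sampled (capped at 10,000
  redraws) until scanning returns exactly the planted truth — no
  accidental sites for the guarded miRNAs, no class promotion of a
  planted site by its flanking bases. Real UTRs have composition
  structure the i.i.d. background lacks.
* **qPCR tables**: $C_t^{target} = C_t^{ref} - \log_2(\mathrm{fold}) +
  \mathcal N(0,\sigma)$ under efficiency 2.

Passing the validation suite on these generators shows the estimators,
tests and scanners are correct *under the stated models*; it does not
certify performance on real data whose noise departs from them
(overdispersed counts, non-lognormal luminescence, compositional
sequence background).

## Validation scales and numerical choices

The test suite and the acceptance script exercise: estimator bias on
10,000 simulated observations at $p = 0.5$ and $0.9$ ($U = 1000$,
$A = 40$); permutation type-I error over 1,000 null datasets with 2,000
permutations each; bootstrap coverage over 1,000 datasets with 1,000
resamples; exact scanner/oracle set equality on 1,000 random 500-nt UTRs
× 10 random miRNAs; alignment score equality with exhaustive search on
200 random pairs of length ≤ 8; reporter recovery of a planted 44%
repression over 1,000 noisy plates; and geometric-mean qPCR fold recovery
over 1,000 replicates. These sizes give Monte Carlo standard errors
comfortably below the tolerances being checked while keeping the default
run in the minutes range on a single core.

Numerical details: permutation/bootstrap comparisons use an absolute
tolerance of $10^{-12}$ when comparing resampled statistics to the
observed one (they are sums of the same floating-point values); seeded
routines save and restore the caller's RNG state; derived seeds stay
within 32-bit integer range; alignment scores are exact integer
arithmetic represented in doubles, compared with a $10^{-9}$ epsilon in
the traceback; degenerate inputs (zero-variance t-tests, all-zero count
replicates, single-observation bootstraps) follow explicit conventions
documented on each function rather than failing obscurely.

## Known limitations

* Seed matching is canonical-only: no wobble, no compensatory 3'
  pairing, no context scoring — by design.
* Conservation is pairwise reference-anchored, not a true MSA.
* The migration estimator's small-sample bias and the percentile
  bootstrap's small-$n$ undercoverage are quantified, not corrected;
  designs with more cells per insert (larger $U$) or more replicates
  shrink both.
* Exactly two treatments are supported by the permutation test, matching
  the two-arm design it was built for.
* The synergy verdict is a tolerance-band classification of effect
  sizes, not a formal interaction test.
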