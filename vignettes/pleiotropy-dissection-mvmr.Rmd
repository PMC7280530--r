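---
title: "Instrument selection, pleiotropy dissection and multivariable MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instrument selection, pleiotropy dissection and multivariable MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(mrdissect)
```

## The problem

Two-sample Mendelian randomization (MR) infers whether an exposure causes
an outcome by regressing, across genetic instruments, the instruments'
outcome associations on their exposure associations. With blood lipids and
coronary artery disease (CAD) the difficulty is threefold: which SNPs out
of a GWAS meta-analysis are *valid* instruments; how instruments associated
with two or more lipid fractions (shared, pleiotropic SNPs) distort
single-exposure estimates; and how to demonstrate that a flagged exposure —
triglycerides (TG) being the canonical case — owes its apparent effect to
pleiotropy rather than causation.

This package implements a complete summary-statistics workflow around those
three questions: staged instrument selection with a convergence scan,
allele harmonization, shared/unique dissection, a suite of causal
estimators, a null-embedding simulation that calibrates the selection's
false discovery rate (FDR), and a synthetic-data generator so the whole
pipeline is testable end to end with no external downloads.

## Instrument selection

Selection from a merged per-SNP table (three lipid exposures plus CAD)
runs in a fixed order:

1. **Association.** Keep SNP $j$ when $P_{vj} \le P_v$, where $P_{vj}$ is
   the *smallest* p-value across the three lipid fractions and
   $P_v = 5\times10^{-8}$ by default. The comparison is inclusive.
2. **Sample-size proportions.** $P_{cj}$ is SNP $j$'s summed exposure
   sample size divided by the largest such sum; $P_{dj}$ is the analogous
   outcome ratio. Keep rows with $P_{cj} > P_c$ *and* $P_{dj} > P_d$
   (strict). SNPs genotyped only in sub-studies carry noisier estimates
   and weaker weights; these filters remove them. The mixed
   inclusive/strict convention is deliberate and documented because it is
   unusual.
3. **Distance thinning.** Within each chromosome, instruments are retained
   so that retained pairs are at least the *adjacent interval length*
   (AIL, base pairs) apart. The greedy runs strongest-first (smallest
   $P_{vj}$, ties by position), dropping anything closer than AIL to a
   retained SNP — the convention of distance-based clumping, which keeps
   the stronger association whenever two candidates conflict and makes
   re-application a no-op.

`scan_grid()` repeats selection + harmonization + multivariable MR over a
threshold grid and reports each point's instrument count, causal estimates,
and an instability score (largest estimate change to a neighbouring grid
point). The scan *advises* — the attribute `"suggested"` marks the most
stable point — but never auto-selects, because the published analyses chose
their operating point by inspecting the convergence plot.

One genuinely open choice: whether stage 2's maxima are taken before or
after stage 1. For real-data selection we default to the full merged table
(`select_instruments(..., proportions_on = "full")`); inside the
null-embedding simulation the stage-1 survivors are the default reference,
because with moment-matched synthetic null sample sizes the full-table
maxima sit in the normal upper tail, above every embedded instrument, and
the high-proportion grid cells would be vacuously empty — inconsistent with
the calibration this simulation is meant to perform. Both sides carry a
switch.

## Harmonization

Estimators need all effects expressed on the same allele. For each
exposure, the exposure's major allele is compared with the CAD reference
allele *by letter*; on mismatch the exposure beta's sign is flipped, the
exposure's allele pair swapped (making the operation idempotent), and the
row flagged. SEs, p-values and sample sizes pass through bit-identical.
No strand inference is attempted: A/T and C/G (palindromic) pairs are
flagged, never dropped, and an exposure allele matching neither the
outcome's alleles nor their complements is an error, not a silent drop.
In lenient mode (used for simulated null rows, whose per-trait alleles are
independent permutations) the letter rule applies without the
reconcilability check.

## Shared and unique instruments

A SNP is associated with a fraction when its p-value is at or below the
partition threshold (default $5\times10^{-8}$; the looser values used in
re-analyses of published instrument sets are plain arguments). SNPs with
exactly one membership are **unique** (restricted) instruments; two or
three make them **shared**, i.e. carriers of potential pleiotropy. All
seven Venn region counts are reported. Comparing estimates between the
total, shared and unique subsets is the dissection device: a causal
exposure keeps its effect on unique instruments; a pleiotropy artifact
loses it.

## Estimators

All estimators operate on the harmonized table; odds ratios are
$e^\beta$ with 95% intervals $e^{\beta \pm 1.959964\,\mathrm{se}}$.

- **IVW**: slope of the origin-constrained regression of outcome betas on
  exposure betas, weights $1/\mathrm{se}_{CAD}^2$; SE and p from the
  weighted fit ($t$, $n-1$ df). A single instrument degenerates to the
  Wald ratio with delta-method SE.
- **MR-Egger**: same regression with an intercept after orienting every
  instrument to a non-negative exposure effect; a non-zero intercept
  indicates directional pleiotropy.
- **Simple median**: median of per-SNP Wald ratios (midpoint convention
  for even counts).
- **Weighted median**: weights $(b_x/\mathrm{se}_y)^2$, linear
  interpolation of the standardized cumulative weight at the 50% point.
  This reduces exactly to the simple median under equal weights; a SNP
  holding the majority of the weight returns (up to interpolation at the
  interval edge) its own ratio.
- **Multivariable MR** (`mr_mvmr()`): the outcome betas regressed jointly
  on the three exposures' beta columns, weighted, no intercept — chosen so
  the single-exposure case reduces *exactly* to IVW. Unweighted and
  intercept variants are switches, since published multivariable analyses
  do not always state their convention. Per-exposure $t$-tests use
  $n - k$ df.
- Median SEs come from a seeded nonparametric bootstrap (default 10,000
  resamples) because no closed form is exact at these sizes; the seed is
  an argument and the bootstrap runs on a private RNG stream.

The per-fraction `r_squared()` groups an exposure's betas by allele-pair
class and returns the one-way ANOVA share of variance between classes,
$SS_B/SS_T$. The underlying published definition ("construct genotypes,
compute genotype and total variances") is ambiguous; this decomposition is
our documented interpretation, consistent with its boundary cases (equal
class means give 0, one observation per class gives 1).

## The null-embedding simulation

The simulation asks: if all cross-exposure pleiotropy were dismantled,
would the selection procedure still pick real instruments, and what would
multivariable MR conclude?

1. **Null profiles.** From a mother table of $M$ SNPs, each trait gets
   null betas from a normal with the mother's beta moments, null p-values
   uniform on $[p_{low}, 1]$, allele pairs permuted (multisets preserved),
   and null sample sizes from a normal with the mother's moments (rounded,
   floored at 1).
2. **Embedding.** Each test SNP, for each fraction it is associated with,
   overwrites one distinct random null row's record for that fraction
   *and* for CAD. Multi-fraction SNPs are duplicated/triplicated to
   separate rows, so each embedded row carries exactly one
   exposure–outcome relationship, unchanged from the test data, with no
   cross-exposure structure. A warning fires when the test/null ratio
   exceeds 0.005, above which random placements start to collide.
3. **Grid.** Per replicate and per $(P_c, P_d)$ cell: select at $P_v$,
   measure FDR (fraction of selected rows that are background), harmonize,
   fit the multivariable model; average over replicates (default 10, each
   on a seeded substream, so results are bit-reproducible).

With $p_{low} = 10^{-7} > P_v = 5\times10^{-8}$ no background SNP can pass
stage 1, so FDR is identically zero — an analytic property the tests
assert over seeds — and the surviving estimates show the pleiotropy-free
pattern. The null p-values are uniform on the *linear* scale, which is the
plain reading of the published range "$10^{-7} \sim 1$". A consequence
worth stating: with a linear-uniform floor of $10^{-12}$ the expected
number of background SNPs passing $5\times10^{-8}$ is
$3M \times 5\times10^{-8} \approx 0.01$ at realistic $M$, so positive FDRs
of the order reported for that profile in the source analyses cannot arise
under this model; the leakage *mechanism* (background SNPs entering when
the stage-1 cutoff sits inside the null support, more of them the laxer
the cutoff) is demonstrated in `analysis/05_null_simulation.R` with the
cutoff moved inside the support instead.

## The synthetic generator

`synth_config()` defaults *are* the study conditions:

- $M = 20{,}000$ SNPs (a desk-scale stand-in for the 78,112-SNP merged
  table; the full size is one argument away), 338 of them truly
  associated, with the published instrument set's Venn architecture:
  unique (76, 96, 83) for (LDL, HDL, TG), pair-only (1, 18, 47) for
  (LDL∩HDL, LDL∩TG, HDL∩TG), 17 triple.
- Planted causal vector $\theta = (0.4, -0.3, 0.0)$ on the log-odds
  scale — LDL adverse, HDL protective, TG null, the configuration the
  dissection is designed to expose.
- True effect magnitudes uniform on $[0.02, 0.12]$ per SD; shared SNPs get
  proportional magnitudes across their fractions (pleiotropic loci act
  through one pathway) with sign concordance 0.5 (LDL–HDL), 0.65 (LDL–TG)
  and 0.05 (HDL–TG) — the strong HDL–TG discordance mirrors the negative
  HDL–TG relationship of real lipid data and is what transmits a spurious
  positive TG signal through $\theta_{HDL} < 0$.
- Sample sizes: $n = n_{max}(1 - z)$, $z \sim \mathrm{Exp}(0.02)$ capped
  at 0.5, $n_{max} = 172{,}000$ (lipids) and $184{,}000$ (CAD). Most SNPs
  sit near the full meta-analysis size with a minority in sub-studies;
  this lower-tail shape is what gives the proportion filters real
  consequences.
- Estimation noise $\mathrm{se} = s/\sqrt{n}$ with $s = 1$ for lipids
  (per-SD units) and $s = 8.5$ for CAD (log-odds SEs of roughly 0.02, the
  scale of large case-control CAD meta-analyses). Observed betas are true
  effects plus this noise; p-values are the exact two-sided Wald values
  (floored at $10^{-300}$), so they round-trip through the SE-from-p
  derivation. Exposure records are reported on a random orientation
  (allele pair swapped, beta negated) half the time, so harmonization is
  genuinely load-bearing in every downstream experiment.

What the generator does *not* emulate: linkage disequilibrium, allele
frequencies and frequency-dependent power, population stratification,
sample overlap between exposure and outcome studies, and horizontal
(SNP-to-outcome) pleiotropy. Passing recovery tests on this generator
therefore demonstrates the correctness of the selection/harmonization/
estimation machinery under the stated model, not robustness to those
real-data complications.

`recovery_experiment()` reruns generate → select → harmonize → MVMR over
replicates and reports per-exposure bias, empirical SE and CI coverage.
`tg_confounding_experiment()` isolates the headline mechanism: with
$\theta_{TG} = 0$, no TG-only instruments, and fully discordant HDL–TG
shared effects, single-variable IVW on the full selected set flags TG
while the unique-subset multivariable model clears it.

## Numerical choices and degenerate inputs

- SE from p uses the upper-tail normal quantile (`qnorm(p/2, lower.tail =
  FALSE)`), accurate down to $p \approx 10^{-300}$; $p \ge 1$ or
  $\beta = 0$ are errors, not NaNs.
- Written tables carry 15 significant digits; read/write round trips are
  exact to $10^{-12}$ relative error.
- Selection monotonicity (counts non-decreasing in $P_v$, non-increasing
  in $P_c$, $P_d$, AIL), AIL idempotence and the pairwise-distance
  invariant are property-tested on random tables.
- Degenerate cases raise typed errors: empty merge intersections, zero
  sample-size maxima, all-zero exposure effects (IVW), fewer than 3 (Egger,
  medians) or 4 (MVMR) instruments, rank-deficient exposure columns
  (named collinearity error), zero total variance in `r_squared()`.
  Grid cells and pipeline subsets that end up under-instrumented are
  flagged, not fatal.
- Every stochastic component (generator, simulation replicates, median
  bootstrap) runs on a private, seeded RNG stream and restores the
  caller's stream afterwards; identical seeds give bit-identical output.

## Problem sizes

The bundled analyses and tests run at $M = 20{,}000$ mother SNPs, 10
simulation replicates over the 15-cell grid, 20-replicate recovery and
confounding experiments, and 1,000-instance estimator-oracle sweeps —
sizes chosen so the complete suite executes in a few minutes on one core
while keeping every Monte-Carlo margin wide (recovery bias is an order of
magnitude below its acceptance bound).

## Limitations

The published instrument tables (the 338- and 363-SNP sets) are journal
supplements and are not redistributed here; the checks that reproduce
their exact Venn counts and odds ratios run only when those files are
placed under `inst/extdata/`. Real consortium-scale inputs (78k–2.4M SNP
merged tables) are supported by the same functions but are not bundled.
The selection procedure's accuracy degrades when sample sizes are small,
since the proportion filters are relative to the per-column maximum — a
property inherited from the method itself, not an implementation artifact.
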