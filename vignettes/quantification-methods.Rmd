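---
title: "Quantification methods for fly TDP-43 proteinopathy assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for fly TDP-43 proteinopathy assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbassays)
```

`mbassays` quantifies five kinds of raw data produced when a TDP-43
proteinopathy is modelled in the *Drosophila* mushroom body: Y-maze
arm-entry sequences, activity-monitor beam counts, lifespan census tables,
confocal stacks, and RNA-IP count tables. This vignette explains each
procedure, the tunable parameters and their defaults, what the synthetic
generators emulate (and do not), and the numerical conventions adopted
where the field's tools leave them implicit.

## Spontaneous alternation

Working memory is read out as spontaneous alternation: a fly that
remembers its last two arm choices tends to enter the remaining arm. Every
window of three consecutive entries within a trial is an *attempt*
(`A_max`); an attempt whose three entries are pairwise distinct is an
*alternation* (`N_alt`); the score is `N_alt / A_max`.

Three conventions needed fixing:

* **Aggregation.** Alternations and attempts are summed within each
  one-minute trial, the per-trial ratio formed, and the fly's score is the
  mean ratio over trials with at least one attempt (`mode = "per_trial"`).
  This is the closest reading of summing per trial and averaging over
  trials; a pooled mode (total alternations over total attempts) is
  available behind `mode = "pooled"`. The two differ whenever attempt
  counts vary across trials.
* **Windows.** Attempts use a sliding (overlapping) window, so a trial
  with *n* entries has `max(n - 2, 0)` attempts; `window = "disjoint"`
  scores non-overlapping triplets instead, for sensitivity analysis.
* **Re-entries.** Same-arm re-entries are real entries: they can only
  break alternations. Flies with no attempt in any trial have no score and
  are flagged (`no_score`), mirroring the removal of non-alternating flies
  from score statistics.

Under no re-entry and a uniform choice between the two available arms the
expected score is exactly 0.5, and each arm is entered 1/3 of the time —
the two analytic nulls the test suite checks by simulation. Arm bias is
each fly's per-arm entry fraction, tested per arm against 1/3 with a
two-sided Wilcoxon signed-rank test. Distance-scaled alternation (total
alternations per mm moved) corrects for hyperactivity.

Entry detection from 2-D trajectories uses three arm polygons plus a
central zone: an entry commits when the path penetrates an arm beyond a
debounce depth, 10% of arm length by default. The value is not critical —
it only has to exceed boundary jitter — and is exposed as
`debounce_frac`.

The generator (`gen_ymaze`) is a second-order Markov chain on the three
arms: with probability `p_reentry` (default 0.1) the current arm is
repeated; otherwise the alternation-completing arm is chosen with
probability `p_alternate`. It emulates choice statistics only — not
locomotor dynamics, pauses, or wall-following — so recovery tests validate
the scoring arithmetic, not trajectory realism.

## Sleep

Fly sleep is defined behaviourally: five or more consecutive minutes
without a beam crossing. `detect_sleep_bouts` takes maximal runs of
zero-count minutes of length >= 5; runs of 1-4 zeros are wake. Summaries
follow the conventions of DAM analysis tools:

* Proportions of day and night slept are sleep minutes over the phase's
  total minutes; a bout spanning the day/night boundary contributes its
  minutes to each phase separately, which conserves total sleep time.
* For bout *counts* and mean bout length, a boundary-spanning bout is
  counted once, in the phase holding its majority (ties go to the phase of
  the bout's first minute). Splitting a bout into two for counting would
  manufacture fragmentation at every dawn and dusk.
* Bouts touching the start or end of the trace are kept and flagged
  (`edge`); dropping them would bias bout length downward.
* Analysis starts at the first midnight of the recording
  (`trim_to_midnight`), excluding the acclimation period.
* The activity-to-sleep-bout-length ratio is not defined identically
  across tools; here it is mean counts per waking minute divided by mean
  bout length, and the formula is recorded in the summary's `formula`
  attribute rather than asserted as canonical.

The generator (`gen_dam`) runs a two-state Markov chain per minute with
phase-dependent transition probabilities, reproducing a stationary sleep
fraction and a geometric bout-length distribution per phase (defaults:
0.4 day / 0.7 night, mean bouts 20 / 40 min, 12:12 light cycle). Waking
minutes emit zero-truncated Poisson counts (rate 2/min) so that the
five-minute rule is well posed; an `untruncated` flag allows silent wake
minutes to study the resulting misclassification. Because short sleep
bouts (< 5 min) are scored as wake, recovered sleep fractions sit about
1-2% below the stationary targets — inside the +/- 0.03 recovery band the
tests use at n = 100 flies. Real circadian structure (siestas, anticipation,
activity peaks) is not modelled.

## Lifespan

Kaplan-Meier estimation, Greenwood variance and log-log pointwise
confidence intervals are delegated to the survival package; the wrapper
fixes the conventions (deaths precede censorings at tied times — ties are
common on a 2-day census grid — and the median CI comes from intersecting
the log-log band with 0.5). The log-rank test covers two or more groups.
The estimator is cross-checked in the tests against a brute-force product
over risk sets on small datasets.

The generator draws Weibull or Gompertz death times, rounds *up* to the
census grid (a death is discovered at the next every-other-day count) and
right-censors at day 100. Round-up matters: on a 2-day grid it shifts the
median of an exponential with true median 34.66 to 36 deterministically,
which is why the closed-form recovery test runs on a 1-day census. The
2-day default reflects the actual counting schedule and its bias is a
property of the design, not a bug.

## Confocal quantification

* `nuclear_total_ratio` is the mean YFP intensity in the nucleus over the
  mean in the whole cell — scale-invariant, and legitimately > 1 for
  punctate nuclear signal. Manual masks are the reference workflow;
  `derive_masks` automates them (Otsu on the dye channel; Otsu plus hole
  filling on YFP) for synthetic validation.
* `count_nuclei` selects every `ceiling(spacing / z_step)`-th plane
  (sections 2 um apart by default, so each nucleus smaller than the
  spacing is counted once) and counts 8-connected components per plane. A
  warning fires when detected nuclei look wider than the spacing. The
  cell-stack generator snaps nucleus z-centers to the counting grid by
  default (`z_snap_um`): without snapping, a nucleus smaller than the
  spacing can fall entirely between counting planes, and exact-recovery
  validation would be impossible. This is a validation-fixture choice,
  not a claim about real anatomy.
* `background_corrected_intensity` implements both plausible readings of
  background correction over >= 3 sections: integrated density minus
  background mean times lobe area (`subtract`), and lobe mean over
  background mean (`ratio`). Normalization to the young-group mean of the
  same genotype and lobe (`normalize_to_young`) makes the young group's
  mean exactly 1 by construction.
* `enhance_contrast` saturates 0.3% of pixels by default, split across
  both tails, then rescales to [0, 1].
* `bernsen_threshold` computes local max/min over a circular window
  (radius 25-50 px in the source protocol; tests use smaller windows on
  smaller images). Midgray = (max + min)/2; where local contrast falls
  below `contrast_threshold` (default 15/255, the 8-bit tool default) the
  neighbourhood is classified by comparing midgray to the global
  mid-intensity, with the bright-object-on-dark-background convention
  (configurable). The implementation is checked against a per-pixel
  brute-force evaluation.
* `analyze_particles` labels 8-connected components, measures calibrated
  area and a Moore-trace chain-code perimeter (straight steps 1, diagonal
  steps sqrt(2); a single pixel gets the square-outline perimeter 4), and
  circularity `4*pi*A/P^2` clamped to 1 — chain-code perimeters slightly
  underestimate smooth outlines, so compact digital shapes can exceed 1
  before clamping. Filters are inclusive at 0.25-3.0 um^2 and 0.25-1.0
  circularity; the perimeter dialect is declared here because tools
  differ and the choice moves circularity by several percent.

The image generators plant spheres/shells (cell stacks) and ellipses of
specified area and eccentricity (lobe images) with Gaussian noise and a
slow background texture. They validate mask arithmetic, thresholding and
particle filtering; they do not simulate a point-spread function, optical
sectioning blur, or overlapping cells.

## RNA-IP enrichment

Counts are normalized by median-of-ratios size factors. The enrichment
test is deliberately simple and transparent: log2 of (IP mean / input
mean) with a 0.5 pseudo-count; a method-of-moments negative-binomial
dispersion per gene, shrunk 80% toward the across-gene median (three
replicates per condition give very noisy per-gene dispersions); and a
Wald statistic on the log ratio. Because the moderated dispersion borrows
strength across genes, the statistic is referred to a t distribution with
`n1 + n2 - 2 + prior_df` degrees of freedom. `prior_df = 16` was set by
null simulation across dispersions 0.02-0.3 so that raw p-values are
approximately uniform (a plain normal reference was anti-conservative, a
t with 4 df far too conservative). The test is declared non-identical to
full DE tools; externally produced DE tables can be fed directly into the
downstream steps.

Downstream conventions: tag-only (YFP) control log2FC is subtracted from
each gene's log2FC, with missing control genes treated as 0 and flagged —
absence of evidence of nonspecific binding. Candidate thresholds are
strict (`log2FC > 1`, `p_adj < 0.05`); by default significance is
assessed on the model's own adjusted p and the subtraction re-ranks
candidates, with the filter-on-adjusted-values order available via
`mode = "adjusted"`. Set overlap between candidate lists is exact set
algebra with percentages kept at full precision. qPCR fold change is
`2^(-ddCt)` with replicate wells averaged before differencing. The
patient-data comparison uses a pooled-variance two-sample t test (the
common independent-t-test default), with the statistic signed as first
group minus second.

`gen_counts` plants negative-binomial counts (dispersion 0.05, three
replicates per condition) with a chosen enriched set in the TDP IP and a
nonspecific set in the YFP IP. `gen_nucleus_expression` emulates the
patient snRNA-seq comparison at its study conditions — 87 cryptic-exon
and 377 canonical nuclei, means 1.65 vs 1.35 — with a common within-group
SD of 0.8, a realistic spread for log-normalized single-nucleus data that
yields the intended ~0.88 power for a 0.3 shift at these group sizes.

## Statistical conventions

All rank tests are two-sided; exact Wilcoxon p-values are used where
sample sizes permit and the normal approximation with tie correction
otherwise (mid-ranks for ties). The nonparametric cascade is
Kruskal-Wallis followed by all pairwise rank-sum tests with
Benjamini-Hochberg adjustment applied jointly to the pairwise p-values.
The parametric path is a fixed-effects linear model; replicate enters as
a fixed effect (the pooled-replicate design treats replicate as a fixed
blocking factor — the original mixed-model phrasing with replicate as a
fixed effect reduces to exactly this), followed by ANOVA and Tukey HSD.

## Problem sizes and runtime

The test suite validates at sizes chosen to keep the full run in a few
minutes on one CPU while leaving Monte-Carlo error well below the
tolerances: 500 flies for the behavioral nulls, 100 monitors x 3 days for
sleep recovery, n = 10^4 for the survival closed form, 2000 genes for
enrichment calibration, 2000/500 replicates for the testing-cascade and
log-rank null calibrations, and exhaustive enumeration where the space is
small (all 3^n entry sequences for n <= 8, all <= 32 x 32 Bernsen
fixtures, n <= 8 survival datasets).

## Known limitations

* Generators emulate summary statistics of each assay, not mechanism;
  passing recovery tests certifies the quantification arithmetic, not
  realism of fly behavior or optics.
* The enrichment test trades power modelling for transparency; its
  dispersion moderation is cruder than full DE shrinkage estimators.
* Sleep phase attribution of boundary bouts (majority rule) is one of
  several defensible conventions; proportions are unaffected, bout counts
  can differ by 1 near dawn/dusk relative to tools that split bouts.
* Particle circularity depends on the perimeter dialect; values are
  comparable within this package but not bit-identical to other tools.
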