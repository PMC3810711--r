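---
title: "Hybrid biomarker panel selection for protein microarrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid biomarker panel selection for protein microarrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protopanel)
```

# The problem

High-density protein microarrays probed with serum measure autoantibody
binding against thousands of proteins at once and are a standard platform for
autoimmune biomarker discovery: find a small panel of proteins whose binding
profile separates a case group from controls. Large studies of this kind face
three recurring hazards that protopanel is built around:

1. **Subgroup responders.** Autoantibody markers are often elevated in only a
   fraction of cases. A statistic that compares group means dilutes such
   markers; the minimum M statistic implemented here is designed to see them.
2. **Production-lot batch effects.** Arrays are manufactured in lots of at
   most a few hundred; spotting-concentration differences between lots create
   features that separate *lots*, not patients. A study whose cases and
   controls sit on different lots will report lot artifacts as biomarkers.
3. **Selection-induced overfitting.** Selecting features on all data and then
   measuring accuracy on the same data — or re-selecting per training split
   with a univariate score and reading training accuracy — yields panels that
   look perfect and generalize barely better than chance.

The package implements a full discovery workflow: batch ingestion of GenePix
results (gpr) files, protein-level matrix assembly, normalization, the
M statistic, a hybrid feature-selection cascade (score voting, manual voting,
preselection, manual selection, and an evolutionary wrapper around a random
forest), repeated train/test validation of the resulting panels, and a
synthetic-study generator with planted ground truth so that every stage is
testable without access to patient data.

# Data model and ingestion

A gpr file (ATF 1.0 dialect) holds one scanned array: per-spot coordinates
(block/row/column), feature name and accession, single-channel (635 nm)
foreground and background median intensities, and a quality flag (negative =
bad). `read_gpr()`/`write_gpr()` round-trip these records exactly;
`load_study()` batch-loads one file per row of a study design table
(`sample_id`, `group`, `lot`, `day`, `filename`), failing loudly when design
rows lack files and skipping (with a warning) files without design rows.

`collapse_features()` turns spot-level scans into a proteins × samples
matrix. Choices made here, each overridable:

* **Background**: `signal = max(f_median − b_median, 1)`. Local-background
  subtraction is the platform default; flooring at 1 scanner count keeps the
  subsequent log2 defined. `background = "none"` disables it.
* **Duplicates**: arithmetic mean of unflagged duplicate spots (median
  selectable). Proteins are spotted in duplicate on this platform.
* **Flags**: spots with `flags < 0` are excluded from aggregation. If *all*
  replicates of a protein are flagged on an array, the array's minimum
  observed protein value is imputed and a warning emitted — downstream
  scoring requires complete columns, and the array minimum is a conservative
  "no signal" stand-in.
* **Controls**: features whose name matches a configurable case-insensitive
  substring list (`control`, `buffer`, `empty` by default) are excluded from
  the matrix but kept in a side table; control nomenclature varies by lot,
  hence patterns rather than a fixed list.

# Normalization

Both normalizations operate on the log2 scale (quantile normalization can
also be run on the raw scale) and delegate the numerics to limma, which is
the standard tool for this step:

* `quantile_normalize()` forces every sample to the across-column mean of
  order statistics; tied input values receive the mean of their tied target
  quantiles, preserving within-column ranks.
* `loess_normalize()` fits, per sample, a locally weighted regression of the
  difference from the row-wise mean reference array on the average intensity
  and subtracts the fitted trend (span 0.3, 4 passes). This is the
  single-channel, mean-reference variant of MA-plot loess normalization —
  O(n·p) rather than all-pairs cyclic, which is adequate for single-color
  arrays.

Two caveats worth knowing. First, loess smoothing is not a projection, so the
normalization is only approximately idempotent: re-applying it changes values
by an amount that scales with the residual noise level (mean absolute change
below 10⁻³ on low-noise data, larger near the intensity extremes where the
smoother extrapolates). Second, which normalization feeds the selection
cascade is a sweep parameter of the pipeline, not a fixed choice; the
comparisons can be run under either.

# The minimum M statistic

For a protein with intensities `x1` (group 1, n₁ samples) and `x2` (group 2,
n₂ samples), every observed intensity `t` defines exceedance counts
`a = #{x1 ≥ t}` and `b = #{x2 ≥ t}`. If the elevated group is group 1, the
chance of drawing at least `a` group-1 members when drawing `a + b` samples
from the pooled n₁ + n₂ under exchangeability is the hypergeometric upper
tail

$$P(X \ge a), \qquad X \sim \mathrm{Hypergeom}(N = n_1 + n_2,\; K = n_1,\; n = a + b),$$

computed in log space via `phyper`. The **M score** is the minimum of this
tail probability over all candidate cutoffs; the reported cutoff is the
observed value attaining it. Because only the top of the pooled ordering
matters, a marker elevated in a minority of cases can still reach a very
small score — the subgroup sensitivity the statistic exists for.

Conventions, all chosen for determinism and testability:

* Cutoff grid = observed values; tail convention = `≥` (both are the
  platform's documented defaults).
* Ties across cutoffs (equal tail probability) break toward the smallest
  `a + b`, i.e. the most specific subgroup. Since mathematically equal tails
  computed at different cutoffs can differ in the last floating-point ulp,
  minima within a relative tolerance of 10⁻⁹ are grouped before tie-breaking.
* Direction is one-sided by default (the elevated group is specified);
  `direction = "both"` minimizes over both orientations and prefers group 1
  on a tie. `standard_comparisons()` runs all four study comparisons
  (control vs case twice, control vs control, lot vs lot) one-sided with the
  second group tested as elevated.
* The statistic depends on the data only through ranks, so it is invariant
  under any strictly increasing transform — in particular, quantile and
  loess normalization change scores only insofar as they reorder samples
  within a protein.

## Calibration: M scores are not p-values

M scores are minima over ~n₁+n₂ strongly dependent tail probabilities and
are **not** adjusted for this multiplicity (nor for testing thousands of
proteins). At small group sizes the discreteness of the hypergeometric keeps
the statistic conservative — with 3 vs 3 samples the smallest attainable
score is 1/C(6,3) = 0.05, reached only by complete separation. At realistic
group sizes the multiplicity dominates: simulation (both with this package
and with an independent SciPy implementation) puts the exchangeable-null
fraction of scores below 0.05 at **≈ 0.22–0.24** for 36 vs 36 samples, not
below the nominal 0.05. Two consequences propagate through the pipeline and
are flagged where they bite:

* A "does-not-discriminate" vote thresholded at 0.05 (the HC-vs-DC exclusion
  vote below) wrongly discards roughly a quarter of true markers, because
  for a case-specific marker the control-vs-control comparison is exactly a
  null comparison.
* Deployed implementations of this statistic mitigate the multiplicity with
  raw-intensity guards (cutoffs restricted to intensities above a floor and
  separated by a margin). Such guards are raw-scale-specific and would break
  the rank invariance above, so they are deliberately not part of this
  implementation.

An optional Benjamini–Hochberg column is available on score tables but is
off by default, since the scores are not p-values to begin with.

# The hybrid selection cascade

`hybrid_selection()` chains the stages; each is usable alone.

**Score voting.** Each protein receives one binary vote per rule. The default
rules are the study's published convention: vote 1 for score < 0.05 in each
case comparison (HCvsPD, DCvsPD), for score ≥ 0.05 in the
control-vs-control comparison (HCvsDC — separating the two control groups is
disqualifying), and for score ≥ 10⁻⁵ in the lot comparison (lot1vslot2 —
lot-discriminating features are manufacturing artifacts). The extremely
small lot threshold reflects that genuine lot artifacts produce
near-complete separation over ~50 arrays per lot, with scores many orders of
magnitude below anything a clinical effect produces.

**Manual voting.** Human raters inspect one intensity plot per protein
(`render_intensity_plots()`: per-sample intensities grouped by clinical
group, point symbol by lot) and vote 0/1; `load_manual_votes()` reads the
resulting TSV. Manual voting cannot be automated — for testing, the
generator ships `simulate_votes()`, raters parameterized by sensitivity and
specificity against the planted truth.

**Preselection.** A conjunction of vote-sum rules over named column subsets.
The default is the strictest reading of the published scheme: all four score
votes required. This makes lot exclusion airtight (a lot-discriminating
protein can never be preselected) at a known cost: the HCvsDC vote's null
miscalibration (above) removes ~25% of true markers. The rule set is a
config value precisely because this trade-off is study-specific; the exact
thresholds behind the original study's 215 preselected proteins were never
published, so 215 is treated as data-dependent, not a target.

**Manual selection.** Among preselected proteins, keep those whose *total*
vote sum (score + manual) reaches an overall threshold — by default all
score votes plus a majority of the five manual votes (8 of 9).

**Automatic selection.** `ea_wrapper_select()` evolves bitmask individuals
over the preselected features. Fitness = multiclass random-forest accuracy
(stratified k-fold CV, or out-of-bag from a single forest) minus
`size_penalty` × panel size (default 0.001/feature, enough to break accuracy
ties toward smaller panels without overriding real signal). Operators:
tournament selection (size 3), uniform crossover (rate 0.7), per-bit
mutation 1/L, elitism 1 — standard choices, fixed since the source protocol
names only "an evolutionary algorithm". "Iterations" counts fitness
evaluations, not generations: the published budget of six runs × 100 000
iterations is only feasible under that reading, and those are the
`ea_config()` defaults. Interactive and test-scale work uses far smaller
budgets (population 40, ~2000 evaluations, out-of-bag fitness). Fitness
values are cached per mask within a run, which also makes the per-run
fitness function deterministic; the entire search is reproducible from
`cfg$seeds`. With elitism the best fitness is non-decreasing across
generations, which the test suite asserts. Wrapper selection interacts with
the classifier and handles the three-class problem directly — the two
capabilities univariate scoring lacks.

**Combination.** The final panel is the de-duplicated union of the manual
and automatic panels (manual first, shared proteins marked `both`),
mirroring the published 22 + 18 → 36 arithmetic.

# Validation

`binarize_groups()` builds the case-vs-combined-controls labeling
(e.g. PD vs "HC+DC", 72 vs 144). `split_stratified()` draws
train/test splits at 2/3–1/3 conserving class proportions
(largest-remainder rounding), reproducibly from (seed, subrun); ten subruns
by default. Two strategies are compared:

* **Fixed panel** (`validate_fixed_panel()`): the candidate panel is fixed
  in advance; per subrun a random forest (500 trees) is trained on the
  training split and evaluated on the test split. Note the deliberate,
  documented optimism: when the panel was itself selected on all data (as in
  the source protocol), its test accuracy still contains selection bias.
  This workflow replicates, rather than fixes, that property; a fully
  nested selection is the known remedy.
* **Per-split top-k M score** (`validate_mscore_only()`): in each subrun the
  k = 36 proteins with the smallest M scores *on the training split only*
  are selected and a forest trained on them. Selection never sees test data
  — the test suite re-derives each subrun's panel from the stored train
  indices to prove it — yet the strategy still overfits, because the
  selection chases the training split.

Reports store **both** resubstitution and out-of-bag training accuracy. The
published tables show 100% training accuracy for per-split selection
(resubstitution-like) next to ~74.5% for the fixed panel (out-of-bag-like)
without defining "train accuracy"; storing both makes either reading
reproducible, and `summary()` lets the caller pick the column.

Averages are arithmetic means of the subrun accuracies, rounded half-up to
one decimal — except that a mean landing exactly on the midpoint of the
first decimal (x.y5) is printed exactly at two decimals. This is the only
rule consistent with all published average cells (73.47 → 73.5,
79.29 → 79.3, 83.63 → 83.6, but 58.25 printed as 58.25).

# The synthetic-study generator

`simulate_study()` emulates the structure the workflow targets, with known
ground truth:

* Defaults mirror a large discovery study: clinical groups HC/PD/DC of 72
  samples each (216 arrays), two production lots, 4652 non-control proteins
  plus 100 controls spotted in duplicate (9504 spots/array).
* Baseline protein log2 intensity ~ Normal(10, 1) (≈10³ scanner counts over
  a ≈2⁶ background), per-sample noise sd 0.5, multiplicative duplicate-spot
  noise (CV 0.1), 1% flagged spots.
* **Markers** (default 36) add `marker_effect` (default 1.5 log2 units) to a
  random responder subset of case samples only (default fraction 0.5) — the
  subgroup-responder regime, since subgroup sensitivity is the statistic's
  selling point. `responder_fraction = 1` gives a uniform group shift.
* **Lot features** (default 50) add `lot_effect` (default 1.0) to all
  samples of the second lot — additive on the log scale, i.e. a
  multiplicative spot-concentration artifact on the raw scale. A separate
  per-array scale-jitter knob covers global array-level effects.
* `balanced_design()` distributes groups equally over lots;
  `confounded_design()` reproduces the criticized design (all cases on one
  lot) under which lot artifacts are indistinguishable from disease markers
  — on such data the case-vs-control comparison flags essentially every
  planted lot feature at score < 0.05, while the balanced design plus the
  lot-exclusion vote removes them completely.

What the generator does **not** emulate: spatial artifacts, scanner
saturation, day/carryover effects, correlated protein families, or
antibody cross-reactivity. Passing tests on synthetic data therefore show
that the machinery is correct and that the design-level arguments
(confounding, overfitting) hold in a controlled world — not that any given
real study will reach the same accuracies.

# Problem sizes used by the test and acceptance code

Chosen to exercise each claim at the smallest scale where it is meaningful:
oracle equivalence at n₁ = n₂ ≤ 4 against exhaustive enumeration with
explicit combination counts; null calibration at 2000 proteins, 36 vs 36;
the overfitting signature at 3000 proteins, 24 cases vs 48 combined
controls, 36 weak markers (effect 0.8, responder fraction 0.3), 10 subruns;
the confounding demonstration at 1000 proteins with 100 lot features;
pipeline recovery at 3000 proteins, 36/group, generator defaults, with the
evolutionary wrapper at test scale (two runs × 1000 evaluations, population
40, out-of-bag fitness, 80 trees).

# Known limitations

* The M score's null exceedance at realistic group sizes (≈0.22 below the
  nominal 0.05 at 36 vs 36) means score-vote thresholds act as *relative*
  rankings, not error rates; the exclusion votes in particular trade marker
  recall for artifact exclusion. Under the default (strictest) preselection
  rules, planted-marker recovery on synthetic studies plateaus around
  60–75% — the HCvsDC vote alone accounts for most of the loss.
* Fixed-panel validation inherits the selection optimism described above.
* Robust-linear-model normalization, empirical-Bayes batch adjustment,
  k-fold/bootstrap validation and two-channel arrays are out of scope.
* The evolutionary wrapper at desk-scale budgets over hundreds of candidate
  features returns unions well above the published 18-protein automatic
  panel; converging to panels that small requires the full published budget
  (6 × 100 000 evaluations).
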