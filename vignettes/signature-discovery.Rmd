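---
title: "Serum antibody-microarray signature discovery with sigpanel"
author: "sigpanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum antibody-microarray signature discovery with sigpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`sigpanel` implements the analysis chain used to derive diagnostic serum
protein signatures from highly multiplexed recombinant antibody (scFv)
microarrays, with pancreatic ductal adenocarcinoma (PDAC) versus
non-pancreatic controls (NPC) and versus other pancreatic diseases (OPD) as
the motivating setting. The chain runs from spot-level fluorescence
intensities to frozen-model test-set metrics:

1. replicate aggregation with a CV dismissal rule,
2. failed-sample exclusion,
3. log10 transform and two-step normalization (round centering, array
   scaling),
4. differential expression (Student *t*, Benjamini-Hochberg *q*-values,
   one-way ANOVA, *p*-filtered PCA),
5. SVM backward elimination ranked by Kullback-Leibler classification
   error, repeated over stratified 2/3 splits, with endurance scoring,
   consensus panels and frozen-model evaluation.

Spot-level data live in a `SpotTable` (one row per sample, antibody and
replicate spot, intensity and local background kept separate so
subtraction is explicit); sample metadata in a `SampleSheet`; matrices in
an `ArrayExpressionSet`, a `SummarizedExperiment` whose `exprs` assay has
antibodies as rows and samples as columns and whose `stage` slot tracks
provenance (`raw_aggregated`, `logged`, `round_normalized`,
`fully_normalized`). Because no public spot-level cohort of this design
exists, the package ships a synthetic generator that is itself first-class,
tested code; every downstream stage is validated against cohorts with known
ground truth.

# Preprocessing model

**Replicate aggregation.** Each antibody is printed in three replicate
spots. After per-spot background subtraction (floored at 1.0 so the later
log10 is total), the value is the replicate mean unless the coefficient of
variation (100·sd/mean, linear scale) exceeds 15%. The dismissal rule
drops the replicate farthest from the three-replicate mean — the choice
that maximally reduces the CV. With only two replicates present nothing is
dismissed (there is no principled way to pick a side), and singletons are
flagged missing.

**Failed samples.** Arrays that yield essentially no signal are detected
by a robust rule: a sample is excluded when the robust z-score of its
median log10 intensity, against the cohort median and MAD of those
medians, falls below −4. When the MAD degenerates to zero the rule falls
back to an absolute floor (median log10 < 1). The emulated study simply
reported excluding two near-signal-free samples without giving a rule;
the robust-z formulation is this package's own operationalization and its
thresholds are deliberately conservative — on the default generator only
the two planted failures (signal attenuated 100-fold) are caught.

**Two-step normalization.** Analysis-round (printing day) batch shifts are
removed per antibody by subtracting the within-round mean and adding back
the global antibody mean ("subtract group mean"); after this step every
(antibody, round) mean equals the global antibody mean to numerical
precision, which the tests assert at 1e-9. Array-to-array differences are
then removed with one scaling factor per subarray, computed from the
reference set of antibodies with the lowest cross-sample CV (bottom 20%,
CV taken on the linear scale after round normalization; ties broken by
antibody id). Working in log10 space the factor is subtractive — the
sample's reference-set mean minus the grand mean of that quantity — which
is equivalent to division on the linear scale and keeps both normalization
steps in a single domain. An alternative reading (multiplicative scaling
on linear intensities before logging) is possible; the log-space form is
the package default and the one all exactness guarantees refer to.

**Preanalytical screening.** Per factor (clinical center, gender, age
quartile, subarray position, analysis round) a one-way ANOVA is run per
antibody on log10 data and the fraction of antibodies with *p* < 0.01 is
reported without multiplicity correction: under the null this fraction
sits near the threshold itself, so inflation is directly readable. The
generator gives age and gender no effect by default, which makes these
null checks meaningful.

# Differential expression

Two-group comparisons use the pooled-variance Student *t*-test (Welch is
available behind a flag), BH step-up *q*-values (via `p.adjust`), and fold
changes reported both as log10 differences and as signed linear ratios
(the field reports fold changes without fixing a scale; both are given).
Degenerate rows follow explicit conventions: zero pooled variance with
equal means gives t = 0, p = 1; with unequal means p = 0 and the row is
flagged. The one-way ANOVA is a vectorized closed-form row statistic
(checked against `stats::aov` to 1e-9 on a thousand random instances) and
with two groups satisfies F = t² to the same precision.

The PCA projection filters antibodies at *p* < 1e-10 (the threshold used
for the study's figures), z-scores each kept antibody across samples —
variance normalization, matching the behavior of the visualization tool
the study used — and fixes each component's sign by making its
largest-magnitude loading positive so coordinates are reproducible.

# The signature engine

**Classifier.** A soft-margin linear-kernel C-SVC with cost 1. The dual is
solved by a sequential-minimal-optimization routine (maximal violating
pair selection, KKT gap < 1e-3, matching the conventional default of
reference solvers) implemented in C++ on precomputed Gram matrices.
Features are standardized with training-set (or training-fold) mean/sd
only; the standardization travels with the frozen model, so test samples
are mapped through training statistics and no information leaks backwards.
The solver is cross-checked against `e1071::svm` on random instances
(weights and decision values agree to solver tolerance).

**K-L error.** The elimination criterion maps decision values through the
logistic link p = 1/(1+e^{−d}), clips to [1e-6, 1−1e-6], and sums the
Kullback-Leibler divergence from the point-mass truth to the prediction —
i.e. the cross-entropy, in nats. A maximally uncertain classifier
contributes ln 2 per sample; a clipped-perfect one about 1e-6. The
original method's exact formulation is not published as a formula; the
cross-entropy reading is consistent in magnitude with the reported values
(a K-L of ~12 over ~124 training samples corresponds to a mean assigned
probability of ~0.91 for the true class, and reported near-chance values
scale like n·ln 2). Whether the original evaluated a distributional
divergence between class-wise decision-value densities instead is left as
an open alternative; the function boundary (`klError`) is the hook for
experimenting with one.

**Decision values during elimination** come from stratified 5-fold
cross-validation inside the training set, never from resubstitution —
resubstitution would drive the K-L of any separating panel to zero and
destroy the ranking. Fold assignments are derived from a named seed stream
and held fixed within an elimination round, so all candidates in a round
are compared on identical folds.

**Backward elimination** is exhaustive: each round refits every candidate
(panel minus one antibody) and removes the one whose absence minimizes the
K-L error, ties broken lexicographically. Efficiency comes from two
observations: for a linear kernel, dropping feature *a* is a rank-1
downdate of the Gram matrix (K − z_a z_aᵀ), and the previous panel's dual
solution is a feasible warm start for every candidate. Together these make
the O(N²) candidate evaluations cheap without changing what is computed;
a naive reimplementation (full restandardization and refit per candidate,
no warm starts) reproduces the removal order exactly in the test suite.
For very large panels a fast mode (`method = "weight"`) removes the
antibody with the smallest mean absolute standardized SVM weight instead
of refitting every candidate; it is an approximation, clearly labeled as
such, and the exhaustive search remains the default.

**Endurance scores and panels.** Over 10 independent stratified 2/3
splits, an antibody removed at position n in a trace has endurance n (1 =
first out, N = last survivor); its score is the mean endurance, and the
top 25 by score form the consensus panel, with distinct-antigen counting
when a clone annotation is supplied. Per trace, the K-L curve across panel
sizes gives the K-L-minimum panel (ties resolved toward the smaller,
more parsimonious panel). Frozen top-25 models are evaluated on the
held-out third: rank-statistic AUC (ties counted 1/2, invariant to
monotone transforms) and sensitivity/specificity/PPV/NPV in percent at a
decision-value threshold of zero.

# The synthetic generator

`buildDesign` reproduces the emulated study's shape: 156 PDAC (with a
97/16/10/16/17 head/body/tail/other/unspecified subsite split), 152 OPD
and 30 NPC samples from 5 hospitals, laid out by seeded permutation over
5 rounds × 8 slides × 13 subarrays, with group-specific gender fractions
and age distributions. `simulateSpotTable` composes, per sample and
antibody, in log10 space: an antibody baseline N(3.0, 0.5²), additive
group/subsite effects, biological noise N(0, 0.15²), a per-round offset
N(0, 0.05²) with round 1 inflated threefold (mimicking a printing-day
humidity artifact, and giving normalization a realistic worst case), and
a per-array offset N(0, 0.1²). Replicate spots then measure
10^level·(1+ε) with linear-scale ε ~ N(0, 0.08²) — producing
intensity-proportional CVs in the high-single-digit percent range typical
of printed triplicates — plus a 2% rate of 1.4× outlier spots, local
background around 100 fluorescence units, and (by default) two OPD
samples attenuated 100-fold to exercise failed-sample detection. Effect
magnitudes default to 0.5 log10, chosen so planted markers are recoverable
but not trivially separable at 30 samples per group; half the informative
markers point downward by default, as published marker tables show both
directions.

What the generator does *not* emulate: antibody cross-reactivity and
correlated marker modules, spot morphology and scanner saturation, and
heteroskedastic replicate noise. The last point matters for one published
summary: with a single replicate-noise sigma the CV distribution is
narrower than a real platform's, so the share of values computed from all
three replicates comes out near 90% rather than the ~70% a wider CV
spread produces at the same 15% cutoff. Tests therefore calibrate against
the mean replicate CV (the suite asserts the 5–12% band around the
platform's reported 8.3%), not against the dismissal share. More broadly,
passing planted-recovery tests shows the machinery is correct and
well-calibrated, not that real serum cohorts will yield panels of any
particular accuracy.

# Numerical choices

* Background-subtracted intensities are floored at 1.0 before any log.
* SMO stopping tolerance 1e-3 (KKT gap); probability clipping at 1e-6;
  all ties — replicate dismissal, elimination, rankings, reference-set
  selection — break deterministically (first index or lexicographic id).
* All randomness flows through named, seed-derived streams (design,
  effects, biology, replicates, split r, folds per round), so components
  are independently reproducible and whole runs are byte-identical under
  a fixed seed.
* Constant features get standardization scale 1; zero-variance rows
  follow the p = 1 convention in tests; MAD = 0 triggers the absolute
  failed-sample floor.

# Problem sizes

The validation suite and the acceptance script run, as the package's own
choice of scale, on reduced cohorts: parameter-recovery and null
calibration on 60 cases / 20 controls × 100 antibodies with 10 split
repeats; elimination-oracle checks on 40 samples × 6 antibodies; the
self-contained `simulateAndRun` demo on 45/45/20 samples × 60 antibodies
with 3 repeats. These sizes keep the exhaustive elimination to seconds
per repeat while preserving every structural feature of the full design
(replicates, rounds, subarrays, subsites, failed samples).

# Known limitations

* The K-L formulation is a reasoned reconstruction (see above), not a
  published formula.
* The dismissal rule's "which replicate" choice and the scaling factor's
  scale/order are underdetermined by the source description; the choices
  here are documented defaults, with the Welch flag and the `klError`
  boundary as the main experimentation hooks.
* Published cohort-specific numbers (specific marker rankings, the 7-plex
  panel's 98%/90% operating point, the 0.98 mean AUC) depend on the
  original serum samples and are not reproducible from synthetic data;
  the package reproduces the *procedure* and verifies it by parameter
  recovery and calibration instead.

# A minimal session

```{r example}
library(sigpanel)

cfg <- cohortConfig(nPdac = 60L, nOpd = 0L, nNpc = 20L,
                    nAntibodies = 100L, seed = 7L)
eff <- plantEffectProfile(antibodyIds(100), kNpc = 10L, kOpd = 0L,
                          kSite = 0L, delta = 0.8, seed = 7L)
sim <- simulateCohort(cfg, effects = eff, seed = 7L)

prep <- runPreprocessing(sim$spots, sim$sheet)
sig <- runSignatureDiscovery(prep$matrix, c("PDAC", "NPC"),
                             nRepeats = 10L, panelSize = 25L, seed = 7L)
sig$summary$mean_auc
intersect(sig$consensus$panel, eff@informativeSets$pdac_vs_npc)
```
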