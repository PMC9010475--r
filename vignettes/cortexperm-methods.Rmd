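---
title: "Methods: cluster-based permutation inference for longitudinal cortical change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-based permutation inference for longitudinal cortical change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexperm)
```

## The problem

Two groups of subjects are measured twice on a parcellated cortical
quantity — here the regional T1w/T2w intensity ratio, a proxy for
intracortical microstructure (myelin and dendrite density) — and the
question is whether the *change* between timepoints differs between
groups, and where. The prototypical design is a sleep-deprivation study:
a control group keeps a normal sleep-wake cycle (NSW, n = 23) while an
exposed group stays awake (SD, n = 18), with scans roughly 32 h apart and
measures extracted for 180 regions per hemisphere of a multimodal
parcellation.

Region-wise tests on 360 regions need multiplicity control, but regions
are spatially organised: real biological effects tend to cover several
adjacent parcels, noise does not. Cluster-based permutation inference
exploits this by using the *size of the largest connected set of
supra-threshold regions* as the test statistic, calibrated by group-label
permutation.

## The pipeline

### Change metric

The primary outcome is the symmetrised percentage change
$$\mathrm{SPC} = \frac{TP2 - TP1}{TP2 + TP1} \times 100,$$
bounded in (−100, 100) for positive measures, antisymmetric in the
timepoints, and invariant to common rescaling of both sessions — which is
why it is preferred over plain percentage change for intensity-derived
measures. The raw difference $TP2 - TP1$ is available as a sensitivity
outcome (`computeRawDiff()`). Non-positive measure values are rejected at
load time rather than masked: the T1w/T2w ratio is physically positive in
cortex, so a non-positive value indicates an upstream extraction fault.

### Region-wise models

For each region, ordinary least squares of the change on group plus
nuisance covariates, with group coded 0 (NSW) / 1 (exposed), so a
positive coefficient means the exposed group increased more. The default
nuisance covariate is a head-movement index derived from the surface
reconstruction Euler number. The Euler number exists per timepoint but
the change model needs one value per subject; the per-subject *mean* of
the two timepoints is used by default, with per-timepoint and difference
options (`headMovementIndex()`). All regions share one design matrix, so
the 360 fits are a single multi-outcome solve.

P-values are two-sided throughout: the two groups can change in opposite
directions, and the cluster maps are interpreted as two-sided effects.

### Cluster formation and the permutation null

Regions with uncorrected $p$ strictly below the cluster-forming threshold
(default 0.05; "below" is taken literally, so $p = 0.05$ does not enter)
are partitioned into connected components of the parcellation adjacency
graph. Adjacency is supplied as data (an edge list), not computed from
surfaces: the inference is agnostic to how borders were obtained, and
synthetic graphs plug in directly. Hemispheres are disjoint components of
the graph, so clusters never span the midline without any special-casing.

The null distribution is built by re-shuffling group membership across
subjects (covariates stay attached to their subjects), refitting all
regions, re-forming clusters, and recording the maximum cluster size over
the *whole* graph — one pooled null across both hemispheres, which
controls the family-wise error across all reported clusters. 5000
permutations is the convention; labelings are drawn uniformly with
replacement, and when the number of distinct labelings
$\binom{n}{n_B}$ does not exceed the requested count the null is instead
enumerated exhaustively (e.g. 70 labelings for a 4 + 4 cohort), making
small-cohort nulls exact.

Corrected p-values use the add-one convention
$p = (1 + \#\{\text{null} \ge k\})/(1 + B)$: never exactly zero, so a
cluster beating all 5000 permutation maxima reports $p \approx 0.0002$,
consistent with "p < 0.0001"-style reporting. Clusters of equal size get
identical corrected p — the statistic is size only, with no mass or
strength weighting. Freedman–Lane-style residual permutation was
considered and not implemented: the design has a single binary factor of
interest and covariates independent of group by design, where simple
label permutation is standard and exact under exchangeability.

### Effect sizes

Hedges g of the unadjusted group difference in mean change,
$g = J \, (\bar x_B - \bar x_A)/s_p$ with
$J = 1 - 3/(4\,df - 1)$; the exact gamma-function correction is available
and agrees to well beyond two decimals at these sample sizes. Effect
sizes are conventionally computed *without* the head-movement covariate
(in contrast to the inference), for interpretability. The sign convention
is fixed at exposed minus reference; published cluster effect sizes flip
sign between analyses, which is an orientation choice, not inference, so
the package fixes one convention and documents it.

### Sensitivity analyses

For significant clusters the per-subject mean over member regions is
extracted, and:

* **covariate adjustment** — the cluster-level group test is refit adding
  haematocrit change ($TP2 - TP1$, the hydration proxy; the change form
  is chosen to match the change outcome) and cluster-mean cortical
  thickness change;
* **outlier exclusion** — the full pipeline is rerun without a named
  subject, with a before/after comparison (cluster counts, significant
  region totals, Jaccard overlap). Outlier *identification* is left
  explicit and manual; an IQR-based flagging helper is provided as a
  clearly-labelled screening extension, never applied automatically;
* **depth reruns** — the whole analysis repeats independently per
  cortical sampling depth (30/50/70%); each rerun is a pure function of
  its own table;
* **off-hemisphere summary** — order statistics of uncorrected p over a
  named region subset (e.g. LH homotopic counterparts of RH-only
  clusters), with homotopy supplied as a two-column pair map, never
  inferred from names.

### Behavioural interactions

Behavioural change scores: sleepiness (KSS, a 9-point scale) and
psychomotor-vigilance measures — lapses (reaction times strictly greater
than 500 ms; 500 ms exactly is not a lapse), median RT, and RT variance
(sample variance convention). The interaction model is OLS of the
cluster-mean change on group, the behavioural change, and their product;
the interaction p is the headline statistic, with within-group Pearson
correlations (Spearman optional) reported descriptively. The imaging
measure is kept as the outcome throughout the package; correlations are
symmetric, so this is an orientation convention. Missing behavioural data
are dropped listwise per analysis with counts reported. The
Benjamini–Hochberg FDR family is, by convention, all clusters × all
measures of one run.

## The synthetic cohort generator

`simulateCohort()` draws
$$TP1_{sr} = b_r + u_s + \epsilon_{sr}, \qquad
  TP2_{sr} = b_r + u_s + d + \delta\,[s \in SD][r \in E] + \epsilon'_{sr}$$
with region baselines $b_r \sim N(1.5, 0.1^2)$ (T1w/T2w-ratio scale),
subject intercepts $u_s \sim N(0, 0.05^2)$, residual noise
$\epsilon \sim N(0, 0.02^2)$ per region and timepoint, optional common
drift $d$, and an additive exposed-group shift $\delta$ on a contiguous
region set $E$ grown breadth-first from the centre of one hemisphere's
lattice. The default graph is a rectangular grid per hemisphere with
4-neighbour adjacency (180 regions = 12 × 15, 333 edges per hemisphere):
planar, internally connected, with trivially verifiable edge counts.

The planted effect size is specified on the Hedges-g scale of the SPC
group difference. By the delta method, with noise small relative to the
baseline, the SPC group difference of means is $\approx 100\delta/(2b_r)$
and its within-group SD $\approx 100\sqrt{2}\sigma_\epsilon/(2b_r)$, so
$$\delta = g \sqrt{2}\, \sigma_\epsilon$$
independent of the baseline. A Monte-Carlo check of this calibration (the
average observed per-region g across replicates) is part of the test
suite. Any draw that would make $TP1 + TP2 \le 0$ is redrawn, so SPC is
defined everywhere; with the default parameters this essentially never
triggers.

Residual variance and intra-subject correlation have no published
estimates for this design; the defaults above are chosen to be realistic
for intensity-ratio measures (between-region spread ≫ within-subject
noise) and are free parameters of the generator, not data-derived.
Nuisance covariates default to independence from group, matching a
randomised design; a confounded mode (`covariateGroupEffect = TRUE`)
shifts head movement and haematocrit by group for robustness testing.
Behavioural change scores are drawn with group-specific means mirroring a
sleep-deprivation design (sleepiness rises in the exposed group).

What the generator does **not** emulate: spatially correlated noise
(regional noise is independent given the subject intercept), non-Gaussian
tails, missing data, scanner or session effects beyond a scalar drift,
and any circadian time-course beyond that drift. Passing calibration and
recovery tests therefore demonstrates correctness of the *inference
machinery* under a clean generative model, not robustness to every
property of real MRI data — in particular, smooth spatially correlated
noise would enlarge null clusters, which the permutation null would track
but which these simulations do not exercise.

## Numerical and design choices

* Degenerate fits (zero residual variance, e.g. all-constant outcomes)
  report $t = 0, p = 1$ rather than 0/0.
* Component and cluster ordering is fixed (size descending, ties by
  lexicographically smallest member) so outputs are byte-reproducible.
* Duplicate and reversed edges collapse on graph construction;
  cross-hemisphere edges are an error by default (downgradable to a
  drop-with-warning).
* Demographic-table recomputations use Welch's unequal-variance t with
  Welch–Satterthwaite df — the choice that reproduces published
  fractional df — in both summary-statistic and raw-vector forms, which
  agree exactly.
* The mixed 2 × 2 (group × time) ANOVA for design checks is fit via
  `stats::aov` with an `Error(subject)` stratum; the test suite verifies
  it against an independent sums-of-squares decomposition.
* Everything stochastic takes an explicit seed; the pipeline is a single
  R process, so results are trivially independent of any thread count,
  and rerunning a configuration with the same seed reproduces
  byte-identical output tables.

## Validation problem sizes

The packaged checks run the full machinery at study scale: family-wise
error calibration uses 200 synthetic null cohorts (23 vs 18 subjects, 360
regions) with 500 permutations each, and planted-effect recovery uses 120
replicates of a 10-region contiguous effect at g = 0.8 with 400
permutations each — sizes at which the binomial confidence intervals are
informative while the suite stays fast. Exactness of the permutation
machinery is checked against exhaustive enumeration on a 4 + 4 cohort
(70 labelings), and cluster formation against a brute-force connectivity
oracle on random graphs.

## Limitations

Two timepoints only; no longitudinal mixed-effects models. Cluster-size
statistics only (no TFCE, cluster mass, or spin nulls). The permutation
scheme assumes exchangeability of subjects under the null with covariates
balanced by design; strongly group-confounded covariates call for
residual-permutation schemes the package deliberately omits. Adjacency
fidelity is the user's responsibility — whether corner-touching parcels
count as neighbours is whatever the supplied edge list encodes.
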