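---
title: "Edge-wise contrasts of resting-state functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-wise contrasts of resting-state functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccontrast)
```

## The model

Resting-state functional connectivity (FC) between two brain regions is the
temporal Pearson correlation $r_{ij}$ of their mean BOLD time series,
summarized on the variance-stabilized Fisher scale $z_{ij} =
\operatorname{atanh}(r_{ij})$. Positive $z$ indicates temporally correlated
(coordinated) activity, negative $z$ inversely correlated activity; both
are physiologically meaningful. Each subject contributes one symmetric
$R \times R$ matrix of $z$ values; the diagonal is not a connection and is
excluded everywhere.

The unit of inference is the *edge*: an unordered region pair, of which
there are $R(R-1)/2$. Two contrasts are supported.

**Cross-sectional.** For two groups (convention: condition A = cases,
condition B = controls), each edge's effect is
$\Delta z = \bar z_A - \bar z_B$, tested with a two-sided unpaired
pooled-variance Student $t$-test on the per-subject $z$ values. Positive
$\Delta z$ means stronger connectivity in the cases.

**Longitudinal (difference-in-differences).** For a two-arm pre/post
design, each subject's change matrix is $z^{post} - z^{pre}$; the
treatment effect at an edge is the arm contrast of mean changes,
$(\overline{\Delta z}_{treated} - \overline{\Delta z}_{control})$, tested
the same way on the change scores. Baseline offsets and shared time trends
cancel exactly (the test suite asserts shift invariance, arm antisymmetry,
and equality with the contrast of precomputed change matrices). The
change-score $t$-test equals the group-by-time interaction of the
$2 \times 2$ repeated-measures ANOVA; rather than building a bespoke ANOVA
engine we prove the equivalence in the test suite against `stats::aov()`
on randomized datasets to $10^{-10}$.

Multiplicity is handled with Benjamini–Hochberg (via `stats::p.adjust`)
over the full family of $R(R-1)/2$ edges by default. The family choice is
configurable (`fdr_family = "per_lobe_pair"` stratifies the adjustment by
anatomical lobe pair), since edge families are a genuine modelling choice;
for the regional scalar layer (per-region group comparisons and marker
regressions) the adjustment is applied *within each lobe*, matching common
practice for anatomically grouped regional hypotheses.

## The noise band and directional categories

Raw $z$ values are used for every computation; a threshold of $\pm 0.05$
is applied *only* for categorical interpretation. Values inside the open
interval $(-0.05, +0.05)$ are "effectively zero": correlations of that
magnitude are negligible regardless of sign, so categorical summaries
should not read noise-level fluctuation as a positive-to-negative
transition. A value exactly at the boundary counts as meaningful, since
the band is defined as what lies strictly between the limits.

Significant edges are classified by the banded signs of the relevant
means:

* cross-sectional — which group has the stronger meaningful connectivity,
  and with which sign (`stronger_positive_in_A`, `stronger_negative_in_B`,
  ...). When one group is clearly positive and the other clearly negative,
  both readings are defensible; the tie is broken toward the group with
  the larger $|\bar z|$, preferring the positive category on an exact tie.
  This case is not defined by the banded-sign semantics alone, so the rule
  is deterministic, documented, and verified cell-by-cell against an
  enumerated decision table in the tests.
* longitudinal — the four-bar scheme (`more_positive`, `less_positive`,
  `more_negative`, `less_negative`) based on banded pre/post means; a
  genuine crossing from meaningful positive to meaningful negative (or
  back) is reported separately as `sign_transition` rather than forced
  into one of the four bars, and both-in-band edges are `indeterminate`.

Each significant edge also gets a nonnegative ribbon weight for
chord-diagram export. The weight combines the effect magnitude with its
significance; the functional form of such significance weighting is a
presentation choice, and we use

$$w = |\Delta z| \cdot (1 - q)$$

which is bounded, monotone in both inputs, and zero when the evidence is
nil. An alternative $|\Delta z| \cdot (-\log_{10} q)$ scaling is available
(`weight_scheme = "neglog10q"`). Classified edges aggregate into symmetric
pair tables at the hemisphere, lobe (8 anatomical divisions) and
functional-network (9 networks) levels — within-label edges land on the
diagonal, and both edge counts and total weight are conserved — plus a
per-region hub table (degree, total weight, strongest partner) sorted
deterministically.

## The synthetic cohort generator

No imaging data ship with the package; a generator produces cohorts whose
truth is known so every downstream stage is testable.

* **Parcellation.** `make_parcellation()` assigns hemispheres, the 8
  lobes and the 9 networks to `n_regions` regions as evenly as possible
  by permuting balanced label pools under a seed. The default analysis
  size is 32 regions (496 edges): large enough to exercise all label
  machinery, small enough for desk-scale replication studies. Real
  atlases are an order of magnitude larger; nothing in the code depends
  on the region count.
* **Designed covariance.** The control condition has a compound base
  correlation `tanh(base_z)` (default base $z = 0.1$–$0.15$, a realistic
  background coupling level). Effects are *injected in the Fisher-z
  domain* — the scale on which effects are reported — by shifting chosen
  edges so that $z_A - z_B$ equals the target exactly, then mapping back
  through `tanh`. If the injection breaks positive definiteness, the
  matrix is repaired by eigenvalue clipping (floor $10^{-6}$,
  reconstruction, diagonal renormalized); the realized gaps are
  re-checked to within $10^{-3}$ of target and the generator errors out
  rather than silently distorting its own ground truth.
* **Time series.** Subjects are stationary Gaussian draws
  $x_t = \varphi x_{t-1} + \sqrt{1-\varphi^2}\, L\varepsilon_t$ with $L$
  the Cholesky factor, so every timepoint has exactly the designed
  covariance. The AR(1) coefficient $\varphi$ (default 0.3 in the
  analysis scripts) stands in for the temporal smoothness of
  band-limited BOLD noise; it leaves contemporaneous correlations
  unbiased but shrinks the effective number of independent timepoints,
  so calibration studies that quantify error rates use $\varphi = 0$.
  Defaults are 116 volumes at TR 3 s. Per-subject seeds derive
  deterministically from the master seed (an affine hash kept below
  $2^{31}$), so whole cohorts regenerate byte-identically.
* **Arms.** Cross-sectional designs default to 56 cases vs 18 controls;
  RCT designs to 20 subjects per arm with paired pre/post series, the
  treated arm's post distribution carrying the injections and the
  control arm's post equal in distribution to pre.

What the generator does *not* emulate: between-subject heterogeneity in
the true correlation structure (all subjects of a condition share one
population matrix, so only sampling noise separates them), hemodynamic
response shape, physiological and motion artifacts, and covariate
structure (age, sex). Passing the calibration suite therefore shows the
statistics behave correctly under idealized sampling noise — it does not
certify performance on real fMRI, where between-subject variance will
lower power relative to these numbers.

## Validation problem sizes and numerical choices

The calibration suite (`null_fdr_study`, `recovery_study`,
`fidelity_study`) runs at 30 regions (435 edges), 20 subjects per
condition and 116 volumes: the scale of the randomized-trial arm of the
emulated designs, and comfortably replicable on a laptop. Two hundred
global-null replicates bound the realized FDR (each replicate's
false-discovery proportion, averaged) at $\alpha + 3 \times$ Monte-Carlo
SE; fifty replicates with ten disjoint injected edges at $\Delta z = 0.5$
measure sensitivity (target $\ge 0.85$; observed 1.0) and realized FDR
(target $\le 0.10$; observed $\approx 0.03$–$0.05$); two hundred subjects
per condition verify the realized mean $z$ gap at injected edges stays
within $\pm 0.05$ of target.

Numerical conventions, chosen once:

* correlations are clamped to $|r| \le 1 - 10^{-6}$ before `atanh`, so a
  duplicated series yields a finite extreme $z \approx 7.25$ rather than
  infinity, and downstream means and tests stay finite;
* a zero-variance region is an error naming the region (its correlation
  is undefined), not a silent `NA`;
* degenerate edges with zero pooled variance report $p = 1$ when the
  means are equal and the smallest representable positive $p$ (with a
  warning) when they differ — vectorized pipelines stay total and exact
  fits never report $p = 0$;
* edges are ordered row-major over the upper triangle, `(0,1), (0,2),
  ..., (1,2), ...`, and every exported table follows that order, so
  reruns diff cleanly;
* exports are plain TSV/JSON with fixed 15-significant-digit formatting
  and manifests carry no timestamps, making identical-input runs
  byte-identical.

## Open choices and limitations

The edge-level model contains no nuisance covariates; whether the
original analyses adjusted for age or sex is unknown, and the unadjusted
test is the documented default. Marker regressions pool all subjects in a
single simple regression per region. Welch's test is available behind
`test = "welch"` but pooled-variance Student is the default, matching the
declared analysis convention. The package exports tables for chord,
bubble and hub displays but does not render figures; graph-theoretic
summaries (modularity, efficiency) are out of scope. Headline connection
counts reported for the original participant cohorts depend on
undeposited imaging data and are not reproduction targets; the package's
claims are about the behaviour of the method, demonstrated on synthetic
cohorts with known truth.
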