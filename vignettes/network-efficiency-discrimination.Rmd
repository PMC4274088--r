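---
title: "Discriminating clinical groups from functional network efficiencies"
author: "brainNetDx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating clinical groups from functional network efficiencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

brainNetDx implements a complete resting-state functional-connectivity
discrimination analysis for a three-group design: normal controls (NC) and
two patient subtypes, here labeled tremor-dominant (TPD) and
non-tremor-dominant (NTPD) Parkinson's disease. The question the pipeline
answers is whether the *regional efficiencies* of each subject's weighted
functional brain network carry enough information to tell the groups apart,
and which network nodes carry that information.

The pipeline has five stages.

**1. Temporal preprocessing.** Regional BOLD time series are cleaned by
dropping the first 5 volumes (scanner equilibration), removing linear
trends, bandpass filtering to 0.01–0.1 Hz, and regressing out nuisance
signals: the Friston 24-parameter motion set (6 rigid-body parameters, their
one-volume lags, and both sets squared) plus mean white-matter and CSF
signals. The global signal is deliberately *not* removed. The bandpass is an
ideal discrete-Fourier filter — coefficients outside the band are zeroed —
because its rectangular response is exactly characterizable in tests; a
consequence worth knowing is that detrending and Fourier filtering do not
commute (an in-band sinusoid has a nonzero least-squares slope), so the
composed chain is not a projection even though each stage individually is
idempotent. Spatial preprocessing (realignment, normalization, smoothing) is
out of scope: inputs are already regional time series.

**2. Network construction.** Edges are Pearson correlations between regional
series, tested with the exact t transform on $T-2$ degrees of freedom,
thresholded at a Bonferroni-corrected $p < 0.05$ over the
$m = N(N-1)/2$ unordered pairs, restricted to positive correlations, and
weighted by the Fisher transform $z = \tfrac12\log\frac{1+r}{1-r}$.
Isolated nodes are retained so that the node set, and hence the feature
vector, is identical across subjects. Two *template arms* are analyzed: the
full node set ("with cerebellum") and the set with a designated cerebellar
node subset removed before correlation, in which case $m$ shrinks
accordingly. Because the Fisher transform is monotone, applying it before or
after thresholding selects the same edges; we transform after.

**3. Graph metrics.** With edge length $1/w$ (the standard convention for
correlation-weighted connectomes) and $d_{ij}$ the shortest path length:

- global efficiency $E_{glob} = \frac{1}{N(N-1)}\sum_{i \ne j} 1/d_{ij}$,
- nodal efficiency $E_{nodal}(i) = \frac{1}{N-1}\sum_{j \ne i} 1/d_{ij}$,
- local efficiency of node $i$: the global efficiency of the subgraph
  induced by $i$'s neighbors ($i$ excluded, original weights kept;
  0 if fewer than two neighbors), averaged over nodes for the network value.

Unreachable pairs contribute $1/\infty = 0$, and denominators always use the
full $N$, so isolated nodes dilute efficiency rather than disappearing. The
mean of the nodal efficiencies equals the global efficiency algebraically,
which the tests assert to $10^{-12}$. For validation the binary clustering
coefficient $C_p$ and hop-count characteristic path length $L_p$ are also
computed; $L_p$ averages over reachable ordered pairs only, with the
unreachable fraction reported alongside.

Small-worldness is assessed by normalizing against 100 degree-preserving
random networks (double-edge-swap rewiring with $10\times$ edge-count
attempted swaps, original weight multiset re-permuted onto the rewired
edges): $\Gamma = E_{loc}/E_{loc}^{rand}$,
$\Lambda = E_{glob}/E_{glob}^{rand}$, $\Sigma = \Gamma/\Lambda$, with
$\Sigma > 1$ the small-world signature. The null preserves the two
first-order confounds — degree sequence and weight distribution — which is
the natural reading of "random networks" for weighted graphs.

**4. Feature selection.** Per-node metrics (local and nodal efficiency by
default) are residualized on age and gender by ordinary least squares, then
screened with a nonparametric two-sample permutation test: the pooled-variance
t statistic per node, a Monte-Carlo null from 10,000 (desk scale: 1,000)
random reassignments of subjects to groups of the original sizes, and the
two-tailed add-one p-value $p = (1 + \#\{|t^*| \ge |t|\})/(1 + P)$, whose
minimum $1/(P+1)$ can never be zero. Selection keeps nodes with
$p < 0.05$, uncorrected — screening, not inference, so no multiplicity
correction is applied.

**5. Classification.** Maximum-uncertainty LDA: the pooled within-class
covariance $S_p$ is eigendecomposed and every eigenvalue below the mean
eigenvalue $\bar\lambda$ is raised to $\bar\lambda$, making the regularized
$S_p^*$ positive-definite even when features outnumber subjects; the
discriminant is $w = S_p^{*-1}(\mu_1 - \mu_2)$ with the equal-priors
midpoint threshold $w^\top(\mu_1+\mu_2)/2$. Tie scores go to the patient
class (deterministic, sensitivity-favoring). Performance is estimated by
leave-one-out cross-validation over four contrasts (mixed patients vs NC,
each subtype vs NC, subtype vs subtype), reported as sensitivity,
specificity and accuracy with the patient group positive.

Two cross-validation modes exist by design. `nested` re-runs
residualization and feature selection inside every training fold and applies
the fold's model to the held-out subject — the methodologically sound
default. `paper_faithful` selects features once on the full sample before
the loop, the common published design; on effect-free synthetic cohorts it
inflates accuracy well above the chance level at which the nested mode
stays, a leakage gap the test suite and the acceptance script measure
rather than hide.

# The synthetic cohort generator

No subject-level imaging data are distributed with analyses of this kind,
so the package ships a generator that emulates the statistical structure the
pipeline assumes, and the generator is first-class, tested code.

Each group has a target correlation matrix: $N$ regions (default 128 at
desk scale; 1024 mirrors a high-resolution random parcellation) in 8 equal
modules, within-module correlation 0.4, between-module 0.1 — values in the
range reported for resting-state ROI correlations. Patient groups differ by
a decrement (default 0.25) of every within-module correlation incident to 10
known *affected nodes*; knowing the ground truth makes feature selection
falsifiable. The block construction can be indefinite after the decrement,
so matrices are projected to the nearest positive-definite correlation
matrix by eigenvalue clipping (floor $10^{-6}$) and diagonal rescaling.
Subjects are i.i.d. multivariate-normal draws of 180 volumes at TR = 2 s
through the Cholesky factor — temporal autocorrelation is left to the
downstream bandpass rather than modeled, keeping the generative model
minimal and analyzable. Six AR(1) motion series (coefficient 0.9), plus
AR(1) white-matter and CSF series, form the nuisance set; a standardized
mixture of WM, CSF and the first motion parameter is added to every
regional series with loading 0.3, and because the mixture lies in the span
of the regressors, nuisance regression can remove it exactly. Ages are
uniform on [40, 80] and gender is Bernoulli(0.55 male), loosely matching a
late-middle-aged clinical sample; exact demographics are not modeled. The
last 16 nodes (one full module) are designated "cerebellar" so the
without-cerebellum arm removes a coherent subsystem.

What the generator does *not* emulate: spatial structure and registration
error, scanner noise spectra, heavy-tailed or subject-varying connectivity,
motion-connectivity coupling, and realistic effect topographies. Passing
tests therefore certify the machinery — that the pipeline recovers what was
planted, stays calibrated under the null, and computes the metrics it claims
— not that any particular clinical effect size is attainable on real data.

A companion utility builds random contiguous parcellations: connected
regions of an integer label volume are split into $k$ parcels by balanced
round-robin region growing from random seed voxels (6-connectivity), so
parcel sizes cluster tightly around the mean; `syntheticHeadMask()`
provides a two-hemisphere-plus-cerebellum test volume, and parcels inherit
their source region so a cerebellar parcel mask can be derived.

# Numerical and design choices

- **Seeds.** Every stage seed derives from one master seed through a
  multiplicative-congruential step modulo $2^{31}-1$; leave-one-out fold
  seeds hash the held-out subject's id, so results are invariant to subject
  ordering. Fixed seed means bitwise-reproducible cohorts, selections and
  reports.
- **Shortest paths** use a dense Floyd–Warshall for graphs up to 48 nodes
  and igraph's C implementation above that; the two backends are asserted
  equal, and both are checked against an exhaustive simple-path enumeration
  oracle on graphs of up to 8 nodes.
- **Bonferroni count.** $m = N(N-1)/2$, counting each unordered pair once
  (the matrix is symmetric, so the two triangles are not independent
  tests). For $N = 1024$, $m = 523{,}776$ and the per-test threshold is
  $9.55\times10^{-8}$.
- **Negative edges.** The default analysis is positive-only. If the sign
  rule is disabled, surviving negative correlations enter by their Fisher-z
  magnitude, because the network container is nonnegative by contract and
  no negative-weight path semantics are defined.
- **Degenerate cases.** Zero-variance regions abort correlation with the
  region named; empty networks yield zero efficiencies; neighbor subgraphs
  with fewer than two nodes score zero local efficiency; folds that would
  select no feature fall back to the single best-p node so every fold emits
  a prediction.
- **Desk-scale sizes.** Shipped defaults run the full design (45 subjects,
  128 regions, 180 volumes, 1,000 permutations, 100-network null ensembles,
  small-world summaries on 5 subjects per group) in minutes on one core;
  all sizes are configuration, and 1024 regions or 10,000 permutations
  reproduce the full-scale design unchanged.

# Calibration results the suite computes

On effect-free cohorts the permutation test's false-positive rate at
$p<0.05$ sits near 0.05, and nested leave-one-out accuracy is consistent
with chance — the chance band is computed for one cohort's 45 dependent
predictions, not for pooled folds, because leave-one-out folds share 44 of
45 training subjects and are far from independent Bernoulli trials. With the
default planted effect, selection recovers essentially all 10 affected
nodes, and nested accuracy on local-efficiency features is high but
fluctuates around 0.9 from one cohort draw to the next. That
fluctuation is worth understanding: at 175 retained volumes bandpassed to
0.01–0.1 Hz, the effective number of independent samples behind each
correlation is only about 64, so within-module correlations of 0.4 hover
near the Bonferroni edge-inclusion threshold and edge membership flickers
between subjects. Regional efficiencies inherit that variance. This is a
genuine power limitation of the design at this scale, not a property of the
classifier — a stronger reference classifier does no better on the same
features.

# Known limitations

- The generator's group effect is a uniform correlation decrement on a
  known node set; real subtype effects are heterogeneous in sign, location
  and magnitude.
- $L_p$ on disconnected graphs averages reachable pairs only; comparing
  $L_p$ across networks with very different unreachable fractions is not
  meaningful (the fraction is reported for exactly this reason).
- The permutation test assumes exchangeability of subjects under the null
  after covariate residualization; site or scanner structure would violate
  it.
- Small-world summaries on a subject subset (default 5 per group) are
  descriptive; no between-group inference is attached to
  $\Gamma, \Lambda, \Sigma$.

# A minimal session

```{r, eval = FALSE}
library(brainNetDx)

cfg <- cohortConfig(seed = 1L)      # 45 subjects, 128 ROIs, planted effect
report <- runExperiment(experimentConfig(cohort = cfg), verbose = TRUE)

report$performance                   # template x contrast x metric grid
summarizeSmallworld(report)          # Gamma / Lambda / Sigma per group
report$selectedNodes[["with_cerebellum|mixed_vs_nc|eLocal"]]
```
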