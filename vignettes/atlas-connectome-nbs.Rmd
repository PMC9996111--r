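---
title: "Atlas-based structural connectomes and Network-Based Statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based structural connectomes and Network-Based Statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connatlas)
```

## The model

`connatlas` studies the association between white-matter microstructural
integrity and a continuous clinical outcome in cohorts with severe brain
injury, where per-subject tractography is unreliable. Its statistical model
has three layers.

**Edge weights.** A probabilistic bundle atlas supplies, for each pair of
parcellation regions, the voxels the connecting bundle occupies together
with (a) a per-edge *presence fraction* — the share of the atlas population
in which the bundle exists at all — and (b) a per-voxel *occupancy
probability*. A subject's connectome entry for edge $e=(u,v)$ is the
unweighted mean of their FA map over the edge's *consistent voxels*:

$$A_i(e) = \frac{1}{|V_e|}\sum_{x \in V_e} \mathrm{FA}_i(x),
  \qquad V_e = \{x : p_e(x) \ge 0.9\},$$

restricted to edges with presence $\ge 0.8$. Both thresholds are inclusive:
the filters are phrased as "present in 80% / 90% of the population", and an
inclusive rule keeps the stated fractions themselves. The mean is unweighted
(not occupancy-weighted) because the filter has already restricted to
high-confidence voxels; weighting would double-count the confidence
information. FA is in $[0,1]$ and dimensionless.

**Edge-wise GLM.** Each edge is regressed on
$X = [\,1,\ \text{score},\ \text{age},\ \text{sex},\ \text{acq}_{PC1}\,]$
and tested with a directed contrast $c$ on the score column,

$$t_e = \frac{c^\top\hat\beta_e}
  {\sqrt{\hat\sigma_e^2\, c^\top (X^\top X)^{-1} c}},
  \qquad \hat\sigma_e^2 = \frac{\mathrm{RSS}_e}{n - \mathrm{rank}\,X}.$$

The DRS (Disability Rating Scale, 0 = no disability, 29 = extreme vegetative
state) is tested with a negative contrast — stronger connectivity is
expected at *lower* disability — and the CRS-R (Coma Recovery Scale –
Revised, 0–23, higher = more conscious behaviour) with a positive one.
Because the contrast is directed, the default test is one-sided; sidedness
is configurable.

**NBS with permutation FWER control.** Edges with $t \ge t_{\text{primary}}$
form a graph; each connected component is a candidate subnetwork whose
*extent* (edge count) is compared against a permutation null of the maximal
component size. The component-level p-value uses the add-one estimator
$p = (1 + \#\{M^{(b)} \ge s\})/(1 + B)$, which is valid and never zero, and
the null comparison uses $\ge$ (conservative, and consistent with the
inclusive suprathreshold rule for ties at the threshold).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| presence threshold | 0.8 | fraction | drops bundles absent in much of the atlas population |
| occupancy threshold | 0.9 | fraction | drops low-probability voxels from the bundle mean |
| primary threshold $t$ | 3.5 | t units | two-sided $p \approx 0.001$ at 39 df; swept over {3.3, 3.5, 3.7} because the choice is conventional, not principled |
| permutations $B$ | 10000 | count | FWER resolution $\approx 10^{-4}$; tests use smaller $B$ |
| $\alpha$ | 0.05 | — | FWER level |

On the threshold's degrees of freedom: a five-column design with $n = 40$
leaves $35$ residual degrees of freedom, while $39 = n - 1$. The package
reports $n - \mathrm{rank}\,X$ from the actual design and, separately,
reproduces the $t = 3.5 \leftrightarrow p \approx 0.001$ correspondence at
39 df as a pure t-distribution computation (`t_to_p(3.5, 39)`); which
convention an external NBS implementation uses is a property of that
implementation, not of the data.

## Permutation scheme

With nuisance covariates present, exchangeability holds only approximately;
the package uses **Freedman–Lane** residual permutation, the accepted
standard for GLM permutation inference in neuroimaging: fit the reduced
(nuisance-only) model $Z$, permute its residuals, reconstitute
$Y^\ast = Z\hat\gamma + P(Y - Z\hat\gamma)$, and recompute the full-model
statistics. Two implementation facts are load-bearing and tested:

- with no nuisance columns beyond the intercept, Freedman–Lane reduces
  *exactly* (in floating point, for a shared permutation sequence) to
  permuting the raw rows;
- at $n = 5$ the sampled p-value converges to the value obtained by
  exhaustive enumeration of all $120$ row orders.

Permutations are drawn independently without deduplication (standard
Monte-Carlo practice), from a single seeded generator whose state is
restored afterwards, so a fixed seed makes every result bit-reproducible.

## The acquisition covariate

Retrospective cohorts mix scanners and protocols, so TR (ms), TE (ms),
number of diffusion directions (count) and interslice gap (mm) vary and are
strongly interdependent. They are compressed into one nuisance covariate:
PCA on the *correlation* structure (the units are incommensurate — a
covariance PCA would be dominated by TR), returning the first-component
*score* per subject. A loading vector is per-variable and cannot serve as a
per-subject covariate, so "first component" is necessarily read as the
score. PCA signs are arbitrary; the convention (first loading nonnegative)
is fixed once, and the regression is invariant to it — a property the test
suite checks explicitly.

Sex is coded 0 = female, 1 = male; any binary coding leaves the score
contrast unchanged.

## What the synthetic generator emulates — and what it does not

`make_toy_atlas()` builds a small parcellation (default 12 nodes on a
circle in a $24^3$ grid of 2 mm voxels) with voxel tubes as bundles; ring
edges get presence $\ge 0.85$ (one pinned at exactly 0.8 to probe the
inclusive rule) and chords get presence in $[0.5, 0.75]$, so the presence
filter has designed keeps and drops. About 20% of each bundle's voxels get
occupancy below 0.9. Bundle voxel sets are made disjoint so a painted edge
value is exactly recoverable as the bundle mean.

`simulate_cohort()` is the forward model of the regression the pipeline
estimates: painted bundle FA is
$\text{baseline} + \beta\, z(\text{score}) \cdot \mathbf{1}[e\
\text{planted}] + a_{\text{age}} z(\text{age}) + a_{\text{sex}}\,\text{sex}
+ a_{\text{acq}} f + \varepsilon$, painted uniformly over the bundle and
degraded with i.i.d. Gaussian voxel noise. Defaults are chosen as the study
conditions a desk-scale validation needs: $n = 40$ subjects (the cohort
size of the clinical setting emulated), baseline FA 0.5, $\beta = -0.05$
FA units per score SD, voxel noise SD 0.02, nuisance slopes
$(-0.01, 0.005, 0.005)$, DRS-like integer scores on 0–29. The acquisition
parameters follow a one-factor latent model so the PCA step has realistic
collinearity to compress (PC1 correlates $> 0.95$ with the latent factor at
$n = 40$). Because voxel noise averages over the bundle, the edge-level
noise shrinks with bundle size; an `edge_noise_sd` option adds bundle-level
shared noise for the regime where it does not.

What the generator does *not* emulate: raw k-space or realistic artefacts
(eddy currents, susceptibility), lesions and mass effect, registration
error, spatially correlated noise, or FA reductions from crossing fibres
and oedema. Passing tests therefore validate the *statistical machinery* —
filters, estimator algebra, permutation calibration, component logic — not
the biological claim that bundle-mean FA tracks recovery in real patients.

The residual noise structure of edge FA across subjects is not identified
by the desk-scale setting at all; i.i.d. Gaussian noise is a modelling
choice made here, and the FWER validation is performed under it.

## Numerical choices

- Bundle voxels are summed in sorted linear-index order, so edge means are
  bitwise independent of voxel enumeration order.
- Negative tensor eigenvalues from noisy fits are clamped to zero before FA
  (count reported via the `n_clamped` attribute); an all-zero eigenvalue
  triple defines FA = 0 so background voxels do not produce 0/0. Direct
  calls to `fractional_anisotropy()` with negative inputs are errors — the
  clamp is an explicit pipeline stage, not a silent repair.
- The tensor fit is plain OLS on the log-signal; non-positive signals and
  rank-deficient gradient schemes (fewer than 6 independent directions plus
  a $b=0$) are errors, never silently patched.
- Edges with zero residual variance (noiseless synthetic data) get signed
  infinite $t$ with a warning and are excluded from the suprathreshold
  graph, so degenerate inputs cannot crash the permutation loop.
- Component extraction uses union-find with path halving; ties in component
  ordering are broken by size, then discovery order. Its output is checked
  against a brute-force depth-first-search oracle (exhaustively on all
  graphs with 4–5 nodes, randomly at 6–8) and against an independent graph
  library.
- Quartiles use Tukey hinges. The quartile convention of the summarised
  clinical table is unstated in its source, but hinges reproduce all four
  published interquartile ranges exactly (12.5, 11, 20.5, 27), while
  type-7 linear interpolation does not (it gives 19.75 for the
  injury-to-scan interval); hinges are therefore the package convention.
- The normality check is the plain one-sample Kolmogorov–Smirnov statistic
  with estimated mean and SD (no Lilliefors correction); only $D$ is
  treated as checkable, to two decimals.
- Spearman p-values use the t approximation (appropriate at $n \approx
  40$), with average ranks for ties.

## The packaged clinical fixture

`table1_cohort.tsv` transcribes a published 40-patient cohort table
(sex, age, scan intervals, aetiology, admission diagnosis, discharge DRS
and CRS-R). The source table's layout made a handful of interval entries
ambiguous to transcribe; the transcription was fixed by requiring exact
agreement with every published summary statistic of that cohort (means,
medians, hinge IQRs, KS statistics, and category counts), which admits a
unique solution. Two rows labelled "MCS-" are tallied as MCS, consistent
with the published 13/16/11 diagnosis split. The published sample-size
narrative (52 scanned, 7 + 2 + 4 excluded) does not arithmetically equal
the final 40; the package reports the table's n and leaves the discrepancy
alone. The published age SD (16.4) differs from the transcribed table's
16.45 only at the rounding boundary.

`table2_subnetworks.tsv` transcribes the published subnetwork edge lists
with their t-values; treating each list as a suprathreshold graph
reproduces the published extents (29 nodes / 41 edges; 8 / 8) and nodal
degrees (16, 7; 4, 3) by direct recomputation.

## Validation problem sizes

The test-suite and acceptance-script simulations use desk-scale sizes
chosen to make Monte-Carlo error small while keeping runs comfortable on a
single CPU: the global-null FWER check uses 500 simulated cohorts of 40
subjects by 100 edges with 200 permutations each (the estimated FWER must
not exceed $0.05 + 2\,\mathrm{SE}_{MC} \approx 0.07$); planted-subnetwork
recovery uses the generator defaults, under which the planted component is
recovered with the smallest attainable p-value; permutation-p agreement is
checked exhaustively at $n = 5$.

## Known limitations

- Preprocessing (denoising, eddy/motion correction, bias field), FA-to-
  template registration and any manual correction are upstream of this
  package; FA maps are assumed to be on the atlas grid already.
- Component "size" is the edge count (extent); the intensity variant of
  NBS is not implemented.
- Complete-case handling at the edge level: an edge invalid in any subject
  leaves the stack for all subjects. With a shared atlas and grid the
  per-subject masks coincide, so this matters only for unusual inputs.
- The real multiscale connectome atlas is not redistributed; a compatible
  container (documented in `write_bundle_atlas()`) loads identically.
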