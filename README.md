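# connatlas

Atlas-based structural connectomes and Network-Based Statistics for studying
white-matter integrity and clinical outcome after severe brain injury.

## The problem

Patients recovering from coma (disorders of consciousness: coma, vegetative
state/unresponsive wakefulness syndrome, minimally conscious state) often have
brain lesions severe enough that per-subject tractography is unreliable. An
alternative is to skip fibre tracking entirely: project each patient's
fractional-anisotropy (FA) map — already normalised to a common stereotactic
space — onto a *population-derived probabilistic bundle atlas* that records,
for every pair of grey-matter parcellation regions, which voxels the
connecting white-matter bundle occupies and how consistently it does so
across a healthy reference population. The bundle-mean FA then serves as the
connectivity strength of that edge, and the question "which connections
support recovery?" becomes a statistical one on the resulting connectomes.

`connatlas` implements that pipeline for researchers in clinical
neuroimaging, end to end and fully testable without patient data.

## The method

**Connectome construction.** For subject *i* and region pair (*u*, *v*) the
edge weight is

    A_i(u, v) = mean{ FA_i(x) : x in B(u, v), P_occ(x) >= 0.9 }

restricted to edges with population presence fraction >= 0.8 — the two
consistency filters that drop rarely present bundles and low-probability
voxels (both rules inclusive).

**Edge-wise inference.** Each edge is regressed on a design
`[1, score, age, sex, acq_pc1]`, where `acq_pc1` is the first principal
component of the z-scored acquisition parameters (TR, TE, number of
diffusion directions, interslice gap — strongly collinear in retrospective
cohorts). A directed contrast *c* on the clinical score (negative for the
Disability Rating Scale, positive for the Coma Recovery Scale – Revised)
gives the t-statistic

    t_e = c'b / sqrt(s^2 c'(X'X)^{-1} c),  s^2 = RSS / (n - rank X).

**Network-Based Statistics (NBS).** Edges with `t >= t_primary` (default
3.5) form a graph; its connected components are candidate subnetworks. A
null distribution of the *maximal* component size is built by Freedman–Lane
permutation: residuals of the nuisance-only model are permuted, recombined
with the nuisance fit, and the full-model statistics and maximal component
size recomputed. Each observed component of size *s* gets the
family-wise-error-corrected p-value

    p = (1 + #{ null max size >= s }) / (1 + n_permutations).

**Reporting.** Nodal degrees, per-subject subnetwork-mean FA and its
Spearman correlation with the score, cohort descriptive statistics, and
BrainNet Viewer `.node`/`.edge` export.

A synthetic-data module generates every input the pipeline needs — a toy
probabilistic bundle atlas, FA phantoms with a planted linear score effect
on a chosen subnetwork, diffusion-weighted signals from known tensors, and
Table-1-style cohort records — and writes its own ground truth.

## Worked example

Simulate a 40-patient cohort with a 6-edge planted subnetwork whose FA
decreases with the discharge DRS score, rebuild connectomes from the phantom
volumes, and run NBS:

```r
library(connatlas)

atlas <- make_toy_atlas(n_nodes = 12, grid_shape = c(24, 24, 24), seed = 7)
cfg <- cohort_config(n_subjects = 40, planted_edges = cbind(0:5, 1:6),
                     effect_slope = -0.05, noise_sd = 0.02, seed = 3)
sim <- simulate_cohort(atlas, cfg)

connectomes <- lapply(seq_along(sim$fa), function(i)
  build_connectome(sim$fa[[i]], atlas, subject_id = sim$cohort$subject_id[i]))
stack <- stack_cohort(connectomes)
design <- build_design(sim$cohort, score = "DRS")   # contrast (0,-1,0,0,0)

result <- nbs_fwer(stack, design, t_threshold = 3.5,
                   n_permutations = 2000, seed = 11)
result
#> NBS at t >= 3.50 (one-sided, 2000 permutations, df = 35)
#>   component 1: 7 nodes, 6 edges, FWER p = 0.0009995 *

sub_fa <- subnetwork_mean_fa(stack, result$components[[1]])
spearman_rho(sub_fa, sim$cohort$drs_discharge)$rho
#> [1] -0.9480246
```

The significant component is exactly the planted 6-edge path (nodes 0–6),
its FWER p-value is the smallest the permutation count allows
(1/2001 ≈ 0.001), and the subnetwork-mean FA correlates strongly and
negatively with the DRS, as planted. Cohort summaries come from
`cohort_descriptives()`:

```r
cohort_descriptives(read_cohort_table())
#> Cohort: n = 40 (16 female)
#>   age: mean 53.5, SD 16.5, range 16-84 (KS D = 0.11)
#>   drs: median 14.5, IQR 12.5 (KS D = 0.16)
#>   crsr: median 20, IQR 11 (KS D = 0.23)
#>   interval_injury_mri: median 29.5, IQR 20.5 (KS D = 0.32)
#>   interval_mri_discharge: median 27, IQR 27 (KS D = 0.11)
#>   diagnosis: COMA=13, MCS=11, VS/UWS=16
#>   etiology: ANOX=4, CVA=18, ENC=2, LEUCO=1, TBI=15
```

The packaged `table1_cohort.tsv` fixture is a transcription of a published
40-patient acute-neurorehabilitation cohort;
`read_subnetwork_edges("DRS")`/`("CRSR")` return the corresponding published
subnetwork edge lists with their t-values.

## Package layout

- `R/synthetic.R` — toy atlas, cohort/FA-phantom, DWI-signal and QC generators
- `R/dti.R` — OLS tensor fit, FA, FA volumes, QC exclusion rule
- `R/atlas.R` — bundle-atlas data model, container I/O, consistency filters
- `R/connectome.R` — bundle-mean edge weights, connectome build, cohort stack
- `R/design.R` — acquisition PCA, clinical-score design and contrast
- `R/nbs.R` — edge GLM t, components, Freedman–Lane permutation FWER, sweep
- `R/report.R` — degrees, subnetwork FA, Spearman, descriptives, BrainNet export
- `vignettes/atlas-connectome-nbs.Rmd` — the methods vignette

## Limitations

DWI preprocessing (denoising, eddy/motion correction, bias-field
correction), co-registration and nonlinear spatial normalisation are out of
scope: inputs are assumed to be FA maps already in the atlas space. The real
multiscale connectome atlas is not redistributed; any atlas exported to the
documented container layout (`nodes.tsv`, `edges.tsv`, one occupancy NIfTI
per edge) loads identically.
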