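# connherit

Twin-based heritability and plasticity gradients of cortical functional
connectivity.

## What it is for

Within a cortical processing hierarchy, how does the balance between
plasticity and stability change from low- to high-level areas? One way to
ask this without longitudinal data is to treat plasticity as the
accumulated deviation of a phenotype from its genetic blueprint: the
complement `1 - h2` of the phenotype's heritability. With resting-state
functional connectivity (RSFC) between visual areas as the phenotype and a
twin cohort as the design, per-area plasticity can be regressed on the
area's hierarchical level.

`connherit` implements that analysis as a reusable, fully tested pipeline
for biostatisticians and imaging-genetics researchers:

* **Synthetic twin cohorts** with known ground truth (pedigrees,
  heritable phenotypes, ROI time series with motion regressors, anatomical
  phenotypes, area adjacency), so every downstream stage is testable
  without restricted family data.
* **Connectivity**: per-run motion-nuisance regression and Fisher
  r-to-z correlation tables, per scan and per session day.
* **Screening**: family-block sign-flip permutation tests with
  Benjamini–Hochberg FDR.
* **Heritability**: the twin AE variance-components model
  `Omega = 2 Phi sigma_g^2 + I sigma_e^2`, maximum likelihood with
  simultaneous covariates, `h2 = sigma_g^2 / sigma_p^2`, and the boundary
  LRT `2(Le - L0)` referred to a 50:50 mixture of a point mass and
  chi-square(1).
* **Reliability**: test–retest ICC(3,1) across session days and a Mantel
  matrix-association control.
* **Hierarchy**: shortest-path (Dijkstra) levels `eta` from V1 over the
  area adjacency graph.
* **Gradient models**: per-area averaging, linear/quadratic level
  regressions with a nested F comparison, the early-visual slope test, and
  the two-component plasticity decomposition
  `h2(eta) = 0.5 - a1 e^(-b1 eta) - a2 e^(b2 eta)` fit by robust
  non-linear least squares, with Akaike-weight attribution of target
  profiles to the short- or long-term component.

## Worked example

A full synthetic study at the real cohort's size — 123 MZ + 67 DZ twin
pairs, 48 visual areas (24 per hemisphere) — generated and analysed end to
end:

```r
library(connherit)

cohort <- generate_pedigree(n_mz = 123, n_dz = 67, seed = 1)
graph  <- visual_graph_fixture()                      # synthetic 48-area adjacency
levels <- hierarchy_levels_multi(graph, roots = c("lh_V1", "rh_V1"))

ds  <- generate_connectivity_dataset(cohort, graph, levels, seed = 2)
res <- analyze_connectivity(ds$z_all, cohort, graph,
                            roots = c("lh_V1", "rh_V1"),
                            z_day1 = ds$z_day1, z_day2 = ds$z_day2,
                            n_perm = 2000, n_perm_mantel = 1000, seed = 3)
print(res)
```

```
Connectivity gradient analysis: 552/1128 connections kept (FDR)
  linear:    R2 = 0.042, F(1, 46) = 2.02, p = 0.162
  quadratic: R2 = 0.804, F(2, 45) = 92.39, p = 1.17e-16
  nested F(1, 45) = 175.11, p = 4.05e-17
  early-visual slope: t(8) = 10.95, p = 4.3e-06
Two-component fit (h_max = 0.50): a1 = 0.1807, b1 = 0.6606, a2 = 0.01652, b2 = 0.2401; R2 = 0.865
```

Reading the output: connections whose group-level Fisher z fails the
family-aware FDR screen (here mostly the weak cross-hemisphere pairs) are
excluded; per-area mean heritability is then strongly *non*-monotonic in
hierarchical level — the quadratic model dominates the linear one (nested
F), heritability *rises* significantly across early visual cortex
(positive slope over the 10 V1–V3 areas, df = 8), and the two-component
curve captures the profile (R2 = 0.87): a decaying short-term and a
growing long-term plasticity component.

The session-day reliability arm of the same run:

```r
res$icc_slope   # t(46) = 10.16, p = 2.4e-13  : ICC increases with level
res$mantel      # R2 = 0.064, p = 0.001       : h2-vs-ICC association
res$component_icc$weights  # short = 1        : ICC tracks the short-term component
```

(In this synthetic world both profiles genuinely share the level gradient,
so the Mantel control is expected to be non-null here, unlike on data
where heritability is unrelated to measurement reliability.)

Anatomical phenotypes with declining heritability prefer the long-term
component:

```r
an <- generate_anatomy_dataset(cohort, levels, seed = 4)
analyze_anatomy(an$thickness, cohort, levels, fixed = res$two_component)
```

A one-command miniature of the whole pipeline — time series included — is
`run_demo(seed = 1, out_dir = "demo_out")`, which writes every stage
table (`screen.tsv`, `heritability.tsv`, `icc.tsv`, `levels.tsv`,
`fits.json`, a run manifest, and the synthetic inputs). File-based runs
are configured with `run_pipeline("config.yaml")`; see
`?run_pipeline` and `?validate_inputs`.

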