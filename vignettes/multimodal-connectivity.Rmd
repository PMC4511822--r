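---
title: "Multimodal connectivity matrices, group algebra and graph metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal connectivity matrices, group algebra and graph metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroconn)
```

## Scope and model

`neuroconn` starts where preprocessing ends. It assumes each subject comes
with a parcellation label volume in a common space, a tractogram in that
space, ROI-level BOLD and PET signal tables (or 4D volumes to extract them
from), and per-ROI morphometry. From these it builds five families of
region-by-region connectivity matrices, combines them across subjects, and
runs graph-theoretic and statistical analyses. Everything travels in one
container, `conn_matrix`, which carries the ROI ordering, modality tag,
directedness and weight semantics, and round-trips losslessly through a
text format.

All matrices share one canonical ROI ordering: block I holds subcortical
regions with left/right homologues interleaved, block II left cortical,
block III right cortical regions, alphabetical within block. The block
scheme is what gives the matrix heatmap its interpretable structure
(intra-subcortical, intra-hemispheric and inter-hemispheric areas); the
alphabetical within-block rule is our own deterministic choice, made so
the ordering is a pure function of the ROI table and never of file order.

## Per-modality construction

**Anatomical (a-CM).** Connectivity from morphometric similarity: for a
measure $m$ defined on the relevant tissue class, $a_{ij} = \min(m_i,
m_j)/\max(m_i, m_j)$. The symmetric min/max convention is a deliberate
design choice — a raw oriented ratio $m_i/m_j$ is neither symmetric nor
bounded; we keep it available as `mode = "directional"` for users who want
the oriented variant. Measures that exist only for one tissue class
(CT/SA/GMV cortical, volume subcortical) produce a matrix over that class
only, avoiding undefined entries.

**Structural (s-CM).** Streamlines are assigned to ROI pairs by their
*endpoints*: each endpoint maps through the inverse affine to a 0-based
voxel index (floored) and takes that voxel's label. Endpoint assignment is
deterministic, cheap to verify against a brute-force per-point lookup, and
matches how deterministic-tractography pipelines define termination.
No dilation or nearest-label search is applied by default — determinism
first. Streamlines with both endpoints in one ROI are loops: they are
excluded from the matrices (the diagonal is identically zero) and counted
in a QC summary. Three matrices result: fiber count, mean fiber length
(arc length of the polyline), and mean fiber orientation. "Mean
orientation between two ROIs" has no single established definition; we use
the normalized mean of sign-aligned end-to-end unit vectors (first nonzero
component made positive), one of several defensible conventions.

**Functional (f-CM).** Pearson correlation between ROI time series, with
two-sided p-values from the t transform $t = r\sqrt{(T-2)/(1-r^2)}$. The
Bonferroni family is the $R(R-1)/2$ unique off-diagonal pairs — the
matrix is symmetric, so counting both triangles would double-penalize. A
permutation-based check of the t-transform p-values lives in the test
suite, not in the analysis path.

**Effective (e-CM).** Pairwise time-domain Granger causality. For
direction $x \to y$ at order $p$ (default 1, the only order used in the
default pipeline), the restricted model regresses $y_t$ on an intercept
and $y_{t-1..t-p}$, the full model adds $x_{t-1..t-p}$, and

$$GC_{x\to y} = \ln \frac{RSS_r}{RSS_f}, \qquad
F = \frac{(RSS_r - RSS_f)/p}{RSS_f/(T_{\mathrm{eff}} - 2p - 1)}$$

with $T_{\mathrm{eff}} = T - p$ usable rows and $F \sim F(p,
T_{\mathrm{eff}} - 2p - 1)$ under the null. The GC scalar stored in the
matrix is the log variance ratio; F and p ride alongside. Because each
direction is a separate test, the Bonferroni family for the binary e-CM is
the $R(R-1)$ *ordered* pairs. A noiseless deterministic coupling drives
$RSS_f \to 0$: the GC value becomes large but finite and a warning is
raised rather than an error. Multivariate/conditional and spectral GC are
out of scope — the implementation is intentionally pairwise and
time-domain.

**PET.** Dynamic frames are summed voxelwise; regional SUV is the ROI mean
of the summed image (optional dose/body-weight scalar), rSUV divides by a
reference region, classically the cerebellum. The PET connectivity matrix
correlates time–activity curves across frames *within subject* — with an
8-frame acquisition that leaves 6 degrees of freedom, which the code flags
with a warning. Correlating regional values across subjects is a
reasonable alternative reading; the TAC mode is the default because the
per-subject pipeline operates within subject, and cross-subject
correlation can be obtained by stacking SUV tables.

## Group algebra

Binary matrices use the stated rules: fiber count > 0 for s-CM, Bonferroni
p < 0.05 for f-CM and e-CM. Across subjects:

- `mean_cm`: elementwise mean of the weighted matrices;
- `robustness_cm`: elementwise mean of the binary matrices — entry 0.1
  means 10% of subjects show the connection, 0.9 means 90%;
- `combined_cm`: $\ast_c = \ast_{mean} \times (\ast_{robustness} > \tau)$
  with $\tau = 0.8$ by default. The inequality is *strict*: robustness
  exactly 0.8 is zeroed. This matches the formula as printed rather than a
  ≥ reading, and the boundary case is pinned by a test.

The hybrid sf-CM is the *elementwise* product of s-CM and f-CM. A true
matrix product would mix entries across ROIs and destroy the
per-connection meaning of each cell; the Hadamard reading keeps sf(i,j) a
statement about the connection (i,j) only.

The binary decomposition splits functional edges into `direct` (also
structural) and `mediated` (functional only): direct = s AND f, mediated
= f AND NOT s. These partition the functional edge set exactly — a law the
suite verifies on hundreds of random pairs. Edges that are structural only
belong to neither part.

`mediated_path` explains a mediated edge by the structural path with the
fewest intermediate regions, via breadth-first search on the binary
structural graph. Ties are broken by canonical ROI order at each
expansion, making the returned path deterministic; an `all_shortest` mode
enumerates every minimum-length path. The search is deliberately
unconstrained by functional module membership and runs on binary graphs
only — weighted shortest paths would answer a different question.

## Graph metrics and null models

Metrics default to binary undirected matrices (thresholding happens
first): degree, the triangle clustering coefficient $C_i = 2t_i/(k_i(k_i -
1))$ (zero when $k_i < 2$), and characteristic path length as the mean
shortest-path length over reachable ordered pairs. Disconnected pairs are
*excluded*, and the excluded fraction is always reported so the choice is
auditable rather than silent.

Normalization uses random graphs that preserve node count, edge count
(hence mean degree) and symmetry: the edge set is re-drawn uniformly on
the upper triangle. We read "maintaining symmetry and mean degree"
literally — mean degree, not the degree sequence; a degree-sequence
preserving rewiring is a stricter null that the literal phrasing does not
require. Ten null graphs is the default. Small-worldness is
$\sigma = (C/\langle C_{null}\rangle)/(L/\langle L_{null}\rangle)$, and
the individual normalized ratios are returned as well since some studies
report them separately.

Community structure uses the multilevel (Louvain) greedy optimizer from
igraph, but the modularity $Q = \sum_i (e_{ii} - a_i^2)$ of the returned
partition is always re-evaluated directly from the adjacency by our own
formula — the number reported is never an optimizer's internal value. On
graphs small enough for exhaustive partition enumeration the greedy
optimum matches the global one in the tests (e.g., two disjoint 4-cliques:
Q = 0.5).

## Group statistics

Group splits are threshold- or label-based (the canonical design splits at
age 40 into 15 young and 20 old adults). The test is Welch's two-sample t
by default — "t-test" alone under-specifies, and the unequal-variance form
is the safer default for unequal group sizes; the pooled-variance form is
available. Covariates are handled by OLS residualization of the pooled
values before testing. Multiplicity correction defaults to `none`
(matching how such per-ROI maps are usually displayed), with Bonferroni
and Benjamini–Hochberg available. Direction is the sign of the group-2
minus group-1 mean; the connectogram paints increases red and decreases
blue, the convention stated in the methods description of the display (the
figure captions of the source tool use the opposite mapping in one place —
the colors are configurable).

## Synthetic data: what it emulates and what it does not

The generator plants known truths in every modality:

- a mirrored-box parcellation (2×2×2-voxel boxes, identity affine), so
  left/right symmetry is exercisable;
- streamlines with exact per-pair fiber counts and optional orphans;
- lag-1 VAR BOLD series $X_t = A X_{t-1} + \varepsilon_t$ (Gaussian
  innovations, 100-sample burn-in, stationarity enforced via the spectral
  radius) — the planted coupling drives both the Pearson and Granger
  checks, with the default study condition a single directed edge of 0.5;
- morphometry with Gaussian subject noise and additive group-2 effects
  (default: −0.5 mm cortical thickness, the kind of age effect group
  comparisons target), ages 19–37 vs 42–73 for groups of 15 and 20;
- 8-frame gamma-variate PET TACs with Gaussian frame noise.

Gaussian noise everywhere is a documented simplification. The fixtures do
not emulate hemodynamics, spatial autocorrelation, motion, partial-volume
effects or kinetic models, so passing tests demonstrate correctness of the
*computational* pipeline and its statistical calibration under idealized
noise — not robustness to real-data artifacts.

## Numerical choices and problem sizes

- p-values: t transform for correlations, F tail for GC; permutation and
  normal-equation oracles are confined to tests.
- Degenerate inputs: constant series error with the ROI named;
  zero-variance test targets are skipped with a warning; empty group
  graphs skip the graph report with a logged notice.
- Determinism: every stochastic step (generators, null graphs, Louvain)
  takes a seed; the full pipeline run twice under one seed produces
  byte-identical numeric outputs, which a test asserts.
- The test suite runs at deliberately desk-sized problems (8–40 nodes,
  T = 100–500, 100–500 replicate simulations), chosen to put Monte-Carlo
  error well inside the asserted tolerances while keeping the suite fast.

## Known limitations

- Only NIfTI, TrackVis `.trk`, TSV and the documented text containers are
  read; DICOM/Analyze/ECAT ingestion belongs to upstream converters.
- The `.trk` reader/writer implements the minimal v2 profile it writes
  (no per-point scalars or per-track properties; unit voxel size with
  identity vox-to-ras, so stored coordinates are mm).
- Renderers are static; the interactive hover behaviour of GUI tools is
  replaced by returned adjacency/count metadata.
- Anatomical connectivity here is the within-subject ratio form, not
  inter-subject covariance networks, which are a different method family.
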