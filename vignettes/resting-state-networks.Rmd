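---
title: "Graph-theoretical analysis of resting-state functional networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restnet)
```

# The analysis model

restnet treats each subject's resting brain as an undirected, unweighted
graph. Nodes are the 90 regions of the AAL parcellation (one label per
hemisphere, `aalRegionLabels()`); edges are the strongest interregional
Pearson correlations of the preprocessed BOLD signals, retained at a fixed
*wiring cost*. The quantities of interest are:

* **Clustering coefficient.** For node $i$ with degree $k_i$ and $E_i$
  edges among its neighbours, $C_i = 2E_i /(k_i(k_i-1))$; the network
  coefficient $C$ is the arithmetic mean of $C_i$ over all nodes.
* **Characteristic path length.** $L$ is the mean of the unweighted
  shortest-path distance $d_{ij}$ over all unordered node pairs. It is
  defined only for connected graphs; restnet refuses to substitute
  infinities or harmonic means and instead raises an error, because a
  silently redefined $L$ is not comparable across subjects.
* **Small-world ratios.** $\gamma = C/C_{rand}$ and
  $\lambda = L/L_{rand}$, where $C_{rand}$, $L_{rand}$ are ensemble means
  over degree-preserving randomizations of the same graph, and
  $\sigma = \gamma/\lambda$. A small-world network combines
  $\gamma \gg 1$ with $\lambda \approx 1$, hence $\sigma > 1$.
* **Betweenness centrality.**
  $B_i = \sum_{j \ne k \ne i} n_{jk}(i)/n_{jk}$ over unordered pairs,
  computed with Brandes' algorithm and reported *unnormalized* (raw pair
  counts). On 90-node graphs this puts hub values in the hundreds, the
  scale on which nodal centrality tables are usually reported, and keeps
  group means interpretable as "number of shortest-path incidences".
* **Robustness.** Targeted attack removes nodes in decreasing order of
  group-mean betweenness and tracks the largest connected component as a
  fraction of the original node count.

Group inference is a 2×2 sex-by-disease design: a two-way ANOVA per
metric (and per Fisher-z edge weight), FDR correction, Tukey contrasts
between the four cells, and partial correlations between disease duration
and topology controlling for age.

The assumptions are the standard ones of this analysis family: linear
(Pearson) coupling is a sufficient connectivity statistic; binarizing at
equal sparsity makes topology comparable across subjects by equalizing
edge count; and degree-preserving rewiring is the right null because it
removes neighbourhood structure while keeping the degree sequence that
sparsity fixed.

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| band-pass | 0.01–0.08 | Hz | the resting-state frequency band; removes drift and high-frequency physiological noise |
| motion limits | 1.5 / 1.5 | mm / degree | exclusion limits, strict inequality ("larger than" fails) |
| sparsity sweep | 0.15–0.25, step 0.01 | fraction | the conventional range over which small-world properties are profiled |
| analysis sparsity | 0.15 | fraction | lowest swept cost at which 90-region networks generally stay fully connected while minimizing spurious edges |
| null ensemble | 100 graphs | — | ensemble-mean error of $C_{rand}$, $L_{rand}$ well below the between-subject spread; configurable |
| rewiring effort | 10 swaps/edge | — | enough attempted double-edge swaps to destroy local structure (see below) |
| FDR level | 0.05 | — | conventional |

# Numerical and procedural choices

Several points are underdetermined by the conventions of the field; the
package fixes them as follows, and each choice is visible in the
configuration echo written with every run.

**Filter realization.** The band-pass is a Butterworth IIR (order 2)
applied forward–backward (`signal::filtfilt`). Zero phase matters:
phase distortion would shift features differently per frequency and bias
the lag-0 Pearson correlations the whole analysis rests on. Filtering
precedes nuisance regression, and the nuisance regressors are passed
through the same filter so regressor and signal spectra match.

**Motion screening** uses per-parameter maxima of absolute values ("any
direction"), not a composite framewise displacement, and strict
inequalities, so a maximum of exactly 1.5 mm passes.

**Nuisance regression** includes an intercept even though correlation is
mean-invariant: it makes residual orthogonality to the regressors exact,
which the tests assert to machine precision.

**Edge selection.** At sparsity $S$ the
$k = \mathrm{round}(S \cdot N(N-1)/2)$ largest *signed* correlations
become edges (rounding half away from zero, so 15% of 4005 pairs is
exactly 601 edges). Signed ranking is the default because binarization
retains coefficients *larger than* a threshold; strong negative
correlations are never competitive at 15–25% cost in practice. An
absolute-value mode exists behind a flag. Ties at the cut rank break
lexicographically on (row, column) indices — reproducible across runs and
platforms. Because ranking is fixed, edge sets nest across the sweep:
every edge at sparsity $s$ is present at every $s' > s$.

**Isolated nodes.** `minConnectedSparsity()` scans ascending candidate
costs and returns the first at which the graph has no isolated node and a
single connected component, reproducing the "lowest threshold avoiding
isolated nodes" rule used to pick the analysis sparsity.

**Low-degree clustering convention.** Nodes with $k_i < 2$ get
$C_i = 0$ and stay in the average. The alternative (dropping them) makes
$C$ undefined on graphs with leaves and changes its value; the convention
is stated here because it matters at sparse costs.

**Rewiring.** "Randomize by reconnecting edges at least ten times" is
ambiguous (per edge? per network?); restnet interprets it as at least 10
successful double-edge swaps *per edge* (Maslov–Sneppen), parameterized
by `nSwapsPerEdge`. Swaps that would create self-loops or multi-edges are
rejected; swaps that would disconnect the graph are rejected and
resampled, because $L$ must stay defined on every null realization. A
swap can only disconnect the two node pairs whose edges it removed, so
connectivity is re-checked with two early-exit breadth-first searches in
the compiled core. Degree-sequence preservation is asserted on every
call.

**Small-worldness scalar.** Group comparison curves of "small-worldness"
sometimes plot $\sigma$ and sometimes $\gamma$ alone; restnet defines
$\sigma = \gamma/\lambda$ (the standard scalar) and always reports both
ratios separately so either convention can be read off.

**Attack order** is fixed from the initial group-mean betweenness, with
ties broken by canonical label order; it is *not* recomputed after each
removal (the ranking "across all subjects" describes a precomputed
order). Per-subject curves are computed with the group-level order on a
common removal grid, then averaged per group. The per-step group test is
a Welch t-test by default — no specific test is canonical for attack
curves — with a permutation alternative behind a flag.

**Unbalanced ANOVA.** With 18 males vs 20 females per group the design is
unbalanced; restnet uses Type II sums of squares by default (invariant to
factor order, appropriate without higher-order terms), with Type III
behind a flag. Zero-variance responses return $F = 0$, $p = 1$ by
convention. FDR is Benjamini–Hochberg by default, Benjamini–Yekutieli by
flag; post-hoc contrasts are Tukey HSD over the four cell means.
Edge-level tests apply the same two-way model to every Fisher-z edge
weight via shared projection matrices and correct over all tested pairs.

**Partial correlation** is the Pearson correlation of the residuals of
both variables after regression (with intercept) on the covariates, with
$n - 2 - k$ degrees of freedom; with no covariates it reduces exactly to
the plain Pearson correlation.

# What the synthetic cohort emulates

`generateCohort()` realizes the full study design: 20 females and 18
males per group (76 subjects), 90 regions × 205 timepoints at TR = 2 s,
demographics and clinical covariates drawn from truncated normals
matching the emulated cell moments (ages ≈ 31–33 ± 2–9 y; duration
10.9 ± 7.4 y in women, 8.1 ± 2.3 y in men; attack frequency, duration and
pain intensity likewise). Disease duration is generated with a deliberate
age dependence so that age is a genuine confound for the partial
correlation to remove.

Signals are multivariate normal with a block (modular) correlation
structure — 9 modules, within-module $r = 0.35$, between-module
$r = 0.08$ — then AR(1)-filtered in time (coefficient 0.3) with
variance-normalized innovations, which preserves the lag-0 cross
correlations. Six slow motion traces plus white-matter and ventricle
proxies are linearly mixed into the regional signals with recorded
weights, so the tests can verify that nuisance regression removes the
injected contamination essentially exactly.

The module count is a structural choice: with 9 modules of 10 regions the
within-module pair count (405) stays below the 601-edge budget at the 15%
analysis cost, so thresholded graphs retain between-module edges and stay
connected — mirroring real connectomes, which are modular but not
disconnected cliques. Fewer, larger modules would let the within-module
pairs absorb the entire edge budget and fragment the graph.

Patient effects enter as additive perturbations of the within-module
coupling on a configurable affected-region set (default: whole brain,
matching a globally altered small-world organization): a disease
reduction (0.03), an extra female-patient reduction (0.06), and a
duration-linked slope (+0.0075 per year, centered at the cohort mean of
11.3 y). The slope was calibrated, before the acceptance suite was
written, so that the observed age-controlled partial correlation between
duration and small-worldness across replicate cohorts averages ≈ 0.5 —
the effect size scale reported for this association. One consequence of
the centered duration term is worth knowing: male patients (mean duration
8.1 y) sit further below the centering point than female patients
(10.9 y), so the duration term partially offsets the configured
sex-by-disease interaction in the default cohort; tests that characterize
interaction power therefore inject the interaction with the duration
slope disabled.

What the generator does **not** emulate: voxel-level structure and
spatial correlations, hemodynamic response dynamics, scanner artifacts
beyond smooth motion/WM/CSF proxies, non-Gaussian or heavy-tailed signal
components, distance-dependent connectivity, and any spatial
correspondence between module assignments and real anatomy. Passing tests
demonstrate that the *pipeline* recovers structure it is designed to
detect under its own statistical assumptions — not that those assumptions
hold in patient fMRI.

# Validation problem sizes

The test suite validates the metrics against independent brute-force
oracles (explicit shortest-path enumeration, direct triangle counting) on
100 random connected graphs of up to 8 nodes, and against igraph on
40-node graphs. Statistical calibration uses 200 replicate null cohorts
at reduced size (6 subjects per cell, 40 regions, 120 timepoints) for the
type-I error of the interaction test, 20 full-size cohorts for
interaction power, and 16 full-size cohorts for the sign of the
duration–small-worldness partial correlation; small-world behaviour is
checked on Watts–Strogatz graphs (90 nodes, mean degree 12, rewiring
probability 0.1) over 20 seeds with 50–100-graph null ensembles. These
sizes were chosen to make the Monte-Carlo error small relative to the
tested margins.

# Known limitations

* Weighted, directed and efficiency-based variants of the metrics are out
  of scope, as are partial-correlation or wavelet connectivity
  estimators.
* The pipeline starts at region × time series; voxel-level preprocessing
  (slice timing, realignment, spatial normalization) and imaging formats
  are not handled. `aggregateRois()` accepts an externally produced
  voxel × time matrix with a voxel-to-region map.
* Disconnected graphs at low sparsity have defined clustering but no
  $L$, $\sigma$ or betweenness; the pipeline records NA for those
  subjects at those costs rather than imputing.
* The per-step attack-curve test and the post-hoc family are choices
  among reasonable alternatives (documented above), not canon.
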