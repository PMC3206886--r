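# restnet

Graph-theoretical analysis of resting-state functional brain networks in
R, built for the 2×2 sex-by-disease designs used in clinical resting-state
fMRI studies (e.g. migraine patients vs. healthy controls). The package
covers the full region-level pipeline — from ROI time series to group
inference — plus a synthetic-cohort generator so that every stage is
testable without access to patient imaging data.

## What it computes

Starting from per-subject region × time BOLD matrices (90 AAL regions by
default), the pipeline:

1. **Screens motion**: subjects whose translation exceeds 1.5 mm or
   rotation exceeds 1.5° on any axis are excluded.
2. **Preprocesses**: zero-phase Butterworth band-pass (0.01–0.08 Hz), then
   regression of six motion parameters plus white-matter and ventricle
   signals.
3. **Builds the connectome**: the 90×90 Pearson correlation matrix,
   binarized at a fixed wiring cost (*sparsity* S = edges present / edges
   possible), swept over S = 15%–25% so all subjects' networks have equal
   edge count.
4. **Quantifies topology**: clustering coefficient
   C = mean over nodes of 2Eᵢ/(kᵢ(kᵢ−1)), characteristic path length L
   (mean shortest-path distance), and the small-world ratios against
   degree-preserving rewired null ensembles:

   γ = C/C_rand, λ = L/L_rand, σ = γ/λ (σ > 1 ⇒ small world),

   plus unnormalized betweenness centrality
   Bᵢ = Σ_{j≠k≠i} n_{jk}(i)/n_{jk} (Brandes' algorithm).
5. **Stress-tests resilience**: targeted attack — nodes removed in
   decreasing group-mean betweenness order — tracking the largest
   connected component.
6. **Infers group effects**: two-way ANOVA (sex × disease, Type II sums of
   squares for the unbalanced 18-vs-20 cells) per metric and per Fisher-z
   edge weight, Benjamini–Hochberg FDR, Tukey post-hoc contrasts, and
   age-controlled partial correlations with disease duration.

The synthetic cohort draws regional signals from a modular (block)
correlation structure with AR(1) temporal autocorrelation, mixes recorded
nuisance components into them, and perturbs patient coupling with
configurable disease, sex-by-disease, and duration-linked effects.

## Worked example

```r
library(restnet)
cohort <- generateCohort(cohortConfig(seed = 1))
cohort
#> SyntheticCohort: 76 subjects
#>           female male
#>   control     20   18
#>   patient     20   18

sub <- subjectTable(cohort)
id  <- sub$subject_id[1]
clean <- preprocessSubject(cohort@series[[id]], cohort@nuisance[[id]])
net <- thresholdBySparsity(correlationMatrix(clean), sparsity = 0.15)
net
#> BinaryGraph: 90 nodes, 601 edges (sparsity 0.1501)

sw <- smallWorldMetrics(net, nRandom = 100, seed = 2)
unlist(sw[c("C", "L", "gamma", "lambda", "sigma")])
#>        C        L    gamma   lambda    sigma
#> 0.441465 2.192260 2.407129 1.107065 2.174334
```

601 edges is exactly `round(0.15 * 4005)` — the fixed wiring cost at 15%
sparsity — and σ ≈ 2.2 says this subject's network is clearly small-world:
2.4× the clustering of its degree-matched random nulls at only 1.1× their
path length. Group inference on the whole cohort:

```r
sub$C <- vapply(sub$subject_id, function(s) {
  pp <- preprocessSubject(cohort@series[[s]], cohort@nuisance[[s]])
  networkClustering(thresholdBySparsity(correlationMatrix(pp), 0.15))
}, numeric(1))
twoWayAnova(sub$C, sub$sex, sub$group)
#> Two-way ANOVA (Type II SS)
#>         term           F            p
#>          sex  9.44914140 2.983216e-03
#>      disease 57.52285206 9.129605e-11
#>  sex:disease  0.04706837 8.288590e-01

pat <- sub[sub$group == "patient", ]
partialCorrelation(pat$disease_duration, pat$C, covariates = pat$age)
#> Partial correlation: r = 0.483, p = 0.002456 (n = 38, 1 covariate)
```

The disease main effect on clustering is unambiguous here, and the
age-controlled correlation between migraine duration and network topology
is recovered with the sign and magnitude the generator injects. A single
seed need not show a significant interaction; the power properties of the
interaction test are characterized in the test suite.

`runPipeline(pipelineConfig(...))` executes all stages end to end and
writes per-stage TSV/CSV outputs plus a JSON manifest; re-running the same
configuration reproduces every file byte-for-byte.

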