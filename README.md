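# wSuStaIn

Data-driven **subtyping and staging of regional brain atrophy** for the
ALS–FTD spectrum, from tabular volumetric cohorts.

Cross-sectional neurodegeneration cohorts confound two axes of
heterogeneity: *which* spatial pattern of atrophy a patient follows
(subtype) and *how far along it* they are (stage). `wSuStaIn` implements
the full analysis chain that separates them:

1. **w-scoring** — per-region OLS of raw volume on age, sex and
   intracranial volume in healthy controls; patient volumes become
   sign-flipped standardized residuals,
   `w = (predicted − observed) / residual SD`, so `w = +1` means one
   control residual SD of volume loss.
2. **BASC** (Bootstrap Analysis of Stable Clusters) — k-means over
   bootstrap resamples of subjects builds a region × region co-clustering
   *stability matrix*; average-linkage consensus clustering plus the
   silhouette index pick a small number of stable anatomical clusters
   whose mean w-scores become the model's biomarkers.
3. **Piecewise-linear SuStaIn** — a mixture of event-sequence models. Each
   biomarker *i* crosses waypoints w = 1, 2, 3; each crossing is an event,
   a subtype *s* is an ordering S_s of all events, and the expected
   severity g_{s,i}(k) interpolates linearly between the stages at which
   the waypoints are reached (13 clusters × 3 waypoints = 39 stages). The
   likelihood of subject x_j mixes subtypes (fractions f_s) and a uniform
   prior over stages:

   log L = Σ_j log Σ_s f_s (N+1)⁻¹ Σ_{k=0..N} Π_i φ(x_{ji}; g_{s,i}(k), σ_i)

   Sequences are fitted by greedy event relocation with random restarts
   and hierarchical subtype splitting; uncertainty comes from
   Metropolis–Hastings sampling over sequence permutations (default
   100,000 iterations).
4. **Model selection** — 10-fold cross-validation;
   CVIC(C) = −2 × Σ out-of-sample log-likelihood selects the number of
   subtypes (a larger C must lower CVIC by more than 6).
5. **Assignment** — per-subject posteriors over (subtype, stage) averaged
   over MCMC samples; subjects with MAP stage 0 form the
   **normal-appearing** group, so every patient is exactly one of
   {normal-appearing, subtype 1, subtype 2, …}.
6. **Longitudinal validation** — subtype stability (same label, or
   normal-appearing → subtype), staging reliability (stage holds or
   advances), and annualized stage change (Δstage / years).
7. **Cohort statistics** — Shapiro–Wilk-gated t / Mann-Whitney tests,
   expected-count-gated chi-squared / Fisher tests, FDR-corrected regional
   GLM contrasts (optionally stage-adjusted), rank correlations, and the
   ALSFRS-R Progression index `(48 − score) / duration (months)`.

Because real cohorts of this kind are not publicly deposited, the package
ships a fully seeded synthetic-cohort generator with ground truth
(`simConfig()`, `generateControls()`, `generatePatients()`,
`generateLongitudinal()`, `generateClinicalLabels()`), used throughout the
tests for end-to-end recovery checks.

## Worked example

```r
library(wSuStaIn)

cfg <- simConfig(seed = 7)          # 200 controls, 300 patients,
controls <- generateControls(cfg)   # 24 regions in 6 true clusters,
patients <- generatePatients(cfg)   # 2 subtypes (0.6/0.4), 30% stage-0

model <- fitWScoreModel(controls)
w <- applyWScore(model, patients$cohort)

solution <- selectClusterNumber(w, kRange = 2:10, B = 100, seed = 3)
solution
#> ClusterSolution: k = 6 clusters over 24 regions
#>   sizes: 4, 4, 4, 4, 4, 4

biomarkers <- reduceFeatures(w, solution)
spec <- trajectorySpec(colnames(biomarkers))
spec
#> TrajectorySpec: 6 biomarkers, 18 events/stages
#>   waypoints: 1, 2, 3  zMax: 3  sigma: 1

fit <- fitSubtypes(biomarkers, spec, C = 2, nRestarts = 8, seed = 5)
fit
#> SubtypeModel: 2 subtype(s), 18 stages
#>   fractions: 0.589, 0.411
#>   log-likelihood: -2847.554

chain <- runMCMC(biomarkers, fit, nIter = 15000, seed = 6)
assignments <- assignSubjects(biomarkers, chain)
table(ifelse(assignments$normalAppearing, "normal-appearing",
             paste0("subtype", assignments$mapSubtype)))
#> normal-appearing         subtype1         subtype2
#>               44              161               95

cor(patients$truth@stage, assignments$mapStage, method = "spearman")
#> [1] 0.944
```

The selected k equals the planted 6 clusters (adjusted Rand index 1
against the generating partition), the mixture fractions 0.59/0.41 recover
the planted 0.6/0.4, and MAP stages track the latent stages (Spearman
r = 0.94). `pipelineConfig()` + `runPipeline()` run the same chain
file-to-file with a JSON manifest (seeds, input MD5s, artifact paths);
`positionalVariance(chain, s)` gives the event-by-stage posterior matrix
behind positional-variance diagrams.

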