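---
title: "Profiling functional connectome idiosyncrasy: methods and design notes"
author: "idioconn authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Profiling functional connectome idiosyncrasy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idioconn)
```

# The problem

Resting-state fMRI case-control studies compare functional connectivity
between groups under the assumption that, after anatomical registration, the
same cortical location hosts the same functional network in every subject.
That assumption fails to a measurable degree: the spatial layout of the
intrinsic connectivity networks (ICNs) — default mode, somatomotor,
attention systems and so on — varies across individuals. We call this
deviation of a subject's network layout from a canonical group template
*idiosyncrasy*. When idiosyncrasy differs between groups, conventional
connectivity contrasts (e.g. degree-centrality differences) can reflect
network displacement rather than genuine coupling changes.

`idioconn` implements a complete, testable pipeline for quantifying
idiosyncrasy and for asking whether group differences in connectivity
survive once idiosyncrasy is controlled. Because the motivating data
(restricted multi-site clinical cohorts) cannot ship with a package, a
synthetic-cohort generator with known ground truth is a first-class module:
every downstream stage is validated against injected effects.

# The pipeline

1. **Connectivity** (`computeFC`): Pearson correlations between parcel
   time series, clipped to $|r| \le 1 - 10^{-7}$, Fisher-z transformed, and
   row-sparsified to the 10% most positive entries per row (diagonal
   excluded, $k = \mathrm{round}(0.1 (P-1))$, ties to the lower column
   index). The group template is the element-wise mean of the *dense* z
   matrices, sparsified once (`groupAverage`).
2. **Embedding** (`diffusionMap`): the sparsified matrix is converted to a
   normalized-angle affinity $a_{ij} = 1 - \arccos(\cos(\text{row}_i,
   \text{row}_j))/\pi$, density-normalized with $\alpha = 0.5$
   ($W' = D^{-\alpha} W D^{-\alpha}$), and the row-stochastic operator
   $M = D'^{-1} W'$ is eigendecomposed through its symmetric conjugate.
   Coordinates are $\lambda_k^t v_k$ at diffusion time $t = 1$ with the
   right eigenvectors normalized in the stationary ($\pi$-weighted) inner
   product, so Euclidean distance in the full embedding *equals* the
   diffusion distance — a property the tests exploit as an exact oracle at
   $K = P-1$. The trivial constant eigenvector is dropped and the leading
   $K = 30$ components retained.
3. **Alignment** (`changeOfBasis`): individual embeddings live in
   dataset-specific spaces; the operator $O = \arg\min \lVert \Phi O - \Psi
   \rVert_F$ (closed-form least squares over all parcel rows) maps each
   subject into the reference space. We deliberately use unconstrained
   least squares rather than orthogonal Procrustes: the goal is a change of
   basis into the reference coordinate system, not a rotation; a
   rank-deficient $\Phi$ falls back to the pseudoinverse with a warning.
4. **Network identification** (`fitReferenceGMM`, `clusterIndividual`):
   a full-covariance Gaussian mixture over embedding coordinates,
   initialized from a 7-network template labeling, assigns each parcel the
   network with the highest posterior probability. Individuals are refit by
   EM starting from the reference parameters (the closest reading of
   "all embeddings were clustered"); assignment under the unrefit reference
   model is available via `refit = FALSE`. Components are matched back to
   reference networks by nearest mean after refitting; any drift is
   reported.
5. **Descriptors** (`surfaceDistance`, `diffusionDistance`,
   `networkOverlap`, `networkEntropy`): surface distance (SD) is the
   geodesic distance (Dijkstra on the parcel graph) from a parcel to the
   nearest reference parcel of the same network; diffusion distance (DD)
   is the squared Euclidean embedding distance to the nearest same-network
   reference point; per network we report Dice, Jaccard, the symmetric mean
   surface distance (MSD) and size; group-level entropy is the Shannon
   entropy (nats) of the across-subject average posterior map. Cortex-wide
   summaries weight networks by reference size.
6. **Statistics** (`glmContrast`, `tfce`, `permutationCorrect`,
   `spinTest`, `fdrBH`, `severityCorrelation`, `ageEffect`,
   `referenceBootstrap`): network-level GLM contrasts with site/sex/age
   covariates and BH-FDR; parcel-wise contrasts enhanced by TFCE
   ($E = 0.5$, $H = 2$, $dh = \max|t|/100$) and corrected family-wise by
   the max-statistic null under permutation of group labels within site;
   spin tests (random sphere rotations, nearest-centroid reassignment) for
   spatial map correlations; severity associations after z-scoring to the
   typical group and regressing out age/sex/site; a bootstrap that rebuilds
   the reference from half-samples to check descriptor robustness.
7. **Centrality** (`degreeCentrality`, `eigenvectorCentrality`,
   `centralityContrast`): degree centrality counts raw correlations
   strictly above 0.2; eigenvector centrality is the unit-norm Perron
   vector. The group contrast is run twice — with the base covariates, and
   with each subject's parcel-wise SD and DD added to the parcel's own
   model — and the significant-parcel counts are compared.

# The synthetic world

`simulateScenario()` states a fixed generative world:

* **Geometry**: an icosphere of radius 100 (mm scale), subdivided 3 times,
  partitioned into 200 spatially contiguous parcels by seeded
  farthest-point sampling with Lloyd-relaxed shortest-path Voronoi growth;
  a 7-network template is grown the same way on the parcel graph. Lloyd
  relaxation balances territory sizes, which one-shot Voronoi growth does
  not; unbalanced templates made per-network descriptors needlessly
  unstable across seeds.
* **Cohort**: two groups of 40, five sites with weights mimicking a
  multi-site exchange (0.38/0.28/0.13/0.11/0.10), age truncated-normal
  (mean 18.4, sd 8, range 5–45 years), 80% male, log-normal framewise
  displacement (meanlog log 0.12, sdlog 0.5) putting ≈3% of subjects above
  the 0.3 mm exclusion cutoff.
* **Idiosyncrasy injection**: each subject's network boundaries are
  displaced by a geodesic front with per-network magnitudes (mm): typical
  group 20 everywhere except the designated network 5 (65); atypical group
  45 in networks 1–4, 8 in network 5, 20 in networks 6–7; subject jitter
  sd 5; shift grows 0.15 mm/year of age with the *same slope in both
  groups* (jitter deliberately dominates the age drift: if shift were
  mostly an age proxy, the severity analysis — which regresses age out —
  would correctly find nothing). Network 5 emulates a region of *reduced*
  idiosyncrasy in
  the atypical group, enabling sign-recovery tests in both directions.
  These magnitudes are **arbitrary by necessity** — no ground-truth effect
  size in mm exists to copy — and were chosen once, by a design sweep at
  the default cohort size, so that recovery at $n \approx 40$/group is
  feasible; they should be read as "a clearly detectable world", not as an
  empirical claim. Note that shifting networks 1–4 also perturbs the parcel
  sets of their *neighbors*, so "no-effect" networks can show spillover
  differences; tests only assert the injected directions.
* **Signals**: one latent Gaussian series per network; a parcel's series is
  its network latent plus independent noise scaled so the expected
  within-network correlation is 0.5 ($\sigma = \sqrt{1/r - 1}$), over 300
  timepoints (TR 2 s). Sites multiply amplitude only, leaving correlations
  — and hence everything downstream — untouched, which keeps site a pure
  nuisance factor.
* **Severity**: for atypical subjects, $1 + 0.4 \times$ (realized mean
  shift in mm) $+\ \mathcal N(0, 0.4)$, floored at 0 — a stand-in for a
  calibrated severity score coupled to expressed idiosyncrasy. "Realized"
  means the subject's drawn per-network geodesic budget, i.e. exactly what
  the boundary-shift operator applies.

What a green test does *not* establish: the generator has no hemodynamics,
no spatially correlated measurement noise, no motion artifacts beyond a
scalar FD, vertex-level effects are absent (everything lives at parcel
resolution), and network shifts are rigid frontal displacements rather than
the diffuse topographic distortions of real cortex. Recovery results
therefore validate the *machinery*, not clinical effect sizes.

# Numerical choices

* Correlations are clipped at $1 - 10^{-7}$ before `atanh`, keeping Fisher
  z finite while preserving order.
* Retention ties break deterministically toward the lower column index.
* The eigendecomposition is a dense symmetric solve (P ≤ ~1000), avoiding
  iterative-solver nondeterminism; each eigenvector's sign is fixed by
  making its first non-negligible entry positive, so repeated runs are
  bit-comparable.
* EM: convergence at relative log-likelihood change $< 10^{-6}$ or 500
  iterations; covariances get $10^{-6}$ on the diagonal (escalated with a
  warning if Cholesky still fails); a component starved of responsibility
  keeps its previous parameters with a floored weight instead of aborting —
  abandoning the refit for one degenerate component discards information
  from all the others.
* TFCE thresholds step by $dh = \max |t| / 100$ per map; the negative tail
  is enhanced on $-t$ symmetrically. Permutation p values are
  $(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$, bounded below by
  $1/(n+1)$.
* Responses numerically inside the nuisance span (e.g. constant maps) get
  $t = 0$ rather than floating-point noise.
* BH-FDR is implemented directly (sort, $p_{(i)} m/i$, cumulative minimum,
  cap at 1) and tested against `stats::p.adjust`. Note the adjustment is
  *not* idempotent in general; tests assert monotonicity and the oracle
  instead.

# Open design decisions (and how they were resolved)

* The 10% retention counts off-diagonal entries only; self-connectivity is
  meaningless. Ranking is by signed z (most positive), configurable in
  principle via the dense matrix.
* Group averaging precedes sparsification: averaging sparsified matrices
  would dilute the retained-set semantics.
* The MSD formula as typeset omits the operator between its two sums; the
  sum (standard symmetric mean surface distance) is implemented — the
  product reading would not vanish when the two sets coincide.
* DD uses the *squared* norm: where prose and displayed formula disagree,
  the formula wins.
* SD zeros at parcels whose label already matches the reference are
  included in means (maskable by the caller).
* Entropy uses the natural log (bound $\ln 7 \approx 1.9459$) and averaged
  GMM posteriors, not hard-label frequencies.
* Permutations exchange group labels within site: site is the dominant
  nuisance in multi-site designs, and free exchange would mix scanner
  effects into the null.
* Per-subject refit (not plain reference-model assignment) is the default
  clustering mode; both are exposed for sensitivity analyses.
* Alignment uses all parcel rows; restricting correspondences to network
  subsets is not implemented.
* Degree centrality is computed on raw correlations (not z, not
  sparsified), strict inequality at the threshold, negatives never counted.

# Limitations

* The GMM with full 30-dimensional covariances is over-parameterized for
  small parcellations (clusters of ~30 parcels); regularization keeps it
  well-posed, but posterior sharpness should not be over-interpreted at
  these sizes. The motivating analyses used 1000 parcels.
* The change-of-basis operator is estimated from all parcels of a single
  subject; with few parcels and many components it can overfit (residuals
  should be monitored — `runPipeline` stores them).
* The bootstrap rebuilds reference clusterings from the *template* labels;
  real applications may prefer bootstrap-specific initializations.
* No vertex-level analysis, no subcortex, no harmonization models
  (e.g. empirical-Bayes site correction) — fixed covariates only, matching
  the analysis being reproduced.

# A worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  scenario = scenarioConfig(cohort = cohortConfig(nTypical = 20L,
                                                  nAtypical = 20L)),
  nPerm = 200L, nRot = 500L)
res <- runPipeline(cfg, seed = 1, verbose = TRUE)
subset(res$networkStats, metric == "msd")
res$summary
```

See the README for the numbers this prints and how to read them.
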