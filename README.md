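# idioconn — idiosyncrasy profiling of functional connectomes

`idioconn` quantifies how far each individual's intrinsic connectivity
networks (ICNs) deviate from a canonical group template — their functional
*idiosyncrasy* — and asks whether conventional case–control connectivity
differences survive once that idiosyncrasy is controlled. It is aimed at
researchers analyzing parcel-level resting-state fMRI in heterogeneous
(e.g. multi-site, case–control) cohorts.

## The method in brief

For each subject with parcel time series \(X \in \mathbb{R}^{P \times T}\):

1. **Connectivity**: Pearson correlations, Fisher-z (`atanh`, correlations
   clipped at \(1-10^{-7}\)), each row keeping only its top 10% entries
   (\(k = \mathrm{round}(0.1(P-1))\), diagonal excluded).
2. **Diffusion-map embedding**: normalized-angle affinity between rows,
   density normalization \(W' = D^{-\alpha} W D^{-\alpha}\) with
   \(\alpha = 0.5\), eigendecomposition of the transition operator
   \(M = D'^{-1} W'\); coordinates \(\lambda_k^t v_k\), \(t = 1\),
   \(K = 30\) components (trivial eigenvector dropped). A reference
   embedding is built the same way from the mean of all subjects' dense z
   matrices.
3. **Alignment**: each embedding \(\Phi\) is mapped into the reference
   space by the change-of-basis operator
   \(O = \arg\min \lVert \Phi O - \Psi \rVert_F\).
4. **Network identification**: a 7-component full-covariance Gaussian
   mixture, initialized at a template labeling, assigns each parcel its
   maximum-posterior network; subjects are refit by EM from the reference
   parameters.
5. **Idiosyncrasy descriptors**: per parcel, the geodesic **surface
   distance** (SD) to the nearest same-network reference parcel and the
   squared embedding **diffusion distance** (DD)
   \(dd(\phi_c, \psi_c^r) = \lVert \phi_c - \psi_c \rVert^2\); per network,
   Dice, Jaccard, symmetric **mean surface distance** (MSD) and size; per
   group, the entropy of averaged posterior probability maps.
6. **Inference**: network-level GLM contrasts (site/sex/age covariates,
   Benjamini–Hochberg FDR), parcel-wise contrasts with TFCE
   (\(E=0.5, H=2\)) and max-statistic permutation correction (labels
   permuted within site), spin permutation tests for spatial map
   correlations, severity and age associations, and a half-sample
   bootstrap of the reference.
7. **Centrality contrasts**: degree centrality (raw correlations \(> 0.2\))
   and eigenvector centrality, contrasted between groups before and after
   adding each subject's parcel-wise SD and DD as covariates.

Because the motivating cohort data are restricted, the package ships a
synthetic world (`simulateScenario()`): a parcellated sphere whose
7-network template is displaced per subject by known geodesic shift
magnitudes, with group differences, an age trend, a coupled severity
score, multi-site structure and a framewise-displacement QC column. Every
stage is tested against this ground truth.

## Worked example

```r
library(idioconn)
cfg <- pipelineConfig()   # 40 subjects/group, 200 parcels, default parameters
res <- runPipeline(cfg, seed = 1)
subset(res$networkStats, metric == "msd")
```

```
  metric network     t        p cohensD     pAdj
1    msd       1  4.26 6.55e-05   1.134 9.17e-05
2    msd       2  3.23 1.92e-03   0.787 1.92e-03
3    msd       3  3.68 4.69e-04   0.908 5.47e-04
4    msd       4  5.66 3.37e-07   1.547 7.86e-07
5    msd       5 -4.54 2.47e-05  -1.047 4.32e-05
6    msd       6 10.76 3.07e-16   2.467 2.15e-15
7    msd       7  6.76 4.14e-09   1.613 1.45e-08
```

The generator injected larger network shifts in the atypical group for
networks 1–4 and a *smaller* shift for network 5; the per-network MSD
contrasts recover exactly that pattern (positive t with FDR-adjusted
p < 0.05 for the increase networks, negative for network 5 — networks 6–7
pick up real spillover from their shifted neighbors). Other headline
outputs from the same run:

```
cortex-wide MSD contrast: t = 6.20, p = 4e-08
severity-DD correlation (cortex-wide): r = 0.50, p = 0.001
DC parcels significant before / after SD+DD control: 58 / 42
spin correlation of entropy and SD difference maps: r = 0.81, p = 0.000999
```

Read: whole-cortex idiosyncrasy is higher in the atypical group; the
severity score (coupled to realized shift by construction) correlates with
diffusion distance; the degree-centrality group contrast loses significant
parcels once SD/DD enter the model — apparent "connectivity alterations"
partly reflect network displacement; and the group-difference maps of
entropy and SD co-localize under a spatial-autocorrelation-preserving spin
null.

See `vignettes/idiosyncrasy-profiling.Rmd` for the full model description,
parameter table, generator design and limitations.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the demonstration analysis from scratch at the demo scale
(20 subjects per group, 200 parcels): it simulates the cohort, applies the
0.3 mm FD exclusion, builds connectivity and the reference embedding,
identifies the 7 networks, computes all idiosyncrasy descriptors, runs the
group statistics and the centrality contrast, prints a short summary, and
writes the JSON report to `--out`.
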