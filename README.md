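# tlsniche

Tools for characterising **tertiary lymphoid structures (TLS)** and
**tumour-cell aggregates (TCA)** in spatial and single-cell transcriptomes of
virus-associated epithelial tumours, with companion statistics for multiplex
imaging, B-cell receptor repertoires, the germinal-centre reaction, and
survival stratification.

## Scientific problem

In Epstein–Barr-virus-positive nasopharyngeal carcinoma and related tumours,
the tissue is organised into immune niches: TLS — ectopic lymphoid aggregates
dominated by B and T cells — and TCA — malignant-cell aggregates that differ
in viral transcriptional load. Clinical observations link three quantities:

1. **Where the niches are.** Spot-level spatial transcriptomics (Visium
   hexagonal lattices, Stereo-seq square bins) can be segmented into
   TLS / TCA / stroma from marker-gene module scores, TCAs resolved into
   connected components, stratified by EBV-signature quartiles and classified
   by plasma-cell co-occurrence ("wP" / "woP").
2. **What happens inside them.** Plasma-cell-associated, EBV-high TCAs show
   elevated tumour apoptosis; germinal centres inside TLS run a cyclic
   dark-zone/light-zone programme that a polar PCA embedding can expose;
   B-cell repertoires quantify maturation through somatic hypermutation
   (SHM) bins, clonal diversity, cluster-to-cluster transition indices and
   clonotype sharing.
3. **What they mean for patients.** A seven-signature TLS cell-type score,
   computed by single-sample GSEA on bulk cohorts, splits patients into
   high/low modules with distinct survival (Kaplan–Meier, Cox, log-rank).

`tlsniche` implements this entire analysis surface in idiomatic R, together
with negative-binomial simulators that plant ground truth for every input, so
each claim above is testable offline without any patient data.

## Worked example

Simulate a 24×24 Visium-like sample with planted compartments, call the
compartment map, and compare apoptosis across TCA classes:

```r
library(tlsniche)

cfg  <- spatialSimConfig(geometry = "hex", extent = 24, seed = 7)
sim  <- generateSpatialSample(cfg)
cmap <- callCompartments(sim$counts, sim$grid, sim$signatures,
                         nCtrl = 15, seed = 1)
cmap
#> CompartmentMap: TLS=85, TCA=168, stroma=323
#>   8 TCA component(s): high-wP, low-wP, high-woP, low-woP, mid-wP,
#>   mid-wP, mid-woP, mid-woP

ev <- evaluateCompartmentRecovery(sim$truth, cmap)
ev$regionAccuracy      #> 0.9983
ev$fourClassAccuracy   #> 1

apo <- moduleScore(logNormalize(sim$counts),
                   geneIds(sim$signatures, "apoptosis"),
                   nCtrl = 15, seed = 2)
cmp <- compareApoptosis(cmap, apo)
cmp$topClass           #> "EBVhigh-wP"
cmp$summary
#>         class  n       mean     median       IQR
#> 1 EBVhigh-woP 21 -0.2405700 -0.2429064 0.2130088
#> 2  EBVhigh-wP 21  0.5980701  0.5874256 0.2654000
#> 3  EBVlow-woP 21 -0.1067292 -0.1686706 0.2704544
#> 4   EBVlow-wP 21  0.3564907  0.3732735 0.2722602
#> 5  EBVmid-woP 42 -0.1556978 -0.1513031 0.1680353
#> 6   EBVmid-wP 42  0.5625591  0.5557897 0.2568135
```

The plasma-associated, EBV-high TCA class has the highest apoptosis score,
as planted.

Repertoire statistics on a simulated B-cell table with 25% of memory cells
drawing from the germinal-centre top-10 clonotypes:

```r
sharing <- matrix(c(0, 0.25, 0, 0), 2, 2, byrow = TRUE,
                  dimnames = list(c("GC", "Mem"), c("GC", "Mem")))
rep <- generateRepertoire(c(GC = 800, Mem = 800), sharing = sharing, seed = 3)
round(topClonotypeSharing(rep, "GC", k = 10), 3)
#>    GC   Mem
#> 0.814 0.248
round(clonalDiversity(rep, "GC"), 3)        #> 0.571
round(transitionIndex(rep, "GC", "Mem"), 3) #> 0.418
```

Germinal-centre polar embedding on cells running a planted cyclic programme:

```r
cyc <- generateCyclicCells(nCells = 500, nGenes = 40, seed = 5)
emb <- gcPolarEmbedding(cyc$expr, rownames(cyc$expr))
emb
#> GCEmbedding: 500 cells, radial offset 4.314
abs(circularCorrelation(embeddingTable(emb)$theta, cyc$phase))
#> 0.995
```

Survival stratification with a planted hazard ratio of 0.3 for the
TLS-high group:

```r
coh <- generateSurvivalCohort(150, beta = log(0.3), seed = 11)
fit <- coxHr(coh$surv, factor(coh$scores$group, levels = c("low", "high")))
round(fit$HR, 3)           #> 0.226
round(fit$ci, 3)           #> 0.141 0.361
logrankTest(coh$surv, coh$scores$group)$p
#> 1.73e-11
```

## Package map

| Area | Key functions |
| --- | --- |
| Preprocessing | `qcFilter`, `logNormalize`, `ddctEbvLoad` |
| Scoring | `moduleScore`, `ssgseaScore`, `rankMarkers`, `topKSignature` |
| Spatial compartments | `callCompartments`, `callRegions`, `findTcaComponents`, `stratifyEbv`, `classifyPlasmaCooccurrence`, `compareApoptosis`, `binStereoSpots` |
| Proximity statistics | `countWithinRadius`, `distanceHistogram`, `csrExpectedCount` |
| Repertoire | `binShm`, `isotypeComposition`, `clonalDiversity`, `transitionIndex`, `topClonotypeSharing` |
| Germinal-centre axis | `gcPolarEmbedding`, `dzLzScores`, `circularCorrelation` |
| Survival | `tlsCsMatrix`, `clusterTwoModules`, `rocOptimalCutoff`, `kmEstimate`, `coxHr`, `logrankTest` |
| Simulators | `generateSpatialSample`, `generateSingleCells`, `generateRepertoire`, `generatePointPattern`, `generateSurvivalCohort`, `generateCyclicCells` |
| I/O | `readCountsMTX`, `readSignaturesGMT`, `readSignaturesJSON`, `readSpotGridCSV`, `writeCompartmentMapCSV`, `readRepertoireTSV` |

See `vignette("tls-niche-methods")` for the method definitions and their
statistical rationale.

## Reproduction

The full test suite (unit, property and acceptance tests) runs with:

```r
testthat::test_dir("tests/testthat", package = "tlsniche")
# or, from a development checkout:
devtools::test()
```

An end-to-end acceptance run against the installed package writes the
headline quantities (compartment recovery accuracy, apoptosis ordering
rate, oracle agreement bounds, circular correlation, Cox HR, and more)
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; repeated runs with the same seed are
bit-identical. With seed 1 the run reports, among others, region-call
accuracy 99.19% (n = 1600 spots), four-class TCA accuracy 100%,
EBV-high-wP top-apoptosis rate 97%, and a simulated Cox HR of 0.33 against
the planted 0.3.
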