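# methylDelta

Consensus-based analysis of longitudinal blood DNA methylation, for
studies where each patient is profiled on a beta-value array at baseline
(T1) and at two follow-up timepoints (T2, T3) after an intervention such
as a dietary change. The package is aimed at epigenetics analysts who
want the per-patient consensus view of differential methylation — a CpG
site counts as responsive only if *most patients individually* shift —
rather than a group-mean test.

## Core model

For patient $p$ and probe $j$, with $\beta \in [0,1]$ the methylation
level,

$$\Delta\beta_{jp} = \mathrm{mean}(\beta_{jp,\mathrm{T2}}, \beta_{jp,\mathrm{T3}}) - \beta_{jp,\mathrm{T1}},$$

falling back to the single available post timepoint if one is missing.
A probe is called **hyper**methylated when at least
$\lceil f \cdot n_{\mathrm{eval}} \rceil$ of the evaluable patients have
$\Delta\beta_{jp} \ge \delta$, and **hypo**methylated symmetrically.
Defaults: $\delta = 0.10$ on the beta scale, $f = 0.77$ (14 of 18
patients), with the per-probe denominator $n_{\mathrm{eval}}$ excluding
patients missing at that probe.

Around the caller the package provides:

- **I/O** for beta matrices, sample sheets and probe manifests (plain
  TSV), with strict validation (`readBetaMatrix()`, `readSampleSheet()`,
  `readProbeManifest()`).
- **Summaries**: per-group median profiles, Brown–Forsythe dispersion
  comparisons, sign-stabilized PCA, and clinical correlations
  (`subsetMedianProfile()`, `subsetVarianceTest()`, `pcaProfiles()`,
  `correlateGlobals()`).
- **Enrichment** of a called subset over genomic-feature categories:
  frequency fold changes against a background manifest with a
  size-matched resampling null (`featureFoldChange()`,
  `enrichmentResampleP()`).
- **Stratification** of an independent liver panel by fibrosis grade:
  Ward clustering with a chi-squared cluster-by-grade test, and a fully
  seeded gradient-boosted classifier with cross-validated ROC
  (`clusterAndTest()`, `classifyGrades()`, `crossTissueHeatmapOrder()`).
- **Clinical statistics**: a longitudinal testing engine with a
  normality gate choosing repeated-measures ANOVA or Friedman, gated
  Bonferroni-adjusted post hocs, and patient-versus-control comparisons
  (`testParameter()`, `compareToControls()`).
- **A synthetic cohort generator** with a planted ground-truth ledger,
  used throughout the test suite (`simulationConfig()`,
  `simulateCohort()`, `simulateLiverPanel()`).

Data containers are Bioconductor-style S4: `BetaSet` extends
`SummarizedExperiment` (assay `"beta"` plus a validated sample sheet in
`colData`), `ProbeManifest` extends `DFrame`, and results are returned
as small classes with `show()` methods and accessors.

## Worked example

Simulate a cohort at the study-design defaults (18 patients × 3
timepoints, 5,000 probes, 100 planted hyper- and 10 hypomethylation
sites, 60 healthy controls) and run the pipeline:

```r
library(methylDelta)

cfg <- simulationConfig(seed = 1L)
sim <- simulateCohort(cfg)
res <- callSites(computeDelta(sim$betas))
res
#> DeltaCallResult: 5000 probes x 18 patients; threshold 0.10, consensus 0.77
#>   calls: 100 hyper, 10 hypo, 4890 none

called <- calledProbes(res)
subsetMedianProfile(sim$betas, called)
#> healthy_blood            T1            T2            T3
#>     0.5392729     0.3755922     0.5362750     0.5399552
```

All planted sites are recovered with no false positives, and at the
called sites the post-diet profiles (T2, T3) have moved onto the healthy
controls while baseline T1 sits apart. The independent liver panel
stratifies cleanly by fibrosis grade on the same CpG panel:

```r
lv <- simulateLiverPanel(cfg, sim$truth)
clusterAndTest(lv, called)
#> ClusterGradeResult (ward.D2 linkage): chi2 = 480, df = 9, p = 1.1e-97
#>        grade
#> cluster  0  1  2  3
#>       1 40  0  0  0
#>       2  0 40  0  0
#>       3  0  0 40  0
#>       4  0  0  0 40

classifyGrades(lv, called, seed = 1)
#> ClassifierReport (grade3 vs grade0, 5-fold, seed 1): mean AUC 1.0000, accuracy 1.0000
```

With feature-biased planting (`planted_feature_bias = TRUE`), enrichment
of the called subset recovers the planted over-representation of
open-sea probes and depletion of CpG islands:

```r
simB <- simulateCohort(simulationConfig(seed = 1L, planted_feature_bias = TRUE))
calledB <- calledProbes(callSites(computeDelta(simB$betas)))
enrichmentResampleP(calledB, simB$manifest, "cgi_relation", nDraws = 1000, seed = 1)
#> EnrichmentTable (axis: cgi_relation)
#>     category observed subset_size background background_size fold_change  empirical_p
#> 1     Island        8         110       1038            5000   0.3503240  0.000999001
#> ...
#> 6    OpenSea       88         110       2644            5000   1.5128593  0.000999001
```

See `vignettes/methylation-consensus.Rmd` for the model, parameter
rationale, and what the simulator does and does not emulate.

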