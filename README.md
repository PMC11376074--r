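# alkylotroph

Detection of methanogenic hydrocarbon degradation in oil-reservoir
samples: an R package plus a five-stage analysis workflow.

Candidatus Methanoliparum degrades long-chain alkanes and produces
methane within a single archaeal cell. Surveys for this process combine
three lines of evidence per sample, and this package implements the
computations behind all of them:

1. **Crude-oil biodegradation scoring (0-4)** from GC-MS total ion
   chromatograms: peak detection, n-alkane / pristane / phytane
   assignment, nC17/Pr and nC18/Ph ratios, an unresolved-complex-mixture
   (UCM) index, and a rule set mapping these diagnostics to degrees 0
   (non-degraded) through 4 (severe, n-alkanes gone).
2. **Alkyl-coenzyme M screening** by targeted MRM: theoretical ion pairs
   for the C4-C28 homolog series from the fragment-mass model
   m/z = 12.00055·n + 1.00837·(2n+1) + 79.9 (alkyl-sulfonate; bisulfite
   80.9, ethenesulfonate 106.9), matched at 0.3 Da with a strict >2000
   intensity threshold on the bisulfite pair; per-sample homolog
   *variety*.
3. **Abundance and activity**: qPCR standard-curve absolute
   quantification (copies per gram), amplicon target-feature fractions,
   length-normalized MAG activity, FPKM.
4. **Integration**: the four co-occurrence evidence groups over
   (16S, acrA transcription, alkyl-CoM) booleans; stratified detection
   proportions; and a ridge regression
   Y = X'β + k with X = ln(FPKM + pseudocount) and Y = logit((d+0.5)/5),
   solved in closed form with an unpenalized intercept and λ by
   leave-one-out cross-validation.

A synthetic-data generator (`simulate_chromatogram()`,
`simulate_mrm_run()`, `simulate_expression()`, `simulate_study()`)
produces all inputs with known ground truth, so the whole pipeline is
testable end to end. See the methods vignette
(`vignettes/oil-reservoir-methanogenesis.Rmd`) for the models, parameter
conventions, and limitations.

## Worked example

```r
library(alkylotroph)

# a moderately degraded oil, scored back from its chromatogram
sim <- simulate_chromatogram(degree = 2, seed = 7)
score_chromatogram(sim$chromatogram)
#> Biodegradation score: 2
#>   UCM index: 0.689 | n-alkanes: 26 | nC17/Pr: 0.428 | nC18/Ph: 0.43

# alkyl-CoM homologs C13-C20 planted at intensity 5000, screened back
run <- simulate_mrm_run(13:20, intensity = 5000, decoy_count = 10, seed = 3)
screen_alkylcom(run)$variety
#> Alkyl-CoM screen: NA
#>   variety: 8
#>   chain lengths: 13, 14, 15, 16, 17, 18, 19, 20
```

The UCM index 0.689 (two thirds of the trace area unresolved) plus both
diagnostic ratios below 1 with pristane/phytane dominant and a full
residual alkane ladder is exactly the degree-2 profile; the screen
recovers the eight planted homologs and none of the decoys.

## The analysis workflow

`analysis/01_simulate_study.R` … `05_integrate_evidence.R` run a
150-sample synthetic survey through every stage, writing tables under
`results/`. Stage highlights from a run with seed 1:

```
scored 150 samples; agreement with planted degree: 99.3%
alkyl-CoM detected in 99 of 150 samples (66%); variety 1-18
standard curve: slope -3.3219, efficiency 100%, R2 1.0000
16S detected in 124 of 150 samples
evidence groups:  1: 72   2: 13   3: 14   4: 12   other: 39
calibration run, truth beta = (0.01, 0.86), intercept 0.49:
  Y = 0.039*fpkm_bacterial + 0.871*fpkm_acrA + 0.410
```

The calibration run shows the ridge stage recovering its generating
coefficients, with the archaeal acrA term dominating the bacterial term —
the computational core of attributing hydrocarbon degradation to
alkylotrophic methanogens rather than bacteria.

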