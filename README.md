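# hilltac

Hill-number diversity profiles, taxa-accumulation curves and
taxon-abundance-distribution fits for amplicon OTU count tables.

## The problem

Bacterial communities are hyperdiverse, and much of their richness lives in
a rare biosphere of taxa seen once or twice. Sequencing is an incomplete
census: observed richness keeps climbing with read depth, so a single
"diversity" number from an undersampled OTU table is not reproducible. This
package is for microbial ecologists who want diversity estimates that state
their own reliability: it measures diversity at several Hill orders,
tracks each order's accumulation with sampling effort, and reports where
(and whether) each curve has flattened at the available depth.

The core quantity is the Hill number of order *a*, the effective number of
taxa

> *N*<sub>*a*</sub> = ( Σ<sub>i</sub> *p*<sub>i</sub><sup>*a*</sup> )<sup>1/(1−*a*)</sup>,

with *N*<sub>0</sub> the observed richness, *N*<sub>1</sub> =
exp(Shannon entropy) (the *a* → 1 limit), and *N*<sub>2</sub> the
reciprocal Simpson index. Larger *a* down-weights rare taxa, so higher
orders converge at shallower depths — which is exactly what the
accumulation analysis exploits. Around that core the package provides
Chao1 and Good's coverage, smoothed taxa-accumulation curves (mean over
random sample orderings of the pooled-community *N*<sub>*a*</sub>),
without-replacement read subsampling with a plateau-stability criterion,
maximum-likelihood log-normal and Zipf taxon-abundance fits with AIC model
selection, a parametric-bootstrap (Lilliefors-type) deviation test against
the log-normal, a synthetic community generator, mothur `.shared`/TSV I/O,
and a reproducible end-to-end pipeline (`runPipeline`, plus a thin CLI in
`inst/scripts/hilltac.R`).

## Worked example

Simulate a 12-sample study of a log-normal community (S = 1500,
σ = 1.5), summarize diversity, locate the stable depth per order, and fit
abundance models:

```r
library(hilltac)
spec <- communitySpec(S = 1500, tad = "lognormal", mu = 0, sigma = 1.5,
                      seed = 1)
ct   <- makeStudy(spec, nSamples = 12, depthPerSample = 10000, seed = 1)
tail(diversityTable(ct), 3)
#>    sample S_obs   N_1   N_2 chao1 coverage F_1 F_2      N
#> 11    S11  1126 412.1 122.1  1438   0.9691 309 153  10000
#> 12    S12  1093 398.9 114.0  1289   0.9741 259 171  10000
#> 13 pooled  1462 427.0 116.3  1476   0.9997  35  45 120000

pool <- poolSamples(ct)
depthAnalysis(pool, depths = c(5000, 10000, 20000, 40000, 80000, 120000),
              orders = c(0, 1, 2), reps = 10, seed = 99)
#> DepthAnalysisResult: 6 depths x 3 orders x 10 replicates
#>   stability depth: a=0: 80,000; a=1: 40,000; a=2: 20,000

selectModel(list(fitLognormal(pool), fitZipf(pool)))
#> RADFitResult: lognormal fit to 1462 taxa
#>   params: mu = 3.245, sigma = 1.484
#>   logLik: -7395.9774  AIC: 14795.955

deviationTest(pool, nBoot = 999, seed = 7)
#> DeviationResult: D = 0.02817 , p = 0.201 ( 999 bootstrap replicates )
```

Reading the output: each sample sees ~1100 of the 1500 taxa; the pooled
coverage (0.9997) says almost every read re-observes a known taxon. The
depth analysis orders the stability depths exactly as the theory predicts —
the rare-taxon-insensitive *N*<sub>2</sub> is reliable from 20,000 reads,
*N*<sub>1</sub> from 40,000, while richness needs 80,000 even in this
moderately sized community. Model selection recovers the generating
log-normal family with σ̂ = 1.48 (truth 1.5), and the deviation test
correctly fails to reject it (p = 0.20). Running the same fits on a
shallow, heavy-tailed Zipf community instead selects the Zipf model and
rejects the log-normal decisively — the qualitative contrast between
deeply and shallowly sequenced soil studies that motivates the framework.

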