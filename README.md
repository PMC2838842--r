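# intensityLM

Genewise linear-model analysis of dual-color (two-channel) gene-expression
microarrays, comparing the classical **ratio-based** analysis with a
**intensity-based** analysis of the separate channels.

## The problem

A two-color array co-hybridizes two Cy3/Cy5-labeled samples, and the
standard analysis models within-array log-ratios — equivalently, a
per-probe ANOVA on single-channel log2 intensities that includes a
per-gene array effect:

    y_ijk = mu + tau_i + eta_j + alpha_k(j) + eps_ijk

with treatment effect `tau`, optional unit (cell line) effect `eta` and
array effect `alpha`.  On modern high-quality oligonucleotide platforms
`alpha` is small, yet it consumes almost half of the degrees of freedom.
Dropping it (the intensity-based model) treats the channels as
exchangeable observations, frees those degrees of freedom, and — as this
package lets you quantify — yields more reproducible gene rankings and
smaller p-values, most markedly in complex direct designs such as
interwoven loops with large biological variation.

The package provides, per probe: least-squares fits of both models,
treatment F-tests, pairwise effect sizes (M-values) and BIC model
selection between the two analyses; quantile normalization of pooled
channels and the A > 7 mean-intensity filter; technical-replicate
splitting of factorial and loop designs; reproducibility metrics
(Spearman rho of p-values, ranked-bin and top-k overlap, M-value
correlations); in-silico reconstruction of ratios from separate
hybridizations; analytic power of the paired versus two-sample analyses
via the non-central t distribution; and a variance-component simulator
with ground truth for every supported design topology.  It is intended
for statisticians and analysts working with two-channel expression data
(or studying when pairing is worth its degrees of freedom).

## Worked example

A brain-like scenario: 49 subjects in 7 groups hybridized twice around an
interwoven loop, with subject-level biological variation (sd 0.6) well
above the typical treatment effect.  Split the channels so each subject
appears once per half, fit both models per half, and compare rankings:

```r
library(intensityLM)

cfg <- simConfig(nProbes = 2000, topology = "interwoven-loop",
                 nGroups = 7, nUnitsPerGroup = 7, sigmaUnit = 0.6, seed = 20)
sim <- simulateDataset(cfg)
sim$channels
#> ChannelSet: 2000 probes x 98 channels ( 49 arrays ), log2 scale
#> provenance: simulated: interwoven-loop, seed 20

sp <- splitReplicates(sim$design, "once-per-subject")
fit <- function(chans, arr) fitDataset(sim$channels[, chans], sim$design,
                                       modelSpec(includeArray = arr))
r1 <- fit(sp@half1, TRUE);  r2 <- fit(sp@half2, TRUE)   # ratio model
i1 <- fit(sp@half1, FALSE); i2 <- fit(sp@half2, FALSE)  # intensity model

pvalueReproducibility(r1, r2)   # 0.506
pvalueReproducibility(i1, i2)   # 0.867
ovR <- topkOverlapCurve(r1, r2); ovR$overlap[ovR$k == 1000]  # 0.678
ovI <- topkOverlapCurve(i1, i2); ovI$overlap[ovI$k == 1000]  # 0.833
```

Between the two technically identical halves, the intensity model
reproduces rankings far better (rho 0.867 vs 0.506; 83% vs 68% of the
top-1000 genes), because the ratio model spends most of its degrees of
freedom on array effects while the arbitrary subject pairing leaks
biological variation into the ratios.  BIC agrees on the full dataset:

```r
sel <- bicSelection(fit(colnames(sim$channels), TRUE),
                    fit(colnames(sim$channels), FALSE))
attr(sel, "fractionIntensity")   # 1: intensity preferred for every probe
```

An analytic view of the same trade-off for a simple paired two-group
design (`powerWithArrayEffect()` / `powerWithoutArrayEffect()`): pairing
cancels array variance but halves the degrees of freedom, so the curves
cross once as the sample size grows whenever the array sd is a moderate
fraction of the noise sd.

A command-line layer over the same functions is installed at
`exec/dualchannel` (subcommands `simulate`, `normalize`, `fit`,
`compare-models`, `reproducibility`, `reconstruct`, `power`, `cluster`).

See `vignettes/intensity-vs-ratio.Rmd` for the model, the design
decisions and the simulator calibration.

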