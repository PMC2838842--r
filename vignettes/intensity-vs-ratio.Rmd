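---
title: "Intensity- versus ratio-based genewise models for dual-color arrays"
author: "intensityLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity- versus ratio-based genewise models for dual-color arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(intensityLM)
  library(SummarizedExperiment)
})
```

## The model

A dual-color (two-channel) microarray co-hybridizes two Cy3/Cy5-labeled
samples on one array, yielding two intensity measurements per probe per
array.  The classical analysis works on within-array log-ratios, which is
equivalent to fitting, per probe, a linear model on the single-channel
log2 intensities that contains a per-gene *array effect*:

$$ y_{ijk} \;=\; \mu + \tau_i + \eta_j + \alpha_{k(j)} + \varepsilon_{ijk}, $$

where $\mu$ is the probe's average log2 intensity, $\tau_i$ the treatment
(group) effect of interest, $\eta_j$ an optional unit effect (for example
a cell line), $\alpha_{k(j)}$ the array effect and $\varepsilon$ Gaussian
noise.  We call this the **ratio-based** model.  Dropping $\alpha$ gives
the **intensity-based** model, which treats the $2n$ channels as
exchangeable observations.  No dye term is fitted in either model: the
supported designs are dye-balanced and quantile normalization removes
dye-wide bias; a nonzero dye effect remains available in the simulator to
study that assumption's failure.

On modern oligonucleotide platforms the array effect is small, while it
still consumes almost half of the degrees of freedom (one parameter per
array).  The package quantifies the consequences of that trade-off:
per-probe F-tests on the treatment factor under both models, BIC model
selection between them, reproducibility of the resulting gene rankings
across technical-replicate halves, in-silico ratio reconstruction, and an
analytic power comparison.

Treatment contrasts use reference-level coding; pairwise effect sizes
(M-values, log2 units) are estimable contrasts and therefore invariant to
that choice.  Rank-deficient designs (treatment and array are partially
confounded in most direct designs) are handled by a sequential
rank-reduction that admits columns in the order intercept, treatment,
unit, array, so that confounded *array* columns are dropped and reported
— never treatment contrasts, and never silently.  If all treatment
contrasts are aliased the fit refuses with an error.

The likelihood behind BIC is the Gaussian profile maximum likelihood at
$\hat\sigma^2 = \mathrm{RSS}/n$ (maximum likelihood, not REML, so that
models with different mean structures are comparable), and
$\mathrm{BIC} = -2\log L + p\log n$ with $p$ equal to the retained mean
parameters plus one for the variance.  Ties prefer the intensity model,
the one with fewer parameters.  Because the array-effect penalty grows
with the number of arrays while the intensity model's is constant, the
BIC preference for the intensity model strengthens with sample size when
both models fit comparably.

## Preprocessing conventions

* **Quantile normalization** pools *all* $2n$ single channels into one
  normalization (rank-wise means; tied values receive the mean of the
  reference values at their tied ranks).  Pooling makes the channels
  exchangeable, which the intensity analysis requires.  The log2
  transform is applied after normalization.  No background correction is
  ever performed, and zero or negative intensities are rejected rather
  than offset-corrected: an implicit pseudocount would silently change
  the A-values the expression filter depends on.
* **Expression filter**: probes are kept when their mean log2 intensity
  over all channels (the A-value) exceeds 7, with a *strict* inequality.
  Removal is global across channels, so per-probe sample sizes stay
  equal.  The threshold is an argument; 7 is the default for the Agilent
  44K-class data the method targets.  Filtering is applied after
  normalizing the full dataset and before any replicate splitting, so
  both halves see identical probe sets.

## Splitting into technical-replicate halves

Reproducibility is measured between two biologically identical halves of
one experiment.  Two split rules cover the supported designs:

* **by-replicate-set** — the whole experiment was hybridized twice and
  channels follow their replicate label; each half is a complete copy of
  the design.
* **once-per-subject** — each subject was hybridized twice (typical for
  loop designs); each half must contain every subject exactly once.  Many
  valid assignments exist.  The deterministic rule used here walks over
  arrays and keeps an array's two channels together whenever both of its
  subjects still need the current half; on a single loop this alternates
  whole arrays between the halves, with the odd leftover array split
  between them.  The rationale is statistical: a half in which almost
  every array contributes only one channel leaves the array effect
  saturated (zero residual degrees of freedom), and the ratio model could
  not be fitted at all.  Keeping arrays intact preserves within-array
  pairs in both halves while still pairing subjects differently across
  halves — exactly the property that makes the comparison between ratio
  and intensity analyses informative.  A seed-driven variant randomizes
  the array order for robustness studies.

```{r split}
d <- makeDesign("interwoven-loop", nGroups = 7, nUnitsPerGroup = 7)
sp <- splitReplicates(d, "once-per-subject")
table(table(designTable(subsetDesign(d, sp@half1))$array_id))
```

## Ranking metrics and tie handling

Gene rankings order by p-value with ties broken by probe identifier, so
every ranking (and hence every overlap fraction) is deterministic.  The
reproducibility metrics are Spearman's rho between p-value vectors
(rank-based, so equivalent on p or $-\log_{10} p$; a Pearson variant on
$-\log_{10} p$ is available), the per-bin overlap of equal-rank bins
(trailing partial bins use their own size as denominator), the top-$k$
overlap curve, and Pearson correlation for M-value and reconstructed
ratio comparisons.  Clustering of channels uses complete linkage on
$1 - r$ (Pearson) distances by default — scale-free and standard for
expression QC — with Euclidean distance as an option; the channel
dendrogram is exportable as Newick.  The smoothed effect-size histograms
use a Gaussian kernel with Silverman's rule-of-thumb bandwidth,
overridable; the "average array effect size" is the mean of the absolute
estimated array coefficients under reference coding (maximum or RMS
would also be defensible summaries; the mean is reported because it is
what the fitted coefficients average to).

## Power analysis

For a direct two-group design (both groups on every array) the two
analyses reduce to textbook tests, and their power follows from the
non-central t distribution:

* with array effect: a paired t-test on within-array differences,
  $df = n - 1$, difference sd $\sqrt2\,\sigma_e$ (the array term cancels
  exactly), $\mathrm{ncp} = \delta / (\sqrt2 \sigma_e / \sqrt n)$;
* without array effect: a pooled two-sample t-test on the $2n$ channels,
  $df = 2n - 2$, per-channel sd $\sqrt{\sigma_a^2 + \sigma_e^2}$,
  $\mathrm{ncp} = \delta / (\sqrt{\sigma_a^2+\sigma_e^2}\,\sqrt{2/n})$.

Array effects are treated as fixed, as the ratio model implies: pairing
removes them exactly, the two-sample analysis absorbs them into the
residual.  Defaults are a two-sided test at $\alpha = 0.05$, both
exposed as arguments.  At $\delta = 0$ both functions return exactly
$\alpha$.  When estimating $(\sigma_e, \sigma_a)$ from data,
$\sigma_e^2$ is the ratio-model residual variance and $\sigma_a^2$ the
difference of the intensity- and ratio-model residual variances, floored
at zero.  The Monte-Carlo validation in the test suite simulates each
analysis under its own sampling assumptions (shared array effects for
the paired test, independent per-channel variance for the two-sample
test) and checks the analytic values within three Monte-Carlo standard
errors at 20,000 replicates.

One nuance: the paired curve is the steeper one from the very first
sample sizes whenever $\sigma_a \gtrsim \sigma_e$, but for small
positive $\sigma_a$ (around half of $\sigma_e$) the two-sample curve
can rise faster initially; the claim "the paired curve is steeper" is
therefore asserted for $\sigma_a \ge \sigma_e$.

```{r power}
powerCurves(0.35, sigmaE = 0.2, sigmaA = 0.1, nGrid = c(2, 5, 10, 20))
```

## The simulator

`simulateDataset()` generates log2 intensities as baseline + treatment
effect + unit effect + spot-level array effect + optional Cy5 shift +
noise, together with the full ground truth, on three topologies:
`two-group-paired` (both groups on every array, dye-swapped),
`factorial-replicated` (every unit receives every treatment; within each
replicate set a unit's treatments are chained around a dye-balanced loop
of arrays, the layout of one multi-array slide) and `interwoven-loop`
(groups chained $g \to g+1$ around one loop over distinct subjects, each
subject hybridized once per dye).  Array effects are simulated per
(probe, array) — spot-level, matching the genewise $\alpha$ the ratio
model estimates — not as an array-wide shift.

Default calibration, chosen once as representative of a modern
high-quality platform and used throughout the tests: baseline
$N(10, 1)$ log2 units, $\sigma_{noise} = 0.2$, $\sigma_{array} = 0.1$
(present but small relative to treatment effects), dye effect 0, 30%
differentially expressed probes with effects $N(0, 0.4)$.  Biological
subject-level variation is 0 in cell-line-like scenarios and 0.6 in the
brain-like scenario, where it deliberately dwarfs the typical effect
size.  One root seed expands into fixed per-component substreams drawn
probe-major, so identical seeds are bit-reproducible and enlarging the
probe count appends draws without perturbing existing ones.

What the simulator does *not* emulate: intensity-dependent
(variance-mean) noise, heavy tails, spatial artifacts, probe-sequence
effects, or spot-quality dropouts.  Passing tests therefore demonstrate
correctness of the statistical machinery under the stated Gaussian
variance-component model, not robustness to every failure mode of real
arrays.

## Study conditions exercised by the tests and the acceptance script

Problem sizes were chosen so each scenario is informative yet quick:
least-squares oracle checks on ~200 random probes over paired,
factorial and loop designs; null calibration on 2,000 probes (8 paired
arrays, $\sigma_a = 0$ so that *both* models are correctly specified
under the null — with $\sigma_a > 0$ the intensity model's p-values are
rightly non-uniform); the power grid $\delta \in \{0.25, 0.5\}$,
$n \in \{4, 8, 16\}$, $\sigma_a \in \{0, \sigma_e\}$ at 20,000
Monte-Carlo replicates; BIC selection on 2,000 probes with 16 paired
arrays over $\sigma_a \in \{0, 1.5, 3\} \times \sigma_e$ (at 16 arrays
the zero-variance selection fraction is analytically ≈0.995, and the
closed-form F-distribution argument reproduces the simulated fractions);
and split-half reproducibility on 4,000 probes for a 7×7 interwoven
loop ($\sigma_{unit} = 0.6$) and a replicated 4-treatment × 2-unit
factorial ($\sigma_{unit} = 0$).  The acceptance script recomputes all
of these from scratch under a caller-supplied seed.

## Known limitations

* Mixed-effects (random array) modeling and limma-style empirical-Bayes
  variance moderation are out of scope; each probe is fitted
  independently.
* No multiple-testing correction is applied anywhere — rankings and
  their reproducibility are the object of study, and FDR-type
  adjustments would distort the model comparison.
* Power analysis covers two-group contrasts with one numerator degree
  of freedom only.
* Optimal-design search for loop layouts is not provided; the simulator
  generates standard topologies and external designs are consumed
  as-is.
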