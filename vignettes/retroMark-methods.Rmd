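---
title: "retroMark: scoring chromatin markers of retroviral integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retroMark: scoring chromatin markers of retroviral integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroMark)
```

## The problem

Retroviruses integrate a cDNA copy of their genome into host chromosomes, and
integration site selection is far from uniform: gammaretroviruses such as MLV
land within 2 kb of promoter-associated chromatin features (H3K4me1/me3,
H3K9ac, STAT1 binding) far more often than chance predicts. Quantifying that
preference is statistically awkward for two reasons. First, the provirus
datasets are cloned with restriction enzymes, which biases where a provirus
*can* be observed; a fair null model must reproduce that bias. Second, the
datasets are highly skewed -- hundreds of proviruses against a genome of
3x10^9 positions -- so p-values explode with sample size and ROC areas are
blind to false-positive inflation. retroMark implements a precision-weighted
association score built for exactly this regime, together with the machinery
around it: matched control generation, a metric-comparison bench, a composite
"supermarker" density that predicts integration probability at base-pair
resolution, and the circular "mandala" visualization.

## Matched controls

Each provirus dataset is matched by in-silico controls that reproduce the
cloning bias: for every experimental site we record its distance to the
nearest recognition site of the cloning enzyme, then place `rho` controls
(default 10 per site) at that same distance from recognition sites drawn
uniformly at random across the genome, the side chosen by a fair coin. The
distance spectrum of the controls is therefore exactly `rho` copies of the
experimental spectrum -- the bias is preserved by construction, not estimated.

Two choices here were genuinely open and are package decisions:

* the matched recognition site is drawn **genome-wide** by default
  (`perChromosome = FALSE`), because the bias being modeled is a property of
  the enzyme, not of chromosome identity; a per-chromosome flag exists.
* a control that would fall outside its chromosome is **resampled** with a
  fresh recognition site (up to 1000 tries) rather than clipped, so the
  matched distance is preserved exactly.

All randomness flows from one explicit seed; regenerating with the same seed
reproduces the control set byte for byte.

## The association score

For a window `w` (default 2000 bp) around the nearest marker peak, the 2x2
table counts experimental sites within (`tp`) and beyond (`fn`) the window,
and control sites within (`fp`) and beyond (`tn`). "Within" is inclusive
(`distance <= w`). Distances are measured to peak **summits** by default; a
`boundary` mode (0 inside the interval, else distance to the nearest edge) is
provided because published peak files do not always carry summits, and the
two modes bracket the plausible conventions. Sites on chromosomes without any
peak count as beyond every window.

The false-positive count is normalized by the control:experimental ratio,

    fp' = fp * V / C,

so precision `P = tp / (tp + fp')` is independent of how many controls were
generated. Recall is `R = tp / V`, and the score is the standard
beta-weighted harmonic mean

    F_beta = (1 + beta^2) * P * R / (beta^2 * P + R),

with `beta = 0.5` to weight precision over recall. A degenerate marker
covering the whole genome has `tp = V` and `fp = C`, hence `P = 0.5`,
`R = 1` exactly. Note that the standard formula then gives
`F_0.5 = 5/9 ~ 0.556`, slightly above the nominal 0.5 baseline; we keep the
standard van Rijsbergen form and simply document the null baseline as ~0.56.
The (0.5, 1] band is still used for the "associated" flag.

Significance is a two-sided Fisher exact test under the point-probability
criterion, computed in log space (`dhyper(log = TRUE)` + log-sum-exp) so that
values like 1e-350 remain representable; the chi-squared approximation
(no continuity correction, also in log space) is substituted automatically
when every expected count is at least 5 and `V + C > 10000`. Bonferroni
correction multiplies by the number of markers in the batch. p-values below
1e-350 print as `<1E-350`.

The properties that make `F_0.5` preferable to the p-value are checked on
synthetic data in the test suite: downsampling the site set 10-fold moves F
by less than 0.05 while the p-value exponent collapses more than 5-fold, and
varying the control ratio from 1 to 10 leaves F essentially unchanged.

## The metric bench

`rankBench()` scores every marker under AUC(ROC) (rank formulation, ties at
1/2), AUPR (precision-recall area using the same normalized `fp'`, trapezoid
over recall), `F_0.5`, `F_1`, `F_2`, odds ratio (Haldane-Anscombe corrected
when a cell is zero), Shannon mutual information (base 2) and difference of
proportions. Markers are then ranked pairwise: `M_X[i, j] = 1` iff marker i
strictly outranks j under metric X, ties leaving both entries 0, and each
matrix is compared to the ranking by significance (`-log10 p`, capped at 350
to mirror the reporting floor) through

    D = 1 - sum |M_X - S| / (N * (N - 1)),

which is 1 exactly when the two rankings agree on every ordered pair. The
published formula for D is reconstructed from its stated properties (range,
D = 1 at perfect agreement); the reconstruction satisfies both. Raw rather
than adjusted p is used for S -- the Bonferroni factor is a monotone
transformation that cannot change the ranking below the cap.

On benches where marker frequency is inversely related to strength (common
markers noisy, rare markers clean), AUC systematically promotes the common
marker while `F_0.5` and significance agree -- the acceptance suite
constructs such a bench and asserts the discordance.

## The supermarker

The integration-probability density combines the peak sets of several
markers. Each marker contributes a kernel density: the mean of Gaussians
centered on its peak summits, with scale sigma set by policy. The default
policy (`width`) uses the **mean peak width in bp as sigma**; the phrase "the
variance is the average peak size" is dimensionally ambiguous (bp vs bp^2),
and sigma = mean width puts the kernel support on the 10^2-10^3 bp scale of
real ChIP-Seq peaks, consistent with the 2 kb window optimum. `sqrt-width`
and `fixed:N` policies are available.

Components are mixed with weights derived from their F scores. The exact
first-order coefficients of the published derivation are not recoverable
from the source, so the default weight is the **odds of the F score**,

    lambda_j = F_j / (1 - F_j),

normalized to sum to 1: monotone in F, vanishing as F -> 0, diverging as
F -> 1, which matches the stated first-order intent. `linear` and `logodds`
weight functions are pluggable alternatives. Since each component integrates
to 1 and the weights are convex, the mixture integrates to 1 up to Gaussian
mass lost beyond chromosome ends (checked to 1e-6 in tests).

The mixture is then reduced to the supermarker peak set Gamma*:

1. the density is evaluated on a 10 bp grid restricted to the union of
   component peak neighborhoods (+/- 4 sigma); 10 bp is far below any
   realistic sigma while keeping the grid tractable, and the grid step is
   validated against `min(sigma) / 4`;
2. local maxima are collected; maxima closer than the smallest component
   sigma are merged keeping the larger (the merge radius is a
   reconstruction -- the source does not state one);
3. maxima are ranked by amplitude, and the F score of the top-k set is
   evaluated for every k; the smallest k attaining the maximum F becomes
   k*, favoring precision on ties. After cumulative-count vectorization the
   full F(k) curve costs O(m), so every k is evaluated outright; an explicit
   `kGrid` argument remains for restricted searches.

`fitSupermarker()` runs this for **every non-empty subset** of up to 8
candidate markers and keeps the subset with the best training F (ties break
toward fewer markers). This reproduces the redundancy phenomenon observed
with strong-but-redundant markers: a marker whose peaks duplicate another's
at an offset adds false positives that survive thresholding and lower the
composite F, so the search drops it.

For downstream probability queries the reduced set carries a single model
sigma, the lambda-weighted mean of the component sigmas (a reconstruction;
the published final-density form is not legible in the source), and
amplitudes act as mixture weights. The normalization constant is the total
truncated-Gaussian mass over the genome, so `locusProbability()` -- a sum of
Gaussian CDF differences per peak, no quadrature -- integrates to exactly 1
over the whole genome. `densityCorrelation()` aggregates model mass and site
counts in non-overlapping windows (default 10 kb) and reports their Pearson
correlation.

Validation follows two routes: `crossvalidateSupermarker()` is a
seed-deterministic k-fold scheme (default 10) in which controls travel with
their source provirus via the provenance table, so folds stay independent
and nothing is regenerated; and `evaluateSupermarker()` freezes a model and
scores any external site/control pair (the cross-dataset route).

## The mandala

Sites are drawn on a circle: the angle is the genomic position along the
circularized chromosome (or all chromosomes concatenated in layout order, no
gaps), and the radius maps distance d to the nearest marker through

    r = 1 - log10(max(d, 1)) / 6,

clipped to [0, 1]: the contour is 1 bp, the center is 1 Mb and beyond.
Distances below 1 bp clamp to 1 before the log. Points within the window
draw blue, beyond red; the window circle is dashed; optional gray shading
(linear in summed amplitude per angular bin, normalized to max 1 -- the
published transfer function is not described) fills the annulus between the
window circle and the contour.

## The synthetic generator

The generator defines the study conditions for every test: a 2 x 5 Mb toy
genome; restriction sites as a Poisson process at 1/256 per bp (a 4-cutter's
expected density); markers of 1000 peaks with log-normal widths around 400
bp; V = 500 proviruses with a planted fraction q = 0.7 placed at a random
target summit plus a Normal(0, s^2) offset at s = 500 bp, the rest uniform;
controls at ratio 10. The Normal offset law is a package choice -- the
displacement of proviruses around marks follows no published law -- made
because it gives closed-form expectations (the within-window rate of a
planted site is `2 * Phi(w / s) - 1`), so recovery tests can be exact.
Ground-truth labels ride along in the metadata for those assertions. The
uniform-in-gene scenario places genes of fixed length (default 20 kb),
integrations uniform within gene bodies, and a virtual one-summit-per-TSS
marker; its F(w) curve rises to a maximum at the gene length and then
plateaus.

What the generator does **not** emulate: co-occurrence structure between
chromatin marks, sequence composition effects, chromosome-scale
heterogeneity (isochores, centromeres), or read-level ChIP-Seq noise.
Passing tests therefore demonstrate correctness of the statistics and
recovery of planted structure, not biological performance on real genomes.

## Numerical choices and problem sizes

* Coordinates are 1-based closed internally (the GRanges convention); BED's
  0-based half-open is converted at the I/O boundary only.
* The Fisher two-sided criterion uses the point-probability rule with the
  customary 1e-7 relative tie tolerance.
* Degenerate Fisher margins give p = 1, flagged. Zero-precision tables give
  F = 0 rather than NaN.
* Kernel evaluation truncates Gaussian tails at 6-8 sigma (relative error
  below 1e-14 per peak).
* Test problem sizes -- 5-10 Mb genomes, 100-500 sites, 200-1000 peaks, 5-10
  fold cross-validation -- were chosen so each statistic sits safely above
  its noise floor (3-sigma binomial bounds at n = 300-500) while the whole
  suite stays in the minutes range.

## Limitations

* The exhaustive subset search is exponential and capped at 8 candidates;
  pre-filter by single-marker F beyond that.
* The per-component sigma collapses to one model sigma in the reduced peak
  set; regions dominated by a marker with an unusual peak-width distribution
  inherit the pooled scale.
* The mandala is a static plot; no interactive viewer is provided.
* Restriction-site matching models cloning bias only -- no partial
  digestion, fragment-size selection, or PCR efficiency.
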