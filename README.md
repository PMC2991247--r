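# retroMark

Quantifying the association between retroviral integration sites and
chromatin features on highly skewed genomic datasets.

Retroviruses (MLV, XMRV, PERV, HIV-1, ...) integrate a cDNA copy of their
genome into host chromosomes, and each viral genus favors particular
chromatin contexts: gammaretroviruses land within 2 kb of promoter marks
such as H3K4me3 and H3K9ac far more often than chance predicts. Measuring
"more often than chance" is delicate here: provirus datasets are cloned with
restriction enzymes (a positional bias the null model must reproduce), and
the data are extremely imbalanced (hundreds of proviruses vs. billions of
genomic positions), which makes raw Fisher p-values scale with sample size
and makes ROC areas insensitive to false positives.

retroMark is a toolkit for researchers in retroviral integration and gene
therapy safety who need to rank chromatin markers, combine them into a
predictive model, and query integration probability at specific loci (e.g.
proto-oncogenes). It provides:

* **Matched controls** — in-silico control sites placed at the same distance
  from a random restriction-enzyme recognition site as each provirus is from
  its nearest one, reproducing the cloning bias exactly
  (`generateMatchedControls()`).
* **The normalized F-score** — with the false-positive count normalized by
  the control:experimental ratio, `fp' = fp·V/C`, precision
  `P = tp/(tp + fp')`, recall `R = tp/V`, and

      F_β = (1 + β²)·P·R / (β²·P + R),   β = 0.5

  weighting precision over recall. An all-genome null predictor gives
  P = 0.5 and R = 1 exactly; markers with F in (0.5, 1] are called
  associated. Fisher exact significance is computed in log space so values
  like 10⁻³⁵⁰ survive (`associate()`, `windowSweep()`).
* **A metric bench** — AUC, AUPR, F₀.₅/F₁/F₂, odds ratio, Shannon mutual
  information, difference of proportions, each compared with the ranking by
  significance through the pairwise similarity `D = 1 − Σ|M_X − S|/(N(N−1))`
  (`rankBench()`).
* **The supermarker** — a Gaussian-mixture density over several markers'
  peak summits, weighted by F-score odds `λ_j = F_j/(1−F_j)`, reduced by
  amplitude thresholding to the peak set Γ* that maximizes training F, with
  exhaustive marker-subset search, 10-fold cross-validation, closed-form
  locus probabilities and genome-wide density/site correlation
  (`fitSupermarker()`, `crossvalidateSupermarker()`, `locusProbability()`,
  `densityCorrelation()`).
* **Chromosome projection mandalas** — circular plots with angle = genomic
  position and radius = log-scaled distance (1 bp at the contour, 1 Mb at
  the center) to the nearest marker (`polarCoords()`, `renderMandala()`).
* **A synthetic-data generator** — toy genomes, Poisson restriction sites,
  ChIP-Seq-like peak sets and provirus sets with planted association
  strength and ground-truth labels, so the entire pipeline is testable
  without downloads (`simConfig()`, `simulateGenome()`, ...).

Inputs are standard formats: BED (sites, peaks), UCSC chrom.sizes, FASTA
(restriction-motif scanning via Biostrings), TSV reports, JSON model files.

## Worked example

```r
library(retroMark)

## a 2 x 5 Mb toy genome with restriction sites, a marker of 1000 peaks,
## and 500 proviruses of which 70% are planted near peak summits (s = 500 bp)
cfg     <- simConfig(seed = 7)
gen     <- simulateGenome(cfg)
marker  <- simulatePeakSet(gen$layout, nPeaks = 1000, meanWidth = 400,
                           seed = 8, label = "H3K4me3-like")
sites   <- simulateIntegrations(gen$layout, marker, V = 500, q = 0.7,
                                s = 500, seed = 9)
controls <- generateMatchedControls(sites, gen$resites, ratio = 10, seed = 10)

associate(sites, controls, marker, window = 2000, beta = 0.5)
#> AssociationResult 'H3K4me3-like' (w = 2000 bp)
#>   wi%: 79.6%  P: 0.707  R: 0.796  F_0.5: 0.723
#>   p (raw): 8E-92  p (adj, n=1): 8E-92  associated, significant
```

79.6% of proviruses lie within 2 kb of the marker; after normalizing the
control counts the precision is 0.71, and F₀.₅ = 0.72 places the marker
well inside the associated band (0.5, 1] at overwhelming significance.
Sweeping the window shows the F-score maximum near the planted offset scale
while recall keeps rising — the false-positive adjustment at work:

```r
windowSweep(sites, controls, marker, c(500, 1000, 2000, 5000, 10000))
#>   window wi_pct     P     R     F  p_raw
#> 1    500   54.6 0.844 0.546 0.761 1E-115
#> 2   1000   72.8 0.792 0.728 0.778 1E-131
#> 3   2000   79.6 0.707 0.796 0.723  8E-92
#> 4   5000   89.4 0.591 0.894 0.634  4E-40
#> 5  10000   96.4 0.529 0.964 0.582  3E-14

model <- fitSupermarker(list(mark = marker), sites, controls)
model
#> SupermarkerModel: mark
#>   Gamma*: 924 peak(s) (k*), sigma = 405.2 bp, training F_0.5 = 0.724 (w = 2000 bp)

locusProbability(model, "chrS1", 1e6, 1.05e6)
#> [1] 0.006742  # probability one integration falls in this 50 kb window
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/retromark`
(installed under `system.file("cli", "retromark", package = "retroMark")`):

```sh
retromark simulate --out-dir fixtures --seed 7
retromark make-controls --genome fixtures/genome.chrom.sizes \
    --sites fixtures/sites.bed --resites fixtures/resites.bed \
    --ratio 10 --seed 17 --out controls.bed
retromark associate --genome fixtures/genome.chrom.sizes \
    --sites fixtures/sites.bed --controls controls.bed \
    --marker fixtures/markers/simMarker.bed --window 2000 --out result.tsv
```

Every run writes a JSON manifest (options, input checksums, seed, version)
beside its outputs; exit codes are 0/1/2 for success/data error/usage error.

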