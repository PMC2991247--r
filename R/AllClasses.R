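#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats dnorm pnorm dhyper pchisq cor rlnorm rnorm rpois runif
#' @importFrom utils head tail read.table write.table combn
NULL

#' ChromLayout: ordered chromosome coordinate system
#'
#' Holds the ordered chromosome names and lengths of a genome assembly,
#' together with the cumulative offsets used to concatenate chromosomes into a
#' single linear (or circular, for the mandala) coordinate axis.
#'
#' @slot chroms character vector of chromosome names, in file order.
#' @slot lengths numeric vector of chromosome lengths in bp.
#' @export
setClass("ChromLayout",
  representation(chroms = "character", lengths = "numeric"))

setValidity("ChromLayout", function(object) {
  if (length(object@chroms) != length(object@lengths))
    return("chroms and lengths differ in length")
  if (!length(object@chroms))
    return("layout must contain at least one chromosome")
  if (anyDuplicated(object@chroms))
    return(sprintf("duplicate chromosome name: %s",
                   object@chroms[duplicated(object@chroms)][1L]))
  if (any(!is.finite(object@lengths)) || any(object@lengths <= 0))
    return("all chromosome lengths must be positive")
  TRUE
})

#' SiteSet: point genomic positions
#'
#' Width-1 genomic positions (proviral integration sites, in-silico control
#' sites, restriction-enzyme recognition sites). Extends [GenomicRanges::GRanges];
#' the layout travels as the `seqinfo`.
#'
#' @slot label character label of the set.
#' @export
setClass("SiteSet", contains = "GRanges",
  representation(label = "character"))

setValidity("SiteSet", function(object) {
  if (length(object@label) != 1L) return("label must be a single string")
  if (length(object) && any(GenomicRanges::width(object) != 1L))
    return("all sites must have width 1")
  TRUE
})

#' PeakSet: scored genomic intervals with summits
#'
#' ChIP-Seq-like peaks: intervals with an amplitude score and a summit
#' position. Extends [GenomicRanges::GRanges] with metadata columns `summit`
#' (1-based coordinate inside the interval) and `score` (>= 0).
#'
#' @slot label character marker label.
#' @export
setClass("PeakSet", contains = "GRanges",
  representation(label = "character"))

setValidity("PeakSet", function(object) {
  if (length(object@label) != 1L) return("label must be a single string")
  mc <- GenomicRanges::mcols(object)
  if (!all(c("summit", "score") %in% colnames(mc)))
    return("PeakSet requires metadata columns 'summit' and 'score'")
  if (length(object)) {
    s <- mc$summit
    if (any(s < GenomicRanges::start(object) | s > GenomicRanges::end(object)))
      return("summit must lie within its peak interval")
    if (any(mc$score < 0)) return("amplitudes must be >= 0")
  }
  TRUE
})

#' ControlSet: matched in-silico control sites
#'
#' A [SiteSet] of control positions plus per-control provenance (index of the
#' source provirus, the chosen restriction site, and the signed offset), the
#' control:experimental ratio, and the seed used for generation.
#'
#' @slot provenance data.frame with columns `source`, `resiteChrom`,
#'   `resitePos`, `offset`.
#' @slot ratio numeric, number of controls per experimental site.
#' @slot seed numeric seed used for generation (NA if none given).
#' @export
setClass("ControlSet", contains = "SiteSet",
  representation(provenance = "data.frame", ratio = "numeric",
                 seed = "numeric"))

setValidity("ControlSet", function(object) {
  if (nrow(object@provenance) != length(object))
    return("provenance must have one row per control site")
  need <- c("source", "resiteChrom", "resitePos", "offset")
  if (!all(need %in% colnames(object@provenance)))
    return("provenance must have columns source, resiteChrom, resitePos, offset")
  TRUE
})

#' ContingencyTable: within-window association counts
#'
#' The 2x2 table underlying the association statistic: experimental sites
#' within (`tp`) / beyond (`fn`) the window of the nearest marker, and control
#' sites within (`fp`) / beyond (`tn`).
#'
#' @slot tp,fn,fp,tn numeric counts.
#' @slot window numeric window half-width in bp.
#' @export
setClass("ContingencyTable",
  representation(tp = "numeric", fn = "numeric", fp = "numeric",
                 tn = "numeric", window = "numeric"))

setValidity("ContingencyTable", function(object) {
  v <- c(object@tp, object@fn, object@fp, object@tn)
  if (any(v < 0)) return("all counts must be >= 0")
  if (length(object@window) != 1L || object@window < 0)
    return("window must be a single non-negative number")
  TRUE
})

#' AssociationResult: full association report for one marker
#'
#' @slot marker character marker label.
#' @slot window numeric window in bp.
#' @slot beta numeric F-score beta.
#' @slot wi numeric fraction of experimental sites within the window.
#' @slot precision,recall,fscore numeric, from the normalized definition.
#' @slot log10p,log10pAdj numeric raw and Bonferroni-adjusted p on log10 scale.
#' @slot nTests numeric number of tests in the Bonferroni correction.
#' @slot associated logical, F in (0.5, 1].
#' @slot significant logical, adjusted p < 0.01.
#' @slot pvalueMethod character, "exact" or "chi2".
#' @slot degenerate logical, p fixed to 1 by the zero-margin convention.
#' @slot table the underlying [ContingencyTable].
#' @export
setClass("AssociationResult",
  representation(marker = "character", window = "numeric", beta = "numeric",
                 wi = "numeric", precision = "numeric", recall = "numeric",
                 fscore = "numeric", log10p = "numeric", log10pAdj = "numeric",
                 nTests = "numeric", associated = "logical",
                 significant = "logical", pvalueMethod = "character",
                 degenerate = "logical", table = "ContingencyTable"))

#' CompositeDensity: weighted Gaussian mixture over marker peak sets
#'
#' The integration-probability density before thresholding: a convex
#' combination of per-marker kernel densities, each a mean of Gaussians
#' centered on peak summits with marker-specific scale sigma.
#'
#' @slot components list; each element has `label`, `pos` (list of numeric
#'   summit vectors per chromosome), `sigma`, `fscore`, `lambda`, `n`.
#' @slot layout the [ChromLayout].
#' @slot weightFn character, weighting rule used for lambda.
#' @export
setClass("CompositeDensity",
  representation(components = "list", layout = "ChromLayout",
                 weightFn = "character"))

setValidity("CompositeDensity", function(object) {
  if (!length(object@components)) return("at least one component required")
  lam <- vapply(object@components, `[[`, numeric(1), "lambda")
  if (any(lam < 0)) return("component weights must be >= 0")
  if (abs(sum(lam) - 1) > 1e-8) return("component weights must sum to 1")
  TRUE
})

#' SupermarkerModel: thresholded composite density
#'
#' The fitted supermarker: the reduced peak set Gamma* (positions +
#' amplitudes) extracted from the composite density, the selected peak count
#' k*, the training F score, and everything needed to reproduce the fit.
#'
#' @slot peaks GRanges of Gamma* summit points with mcol `amplitude`.
#' @slot sigma numeric model kernel scale in bp.
#' @slot normConst numeric normalization constant K (truncated Gaussian mass).
#' @slot kStar numeric number of peaks retained.
#' @slot trainF numeric training F score of Gamma*.
#' @slot markers character labels of the chosen marker subset.
#' @slot weights named numeric normalized mixture weights lambda_j.
#' @slot window,beta numeric fitting parameters.
#' @slot layout the [ChromLayout].
#' @slot meta list of provenance (seed, weightFn, sigmaPolicy, gridStep, ...).
#' @export
setClass("SupermarkerModel",
  representation(peaks = "GRanges", sigma = "numeric", normConst = "numeric",
                 kStar = "numeric", trainF = "numeric", markers = "character",
                 weights = "numeric", window = "numeric", beta = "numeric",
                 layout = "ChromLayout", meta = "list"))

setValidity("SupermarkerModel", function(object) {
  if (length(object@peaks) != object@kStar)
    return("kStar must equal the number of retained peaks")
  if (object@sigma <= 0) return("sigma must be > 0")
  if (!"amplitude" %in% colnames(GenomicRanges::mcols(object@peaks)))
    return("peaks require an 'amplitude' metadata column")
  TRUE
})

#' CVReport: cross-validation report for the supermarker
#'
#' @slot folds numeric fold count.
#' @slot perFold data.frame with one row per fold (kStar, trainF, testF,
#'   testWi, testLog10p, nTest).
#' @slot seed numeric seed of the fold partition.
#' @export
setClass("CVReport",
  representation(folds = "numeric", perFold = "data.frame", seed = "numeric"))
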