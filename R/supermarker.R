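## Supermarker: a Gaussian-mixture integration-probability density over the
## peak sets of several markers, weighted by their F scores, thresholded by
## amplitude into a reduced peak set Gamma* that maximizes the training F.

weightFromF <- function(f, weightFn) {
  switch(weightFn,
    odds = {
      if (any(f <= 0 | f >= 1))
        inputError("odds weighting requires 0 < F < 1; exclude such markers")
      f / (1 - f)
    },
    linear = {
      if (any(f <= 0)) inputError("linear weighting requires F > 0")
      f
    },
    logodds = {
      w <- log(f / (1 - f))
      if (any(!is.finite(w) | w <= 0))
        inputError("log-odds weighting requires F > 0.5; exclude such markers")
      w
    },
    inputError(sprintf("unknown weight function '%s'", weightFn)))
}

sigmaFromPolicy <- function(peaks, sigmaPolicy) {
  if (grepl("^fixed:", sigmaPolicy)) {
    s <- as.numeric(sub("^fixed:", "", sigmaPolicy))
    if (!is.finite(s) || s <= 0) inputError("fixed sigma must be > 0")
    return(s)
  }
  switch(sigmaPolicy,
    width = meanPeakWidth(peaks),
    `sqrt-width` = sqrt(meanPeakWidth(peaks)),
    inputError(sprintf("unknown sigma policy '%s'", sigmaPolicy)))
}

## One mixture component: per-chromosome sorted summit positions.
makeComponent <- function(peaks, fscore, sigma, lambda = NA_real_) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  pos <- peakSummits(peaks)
  list(label = peaks@label,
       pos = lapply(split(pos, chrom), sort),
       sigma = sigma, fscore = fscore, lambda = lambda, n = length(peaks))
}

#' Kernel density of a single marker
#'
#' The marker's probability mass over the genome, modeled as the mean of
#' Gaussian kernels centered on its peak summits with scale `sigma` (default:
#' the mean peak width, so the kernel variance is the squared average peak
#' size). The result is a [CompositeDensity-class] with a single component.
#'
#' @param peaks a non-empty [PeakSet-class].
#' @param sigma kernel scale in bp; default from `sigmaPolicy`.
#' @param sigmaPolicy "width", "sqrt-width" or "fixed:N".
#' @return a [CompositeDensity-class].
#' @export
markerDensity <- function(peaks, sigma = NULL, sigmaPolicy = "width") {
  if (!length(peaks)) inputError("empty peak set")
  sigma <- sigma %||% sigmaFromPolicy(peaks, sigmaPolicy)
  stopifnotScalarNum(sigma, "sigma", positive = TRUE)
  new("CompositeDensity",
      components = list(makeComponent(peaks, NA_real_, sigma, lambda = 1)),
      layout = layoutFromSeqinfo(peaks), weightFn = "single")
}

#' Composite integration-probability density over several markers
#'
#' Linear combination of per-marker kernel densities with mixture weights
#' derived from each marker's F score; the default weight is the odds
#' `lambda_j = F_j / (1 - F_j)`, normalized to sum to 1 (the normalization
#' constant K). Because each component integrates to 1, so does the mixture
#' (up to Gaussian mass beyond chromosome ends).
#'
#' @param markers named list of [PeakSet-class] objects.
#' @param fscores numeric vector of per-marker F scores on the training data,
#'   same length/order as `markers`; each must lie in (0, 1) for odds
#'   weighting.
#' @param weightFn "odds" (default), "linear" or "logodds".
#' @param sigmaPolicy see [markerDensity()].
#' @return a [CompositeDensity-class].
#' @export
compositeDensity <- function(markers, fscores, weightFn = "odds",
                             sigmaPolicy = "width") {
  if (!length(markers)) inputError("at least one marker required")
  if (length(fscores) != length(markers))
    inputError("one F score per marker required")
  lam <- weightFromF(fscores, weightFn)
  lam <- lam / sum(lam)
  comps <- lapply(seq_along(markers), function(j)
    makeComponent(markers[[j]], fscores[j],
                  sigmaFromPolicy(markers[[j]], sigmaPolicy), lam[j]))
  layouts <- lapply(markers, layoutFromSeqinfo)
  for (l in layouts[-1])
    if (!sameLayout(layouts[[1]], l))
      inputError("markers have mismatched layouts")
  new("CompositeDensity", components = comps, layout = layouts[[1]],
      weightFn = weightFn)
}

#' Evaluate a composite density at genomic positions
#'
#' @param cd a [CompositeDensity-class].
#' @param chrom single chromosome name.
#' @param pos numeric positions on that chromosome.
#' @return numeric density values (per-bp probability mass).
#' @export
densityAt <- function(cd, chrom, pos) {
  out <- numeric(length(pos))
  for (comp in cd@components) {
    s <- comp$pos[[chrom]]
    if (is.null(s) || !length(s)) next
    w <- comp$lambda / comp$n
    cut <- 8 * comp$sigma
    lo <- findInterval(pos - cut, s) + 1L
    hi <- findInterval(pos + cut, s)
    for (i in seq_along(pos)) {
      if (hi[i] >= lo[i])
        out[i] <- out[i] + w * sum(dnorm(s[lo[i]:hi[i]], pos[i], comp$sigma))
    }
  }
  out
}

#' Extract and rank the peaks of a composite density
#'
#' Local maxima of the density on a regular grid restricted to the union of
#' component peak neighborhoods (+/- 4 sigma); maxima closer than the
#' smallest component sigma are merged keeping the larger; the result is
#' sorted by amplitude, descending.
#'
#' @param cd a [CompositeDensity-class].
#' @param gridStep grid step in bp; must be <= min(sigma) / 4 (default 10).
#' @return GRanges of summit points with mcols `amplitude` and `rank`.
#' @export
extractPeaks <- function(cd, gridStep = 10) {
  sigmas <- vapply(cd@components, `[[`, numeric(1), "sigma")
  if (gridStep > min(sigmas) / 4)
    inputError(sprintf("gridStep must be <= min(sigma)/4 = %.1f",
                       min(sigmas) / 4))
  lens <- chromLengths(cd@layout)
  posAll <- numeric(0); ampAll <- numeric(0); chromAll <- character(0)
  for (ch in chromNames(cd@layout)) {
    ir <- NULL
    for (comp in cd@components) {
      s <- comp$pos[[ch]]
      if (is.null(s) || !length(s)) next
      r <- IRanges::IRanges(start = pmax(1, s - 4 * comp$sigma),
                            end = pmin(lens[[ch]], s + 4 * comp$sigma))
      ir <- if (is.null(ir)) r else c(ir, r)
    }
    if (is.null(ir) || !length(ir)) next
    ir <- IRanges::reduce(ir)
    grids <- lapply(seq_along(ir), function(i)
      seq(IRanges::start(ir)[i], IRanges::end(ir)[i], by = gridStep))
    G <- unlist(grids)
    intervalId <- rep(seq_along(ir), lengths(grids))
    v <- numeric(length(G))
    for (comp in cd@components) {
      s <- comp$pos[[ch]]
      if (is.null(s) || !length(s)) next
      w <- comp$lambda / comp$n
      cut <- 6 * comp$sigma
      lo <- findInterval(s - cut, G) + 1L
      hi <- findInterval(s + cut, G)
      for (j in seq_along(s)) {
        if (hi[j] >= lo[j]) {
          idx <- lo[j]:hi[j]
          v[idx] <- v[idx] + w * dnorm(G[idx], s[j], comp$sigma)
        }
      }
    }
    n <- length(v)
    left <- c(-Inf, v[-n]); right <- c(v[-1], -Inf)
    sameLeft <- c(FALSE, intervalId[-n] == intervalId[-1])
    sameRight <- c(intervalId[-n] == intervalId[-1], FALSE)
    left[!sameLeft] <- -Inf; right[!sameRight] <- -Inf
    isMax <- v > left & v >= right
    pk <- G[isMax]; amp <- v[isMax]
    ## merge maxima closer than the smallest sigma, keeping the larger
    if (length(pk) > 1) {
      minSig <- min(sigmas)
      cl <- cumsum(c(TRUE, diff(pk) >= minSig))
      keep <- vapply(split(seq_along(pk), cl),
                     function(ii) ii[which.max(amp[ii])], integer(1))
      pk <- pk[keep]; amp <- amp[keep]
    }
    posAll <- c(posAll, pk); ampAll <- c(ampAll, amp)
    chromAll <- c(chromAll, rep(ch, length(pk)))
  }
  if (!length(posAll)) inputError("density has empty support")
  o <- order(ampAll, decreasing = TRUE)
  GenomicRanges::GRanges(
    seqnames = factor(chromAll[o], levels = chromNames(cd@layout)),
    ranges = IRanges::IRanges(start = posAll[o], width = 1L),
    amplitude = ampAll[o], rank = seq_along(o),
    seqinfo = layoutSeqinfo(cd@layout))
}

## First rank (in the amplitude ordering) at which each query site falls
## within `window` of a retained peak; Inf if never.
firstCoveringRank <- function(query, rankedPeaks, window) {
  pad <- suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
    GenomicRanges::granges(query), width = 2 * window + 1, fix = "center")))
  hit <- GenomicRanges::findOverlaps(pad, rankedPeaks)
  out <- rep(Inf, length(query))
  if (length(hit)) {
    agg <- tapply(S4Vectors::subjectHits(hit), S4Vectors::queryHits(hit), min)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Select the amplitude threshold (peak count) maximizing the training F
#'
#' Evaluates the F score of the top-k peak set over a k-grid (by default
#' every k) and returns the argmax; ties break to the smallest k, favoring
#' precision.
#'
#' @param rankedPeaks GRanges from [extractPeaks()] (amplitude-ranked).
#' @param sites,controls training [SiteSet-class]s.
#' @param window,beta association parameters.
#' @param kGrid optional integer vector of candidate k values.
#' @return list with `kStar`, `trainF`, `peaks` (the reduced set Gamma*),
#'   and `curve` (data.frame k, fscore over the evaluated grid).
#' @export
selectThreshold <- function(rankedPeaks, sites, controls, window = 2000,
                            beta = 0.5, kGrid = NULL) {
  if (!length(sites) || !length(controls))
    inputError("training sets must be non-empty")
  m <- length(rankedPeaks)
  if (!m) inputError("no peaks to threshold")
  kGrid <- sort(unique(as.integer(kGrid %||% seq_len(m))))
  if (any(kGrid < 1 | kGrid > m)) inputError("kGrid out of range")
  rs <- firstCoveringRank(sites, rankedPeaks, window)
  rc <- firstCoveringRank(controls, rankedPeaks, window)
  V <- length(sites); C <- length(controls)
  tpAt <- cumsum(tabulate(rs[is.finite(rs)], m))
  fpAt <- cumsum(tabulate(rc[is.finite(rc)], m))
  tp <- tpAt[kGrid]; fp <- fpAt[kGrid]
  fpn <- fp * V / C
  P <- ifelse(tp + fpn > 0, tp / (tp + fpn), 0)
  R <- tp / V
  Fk <- ifelse(P + R > 0, (1 + beta^2) * P * R / (beta^2 * P + R), 0)
  if (max(Fk) <= 0)
    inputError(sprintf(
      "no peak count achieves F > 0 (V=%d, C=%d, %d peaks, window=%g)",
      V, C, m, window))
  best <- which.max(Fk)   # first maximum = smallest k on the sorted grid
  list(kStar = kGrid[best], trainF = Fk[best],
       peaks = rankedPeaks[seq_len(kGrid[best])],
       curve = data.frame(k = kGrid, fscore = Fk))
}

#' Fit a supermarker by exhaustive subset search
#'
#' For every non-empty subset of the candidate markers: build the composite
#' density, extract and rank its peaks, select the amplitude threshold on the
#' training data, and record the training F. The subset with the best
#' training F (ties: fewer markers, then candidate order) becomes the
#' supermarker.
#'
#' @param markers named list of candidate [PeakSet-class] objects (1 to
#'   `maxSubset`).
#' @param sites,controls training data; `controls` should be a
#'   [ControlSet-class] if cross-validation will follow.
#' @param window,beta association parameters (defaults 2000 bp, 0.5).
#' @param weightFn,sigmaPolicy see [compositeDensity()].
#' @param gridStep peak-extraction grid in bp.
#' @param maxSubset cap on the exhaustive search (default 8).
#' @param mode distance mode for the single-marker F scores.
#' @param seed recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return a [SupermarkerModel-class].
#' @export
fitSupermarker <- function(markers, sites, controls, window = 2000,
                           beta = 0.5, weightFn = "odds",
                           sigmaPolicy = "width", gridStep = 10,
                           maxSubset = 8, mode = "summit", seed = NULL) {
  if (is.null(names(markers)) || anyDuplicated(names(markers)))
    inputError("markers must be a uniquely named list")
  if (length(markers) > maxSubset)
    inputError(sprintf(
      "%d candidates exceed maxSubset = %d; pre-filter by single-marker F",
      length(markers), maxSubset))
  fAll <- vapply(markers, function(m)
    associate(sites, controls, m, window, beta, mode)@fscore, numeric(1))
  usable <- names(markers)[fAll > 0 & fAll < 1]
  if (!length(usable))
    inputError("no candidate has F score in (0, 1)")
  best <- NULL
  nTried <- 0L
  for (size in seq_along(usable)) {
    for (subset in as.data.frame(combn(usable, size), stringsAsFactors = FALSE)) {
      subset <- as.character(subset)
      nTried <- nTried + 1L
      cd <- compositeDensity(markers[subset], fAll[subset], weightFn,
                             sigmaPolicy)
      pk <- extractPeaks(cd, gridStep)
      sel <- tryCatch(selectThreshold(pk, sites, controls, window, beta),
                      rm_input_error = function(e) NULL)
      if (is.null(sel)) next
      if (is.null(best) || sel$trainF > best$sel$trainF + 1e-12)
        best <- list(subset = subset, cd = cd, sel = sel)
    }
  }
  if (is.null(best)) inputError("no subset achieves F > 0")
  lam <- vapply(best$cd@components, `[[`, numeric(1), "lambda")
  sig <- vapply(best$cd@components, `[[`, numeric(1), "sigma")
  modelSigma <- sum(lam * sig)
  peaks <- best$sel$peaks
  model <- new("SupermarkerModel", peaks = peaks, sigma = modelSigma,
      normConst = 1, kStar = as.numeric(best$sel$kStar),
      trainF = best$sel$trainF, markers = best$subset,
      weights = stats::setNames(lam, best$subset), window = window,
      beta = beta, layout = best$cd@layout,
      meta = list(weightFn = weightFn, sigmaPolicy = sigmaPolicy,
                  gridStep = gridStep, mode = mode,
                  seed = if (is.null(seed)) NA_real_ else seed,
                  candidateF = fAll, subsetsTried = nTried))
  model@normConst <- supermarkerNorm(model)
  model
}

## Total truncated Gaussian mass of the model over its genome: the exact
## normalization constant, so locus probabilities integrate to 1.
supermarkerNorm <- function(model) {
  amp <- GenomicRanges::mcols(model@peaks)$amplitude
  w <- amp / sum(amp)
  ch <- as.character(GenomicRanges::seqnames(model@peaks))
  x <- as.numeric(GenomicRanges::start(model@peaks))
  lens <- chromLengths(model@layout)
  sum(w * (pnorm((lens[ch] - x) / model@sigma) -
           pnorm((0 - x) / model@sigma)))
}

setMethod("show", "SupermarkerModel", function(object) {
  cat(sprintf("SupermarkerModel: %s\n", paste(object@markers, collapse = " + ")))
  cat(sprintf("  Gamma*: %g peak(s) (k*), sigma = %.1f bp, training F_%g = %.3f (w = %g bp)\n",
              object@kStar, object@sigma, object@beta, object@trainF,
              object@window))
})

#' Supermarker peak set as a PeakSet of summit points
#'
#' @param model a [SupermarkerModel-class].
#' @return a [PeakSet-class] (width-1 intervals at Gamma* positions,
#'   amplitude in the score).
#' @export
supermarkerPeaks <- function(model) {
  ch <- as.character(GenomicRanges::seqnames(model@peaks))
  x <- as.numeric(GenomicRanges::start(model@peaks))
  PeakSet(ch, x, x, model@layout, summit = x,
          score = GenomicRanges::mcols(model@peaks)$amplitude,
          label = "supermarker")
}

#' Evaluate a fitted supermarker on a site/control pair
#'
#' Cross-dataset entry point: associates any experimental/control pair with
#' the frozen reduced peak set Gamma*.
#'
#' @param model a [SupermarkerModel-class].
#' @param sites,controls [SiteSet-class]s.
#' @param nTests Bonferroni denominator.
#' @return an [AssociationResult-class].
#' @export
evaluateSupermarker <- function(model, sites, controls, nTests = 1) {
  associate(sites, controls, supermarkerPeaks(model), model@window,
            model@beta, mode = "summit", nTests = nTests)
}

#' k-fold cross-validation of the supermarker fit
#'
#' Seed-deterministic partition of the experimental sites into folds of size
#' differing by at most 1; controls travel with their source provirus (via
#' the [ControlSet-class] provenance). Each fold's model is fitted -- subset
#' search and threshold selection included -- on the remaining folds and
#' evaluated on the held-out sites and their controls.
#'
#' @inheritParams fitSupermarker
#' @param folds fold count (default 10); must not exceed the site count.
#' @param seed RNG seed for the partition.
#' @return a [CVReport-class].
#' @export
crossvalidateSupermarker <- function(markers, sites, controls, window = 2000,
                                     beta = 0.5, folds = 10, seed = NULL,
                                     weightFn = "odds", sigmaPolicy = "width",
                                     gridStep = 10, maxSubset = 8,
                                     mode = "summit") {
  V <- length(sites)
  if (folds > V) inputError("more folds than sites")
  if (!methods::is(controls, "ControlSet"))
    inputError("cross-validation requires a ControlSet with provenance")
  layout <- layoutFromSeqinfo(sites)
  foldId <- withSeed(seed, sample(rep(seq_len(folds), length.out = V)))
  rows <- lapply(seq_len(folds), function(f) {
    testIdx <- which(foldId == f); trainIdx <- which(foldId != f)
    trainSites <- SiteSet(siteChroms(sites)[trainIdx],
                          sitePositions(sites)[trainIdx], layout,
                          label = sites@label)
    testSites <- SiteSet(siteChroms(sites)[testIdx],
                         sitePositions(sites)[testIdx], layout,
                         label = sites@label)
    trainCtrl <- controlsForSources(controls, trainIdx)
    testCtrl <- controlsForSources(controls, testIdx)
    model <- fitSupermarker(markers, trainSites, trainCtrl, window, beta,
                            weightFn, sigmaPolicy, gridStep, maxSubset, mode)
    res <- evaluateSupermarker(model, testSites, testCtrl)
    data.frame(fold = f, nTest = length(testIdx), kStar = model@kStar,
               markers = paste(model@markers, collapse = "+"),
               trainF = model@trainF, testF = res@fscore, testWi = res@wi,
               testLog10p = res@log10p)
  })
  new("CVReport", folds = folds, perFold = do.call(rbind, rows),
      seed = if (is.null(seed)) NA_real_ else seed)
}

#' @rdname CVReport-class
#' @param x a [CVReport-class].
#' @export
cvSummary <- function(x) {
  pf <- x@perFold
  c(meanTestF = mean(pf$testF), sdTestF = stats::sd(pf$testF),
    meanTrainF = mean(pf$trainF), meanTestWi = mean(pf$testWi),
    meanTestLog10p = mean(pf$testLog10p))
}

setMethod("show", "CVReport", function(object) {
  s <- cvSummary(object)
  cat(sprintf("CVReport: %g folds (seed %s)\n", object@folds,
              format(object@seed)))
  cat(sprintf("  test F = %.3f +/- %.3f (train F = %.3f), test wi%% = %.1f%%\n",
              s["meanTestF"], s["sdTestF"], s["meanTrainF"],
              100 * s["meanTestWi"]))
})

#' Probability that an integration falls in a region
#'
#' Closed-form integral of the model's normalized density over the region:
#' a sum of truncated-Gaussian masses over the Gamma* peaks (no quadrature).
#' The whole genome integrates to 1 exactly.
#'
#' @param model a [SupermarkerModel-class].
#' @param chrom,start,end region coordinates (1-based closed), vectorized.
#' @return numeric probabilities.
#' @export
locusProbability <- function(model, chrom, start, end) {
  lens <- chromLengths(model@layout)
  if (any(!chrom %in% names(lens))) inputError("unknown chromosome in region")
  if (any(start < 1 | end > lens[chrom] | start > end))
    inputError("region outside chromosome bounds")
  amp <- GenomicRanges::mcols(model@peaks)$amplitude
  w <- amp / sum(amp)
  pc <- as.character(GenomicRanges::seqnames(model@peaks))
  px <- as.numeric(GenomicRanges::start(model@peaks))
  vapply(seq_along(chrom), function(i) {
    sel <- pc == chrom[i]
    if (!any(sel)) return(0)
    sum(w[sel] * (pnorm((end[i] - px[sel]) / model@sigma) -
                  pnorm((start[i] - 1 - px[sel]) / model@sigma))) /
      model@normConst
  }, numeric(1))
}

#' Correlation between supermarker density and site density
#'
#' Both the model density (as truncated-Gaussian mass) and the site counts
#' are aggregated in non-overlapping windows tiling the genome; the Pearson
#' correlation of the two window vectors is returned.
#'
#' @param model a [SupermarkerModel-class].
#' @param sites a [SiteSet-class].
#' @param window tile width in bp (default 10000).
#' @return list with `r` (Pearson), and the per-window data.frame.
#' @export
densityCorrelation <- function(model, sites, window = 10000) {
  stopifnotScalarNum(window, "window", positive = TRUE)
  lens <- chromLengths(model@layout)
  amp <- GenomicRanges::mcols(model@peaks)$amplitude
  w <- amp / sum(amp)
  pc <- as.character(GenomicRanges::seqnames(model@peaks))
  px <- as.numeric(GenomicRanges::start(model@peaks))
  sc <- siteChroms(sites); sp <- sitePositions(sites)
  dens <- numeric(0); cnt <- numeric(0); chOut <- character(0)
  for (ch in chromNames(model@layout)) {
    nw <- floor(lens[[ch]] / window)
    if (nw < 1) next
    breaks <- window * (0:nw)
    sel <- pc == ch
    mass <- if (any(sel)) {
      cdf <- vapply(breaks, function(b)
        sum(w[sel] * pnorm((b - px[sel]) / model@sigma)), numeric(1))
      diff(cdf)
    } else rep(0, nw)
    p <- sp[sc == ch]
    counts <- tabulate(findInterval(p[p <= breaks[nw + 1]], breaks,
                                    left.open = TRUE), nw)
    dens <- c(dens, mass); cnt <- c(cnt, counts)
    chOut <- c(chOut, rep(ch, nw))
  }
  if (length(dens) < 3) inputError("fewer than 3 windows; enlarge the genome")
  list(r = stats::cor(dens, cnt),
       windows = data.frame(chrom = chOut, density = dens, count = cnt))
}

#' Serialize / restore a supermarker model as JSON
#'
#' Full-precision round trip including the layout, Gamma* positions and
#' amplitudes, weights, and fit provenance.
#'
#' @param model a [SupermarkerModel-class].
#' @param path JSON file path.
#' @return `writeSupermarker`: the path, invisibly. `readSupermarker`: the
#'   restored [SupermarkerModel-class].
#' @export
writeSupermarker <- function(model, path) {
  obj <- list(
    format = "retroMark-supermarker-v1",
    markers = model@markers,
    weights = as.list(model@weights),
    sigma = model@sigma, kStar = model@kStar, trainF = model@trainF,
    window = model@window, beta = model@beta, normConst = model@normConst,
    layout = list(chroms = chromNames(model@layout),
                  lengths = unname(chromLengths(model@layout))),
    peaks = list(chrom = as.character(GenomicRanges::seqnames(model@peaks)),
                 pos = as.numeric(GenomicRanges::start(model@peaks)),
                 amplitude = GenomicRanges::mcols(model@peaks)$amplitude),
    meta = model@meta[setdiff(names(model@meta), "candidateF")],
    candidateF = as.list(model@meta$candidateF %||% numeric(0)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSupermarker
#' @export
readSupermarker <- function(path) {
  if (!file.exists(path)) inputError(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "retroMark-supermarker-v1"))
    inputError("not a retroMark supermarker file")
  layout <- ChromLayout(obj$layout$chroms, obj$layout$lengths)
  peaks <- GenomicRanges::GRanges(
    seqnames = factor(obj$peaks$chrom, levels = chromNames(layout)),
    ranges = IRanges::IRanges(start = obj$peaks$pos, width = 1L),
    amplitude = obj$peaks$amplitude,
    rank = seq_along(obj$peaks$pos),
    seqinfo = layoutSeqinfo(layout))
  meta <- obj$meta
  meta$candidateF <- unlist(obj$candidateF)
  new("SupermarkerModel", peaks = peaks, sigma = obj$sigma,
      normConst = obj$normConst, kStar = obj$kStar, trainF = obj$trainF,
      markers = obj$markers, weights = unlist(obj$weights),
      window = obj$window, beta = obj$beta, layout = layout, meta = meta)
}

#' Export the reduced peak set as BED
#'
#' @param model a [SupermarkerModel-class].
#' @param path BED output path (amplitude in the score column).
#' @export
exportSupermarkerBed <- function(model, path) {
  writePeaks(supermarkerPeaks(model), path)
}
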