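## Core association statistic: within-window counts against matched controls,
## exact Fisher significance carried in log10 space, and the normalized
## F-beta score that makes precision independent of the control sample size.

#' Distance from each site to the nearest marker peak
#'
#' In `summit` mode the distance is to the nearest peak summit; in `boundary`
#' mode it is 0 for sites inside a peak interval and otherwise the distance
#' to the nearest interval edge. Sites on chromosomes without any peak get
#' `Inf` (they count as beyond any window).
#'
#' @param query a [SiteSet-class].
#' @param marker a [PeakSet-class] (non-empty).
#' @param mode "summit" or "boundary".
#' @return numeric vector of distances in bp, one per query site.
#' @export
markerDistances <- function(query, marker, mode = c("summit", "boundary")) {
  mode <- match.arg(mode)
  if (!length(marker)) inputError("empty marker peak set")
  qc <- siteChroms(query); qp <- sitePositions(query)
  mc <- as.character(GenomicRanges::seqnames(marker))
  out <- rep(Inf, length(qp))
  for (ch in unique(qc)) {
    sel <- qc == ch
    msel <- mc == ch
    if (!any(msel)) next
    if (mode == "summit") {
      ref <- sort(peakSummits(marker)[msel])
      out[sel] <- nearestPointDistance(qp[sel], ref)
    } else {
      st <- GenomicRanges::start(marker)[msel]
      en <- GenomicRanges::end(marker)[msel]
      edges <- sort(c(st, en))
      d <- nearestPointDistance(qp[sel], edges)
      ir <- IRanges::reduce(IRanges::IRanges(start = st, end = en))
      inside <- IRanges::overlapsAny(
        IRanges::IRanges(start = qp[sel], width = 1L), ir)
      d[inside] <- 0
      out[sel] <- d
    }
  }
  out
}

#' Build the within-window contingency table
#'
#' Experimental and control sites are classified as within (distance <= w,
#' inclusive) or beyond the window of the nearest marker.
#'
#' @param sites experimental [SiteSet-class].
#' @param controls control [SiteSet-class] (e.g. a [ControlSet-class]).
#' @param marker a [PeakSet-class].
#' @param window window half-width w in bp (> 0; w = 0 is allowed and counts
#'   only sites exactly on a summit/edge).
#' @param mode distance mode, see [markerDistances()].
#' @return a [ContingencyTable-class].
#' @export
buildContingency <- function(sites, controls, marker, window = 2000,
                             mode = c("summit", "boundary")) {
  mode <- match.arg(mode)
  ds <- markerDistances(sites, marker, mode)
  dc <- markerDistances(controls, marker, mode)
  contingencyFromDistances(ds, dc, window)
}

contingencyFromDistances <- function(ds, dc, window) {
  new("ContingencyTable",
      tp = sum(ds <= window), fn = sum(ds > window),
      fp = sum(dc <= window), tn = sum(dc > window),
      window = as.numeric(window))
}

#' @rdname tableCounts
#' @export
setMethod("tableCounts", "ContingencyTable", function(x) {
  c(tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn,
    V = x@tp + x@fn, C = x@fp + x@tn, window = x@window)
})

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable (w = %g bp): tp=%g fn=%g fp=%g tn=%g (V=%g, C=%g)\n",
              object@window, object@tp, object@fn, object@fp, object@tn,
              object@tp + object@fn, object@fp + object@tn))
})

#' Two-sided Fisher exact test (log-space), with chi-squared option
#'
#' Exact two-sided p under the point-probability criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed the observed one (relative tolerance
#' 1e-7, as in [stats::fisher.test]). Computed in log space so values far
#' below double precision (e.g. 1e-350) remain representable. `auto` switches
#' to the chi-squared approximation (no continuity correction) when every
#' expected count is >= 5 and V + C > 10000. Degenerate margins (an empty row
#' or column) give p = 1, flagged.
#'
#' @param tab a [ContingencyTable-class].
#' @param method "exact", "chi2" or "auto".
#' @return list with `p` (may underflow to 0), `log10p`, `method` used and
#'   `degenerate` flag.
#' @export
fisherPvalue <- function(tab, method = c("auto", "exact", "chi2")) {
  method <- match.arg(method)
  tp <- tab@tp; fn <- tab@fn; fp <- tab@fp; tn <- tab@tn
  V <- tp + fn; C <- fp + tn
  W <- tp + fp; B <- fn + tn
  N <- V + C
  if (V == 0 || C == 0 || W == 0 || B == 0)
    return(list(p = 1, log10p = 0, method = "degenerate", degenerate = TRUE))
  if (method == "auto") {
    expected <- outer(c(V, C), c(W, B)) / N
    method <- if (all(expected >= 5) && N > 10000) "chi2" else "exact"
  }
  if (method == "chi2") {
    obs <- matrix(c(tp, fp, fn, tn), 2)
    expd <- outer(c(V, C), c(W, B)) / N
    stat <- sum((obs - expd)^2 / expd)
    lp <- pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
    return(list(p = 10^lp, log10p = lp, method = "chi2", degenerate = FALSE))
  }
  x <- max(0, W - C):min(V, W)
  ld <- dhyper(x, m = V, n = C, k = W, log = TRUE)
  lobs <- dhyper(tp, m = V, n = C, k = W, log = TRUE)
  keep <- ld <= lobs + log(1 + 1e-7)
  lp <- min(logSumExp(ld[keep]), 0) / log(10)
  list(p = 10^lp, log10p = lp, method = "exact", degenerate = FALSE)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param nTests number of tests (>= 1).
#' @return `min(1, p * nTests)`.
#' @export
bonferroni <- function(p, nTests = 1) {
  stopifnotScalarNum(nTests, "nTests", positive = TRUE)
  pmin(1, p * nTests)
}

## log10-scale companion (exact for p far below double range).
bonferroniLog10 <- function(log10p, nTests) pmin(0, log10p + log10(nTests))

#' Normalized precision, recall and F-beta score
#'
#' The false-positive count is first normalized by the control:experimental
#' ratio, `fp' = fp * V / C`, so that precision `P = tp / (tp + fp')` does not
#' depend on the control sample size. Recall is `R = tp / V`. The score is the
#' standard beta-weighted harmonic mean
#' `F = (1 + beta^2) P R / (beta^2 P + R)`; beta = 0.5 weights precision over
#' recall. A degenerate all-genome marker (tp = V, fp = C) gives P = 0.5,
#' R = 1 and F_0.5 = 5/9.
#'
#' @param tab a [ContingencyTable-class] with V > 0 and C > 0.
#' @param beta weight of recall relative to precision (default 0.5).
#' @return list with `precision`, `recall`, `fscore`.
#' @export
fScore <- function(tab, beta = 0.5) {
  V <- tab@tp + tab@fn; C <- tab@fp + tab@tn
  if (V == 0 || C == 0)
    inputError("fScore requires V > 0 and C > 0")
  fpn <- tab@fp * V / C
  P <- if (tab@tp + fpn > 0) tab@tp / (tab@tp + fpn) else 0
  R <- tab@tp / V
  Fb <- if (P + R > 0) (1 + beta^2) * P * R / (beta^2 * P + R) else 0
  list(precision = P, recall = R, fscore = Fb)
}

#' Full association between a site set and a marker
#'
#' Bundles the within-window fraction, normalized precision/recall/F,
#' Fisher significance with Bonferroni correction, and the association and
#' significance flags. A marker is called associated when F lies in (0.5, 1];
#' significant when the adjusted p-value is < 0.01.
#'
#' @inheritParams buildContingency
#' @param beta F-score beta (default 0.5).
#' @param nTests Bonferroni denominator (number of markers tested in the
#'   batch; default 1).
#' @param pvalueMethod see [fisherPvalue()].
#' @return an [AssociationResult-class].
#' @export
associate <- function(sites, controls, marker, window = 2000, beta = 0.5,
                      mode = c("summit", "boundary"), nTests = 1,
                      pvalueMethod = "auto") {
  mode <- match.arg(mode)
  if (window <= 0) inputError("window must be > 0")
  tab <- buildContingency(sites, controls, marker, window, mode)
  associationFromTable(tab, marker@label, beta, nTests, pvalueMethod)
}

associationFromTable <- function(tab, markerLabel, beta = 0.5, nTests = 1,
                                 pvalueMethod = "auto") {
  fs <- fScore(tab, beta)
  pv <- fisherPvalue(tab, pvalueMethod)
  l10adj <- bonferroniLog10(pv$log10p, nTests)
  V <- tab@tp + tab@fn
  new("AssociationResult", marker = markerLabel, window = tab@window,
      beta = beta, wi = tab@tp / V, precision = fs$precision,
      recall = fs$recall, fscore = fs$fscore, log10p = pv$log10p,
      log10pAdj = l10adj, nTests = nTests,
      associated = fs$fscore > 0.5 & fs$fscore <= 1,
      significant = l10adj < log10(0.01),
      pvalueMethod = pv$method, degenerate = pv$degenerate, table = tab)
}

#' @rdname fscore
#' @export
setMethod("fscore", "AssociationResult", function(x) x@fscore)

#' @rdname fscore
#' @export
setMethod("log10Pvalue", "AssociationResult", function(x) x@log10p)

#' Format a p-value the way reports print it
#'
#' p-values below the 1e-350 reporting floor are printed as "<1E-350".
#' @param log10p p-value on the log10 scale.
#' @return character.
#' @export
formatPvalue <- function(log10p) {
  ifelse(log10p < -350, "<1E-350",
         ifelse(log10p == 0, "1",
                sprintf("%.0E", 10^pmax(log10p, -350))))
}

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult '%s' (w = %g bp)\n", object@marker,
              object@window))
  cat(sprintf("  wi%%: %.1f%%  P: %.3f  R: %.3f  F_%g: %.3f\n",
              100 * object@wi, object@precision, object@recall, object@beta,
              object@fscore))
  cat(sprintf("  p (raw): %s  p (adj, n=%g): %s  %s%s\n",
              formatPvalue(object@log10p), object@nTests,
              formatPvalue(object@log10pAdj),
              if (object@associated) "associated" else "not associated",
              if (object@significant) ", significant" else ""))
})

#' Association as a one-row data.frame (report row)
#'
#' @param x an [AssociationResult-class].
#' @return data.frame with the TSV report columns.
#' @export
associationRow <- function(x) {
  cnt <- tableCounts(x@table)
  data.frame(marker = x@marker, window = x@window, N = unname(cnt["V"]),
             wi_pct = 100 * x@wi, P = x@precision, R = x@recall,
             F = x@fscore, log10_p_raw = x@log10p, log10_p_adj = x@log10pAdj,
             p_raw = formatPvalue(x@log10p), p_adj = formatPvalue(x@log10pAdj),
             associated = x@associated, significant = x@significant)
}

#' Sweep the association over window sizes
#'
#' Distances are computed once; one [AssociationResult-class] per window. tp
#' and fp are non-decreasing in the window.
#'
#' @inheritParams associate
#' @param windows strictly increasing numeric vector of windows in bp.
#' @return data.frame with one row per window (see [associationRow()]).
#' @export
windowSweep <- function(sites, controls, marker, windows, beta = 0.5,
                        mode = c("summit", "boundary"), nTests = 1,
                        pvalueMethod = "auto") {
  mode <- match.arg(mode)
  if (any(diff(windows) <= 0))
    inputError("windows must be strictly increasing")
  ds <- markerDistances(sites, marker, mode)
  dc <- markerDistances(controls, marker, mode)
  rows <- lapply(windows, function(w) {
    tab <- contingencyFromDistances(ds, dc, w)
    associationRow(associationFromTable(tab, marker@label, beta, nTests,
                                        pvalueMethod))
  })
  do.call(rbind, rows)
}
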