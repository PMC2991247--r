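## Shared fixtures and independent brute-force oracles. Oracles deliberately
## use naive formulations (O(n*m) scans, exp-space sums, outer products) so
## they stay independent of the implementation paths they check.

toyLayout <- function(lens = c(chrA = 10000, chrB = 8000)) {
  ChromLayout(names(lens), unname(lens))
}

## O(n*m) nearest-point distance.
bruteNearest <- function(q, ref) {
  vapply(q, function(p) if (length(ref)) min(abs(p - ref)) else Inf,
         numeric(1))
}

## Two-sided Fisher p by explicit enumeration with lchoose sums (exp space).
bruteFisherP <- function(tp, fn, fp, tn) {
  V <- tp + fn; C <- fp + tn; W <- tp + fp; N <- V + C
  xs <- max(0, W - C):min(V, W)
  pr <- exp(lchoose(V, xs) + lchoose(C, W - xs) - lchoose(N, W))
  obs <- pr[xs == tp]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

## AUC by explicit pairwise comparison.
bruteAUC <- function(ds, dc) {
  cmp <- outer(ds, dc, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

## AUPR by exhaustive threshold enumeration + trapezoid (mirrors the stated
## construction but recomputed from scratch per threshold).
bruteAUPR <- function(ds, dc, V = length(ds), C = length(dc)) {
  th <- sort(unique(c(ds, dc)))
  pts <- t(vapply(th, function(t) {
    tp <- sum(ds <= t); fpn <- sum(dc <= t) * V / C
    c(R = tp / V, P = if (tp + fpn > 0) tp / (tp + fpn) else 1)
  }, numeric(2)))
  R <- c(0, pts[, "R"]); P <- c(pts[1, "P"], pts[, "P"])
  sum(diff(R) * (P[-1] + P[-length(P)]) / 2)
}

## A deterministic planted fixture used across association/metrics tests.
plantedFixture <- function(seed = 101, V = 500, q = 0.7, s = 500,
                           ratio = 10, nPeaks = 1000) {
  cfg <- simConfig(seed = seed, V = V, q = q, s = s, ratio = ratio,
                   nPeaks = nPeaks)
  gen <- simulateGenome(cfg)
  marker <- suppressWarnings(
    simulatePeakSet(gen$layout, nPeaks, 400, seed = seed + 1,
                    label = "plantedMarker"))
  sites <- simulateIntegrations(gen$layout, marker, V, q, s, seed = seed + 2)
  controls <- generateMatchedControls(sites, gen$resites, ratio,
                                      seed = seed + 3)
  list(layout = gen$layout, resites = gen$resites, marker = marker,
       sites = sites, controls = controls)
}

## Hand-built one-peak supermarker model (peak mid-chromosome so boundary
## truncation is negligible).
singlePeakModel <- function(lay = ChromLayout("chrA", 1e6), pos = 5e5,
                            sigma = 400) {
  peaks <- GenomicRanges::GRanges("chrA", IRanges::IRanges(pos, width = 1),
                                  amplitude = 1, rank = 1,
                                  seqinfo = layoutSeqinfo(lay))
  m <- new("SupermarkerModel", peaks = peaks, sigma = sigma, normConst = 1,
           kStar = 1, trainF = 0.9, markers = "single",
           weights = c(single = 1), window = 2000, beta = 0.5, layout = lay,
           meta = list())
  m@normConst <- retroMark:::supermarkerNorm(m)
  m
}

## Fraction of the genome within w of any summit of a peak set (exact).
coverageFraction <- function(marker, layout, w) {
  gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(marker),
    ranges = IRanges::IRanges(start = pmax(1, peakSummits(marker) - w),
                              end = pmin(chromLengths(layout)[
                                as.character(GenomicRanges::seqnames(marker))],
                                peakSummits(marker) + w)))
  sum(GenomicRanges::width(GenomicRanges::reduce(gr))) / totalLength(layout)
}
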