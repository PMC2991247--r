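## Synthetic-data generator: toy genomes, restriction-site processes, marker
## peak sets and provirus sets with planted association strength, so the
## whole pipeline is testable without external downloads.

#' Simulation configuration
#'
#' Bundles the generator parameters with their defaults: a 2 x 5 Mb toy
#' genome, a Poisson restriction-site process at 1/256 per bp (the density of
#' a 4-cutter), 1000 marker peaks with log-normal widths around 400 bp,
#' V = 500 proviruses of which a fraction q = 0.7 is planted near marker
#' summits with Normal(0, s^2) offsets at s = 500 bp, and a control ratio of
#' 10 -- the structure of the provirus/ChIP-Seq datasets the association
#' statistic was designed for.
#'
#' @param seed RNG seed.
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param resiteRate restriction sites per bp.
#' @param nPeaks peaks per simulated marker.
#' @param peakMeanWidth mean peak width in bp (log-normal).
#' @param peakWidthSdlog sdlog of the log-normal width distribution.
#' @param clusteredPeaks if TRUE, summits cluster around Poisson cluster
#'   centers instead of being uniform.
#' @param V provirus count.
#' @param q planted association fraction in `[0, 1]`.
#' @param s planted offset scale in bp (> 0).
#' @param ratio control:experimental ratio.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(seed = 1, chromLengths = c(chrS1 = 5e6, chrS2 = 5e6),
                      resiteRate = 1 / 256, nPeaks = 1000,
                      peakMeanWidth = 400, peakWidthSdlog = 0.5,
                      clusteredPeaks = FALSE, V = 500, q = 0.7, s = 500,
                      ratio = 10) {
  if (q < 0 || q > 1) inputError("q must lie in [0, 1]")
  stopifnotScalarNum(s, "s", positive = TRUE)
  if (any(c(V, nPeaks, ratio) <= 0)) inputError("counts must be > 0")
  structure(as.list(environment()), class = "simConfig")
}

#' Simulate a toy genome and its restriction index
#'
#' Chromosome layout from the config; restriction sites as an independent
#' Poisson process per chromosome at the configured rate. Deterministic given
#' the seed; chromosomes that draw zero sites are regenerated (up to 10
#' times, then an error).
#'
#' @param config a [simConfig()].
#' @return list with `layout` ([ChromLayout-class]) and `resites`
#'   ([SiteSet-class]).
#' @export
simulateGenome <- function(config) {
  layout <- ChromLayout(names(config$chromLengths),
                        unname(config$chromLengths))
  withSeed(config$seed, {
    chrom <- character(0); pos <- numeric(0)
    for (ch in chromNames(layout)) {
      len <- chromLengths(layout)[[ch]]
      p <- numeric(0)
      for (try in 1:10) {
        n <- rpois(1, len * config$resiteRate)
        if (n > 0) { p <- sort(ceiling(runif(n) * len)); break }
        warning(sprintf("no restriction site drawn on %s; regenerating", ch),
                call. = FALSE)
      }
      if (!length(p))
        inputError(sprintf("restriction rate too low for chromosome %s", ch))
      chrom <- c(chrom, rep(ch, length(p))); pos <- c(pos, p)
    }
    list(layout = layout,
         resites = SiteSet(chrom, pos, layout, label = "resites"))
  })
}

#' Simulate a ChIP-Seq-like marker peak set
#'
#' Summits uniform over the genome (or clustered), widths log-normal with
#' the configured mean, amplitudes log-normal; peaks extending past a
#' chromosome end are clipped (flagged with a warning).
#'
#' @param layout a [ChromLayout-class].
#' @param nPeaks number of peaks.
#' @param meanWidth mean width in bp.
#' @param widthSdlog sdlog of the width distribution.
#' @param clustered cluster the summits (Poisson cluster process with ~20
#'   summits per cluster, cluster scale 50 kb).
#' @param seed RNG seed.
#' @param label marker label.
#' @return a [PeakSet-class].
#' @export
simulatePeakSet <- function(layout, nPeaks = 1000, meanWidth = 400,
                            widthSdlog = 0.5, clustered = FALSE, seed = NULL,
                            label = "simMarker") {
  lens <- chromLengths(layout)
  total <- totalLength(layout)
  withSeed(seed, {
    if (clustered) {
      nClust <- max(1, round(nPeaks / 20))
      centers <- runif(nClust) * total
      g <- centers[sample.int(nClust, nPeaks, replace = TRUE)] +
        rnorm(nPeaks, 0, 50000)
      g <- pmin(pmax(g, 1), total)
    } else {
      g <- runif(nPeaks) * total
    }
    off <- chromOffsets(layout)
    ci <- findInterval(g, off)        # offsets start at 0 -> index >= 1
    chrom <- chromNames(layout)[ci]
    pos <- ceiling(g - off[ci])
    pos <- pmin(pmax(pos, 1), lens[chrom])
    meanlog <- log(meanWidth) - widthSdlog^2 / 2
    w <- pmax(2, round(rlnorm(nPeaks, meanlog, widthSdlog)))
    start <- pos - floor(w / 2); end <- start + w - 1
    clippedLo <- start < 1; clippedHi <- end > lens[chrom]
    if (any(clippedLo | clippedHi))
      warning(sprintf("%d peak(s) clipped at chromosome ends",
                      sum(clippedLo | clippedHi)), call. = FALSE)
    start <- pmax(start, 1); end <- pmin(end, lens[chrom])
    amp <- rlnorm(nPeaks, 0, 1)
    PeakSet(chrom, start, end, layout, summit = pos, score = amp,
            label = label)
  })
}

#' Simulate proviral integration sites with planted association
#'
#' A fraction q of the V sites is placed at a uniformly chosen summit of the
#' target marker plus a Normal(0, s^2) offset; the remainder is uniform over
#' the genome. Out-of-bounds placements are resampled. Ground-truth labels
#' (`planted`) are kept in the metadata columns for test assertions.
#'
#' @param layout a [ChromLayout-class].
#' @param target target [PeakSet-class].
#' @param V site count.
#' @param q planted fraction in `[0, 1]`.
#' @param s offset scale in bp.
#' @param seed RNG seed.
#' @param label site-set label.
#' @return a [SiteSet-class] with mcol `planted` (logical).
#' @export
simulateIntegrations <- function(layout, target, V = 500, q = 0.7, s = 500,
                                 seed = NULL, label = "simSites") {
  if (q < 0 || q > 1) inputError("q must lie in [0, 1]")
  lens <- chromLengths(layout)
  total <- totalLength(layout)
  nPlanted <- ceiling(q * V)
  withSeed(seed, {
    chrom <- character(V); pos <- numeric(V)
    if (nPlanted > 0) {
      if (!length(target)) inputError("planting requires a non-empty target")
      tc <- as.character(GenomicRanges::seqnames(target))
      ts <- peakSummits(target)
      for (i in seq_len(nPlanted)) {
        repeat {
          j <- sample.int(length(ts), 1L)
          p <- round(ts[j] + rnorm(1, 0, s))
          if (p >= 1 && p <= lens[tc[j]]) break
        }
        chrom[i] <- tc[j]; pos[i] <- p
      }
    }
    if (nPlanted < V) {
      idx <- (nPlanted + 1):V
      g <- runif(length(idx)) * total
      off <- chromOffsets(layout)
      ci <- findInterval(g, off)
      chrom[idx] <- chromNames(layout)[ci]
      pos[idx] <- pmin(pmax(ceiling(g - off[ci]), 1), lens[chrom[idx]])
    }
    out <- SiteSet(chrom, pos, layout, label = label)
    GenomicRanges::mcols(out)$planted <- seq_len(V) <= nPlanted
    out
  })
}

#' Simulate the uniform-in-gene integration scenario
#'
#' Genes of the given length are placed uniformly (TSS at the start for "+"
#' strand, at the end for "-"); integration sites are uniform within gene
#' bodies; the virtual marker is one summit per TSS. Intended for window
#' sweeps: with 20 kb genes the F score plateaus once the window covers the
#' gene length.
#'
#' @param layout a [ChromLayout-class].
#' @param nGenes gene count.
#' @param geneLength gene length in bp (> 0; default 20000).
#' @param V site count.
#' @param seed RNG seed.
#' @return list with `sites` ([SiteSet-class]), `tss` ([PeakSet-class]), and
#'   `genes` (data.frame chrom/start/end/strand).
#' @export
simulateGeneScenario <- function(layout, nGenes = 300, geneLength = 20000,
                                 V = 500, seed = NULL) {
  stopifnotScalarNum(geneLength, "geneLength", positive = TRUE)
  if (geneLength < 1) inputError("degenerate gene length")
  lens <- chromLengths(layout)
  total <- totalLength(layout)
  withSeed(seed, {
    off <- chromOffsets(layout)
    g <- runif(nGenes) * (total - geneLength)
    ci <- findInterval(g, off)
    chrom <- chromNames(layout)[ci]
    start <- pmin(pmax(ceiling(g - off[ci]), 1), lens[chrom] - geneLength + 1)
    end <- start + geneLength - 1
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    tssPos <- ifelse(strand == "+", start, end)
    gi <- sample.int(nGenes, V, replace = TRUE)
    pos <- start[gi] + floor(runif(V) * geneLength)
    list(sites = SiteSet(chrom[gi], pos, layout, label = "geneSites"),
         tss = PeakSet(chrom, tssPos, tssPos, layout, summit = tssPos,
                       score = rep(1, nGenes), label = "virtualTSS"),
         genes = data.frame(chrom = chrom, start = start, end = end,
                            strand = strand))
  })
}
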