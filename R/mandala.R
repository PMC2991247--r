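## Chromosome projection mandala: proviruses on a circle, angle = genomic
## position on the circularized chromosome(s), radius = log-scaled distance
## to the nearest marker (contour = 1 bp, center = 1 Mb and beyond).

#' Polar coordinates for a mandala
#'
#' theta is proportional to genomic position along the circularized scope
#' (one chromosome, or all chromosomes concatenated in layout order with no
#' gaps). The radius maps distance d to `r = 1 - log10(max(d, 1)) / 6`,
#' clipped to `[0, 1]`: r = 1 on the contour at d <= 1 bp, r = 0 at the
#' center for d >= 1 Mb.
#'
#' @param sites a [SiteSet-class].
#' @param distances per-site distances to the nearest marker (bp), e.g. from
#'   [markerDistances()]; no missing values allowed.
#' @param scope "genome" or a chromosome name.
#' @param window window used for the within/beyond coloring flag (default
#'   2000 bp).
#' @return data.frame with theta, r, within, chrom, pos, distance.
#' @export
polarCoords <- function(sites, distances, scope = "genome", window = 2000) {
  if (length(distances) != length(sites))
    inputError("one distance per site required")
  if (any(is.na(distances)))
    inputError("missing distance")
  layout <- layoutFromSeqinfo(sites)
  ch <- siteChroms(sites); pos <- sitePositions(sites)
  if (identical(scope, "genome")) {
    g <- globalPosition(layout, ch, pos)
    L <- totalLength(layout)
  } else {
    if (!scope %in% chromNames(layout))
      inputError(sprintf("unknown scope '%s'", scope))
    keep <- ch == scope
    ch <- ch[keep]; pos <- pos[keep]; distances <- distances[keep]
    g <- pos
    L <- chromLengths(layout)[[scope]]
  }
  theta <- 2 * pi * g / L
  r <- pmin(pmax(1 - log10(pmax(distances, 1)) / 6, 0), 1)
  data.frame(theta = theta, r = r, within = distances <= window,
             chrom = ch, pos = pos, distance = distances)
}

mandalaRadius <- function(d) pmin(pmax(1 - log10(pmax(d, 1)) / 6, 0), 1)

#' Render a chromosome projection mandala
#'
#' Blue points for sites within the window, red beyond; the window-distance
#' circle is drawn dashed; optional radial gray shading (e.g. supermarker
#' density by angular bin) fills the annulus between the window circle and
#' the contour. A caption strip reports the F score and wi% when given.
#' Output device is chosen by file extension: .svg, .png or .pdf.
#'
#' @param coords data.frame from [polarCoords()].
#' @param file output image path.
#' @param window window in bp (drawn as the dashed circle).
#' @param fscore,wi optional caption values (F score, within-window
#'   fraction).
#' @param shading optional numeric vector of angular-bin intensities in
#'   `[0, 1]` (linear amplitude-to-gray), length = number of bins.
#' @param main plot title.
#' @return the coords, invisibly.
#' @export
renderMandala <- function(coords, file, window = 2000, fscore = NULL,
                          wi = NULL, shading = NULL, main = "") {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    svg = grDevices::svg(file, width = 7, height = 7.5),
    png = grDevices::png(file, width = 700, height = 750),
    pdf = grDevices::pdf(file, width = 7, height = 7.5),
    inputError(sprintf("unsupported image format '.%s' (svg/png/pdf)", ext)))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.15, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  tt <- seq(0, 2 * pi, length.out = 512)
  rw <- mandalaRadius(window)
  if (!is.null(shading)) {
    nb <- length(shading)
    edges <- seq(0, 2 * pi, length.out = nb + 1)
    for (b in seq_len(nb)) {
      a <- seq(edges[b], edges[b + 1], length.out = 16)
      graphics::polygon(c(sin(a), rev(rw * sin(a))),
                        c(cos(a), rev(rw * cos(a))),
                        col = grDevices::gray(1 - 0.8 * min(max(
                          shading[b], 0), 1)), border = NA)
    }
  }
  graphics::lines(sin(tt), cos(tt))
  graphics::lines(rw * sin(tt), rw * cos(tt), lty = 2, col = "gray40")
  graphics::points(coords$r * sin(coords$theta), coords$r * cos(coords$theta),
                   pch = 16, cex = 0.5,
                   col = ifelse(coords$within, "blue", "red"))
  cap <- character(0)
  if (!is.null(fscore)) cap <- c(cap, sprintf("F = %.2f", fscore))
  if (!is.null(wi)) cap <- c(cap, sprintf("wi%gkB = %.0f%%", window / 1000,
                                          100 * wi))
  if (length(cap))
    graphics::mtext(paste(cap, collapse = "   "), side = 1, line = 1)
  invisible(coords)
}

#' Angular density bins for mandala shading
#'
#' Aggregates the supermarker density into angular bins of the genome circle
#' (linear in amplitude, normalized to max 1), for use as the `shading`
#' argument of [renderMandala()].
#'
#' @param model a [SupermarkerModel-class].
#' @param bins number of angular bins.
#' @return numeric vector of length `bins` in `[0, 1]`.
#' @export
mandalaShading <- function(model, bins = 360) {
  L <- totalLength(model@layout)
  step <- L / bins
  off <- chromOffsets(model@layout)
  g <- off[as.character(GenomicRanges::seqnames(model@peaks))] +
    as.numeric(GenomicRanges::start(model@peaks))
  amp <- GenomicRanges::mcols(model@peaks)$amplitude
  v <- vapply(split(amp, pmin(floor(g / step) + 1, bins))[as.character(
    seq_len(bins))], function(x) sum(x, na.rm = TRUE), numeric(1))
  v[is.na(v)] <- 0
  if (max(v) > 0) v / max(v) else v
}
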