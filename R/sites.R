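#' Construct a SiteSet
#'
#' Point genomic positions (1-based, GRanges convention). BED input is 0-based
#' half-open and is converted by [readSites()].
#'
#' @param chrom character chromosome names.
#' @param pos numeric 1-based positions.
#' @param layout a [ChromLayout-class]; every chromosome must exist in it.
#' @param label single character label.
#' @param strand optional strand ("+", "-", "*"); ignored by all distance
#'   computations.
#' @return a [SiteSet-class].
#' @export
SiteSet <- function(chrom, pos, layout, label = "sites", strand = NULL) {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) != length(pos))
    inputError("chrom and pos must have the same length")
  lens <- chromLengths(layout)
  unknown <- setdiff(unique(chrom), names(lens))
  if (length(unknown))
    inputError(sprintf("unknown chromosome(s): %s",
                       paste(unknown, collapse = ", ")))
  bad <- which(pos < 1 | pos > lens[chrom])
  if (length(bad))
    inputError(sprintf("%d position(s) outside chromosome bounds (first: %s:%.0f)",
                       length(bad), chrom[bad[1L]], pos[bad[1L]]))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(lens)),
    ranges = IRanges::IRanges(start = pos, width = 1L),
    strand = rep(strand %||% "*", length.out = length(chrom)),
    seqinfo = layoutSeqinfo(layout))
  new("SiteSet", gr, label = label)
}

#' @rdname SiteSet
#' @param x a [SiteSet-class].
#' @export
sitePositions <- function(x) as.numeric(GenomicRanges::start(x))

#' @rdname SiteSet
#' @export
siteChroms <- function(x) as.character(GenomicRanges::seqnames(x))

#' @rdname setLabel
#' @export
setMethod("setLabel", "SiteSet", function(x) x@label)

setMethod("show", "SiteSet", function(object) {
  cat(sprintf("SiteSet '%s': %d site(s) on %d chromosome(s)\n", object@label,
              length(object),
              length(unique(as.character(GenomicRanges::seqnames(object))))))
})

#' Construct a PeakSet
#'
#' Scored intervals with summits, 1-based closed coordinates.
#'
#' @param chrom,start,end interval coordinates (1-based closed).
#' @param layout a [ChromLayout-class].
#' @param summit optional numeric summit positions (1-based); defaults to the
#'   interval midpoint.
#' @param score optional non-negative amplitudes; default 0.
#' @param label single character marker label.
#' @return a [PeakSet-class].
#' @export
PeakSet <- function(chrom, start, end, layout, summit = NULL, score = NULL,
                    label = "peaks") {
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start > end)) inputError("peak start must be <= end")
  lens <- chromLengths(layout)
  unknown <- setdiff(unique(chrom), names(lens))
  if (length(unknown))
    inputError(sprintf("unknown chromosome(s): %s",
                       paste(unknown, collapse = ", ")))
  if (any(start < 1 | end > lens[chrom]))
    inputError("peak interval outside chromosome bounds")
  summit <- summit %||% floor((start + end) / 2)
  score <- score %||% rep(0, length(chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(lens)),
    ranges = IRanges::IRanges(start = start, end = end),
    summit = as.numeric(summit), score = as.numeric(score),
    seqinfo = layoutSeqinfo(layout))
  new("PeakSet", gr, label = label)
}

#' @rdname PeakSet-class
#' @export
setMethod("peakSummits", "PeakSet",
          function(x) as.numeric(GenomicRanges::mcols(x)$summit))

#' @rdname PeakSet-class
#' @export
setMethod("meanPeakWidth", "PeakSet", function(x) {
  if (!length(x)) inputError("empty peak set has no mean width")
  mean(GenomicRanges::width(x))
})

#' @rdname setLabel
#' @export
setMethod("setLabel", "PeakSet", function(x) x@label)

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet '%s': %d peak(s), mean width %.1f bp\n", object@label,
              length(object),
              if (length(object)) mean(GenomicRanges::width(object)) else NA))
})

## Shared BED-line tokenizer. Returns a list of character field vectors plus
## original line numbers; skips blank/comment/track lines.
readBedFields <- function(path) {
  if (!file.exists(path)) inputError(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)
  list(fields = strsplit(trimws(lines[keep]), "[ \t]+"), lineNo = which(keep))
}

bedNumeric <- function(fields, col, path, lineNo) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), col)))
  bad <- which(is.na(v))
  if (length(bad))
    inputError(sprintf("%s: non-numeric field %d at line %d", path, col,
                       lineNo[bad[1L]]))
  v
}

#' Read point sites from a BED file
#'
#' BED3/BED6; 0-based half-open. Each interval collapses to its midpoint
#' (floor of the 0-based interval center), following the convention that
#' integration sites are points. Records on chromosomes absent from the
#' layout, or outside chromosome bounds, are rejected; the rejected count is
#' reported as a warning and attached as `attr(x, "rejected")`.
#'
#' @param path BED file path.
#' @param layout a [ChromLayout-class].
#' @param label set label; default the file name.
#' @return a [SiteSet-class].
#' @export
readSites <- function(path, layout, label = basename(path)) {
  b <- readBedFields(path)
  if (!length(b$fields))
    return(SiteSet(character(), numeric(), layout, label = label))
  if (any(lengths(b$fields) < 3L)) {
    i <- which(lengths(b$fields) < 3L)[1L]
    inputError(sprintf("%s: fewer than 3 BED fields at line %d", path,
                       b$lineNo[i]))
  }
  chrom <- vapply(b$fields, `[[`, character(1), 1L)
  start0 <- bedNumeric(b$fields, 2L, path, b$lineNo)
  end0 <- bedNumeric(b$fields, 3L, path, b$lineNo)
  strand <- rep("*", length(chrom))
  has6 <- lengths(b$fields) >= 6L
  strand[has6] <- vapply(b$fields[has6], `[[`, character(1), 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  pos <- floor((start0 + end0) / 2) + 1   # midpoint, to 1-based
  lens <- chromLengths(layout)
  ok <- chrom %in% names(lens) & start0 >= 0 & end0 > start0
  ok[ok] <- pos[ok] >= 1 & pos[ok] <= lens[chrom[ok]] & end0[ok] <= lens[chrom[ok]]
  nRej <- sum(!ok)
  if (nRej > 0)
    warning(sprintf("%s: rejected %d out-of-layout record(s)", path, nRej),
            call. = FALSE)
  out <- SiteSet(chrom[ok], pos[ok], layout, label = label,
                 strand = strand[ok])
  attr(out, "rejected") <- nRej
  out
}

#' Read ChIP-Seq-like peaks from a BED file
#'
#' BED3/BED6 with an optional 7th column giving the summit as a 0-based
#' offset from the interval start (narrowPeak convention; -1 means absent).
#' Without a summit column the summit defaults to the interval midpoint.
#' Out-of-layout records are rejected and counted as in [readSites()].
#'
#' @inheritParams readSites
#' @return a [PeakSet-class].
#' @export
readPeaks <- function(path, layout, label = basename(path)) {
  b <- readBedFields(path)
  if (!length(b$fields))
    return(PeakSet(character(), numeric(), numeric(), layout, label = label))
  if (any(lengths(b$fields) < 3L)) {
    i <- which(lengths(b$fields) < 3L)[1L]
    inputError(sprintf("%s: fewer than 3 BED fields at line %d", path,
                       b$lineNo[i]))
  }
  chrom <- vapply(b$fields, `[[`, character(1), 1L)
  start0 <- bedNumeric(b$fields, 2L, path, b$lineNo)
  end0 <- bedNumeric(b$fields, 3L, path, b$lineNo)
  n <- length(chrom)
  score <- rep(0, n)
  has5 <- lengths(b$fields) >= 5L
  if (any(has5)) {
    v <- suppressWarnings(as.numeric(vapply(b$fields[has5], `[[`,
                                            character(1), 5L)))
    score[has5][!is.na(v) & v >= 0] <- v[!is.na(v) & v >= 0]
  }
  summit0 <- floor((start0 + end0) / 2)          # 0-based midpoint
  has7 <- lengths(b$fields) >= 7L
  if (any(has7)) {
    off <- suppressWarnings(as.numeric(vapply(b$fields[has7], `[[`,
                                              character(1), 7L)))
    use <- !is.na(off) & off >= 0
    summit0[has7][use] <- start0[has7][use] + off[use]
  }
  lens <- chromLengths(layout)
  ok <- chrom %in% names(lens) & start0 >= 0 & end0 > start0
  ok[ok] <- end0[ok] <= lens[chrom[ok]] &
    summit0[ok] >= start0[ok] & summit0[ok] < end0[ok]
  nRej <- sum(!ok)
  if (nRej > 0)
    warning(sprintf("%s: rejected %d out-of-layout record(s)", path, nRej),
            call. = FALSE)
  out <- PeakSet(chrom[ok], start0[ok] + 1, end0[ok], layout,
                 summit = summit0[ok] + 1, score = score[ok], label = label)
  attr(out, "rejected") <- nRej
  out
}

#' Write sites / peaks as BED
#'
#' Inverse of [readSites()] / [readPeaks()]: coordinates are converted back to
#' 0-based half-open. `writePeaks` emits 7 columns, the 7th being the summit
#' offset from the interval start.
#'
#' @param x a [SiteSet-class] or [PeakSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSites <- function(x, path) {
  df <- data.frame(chrom = siteChroms(x), start = sitePositions(x) - 1,
                   end = sitePositions(x), name = x@label, score = 0,
                   strand = as.character(GenomicRanges::strand(x)))
  df$strand[df$strand == "*"] <- "."
  write.table(format(df, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSites
#' @export
writePeaks <- function(x, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1,
                   end = GenomicRanges::end(x), name = x@label,
                   score = GenomicRanges::mcols(x)$score, strand = ".",
                   summit = GenomicRanges::mcols(x)$summit -
                     GenomicRanges::start(x))
  write.table(format(df, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge two peak sets into one marker
#'
#' Union of the two interval sets; overlapping or bookended intervals are
#' merged, the merged summit is the merged-interval midpoint, and the merged
#' score is the maximum of the contributing scores. Used e.g. to combine CpG
#' islands and TSS annotation into a single marker.
#'
#' @param a,b [PeakSet-class] objects on the same layout.
#' @param label label of the merged marker; default "a+b".
#' @return a [PeakSet-class].
#' @export
mergePeakSets <- function(a, b, label = paste(a@label, b@label, sep = "+")) {
  la <- layoutFromSeqinfo(a); lb <- layoutFromSeqinfo(b)
  if (!sameLayout(la, lb)) inputError("peak sets have mismatched layouts")
  u <- c(GenomicRanges::granges(a), GenomicRanges::granges(b))
  scores <- c(GenomicRanges::mcols(a)$score, GenomicRanges::mcols(b)$score)
  red <- GenomicRanges::reduce(u)
  hit <- GenomicRanges::findOverlaps(red, u)
  mergedScore <- rep(0, length(red))
  agg <- tapply(scores[S4Vectors::subjectHits(hit)],
                S4Vectors::queryHits(hit), max)
  mergedScore[as.integer(names(agg))] <- as.numeric(agg)
  PeakSet(as.character(GenomicRanges::seqnames(red)),
          GenomicRanges::start(red), GenomicRanges::end(red), la,
          summit = floor((GenomicRanges::start(red) +
                          GenomicRanges::end(red)) / 2),
          score = mergedScore, label = label)
}
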