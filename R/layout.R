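#' Construct a chromosome layout
#'
#' @param chroms character vector of chromosome names (kept in this order).
#' @param lengths numeric vector of chromosome lengths in bp.
#' @return a [ChromLayout-class] object.
#' @examples
#' ChromLayout(c("chr1", "chr2"), c(1000, 500))
#' @export
ChromLayout <- function(chroms, lengths) {
  new("ChromLayout", chroms = as.character(chroms),
      lengths = as.numeric(lengths))
}

#' Read a UCSC chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name and length in bp.
#' Chromosome order is file order. Malformed lines, non-positive lengths and
#' duplicated names are input errors naming the offending line.
#'
#' @param path path to a chrom.sizes file.
#' @return a [ChromLayout-class].
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path)) inputError(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    inputError(sprintf("%s: malformed line %d: '%s'", path, lineNo[bad[1L]],
                       lines[lineNo[bad[1L]]]))
  chroms <- vapply(fields, `[[`, character(1), 1L)
  lens <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  bad <- which(is.na(lens) | lens <= 0)
  if (length(bad))
    inputError(sprintf("%s: non-positive or non-numeric length at line %d",
                       path, lineNo[bad[1L]]))
  if (anyDuplicated(chroms)) {
    d <- which(duplicated(chroms))[1L]
    inputError(sprintf("%s: duplicate chromosome '%s' at line %d",
                       path, chroms[d], lineNo[d]))
  }
  ChromLayout(chroms, lens)
}

#' @rdname ChromLayout-class
#' @aliases chromNames,ChromLayout-method
#' @export
setMethod("chromNames", "ChromLayout", function(x) x@chroms)

#' @rdname ChromLayout-class
#' @export
setMethod("chromLengths", "ChromLayout",
          function(x) stats::setNames(x@lengths, x@chroms))

#' @rdname ChromLayout-class
#' @export
setMethod("chromOffsets", "ChromLayout", function(x) {
  stats::setNames(cumsum(c(0, x@lengths[-length(x@lengths)])), x@chroms)
})

#' @rdname ChromLayout-class
#' @export
setMethod("totalLength", "ChromLayout", function(x) sum(x@lengths))

setMethod("show", "ChromLayout", function(object) {
  cat(sprintf("ChromLayout: %d chromosome(s), %.0f bp total\n",
              length(object@chroms), totalLength(object)))
  n <- min(length(object@chroms), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %-8s %12.0f bp  offset %12.0f\n", object@chroms[i],
                object@lengths[i], chromOffsets(object)[i]))
  if (length(object@chroms) > n) cat("  ...\n")
})

#' Coerce a layout to a Seqinfo
#' @param layout a [ChromLayout-class].
#' @return a [GenomeInfoDb::Seqinfo] with the same chromosomes and lengths.
#' @export
layoutSeqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = layout@chroms,
                        seqlengths = as.integer(layout@lengths))
}

## Recover a ChromLayout from any GRanges that carries seqlengths.
layoutFromSeqinfo <- function(gr) {
  si <- GenomeInfoDb::seqinfo(gr)
  lens <- GenomeInfoDb::seqlengths(si)
  if (any(is.na(lens)))
    inputError("object carries no chromosome lengths")
  ChromLayout(GenomeInfoDb::seqnames(si), lens)
}

sameLayout <- function(a, b) {
  identical(chromNames(a), chromNames(b)) &&
    isTRUE(all.equal(unname(chromLengths(a)), unname(chromLengths(b))))
}

#' Genome-concatenated position
#'
#' Maps (chromosome, position) to a single coordinate on the concatenation of
#' all chromosomes in layout order (no gaps).
#'
#' @param layout a [ChromLayout-class].
#' @param chrom character chromosome names.
#' @param pos numeric 1-based positions.
#' @return numeric global positions (1-based).
#' @export
globalPosition <- function(layout, chrom, pos) {
  off <- chromOffsets(layout)
  unknown <- setdiff(unique(chrom), names(off))
  if (length(unknown))
    inputError(sprintf("unknown chromosome(s): %s",
                       paste(unknown, collapse = ", ")))
  unname(off[chrom]) + pos
}
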