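## Matched-control generation: reproduce the restriction-enzyme cloning bias
## of a provirus dataset by placing each control at the same distance from a
## randomly chosen recognition site as the provirus is from its nearest one.

#' Distance to the nearest restriction site
#'
#' Minimum absolute distance from each query site to any recognition site on
#' the same chromosome.
#'
#' @param sites a [SiteSet-class] of query positions.
#' @param index a [SiteSet-class] of recognition-site positions (the
#'   restriction index; label = motif).
#' @return numeric vector of distances in bp.
#' @export
nearestRestrictionDistance <- function(sites, index) {
  qc <- siteChroms(sites); qp <- sitePositions(sites)
  ic <- siteChroms(index); ip <- sitePositions(index)
  out <- numeric(length(qp))
  for (ch in unique(qc)) {
    ref <- sort(ip[ic == ch])
    if (!length(ref))
      inputError(sprintf("no recognition site on chromosome %s", ch))
    sel <- qc == ch
    out[sel] <- nearestPointDistance(qp[sel], ref)
  }
  out
}

## Min distance from each query point to a sorted reference point vector.
nearestPointDistance <- function(q, refSorted) {
  i <- findInterval(q, refSorted)
  dLeft <- ifelse(i >= 1, q - refSorted[pmax(i, 1L)], Inf)
  dRight <- ifelse(i < length(refSorted), refSorted[pmin(i + 1L,
                   length(refSorted))] - q, Inf)
  pmin(dLeft, dRight)
}

#' Generate matched in-silico control sites
#'
#' For each experimental site, `ratio` controls are generated: a recognition
#' site is drawn uniformly at random genome-wide from the restriction index
#' (or per chromosome with `perChromosome = TRUE`), and the control is placed
#' at the experimental site's nearest-restriction-site distance from it, on a
#' uniformly random side. Controls falling outside chromosome bounds are
#' resampled (up to `maxRetry` times each, then an error).
#'
#' @param sites experimental [SiteSet-class].
#' @param index restriction-site [SiteSet-class].
#' @param ratio integer >= 1, controls per experimental site (default 10).
#' @param seed RNG seed; generation is fully reproducible from it.
#' @param perChromosome if TRUE, the matched recognition site is drawn from
#'   the experimental site's own chromosome.
#' @param maxRetry retry budget per control.
#' @return a [ControlSet-class].
#' @export
generateMatchedControls <- function(sites, index, ratio = 10, seed = NULL,
                                    perChromosome = FALSE, maxRetry = 1000) {
  stopifnotScalarNum(ratio, "ratio", positive = TRUE)
  if (ratio != round(ratio) || ratio < 1)
    inputError("ratio must be an integer >= 1")
  if (!length(index)) inputError("empty restriction index")
  if (!length(sites)) inputError("empty site set")
  layout <- layoutFromSeqinfo(sites)
  lens <- chromLengths(layout)
  d <- nearestRestrictionDistance(sites, index)
  ic <- siteChroms(index); ip <- sitePositions(index)
  nS <- length(sites)
  withSeed(seed, {
    srcIdx <- rep(seq_len(nS), each = ratio)
    dist <- d[srcIdx]
    n <- length(srcIdx)
    chromOut <- character(n); posOut <- numeric(n)
    reChromOut <- character(n); rePosOut <- numeric(n); offOut <- numeric(n)
    pool <- seq_along(ip)
    for (k in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(maxRetry)) {
        if (perChromosome) {
          cand <- which(ic == siteChroms(sites)[srcIdx[k]])
          j <- cand[sample.int(length(cand), 1L)]
        } else {
          j <- pool[sample.int(length(pool), 1L)]
        }
        sgn <- if (sample.int(2L, 1L) == 1L) 1 else -1
        p <- ip[j] + sgn * dist[k]
        if (p >= 1 && p <= lens[ic[j]]) {
          chromOut[k] <- ic[j]; posOut[k] <- p
          reChromOut[k] <- ic[j]; rePosOut[k] <- ip[j]; offOut[k] <- sgn * dist[k]
          ok <- TRUE
          break
        }
      }
      if (!ok)
        inputError(sprintf(
          "could not place control %d within bounds after %d retries", k,
          maxRetry))
    }
    ss <- SiteSet(chromOut, posOut, layout,
                  label = paste0(sites@label, ".controls"))
    new("ControlSet", ss,
        label = paste0(sites@label, ".controls"),
        provenance = data.frame(source = srcIdx, resiteChrom = reChromOut,
                                resitePos = rePosOut, offset = offOut),
        ratio = ratio, seed = if (is.null(seed)) NA_real_ else seed)
  })
}

#' @rdname ControlSet-class
#' @export
setMethod("provenance", "ControlSet", function(x) x@provenance)

#' @rdname ControlSet-class
#' @export
setMethod("controlRatio", "ControlSet", function(x) x@ratio)

setMethod("show", "ControlSet", function(object) {
  cat(sprintf("ControlSet '%s': %d control(s), ratio %g, seed %s\n",
              object@label, length(object), object@ratio,
              format(object@seed)))
})

#' Subset a ControlSet to the controls of given source sites
#'
#' Used by cross-validation: controls are partitioned with their source
#' provirus so folds stay independent.
#'
#' @param x a [ControlSet-class].
#' @param sourceIdx indices of experimental sites whose controls to keep.
#' @return a [ControlSet-class].
#' @export
controlsForSources <- function(x, sourceIdx) {
  keep <- which(x@provenance$source %in% sourceIdx)
  prov <- x@provenance[keep, , drop = FALSE]
  ## renumber sources to the position within sourceIdx
  prov$source <- match(prov$source, sourceIdx)
  layout <- layoutFromSeqinfo(x)
  ss <- SiteSet(siteChroms(x)[keep], sitePositions(x)[keep], layout,
                label = x@label)
  new("ControlSet", ss, label = x@label, provenance = prov,
      ratio = x@ratio, seed = x@seed)
}

#' Write controls as BED with a provenance sidecar
#'
#' @param x a [ControlSet-class].
#' @param path BED output path; the provenance TSV goes to
#'   `paste0(path, ".provenance.tsv")`.
#' @return the BED path, invisibly.
#' @export
writeControls <- function(x, path) {
  writeSites(x, path)
  prov <- x@provenance
  write.table(prov, paste0(path, ".provenance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
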