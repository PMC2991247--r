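#' @rdname ChromLayout-class
#' @param x a retroMark object.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname ChromLayout-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname ChromLayout-class
#' @export
setGeneric("chromOffsets", function(x) standardGeneric("chromOffsets"))

#' @rdname ChromLayout-class
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' Label of a site or peak set
#' @param x a [SiteSet] or [PeakSet].
#' @return single character label.
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' @rdname PeakSet-class
#' @param x a [PeakSet].
#' @export
setGeneric("peakSummits", function(x) standardGeneric("peakSummits"))

#' @rdname PeakSet-class
#' @export
setGeneric("meanPeakWidth", function(x) standardGeneric("meanPeakWidth"))

#' @rdname ControlSet-class
#' @param x a [ControlSet].
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ControlSet-class
#' @export
setGeneric("controlRatio", function(x) standardGeneric("controlRatio"))

#' Counts of a contingency table
#' @param x a [ContingencyTable].
#' @return named numeric vector (tp, fn, fp, tn, V, C, window).
#' @export
setGeneric("tableCounts", function(x) standardGeneric("tableCounts"))

#' F score, precision, recall and p-value accessors
#' @param x an [AssociationResult].
#' @export
setGeneric("fscore", function(x) standardGeneric("fscore"))

#' @rdname fscore
#' @export
setGeneric("log10Pvalue", function(x) standardGeneric("log10Pvalue"))
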