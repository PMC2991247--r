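#' Scan a genome for restriction-enzyme recognition sites
#'
#' Exact occurrences of the motif and of its reverse complement on the
#' forward strand, deduplicated (a palindromic motif reports each occurrence
#' once). Overlapping occurrences are all reported. Positions are the 1-based
#' start of each occurrence.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param motif recognition sequence over A/C/G/T.
#' @param layout optional [ChromLayout-class]; defaults to the sequences in
#'   the FASTA. Every layout chromosome must have a sequence.
#' @return a [SiteSet-class] labelled with the motif.
#' @export
scanRestrictionSites <- function(fasta, motif, layout = NULL) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    inputError("motif must be a non-empty string")
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif))
    inputError(sprintf("motif may contain only A/C/G/T, got '%s'", motif))
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(layout))
    layout <- ChromLayout(names(seqs), Biostrings::width(seqs))
  missing <- setdiff(chromNames(layout), names(seqs))
  if (length(missing))
    inputError(sprintf("missing sequence for chromosome(s): %s",
                       paste(missing, collapse = ", ")))
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  chromOut <- character(0); posOut <- numeric(0)
  for (ch in chromNames(layout)) {
    hits <- Biostrings::start(Biostrings::matchPattern(fwd, seqs[[ch]]))
    if (as.character(rev) != motif)
      hits <- c(hits, Biostrings::start(Biostrings::matchPattern(rev, seqs[[ch]])))
    hits <- sort(unique(hits))
    chromOut <- c(chromOut, rep(ch, length(hits)))
    posOut <- c(posOut, hits)
  }
  SiteSet(chromOut, posOut, layout, label = motif)
}
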