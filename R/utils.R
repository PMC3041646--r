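#' @useDynLib ticfinder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "accession", "acceptor_pos", "chrom", "donor_pos",
  "exon_index", "gene_id", "junction_id", "kind", "mismatches", "n_reads",
  "pos", "read_idx", "sample_id", "strand", "target_idx", "category",
  "exon_rank", "read_id", "keep", "tstart", "tend"
))

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of plain character DNA
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract genome sequence [start, end] (1-based inclusive) on a strand.
# On "-" the reverse complement is returned, i.e. the transcribed sequence.
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom)
  }
  len <- nchar(genome[[chrom]])
  if (any(start < 1L) || any(end > len) || any(start > end)) {
    stop(sprintf("coordinates [%d, %d] outside chromosome %s (length %d)",
                 min(start), max(end), chrom, len))
  }
  s <- substring(genome[[chrom]], start, end)
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable paste-key helper for deduplication
site_key <- function(chrom, strand, pos, kind) {
  paste(chrom, strand, pos, kind, sep = ":")
}
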