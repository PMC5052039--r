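#' Read a genome FASTA into an in-memory genome object
#'
#' Sequences are held as upper-case character strings keyed by chromosome
#' name (anything after the first whitespace in the FASTA header is dropped).
#' All coordinates used against a genome object are 0-based half-open.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of class `genome_seq`.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(seqs))
  names(g) <- sub("\\s.*$", "", names(seqs))
  structure(g, class = "genome_seq")
}

#' Write a genome object to FASTA
#'
#' @param genome a `genome_seq` object or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome object
#' @param genome a `genome_seq` object.
#' @return named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  vapply(unclass(genome), nchar, integer(1))
}

#' Extract a genomic subsequence
#'
#' @param genome a `genome_seq` object.
#' @param chrom chromosome name.
#' @param start 0-based start.
#' @param end end-exclusive coordinate; the returned string has exactly
#'   `end - start` characters.
#' @return a character string.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not present in genome", call. = FALSE)
  }
  len <- nchar(genome[[chrom]])
  if (start < 0 || end < start || end > len) {
    stop(sprintf("invalid slice %s:%d-%d (length %d)", chrom, start, end, len),
         call. = FALSE)
  }
  substr(genome[[chrom]], start + 1L, end)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorized; IUPAC ambiguity codes are handled by Biostrings.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}
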