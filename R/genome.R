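#' Coerce to a genome (named DNAStringSet)
#'
#' The package represents a reference genome as a named
#' [Biostrings::DNAStringSet]: one entry per contig, uppercase A/C/G/T/N.
#' Character vectors (named) and file paths to FASTA are accepted.
#'
#' @param x A named character vector of contig sequences, a
#'   `DNAStringSet`, or the path to a FASTA file.
#' @return A named `DNAStringSet` with unique contig names.
#' @examples
#' g <- as_genome(c(chr1 = "ACGTACGTACGT"))
#' @export
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) {
    g <- x
  } else if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
             !is.na(x) && file.exists(x)) {
    g <- Biostrings::readDNAStringSet(x)
    # FASTA headers may carry descriptions; keep the first token as the name
    names(g) <- sub("\\s.*$", "", names(g))
  } else if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("character genomes must be named by contig")
    g <- Biostrings::DNAStringSet(toupper(x))
  } else {
    stop("cannot interpret 'x' as a genome")
  }
  if (anyDuplicated(names(g))) stop("duplicate contig names in genome")
  if (any(Biostrings::width(g) == 0L)) stop("empty contig sequence")
  letters <- Biostrings::uniqueLetters(g)
  if (!all(letters %in% c("A", "C", "G", "T", "N")))
    stop("genome alphabet restricted to A/C/G/T/N, found: ",
         paste(setdiff(letters, c("A", "C", "G", "T", "N")), collapse = ","))
  g
}

contig_seq <- function(genome, contig) {
  i <- match(contig, names(genome))
  if (is.na(i)) stop("contig '", contig, "' not in genome")
  genome[[i]]
}

contig_length <- function(genome, contig) {
  length(contig_seq(genome, contig))
}

#' Reverse complement of a nucleotide string
#'
#' @param s A character string over A/C/G/T/N.
#' @return The reverse complement, as a character string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

subseq_chr <- function(dna, start, end) {
  as.character(Biostrings::subseq(dna, start = start, end = end))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output file path.
#' @param descriptions Optional character vector appended after the name in
#'   each header line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, descriptions = NULL) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (!is.null(descriptions))
    names(seqs) <- paste(names(seqs), descriptions)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
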