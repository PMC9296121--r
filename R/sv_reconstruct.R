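# Flank retained by a breakend at the junction, as a character string.
# A-role flanks end with the junction-adjacent base; B-role flanks start
# with it. Truncates at contig ends with a warning.
breakend_flank <- function(genome, be, flank_len) {
  if (flank_len < 1L) stop("flank_len must be >= 1")
  validate_breakend_in_genome(be, genome)
  dna <- contig_seq(genome, be$contig)
  len <- length(dna)
  if (be$side == "upstream") {
    start <- be$pos - flank_len + 1L
    end <- be$pos
    if (start < 1L) {
      warning("flank truncated at start of contig '", be$contig, "'")
      start <- 1L
    }
  } else {
    start <- be$pos
    end <- be$pos + flank_len - 1L
    if (end > len) {
      warning("flank truncated at end of contig '", be$contig, "'")
      end <- len
    }
  }
  s <- subseq_chr(dna, start, end)
  if (be$strand == "-") s <- revcomp(s)
  s
}

#' Reconstruct the junction sequence of a structural variant
#'
#' Rebuilds the read-through sequence across an SV junction:
#' A-flank + non-templated insert + B-flank, each flank being the
#' `flank_len` reference bases retained on the stated side of its breakend,
#' reverse-complemented when the breakend strand is `-`. Whenever the two
#' retained flanks are not adjacent in the reference, the result is a
#' sequence unique to the rearranged genome — the substrate for a
#' breakpoint-spanning ddPCR assay.
#'
#' @param genome A genome acceptable to [as_genome()].
#' @param spec A [junction_spec()].
#' @param flank_len Bases of reference context retained on each side.
#' @return An object of class `junction_sequence` with fields
#'   `junction_id`, `sequence`, `junction_offset` (number of A-flank bases,
#'   i.e. the 0-based index of the first inserted/B base) and `flank_len`.
#' @examples
#' g <- as_genome(c(chr1 = "AAAACCCCGGGGTTTT"))
#' del <- junction_spec("del1", breakend("chr1", 4),
#'                      breakend("chr1", 13, "downstream"))
#' reconstruct_junction(g, del, flank_len = 4)$sequence  # "AAAATTTT"
#' @export
reconstruct_junction <- function(genome, spec, flank_len = 150L) {
  stopifnot(inherits(spec, "junction_spec"))
  genome <- as_genome(genome)
  flank_len <- as.integer(flank_len)
  if (is.na(flank_len) || flank_len < 1L)
    stop("flank_len must be a positive number of bases")
  a <- breakend_flank(genome, spec$end_a, flank_len)
  b <- breakend_flank(genome, spec$end_b, flank_len)
  structure(list(junction_id = spec$id,
                 sequence = paste0(a, spec$insert_seq, b),
                 junction_offset = nchar(a),
                 flank_len = flank_len,
                 insert_len = nchar(spec$insert_seq)),
            class = "junction_sequence")
}

#' @export
print.junction_sequence <- function(x, ...) {
  cat(sprintf("<junction_sequence %s: %d bp, breakpoint after base %d>\n",
              x$junction_id, nchar(x$sequence), x$junction_offset))
  invisible(x)
}

#' Write junction sequences to FASTA
#'
#' One record per junction; the description encodes the junction offset and
#' insert length so [read_junctions()] can round-trip the objects.
#'
#' @param junctions A list of `junction_sequence` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path) {
  if (inherits(junctions, "junction_sequence")) junctions <- list(junctions)
  seqs <- vapply(junctions, function(j) j$sequence, character(1))
  names(seqs) <- vapply(junctions, function(j) j$junction_id, character(1))
  desc <- vapply(junctions, function(j)
    sprintf("junction_offset=%d insert_len=%d flank_len=%d",
            j$junction_offset, j$insert_len, j$flank_len), character(1))
  write_fasta(seqs, path, descriptions = desc)
}

#' Read junction sequences from FASTA
#'
#' @param path FASTA written by [write_junctions()].
#' @return A list of `junction_sequence` objects.
#' @export
read_junctions <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  grab <- function(key, default = NA_integer_) {
    m <- regmatches(full, regexpr(paste0(key, "=\\d+"), full))
    out <- rep(default, length(full))
    hit <- grepl(paste0(key, "=\\d+"), full)
    out[hit] <- as.integer(sub(paste0(key, "="), "", m))
    out
  }
  off <- grab("junction_offset")
  ins <- grab("insert_len", 0L)
  fl <- grab("flank_len")
  lapply(seq_along(x), function(i) {
    structure(list(junction_id = ids[i],
                   sequence = as.character(x[[i]]),
                   junction_offset = off[i],
                   flank_len = if (is.na(fl[i])) off[i] else fl[i],
                   insert_len = ins[i]),
              class = "junction_sequence")
  })
}
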