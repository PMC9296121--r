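# Count genome-wide occurrences (both strands) of each query k-mer.
# Uses Biostrings PDict for the scan; queries must be constant width, ACGT.
count_kmer_hits <- function(genome, kmers) {
  genome <- as_genome(genome)
  kmers <- unique(kmers)
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1L)
  q_fwd <- Biostrings::DNAStringSet(kmers)
  q_rev <- Biostrings::reverseComplement(q_fwd)
  n_fwd <- n_rev <- integer(length(kmers))
  for (i in seq_along(genome)) {
    if (Biostrings::width(genome)[i] < k) next
    subject <- genome[[i]]
    n_fwd <- n_fwd + Biostrings::countPDict(Biostrings::PDict(q_fwd), subject)
    n_rev <- n_rev + Biostrings::countPDict(Biostrings::PDict(q_rev), subject)
  }
  setNames(n_fwd + n_rev, kmers)
}

max_homopolymer_run <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

string_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) character(0)
  else substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Screen junction flanks for repeats and low complexity
#'
#' An automated stand-in for manual inspection of candidate breakpoints in a
#' genome browser: junctions whose flanks fall in homopolymer stretches or
#' repetitive regions make poor PCR targets and are rejected. A flank fails
#' if it contains an ambiguous base (N), a homopolymer run longer than
#' `max_homopolymer`, or any k-mer occurring more than `max_kmer_hits` times
#' in the genome (both strands counted).
#'
#' @param genome A genome acceptable to [as_genome()].
#' @param spec A [junction_spec()].
#' @param flank_len Bases of flank examined on each side of the junction.
#' @param k k-mer size for the uniqueness scan.
#' @param max_homopolymer Longest tolerated single-base run (bases).
#' @param max_kmer_hits Highest tolerated genome-wide k-mer multiplicity; 1
#'   demands every flank k-mer be unique in the genome.
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   empty when passing, one entry per violated rule).
#' @export
repeat_screen <- function(genome, spec, flank_len = 150L, k = 15L,
                          max_homopolymer = 8L, max_kmer_hits = 1L) {
  genome <- as_genome(genome)
  stopifnot(inherits(spec, "junction_spec"))
  flank_len <- as.integer(flank_len)
  k <- as.integer(k)
  if (flank_len < k)
    stop("flank_len (", flank_len, ") must be >= k-mer size (", k, ")")
  flanks <- list(A = breakend_flank(genome, spec$end_a, flank_len),
                 B = breakend_flank(genome, spec$end_b, flank_len))
  reasons <- character(0)
  for (nm in names(flanks)) {
    fl <- flanks[[nm]]
    if (grepl("N", fl, fixed = TRUE)) {
      reasons <- c(reasons, sprintf(
        "ambiguous-base: flank %s contains N", nm))
      next  # k-mer machinery requires ACGT; other checks moot
    }
    run <- max_homopolymer_run(fl)
    if (run > max_homopolymer)
      reasons <- c(reasons, sprintf(
        "homopolymer-run: flank %s has a %d-base run (max %d)",
        nm, run, max_homopolymer))
    hits <- count_kmer_hits(genome, string_kmers(fl, k))
    bad <- hits[hits > max_kmer_hits]
    if (length(bad))
      reasons <- c(reasons, sprintf(
        "kmer-multiplicity: flank %s has %d/%d %d-mers with >%d genome hits (worst %d)",
        nm, length(bad), length(hits), k, max_kmer_hits, max(bad)))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
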