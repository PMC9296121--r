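find_exact <- function(pattern, subject_dna) {
  # start positions of exact matches of `pattern` (character) in a DNAString
  if (nchar(pattern) == 0L) stop("empty primer")
  if (nchar(pattern) > length(subject_dna)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(pattern), subject_dna, fixed = TRUE))
}

#' Exact-match in-silico PCR
#'
#' Scans every template for convergent exact matches of a primer pair: one
#' primer annealing forward on a strand and the other annealing downstream
#' on the opposite strand, with product length at most `max_product_len`.
#' No mismatches or thermodynamics — the specificity screen is exact by
#' design. Hits are reported in template coordinates (1-based inclusive),
#' with `strand` giving the strand the forward-annealing primer matched,
#' sorted by (template, start).
#'
#' @param templates Named character vector or `DNAStringSet` of template
#'   sequences (e.g. a reference genome, or a junction sequence).
#' @param forward,reverse Primer sequences (5'->3').
#' @param max_product_len Longest product reported (bp, default 1000).
#' @return A data.frame with columns `template`, `start`, `end`, `strand`,
#'   `product_len` (zero rows when nothing amplifies).
#' @export
in_silico_pcr <- function(templates, forward, reverse,
                          max_product_len = 1000L) {
  templates <- as_genome(templates)
  forward <- toupper(forward); reverse <- toupper(reverse)
  hits <- list()
  for (tn in names(templates)) {
    subject <- templates[[tn]]
    # plus-strand products: P1 forward at a, revcomp(P2) ending at b >= a
    for (orient in list(c(forward, reverse), c(reverse, forward))) {
      p1 <- orient[1]; p2 <- orient[2]
      a <- find_exact(p1, subject)
      b_start <- find_exact(revcomp(p2), subject)
      if (length(a) == 0L || length(b_start) == 0L) next
      b_end <- b_start + nchar(p2) - 1L
      for (s0 in a) {
        # the reverse-primer site must lie fully downstream of the forward
        # primer site (convergent, non-overlapping primers)
        ends <- b_end[b_start >= s0 + nchar(p1) &
                        b_end - s0 + 1L <= max_product_len]
        for (e0 in ends) {
          strand <- if (identical(p1, forward)) "+" else "-"
          hits[[length(hits) + 1L]] <- data.frame(
            template = tn, start = s0, end = e0, strand = strand,
            product_len = e0 - s0 + 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(template = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      product_len = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- unique(out)
  out <- out[order(out$template, out$start, out$end, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Specificity check of an assay against junction and reference genome
#'
#' Passes when the primer pair amplifies exactly one product from the
#' junction sequence, that product contains the junction point, and nothing
#' amplifies from the reference genome. This is the in-silico analogue of
#' validating a breakpoint assay against the unrearranged genome.
#'
#' @param design An `assay_design` from [design_assay()].
#' @param junction The `junction_sequence` the assay was designed on.
#' @param genome A genome acceptable to [as_genome()].
#' @param max_product_len Longest off-target product considered (default
#'   1000 bp).
#' @return A list with `pass` (logical), `junction_hits` and `genome_hits`
#'   (data.frames), and `reasons` (character vector).
#' @export
specificity_check <- function(design, junction, genome,
                              max_product_len = 1000L) {
  stopifnot(inherits(design, "assay_design"),
            inherits(junction, "junction_sequence"))
  jt <- setNames(junction$sequence, junction$junction_id)
  jh <- in_silico_pcr(jt, design$forward_primer$seq,
                      design$reverse_primer$seq, max_product_len)
  gh <- in_silico_pcr(genome, design$forward_primer$seq,
                      design$reverse_primer$seq, max_product_len)
  reasons <- character(0)
  if (nrow(jh) != 1L)
    reasons <- c(reasons, sprintf(
      "expected exactly 1 junction amplicon, found %d", nrow(jh)))
  else {
    jo <- junction$junction_offset
    ins <- if (is.null(junction$insert_len)) 0L else junction$insert_len
    if (!(jh$start[1] <= jo && jh$end[1] >= jo + ins + 1L))
      reasons <- c(reasons, "junction amplicon does not span the breakpoint")
  }
  if (nrow(gh) > 0L)
    reasons <- c(reasons, sprintf(
      "%d off-target product(s) in the reference genome (first: %s:%d-%d)",
      nrow(gh), gh$template[1], gh$start[1], gh$end[1]))
  list(pass = length(reasons) == 0L, junction_hits = jh, genome_hits = gh,
       reasons = reasons)
}
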