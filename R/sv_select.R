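#' Read a recurrent-aberration region list from BED
#'
#' BED input is 0-based half-open; the returned [GenomicRanges::GRanges] is
#' 1-based inclusive (the conversion is done by the reader).
#'
#' @param path Path to a BED file (chrom, start, end, name).
#' @return A `GRanges` with a `name` metadata column, sorted.
#' @export
read_region_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::sort(gr)
}

#' Default recurrent-aberration regions for ALL
#'
#' A small, user-replaceable list of genes recurrently rearranged or deleted
#' in acute lymphoblastic leukemia (TCF3, ZNF384, KRAS, IKZF1, PAX5,
#' CDKN2A/B, TLX3, CDK6, STIL, TAL1), with approximate GRCh37/hg19 spans.
#' Intended as a starting point for ranking candidate junctions; replace it
#' with a curated list for production use via the `regions` argument of
#' [select_targets()].
#'
#' @return A `GRanges` of gene regions.
#' @export
default_recurrent_regions <- function() {
  read_region_bed(system.file("extdata", "recurrent_all_regions_hg19.bed",
                              package = "svmrd", mustWork = TRUE))
}

# Does either breakend (widened by flank_len) overlap the region list?
junction_in_regions <- function(spec, regions, flank_len = 150L) {
  if (is.null(regions) || length(regions) == 0L) return(FALSE)
  pts <- GenomicRanges::GRanges(
    seqnames = c(spec$end_a$contig, spec$end_b$contig),
    ranges = IRanges::IRanges(
      start = pmax(1L, c(spec$end_a$pos, spec$end_b$pos) - flank_len),
      end = c(spec$end_a$pos, spec$end_b$pos) + flank_len))
  # region lists routinely cover contigs absent from a candidate's pair;
  # the seqlevel-mismatch warning is expected noise
  any(suppressWarnings(IRanges::overlapsAny(pts, regions)))
}

#' Select and rank junction targets for ddPCR assay design
#'
#' Applies the three selection criteria for patient-specific MRD targets:
#' (i) presence in a majority of leukemic blasts (estimated cell fraction at
#' least `min_prevalence`), (ii) a unique junction sequence (the candidate
#' must pass [repeat_screen()]), and (iii) preference for junctions touching
#' recurrent leukemia loci. Survivors are ranked by recurrent-region overlap
#' first, then prevalence (descending), then supporting reads (descending),
#' then id, and at most `max_targets` are returned.
#'
#' @param cands List of [sv_candidate()] objects.
#' @param genome A genome acceptable to [as_genome()].
#' @param regions A `GRanges` of recurrent regions (e.g.
#'   [default_recurrent_regions()]), or `NULL` to skip criterion (iii).
#' @param min_prevalence Minimum estimated cell fraction (default 0.5,
#'   "majority of blasts").
#' @param max_targets Maximum junctions returned (default 3).
#' @param flank_len,k,max_homopolymer,max_kmer_hits Passed to
#'   [repeat_screen()].
#' @return A list of [junction_spec()] objects, ranked; attribute
#'   `"selection"` holds a data.frame with per-candidate prevalence, screen
#'   outcome and rank.
#' @export
select_targets <- function(cands, genome, regions = NULL,
                           min_prevalence = 0.5, max_targets = 3L,
                           flank_len = 150L, k = 15L, max_homopolymer = 8L,
                           max_kmer_hits = 1L) {
  genome <- as_genome(genome)
  max_targets <- as.integer(max_targets)
  if (is.na(max_targets) || max_targets < 1L)
    stop("max_targets must be >= 1")
  if (length(cands) == 0L) {
    message("no SV candidates supplied; returning an empty target list")
    return(structure(list(), selection = data.frame()))
  }
  stopifnot(all(vapply(cands, inherits, logical(1), "sv_candidate")))

  info <- do.call(rbind, lapply(cands, function(cd) {
    prev <- tryCatch(estimate_prevalence(cd), error = function(e) NA_real_)
    scr <- repeat_screen(genome, cd$junction, flank_len = flank_len, k = k,
                         max_homopolymer = max_homopolymer,
                         max_kmer_hits = max_kmer_hits)
    data.frame(id = cd$junction$id,
               prevalence = prev,
               support_reads = cd$support_reads,
               screen_pass = scr$pass,
               screen_reasons = paste(scr$reasons, collapse = "; "),
               in_recurrent_region = junction_in_regions(cd$junction, regions,
                                                         flank_len),
               stringsAsFactors = FALSE)
  }))
  info$eligible <- info$screen_pass & !is.na(info$prevalence) &
    info$prevalence >= min_prevalence
  ord <- order(!info$in_recurrent_region, -info$prevalence,
               -info$support_reads, info$id)
  info <- info[ord, , drop = FALSE]
  cands <- cands[ord]
  keep <- which(info$eligible)
  info$rank <- NA_integer_
  info$rank[keep] <- seq_along(keep)
  sel <- head(keep, max_targets)
  if (length(sel) == 0L)
    message("no candidate met the selection criteria")
  out <- lapply(cands[sel], function(cd) cd$junction)
  attr(out, "selection") <- info
  out
}
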