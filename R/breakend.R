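#' Construct a breakend
#'
#' One side of a rearrangement junction. `side` states which reference flank
#' is retained at the junction: `"upstream"` keeps the bases at and 5' of
#' `pos`, `"downstream"` keeps the bases at and 3' of `pos`. `strand == "-"`
#' means the retained flank enters the junction reverse-complemented.
#'
#' In a junction the first (A) end must present its junction-adjacent base
#' last, so it is either (`upstream`, `+`) or (`downstream`, `-`); the second
#' (B) end presents its junction-adjacent base first, so it is either
#' (`downstream`, `+`) or (`upstream`, `-`).
#'
#' @param contig Contig name.
#' @param pos 1-based position of the junction-adjacent retained base.
#' @param side `"upstream"` or `"downstream"`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `breakend`.
#' @export
breakend <- function(contig, pos, side = c("upstream", "downstream"),
                     strand = c("+", "-")) {
  side <- match.arg(side)
  strand <- match.arg(strand)
  stopifnot(is.character(contig), length(contig) == 1L, nzchar(contig))
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("breakend pos must be >= 1")
  structure(list(contig = contig, pos = pos, side = side, strand = strand),
            class = "breakend")
}

#' @export
print.breakend <- function(x, ...) {
  cat(sprintf("<breakend %s:%d %s %s>\n", x$contig, x$pos, x$side, x$strand))
  invisible(x)
}

# A-role ends present their junction-adjacent base last.
is_a_role <- function(be) {
  (be$side == "upstream" && be$strand == "+") ||
    (be$side == "downstream" && be$strand == "-")
}

validate_breakend_in_genome <- function(be, genome) {
  len <- contig_length(genome, be$contig)
  if (be$pos > len)
    stop("breakend position ", be$pos, " beyond end of contig '",
         be$contig, "' (length ", len, ")")
  invisible(be)
}

#' Construct a junction specification
#'
#' A leukemia-specific junction: two breakends joined with an optional
#' non-templated insertion between them. The read-through sequence is
#' A-flank + insert + B-flank.
#'
#' @param id Junction identifier.
#' @param end_a,end_b [breakend()] objects. `end_a` must be A-role
#'   (junction-adjacent base last), `end_b` B-role.
#' @param insert_seq Non-templated insertion (possibly empty string), A/C/G/T.
#' @param sv_class One of `"deletion"`, `"reciprocal-translocation-derivative"`,
#'   `"inversion-junction"`, `"unbalanced-rearrangement"`.
#' @return An object of class `junction_spec`.
#' @export
junction_spec <- function(id, end_a, end_b, insert_seq = "",
                          sv_class = c("deletion",
                                       "reciprocal-translocation-derivative",
                                       "inversion-junction",
                                       "unbalanced-rearrangement")) {
  sv_class <- match.arg(sv_class)
  stopifnot(inherits(end_a, "breakend"), inherits(end_b, "breakend"),
            is.character(id), length(id) == 1L, nzchar(id))
  insert_seq <- toupper(insert_seq)
  if (!grepl("^[ACGT]*$", insert_seq))
    stop("insert_seq must be over A/C/G/T (possibly empty)")
  if (!is_a_role(end_a))
    stop("end_a must retain its flank 5' of the junction ",
         "(upstream/+ or downstream/-)")
  if (is_a_role(end_b))
    stop("end_b must retain its flank 3' of the junction ",
         "(downstream/+ or upstream/-)")
  structure(list(id = id, end_a = end_a, end_b = end_b,
                 insert_seq = insert_seq, sv_class = sv_class),
            class = "junction_spec")
}

#' @export
print.junction_spec <- function(x, ...) {
  cat(sprintf("<junction %s [%s]>\n", x$id, x$sv_class))
  cat(sprintf("  A: %s:%d (%s,%s)\n", x$end_a$contig, x$end_a$pos,
              x$end_a$side, x$end_a$strand))
  cat(sprintf("  B: %s:%d (%s,%s)\n", x$end_b$contig, x$end_b$pos,
              x$end_b$side, x$end_b$strand))
  if (nzchar(x$insert_seq))
    cat(sprintf("  non-templated insert: %s (%d bp)\n", x$insert_seq,
                nchar(x$insert_seq)))
  invisible(x)
}

#' Construct an SV candidate
#'
#' A junction plus its read-level evidence, as parsed from a caller VCF.
#'
#' @param junction A [junction_spec()].
#' @param support_reads Junction-supporting reads (split + discordant).
#' @param ref_reads Reference-spanning reads at the breakpoint.
#' @param caller_names Character vector of caller names.
#' @return An object of class `sv_candidate`.
#' @export
sv_candidate <- function(junction, support_reads, ref_reads,
                         caller_names = character()) {
  stopifnot(inherits(junction, "junction_spec"))
  support_reads <- as.integer(support_reads)
  ref_reads <- as.integer(ref_reads)
  if (is.na(support_reads) || support_reads < 0L)
    stop("support_reads must be a non-negative count")
  if (is.na(ref_reads) || ref_reads < 0L)
    stop("ref_reads must be a non-negative count")
  structure(list(junction = junction, support_reads = support_reads,
                 ref_reads = ref_reads,
                 caller_names = as.character(caller_names)),
            class = "sv_candidate")
}

#' @export
print.sv_candidate <- function(x, ...) {
  cat(sprintf("<sv_candidate %s: %d supporting / %d reference reads%s>\n",
              x$junction$id, x$support_reads, x$ref_reads,
              if (length(x$caller_names))
                paste0(" [", paste(x$caller_names, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Estimate the fraction of cells carrying a junction
#'
#' Under the heterozygous-autosomal assumption (one junction copy per leukemic
#' genome, two reference homologs in normal cells), the cell fraction is twice
#' the variant allele fraction, capped at 1. A per-candidate override of the
#' junction copy number is available for non-heterozygous events.
#'
#' @param cand An [sv_candidate()].
#' @param copies_per_genome Junction copies per leukemic genome (default 1).
#' @return Estimated cell fraction in \[0, 1\].
#' @examples
#' j <- junction_spec("j1", breakend("c", 10), breakend("c", 20, "downstream"))
#' estimate_prevalence(sv_candidate(j, 5, 15))  # VAF 0.25 -> half of cells
#' @export
estimate_prevalence <- function(cand, copies_per_genome = 1) {
  stopifnot(inherits(cand, "sv_candidate"))
  tot <- cand$support_reads + cand$ref_reads
  if (tot <= 0L)
    stop("prevalence unavailable: no reads at breakpoint of '",
         cand$junction$id, "'")
  vaf <- cand$support_reads / tot
  min(1, 2 * vaf / copies_per_genome)
}
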