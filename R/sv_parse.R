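# Pull a single key's value out of a raw VCF INFO string; NA when absent.
info_key <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regexpr(pat, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  hit <- m > 0
  out[hit] <- sub(pat, "\\1", regmatches(info, m), perl = TRUE)
  out
}

info_int <- function(info, key) {
  suppressWarnings(as.integer(info_key(info, key)))
}

# Decode one BND ALT (VCF 4.2 bracket notation) into junction ends plus the
# non-templated insert. Returns NULL for non-bracket ALTs; stops on malformed
# bracket records (caught and collected by the caller).
decode_bnd_alt <- function(chrom, pos, ref, alt) {
  bnd <- "([^:\\[\\]]+):([0-9]+)"
  if (grepl(paste0("^[ACGTN]+\\[", bnd, "\\[$"), alt, perl = TRUE)) {
    # t[c2:p2[ — local left flank joined to partner right flank
    seq_part <- sub("\\[.*$", "", alt)
    c2 <- sub(paste0("^[ACGTN]+\\[", bnd, "\\[$"), "\\1", alt, perl = TRUE)
    p2 <- as.integer(sub(paste0("^[ACGTN]+\\[", bnd, "\\[$"), "\\2", alt, perl = TRUE))
    list(end_a = breakend(chrom, pos, "upstream", "+"),
         end_b = breakend(c2, p2, "downstream", "+"),
         insert = substr(seq_part, nchar(ref) + 1L, nchar(seq_part)))
  } else if (grepl(paste0("^[ACGTN]+\\]", bnd, "\\]$"), alt, perl = TRUE)) {
    # t]c2:p2] — local left flank joined to reverse-complemented partner
    # left flank (inversion-type)
    seq_part <- sub("\\].*$", "", alt)
    c2 <- sub(paste0("^[ACGTN]+\\]", bnd, "\\]$"), "\\1", alt, perl = TRUE)
    p2 <- as.integer(sub(paste0("^[ACGTN]+\\]", bnd, "\\]$"), "\\2", alt, perl = TRUE))
    list(end_a = breakend(chrom, pos, "upstream", "+"),
         end_b = breakend(c2, p2, "upstream", "-"),
         insert = substr(seq_part, nchar(ref) + 1L, nchar(seq_part)))
  } else if (grepl(paste0("^\\]", bnd, "\\][ACGTN]+$"), alt, perl = TRUE)) {
    # ]c2:p2]t — partner left flank joined to local right flank
    seq_part <- sub("^.*\\]", "", alt)
    c2 <- sub(paste0("^\\]", bnd, "\\][ACGTN]+$"), "\\1", alt, perl = TRUE)
    p2 <- as.integer(sub(paste0("^\\]", bnd, "\\][ACGTN]+$"), "\\2", alt, perl = TRUE))
    list(end_a = breakend(c2, p2, "upstream", "+"),
         end_b = breakend(chrom, pos, "downstream", "+"),
         insert = substr(seq_part, 1L, nchar(seq_part) - nchar(ref)))
  } else if (grepl(paste0("^\\[", bnd, "\\[[ACGTN]+$"), alt, perl = TRUE)) {
    # [c2:p2[t — reverse-complemented partner right flank joined to local
    # right flank (inversion-type)
    seq_part <- sub("^.*\\[", "", alt)
    c2 <- sub(paste0("^\\[", bnd, "\\[[ACGTN]+$"), "\\1", alt, perl = TRUE)
    p2 <- as.integer(sub(paste0("^\\[", bnd, "\\[[ACGTN]+$"), "\\2", alt, perl = TRUE))
    list(end_a = breakend(c2, p2, "downstream", "-"),
         end_b = breakend(chrom, pos, "downstream", "+"),
         insert = substr(seq_part, 1L, nchar(seq_part) - nchar(ref)))
  } else if (grepl("[][]", alt)) {
    stop("malformed BND bracket notation: '", alt, "'")
  } else {
    NULL
  }
}

bnd_sv_class <- function(end_a, end_b) {
  if (end_a$contig != end_b$contig) return("reciprocal-translocation-derivative")
  if (end_a$strand != end_b$strand) return("inversion-junction")
  if (end_a$side == "upstream" && end_b$side == "downstream" &&
      end_a$pos < end_b$pos) return("deletion")
  "unbalanced-rearrangement"
}

# Canonical mate of a BND pair: the record whose own coordinate sorts first.
bnd_is_canonical <- function(chrom, pos, mate_chrom, mate_pos) {
  if (chrom != mate_chrom) return(order(c(chrom, mate_chrom))[1] == 1L)
  if (pos != mate_pos) return(pos < mate_pos)
  TRUE  # degenerate self-mate: keep
}

#' Parse structural-variant calls from a VCF
#'
#' Adapter from SV-caller output to the package's candidate model. Breakend
#' (BND) records with bracket notation and symbolic `<DEL>`/`<INV>` records
#' with INFO `END` are supported. Each BND mate pair yields one candidate
#' (the mate with the lower coordinate is canonical); a symbolic deletion of
#' region \[s, e\] yields the junction joining the upstream flank at s-1 to
#' the downstream flank at e+1; a symbolic inversion yields its two
#' junctions. Records on contigs absent from `genome` are skipped with a
#' warning; malformed bracket records are collected (attribute `"errors"`),
#' not fatal.
#'
#' @param vcf_path Path to a VCF 4.x file.
#' @param genome A genome acceptable to [as_genome()].
#' @param support_keys INFO keys summed for junction-supporting reads.
#' @param ref_key INFO key holding reference-spanning reads.
#' @param caller_key INFO key holding the caller name.
#' @return A list of [sv_candidate()] objects; attribute `"errors"` holds
#'   per-record parse errors (character vector, possibly empty).
#' @export
parse_sv_calls <- function(vcf_path, genome,
                           support_keys = c("SR", "PE"),
                           ref_key = "RO", caller_key = "CALLER") {
  genome <- as_genome(genome)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix)))  # single record drops to a vector
    fix <- t(as.matrix(fix))
  if (is.null(fix) || nrow(fix) == 0L)
    return(structure(list(), errors = character(0)))
  info <- vcfR::getINFO(vcf)
  chrom <- unname(fix[, "CHROM"])
  pos <- as.integer(unname(fix[, "POS"]))
  id <- unname(fix[, "ID"])
  ref <- unname(fix[, "REF"])
  alt <- unname(fix[, "ALT"])
  id[is.na(id) | id == "."] <- paste0("sv_", seq_len(nrow(fix)))[
    is.na(id) | id == "."]

  support <- rep(0L, nrow(fix))
  for (kk in support_keys) {
    v <- info_int(info, kk)
    support <- support + ifelse(is.na(v), 0L, v)
  }
  refr <- info_int(info, ref_key)
  refr[is.na(refr)] <- 0L
  caller <- info_key(info, caller_key)

  out <- list()
  errors <- character(0)
  for (i in seq_len(nrow(fix))) {
    rec <- tryCatch({
      if (alt[i] %in% c("<DEL>", "<INV>")) {
        e <- info_int(info[i], "END")
        if (is.na(e)) stop("symbolic ALT without INFO END")
        if (!(chrom[i] %in% names(genome))) {
          warning("skipping record on contig '", chrom[i],
                  "' absent from genome")
          NULL
        } else if (alt[i] == "<DEL>") {
          list(list(id = id[i],
                    end_a = breakend(chrom[i], pos[i], "upstream", "+"),
                    end_b = breakend(chrom[i], e + 1L, "downstream", "+"),
                    insert = "", sv_class = "deletion"))
        } else {
          list(list(id = paste0(id[i], "_jxn1"),
                    end_a = breakend(chrom[i], pos[i], "upstream", "+"),
                    end_b = breakend(chrom[i], e, "upstream", "-"),
                    insert = "", sv_class = "inversion-junction"),
               list(id = paste0(id[i], "_jxn2"),
                    end_a = breakend(chrom[i], pos[i] + 1L, "downstream", "-"),
                    end_b = breakend(chrom[i], e + 1L, "downstream", "+"),
                    insert = "", sv_class = "inversion-junction"))
        }
      } else {
        d <- decode_bnd_alt(chrom[i], pos[i], ref[i], alt[i])
        if (is.null(d)) NULL  # not an SV record (SNV/indel): ignore
        else {
          mate_end <- if (d$end_a$contig == chrom[i] && d$end_a$pos == pos[i])
            d$end_b else d$end_a
          if (!bnd_is_canonical(chrom[i], pos[i],
                                mate_end$contig, mate_end$pos)) NULL
          else if (!(chrom[i] %in% names(genome)) ||
                   !(mate_end$contig %in% names(genome))) {
            warning("skipping BND '", id[i], "' on contig absent from genome")
            NULL
          } else {
            list(list(id = id[i], end_a = d$end_a, end_b = d$end_b,
                      insert = d$insert,
                      sv_class = bnd_sv_class(d$end_a, d$end_b)))
          }
        }
      }
    }, error = function(e) {
      errors <<- c(errors, sprintf("record %d (%s): %s", i, id[i],
                                   conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) next
    for (r in rec) {
      js <- junction_spec(r$id, r$end_a, r$end_b, insert_seq = r$insert,
                          sv_class = r$sv_class)
      out[[length(out) + 1L]] <- sv_candidate(
        js, support_reads = support[i], ref_reads = refr[i],
        caller_names = if (is.na(caller[i])) character(0) else
          strsplit(caller[i], ",", fixed = TRUE)[[1]])
    }
  }
  structure(out, errors = errors)
}
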