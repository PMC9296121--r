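#' Read a well-count table
#'
#' Documented CSV dialect: columns `sample_id`, `well_id`, `n_total`,
#' `n_target_pos`, `n_ref_pos`; one row per well. Lines starting with `#`
#' (e.g. a seed header written by the simulator) are ignored.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_well_counts <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "well_id", "n_total", "n_target_pos", "n_ref_pos")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("well-count table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a sample-metadata table
#'
#' Documented CSV dialect: columns `sample_id`, `compartment` (`BM-gDNA`,
#' `plasma-cfDNA` or `CSF-cfDNA`), `n_targets`, `volume_ml`, `mass_ng`,
#' `dilution`, `timepoint_day`; optional `patient_id`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "compartment", "n_targets", "volume_ml", "mass_ng",
            "dilution", "timepoint_day")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a dilution-series table
#'
#' Documented CSV dialect: columns `assay_id`, `dilution`, `well_id`,
#' `n_total`, `n_target_pos`, `n_ref_pos`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_dilution_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("assay_id", "dilution", "well_id", "n_total", "n_target_pos",
            "n_ref_pos")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dilution series missing column(s): ", paste(miss, collapse = ", "))
  df
}

sample_spec_from_meta <- function(row) {
  sample_spec(row$sample_id, row$compartment,
              n_targets_multiplexed = row$n_targets,
              liquid_volume_ml = if (is.na(row$volume_ml)) NA_real_ else
                row$volume_ml,
              dna_mass_ng = if (is.na(row$mass_ng)) NA_real_ else row$mass_ng,
              dilution = if (is.na(row$dilution)) 1 else row$dilution)
}

#' Quantify every sample in a counts/metadata pair
#'
#' @param counts Well-count data.frame ([read_well_counts()] dialect).
#' @param meta Sample-metadata data.frame ([read_sample_meta()] dialect).
#' @return A data.frame with one row per sample: merged counts, copies,
#'   positivity, CN/ml, ratio and its report rendering.
#' @export
quantify_samples <- function(counts, meta) {
  out <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    wc <- counts[counts$sample_id == row$sample_id, , drop = FALSE]
    if (nrow(wc) == 0L) {
      warning("no wells for sample '", row$sample_id, "'; skipped")
      return(NULL)
    }
    spec <- sample_spec_from_meta(row)
    wells <- lapply(seq_len(nrow(wc)), function(j)
      suppressWarnings(well_counts(wc$well_id[j], wc$n_total[j],
                                   wc$n_target_pos[j], wc$n_ref_pos[j])))
    q <- quantify_sample(wells, spec)
    data.frame(sample_id = q$sample_id,
               patient_id = if ("patient_id" %in% names(row))
                 row$patient_id else NA_character_,
               compartment = q$compartment,
               timepoint_day = row$timepoint_day,
               n_wells = nrow(wc),
               n_total = q$merged$n_total,
               n_target_pos = q$merged$n_target_pos,
               n_ref_pos = q$merged$n_ref_pos,
               target_copies = q$target_copies,
               ref_copies = q$ref_copies,
               positivity = q$positivity,
               target_cn_per_ml = q$target_cn_per_ml,
               ref_cn_per_ml = q$ref_cn_per_ml,
               ratio_percent = q$ratio_percent,
               ratio_display = format_ratio_percent(q$ratio_percent,
                                                    q$positivity == "trace",
                                                    q$positivity ==
                                                      "not_detected"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame()
  out
}

#' Format a ratio percentage for reports
#'
#' Table conventions: values of at least 0.01% print with 2 decimals,
#' smaller positive values with 4 decimals; trace values are parenthesized;
#' not-detected renders as `"ND"`; whole-percent style rounds to an integer
#' (used for CSF summaries).
#'
#' @param x Ratio in percent.
#' @param trace Parenthesize (trace amount)?
#' @param nd Render as not detected?
#' @param whole Round to a whole percent?
#' @return A character scalar.
#' @export
format_ratio_percent <- function(x, trace = FALSE, nd = FALSE,
                                 whole = FALSE) {
  if (nd) return("ND")
  if (is.na(x)) return("NA")
  s <- if (whole) sprintf("%d", round(x))
  else if (x >= 0.01 || x == 0) sprintf("%.2f", x)
  else sprintf("%.4f", x)
  if (trace) paste0("(", s, ")") else s
}

#' Write an assay sheet (TSV + JSON)
#'
#' One row per oligo: junction id, role, sequence, 1-based start/end on the
#' junction sequence, strand, Tm and amplicon length.
#'
#' @param designs A list of `assay_design` objects (failures are skipped
#'   with a note column in the JSON).
#' @param tsv_path,json_path Output paths (`NULL` to skip one format).
#' @return The TSV data.frame, invisibly.
#' @export
write_assay_sheet <- function(designs, tsv_path = NULL, json_path = NULL) {
  if (inherits(designs, "assay_design") ||
      inherits(designs, "assay_design_failure")) designs <- list(designs)
  rows <- list()
  failures <- list()
  for (d in designs) {
    if (inherits(d, "assay_design_failure")) {
      failures[[length(failures) + 1L]] <-
        list(junction_id = d$junction_id, reasons = d$reasons)
      next
    }
    oligos <- c(list(list(role = "forward_primer", o = d$forward_primer,
                          strand = "+"),
                     list(role = "reverse_primer", o = d$reverse_primer,
                          strand = "-")),
                lapply(seq_along(d$probes), function(i)
                  list(role = paste0("probe", i), o = d$probes[[i]],
                       strand = d$probes[[i]]$strand)))
    for (ol in oligos) {
      rows[[length(rows) + 1L]] <- data.frame(
        junction_id = d$junction_id, role = ol$role, sequence = ol$o$seq,
        start = ol$o$start, end = ol$o$end, strand = ol$strand,
        tm = round(ol$o$tm, 2), amplicon_length = d$amplicon$length,
        stringsAsFactors = FALSE)
    }
  }
  sheet <- if (length(rows)) do.call(rbind, rows) else
    data.frame(junction_id = character(0), role = character(0),
               sequence = character(0), start = integer(0), end = integer(0),
               strand = character(0), tm = numeric(0),
               amplicon_length = integer(0))
  if (!is.null(tsv_path))
    write.table(sheet, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(oligos = sheet, failures = failures),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(sheet)
}

#' Write simulator outputs in the package's input dialects
#'
#' Emits a well-count CSV (and optionally metadata / dilution-series CSVs)
#' with the seed recorded in a `#` header comment, so every fixture is
#' self-describing.
#'
#' @param df The data.frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# simulated with svmrd, seed=%s", seed), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a minimal SV VCF for simulated junctions
#'
#' Emits VCF 4.2 with symbolic `<DEL>` records for deletions and BND
#' bracket-notation mate pairs for other junction classes, carrying the
#' package's INFO dialect (SR/PE support, RO reference reads, CALLER).
#'
#' @param specs List of [junction_spec()] objects.
#' @param genome The genome the specs refer to (for contig headers and
#'   anchor bases).
#' @param path Output VCF path.
#' @param support,ref_reads Per-junction read support (recycled).
#' @param caller Caller name written to INFO.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(specs, genome, path, support = 30L,
                          ref_reads = 30L, caller = "svmrd-sim") {
  genome <- as_genome(genome)
  if (inherits(specs, "junction_spec")) specs <- list(specs)
  support <- rep_len(as.integer(support), length(specs))
  ref_reads <- rep_len(as.integer(ref_reads), length(specs))
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(genome),
                     Biostrings::width(genome)),
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split reads\">",
             "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Discordant pairs\">",
             "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference-spanning reads\">",
             "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Caller\">",
             "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
  base_at <- function(ctg, pos)
    subseq_chr(contig_seq(genome, ctg), pos, pos)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    inf <- sprintf("SR=%d;PE=0;RO=%d;CALLER=%s", support[i], ref_reads[i],
                   caller)
    if (sp$sv_class == "deletion" && sp$end_a$contig == sp$end_b$contig &&
        nchar(sp$insert_seq) == 0L) {
      lines <- c(lines, paste(
        sp$end_a$contig, sp$end_a$pos, sp$id,
        base_at(sp$end_a$contig, sp$end_a$pos), "<DEL>", ".", "PASS",
        sprintf("SVTYPE=DEL;END=%d;%s", sp$end_b$pos - 1L, inf),
        sep = "\t"))
    } else {
      # BND mate pair; the end_a record is canonical in the read-through
      # orientation, its mate the symmetric decoding
      a <- sp$end_a; b <- sp$end_b
      ref_a <- base_at(a$contig, a$pos)
      ref_b <- base_at(b$contig, b$pos)
      alt_a <- if (b$side == "downstream" && b$strand == "+")
        sprintf("%s%s[%s:%d[", ref_a, sp$insert_seq, b$contig, b$pos)
      else  # (upstream, -) inversion-type partner
        sprintf("%s%s]%s:%d]", ref_a, sp$insert_seq, b$contig, b$pos)
      alt_b <- if (b$side == "downstream" && b$strand == "+")
        sprintf("]%s:%d]%s%s", a$contig, a$pos, sp$insert_seq, ref_b)
      else
        sprintf("%s%s]%s:%d]", ref_b, revcomp(sp$insert_seq), a$contig,
                a$pos)
      lines <- c(lines, paste(
        a$contig, a$pos, paste0(sp$id, "_1"), ref_a, alt_a, ".", "PASS",
        sprintf("SVTYPE=BND;MATEID=%s_2;%s", sp$id, inf), sep = "\t"))
      lines <- c(lines, paste(
        b$contig, b$pos, paste0(sp$id, "_2"), ref_b, alt_b, ".", "PASS",
        sprintf("SVTYPE=BND;MATEID=%s_1;%s", sp$id, inf), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
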