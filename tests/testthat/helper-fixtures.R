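# Shared fixtures and independent brute-force oracles for the suite.

# deterministic random sequence without touching the global RNG stream
# of the test that calls it
rand_seq <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# character-level reverse complement written independently of the package
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# brute-force genome-wide k-mer count (both strands) by substring scan
bf_kmer_count <- function(contigs, kmer) {
  k <- nchar(kmer)
  total <- 0L
  for (s in contigs) {
    n <- nchar(s)
    if (n < k) next
    subs <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    total <- total + sum(subs == kmer) + sum(subs == rc_chr(kmer))
  }
  total
}

# brute-force all-pairs in-silico PCR over one template string
bf_pcr <- function(template, fwd, rev, max_len) {
  n <- nchar(template)
  occ <- function(p) {
    k <- nchar(p)
    if (k > n) return(integer(0))
    which(substring(template, seq_len(n - k + 1L),
                    seq_len(n - k + 1L) + k - 1L) == p)
  }
  hits <- list()
  for (orient in list(list(p1 = fwd, p2 = rev, strand = "+"),
                      list(p1 = rev, p2 = fwd, strand = "-"))) {
    a <- occ(orient$p1)
    b <- occ(rc_chr(orient$p2))
    for (s0 in a) for (b0 in b) {
      e0 <- b0 + nchar(orient$p2) - 1L
      if (b0 >= s0 + nchar(orient$p1) && e0 - s0 + 1L <= max_len)
        hits[[length(hits) + 1L]] <- list(start = s0, end = e0,
                                          strand = orient$strand)
    }
  }
  hits
}

# a balanced-composition junction sequence for design tests: two unique
# random flanks joined at the middle
toy_junction <- function(len = 240L, seed = 101, insert = "") {
  half <- len %/% 2L
  structure(list(junction_id = "toy",
                 sequence = paste0(rand_seq(half, seed), insert,
                                   rand_seq(half, seed + 1L)),
                 junction_offset = half,
                 flank_len = half,
                 insert_len = nchar(insert)),
            class = "junction_sequence")
}

# wells data.frame -> list of well_counts
as_wells <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    suppressWarnings(well_counts(df$well_id[i], df$n_total[i],
                                 df$n_target_pos[i], df$n_ref_pos[i])))
}

# write a minimal VCF body with the given data lines
write_test_vcf <- function(lines, contigs = c(chr1 = 16L)) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       contigs),
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"s\">",
               "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"p\">",
               "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"r\">",
               "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"c\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               lines), path)
  path
}
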