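test_that("symbolic DEL, BND mate pairs and empty VCFs parse correctly", {
  g16 <- as_genome(c(chr1 = "AAAACCCCGGGGTTTT"))
  # deletion of positions 5-12: anchored at 4, END = 12
  vcf <- write_test_vcf(paste("chr1", 4, "del1", "A", "<DEL>", ".", "PASS",
                              "SVTYPE=DEL;END=12;SR=12;PE=3;RO=5;CALLER=sim",
                              sep = "\t"))
  cands <- parse_sv_calls(vcf, g16)
  expect_length(cands, 1L)
  j <- cands[[1]]$junction
  expect_equal(j$end_a$pos, 4L)
  expect_equal(j$end_a$side, "upstream")
  expect_equal(j$end_b$pos, 13L)
  expect_equal(j$end_b$side, "downstream")
  expect_equal(j$sv_class, "deletion")
  expect_equal(cands[[1]]$support_reads, 15L)  # SR + PE
  expect_equal(cands[[1]]$ref_reads, 5L)
  expect_equal(cands[[1]]$caller_names, "sim")

  # a reciprocal translocation: two junctions, each a BND mate pair
  gtx <- as_genome(c(chrA = strrep("ACGT", 10), chrB = strrep("TTGCA", 8)))
  lines <- c(
    paste("chrA", 8, "t_der1_1", "T", "T[chrB:21[", ".", "PASS",
          "SVTYPE=BND;SR=10;RO=10", sep = "\t"),
    paste("chrB", 21, "t_der1_2", "T", "]chrA:8]T", ".", "PASS",
          "SVTYPE=BND;SR=10;RO=10", sep = "\t"),
    paste("chrB", 20, "t_der2_1", "A", "A[chrA:9[", ".", "PASS",
          "SVTYPE=BND;SR=8;RO=12", sep = "\t"),
    paste("chrA", 9, "t_der2_2", "C", "]chrB:20]C", ".", "PASS",
          "SVTYPE=BND;SR=8;RO=12", sep = "\t"))
  vcf2 <- write_test_vcf(lines, contigs = c(chrA = 40L, chrB = 40L))
  cands2 <- parse_sv_calls(vcf2, gtx)
  expect_length(cands2, 2L)  # one candidate per derivative, mates deduped
  expect_setequal(
    vapply(cands2, function(cd) cd$junction$sv_class, character(1)),
    rep("reciprocal-translocation-derivative", 2))

  # empty body -> empty list; malformed bracket -> collected, not fatal
  vcf3 <- write_test_vcf(character(0))
  expect_length(parse_sv_calls(vcf3, g16), 0L)
  vcf4 <- write_test_vcf(paste("chr1", 4, "bad", "A", "A[chr1:", ".",
                               "PASS", "SVTYPE=BND", sep = "\t"))
  cands4 <- parse_sv_calls(vcf4, g16)
  expect_length(cands4, 0L)
  expect_match(attr(cands4, "errors"), "malformed", all = TRUE)
  expect_length(attr(cands4, "errors"), 1L)

  # record on a contig absent from the genome is skipped with a warning
  vcf5 <- write_test_vcf(paste("chrZ", 4, "z1", "A", "<DEL>", ".", "PASS",
                               "SVTYPE=DEL;END=12", sep = "\t"),
                         contigs = c(chrZ = 16L))
  expect_warning(cands5 <- parse_sv_calls(vcf5, g16), "absent")
  expect_length(cands5, 0L)
})

test_that("non-templated inserts in BND records survive the round trip", {
  g <- as_genome(c(chr1 = "AAAACCCCGGGGTTTT"))
  vcf <- write_test_vcf(paste("chr1", 4, "ins1", "A", "AGA[chr1:13[", ".",
                              "PASS", "SVTYPE=BND;SR=10;RO=10", sep = "\t"))
  cands <- parse_sv_calls(vcf, g)
  expect_equal(cands[[1]]$junction$insert_seq, "GA")
  rec <- reconstruct_junction(g, cands[[1]]$junction, flank_len = 4)
  expect_equal(rec$sequence, "AAAAGATTTT")
})

test_that("prevalence follows the heterozygous cell-fraction model", {
  j <- junction_spec("j", breakend("c", 10), breakend("c", 20, "downstream"))
  expect_equal(estimate_prevalence(sv_candidate(j, 10, 10)), 1.0)
  expect_equal(estimate_prevalence(sv_candidate(j, 5, 15)), 0.5)
  expect_equal(estimate_prevalence(sv_candidate(j, 0, 20)), 0.0)
  expect_error(estimate_prevalence(sv_candidate(j, 0, 0)), "no reads")
  # copy-number override halves the inferred fraction
  expect_equal(estimate_prevalence(sv_candidate(j, 10, 10),
                                   copies_per_genome = 2), 0.5)
})

test_that("junction reconstruction reads flanks off the reference", {
  g <- as_genome(c(chr1 = "AAAACCCCGGGGTTTT"))
  del <- junction_spec("d", breakend("chr1", 4),
                       breakend("chr1", 13, "downstream"))
  r <- reconstruct_junction(g, del, flank_len = 4)
  expect_equal(r$sequence, "AAAATTTT")
  expect_equal(r$junction_offset, 4L)

  del_ins <- junction_spec("di", breakend("chr1", 4),
                           breakend("chr1", 13, "downstream"),
                           insert_seq = "GA")
  ri <- reconstruct_junction(g, del_ins, flank_len = 4)
  expect_equal(ri$sequence, "AAAAGATTTT")
  expect_equal(ri$junction_offset, 4L)

  # flank truncation at both contig ends warns once per flank
  w <- capture_warnings(rt <- reconstruct_junction(g, del, flank_len = 10))
  expect_length(w, 2L)
  expect_match(w, "truncated", all = TRUE)
  expect_equal(rt$junction_offset, 4L)
  expect_error(reconstruct_junction(g, del, flank_len = 0), "positive")
})

test_that("minus-strand flanks are reverse-complemented at the junction", {
  ctg <- "ACGTTGCAAGCTTGGCACGT"  # 20 bp toy contig
  g <- as_genome(c(cx = ctg))
  # inversion-type junction: plus-strand left flank at 8 joined to the
  # reverse-complemented left flank at 17
  inv <- junction_spec("inv", breakend("cx", 8),
                       breakend("cx", 17, "upstream", "-"),
                       sv_class = "inversion-junction")
  r <- reconstruct_junction(g, inv, flank_len = 4)
  # manual oracle: A-flank = bases 5..8; B-flank = revcomp(bases 14..17)
  expect_equal(r$sequence,
               paste0(substr(ctg, 5, 8), rc_chr(substr(ctg, 14, 17))))
})

test_that("repeat screen rejects homopolymers, Ns and repeated k-mers", {
  flank_a <- "AAAAAAAAAAGTCGATCGGTACGATCGA"  # run of 10
  uniq <- rand_seq(400, 7)
  g <- as_genome(c(c1 = paste0(flank_a, uniq)))
  sp <- junction_spec("h", breakend("c1", 28),
                      breakend("c1", 100, "downstream"))
  res <- repeat_screen(g, sp, flank_len = 28, k = 15, max_homopolymer = 8)
  expect_false(res$pass)
  expect_match(res$reasons, "homopolymer-run", all = FALSE)

  # unique random genome: flanks pass, and the package's k-mer counter
  # agrees with the brute-force census
  g2 <- make_genome(sim_config(seed = 23), n_contigs = 1,
                    contig_len = 4000)
  sp2 <- junction_spec("u", breakend("ctg1", 1000),
                       breakend("ctg1", 3000, "downstream"))
  expect_true(repeat_screen(g2, sp2, flank_len = 60)$pass)
  s2 <- as.character(g2[[1]])
  some_kmers <- substring(s2, c(1, 500, 986), c(15, 514, 1000))
  hits <- svmrd:::count_kmer_hits(g2, some_kmers)
  expect_equal(unname(hits),
               vapply(some_kmers, function(k) bf_kmer_count(s2, k),
                      integer(1), USE.NAMES = FALSE))

  # triplicated segment: every flank 15-mer occurs 3x > 2
  seg <- rand_seq(300, 9)
  g3 <- as_genome(c(c3 = paste0(seg, seg, seg)))
  sp3 <- junction_spec("r", breakend("c3", 150),
                       breakend("c3", 200, "downstream"))
  res3 <- repeat_screen(g3, sp3, flank_len = 30, max_kmer_hits = 2)
  expect_false(res3$pass)
  expect_match(res3$reasons, "kmer-multiplicity", all = FALSE)
  expect_match(res3$reasons, "worst 3", all = FALSE)
  expect_equal(bf_kmer_count(paste0(seg, seg, seg), substr(seg, 100, 114)),
               3L)

  # ambiguous base in a flank fails; flank shorter than k errors
  g4 <- as_genome(c(c4 = paste0(rand_seq(100, 3), "N", rand_seq(100, 4))))
  sp4 <- junction_spec("n", breakend("c4", 105),
                       breakend("c4", 150, "downstream"))
  res4 <- repeat_screen(g4, sp4, flank_len = 20)
  expect_false(res4$pass)
  expect_match(res4$reasons, "ambiguous-base", all = FALSE)
  expect_error(repeat_screen(g4, sp4, flank_len = 10, k = 15), "k-mer size")
})

test_that("target selection applies prevalence, screen and region ranking", {
  g <- make_genome(sim_config(seed = 31), n_contigs = 2, contig_len = 4000)
  mk <- function(id, contig, p1, sup, ref) {
    sv_candidate(junction_spec(id, breakend(contig, p1),
                               breakend(contig, p1 + 800, "downstream")),
                 sup, ref)
  }
  cands <- list(mk("c_low", "ctg1", 500, 5, 25),    # prevalence 1/3
                mk("b_plain", "ctg1", 1500, 20, 20),
                mk("a_plain", "ctg2", 400, 20, 20),
                mk("d_region", "ctg2", 1500, 15, 25),
                mk("e_region", "ctg2", 2500, 18, 22))
  regions <- GenomicRanges::GRanges(
    "ctg2", IRanges::IRanges(start = c(1400, 2400), end = c(1700, 2700)))
  sel <- select_targets(cands, g, regions, min_prevalence = 0.5,
                        max_targets = 3)
  ids <- vapply(sel, `[[`, character(1), "id")
  # region-overlapping candidates first (by prevalence), low-prevalence gone
  expect_equal(ids, c("e_region", "d_region", "a_plain"))
  # max_targets caps the output; 4 candidates are eligible here
  sel2 <- select_targets(cands, g, regions, max_targets = 2)
  expect_length(sel2, 2L)
  info <- attr(sel, "selection")
  expect_false(info$eligible[info$id == "c_low"])
  # ties on region/prevalence/support resolve lexicographically by id
  sel3 <- select_targets(cands[2:3], g, regions = NULL, max_targets = 2)
  expect_equal(vapply(sel3, `[[`, character(1), "id"),
               c("a_plain", "b_plain"))
  # empty input: empty result with a notice
  expect_message(sel4 <- select_targets(list(), g, NULL), "empty")
  expect_length(sel4, 0L)
})

test_that("selection output is deterministic and a subset of the input", {
  g <- make_genome(sim_config(seed = 31), n_contigs = 2, contig_len = 4000)
  cands <- lapply(1:5, function(i)
    sv_candidate(junction_spec(sprintf("j%d", i),
                               breakend("ctg1", 300 * i),
                               breakend("ctg2", 300 * i, "downstream")),
                 10 + i, 10))
  s1 <- select_targets(cands, g, NULL)
  s2 <- select_targets(cands, g, NULL)
  expect_identical(vapply(s1, `[[`, character(1), "id"),
                   vapply(s2, `[[`, character(1), "id"))
  expect_true(all(vapply(s1, `[[`, character(1), "id") %in%
                    vapply(cands, function(cd) cd$junction$id,
                           character(1))))
  expect_lte(length(s1), 3L)
})

test_that("simulated junctions round-trip and are absent from the genome", {
  panel <- simulate_junction_panel(n_junctions = 6,
                                   config = sim_config(seed = 11))
  for (i in seq_along(panel$specs)) {
    rec <- reconstruct_junction(panel$genome, panel$specs[[i]],
                                flank_len = 150)
    expect_identical(rec$sequence, panel$svs[[i]]$read_through)
    # novelty: junction sequence absent from the reference, both strands
    n_hits <- sum(Biostrings::vcountPattern(rec$sequence, panel$genome)) +
      sum(Biostrings::vcountPattern(revcomp(rec$sequence), panel$genome))
    expect_equal(n_hits, 0L)
  }
})
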