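test_that("nearest-neighbor Tm behaves like duplex thermodynamics", {
  # GC stabilization ordering
  expect_lt(melting_temperature("AAAAAAAAAA"),
            melting_temperature("GCGCGCGCGC"))
  # duplex symmetry: an oligo and its reverse complement share one Tm
  for (seed in 1:5) {
    o <- rand_seq(22, seed)
    expect_equal(melting_temperature(o), melting_temperature(rc_chr(o)))
  }
  # frozen values from an independent dinucleotide-table hand sum
  # (SantaLucia unified parameters, 50 mM monovalent + 3.8 mM divalent,
  # 250 nM strands)
  expect_equal(melting_temperature("ACGTTGCAAGCTTGGCACGT"), 69.1439,
               tolerance = 1e-4)
  expect_equal(melting_temperature("GATTACAGATTACAGATTAC"), 50.7946,
               tolerance = 1e-4)
  expect_equal(melting_temperature("CCGGAACCTTGGAACCGGTT"), 67.8455,
               tolerance = 1e-4)
  expect_error(melting_temperature("ACGTNACGTNACGT"), "ACGT")
  expect_error(melting_temperature("ACGT"), "at least 8")
})

test_that("assay design yields a sub-100 bp breakpoint-spanning layout", {
  jj <- toy_junction(240, seed = 101)
  cs <- design_constraints()
  d <- design_assay(jj, cs)
  expect_s3_class(d, "assay_design")
  expect_lt(d$amplicon$length, 100)
  # probe strictly contains the junction point with the required overhang
  pr <- d$probes[[1]]
  expect_lte(pr$start, jj$junction_offset - cs$min_probe_overhang + 1L)
  expect_gte(pr$end, jj$junction_offset + cs$min_probe_overhang)
  # independent re-validation
  v <- validate_assay_design(d, jj, cs)
  expect_true(v$ok)
  # an insert-bearing junction is covered insert and all
  jji <- toy_junction(240, seed = 77, insert = "GATTACAA")
  di <- design_assay(jji, cs)
  expect_s3_class(di, "assay_design")
  expect_true(validate_assay_design(di, jji, cs)$ok)
})

test_that("designs are byte-identical across repeated runs", {
  jj <- toy_junction(240, seed = 55)
  expect_identical(design_assay(jj), design_assay(jj))
})

test_that("double-probe mode places opposite-strand probes over the junction", {
  cs <- design_constraints(double_probe = TRUE)
  jj <- toy_junction(240, seed = 101)
  d <- design_assay(jj, cs)
  expect_s3_class(d, "assay_design")
  expect_length(d$probes, 2L)
  expect_setequal(vapply(d$probes, `[[`, character(1), "strand"),
                  c("+", "-"))
  p1 <- d$probes[[1]]; p2 <- d$probes[[2]]
  expect_true(p1$end < p2$start || p2$end < p1$start)
  expect_true(validate_assay_design(d, jj, cs)$ok)
})

test_that("impossible layouts fail with constraint-naming reasons", {
  # B-flank is a 60 bp homopolymer: no valid reverse primer can exist
  jj <- structure(list(junction_id = "homo",
                       sequence = paste0(rand_seq(120, 8), strrep("A", 120)),
                       junction_offset = 120L, flank_len = 120L,
                       insert_len = 0L),
                  class = "junction_sequence")
  d <- design_assay(jj)
  expect_s3_class(d, "assay_design_failure")
  expect_match(d$reasons, "reverse primer|probe", all = FALSE)
  # junction shorter than the minimal layout errors outright
  short <- structure(list(junction_id = "s", sequence = rand_seq(60, 9),
                          junction_offset = 30L, flank_len = 30L,
                          insert_len = 0L),
                     class = "junction_sequence")
  expect_error(design_assay(short), "shorter")
})

test_that("in-silico PCR equals the brute-force all-pairs scan", {
  jj <- toy_junction(240, seed = 101)
  fwd <- substr(jj$sequence, 81, 100)   # copied off the A flank
  rev <- rc_chr(substr(jj$sequence, 141, 160))
  hits <- in_silico_pcr(c(jxn = jj$sequence), fwd, rev)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 81L)
  expect_equal(hits$end, 160L)
  expect_equal(hits$product_len, 80L)

  # primers spanning a novel junction find nothing in the reference
  panel <- simulate_junction_panel(n_junctions = 3,
                                   config = sim_config(seed = 19))
  j1 <- panel$junctions[[1]]
  f1 <- substr(j1$sequence, j1$junction_offset - 24L,
               j1$junction_offset - 5L)
  r1 <- rc_chr(substr(j1$sequence, j1$junction_offset + 5L,
                      j1$junction_offset + 24L))
  expect_equal(nrow(in_silico_pcr(panel$genome, f1, r1)), 0L)

  # planted twice: positions must match the brute-force oracle
  core <- rand_seq(60, 42)
  fwd2 <- substr(core, 1, 18)
  rev2 <- rc_chr(substr(core, 43, 60))
  tmpl <- paste0(rand_seq(500, 1), core, rand_seq(400, 2), core,
                 rand_seq(300, 3))
  got <- in_silico_pcr(c(t1 = tmpl), fwd2, rev2)
  oracle <- bf_pcr(tmpl, fwd2, rev2, 1000L)
  expect_equal(nrow(got), length(oracle))
  expect_equal(got$start, sort(vapply(oracle, function(h) h$start, integer(1))))
  # oracle equality on a larger random template with seeded primer pairs
  big <- rand_seq(50000, 1234)
  for (seed in 1:3) {
    s0 <- withr::with_seed(seed, sample(49000, 1))
    f3 <- substr(big, s0, s0 + 19L)
    r3 <- rc_chr(substr(big, s0 + 60L, s0 + 79L))
    got3 <- in_silico_pcr(c(g = big), f3, r3, max_product_len = 2000L)
    orc3 <- bf_pcr(big, f3, r3, 2000L)
    expect_equal(nrow(got3), length(orc3))
    if (length(orc3))
      expect_equal(got3$start,
                   sort(vapply(orc3, function(h) h$start, integer(1))))
  }
})

test_that("specificity check demands one junction hit and a clean genome", {
  panel <- simulate_junction_panel(n_junctions = 3,
                                   config = sim_config(seed = 19))
  jj <- panel$junctions[[1]]
  d <- design_assay(jj)
  expect_s3_class(d, "assay_design")
  sc <- specificity_check(d, jj, panel$genome)
  expect_true(sc$pass)
  expect_equal(nrow(sc$junction_hits), 1L)
  expect_equal(nrow(sc$genome_hits), 0L)

  # an amplicon confined to the A flank does not span the junction
  off <- jj$junction_offset
  fake <- d
  fake$forward_primer <- list(seq = substr(jj$sequence, off - 119L,
                                           off - 100L),
                              start = off - 119L, end = off - 100L,
                              tm = 60, gc = 0.5)
  fake$reverse_primer <- list(seq = rc_chr(substr(jj$sequence, off - 39L,
                                                  off - 20L)),
                              start = off - 39L, end = off - 20L,
                              tm = 60, gc = 0.5)
  sc2 <- specificity_check(fake, jj, panel$genome)
  expect_false(sc2$pass)
  expect_match(sc2$reasons, "span", all = FALSE)

  # planting the amplicon into the genome creates a reported off-target
  amp_seq <- substr(jj$sequence, d$amplicon$start, d$amplicon$end)
  g2 <- as_genome(c(as.character(panel$genome),
                    decoy = paste0(rand_seq(200, 5), amp_seq,
                                   rand_seq(200, 6))))
  sc3 <- specificity_check(d, jj, g2)
  expect_false(sc3$pass)
  expect_equal(nrow(sc3$genome_hits), 1L)
  expect_equal(sc3$genome_hits$template, "decoy")
  expect_match(sc3$reasons, "off-target", all = FALSE)
})

test_that("assay sheets serialize every oligo with its coordinates", {
  jj <- toy_junction(240, seed = 101)
  d <- design_assay(jj)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  sheet <- write_assay_sheet(list(d), tsv, js)
  expect_equal(nrow(sheet), 3L)  # F, R, probe
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$sequence[back$role == "forward_primer"],
               d$forward_primer$seq)
  expect_equal(unique(back$amplicon_length), d$amplicon$length)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$oligos), 3L)
})
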