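test_that("Poisson copy estimates follow partition statistics", {
  expect_equal(poisson_copies(0, 20000), 0)
  expect_equal(poisson_copies(10000, 20000), 20000 * log(2))
  expect_equal(poisson_copies(3, 20000), 3.000225, tolerance = 1e-6)
  expect_error(poisson_copies(20000, 20000), "saturated")
  # strictly increasing in the positive count
  copies <- vapply(0:100, poisson_copies, numeric(1), n_total = 20000)
  expect_true(all(diff(copies) > 0))
  # dilute limit: the relative excess of the Poisson estimate over the raw
  # count is ~p/2, so it stays under 0.1% while p < 0.2%
  for (np in c(1, 17, 39)) {
    expect_lt(abs(poisson_copies(np, 20000) - np) / np, 0.001)
  }
  expect_lt(abs(poisson_copies(150, 20000) - 150) / 150, 0.004)
})

test_that("replicate wells merge by component-wise summation", {
  w <- replicate(3, well_counts("w", 20000, 2, 5000), simplify = FALSE)
  m <- merge_wells(w)
  expect_equal(m$n_total, 60000L)
  expect_equal(m$n_target_pos, 6L)
  expect_equal(m$n_ref_pos, 15000L)
  one <- well_counts("solo", 20000, 7, 4000)
  m1 <- merge_wells(list(one))
  expect_equal(m1$n_target_pos, one$n_target_pos)
  expect_equal(m1$n_total, one$n_total)
  expect_error(merge_wells(list()), "no wells")
  expect_error(well_counts("bad", 100, 200, 5), "n_target_pos")
})

test_that("positivity classes are exactly {0}, {1,2}, {3,...}", {
  for (n in 0:10) {
    expected <- if (n == 0) "not_detected" else if (n <= 2) "trace" else
      "positive"
    expect_equal(classify_positivity(well_counts("w", 20000, n, 0)),
                 expected)
  }
})

test_that("CN/ml divides merged copies by the liquid-biopsy volume", {
  pl <- sample_spec("p", "plasma-cfDNA", liquid_volume_ml = 2)
  expect_equal(cn_per_ml(112, pl), 56)
  expect_equal(cn_per_ml(0, pl), 0)
  csf <- sample_spec("p2csf", "CSF-cfDNA", n_targets_multiplexed = 2,
                     liquid_volume_ml = 1)
  expect_equal(cn_per_ml(56, csf), 56)
  bm <- sample_spec("b", "BM-gDNA", dna_mass_ng = 100)
  expect_error(cn_per_ml(10, bm), "cfDNA")
  # optional eluate-fraction correction scales the estimate up
  expect_equal(cn_per_ml(50, pl, eluate_fraction_loaded = 0.5), 50)
})

test_that("MRD ratio reproduces the diagnostic CSF table rows", {
  csf2 <- sample_spec("pt2", "CSF-cfDNA", n_targets_multiplexed = 2,
                      liquid_volume_ml = 1)
  csf3 <- sample_spec("pt4", "CSF-cfDNA", n_targets_multiplexed = 3,
                      liquid_volume_ml = 1)
  expect_equal(round(mrd_ratio(56, 92, csf2)), 61)
  expect_equal(round(mrd_ratio(103, 164, csf3)), 42)
  expect_equal(round(mrd_ratio(24, 34, csf3)), 47)
  expect_equal(mrd_ratio(0, 500, csf2), 0)
  expect_error(mrd_ratio(5, 0, csf2), "not quantifiable")
  # invariant under common rescaling of both channels
  expect_equal(mrd_ratio(56, 92, csf2), mrd_ratio(560, 920, csf2))
  expect_equal(mrd_ratio(56, 92, csf2), mrd_ratio(5.6, 9.2, csf2))
  # per-genome target copies rescale the correction
  csf2b <- sample_spec("pt2b", "CSF-cfDNA", n_targets_multiplexed = 2,
                       liquid_volume_ml = 1, target_copies_per_genome = 2)
  expect_equal(mrd_ratio(56, 92, csf2b), mrd_ratio(56, 92, csf2) / 2)
})

test_that("theoretical copies derive from the 6.6 pg diploid genome", {
  th <- theoretical_cn(1, 1)
  expect_equal(th$genomes, 1000 / 6.6, tolerance = 1e-12)
  expect_equal(th$target_copies, 151.5152, tolerance = 1e-4)
  expect_equal(th$ref_copies, 303.0303, tolerance = 1e-4)
  deep <- theoretical_cn(500, 1e-6)
  expect_equal(deep$target_copies, 0.07575758, tolerance = 1e-6)
  expect_equal(theoretical_cn(0, 1)$target_copies, 0)
  # configurable genome mass
  expect_equal(theoretical_cn(1, 1, diploid_genome_mass_pg = 10)$genomes,
               100)
})

test_that("fold range summarizes spread at 2 significant figures", {
  expect_equal(fold_range(c(2.2e4, 5.8e6)), 260)
  expect_equal(fold_range(c(5, 5)), 1.0)
  expect_equal(fold_range(c(1e3, 6.9e3, 1.4e3)), 6.9)
  expect_error(fold_range(c(5)), "two values")
  expect_error(fold_range(c(0, 5)), "positive")
})

test_that("sample quantification integrates merging, Poisson and ratio", {
  spec <- sample_spec("s1", "plasma-cfDNA", n_targets_multiplexed = 2,
                      liquid_volume_ml = 2)
  wells <- as_wells(data.frame(well_id = c("A", "B", "C"),
                               n_total = 20000L,
                               n_target_pos = c(40, 35, 37),
                               n_ref_pos = c(3000, 3100, 2900)))
  q <- quantify_sample(wells, spec)
  expect_equal(q$positivity, "positive")
  expect_equal(q$target_copies, poisson_copies(112, 60000))
  expect_equal(q$target_cn_per_ml, q$target_copies / 2)
  expect_equal(q$ratio_percent,
               mrd_ratio(q$target_copies, q$ref_copies, spec))
  # trace sample: quantified but flagged
  tr <- quantify_sample(as_wells(data.frame(
    well_id = "A", n_total = 20000L, n_target_pos = 2L,
    n_ref_pos = 5000L)), spec)
  expect_equal(tr$positivity, "trace")
  expect_true(tr$trace_flag)
  expect_gt(tr$ratio_percent, 0)
  # not detected reports zero target copies
  nd <- quantify_sample(as_wells(data.frame(
    well_id = "A", n_total = 20000L, n_target_pos = 0L,
    n_ref_pos = 5000L)), spec)
  expect_equal(nd$positivity, "not_detected")
  expect_equal(nd$target_copies, 0)
})
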