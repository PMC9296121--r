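#' Simulation configuration
#'
#' Vendor-standard ddPCR constants plus the seed that fixes every downstream
#' draw.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param n_droplets_per_well Accepted droplets per well (default 20000).
#' @param droplet_volume_nl Droplet volume (nl, default 0.85).
#' @param diploid_genome_mass_pg Mass of a diploid genome (pg, default 6.6).
#' @param wells_per_sample Replicate wells per sample (default 3).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, n_droplets_per_well = 20000L,
                       droplet_volume_nl = 0.85,
                       diploid_genome_mass_pg = 6.6,
                       wells_per_sample = 3L) {
  stopifnot(n_droplets_per_well > 0, droplet_volume_nl > 0,
            diploid_genome_mass_pg > 0, wells_per_sample > 0)
  structure(list(seed = if (is.null(seed)) NULL else as.integer(seed),
                 n_droplets_per_well = as.integer(n_droplets_per_well),
                 droplet_volume_nl = droplet_volume_nl,
                 diploid_genome_mass_pg = diploid_genome_mass_pg,
                 wells_per_sample = as.integer(wells_per_sample)),
            class = "sim_config")
}

maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
}

#' Generate a seeded random genome
#'
#' Uniform-random contigs, optionally salted with repeat tracts
#' (homopolymers and short tandem repeats) covering about `repeat_fraction`
#' of each contig, to exercise the repeat screen. With `repeat_fraction = 0`
#' and total size up to ~200 kb, the generator verifies that no 15-mer
#' occurs twice (both strands) and redraws on the (rare) collision, so
#' flanks drawn from it are guaranteed unique.
#'
#' @param config A [sim_config()]; its seed fixes the genome.
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig (>= 1000 bp).
#' @param repeat_fraction Fraction of each contig covered by repeat tracts,
#'   in \[0, 1).
#' @return A named `DNAStringSet`.
#' @export
make_genome <- function(config = sim_config(), n_contigs = 1L,
                        contig_len = 10000L, repeat_fraction = 0) {
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    stop("repeat_fraction must be in [0, 1)")
  contig_len <- as.integer(contig_len)
  if (any(contig_len < 1000L)) stop("contig_len must be >= 1 kb")
  maybe_seed(config)
  lens <- rep_len(contig_len, n_contigs)
  total <- sum(lens)
  check_unique <- repeat_fraction == 0 && total <= 200000L
  for (attempt in 1:10) {
    contigs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    names(contigs) <- paste0("ctg", seq_len(n_contigs))
    if (repeat_fraction > 0) {
      contigs <- vapply(contigs, salt_with_repeats, character(1),
                        repeat_fraction = repeat_fraction)
      names(contigs) <- paste0("ctg", seq_len(n_contigs))
    }
    if (!check_unique || genome_kmers_unique(contigs, 15L)) break
  }
  as_genome(contigs)
}

# Overwrite ~repeat_fraction of the contig with homopolymer and tandem
# tracts (always at least one homopolymer >= 20 bp).
salt_with_repeats <- function(s, repeat_fraction) {
  L <- nchar(s)
  budget <- ceiling(L * repeat_fraction)
  placed <- 0L
  first <- TRUE
  while (placed < budget) {
    tract_len <- if (first) max(20L, sample(20:60, 1)) else sample(15:60, 1)
    tract <- if (first || stats::runif(1) < 0.5) {
      strrep(sample(c("A", "C", "G", "T"), 1), tract_len)
    } else {
      unit <- paste(sample(c("A", "C", "G", "T"), sample(2:4, 1),
                           replace = TRUE), collapse = "")
      substr(strrep(unit, ceiling(tract_len / nchar(unit))), 1L, tract_len)
    }
    start <- sample(L - tract_len, 1)
    substr(s, start, start + tract_len - 1L) <- tract
    placed <- placed + tract_len
    first <- FALSE
  }
  s
}

# TRUE when no k-mer occurs twice genome-wide counting both strands: no
# duplicated forward k-mer, and no forward k-mer also present on the
# reverse strand (whose k-mer set is that of the reverse-complemented
# contigs).
genome_kmers_unique <- function(contigs, k) {
  km <- unlist(lapply(contigs, string_kmers, k = k), use.names = FALSE)
  if (anyDuplicated(km) > 0L) return(FALSE)
  rc_contigs <- vapply(contigs, revcomp, character(1), USE.NAMES = FALSE)
  km_rc <- unlist(lapply(rc_contigs, string_kmers, k = k),
                  use.names = FALSE)
  !any(km %in% km_rc)
}

#' Implant SV junctions into a genome
#'
#' Builds one rearranged haplotype per junction specification — prefix arm
#' of `end_a` + non-templated insert + suffix arm of `end_b`, each arm
#' reverse-complemented when its breakend strand is minus — and records the
#' exact read-through sequence as ground truth for round-trip tests.
#' A reciprocal translocation is supplied as its two derivative junctions
#' and yields two haplotypes.
#'
#' @param genome A genome acceptable to [as_genome()].
#' @param specs A list of [junction_spec()] objects.
#' @param flank_len Bases recorded on each side of the junction in the truth
#'   read-through (default 150).
#' @param prevalence Truth cell fraction attached to each simulated SV.
#' @return A list of `simulated_sv` objects with fields `spec`, `haplotype`,
#'   `read_through`, `junction_offset_in_haplotype`, `prevalence`.
#' @export
implant_svs <- function(genome, specs, flank_len = 150L, prevalence = 1) {
  genome <- as_genome(genome)
  if (inherits(specs, "junction_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "junction_spec")))
  # conflicting deletion intervals on one contig cannot coexist on a
  # haplotype; reject them
  dels <- Filter(function(sp) sp$sv_class == "deletion" &&
                   sp$end_a$contig == sp$end_b$contig, specs)
  if (length(dels) > 1L) {
    iv <- do.call(rbind, lapply(dels, function(sp)
      data.frame(contig = sp$end_a$contig, lo = sp$end_a$pos,
                 hi = sp$end_b$pos)))
    iv <- iv[order(iv$contig, iv$lo), , drop = FALSE]
    for (i in seq_len(nrow(iv) - 1L)) {
      if (iv$contig[i] == iv$contig[i + 1L] && iv$hi[i] >= iv$lo[i + 1L])
        stop("overlapping junction specs on contig '", iv$contig[i], "'")
    }
  }
  lapply(specs, function(sp) {
    validate_breakend_in_genome(sp$end_a, genome)
    validate_breakend_in_genome(sp$end_b, genome)
    a_dna <- contig_seq(genome, sp$end_a$contig)
    b_dna <- contig_seq(genome, sp$end_b$contig)
    arm_a <- if (sp$end_a$side == "upstream")
      subseq_chr(a_dna, 1L, sp$end_a$pos)
    else subseq_chr(a_dna, sp$end_a$pos, length(a_dna))
    if (sp$end_a$strand == "-") arm_a <- revcomp(arm_a)
    arm_b <- if (sp$end_b$side == "downstream")
      subseq_chr(b_dna, sp$end_b$pos, length(b_dna))
    else subseq_chr(b_dna, 1L, sp$end_b$pos)
    if (sp$end_b$strand == "-") arm_b <- revcomp(arm_b)
    hap <- paste0(arm_a, sp$insert_seq, arm_b)
    off <- nchar(arm_a)
    rt_start <- max(1L, off - flank_len + 1L)
    rt_end <- min(nchar(hap), off + nchar(sp$insert_seq) + flank_len)
    structure(list(spec = sp, haplotype = hap,
                   read_through = substr(hap, rt_start, rt_end),
                   junction_offset_in_haplotype = off,
                   prevalence = prevalence),
              class = "simulated_sv")
  })
}

#' Simulate droplet counts for one well, one channel
#'
#' Forward model of ddPCR partitioning: each of `n` droplets is positive
#' with probability \eqn{p = 1 - e^{-copies/n}}, so the positive count is
#' Binomial(n, p). This is exactly the model [poisson_copies()] inverts.
#' Uses the current RNG state (seed once per scenario, not per well).
#'
#' @param expected_copies Expected copies loaded into the well (>= 0).
#' @param config A [sim_config()] (droplet count; seed NOT applied here).
#' @return Integer count of positive droplets.
#' @export
simulate_well <- function(expected_copies, config = sim_config()) {
  stopifnot(expected_copies >= 0)
  n <- config$n_droplets_per_well
  p <- 1 - exp(-expected_copies / n)
  rbinom(1L, n, p)
}

#' Simulate the replicate wells of one MRD sample
#'
#' Computes the expected reference load from the sample's mass (gDNA) or a
#' supplied reference concentration (cfDNA), sets the expected target load
#' consistent with `true_ratio` under the sample's correction factors, and
#' draws both channels for `wells_per_sample` wells. Loads driving the
#' positive-droplet probability above 0.999 raise the saturation flag.
#'
#' @param true_ratio True target:reference ratio as a fraction in \[0, 1\]
#'   (1 = every genome carries each junction).
#' @param spec A [sample_spec()].
#' @param config A [sim_config()]; its seed (if set) is applied on entry.
#' @param ref_cn_per_ml Reference CN/ml for cfDNA compartments (expected
#'   reference copies = `ref_cn_per_ml * liquid_volume_ml`).
#' @return A list with `wells` (data.frame: well_id, n_total, n_target_pos,
#'   n_ref_pos), `expected_target`, `expected_ref` (totals across wells) and
#'   `saturation_flag`.
#' @export
simulate_mrd_sample <- function(true_ratio, spec, config = sim_config(),
                                ref_cn_per_ml = NULL) {
  stopifnot(inherits(spec, "sample_spec"), true_ratio >= 0, true_ratio <= 1)
  maybe_seed(config)
  if (spec$compartment == "BM-gDNA") {
    th <- theoretical_cn(spec$dna_mass_ng, 1, spec,
                         config$diploid_genome_mass_pg)
    ref_total <- th$ref_copies
  } else {
    if (is.null(ref_cn_per_ml))
      stop("cfDNA simulation needs ref_cn_per_ml")
    ref_total <- ref_cn_per_ml * spec$liquid_volume_ml
  }
  # mrd_ratio inverts to: target = ratio * (ref/ploidy) * n_targets * c_T
  target_total <- true_ratio * (ref_total / spec$reference_ploidy) *
    spec$n_targets_multiplexed * spec$target_copies_per_genome
  w <- config$wells_per_sample
  per_well_ref <- ref_total / w
  per_well_target <- target_total / w
  n <- config$n_droplets_per_well
  sat <- (1 - exp(-per_well_ref / n)) > 0.999 ||
    (1 - exp(-per_well_target / n)) > 0.999
  wells <- data.frame(
    well_id = sprintf("W%02d", seq_len(w)),
    n_total = n,
    n_target_pos = vapply(seq_len(w), function(i)
      simulate_well(per_well_target, config), integer(1)),
    n_ref_pos = vapply(seq_len(w), function(i)
      simulate_well(per_well_ref, config), integer(1)),
    stringsAsFactors = FALSE)
  list(wells = wells, expected_target = target_total,
       expected_ref = ref_total, saturation_flag = sat)
}

#' Simulate a serial 10-fold dilution series
#'
#' Positive-control DNA carrying the junctions diluted into negative-control
#' DNA: at dilution d, expected target copies are
#' `d * genomes * copies_per_genome * n_targets / n_targets`
#' per target assay (the series is per assay, one target), while the
#' reference channel sees every genome. Defaults follow performance-testing
#' practice of 500 ng of input split across 5 wells.
#'
#' @param dilutions Dilution fractions (default `10^-(1:6)`).
#' @param total_mass_ng Total input mass across wells (default 500 ng).
#' @param wells_per_dilution Wells per dilution level (default 5).
#' @param diag_ratio Target:reference ratio of the undiluted positive
#'   control, as a fraction (default 1: every leukemic genome carries the
#'   junction; the diagnostic sample is entirely leukemic).
#' @param spec A [sample_spec()] for the correction factors.
#' @param config A [sim_config()]; seed applied on entry.
#' @return A data.frame in the dilution-series dialect: `dilution`,
#'   `well_id`, `n_total`, `n_target_pos`, `n_ref_pos`.
#' @export
simulate_dilution_series <- function(dilutions = 10^-(1:6),
                                     total_mass_ng = 500,
                                     wells_per_dilution = 5L,
                                     diag_ratio = 1,
                                     spec = sample_spec("PC", "BM-gDNA",
                                                        dna_mass_ng = 500),
                                     config = sim_config()) {
  maybe_seed(config)
  th <- theoretical_cn(total_mass_ng, 1, spec, config$diploid_genome_mass_pg)
  out <- list()
  for (d in sort(dilutions, decreasing = TRUE)) {
    target_total <- diag_ratio * th$genomes * d * spec$target_copies_per_genome
    ref_total <- th$ref_copies
    for (wi in seq_len(wells_per_dilution)) {
      out[[length(out) + 1L]] <- data.frame(
        dilution = d, well_id = sprintf("d%g_W%02d", log10(d), wi),
        n_total = config$n_droplets_per_well,
        n_target_pos = simulate_well(target_total / wells_per_dilution,
                                     config),
        n_ref_pos = simulate_well(ref_total / wells_per_dilution, config),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a panel of unique junction sequences
#'
#' Generates a seeded random genome, implants a mix of deletions,
#' translocation derivatives and inversion junctions (some with
#' non-templated inserts), and returns the reconstructed junction
#' sequences — ready for [design_assay()].
#'
#' @param n_junctions Number of junctions (default 15).
#' @param config A [sim_config()]; seed applied on entry.
#' @param flank_len Flank length for the reconstructed sequences.
#' @param contig_len Length of each simulated contig.
#' @return A list with `genome`, `specs`, `svs` (from [implant_svs()]) and
#'   `junctions` (list of `junction_sequence`).
#' @export
simulate_junction_panel <- function(n_junctions = 15L,
                                    config = sim_config(),
                                    flank_len = 150L,
                                    contig_len = 6000L) {
  maybe_seed(config)
  n_contigs <- max(2L, ceiling(n_junctions / 2))
  genome <- make_genome(sim_config(seed = NULL,
                                   n_droplets_per_well =
                                     config$n_droplets_per_well),
                        n_contigs = n_contigs, contig_len = contig_len)
  contigs <- names(genome)
  specs <- vector("list", n_junctions)
  for (i in seq_len(n_junctions)) {
    kind <- c("deletion", "reciprocal-translocation-derivative",
              "inversion-junction")[(i %% 3L) + 1L]
    ins <- if (i %% 4L == 0L)
      paste(sample(c("A", "C", "G", "T"), sample(2:12, 1), replace = TRUE),
            collapse = "") else ""
    lo <- flank_len + 200L
    hi <- contig_len - flank_len - 200L
    if (kind == "deletion") {
      ctg <- contigs[(i %% n_contigs) + 1L]
      # avoid overlapping deletion intervals on a shared contig
      for (try in 1:50) {
        p1 <- sample(lo:(hi - 1600L), 1)
        p2 <- p1 + sample(1100:1500, 1)  # span exceeds in-silico PCR
                                         # product limits, as real leukemic
                                         # deletions (kb-Mb) do
        clash <- any(vapply(specs[seq_len(i - 1L)], function(sp) {
          !is.null(sp) && sp$sv_class == "deletion" &&
            sp$end_a$contig == ctg &&
            sp$end_a$pos <= p2 && sp$end_b$pos >= p1
        }, logical(1)))
        if (!clash) break
      }
      specs[[i]] <- junction_spec(sprintf("sim_del_%02d", i),
                                  breakend(ctg, p1, "upstream", "+"),
                                  breakend(ctg, p2, "downstream", "+"),
                                  insert_seq = ins, sv_class = "deletion")
    } else if (kind == "reciprocal-translocation-derivative") {
      c1 <- contigs[(i %% n_contigs) + 1L]
      c2 <- contigs[((i + 1L) %% n_contigs) + 1L]
      specs[[i]] <- junction_spec(
        sprintf("sim_tra_%02d", i),
        breakend(c1, sample(lo:hi, 1), "upstream", "+"),
        breakend(c2, sample(lo:hi, 1), "downstream", "+"),
        insert_seq = ins,
        sv_class = "reciprocal-translocation-derivative")
    } else {
      ctg <- contigs[(i %% n_contigs) + 1L]
      p1 <- sample(lo:(hi - 500L), 1)
      p2 <- p1 + sample(300:450, 1)
      specs[[i]] <- junction_spec(sprintf("sim_inv_%02d", i),
                                  breakend(ctg, p1, "upstream", "+"),
                                  breakend(ctg, p2, "upstream", "-"),
                                  insert_seq = ins,
                                  sv_class = "inversion-junction")
    }
  }
  svs <- implant_svs(genome, specs, flank_len = flank_len)
  junctions <- lapply(specs, function(sp)
    reconstruct_junction(genome, sp, flank_len = flank_len))
  list(genome = genome, specs = specs, svs = svs, junctions = junctions)
}
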