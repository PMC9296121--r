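#' Droplet counts for one ddPCR well
#'
#' Accepted-droplet and channel-positive counts for a single well, after
#' thresholding. Double-positive droplets are included in both channel
#' counts.
#'
#' @param well_id Well identifier.
#' @param n_total Accepted droplets.
#' @param n_target_pos Droplets positive in the target (FAM) channel.
#' @param n_ref_pos Droplets positive in the reference (HEX) channel.
#' @param min_droplets Accepted-droplet count below which a warning is
#'   emitted (vendor practice; default 10000).
#' @return An object of class `well_counts`.
#' @export
well_counts <- function(well_id, n_total, n_target_pos, n_ref_pos,
                        min_droplets = 10000L) {
  n_total <- as.integer(n_total)
  n_target_pos <- as.integer(n_target_pos)
  n_ref_pos <- as.integer(n_ref_pos)
  if (is.na(n_total) || n_total <= 0L) stop("n_total must be > 0")
  if (n_target_pos < 0L || n_target_pos > n_total)
    stop("n_target_pos must be in [0, n_total]")
  if (n_ref_pos < 0L || n_ref_pos > n_total)
    stop("n_ref_pos must be in [0, n_total]")
  if (n_total < min_droplets)
    warning("well '", well_id, "' has only ", n_total,
            " accepted droplets (< ", min_droplets, ")")
  structure(list(well_id = as.character(well_id), n_total = n_total,
                 n_target_pos = n_target_pos, n_ref_pos = n_ref_pos),
            class = "well_counts")
}

#' Sample metadata for quantification
#'
#' @param sample_id Sample identifier.
#' @param compartment One of `"BM-gDNA"`, `"plasma-cfDNA"`, `"CSF-cfDNA"`.
#' @param n_targets_multiplexed Number of patient targets multiplexed in the
#'   FAM channel (>= 1).
#' @param liquid_volume_ml Initial liquid-biopsy volume (ml; cfDNA samples).
#' @param dna_mass_ng DNA input mass (ng; gDNA samples).
#' @param dilution Dilution fraction in (0, 1].
#' @param reference_ploidy Reference-gene copies per genome (default 2).
#' @param target_copies_per_genome Copies of each junction per leukemic
#'   genome (default 1, the heterozygous assumption).
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id,
                        compartment = c("BM-gDNA", "plasma-cfDNA",
                                        "CSF-cfDNA"),
                        n_targets_multiplexed = 1L,
                        liquid_volume_ml = NA_real_,
                        dna_mass_ng = NA_real_,
                        dilution = 1,
                        reference_ploidy = 2,
                        target_copies_per_genome = 1) {
  compartment <- match.arg(compartment)
  n_targets_multiplexed <- as.integer(n_targets_multiplexed)
  stopifnot(n_targets_multiplexed >= 1L, dilution > 0, dilution <= 1,
            reference_ploidy > 0, target_copies_per_genome > 0)
  cfdna <- compartment != "BM-gDNA"
  if (cfdna && (is.na(liquid_volume_ml) || liquid_volume_ml <= 0))
    stop("cfDNA samples need a positive liquid_volume_ml")
  if (!cfdna && (is.na(dna_mass_ng) || dna_mass_ng <= 0))
    stop("gDNA samples need a positive dna_mass_ng")
  structure(list(sample_id = as.character(sample_id),
                 compartment = compartment,
                 n_targets_multiplexed = n_targets_multiplexed,
                 liquid_volume_ml = liquid_volume_ml,
                 dna_mass_ng = dna_mass_ng, dilution = dilution,
                 reference_ploidy = reference_ploidy,
                 target_copies_per_genome = target_copies_per_genome),
            class = "sample_spec")
}

#' Poisson copy estimate from droplet counts
#'
#' Digital PCR partition statistics: with `n_pos` of `n_total` droplets
#' positive, the mean copies per droplet is
#' \eqn{\lambda = -\ln(1 - n_{pos}/n_{total})} and the copies in the
#' partitioned reaction \eqn{\lambda \, n_{total}}. Saturated wells
#' (all droplets positive) are not estimable and raise an error advising
#' input titration.
#'
#' @param n_pos Positive droplets.
#' @param n_total Accepted droplets.
#' @return Estimated copies in the partitioned volume.
#' @examples
#' poisson_copies(10000, 20000)  # 20000 * ln 2
#' @export
poisson_copies <- function(n_pos, n_total) {
  stopifnot(n_total > 0, n_pos >= 0)
  if (n_pos >= n_total)
    stop("well saturated (all ", n_total, " droplets positive): copies not ",
         "estimable; titrate the input and repeat")
  lambda <- -log1p(-n_pos / n_total)
  lambda * n_total
}

#' Merge replicate wells by summing droplet counts
#'
#' Replicate ddPCR wells are merged by component-wise summation of accepted
#' and channel-positive droplets; all downstream estimates (copies,
#' positivity, CN/ml) use the merged counts, equivalent to having run one
#' large partitioning.
#'
#' @param wells A list of [well_counts()] objects (at least one).
#' @return A single merged `well_counts` (well_id `"merged"`).
#' @export
merge_wells <- function(wells) {
  if (inherits(wells, "well_counts")) wells <- list(wells)
  if (length(wells) == 0L) stop("no wells to merge")
  stopifnot(all(vapply(wells, inherits, logical(1), "well_counts")))
  suppressWarnings(well_counts(
    "merged",
    n_total = sum(vapply(wells, `[[`, integer(1), "n_total")),
    n_target_pos = sum(vapply(wells, `[[`, integer(1), "n_target_pos")),
    n_ref_pos = sum(vapply(wells, `[[`, integer(1), "n_ref_pos"))))
}

#' Classify target positivity from merged droplet counts
#'
#' A sample is target positive when three or more FAM-positive droplets are
#' seen across the merged replicates; one to two droplets are a trace
#' amount; zero droplets is not detected.
#'
#' @param merged A merged [well_counts()] (or anything with `n_target_pos`).
#' @return `"positive"`, `"trace"`, or `"not_detected"`.
#' @export
classify_positivity <- function(merged) {
  n <- if (is.list(merged)) merged$n_target_pos else merged
  n <- as.integer(n)
  stopifnot(!is.na(n), n >= 0L)
  if (n >= 3L) "positive" else if (n >= 1L) "trace" else "not_detected"
}

#' Copies per ml of liquid biopsy
#'
#' Divides the merged copy estimate (the sum of all signals across the
#' replicate wells) by the initial plasma/CSF volume. No correction for any
#' unloaded eluate fraction is applied by default; `eluate_fraction_loaded`
#' scales the estimate up when a known fraction of the extraction eluate was
#' partitioned.
#'
#' @param copies Merged copy estimate for one channel.
#' @param spec A [sample_spec()] with a cfDNA compartment.
#' @param eluate_fraction_loaded Fraction of the eluate loaded across the
#'   wells (default 1 = no correction).
#' @return Copies per ml.
#' @export
cn_per_ml <- function(copies, spec, eluate_fraction_loaded = 1) {
  stopifnot(inherits(spec, "sample_spec"))
  if (spec$compartment == "BM-gDNA")
    stop("CN/ml is defined for cfDNA compartments only")
  v <- spec$liquid_volume_ml
  if (is.na(v) || v <= 0) stop("liquid_volume_ml must be positive")
  stopifnot(eluate_fraction_loaded > 0, eluate_fraction_loaded <= 1)
  (copies / eluate_fraction_loaded) / v
}

#' Target:reference MRD ratio, corrected for target multiplexing
#'
#' The per-target, per-haploid-equivalent ratio
#' \deqn{100 \cdot \frac{T / (n_{targets} \cdot c_{T})}{R / \rho}}
#' where \eqn{T} and \eqn{R} are target and reference quantities in the same
#' units (copies or CN/ml — units cancel), \eqn{n_{targets}} the number of
#' multiplexed junction targets, \eqn{c_T} the junction copies per leukemic
#' genome and \eqn{\rho} the reference ploidy. With defaults this is the
#' percentage of genomes carrying each junction.
#'
#' @param target_cn Target quantity (copies or CN/ml).
#' @param ref_cn Reference quantity in the same units; must be > 0.
#' @param spec A [sample_spec()] (supplies the correction factors).
#' @return Ratio in percent.
#' @examples
#' csf <- sample_spec("p2", "CSF-cfDNA", n_targets_multiplexed = 2,
#'                    liquid_volume_ml = 1)
#' mrd_ratio(56, 92, csf)  # 60.9 -> prints as 61% in reports
#' @export
mrd_ratio <- function(target_cn, ref_cn, spec) {
  stopifnot(inherits(spec, "sample_spec"), target_cn >= 0)
  if (ref_cn <= 0)
    stop("reference channel empty: sample not quantifiable")
  per_target <- target_cn / (spec$n_targets_multiplexed *
                               spec$target_copies_per_genome)
  per_genome_ref <- ref_cn / spec$reference_ploidy
  100 * per_target / per_genome_ref
}

#' Theoretical copies from input mass, assuming no losses
#'
#' Expected copies in a reaction given DNA mass and dilution, assuming no
#' pipetting losses and 100% partitioning efficiency: genomes =
#' mass x dilution / diploid genome mass (6.6 pg), targets = genomes x
#' copies per genome, reference = genomes x ploidy.
#'
#' @param dna_mass_ng Input DNA mass (ng).
#' @param dilution Fraction of the mass that is positive-control (leukemic)
#'   DNA, in (0, 1].
#' @param spec A [sample_spec()] (ploidy/copies-per-genome), or `NULL` for
#'   defaults.
#' @param diploid_genome_mass_pg Mass of one diploid genome (pg; default 6.6).
#' @return A list with `genomes`, `target_copies`, `ref_copies`.
#' @examples
#' theoretical_cn(1, 1)  # ~151.5 genomes in 1 ng
#' @export
theoretical_cn <- function(dna_mass_ng, dilution = 1, spec = NULL,
                           diploid_genome_mass_pg = 6.6) {
  stopifnot(dna_mass_ng >= 0, dilution > 0, dilution <= 1,
            diploid_genome_mass_pg > 0)
  tcpg <- if (is.null(spec)) 1 else spec$target_copies_per_genome
  ploidy <- if (is.null(spec)) 2 else spec$reference_ploidy
  genomes <- dna_mass_ng * 1000 * dilution / diploid_genome_mass_pg
  list(genomes = genomes,
       target_copies = genomes * tcpg,
       ref_copies = genomes * ploidy)
}

#' Fold range of a set of concentrations
#'
#' Maximum divided by minimum, rounded to 2 significant figures; used to
#' summarize the spread of cfDNA levels across patients.
#'
#' @param values Positive values (at least two).
#' @return max/min at 2 significant figures.
#' @examples
#' fold_range(c(2.2e4, 5.8e6))  # 260
#' @export
fold_range <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive and finite")
  signif(max(values) / min(values), 2)
}

#' Quantify one sample from its replicate wells
#'
#' Merges the wells, estimates copies per channel by Poisson statistics,
#' classifies positivity, and computes CN/ml (cfDNA) and the corrected
#' target:reference ratio. Not-detected samples report 0 target copies;
#' trace samples are quantified with `trace_flag` set.
#'
#' @param wells List of [well_counts()] for this sample.
#' @param spec The sample's [sample_spec()].
#' @return An object of class `quant_result`.
#' @export
quantify_sample <- function(wells, spec) {
  stopifnot(inherits(spec, "sample_spec"))
  merged <- merge_wells(wells)
  target_copies <- poisson_copies(merged$n_target_pos, merged$n_total)
  ref_copies <- poisson_copies(merged$n_ref_pos, merged$n_total)
  positivity <- classify_positivity(merged)
  if (positivity == "not_detected") target_copies <- 0
  cfdna <- spec$compartment != "BM-gDNA"
  target_cn_ml <- if (cfdna) cn_per_ml(target_copies, spec) else NA_real_
  ref_cn_ml <- if (cfdna) cn_per_ml(ref_copies, spec) else NA_real_
  ratio <- if (ref_copies > 0)
    mrd_ratio(target_copies, ref_copies, spec) else NA_real_
  structure(list(sample_id = spec$sample_id,
                 compartment = spec$compartment,
                 merged = merged,
                 target_copies = target_copies, ref_copies = ref_copies,
                 positivity = positivity,
                 trace_flag = positivity == "trace",
                 target_cn_per_ml = target_cn_ml,
                 ref_cn_per_ml = ref_cn_ml,
                 ratio_percent = ratio),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result %s [%s]: %s>\n", x$sample_id, x$compartment,
              x$positivity))
  cat(sprintf("  target %.2f copies, reference %.2f copies\n",
              x$target_copies, x$ref_copies))
  if (!is.na(x$target_cn_per_ml))
    cat(sprintf("  CN/ml: target %.2f, reference %.2f\n",
                x$target_cn_per_ml, x$ref_cn_per_ml))
  if (!is.na(x$ratio_percent))
    cat(sprintf("  ratio: %s%%\n", format_ratio_percent(x$ratio_percent,
                                                        x$trace_flag)))
  invisible(x)
}
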