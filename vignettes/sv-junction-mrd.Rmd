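---
title: "Quantifying residual leukemia with patient-specific SV-junction ddPCR assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying residual leukemia with patient-specific SV-junction ddPCR assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmrd)
```

## The problem

Measurable residual disease (MRD) — the small fraction of leukemic cells that
survives induction therapy — is the strongest prognostic factor in pediatric
acute lymphoblastic leukemia (ALL), and treatment protocols stratify patients
on it. The routine MRD methods (flow cytometry of leukemia-associated
immunophenotypes, RQ-PCR of clonal IG/TR rearrangements) are not available or
not informative for every patient. Somatic structural variants (SVs) offer an
alternative marker class: the junction where two genomic segments are joined
by a rearrangement is a DNA sequence that exists only in the leukemic clone.
A droplet digital PCR (ddPCR) assay whose probe sits across that junction is
therefore perfectly specific in principle, and because junctions are clonal
marks acquired early, they are stable across therapy and relapse.

`svmrd` implements the full computational side of such a workflow: choosing
junction targets from whole-genome-sequencing SV calls, rebuilding the
junction sequence, designing and specificity-checking breakpoint-spanning
primer/probe assays, turning droplet counts into copy estimates and MRD
ratios (in bone-marrow gDNA and in plasma/CSF cell-free DNA), and
characterizing assay sensitivity from serial dilution series. A simulation
module generates every input with known ground truth, which is how the
package validates itself.

## Target selection

`parse_sv_calls()` adapts caller output (VCF breakends in bracket notation,
symbolic `<DEL>`/`<INV>` records) to a common junction model: two breakends,
each retaining one reference flank (possibly reverse-complemented), joined
with an optional non-templated insertion. Three criteria decide which
junctions make good targets:

1. **Clonality.** The junction should be present in the majority of blasts.
   `estimate_prevalence()` converts read support to a cell fraction under a
   heterozygous-autosomal assumption (cell fraction = 2 x VAF, capped at 1);
   `min_prevalence = 0.5` is the default cut. The copies-per-genome argument
   covers non-heterozygous cases such as homozygous deletions.
2. **Sequence context.** Junctions in repetitive or low-complexity DNA fail
   in PCR. `repeat_screen()` makes this judgement explicit and testable
   instead of a manual browser inspection: a flank fails on an ambiguous
   base, on a homopolymer run longer than 8 bp, or on any 15-mer occurring
   more than once genome-wide (both strands). All three thresholds are
   arguments; the defaults were chosen once as conventional primer-design
   heuristics and are deliberately strict on the small, repeat-free test
   genomes the simulator produces.
3. **Biology.** Junctions touching loci recurrently rearranged in ALL
   (TCF3::ZNF384, IKZF1, PAX5, CDKN2A/B, STIL::TAL1, TLX3::CDK6, ...) are
   preferred because they are likelier to be truncal driver events. The
   package ships a small hg19 gene list (`default_recurrent_regions()`) as
   a replaceable default; any BED file can stand in for it.

`select_targets()` ranks survivors (region overlap, then prevalence, then
read support, then id — a total order, so selection is deterministic) and
returns at most `max_targets = 3` junctions, the practical limit for
multiplexing patient assays in one ddPCR channel.

### Coordinates

All internal coordinates are 1-based inclusive, the R/Bioconductor
convention used by `Biostrings::subseq` and `GenomicRanges`; VCF positions
are native 1-based, and BED input is converted from 0-based half-open by
`rtracklayer` on read. The one 0-based quantity is `junction_offset` in
junction FASTA descriptions: the number of A-flank bases, which is both the
0-based index of the first post-junction base and the 1-based index of the
last A-flank base — the two conventions coincide for this field.

## Assay design

`design_assay()` searches primer/probe layouts on the reconstructed junction
sequence exhaustively. The constraints (all in `design_constraints()`):

| parameter | default | rationale |
|---|---|---|
| amplicon length | < 100 bp | short amplicons amplify fragmented cfDNA efficiently |
| primer length | 18–27 nt | conventional PCR primer range |
| primer Tm | 58–62 °C | standard ddPCR annealing window |
| probe length | 18–30 nt | hydrolysis-probe range |
| probe Tm | 63–70 °C | 3–10 °C above the primer midpoint |
| GC fraction | 0.30–0.70 | avoids extreme-composition oligos |
| probe overhang | ≥ 4 bp | probe must read genuinely novel sequence on both sides of the junction |

Tm is computed from SantaLucia (1998) unified nearest-neighbor
thermodynamics with the entropic salt correction
ΔS' = ΔS + 0.368·N·ln[Na⁺]eq and divalent cations folded into an equivalent
monovalent concentration ([Na⁺]eq = [mono] + 120·√[Mg²⁺], mM); defaults are
50 mM monovalent, 3.8 mM divalent, 250 nM strands. Among valid layouts the
lowest penalty wins: 1.0 per °C of Tm deviation from the window midpoint,
10 per unit of GC deviation, 0.05 per amplicon base. Ties break to the
shorter amplicon and then the lexicographically smallest forward primer, so
identical inputs give byte-identical designs. Failures return the list of
constraints that eliminated all candidates rather than an error — mirroring
the practical reality that some junctions (long homopolymer flanks,
GC-extreme contexts) simply do not admit an assay.

The probe must contain the junction's novel interval (the non-templated
insert widened by the overhang on each side). In **double-probe mode** —
used when a patient has only a single usable junction and detection
probability matters more than reagent economy — two non-overlapping probes
on opposite strands jointly cover that interval, splitting it at an internal
boundary. A single interval cannot be strictly inside two disjoint probes,
so joint coverage is the only consistent reading of a non-overlapping
opposite-strand pair "over the junction", and it is what
`validate_assay_design()` (an independent checker, used by the tests to
re-verify every emitted design) enforces in that mode.

Specificity is checked by exact-match in-silico PCR (`in_silico_pcr()`): no
mismatch tolerance, no thermodynamic off-target model — a primer pair
amplifies wherever both match perfectly in convergent orientation within
the product-size limit. `specificity_check()` passes a design only if the
junction template yields exactly one product spanning the breakpoint and
the reference genome yields none. Deletion junctions illustrate the limit
of the exact-match rule: the same primer pair *does* amplify the reference
allele as a product longer by the deleted length, so specificity holds only
when the deletion exceeds the product-size limit. Real leukemic deletions
(tens of kb to Mb) always do; the simulator's deletions are drawn at
1.1–1.5 kb for the same reason.

## Quantification model

ddPCR partitions a reaction into ~20,000 droplets. With `n_pos` of
`n_total` droplets positive, the per-droplet mean copy number is
λ = −ln(1 − n_pos/n_total), and the reaction contains λ·n_total copies
(`poisson_copies()`). Saturated wells (every droplet positive) are not
estimable and raise an error advising titration — the situation seen with
high-load diagnostic cfDNA. Replicate wells are merged by summing counts
(`merge_wells()`), which is statistically identical to one larger
partitioning and is how triplicate reactions are treated throughout.

Positivity follows a droplet-count rule: ≥ 3 FAM-positive droplets in the
merged wells is positive, 1–2 is a *trace* (detected, below the positivity
threshold, still quantified but flagged and parenthesized in reports), 0 is
not detected. For cell-free DNA, `cn_per_ml()` divides merged copies by the
initial liquid-biopsy volume; no correction is applied for any eluate
fraction left unloaded (an optional factor exists, off by default, so the
reported CN/ml is exactly "copies seen per ml collected").

The MRD ratio corrects for multiplexing and ploidy:

ratio% = 100 · (T / (n_targets · c_T)) / (R / ρ)

with T, R the target and reference quantities in any common unit,
n_targets the number of junction assays pooled in the FAM channel, c_T the
junction copies per leukemic genome (default 1) and ρ the reference-gene
ploidy (default 2). With defaults this reads "percent of genomes carrying
each junction". `theoretical_cn()` provides the no-loss expectation from
input mass using a 6.6 pg diploid genome (configurable), used for
low-input QC and for sizing dilution series.

## Sensitivity analysis

`dilution_series()` is the package's one model-fitting interface and
returns a classed fit object with `print`/`summary`/`coef`/`predict`/
`plot`/`residuals` methods. Per dilution level it merges wells and computes
the ratio; linearity is least-squares on log10(ratio) vs log10(dilution)
over positive points only (trace and negative levels carry too little
information to constrain a regression and are excluded).

* **LoD** is the most dilute level of the unbroken detection chain
  (≥ 1 droplet) from the top of the series; an isolated detection below a
  blank level flags the series non-monotone and the chain stops at the gap.
  Trace detections count: at 500 ng input a 10⁻⁶ dilution holds only
  ~0.076 expected copies, so detection there is necessarily a
  single-droplet event (probability ≈ 7%) — which is why only some assays
  ever reach 10⁻⁶.
* **LoQ** is the most dilute level at which the level itself is positive
  and accurate (within 0.5 log10 of the proportional expectation anchored
  at the least dilute positive level) and the fit restricted to that level
  and above stays linear (|slope − 1| ≤ 0.15, r² ≥ 0.98). These three
  criteria are this package's explicit stand-in for a linearity judgement
  that is usually made by eye; all are arguments.

`extrapolate_theoretical_ratio()` evaluates the fit at any dilution —
typically 1 — to reconstruct a diagnostic-sample ratio when no diagnostic
material was run, the documented fallback for missing baseline samples.

Performance testing defaults to 500 ng of input split across 5 wells
(100 ng/well). The protocol description is ambiguous between "500 ng per
well" and "500 ng split"; the split reading was chosen because it matches
the per-well input used for patient samples, and it is a default, not an
assertion about any particular laboratory's practice.

## The simulator, and what passing tests do (and do not) show

`make_genome()` draws uniform-random contigs (optionally salted with
homopolymer/tandem tracts to exercise the repeat screen) and, for clean
genomes up to ~200 kb, verifies that no 15-mer repeats on either strand,
redrawing on collision. `implant_svs()` realizes junctions as rearranged
haplotypes and records the exact read-through, giving the round-trip oracle
for `reconstruct_junction()`. `simulate_well()` is the forward model the
Poisson estimator inverts: each droplet positive with probability
1 − e^(−copies/n), counts Binomial. `simulate_mrd_sample()` and
`simulate_dilution_series()` compose these into full scenarios; every
generator takes a seed through `sim_config()` and identical configurations
reproduce byte-identical outputs.

Test problem sizes were fixed once at desk scale: 6–8 kb contigs, panels of
15 junctions for design properties and 100 for round-trip properties,
200-replicate recovery studies at ratios 10⁻¹–10⁻⁴, 1000-replicate
estimator-coverage checks, 50 kb templates for the in-silico PCR oracle.

The simulator is deliberately idealized: uniform base composition, no
sequencing error in the SV calls, no droplet-count jitter, no PCR
efficiency loss, no cfDNA fragment-size structure, no false-positive
droplets by default (a configurable background rate exists). Passing tests
therefore demonstrate that the *computational* pipeline is correct —
coordinates, orientations, estimators, classifications and rankings do what
the model says — not that any particular wet-lab assay will achieve the
simulated sensitivity on patient material. Repeat-screen defaults tuned for
a repeat-free synthetic genome (every flank 15-mer unique) are far stricter
than anything a human genome can satisfy; on real data `max_kmer_hits`
must be relaxed to the mappability of the locus.

## Numerical and degenerate-input choices

* λ estimation uses `log1p` for accuracy at few positive droplets; a
  saturated channel is an error, not an `Inf`.
* Ratio rendering follows the clinical-table conventions: ≥ 0.01% printed
  to 2 decimals, smaller values to 4, traces parenthesized, "ND" for not
  detected, CSF summaries as whole percent.
* Flanks running off a contig end are truncated with a warning (junction
  offsets stay correct); a zero-length flank is an error.
* Design tie-breaks (penalty, then amplicon length, then primer sequence)
  make every search result reproducible to the byte.
* Empty candidate lists, all-negative dilution series and samples with an
  empty reference channel return empty/`NA` results with messages rather
  than failing the batch; a duplicate timepoint within one patient series
  is a hard error in report assembly.

## Known limitations

* SV calling itself is out of scope: the package consumes VCF and trusts
  the caller's breakpoints (the reconstruction round-trip verifies
  consistency, not correctness, of a call).
* Specificity is exact-match only; a primer pair one mismatch away from a
  reference locus passes. The screen is a necessary condition, not a
  thermodynamic off-target model.
* No confidence intervals on λ or the ratio are reported (a documented
  extension point); replicate merging gives point estimates.
* The prevalence model assumes one junction copy per genome by default;
  copy-number-amplified junctions need the per-candidate override.
* Absolute copy-number reproduction from published summary tables is not
  possible without the underlying per-well droplet counts; the package's
  validation therefore rests on printed worked examples plus
  simulation-backed recovery properties.
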