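#' Constraints for breakpoint-spanning ddPCR assay design
#'
#' Defaults follow rare-mutation-detection ddPCR practice: amplicons under
#' 100 bp, primers 18-27 nt with Tm 58-62 C, hydrolysis probes 18-30 nt with
#' Tm 3-10 C above the primer window midpoint, and a probe laid over the
#' junction with at least `min_probe_overhang` reference bases on each side
#' of the novel sequence.
#'
#' @param max_amplicon_len Maximum amplicon length (bp, default 99 so that
#'   every amplicon is < 100 bp).
#' @param primer_len Length range for primers (nt).
#' @param probe_len Length range for probes (nt).
#' @param primer_tm Tm window for primers (degrees C).
#' @param probe_tm Tm window for probes (degrees C).
#' @param gc GC-fraction range for all oligos.
#' @param min_probe_overhang Minimum bases of probe on each side of the
#'   junction's novel sequence.
#' @param double_probe Design two non-overlapping probes over the junction,
#'   one per strand (used to maximize detection for single-target patients).
#' @param penalty_tm,penalty_gc,penalty_len Penalty weights: per degree C of
#'   Tm deviation from the window midpoint, per unit GC-fraction deviation
#'   from the range midpoint, and per base of amplicon length.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(max_amplicon_len = 99L,
                               primer_len = c(18L, 27L),
                               probe_len = c(18L, 30L),
                               primer_tm = c(58, 62),
                               probe_tm = c(63, 70),
                               gc = c(0.30, 0.70),
                               min_probe_overhang = 4L,
                               double_probe = FALSE,
                               penalty_tm = 1.0,
                               penalty_gc = 10.0,
                               penalty_len = 0.05) {
  stopifnot(max_amplicon_len >= 1, primer_len[1] <= primer_len[2],
            probe_len[1] <= probe_len[2], primer_tm[1] <= primer_tm[2],
            probe_tm[1] <= probe_tm[2], gc[1] <= gc[2],
            min_probe_overhang >= 1)
  structure(list(max_amplicon_len = as.integer(max_amplicon_len),
                 primer_len = as.integer(primer_len),
                 probe_len = as.integer(probe_len),
                 primer_tm = primer_tm, probe_tm = probe_tm, gc = gc,
                 min_probe_overhang = as.integer(min_probe_overhang),
                 double_probe = isTRUE(double_probe),
                 penalty_tm = penalty_tm, penalty_gc = penalty_gc,
                 penalty_len = penalty_len),
            class = "design_constraints")
}

seq_safe <- function(lo, hi) if (hi < lo) integer(0) else seq(lo, hi)

# Enumerate oligo placements starting at `starts` with lengths `lens` on the
# template, filtered to Tm/GC windows. Returns a data.frame with penalties.
enumerate_oligos <- function(template, starts, lens, tm_window, gc_range,
                             penalty_tm, penalty_gc, revcomp_seq = FALSE) {
  n <- nchar(template)
  if (length(starts) == 0L) return(NULL)
  grid <- expand.grid(start = starts, len = lens)
  grid$end <- grid$start + grid$len - 1L
  grid <- grid[grid$start >= 1L & grid$end <= n, , drop = FALSE]
  if (nrow(grid) == 0L) return(NULL)
  seqs <- substring(template, grid$start, grid$end)
  ok <- grepl("^[ACGT]+$", seqs)
  grid <- grid[ok, , drop = FALSE]; seqs <- seqs[ok]
  if (nrow(grid) == 0L) return(NULL)
  if (revcomp_seq)
    seqs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
  grid$seq <- seqs
  grid$tm <- vapply(seqs, melting_temperature, numeric(1), USE.NAMES = FALSE)
  grid$gc <- vapply(seqs, gc_fraction, numeric(1), USE.NAMES = FALSE)
  grid$tm_ok <- grid$tm >= tm_window[1] & grid$tm <= tm_window[2]
  grid$gc_ok <- grid$gc >= gc_range[1] & grid$gc <= gc_range[2]
  grid$penalty <- penalty_tm * abs(grid$tm - mean(tm_window)) +
    penalty_gc * abs(grid$gc - mean(gc_range))
  grid
}

design_failure <- function(junction_id, reasons) {
  structure(list(junction_id = junction_id, reasons = reasons),
            class = "assay_design_failure")
}

#' @export
print.assay_design_failure <- function(x, ...) {
  cat(sprintf("<assay design FAILED for %s>\n", x$junction_id))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Design a breakpoint-spanning primer/probe assay on a junction sequence
#'
#' Exhaustive search over primer and probe placements on the junction
#' sequence subject to [design_constraints()]: the amplicon must contain the
#' junction's novel sequence, the probe(s) must lie between the primers and
#' over the junction, and all oligos must sit inside their Tm and GC
#' windows. Among valid layouts the one with the lowest penalty
#' (Tm deviation + GC deviation + amplicon length, under the constraint
#' weights) wins; ties break to the shorter amplicon, then the
#' lexicographically smallest forward primer. In double-probe mode two
#' non-overlapping probes jointly cover the junction, the 5' probe on the
#' plus and the 3' probe on the minus strand.
#'
#' @param junction A `junction_sequence` (from [reconstruct_junction()] or
#'   [read_junctions()]).
#' @param constraints A [design_constraints()] object.
#' @return An object of class `assay_design`, or `assay_design_failure`
#'   listing each constraint that eliminated all candidates.
#' @export
design_assay <- function(junction, constraints = design_constraints()) {
  stopifnot(inherits(junction, "junction_sequence"),
            inherits(constraints, "design_constraints"))
  cs <- constraints
  s <- junction$sequence
  n <- nchar(s)
  jo <- junction$junction_offset          # last A-flank base (1-based)
  ins <- if (is.null(junction$insert_len)) 0L else junction$insert_len
  if (n < cs$max_amplicon_len)
    stop("junction sequence (", n, " bp) shorter than max amplicon length (",
         cs$max_amplicon_len, " bp); reconstruct with longer flanks")
  ov <- cs$min_probe_overhang
  j_start <- jo - ov + 1L                 # junction interval the probe must
  j_end <- jo + ins + ov                  # cover: overhang + insert + overhang
  if (j_start < 1L || j_end > n)
    return(design_failure(junction$junction_id,
                          "junction too close to sequence end for probe overhang"))
  reasons <- character(0)

  plens <- seq(cs$primer_len[1], cs$primer_len[2])
  # Forward primers end at least one base 5' of the probe region.
  fwd <- enumerate_oligos(
    s, starts = seq_safe(max(1L, j_start - cs$max_amplicon_len), j_start - 1L),
    lens = plens, tm_window = cs$primer_tm, gc_range = cs$gc,
    penalty_tm = cs$penalty_tm, penalty_gc = cs$penalty_gc)
  if (!is.null(fwd)) fwd <- fwd[fwd$end < j_start, , drop = FALSE]
  fwd_ok <- if (is.null(fwd)) fwd else fwd[fwd$tm_ok & fwd$gc_ok, , drop = FALSE]
  if (is.null(fwd_ok) || nrow(fwd_ok) == 0L) {
    reasons <- c(reasons, oligo_fail_reason("forward primer", fwd))
  }
  # Reverse primers start at least one base 3' of the probe region.
  rev <- enumerate_oligos(
    s, starts = seq_safe(j_end + 1L, min(n, j_start + cs$max_amplicon_len)),
    lens = plens, tm_window = cs$primer_tm, gc_range = cs$gc,
    penalty_tm = cs$penalty_tm, penalty_gc = cs$penalty_gc,
    revcomp_seq = TRUE)
  rev_ok <- if (is.null(rev)) rev else rev[rev$tm_ok & rev$gc_ok, , drop = FALSE]
  if (is.null(rev_ok) || nrow(rev_ok) == 0L) {
    reasons <- c(reasons, oligo_fail_reason("reverse primer", rev))
  }
  # Probe candidates (Tm is strand-symmetric, so enumerate on plus strand).
  probes <- enumerate_oligos(
    s, starts = seq_safe(max(1L, j_end - cs$probe_len[2] + 1L), j_start),
    lens = seq(cs$probe_len[1], cs$probe_len[2]),
    tm_window = cs$probe_tm, gc_range = cs$gc,
    penalty_tm = cs$penalty_tm, penalty_gc = cs$penalty_gc)
  if (!cs$double_probe) {
    # single probe must contain the whole junction interval
    if (!is.null(probes))
      probes <- probes[probes$start <= j_start & probes$end >= j_end, ,
                       drop = FALSE]
    pr_ok <- if (is.null(probes)) probes else
      probes[probes$tm_ok & probes$gc_ok, , drop = FALSE]
    if (is.null(pr_ok) || nrow(pr_ok) == 0L)
      reasons <- c(reasons, oligo_fail_reason("probe", probes))
    if (length(reasons)) return(design_failure(junction$junction_id, reasons))
    pr_ok <- pr_ok[order(pr_ok$penalty, pr_ok$seq), , drop = FALSE]
    probe_sets <- lapply(seq_len(nrow(pr_ok)), function(i) {
      p <- pr_ok[i, ]
      list(penalty = p$penalty, lo = p$start, hi = p$end,
           probes = list(list(seq = p$seq, start = p$start, end = p$end,
                              strand = "+", tm = p$tm, gc = p$gc)))
    })
  } else {
    probe_sets <- double_probe_sets(s, cs, j_start, j_end)
    if (length(probe_sets) == 0L)
      reasons <- c(reasons,
                   "double probe: no non-overlapping opposite-strand pair covers the junction within Tm/GC windows")
    if (length(reasons)) return(design_failure(junction$junction_id, reasons))
  }
  if (length(reasons)) return(design_failure(junction$junction_id, reasons))

  # Order probe sets by penalty; for each primer pair take the first fitting.
  probe_sets <- probe_sets[order(vapply(probe_sets, `[[`, numeric(1),
                                        "penalty"))]
  fwd_ok <- fwd_ok[order(fwd_ok$penalty), , drop = FALSE]
  rev_ok <- rev_ok[order(rev_ok$penalty), , drop = FALSE]

  best <- NULL
  amplicon_seen <- FALSE
  f_start <- fwd_ok$start; f_end <- fwd_ok$end; f_pen <- fwd_ok$penalty
  r_start <- rev_ok$start; r_end <- rev_ok$end; r_pen <- rev_ok$penalty
  ps_pen <- vapply(probe_sets, `[[`, numeric(1), "penalty")
  ps_lo <- vapply(probe_sets, `[[`, numeric(1), "lo")
  ps_hi <- vapply(probe_sets, `[[`, numeric(1), "hi")
  for (i in seq_along(f_start)) {
    amp_len_j <- r_end - f_start[i] + 1L
    fit_amp <- which(amp_len_j <= cs$max_amplicon_len)
    if (length(fit_amp)) amplicon_seen <- TRUE
    for (j in fit_amp) {
      base_pen <- f_pen[i] + r_pen[j] + cs$penalty_len * amp_len_j[j]
      if (!is.null(best) && base_pen + ps_pen[1] > best$penalty + 1e-9) next
      k <- which(ps_lo > f_end[i] & ps_hi < r_start[j])
      if (length(k) == 0L) next
      k <- k[1]  # probe sets sorted by penalty: first fitting is best
      cand <- list(f = fwd_ok[i, ], r = rev_ok[j, ], ps = probe_sets[[k]],
                   penalty = base_pen + ps_pen[k],
                   amp_len = amp_len_j[j])
      if (is.null(best) || better_design(cand, best)) best <- cand
    }
  }
  if (is.null(best)) {
    reasons <- if (!amplicon_seen)
      sprintf("amplicon: no primer pair yields an amplicon <= %d bp spanning the junction",
              cs$max_amplicon_len)
    else
      "probe placement: no probe fits between any valid primer pair"
    return(design_failure(junction$junction_id, reasons))
  }
  f <- best$f; r <- best$r
  tms <- c(forward = f$tm, reverse = r$tm,
           setNames(vapply(best$ps$probes, `[[`, numeric(1), "tm"),
                    paste0("probe", seq_along(best$ps$probes))))
  structure(list(junction_id = junction$junction_id,
                 forward_primer = list(seq = f$seq, start = f$start,
                                       end = f$end, tm = f$tm, gc = f$gc),
                 reverse_primer = list(seq = r$seq, start = r$start,
                                       end = r$end, tm = r$tm, gc = r$gc),
                 probes = best$ps$probes,
                 amplicon = list(start = f$start, end = r$end,
                                 length = best$amp_len),
                 junction_offset = jo, insert_len = ins,
                 tm = tms, penalty = best$penalty),
            class = "assay_design")
}

# Deterministic tie-breaking: penalty, then amplicon length, then forward
# primer sequence.
better_design <- function(a, b) {
  if (abs(a$penalty - b$penalty) > 1e-9) return(a$penalty < b$penalty)
  if (a$amp_len != b$amp_len) return(a$amp_len < b$amp_len)
  a$f$seq < b$f$seq
}

oligo_fail_reason <- function(role, grid) {
  if (is.null(grid) || nrow(grid) == 0L)
    return(sprintf("%s: no placement of the allowed lengths fits the sequence",
                   role))
  sprintf("%s: %d placements, none inside windows (Tm ok: %d, GC ok: %d)",
          role, nrow(grid), sum(grid$tm_ok), sum(grid$gc_ok))
}

# Enumerate adjacent probe pairs jointly covering [j_start, j_end]: the 5'
# probe (plus strand) covers [.., b], the 3' probe (minus strand) [b+1, ..],
# for every boundary b inside the junction interval.
double_probe_sets <- function(s, cs, j_start, j_end) {
  n <- nchar(s)
  out <- list()
  for (b in seq(j_start, j_end - 1L)) {
    for (ll in seq(cs$probe_len[1], cs$probe_len[2])) {
      ls <- b - ll + 1L
      if (ls < 1L || ls > j_start) next
      lseq <- substr(s, ls, b)
      if (!grepl("^[ACGT]+$", lseq)) next
      ltm <- melting_temperature(lseq); lgc <- gc_fraction(lseq)
      if (ltm < cs$probe_tm[1] || ltm > cs$probe_tm[2]) next
      if (lgc < cs$gc[1] || lgc > cs$gc[2]) next
      lpen <- cs$penalty_tm * abs(ltm - mean(cs$probe_tm)) +
        cs$penalty_gc * abs(lgc - mean(cs$gc))
      for (rl in seq(cs$probe_len[1], cs$probe_len[2])) {
        re <- b + rl
        if (re > n || re < j_end) next
        rtmpl <- substr(s, b + 1L, re)
        if (!grepl("^[ACGT]+$", rtmpl)) next
        rtm <- melting_temperature(rtmpl); rgc <- gc_fraction(rtmpl)
        if (rtm < cs$probe_tm[1] || rtm > cs$probe_tm[2]) next
        if (rgc < cs$gc[1] || rgc > cs$gc[2]) next
        rpen <- cs$penalty_tm * abs(rtm - mean(cs$probe_tm)) +
          cs$penalty_gc * abs(rgc - mean(cs$gc))
        out[[length(out) + 1L]] <- list(
          penalty = lpen + rpen, lo = ls, hi = re,
          probes = list(
            list(seq = lseq, start = ls, end = b, strand = "+",
                 tm = ltm, gc = lgc),
            list(seq = revcomp(rtmpl), start = b + 1L, end = re,
                 strand = "-", tm = rtm, gc = rgc)))
      }
    }
  }
  out
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("<assay_design %s: amplicon %d bp [%d-%d]>\n", x$junction_id,
              x$amplicon$length, x$amplicon$start, x$amplicon$end))
  cat(sprintf("  F  %s (%d-%d, Tm %.1f)\n", x$forward_primer$seq,
              x$forward_primer$start, x$forward_primer$end,
              x$forward_primer$tm))
  cat(sprintf("  R  %s (%d-%d, Tm %.1f)\n", x$reverse_primer$seq,
              x$reverse_primer$start, x$reverse_primer$end,
              x$reverse_primer$tm))
  for (p in x$probes)
    cat(sprintf("  P%s %s (%d-%d, Tm %.1f)\n", p$strand, p$seq, p$start,
                p$end, p$tm))
  invisible(x)
}

#' Independently re-validate an assay design against its constraints
#'
#' A checker deliberately separate from the search in [design_assay()]:
#' verifies oligo/template consistency, amplicon size and junction
#' containment, probe layout (including the double-probe coverage rule) and
#' all Tm/GC windows. Used by the test-suite to confirm every emitted design
#' honours its constraints.
#'
#' @param design An `assay_design`.
#' @param junction The `junction_sequence` it was designed on.
#' @param constraints The [design_constraints()] used.
#' @return A list with `ok` (logical) and `problems` (character vector).
#' @export
validate_assay_design <- function(design, junction,
                                  constraints = design_constraints()) {
  cs <- constraints
  s <- junction$sequence
  jo <- junction$junction_offset
  ins <- if (is.null(junction$insert_len)) 0L else junction$insert_len
  j_start <- jo - cs$min_probe_overhang + 1L
  j_end <- jo + ins + cs$min_probe_overhang
  p <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  f <- design$forward_primer; r <- design$reverse_primer
  chk(design$amplicon$length < 100, "amplicon not < 100 bp")
  chk(design$amplicon$length <= cs$max_amplicon_len,
      "amplicon exceeds max_amplicon_len")
  chk(f$end < r$start, "forward primer not upstream of reverse primer")
  chk(identical(substr(s, f$start, f$end), f$seq),
      "forward primer does not match template")
  chk(identical(revcomp(substr(s, r$start, r$end)), r$seq),
      "reverse primer is not the reverse complement of its template interval")
  chk(design$amplicon$start <= j_start && design$amplicon$end >= j_end,
      "amplicon does not contain the junction")
  for (pl in list(f, r)) {
    chk(nchar(pl$seq) >= cs$primer_len[1] && nchar(pl$seq) <= cs$primer_len[2],
        "primer length outside range")
    chk(pl$tm >= cs$primer_tm[1] && pl$tm <= cs$primer_tm[2],
        "primer Tm outside window")
    chk(pl$gc >= cs$gc[1] && pl$gc <= cs$gc[2], "primer GC outside range")
  }
  covered <- integer(0)
  for (pr in design$probes) {
    tmpl <- substr(s, pr$start, pr$end)
    want <- if (pr$strand == "+") tmpl else revcomp(tmpl)
    chk(identical(pr$seq, want), "probe sequence/strand/template mismatch")
    chk(nchar(pr$seq) >= cs$probe_len[1] && nchar(pr$seq) <= cs$probe_len[2],
        "probe length outside range")
    chk(pr$tm >= cs$probe_tm[1] && pr$tm <= cs$probe_tm[2],
        "probe Tm outside window")
    chk(pr$gc >= cs$gc[1] && pr$gc <= cs$gc[2], "probe GC outside range")
    chk(pr$start > f$end && pr$end < r$start,
        "probe overlaps a primer")
    chk(pr$start <= j_end && pr$end >= j_start,
        "probe does not overlap the junction interval")
    covered <- c(covered, seq(pr$start, pr$end))
  }
  if (length(design$probes) == 1L) {
    pr <- design$probes[[1]]
    chk(pr$start <= j_start && pr$end >= j_end,
        "single probe does not contain the junction with the required overhang")
  } else if (length(design$probes) == 2L) {
    s1 <- design$probes[[1]]; s2 <- design$probes[[2]]
    chk(s1$end < s2$start || s2$end < s1$start, "double probes overlap")
    chk(!identical(s1$strand, s2$strand), "double probes on the same strand")
    chk(all(seq(j_start, j_end) %in% covered),
        "double probes do not jointly cover the junction interval")
  } else {
    p <- c(p, "unexpected number of probes")
  }
  list(ok = length(p) == 0L, problems = p)
}
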