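#' Assemble a longitudinal MRD report
#'
#' Organizes per-sample quantification results into per-patient,
#' per-compartment time series: ratios rendered with the table conventions
#' (trace in parentheses, `"ND"` for not detected), plus log10 changes of
#' the reference-channel CN/ml between the first and each later timepoint
#' (cfDNA kinetics). Samples without a reference signal are omitted with a
#' warning.
#'
#' @param results Data.frame from [quantify_samples()].
#' @param whole_percent_compartments Compartments whose ratios are rendered
#'   as whole percentages (default `"CSF-cfDNA"`).
#' @return An object of class `mrd_report`: list with `table` (long format,
#'   ordered by patient/compartment/timepoint) and `log10_changes`.
#' @export
build_report <- function(results,
                         whole_percent_compartments = "CSF-cfDNA") {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  drop <- !is.na(results$ref_copies) & results$ref_copies <= 0
  if (any(drop)) {
    warning("omitting ", sum(drop),
            " sample(s) with no reference-channel signal: ",
            paste(results$sample_id[drop], collapse = ", "))
    results <- results[!drop, , drop = FALSE]
  }
  if (!"patient_id" %in% names(results) || all(is.na(results$patient_id)))
    results$patient_id <- "patient"
  ord <- order(results$patient_id, results$compartment,
               results$timepoint_day)
  tab <- results[ord, , drop = FALSE]
  dup <- duplicated(tab[c("patient_id", "compartment", "timepoint_day")])
  if (any(dup))
    stop("timepoints not strictly increasing: duplicate day(s) ",
         paste(unique(tab$timepoint_day[dup]), collapse = ", "),
         " within a patient/compartment series")
  tab$ratio_display <- vapply(seq_len(nrow(tab)), function(i)
    format_ratio_percent(tab$ratio_percent[i],
                         trace = tab$positivity[i] == "trace",
                         nd = tab$positivity[i] == "not_detected",
                         whole = tab$compartment[i] %in%
                           whole_percent_compartments), character(1))
  changes <- list()
  for (pt in unique(tab$patient_id)) {
    for (cp in unique(tab$compartment[tab$patient_id == pt])) {
      sub <- tab[tab$patient_id == pt & tab$compartment == cp, ,
                 drop = FALSE]
      if (nrow(sub) < 2L || cp == "BM-gDNA") next
      first <- sub[1L, ]
      for (i in 2:nrow(sub)) {
        if (is.na(first$ref_cn_per_ml) || is.na(sub$ref_cn_per_ml[i]) ||
            first$ref_cn_per_ml <= 0 || sub$ref_cn_per_ml[i] <= 0) next
        changes[[length(changes) + 1L]] <- data.frame(
          patient_id = pt, compartment = cp,
          from_day = first$timepoint_day, to_day = sub$timepoint_day[i],
          log10_change = round(log10(first$ref_cn_per_ml /
                                       sub$ref_cn_per_ml[i]), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(patient_id = character(0), compartment = character(0),
               from_day = numeric(0), to_day = numeric(0),
               log10_change = numeric(0))
  structure(list(table = tab, log10_changes = changes),
            class = "mrd_report")
}

#' @export
print.mrd_report <- function(x, ...) {
  cat("<mrd_report>\n")
  cols <- c("patient_id", "compartment", "timepoint_day", "positivity",
            "ratio_display")
  print(x$table[, intersect(cols, names(x$table))], row.names = FALSE)
  if (nrow(x$log10_changes)) {
    cat("\nreference-channel cfDNA log10 changes:\n")
    print(x$log10_changes, row.names = FALSE)
  }
  invisible(x)
}

#' Write an MRD report to TSV and JSON
#'
#' @param report An `mrd_report`.
#' @param tsv_path,json_path Output paths (`NULL` to skip).
#' @return The report, invisibly.
#' @export
write_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "mrd_report"))
  if (!is.null(tsv_path))
    write.table(report$table, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(table = report$table,
                              log10_changes = report$log10_changes),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(report)
}
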