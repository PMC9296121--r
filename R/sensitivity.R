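#' Fit a ddPCR dilution series: linearity, LoD and LoQ
#'
#' Analyzes a serial (typically 10-fold) dilution series of positive-control
#' DNA in negative-control DNA. Per dilution, replicate wells are merged,
#' copies estimated by Poisson statistics and the corrected
#' target:reference ratio computed; linearity is the least-squares
#' regression of log10(ratio) on log10(dilution) over target-positive
#' points. The limit of detection (LoD) is the most dilute level of the
#' unbroken detection chain from the top of the series (trace counts as
#' detected); the limit of quantifiability (LoQ) is the most dilute level
#' at which the point itself is positive and accurate and the fit down to
#' that level remains linear.
#'
#' @param points A data.frame with columns `dilution`, `n_total`,
#'   `n_target_pos`, `n_ref_pos` (one row per well; wells sharing a dilution
#'   are merged).
#' @param spec A [sample_spec()] supplying the ratio correction factors
#'   (default: single target, diploid reference, gDNA).
#' @param slope_tolerance Maximum |slope - 1| for the restricted fit at the
#'   LoQ (default 0.15).
#' @param r2_min Minimum r-squared for the restricted fit (default 0.98).
#' @param accuracy_tolerance_log10 Maximum |log10(measured/expected)| of the
#'   candidate LoQ point, expected ratios extrapolating proportionally from
#'   the least dilute positive point (default 0.5).
#' @return An object of class `dilution_fit` with the per-point table
#'   (`$points`), `slope`, `intercept`, `r_squared`, `lod_dilution`,
#'   `loq_dilution` and `non_monotone` flag. `slope`/`intercept` are `NA`
#'   when fewer than 3 points are positive.
#' @seealso [extrapolate_theoretical_ratio()], [predict.dilution_fit()]
#' @export
dilution_series <- function(points,
                            spec = sample_spec("PC", "BM-gDNA",
                                               dna_mass_ng = 500),
                            slope_tolerance = 0.15, r2_min = 0.98,
                            accuracy_tolerance_log10 = 0.5) {
  stopifnot(is.data.frame(points),
            all(c("dilution", "n_total", "n_target_pos", "n_ref_pos") %in%
                  names(points)))
  if (any(points$dilution <= 0 | points$dilution > 1))
    stop("dilutions must be in (0, 1]")
  agg <- aggregate(points[c("n_total", "n_target_pos", "n_ref_pos")],
                   by = list(dilution = points$dilution), FUN = sum)
  agg <- agg[order(-agg$dilution), , drop = FALSE]  # least dilute first
  rownames(agg) <- NULL
  n <- nrow(agg)
  agg$target_copies <- agg$ref_copies <- agg$ratio_percent <- NA_real_
  agg$positivity <- NA_character_
  for (i in seq_len(n)) {
    agg$target_copies[i] <- poisson_copies(agg$n_target_pos[i],
                                           agg$n_total[i])
    agg$ref_copies[i] <- poisson_copies(agg$n_ref_pos[i], agg$n_total[i])
    agg$positivity[i] <- classify_positivity(agg$n_target_pos[i])
    if (agg$positivity[i] == "not_detected") agg$target_copies[i] <- 0
    agg$ratio_percent[i] <- if (agg$ref_copies[i] > 0)
      mrd_ratio(agg$target_copies[i], agg$ref_copies[i], spec) else NA_real_
  }
  fit <- fit_linearity(agg)
  lod <- determine_lod(agg)
  loq <- determine_loq(agg, spec, slope_tolerance, r2_min,
                       accuracy_tolerance_log10)
  structure(list(points = agg, spec = spec,
                 slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, n_fit = fit$n_points,
                 lod_dilution = lod$lod, non_monotone = lod$non_monotone,
                 loq_dilution = loq,
                 criteria = list(slope_tolerance = slope_tolerance,
                                 r2_min = r2_min,
                                 accuracy_tolerance_log10 =
                                   accuracy_tolerance_log10)),
            class = "dilution_fit")
}

#' Least-squares linearity fit of a dilution series
#'
#' Regression of log10(measured ratio) on log10(dilution) over
#' target-positive points only; undefined (all `NA`) with fewer than three
#' positive points.
#'
#' @param points Data.frame with `dilution`, `ratio_percent`, `positivity`.
#' @return List with `slope`, `intercept` (log10 percent), `r_squared`,
#'   `n_points`.
#' @export
fit_linearity <- function(points) {
  use <- points$positivity == "positive" & is.finite(points$ratio_percent) &
    points$ratio_percent > 0
  if (sum(use) < 3L)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n_points = sum(use)))
  x <- log10(points$dilution[use])
  y <- log10(points$ratio_percent[use])
  m <- lm(y ~ x)
  list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       r_squared = summary(m)$r.squared, n_points = sum(use))
}

# LoD: most dilute level of the unbroken >=1-droplet chain from the least
# dilute point; a detected point below an undetected one marks the series
# non-monotone and the chain stops at the gap.
determine_lod <- function(points) {
  detected <- points$n_target_pos >= 1L  # sorted least dilute first
  if (!any(detected)) return(list(lod = NA_real_, non_monotone = FALSE))
  run <- cumprod(detected) == 1
  non_monotone <- any(detected & !run)
  lod <- if (any(run)) points$dilution[max(which(run))] else NA_real_
  list(lod = lod, non_monotone = non_monotone)
}

# LoQ: most dilute level d where the point is positive and accurate and the
# fit over dilutions >= d stays linear.
determine_loq <- function(points, spec, slope_tolerance, r2_min,
                          accuracy_tolerance_log10) {
  pos <- points$positivity == "positive" & is.finite(points$ratio_percent) &
    points$ratio_percent > 0
  if (!any(pos)) return(NA_real_)
  anchor <- min(which(pos))  # least dilute positive point
  r0 <- points$ratio_percent[anchor] / points$dilution[anchor]
  for (i in rev(seq_len(nrow(points)))) {    # most dilute first
    if (!pos[i]) next
    expected <- r0 * points$dilution[i]
    if (abs(log10(points$ratio_percent[i] / expected)) >
        accuracy_tolerance_log10) next
    sub <- points[points$dilution >= points$dilution[i], , drop = FALSE]
    f <- fit_linearity(sub)
    if (is.na(f$slope)) next
    if (abs(f$slope - 1) <= slope_tolerance && f$r_squared >= r2_min)
      return(points$dilution[i])
  }
  NA_real_
}

#' Extrapolate a theoretical diagnostic ratio from a dilution series
#'
#' When no diagnostic sample was analyzed, the diagnostic (or any other)
#' ratio can be extrapolated from the series fit:
#' \eqn{10^{(intercept + slope \cdot \log_{10} d)}} percent at dilution `d`.
#'
#' @param fit A `dilution_fit`.
#' @param at_dilution Dilution at which to evaluate (default 1 = undiluted).
#' @return Ratio in percent.
#' @export
extrapolate_theoretical_ratio <- function(fit, at_dilution = 1) {
  stopifnot(inherits(fit, "dilution_fit"))
  if (is.na(fit$slope))
    stop("linearity fit undefined (fewer than 3 positive points); ",
         "cannot extrapolate")
  10^(fit$intercept + fit$slope * log10(at_dilution))
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf("<dilution_fit: %d levels, %d in fit>\n", nrow(x$points),
              x$n_fit))
  if (!is.na(x$slope))
    cat(sprintf("  log-log slope %.3f, intercept %.3f, r^2 %.4f\n",
                x$slope, x$intercept, x$r_squared))
  else cat("  linearity undefined (<3 positive points)\n")
  cat(sprintf("  LoD %s   LoQ %s%s\n", format_dilution(x$lod_dilution),
              format_dilution(x$loq_dilution),
              if (x$non_monotone) "   [non-monotone detection]" else ""))
  invisible(x)
}

#' @export
summary.dilution_fit <- function(object, ...) {
  print(object)
  df <- object$points
  df$dilution <- format_dilution(df$dilution)
  print(df[, c("dilution", "n_total", "n_target_pos", "n_ref_pos",
               "ratio_percent", "positivity")], digits = 4)
  invisible(object)
}

#' @export
coef.dilution_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict ratios at new dilutions from a dilution-series fit
#'
#' @param object A `dilution_fit`.
#' @param newdata Numeric vector of dilutions (default: the fitted levels).
#' @param ... Unused.
#' @return Predicted ratio_percent values.
#' @export
predict.dilution_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$points$dilution
  vapply(newdata, function(d) extrapolate_theoretical_ratio(object, d),
         numeric(1))
}

#' @export
residuals.dilution_fit <- function(object, ...) {
  use <- object$points$positivity == "positive" &
    is.finite(object$points$ratio_percent) & object$points$ratio_percent > 0
  log10(object$points$ratio_percent[use]) -
    log10(predict(object, object$points$dilution[use]))
}

#' Plot a dilution-series fit (log-log)
#'
#' @param x A `dilution_fit`.
#' @param ... Passed to [plot.default()].
#' @export
plot.dilution_fit <- function(x, ...) {
  df <- x$points
  ok <- is.finite(df$ratio_percent) & df$ratio_percent > 0
  graphics::plot(log10(df$dilution[ok]), log10(df$ratio_percent[ok]),
                 xlab = "log10 dilution", ylab = "log10 ratio (%)",
                 pch = ifelse(df$positivity[ok] == "positive", 19, 1), ...)
  if (!is.na(x$slope))
    graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

format_dilution <- function(d) {
  ifelse(is.na(d), "none",
         ifelse(d == 1, "1", sprintf("10^%g", log10(d))))
}
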