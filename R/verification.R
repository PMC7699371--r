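# Verification: bin-wise relative uncertainty from bias and precision,
# judged against the accuracy target, and fold-improvement of the full
# correction model over an average (monitor-only) correction.

#' Default concentration bin edges
#'
#' Half-open bins with uppers 500, 1000, 1500, 2000, 3000 and 5000 ug/m^3,
#' the bin layout used for the verification of corrected monitors.
#'
#' @return Numeric vector of edges.
#' @export
default_bin_edges <- function() c(0, 500, 1000, 1500, 2000, 3000, 5000)

#' Assign prediction/reference pairs to concentration bins
#'
#' Bins are half-open `[lower, upper)` on the reference (true-concentration)
#' axis; a pair at exactly an edge goes to the bin opening at that edge.
#' Pairs at or above the last edge are excluded and counted.
#'
#' @param predictions Corrected monitor concentrations (ug/m^3).
#' @param reference Paired reference concentrations (ug/m^3).
#' @param edges Strictly increasing bin edges (default
#'   [default_bin_edges()]).
#' @return List with `bins` (list of data.frames with `prediction`,
#'   `reference`), `lower`, `upper`, `n` (per-bin counts),
#'   `n_excluded` (pairs at/above the last edge or below the first).
#' @export
bin_by_reference <- function(predictions, reference,
                             edges = default_bin_edges()) {
  if (length(predictions) != length(reference))
    stopf("'predictions' and 'reference' must be paired")
  if (any(diff(edges) <= 0)) stopf("'edges' must be strictly increasing")
  k <- length(edges) - 1L
  idx <- findInterval(reference, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  in_range <- idx >= 1L & idx <= k
  bins <- lapply(seq_len(k), function(b) {
    sel <- in_range & idx == b
    data.frame(prediction = predictions[sel], reference = reference[sel])
  })
  list(bins = bins, lower = edges[-length(edges)], upper = edges[-1L],
       n = vapply(bins, nrow, 0L), n_excluded = sum(!in_range))
}

#' Bin-wise bias and precision
#'
#' Bias is the mean relative deviation of predictions from the reference;
#' the raw relative spread is the SD of the prediction/reference ratio.
#' Because the reference instrument itself carries relative uncertainty
#' (10% by default), that component is removed in quadrature, floored at
#' zero, to isolate the monitor's own precision:
#' \deqn{S = \sqrt{\max(S_{obs}^2 - u_{ref}^2 - u_{extra}^2,\, 0)}}
#'
#' @param prediction Corrected monitor concentrations within one bin.
#' @param reference Paired reference concentrations (> 0).
#' @param ref_uncertainty Relative SD of the reference (default 0.10).
#' @param extra_uncertainty Optional additional relative SD for exposure
#'   concentration instability (default 0).
#' @param n_min Minimum pairs required (default 30); below it the result
#'   has status `"insufficient_data"` with NA statistics.
#' @return List with `bias`, `precision`, `n`, `status`.
#' @export
bias_precision <- function(prediction, reference, ref_uncertainty = 0.10,
                           extra_uncertainty = 0, n_min = 30) {
  ok <- is.finite(prediction) & is.finite(reference) & reference > 0
  prediction <- prediction[ok]; reference <- reference[ok]
  n <- length(prediction)
  if (n < n_min)
    return(list(bias = NA_real_, precision = NA_real_, n = n,
                status = "insufficient_data"))
  ratio <- prediction / reference
  bias <- mean(ratio) - 1
  s_obs <- sd(ratio)
  s <- sqrt(max(s_obs^2 - ref_uncertainty^2 - extra_uncertainty^2, 0))
  list(bias = bias, precision = s, n = n, status = "ok")
}

#' Relative uncertainty from bias and precision
#'
#' The symmetric 95% accuracy band combining systematic and random error:
#' \deqn{U = (|B| + 1.96\,S) \times 100\%}
#' With zero bias and normal multiplicative errors, ~95% of readings fall
#' within +/- U of the reference. Implemented as a single small function so
#' an alternative accuracy criterion can be swapped in.
#'
#' @param bias Relative bias (dimensionless).
#' @param precision Relative precision SD (>= 0).
#' @return Relative uncertainty in percent.
#' @examples
#' relative_uncertainty(0.10, 0.05)  # 19.8
#' @export
relative_uncertainty <- function(bias, precision) {
  if (any(precision < 0, na.rm = TRUE)) stopf("'precision' must be >= 0")
  (abs(bias) + 1.96 * precision) * 100
}

#' Bin-wise uncertainty report for one monitor
#'
#' Bins verification pairs by reference concentration, computes bias,
#' precision and relative uncertainty per bin, and judges each bin against
#' the accuracy target.
#'
#' @param predictions Corrected monitor concentrations (ug/m^3).
#' @param reference Paired reference concentrations.
#' @param edges Bin edges (default [default_bin_edges()]).
#' @param target Target relative uncertainty in percent (default 50).
#' @param ref_uncertainty,extra_uncertainty,n_min Passed to
#'   [bias_precision()].
#' @param monitor Monitor label for the report.
#' @return An object of class `uncertainty_report`; its `bins` element is a
#'   data.frame with `lower`, `upper`, `n`, `bias`, `precision`,
#'   `uncertainty` (%), `meets_target`, `status`.
#' @export
uncertainty_report <- function(predictions, reference,
                               edges = default_bin_edges(), target = 50,
                               ref_uncertainty = 0.10,
                               extra_uncertainty = 0, n_min = 30,
                               monitor = "monitor") {
  bb <- bin_by_reference(predictions, reference, edges)
  rows <- lapply(seq_along(bb$bins), function(i) {
    bp <- bias_precision(bb$bins[[i]]$prediction, bb$bins[[i]]$reference,
                         ref_uncertainty = ref_uncertainty,
                         extra_uncertainty = extra_uncertainty,
                         n_min = n_min)
    u <- if (bp$status == "ok")
      relative_uncertainty(bp$bias, bp$precision) else NA_real_
    data.frame(lower = bb$lower[i], upper = bb$upper[i], n = bp$n,
               bias = bp$bias, precision = bp$precision, uncertainty = u,
               meets_target = if (is.na(u)) NA else u <= target,
               status = bp$status)
  })
  bins <- do.call(rbind, rows)
  ok <- bins$status == "ok"
  structure(list(monitor = monitor, bins = bins, target = target,
                 overall_range_uncertainty =
                   if (any(ok)) max(bins$uncertainty[ok]) else NA_real_,
                 n_excluded = bb$n_excluded),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report> %s (target <= %g%%)\n", x$monitor,
              x$target))
  b <- x$bins
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  [%4.0f, %4.0f): %s\n", b$lower[i], b$upper[i],
                if (b$status[i] != "ok") "NA (insufficient data)"
                else sprintf("%6.1f%% (n=%d)%s", b$uncertainty[i], b$n[i],
                             if (isTRUE(b$meets_target[i])) " *" else "")))
  }
  invisible(x)
}

#' Compare the full correction against an average correction
#'
#' Applies both the full correction model (with evaluation variables) and a
#' reduced "average" correction (transformed reference ~ transformed
#' monitor only) to the same verification data, computes bin-wise relative
#' uncertainty for each, and reports the per-bin fold ratio
#' (reduced / full; > 1 means the evaluation variables helped) and its
#' average over bins defined for both models.
#'
#' @param full A `correction_model` including the selected variables.
#' @param reduced The base `correction_model` (monitor term only).
#' @param verification_data Long experiment table of the verification
#'   (full-factorial) experiments.
#' @param edges,target,ref_uncertainty,extra_uncertainty,n_min As in
#'   [uncertainty_report()].
#' @return List with `full_report`, `reduced_report`, `folds` (per-bin
#'   data.frame) and `average_fold`.
#' @export
compare_corrections <- function(full, reduced, verification_data,
                                edges = default_bin_edges(), target = 50,
                                ref_uncertainty = 0.10,
                                extra_uncertainty = 0, n_min = 30) {
  cond_cols <- c("material", "temperature", "relative_humidity", "power",
                 "pattern", "session_time", "unit_id")
  keep <- is.finite(verification_data$monitor) &
    is.finite(verification_data$reference) &
    verification_data$monitor > 0 & verification_data$reference > 0
  vd <- verification_data[keep, , drop = FALSE]
  pf <- predict_concentration(full, vd$monitor, vd[, cond_cols])
  pr <- predict_concentration(reduced, vd$monitor, vd[, cond_cols])
  rep_f <- uncertainty_report(pf, vd$reference, edges = edges,
                              target = target,
                              ref_uncertainty = ref_uncertainty,
                              extra_uncertainty = extra_uncertainty,
                              n_min = n_min, monitor = "full")
  rep_r <- uncertainty_report(pr, vd$reference, edges = edges,
                              target = target,
                              ref_uncertainty = ref_uncertainty,
                              extra_uncertainty = extra_uncertainty,
                              n_min = n_min, monitor = "reduced")
  both_ok <- rep_f$bins$status == "ok" & rep_r$bins$status == "ok"
  folds <- data.frame(lower = rep_f$bins$lower, upper = rep_f$bins$upper,
                      uncertainty_full = rep_f$bins$uncertainty,
                      uncertainty_reduced = rep_r$bins$uncertainty,
                      fold = rep_r$bins$uncertainty / rep_f$bins$uncertainty,
                      defined = both_ok)
  folds$fold[!both_ok] <- NA_real_
  list(full_report = rep_f, reduced_report = rep_r, folds = folds,
       average_fold = mean(folds$fold[both_ok]))
}
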