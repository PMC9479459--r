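# DTDI (dose-target-determination index), focality classification, and the
# iterative threshold sweep.

#' Dose-target-determination index
#'
#' Ratio of the mean current density at the target ROI to the peak ROI-mean
#' current density. The denominator maximizes over all ROI means
#' *including* the target, so the index lies in [0, 1] and equals 1
#' exactly when the peak forms at the target ROI. The index is invariant
#' to rescaling all densities by a common factor, hence dose-invariant in
#' a linear conduction model.
#'
#' @param table data.frame from [roi_mean_density()].
#' @param target_roi target ROI id (integer label) or name.
#' @return DTDI value in [0, 1].
#' @export
dtdi <- function(table, target_roi) {
  stopifnot(is.data.frame(table), all(c("roi", "mean_mA_m2") %in% names(table)))
  row <- if (is.character(target_roi)) match(target_roi, table$name)
         else match(as.integer(target_roi), table$roi)
  if (is.na(row))
    stop_ff("lookup_error", "target ROI '%s' not present in density table",
            as.character(target_roi))
  peak <- max(table$mean_mA_m2)
  if (peak <= 0)
    stop_ff("undefined_dtdi_error", "all ROI mean densities are zero; DTDI undefined")
  table$mean_mA_m2[row] / peak
}

#' Classify focality from DTDI
#'
#' Subjects with DTDI at or above the threshold receive focal stimulation;
#' the boundary is inclusive (DTDI >= 0.75 is focal).
#'
#' @param dtdi_value numeric vector of DTDI values in [0, 1].
#' @param threshold classification threshold (default 0.75).
#' @return Character vector, `"focal"` or `"nonfocal"`.
#' @export
classify_focality <- function(dtdi_value, threshold = 0.75) {
  if (any(!is.finite(dtdi_value)) || any(dtdi_value < 0 | dtdi_value > 1))
    stop_ff("domain_error", "DTDI values must lie in [0, 1]")
  ifelse(dtdi_value >= threshold, "focal", "nonfocal")
}

#' Iterative DTDI threshold sweep
#'
#' Starting from `start`, the cohort is reclassified at thresholds
#' `start, start - step, ...` and the focal-ROI scan repeated at each.
#' The sweep stops at the first threshold whose outcome is inconsistent
#' with the starting outcome — i.e. the set of significant focal ROIs
#' changes (including loss of all significance) — and reports the last
#' consistent threshold.
#'
#' @param cohort cohort table with `dtdi` and per-ROI volume columns.
#' @param scan function taking a cohort and returning the character vector
#'   of flagged focal ROIs; defaults to [focal_roi_scan()] with its
#'   defaults.
#' @param start starting threshold (default 0.75).
#' @param step decrement per iteration (default 0.01).
#' @param min_threshold hard floor below which the sweep stops regardless.
#' @return Object of class `sweep_result`: data.frame of per-threshold
#'   outcomes and `last_consistent`, the lowest threshold that preserved
#'   the starting findings.
#' @export
threshold_sweep <- function(cohort, scan = NULL, start = 0.75, step = 0.01,
                            min_threshold = 0.5) {
  stopifnot(is.data.frame(cohort), "dtdi" %in% names(cohort))
  scan <- scan %||% function(ch) focal_roi_scan(ch)$focal_rois
  reclass <- function(thr) {
    cohort$focality <- classify_focality(cohort$dtdi, thr)
    cohort
  }
  ref <- sort(scan(reclass(start)))
  if (!length(ref))
    stop_ff("sweep_undefined_error",
            "no significant focal ROI at the starting threshold %.2f", start)
  thresholds <- start
  sets <- list(ref)
  consistent <- TRUE
  last <- start
  thr <- start - step
  while (thr >= min_threshold - 1e-9) {
    found <- sort(scan(reclass(thr)))
    ok <- identical(found, ref)
    thresholds <- c(thresholds, thr)
    sets <- c(sets, list(found))
    consistent <- c(consistent, ok)
    if (!ok) break
    last <- thr
    thr <- thr - step
  }
  structure(list(
    outcomes = data.frame(threshold = thresholds,
                          n_focal_rois = lengths(sets),
                          consistent = consistent),
    focal_roi_sets = sets,
    reference = ref,
    last_consistent = last), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("DTDI threshold sweep: findings consistent down to %.2f\n",
              x$last_consistent))
  print(x$outcomes)
  invisible(x)
}
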