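# Partial-volume regional volumetrics: per-ROI CSF/GM/WM volumes from
# tissue-fraction maps, scaling by total intracranial volume (TIV), and
# covariate residualization.

#' Regional CSF/GM/WM volumes
#'
#' The tissue volume of an ROI is the sum over its voxels of the tissue
#' fraction times the voxel volume, so partial-volume voxels contribute
#' fractionally to several tissues. Volumes are in ml (1 ml = 1000 mm^3).
#' TIV is the total CSF + GM + WM volume over the whole grid regardless of
#' parcellation coverage, so summed regional volumes equal TIV exactly
#' when the parcellation covers all brain voxels, and fall short under
#' partial coverage.
#'
#' @param phantom a `head_phantom` (its fraction maps are used).
#' @param parc optional `atlas_parcellation`; defaults to the phantom's
#'   own sector labels.
#' @return data.frame with columns `roi`, `name`, `csf_ml`, `gm_ml`,
#'   `wm_ml` and attribute `tiv_ml`.
#' @export
regional_volumes <- function(phantom, parc = NULL) {
  stopifnot(inherits(phantom, "head_phantom"))
  parc <- parc %||% phantom_parcellation(phantom)
  if (!identical(dim(parc$labels), dim(phantom$labels)))
    stop_ff("dimension_error", "parcellation grid does not match the phantom")
  vv_ml <- phantom$voxel_size_mm^3 / 1000
  lab <- as.vector(parc$labels)
  roi <- sort(setdiff(unique(lab), 0L))
  per_tissue <- sapply(BRAIN_TISSUES, function(t) {
    f <- as.vector(phantom$fractions[, , , t]) * vv_ml
    vapply(roi, function(r) sum(f[lab == r]), 0)
  })
  per_tissue <- matrix(per_tissue, nrow = length(roi),
                       dimnames = list(NULL, BRAIN_TISSUES))
  out <- data.frame(roi = roi,
                    name = parc$lookup$name[match(roi, parc$lookup$label)],
                    csf_ml = per_tissue[, "csf"],
                    gm_ml = per_tissue[, "gm"],
                    wm_ml = per_tissue[, "wm"])
  rownames(out) <- NULL
  attr(out, "tiv_ml") <- phantom_tiv_ml(phantom)
  out
}

#' Scale regional volumes by total intracranial volume
#'
#' Divides each raw regional volume by TIV (total CSF + GM + WM), adding
#' dimensionless columns `csf_s`, `gm_s`, `wm_s` and `tiv_ml`. When the
#' parcellation covers all brain tissue the scaled values sum to 1.
#'
#' @param table output of [regional_volumes()] (must carry the `tiv_ml`
#'   attribute, or a `tiv_ml` column).
#' @return The table with scaled columns appended.
#' @export
tiv_scale <- function(table) {
  tiv <- attr(table, "tiv_ml") %||% table$tiv_ml[1]
  if (is.null(tiv) || !is.finite(tiv) || tiv <= 0)
    stop_ff("degenerate_input_error", "TIV must be positive")
  table$csf_s <- table$csf_ml / tiv
  table$gm_s <- table$gm_ml / tiv
  table$wm_s <- table$wm_ml / tiv
  table$tiv_ml <- tiv
  table
}

#' Regress age and sex out of cohort volume columns
#'
#' Replaces each regional volume column by the residuals of an ordinary
#' least-squares fit on an intercept, the numeric age-group code
#' (young = 0, middle = 1, older = 2) and a sex indicator (M = 0, F = 1).
#' Age enters as the 3-level group code because the cohort design carries
#' age groups, not continuous age. Residualizing twice is a no-op.
#'
#' @param cohort cohort data.frame with `age_group`, `sex` and volume
#'   columns.
#' @param columns character vector of columns to residualize; defaults to
#'   every column matching `_(csf|gm|wm)_ml$`.
#' @return The cohort with residualized columns and attribute
#'   `residualized = TRUE`.
#' @export
residualize_covariates <- function(cohort, columns = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("age_group", "sex") %in% names(cohort)))
  columns <- columns %||% grep("_(csf|gm|wm)_ml$", names(cohort), value = TRUE)
  if (!length(columns)) stop_ff("config_error", "no volume columns to residualize")
  age_code <- age_group_code(cohort$age_group)
  sex_ind <- as.numeric(factor(cohort$sex, levels = c("M", "F"))) - 1
  if (anyNA(age_code) || anyNA(sex_ind))
    stop_ff("config_error", "age_group must be young/middle/older and sex M/F")
  X <- cbind(1, age_code, sex_ind)
  if (nrow(X) < ncol(X) + 3L)
    stop_ff("degenerate_covariate_error", "need at least %d subjects", ncol(X) + 3L)
  if (qr(X)$rank < ncol(X))
    stop_ff("degenerate_covariate_error", "rank-deficient covariate design")
  Y <- as.matrix(cohort[columns])
  cohort[columns] <- stats::lm.fit(X, Y)$residuals
  attr(cohort, "residualized") <- TRUE
  cohort
}

#' @keywords internal
#' @noRd
age_group_code <- function(age_group) {
  as.numeric(factor(as.character(age_group),
                    levels = c("young", "middle", "older"))) - 1
}
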