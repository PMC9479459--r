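# Atlas parcellation handling and per-ROI aggregation of current density.
# Aggregation happens on the native grid: phantom atlas and field share one
# grid by construction, so no spatial normalization step is involved.

#' Construct / validate an atlas parcellation
#'
#' @param labels integer 3-D array of ROI labels; 0 is background.
#' @param lookup data.frame with columns `label` (integer > 0) and `name`;
#'   every nonzero label present in `labels` must appear here.
#' @param voxel_size_mm voxel edge length in mm.
#' @return Object of class `atlas_parcellation`.
#' @export
atlas_parcellation <- function(labels, lookup, voxel_size_mm) {
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop_ff("format_error", "parcellation labels must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  stopifnot(is.integer(labels), is.data.frame(lookup),
            all(c("label", "name") %in% names(lookup)))
  if (any(labels < 0L)) stop_ff("validation_error", "negative ROI labels")
  lookup$label <- as.integer(lookup$label)
  lookup$name <- as.character(lookup$name)
  if (anyDuplicated(lookup$label))
    stop_ff("validation_error", "duplicated labels in lookup table")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  orphan <- setdiff(present, lookup$label)
  if (length(orphan))
    stop_ff("validation_error", "labels missing from lookup: %s",
            paste(orphan, collapse = ", "))
  structure(list(labels = labels, lookup = lookup,
                 voxel_size_mm = voxel_size_mm),
            class = "atlas_parcellation")
}

#' Parcellation of a phantom's sector labels
#'
#' @param phantom a `head_phantom`.
#' @param names optional ROI names; defaults to `roi01`, `roi02`, ...
#' @return An `atlas_parcellation` on the phantom grid.
#' @export
phantom_parcellation <- function(phantom, names = NULL) {
  stopifnot(inherits(phantom, "head_phantom"))
  n <- max(phantom$labels)
  names <- names %||% sprintf("roi%02d", seq_len(n))
  atlas_parcellation(phantom$labels,
                     data.frame(label = seq_len(n), name = names),
                     phantom$voxel_size_mm)
}

#' Read / write a parcellation (NIfTI labels + TSV lookup)
#'
#' The lookup is a two-column tab-separated file `label<TAB>name`.
#'
#' @param nifti_path path to the integer NIfTI label volume.
#' @param lookup_path path to the lookup TSV.
#' @return `load_parcellation()` returns an `atlas_parcellation`.
#' @export
load_parcellation <- function(nifti_path, lookup_path) {
  if (!file.exists(nifti_path) || !file.exists(lookup_path))
    stop_ff("format_error", "parcellation files not found")
  img <- RNifti::readNifti(nifti_path)
  lookup <- utils::read.delim(lookup_path, header = TRUE,
                              stringsAsFactors = FALSE)
  labels <- as.array(img)
  attributes(labels) <- list(dim = dim(labels))
  atlas_parcellation(labels, lookup, RNifti::pixdim(img)[1])
}

#' @rdname load_parcellation
#' @param parc an `atlas_parcellation` to write.
#' @export
write_parcellation <- function(parc, nifti_path, lookup_path) {
  stopifnot(inherits(parc, "atlas_parcellation"))
  img <- RNifti::asNifti(parc$labels)
  h <- parc$voxel_size_mm
  dims <- dim(parc$labels)
  RNifti::pixdim(img) <- c(h, h, h)
  affine <- diag(c(h, h, h, 1))
  affine[1:3, 4] <- -(dims + 1) / 2 * h
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, nifti_path, datatype = "int16", compression = 0)
  utils::write.table(parc$lookup[, c("label", "name")], lookup_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nifti_path)
}

#' Mean current-density magnitude per ROI
#'
#' Arithmetic mean of |J| over the voxels of each nonzero label
#' (background excluded). ROIs present in the lookup but empty on the grid
#' are omitted with a warning.
#'
#' @param field a `current_density_field`, or a numeric 3-D array of |J|
#'   values in mA/m^2.
#' @param parc an `atlas_parcellation` on the same grid.
#' @return data.frame with columns `roi`, `name`, `n_voxels`,
#'   `mean_mA_m2`.
#' @export
roi_mean_density <- function(field, parc) {
  stopifnot(inherits(parc, "atlas_parcellation"))
  mag <- if (inherits(field, "current_density_field")) field$magnitude else field
  if (!identical(dim(mag), dim(parc$labels)))
    stop_ff("dimension_error", "field and parcellation grids differ")
  lab <- as.vector(parc$labels)
  keep <- lab > 0L
  sums <- rowsum(as.vector(mag)[keep], lab[keep])
  counts <- rowsum(rep(1L, sum(keep)), lab[keep])
  roi <- as.integer(rownames(sums))
  out <- data.frame(roi = roi,
                    name = parc$lookup$name[match(roi, parc$lookup$label)],
                    n_voxels = as.integer(counts[, 1]),
                    mean_mA_m2 = sums[, 1] / counts[, 1])
  empty <- setdiff(parc$lookup$label, roi)
  if (length(empty))
    warning(sprintf("ROI(s) with no voxels omitted: %s",
                    paste(empty, collapse = ", ")))
  rownames(out) <- NULL
  out
}

#' Write an ROI density table as TSV
#' @param table data.frame from [roi_mean_density()].
#' @param path output path.
#' @export
write_roi_density <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
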