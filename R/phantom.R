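# Synthetic layered head phantoms: concentric tissue shells with 1-voxel
# partial-volume ramps, an angular-sector parcellation of the brain
# compartment, and spherical-cap electrode masks on the scalp.

TISSUES <- c("skin", "skull", "csf", "gm", "wm", "air")
BRAIN_TISSUES <- c("csf", "gm", "wm")

#' Specify a layered head phantom
#'
#' A phantom is a voxel grid holding five concentric tissue shells
#' (white matter core, then gray matter, CSF, skull and skin) around the
#' grid center, an angular-sector region-of-interest (ROI) parcellation of
#' the brain compartment, and two electrode contact patches on the scalp.
#' It is the synthetic stand-in for a segmented head MRI: coarse, but it
#' carries the features current-flow modeling depends on (a highly
#' conductive CSF layer under a resistive skull, partial-volume voxels at
#' every tissue boundary, and ROIs lying under and between the electrodes).
#'
#' @param grid_shape integer vector of length 3, voxels per axis.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param shell_radii_mm strictly increasing outer radii (mm) of the
#'   WM, GM, CSF, skull and skin shells. Must fit inside the grid.
#' @param n_rois number of angular sectors (>= 2) used to parcellate the
#'   brain compartment. Sector 1 is centered on the +x axis (under the
#'   default anode); sectors increase counter-clockwise in the x-y plane.
#' @param electrode_centers list with unit direction vectors `anode` and
#'   `cathode` pointing from the grid center to each electrode cap.
#' @param electrode_radius_mm geodesic radius (mm) of the spherical-cap
#'   electrode contact on the scalp surface.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_size_mm = 1.25,
                         shell_radii_mm = c(wm = 12, gm = 18, csf = 20.5,
                                            skull = 23.5, skin = 26.5),
                         n_rois = 12L,
                         electrode_centers = list(anode = c(1, 0, 0),
                                                  cathode = c(-1, 0, 0)),
                         electrode_radius_mm = 8) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(voxel_size_mm) == 1L, voxel_size_mm > 0,
            length(shell_radii_mm) == 5L,
            length(electrode_radius_mm) == 1L, electrode_radius_mm > 0)
  if (any(diff(shell_radii_mm) <= 0) || shell_radii_mm[1] <= 0)
    stop_ff("config_error", "shell_radii_mm must be positive and strictly increasing")
  names(shell_radii_mm) <- c("wm", "gm", "csf", "skull", "skin")
  half_extent <- min(grid_shape) * voxel_size_mm / 2
  if (shell_radii_mm["skin"] + voxel_size_mm > half_extent)
    stop_ff("config_error",
            "outer shell radius %.1f mm does not fit inside the grid (half extent %.1f mm)",
            shell_radii_mm["skin"], half_extent)
  n_rois <- as.integer(n_rois)
  if (n_rois < 2L) stop_ff("config_error", "n_rois must be >= 2")
  unitize <- function(v) {
    stopifnot(length(v) == 3L, sum(v^2) > 0)
    v / sqrt(sum(v^2))
  }
  electrode_centers <- list(anode = unitize(electrode_centers$anode),
                            cathode = unitize(electrode_centers$cathode))
  cap_half_angle <- electrode_radius_mm / shell_radii_mm["skin"]
  sep_angle <- acos(pmin(1, pmax(-1,
    sum(electrode_centers$anode * electrode_centers$cathode))))
  if (sep_angle <= 2 * cap_half_angle)
    stop_ff("config_error", "electrode caps overlap (separation %.2f rad, cap half-angle %.2f rad)",
            sep_angle, cap_half_angle)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 shell_radii_mm = shell_radii_mm, n_rois = n_rois,
                 electrode_centers = electrode_centers,
                 electrode_radius_mm = electrode_radius_mm),
            class = "phantom_spec")
}

# World coordinates (mm) of voxel centers along each axis; origin at the
# grid center.
#' @keywords internal
#' @noRd
axis_coords <- function(n, voxel_size_mm) {
  (seq_len(n) - (n + 1) / 2) * voxel_size_mm
}

#' @keywords internal
#' @noRd
voxel_coordinates <- function(grid_shape, voxel_size_mm) {
  cx <- axis_coords(grid_shape[1], voxel_size_mm)
  cy <- axis_coords(grid_shape[2], voxel_size_mm)
  cz <- axis_coords(grid_shape[3], voxel_size_mm)
  list(
    x = array(cx, grid_shape),
    y = array(rep(cy, each = grid_shape[1]), grid_shape),
    z = array(rep(cz, each = grid_shape[1] * grid_shape[2]), grid_shape)
  )
}

#' Build a head phantom from a specification
#'
#' Tissue fractions are assigned per voxel from the radial distance to the
#' grid center: inside each shell the voxel is pure tissue, and at every
#' shell boundary a linear ramp exactly one voxel wide splits the voxel
#' between the adjacent tissues, so boundary voxels are genuine
#' partial-volume mixtures. Fractions carry an explicit background (air)
#' component, so the six components sum to exactly 1 in every voxel.
#' The brain compartment (CSF + GM + WM fraction > 0) is parcellated into
#' `n_rois` angular sectors around the z axis; electrode masks are
#' spherical caps of scalp voxels around the two electrode directions.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `head_phantom`: list with `fractions`
#'   (4-D array, last dimension the tissues skin/skull/csf/gm/wm/air),
#'   `labels` (integer 3-D array, 0 = non-brain), `voxel_size_mm`,
#'   `electrode_masks` (logical arrays `anode`, `cathode`) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  h <- spec$voxel_size_mm
  co <- voxel_coordinates(dims, h)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)

  # fraction of the voxel lying inside a sphere of radius R: linear ramp of
  # width one voxel centered on the boundary
  inside <- function(R) pmin(pmax((R - r) / h + 0.5, 0), 1)
  cum <- lapply(spec$shell_radii_mm, inside)   # wm, gm, csf, skull, skin

  frac <- array(0, c(dims, length(TISSUES)),
                dimnames = list(NULL, NULL, NULL, TISSUES))
  frac[, , , "wm"]    <- cum$wm
  frac[, , , "gm"]    <- cum$gm - cum$wm
  frac[, , , "csf"]   <- cum$csf - cum$gm
  frac[, , , "skull"] <- cum$skull - cum$csf
  frac[, , , "skin"]  <- cum$skin - cum$skull
  frac[, , , "air"]   <- 1 - cum$skin

  brain <- (frac[, , , "csf"] + frac[, , , "gm"] + frac[, , , "wm"]) > 0
  # sector index in the x-y plane, sector 1 centered on +x
  phi <- atan2(co$y, co$x)
  sector_width <- 2 * pi / spec$n_rois
  sector <- (floor(((phi + sector_width / 2) %% (2 * pi)) / sector_width) %%
               spec$n_rois) + 1L
  labels <- array(0L, dims)
  labels[brain] <- as.integer(sector[brain])

  cap_mask <- function(center) {
    with_r <- pmax(r, .Machine$double.eps)
    cosang <- (co$x * center[1] + co$y * center[2] + co$z * center[3]) / with_r
    ang <- acos(pmin(pmax(cosang, -1), 1))
    (frac[, , , "skin"] >= 0.5) & (ang <= spec$electrode_radius_mm / spec$shell_radii_mm["skin"])
  }
  masks <- list(anode = cap_mask(spec$electrode_centers$anode),
                cathode = cap_mask(spec$electrode_centers$cathode))
  if (!any(masks$anode) || !any(masks$cathode))
    stop_ff("config_error", "electrode cap contains no scalp voxels; enlarge the grid or the cap")

  structure(list(fractions = frac, labels = labels, voxel_size_mm = h,
                 electrode_masks = masks, spec = spec),
            class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  dims <- dim(x$labels)
  cat(sprintf("head_phantom: %dx%dx%d voxels at %.2f mm, %d ROIs, TIV %.1f ml\n",
              dims[1], dims[2], dims[3], x$voxel_size_mm,
              max(x$labels), phantom_tiv_ml(x)))
  invisible(x)
}

#' @keywords internal
#' @noRd
phantom_tiv_ml <- function(phantom) {
  vv <- phantom$voxel_size_mm^3 / 1000
  sum(phantom$fractions[, , , BRAIN_TISSUES]) * vv
}

#' Inject a CSF pocket into one ROI
#'
#' Converts GM/WM tissue fraction to CSF inside the given ROI until the
#' requested CSF volume has been added, filling voxels nearest the CSF
#' shell (largest radius) first; the last voxel is converted partially so
#' the added volume is met exactly. This is the synthetic lever for the
#' mechanism under study: regional CSF pockets that channel stimulation
#' current.
#'
#' @param phantom a `head_phantom`.
#' @param roi integer ROI label to modify.
#' @param added_volume_ml CSF volume (ml) to add; 0 returns the phantom
#'   unchanged.
#' @return The modified `head_phantom`.
#' @export
inject_csf_pocket <- function(phantom, roi, added_volume_ml) {
  stopifnot(inherits(phantom, "head_phantom"),
            length(added_volume_ml) == 1L, added_volume_ml >= 0)
  roi <- as.integer(roi)
  idx <- which(phantom$labels == roi)
  if (!length(idx)) stop_ff("lookup_error", "ROI %d not present in phantom", roi)
  if (added_volume_ml == 0) return(phantom)

  dims <- dim(phantom$labels)
  nvox <- prod(dims)
  frac <- phantom$fractions
  gm <- frac[, , , "gm"][idx]
  wm <- frac[, , , "wm"][idx]
  convertible <- gm + wm
  vv <- phantom$voxel_size_mm^3          # mm^3 per voxel
  target_mm3 <- added_volume_ml * 1000
  total_mm3 <- sum(convertible) * vv
  if (target_mm3 > total_mm3 + 1e-9)
    stop_ff("capacity_error",
            "requested %.2f ml exceeds convertible GM+WM volume %.2f ml in ROI %d",
            added_volume_ml, total_mm3 / 1000, roi)

  co <- voxel_coordinates(dims, phantom$voxel_size_mm)
  r <- sqrt(co$x[idx]^2 + co$y[idx]^2 + co$z[idx]^2)
  ord <- order(r, decreasing = TRUE)     # nearest the CSF shell first
  cum <- cumsum(convertible[ord]) * vv
  k <- which(cum >= target_mm3 - 1e-12)[1]
  take <- numeric(length(idx))
  take[ord[seq_len(k)]] <- convertible[ord[seq_len(k)]]
  # partial conversion of the last voxel to hit the target exactly
  excess <- (cum[k] - target_mm3) / vv
  take[ord[k]] <- take[ord[k]] - excess

  share <- ifelse(convertible > 0, take / convertible, 0)
  d_gm <- gm * share
  d_wm <- wm * share
  lin <- function(t) idx + (match(t, TISSUES) - 1L) * nvox
  frac[lin("gm")] <- gm - d_gm
  frac[lin("wm")] <- wm - d_wm
  frac[lin("csf")] <- frac[lin("csf")] + d_gm + d_wm
  phantom$fractions <- frac
  phantom
}

#' Write / read a phantom as NIfTI-1 volumes
#'
#' One float volume per tissue fraction, one integer label volume and one
#' integer electrode-mask volume (0 none, 1 anode, 2 cathode), all with an
#' RAS affine equal to `voxel_size_mm` times the identity and the world
#' origin at the grid center.
#'
#' @param phantom a `head_phantom`.
#' @param dir output directory (created if missing).
#' @return `write_phantom()` returns the directory invisibly;
#'   `read_phantom()` returns a `head_phantom` (without the original
#'   `spec`, which is not stored in the images).
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "head_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- phantom$voxel_size_mm
  dims <- dim(phantom$labels)
  origin <- -(dims + 1) / 2 * h
  affine <- diag(c(h, h, h, 1))
  affine[1:3, 4] <- origin
  wr <- function(data, file, datatype) {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- c(h, h, h)
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    RNifti::writeNifti(img, file.path(dir, file), datatype = datatype,
                       compression = 0)
  }
  for (t in TISSUES)
    wr(phantom$fractions[, , , t], sprintf("fraction_%s.nii", t), "float")
  wr(phantom$labels, "labels.nii", "int16")
  emask <- array(0L, dims)
  emask[phantom$electrode_masks$anode] <- 1L
  emask[phantom$electrode_masks$cathode] <- 2L
  wr(emask, "electrodes.nii", "int16")
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop_ff("format_error", "missing phantom volume %s", path)
    img <- RNifti::readNifti(path)
    out <- as.array(img)
    attributes(out) <- list(dim = dim(out))
    out
  }
  first <- RNifti::readNifti(file.path(dir, "fraction_csf.nii"))
  h <- RNifti::pixdim(first)[1]
  dims <- dim(first)
  frac <- array(0, c(dims, length(TISSUES)),
                dimnames = list(NULL, NULL, NULL, TISSUES))
  for (t in TISSUES) frac[, , , t] <- rd(sprintf("fraction_%s.nii", t))
  labels <- rd("labels.nii")
  storage.mode(labels) <- "integer"
  emask <- rd("electrodes.nii")
  structure(list(fractions = frac, labels = labels, voxel_size_mm = h,
                 electrode_masks = list(anode = emask == 1, cathode = emask == 2),
                 spec = NULL),
            class = "head_phantom")
}
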