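# Quasi-static volume-conductor solver: 7-point finite differences on the
# voxel grid with harmonic-mean face conductances, Dirichlet electrodes and
# post-hoc rescaling of the potential to the injected current.
#
# The governing physics is the stationary current equation
# div(sigma grad V) = 0 with no-flux boundaries everywhere except the two
# electrode patches. Dirichlet values V = 1 (anode) and V = 0 (cathode) are
# imposed and the solution is afterwards scaled so the total current
# entering at the anode equals the requested dose, which is exact because
# the problem is linear in V.

#' Tissue conductivities (S/m)
#'
#' Standard literature values used by current-flow simulators: WM 0.126,
#' GM 0.276, CSF 1.65, skull (compact bone) 0.01, skin 0.465,
#' air 2.5e-14, electrode gel 0.3 and electrode metal 5.9e7 S/m.
#'
#' @param ... named overrides, e.g. `tissue_conductivities(csf = 1.8)`.
#' @return Named numeric vector of conductivities in S/m.
#' @export
tissue_conductivities <- function(...) {
  sigma <- c(wm = 0.126, gm = 0.276, csf = 1.65, skull = 0.01,
             skin = 0.465, air = 2.5e-14, gel = 0.3, electrode = 5.9e7)
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop_ff("config_error", "conductivity overrides must be named")
    unknown <- setdiff(names(dots), names(sigma))
    sigma[setdiff(names(dots), unknown)] <- dots[setdiff(names(dots), unknown)]
    if (length(unknown)) sigma <- c(sigma, dots[unknown])
  }
  if (any(sigma <= 0)) stop_ff("config_error", "conductivities must be > 0")
  sigma
}

#' Hard segmentation of a phantom
#'
#' Assigns each voxel the tissue with the largest fraction; ties are broken
#' by the fixed order CSF > GM > WM > skull > skin > air, so a 50/50
#' CSF/GM boundary voxel is treated as CSF (the more conductive tissue).
#'
#' @param phantom a `head_phantom`.
#' @return Character array of tissue names, same shape as the grid.
#' @export
hard_segment <- function(phantom) {
  stopifnot(inherits(phantom, "head_phantom"))
  order_pref <- c("csf", "gm", "wm", "skull", "skin", "air")
  m <- sapply(order_pref, function(t) as.vector(phantom$fractions[, , , t]))
  winner <- max.col(m, ties.method = "first")
  array(order_pref[winner], dim(phantom$labels))
}

#' Electrode montage configuration
#'
#' @param anode_mask,cathode_mask logical voxel arrays marking the
#'   electrode contact voxels (non-empty, disjoint).
#' @param current_mA injected direct current in mA (1 or 2 mA typical).
#' @return Object of class `montage_config`.
#' @export
montage_config <- function(anode_mask, cathode_mask, current_mA = 1) {
  stopifnot(is.logical(anode_mask), is.logical(cathode_mask),
            identical(dim(anode_mask), dim(cathode_mask)),
            length(current_mA) == 1L, current_mA > 0)
  if (!any(anode_mask) || !any(cathode_mask))
    stop_ff("config_error", "electrode masks must be non-empty")
  if (any(anode_mask & cathode_mask))
    stop_ff("config_error", "electrode masks overlap")
  structure(list(anode_mask = anode_mask, cathode_mask = cathode_mask,
                 current_mA = current_mA),
            class = "montage_config")
}

# Face-neighbor pairs along one axis as linear voxel indices.
#' @keywords internal
#' @noRd
axis_pairs <- function(dims, axis) {
  idx <- array(seq_len(prod(dims)), dims)
  switch(axis,
         list(a = as.vector(idx[-dims[1], , ]), b = as.vector(idx[-1, , ])),
         list(a = as.vector(idx[, -dims[2], ]), b = as.vector(idx[, -1, ])),
         list(a = as.vector(idx[, , -dims[3]]), b = as.vector(idx[, , -1])))
}

# All conductive face-neighbor pairs with their conductances (siemens).
# Harmonic-mean face conductivity is the flux-conserving choice when sigma
# jumps between voxels; for a cubic voxel of edge h the geometric factor
# area/distance reduces to h (in meters).
#' @keywords internal
#' @noRd
face_conductances <- function(sigma, conductive, voxel_size_mm) {
  dims <- dim(sigma)
  h_m <- voxel_size_mm / 1000
  out <- list(a = integer(0), b = integer(0), g = numeric(0),
              axis = integer(0))
  for (axis in 1:3) {
    p <- axis_pairs(dims, axis)
    keep <- conductive[p$a] & conductive[p$b]
    a <- p$a[keep]; b <- p$b[keep]
    sa <- sigma[a]; sb <- sigma[b]
    g <- 2 * sa * sb / (sa + sb) * h_m
    out$a <- c(out$a, a); out$b <- c(out$b, b); out$g <- c(out$g, g)
    out$axis <- c(out$axis, rep.int(axis, length(a)))
  }
  out
}

#' Solve the electric potential for a montage
#'
#' Discretizes `div(sigma grad V) = 0` with a 7-point stencil and
#' harmonic-mean face conductances, imposes V = 1 on the anode voxels and
#' V = 0 on the cathode voxels with zero-flux conditions elsewhere, solves
#' the resulting sparse symmetric positive-definite system by sparse
#' Cholesky factorization, and rescales the solution so the current
#' entering at the anode equals `current_mA` (exact by linearity).
#' Voxels whose conductivity falls below `sigma_floor` (air) are treated
#' as perfect insulators and excluded from the system.
#'
#' @param labels character array of tissue names (e.g. from
#'   [hard_segment()]), or a numeric array of conductivities in S/m.
#' @param conductivities named conductivity vector; ignored when `labels`
#'   is already numeric.
#' @param montage a [montage_config()].
#' @param voxel_size_mm voxel edge length in mm.
#' @param tol maximum acceptable relative residual of the linear solve.
#' @param sigma_floor conductivity (S/m) below which a voxel is excluded
#'   from the conductive domain.
#' @return Object of class `potential_field`: `potential` (volts),
#'   `sigma`, `conductive`, the montage, and `diagnostics` with the final
#'   relative residual.
#' @export
solve_potential <- function(labels, conductivities = tissue_conductivities(),
                            montage, voxel_size_mm,
                            tol = 1e-8, sigma_floor = 1e-6) {
  stopifnot(inherits(montage, "montage_config"))
  if (is.character(labels)) {
    missing_t <- setdiff(unique(as.vector(labels)), names(conductivities))
    if (length(missing_t))
      stop_ff("config_error", "no conductivity for tissue(s): %s",
              paste(missing_t, collapse = ", "))
    sigma <- array(conductivities[as.vector(labels)], dim(labels))
  } else {
    sigma <- labels
  }
  dims <- dim(sigma)
  if (!identical(dims, dim(montage$anode_mask)))
    stop_ff("dimension_error", "montage masks do not match the grid")

  conductive <- sigma >= sigma_floor
  if (any(montage$anode_mask & !conductive) || any(montage$cathode_mask & !conductive))
    stop_ff("config_error", "electrode voxels must be conductive")

  dirichlet <- array(NA_real_, dims)
  dirichlet[montage$anode_mask] <- 1
  dirichlet[montage$cathode_mask] <- 0
  free <- conductive & is.na(dirichlet)
  nf <- sum(free)
  if (nf == 0L) stop_ff("config_error", "no free conductive voxels between the electrodes")
  node <- array(NA_integer_, dims)
  node[free] <- seq_len(nf)

  fc <- face_conductances(sigma, conductive, voxel_size_mm)
  fa_free <- free[fc$a]; fb_free <- free[fc$b]

  both <- fa_free & fb_free
  ia <- node[fc$a[both]]; ib <- node[fc$b[both]]; gb <- fc$g[both]
  # free-Dirichlet faces add to the diagonal and the right-hand side
  ad <- fa_free & !fb_free
  bd <- fb_free & !fa_free
  di <- c(node[fc$a[ad]], node[fc$b[bd]])
  dg <- c(fc$g[ad], fc$g[bd])
  dv <- c(dirichlet[fc$b[ad]], dirichlet[fc$a[bd]])

  A <- Matrix::forceSymmetric(Matrix::sparseMatrix(
    i = c(ia, ib, ia, ib, di),
    j = c(ib, ia, ia, ib, di),
    x = c(-gb, -gb, gb, gb, dg),
    dims = c(nf, nf)))
  b <- rep(0, nf)
  acc <- rowsum(dg * dv, di)
  b[as.integer(rownames(acc))] <- acc[, 1]

  x <- tryCatch(
    as.vector(Matrix::solve(A, b)),
    error = function(e) stop_ff("singular_system_error",
      "linear system is singular; no conductive path between the electrodes (%s)",
      conditionMessage(e)))
  resid <- sqrt(sum((as.vector(A %*% x) - b)^2))
  bnorm <- sqrt(sum(b^2))
  rel_resid <- if (bnorm > 0) resid / bnorm else resid
  if (!is.finite(rel_resid) || rel_resid > tol)
    stop_ff("convergence_error", "solver residual %.3e exceeds tolerance %.1e",
            rel_resid, tol)

  V <- array(0, dims)
  V[free] <- x
  V[montage$anode_mask] <- 1
  V[montage$cathode_mask] <- 0

  anode_out_A <- set_outflow(V, fc, montage$anode_mask)
  anode_g <- sum(fc$g[xor(montage$anode_mask[fc$a], montage$anode_mask[fc$b])])
  if (anode_out_A <= 1e-9 * anode_g)
    stop_ff("singular_system_error", "no current leaves the anode; electrodes disconnected")
  scale <- (montage$current_mA / 1000) / anode_out_A
  V <- V * scale

  structure(list(potential = V, sigma = sigma, conductive = conductive,
                 montage = montage, voxel_size_mm = voxel_size_mm,
                 faces = fc,
                 diagnostics = list(method = "sparse Cholesky (direct)",
                                    n_unknowns = nf,
                                    relative_residual = rel_resid,
                                    scale = scale)),
            class = "potential_field")
}

# Net current (A) flowing out of a voxel set through conductive faces.
#' @keywords internal
#' @noRd
set_outflow <- function(V, faces, mask) {
  a_in <- mask[faces$a]; b_in <- mask[faces$b]
  out_ab <- a_in & !b_in
  out_ba <- b_in & !a_in
  sum(faces$g[out_ab] * (V[faces$a[out_ab]] - V[faces$b[out_ab]])) +
    sum(faces$g[out_ba] * (V[faces$b[out_ba]] - V[faces$a[out_ba]]))
}

#' Current density from a solved potential
#'
#' J = -sigma grad V evaluated in the flux-consistent discrete form: the
#' current through each conductive face (face conductance times the
#' potential difference, in A) is divided by the face area, and each
#' voxel's J component along an axis is the average of its two adjacent
#' face values (the single available face at conductive-domain
#' boundaries; 0 on insulating voxels). In homogeneous regions this is
#' exactly the central-difference gradient times sigma; across
#' conductivity interfaces it preserves the continuity of the normal
#' current component, which a naive central difference does not.
#' Potentials are in volts and the grid in mm; J is reported in mA/m^2.
#'
#' @param field a `potential_field` from [solve_potential()].
#' @return Object of class `current_density_field` with the component
#'   array `J` (x,y,z; mA/m^2), `magnitude`, and the solve context needed
#'   for conservation checks.
#' @export
current_density <- function(field) {
  stopifnot(inherits(field, "potential_field"))
  V <- field$potential
  dims <- dim(V)
  nvox <- prod(dims)
  h_m <- field$voxel_size_mm / 1000
  fc <- field$faces

  J <- array(0, c(dims, 3), dimnames = list(NULL, NULL, NULL, c("x", "y", "z")))
  for (axis in 1:3) {
    sel <- fc$axis == axis
    a <- fc$a[sel]; b <- fc$b[sel]
    # face current density, mA/m^2, positive along +axis (a -> b)
    jf <- fc$g[sel] * (V[a] - V[b]) / h_m^2 * 1000
    sums <- numeric(nvox)
    cnts <- numeric(nvox)
    acc_s <- rowsum(c(jf, jf), c(a, b))
    acc_n <- rowsum(rep(1, 2 * length(jf)), c(a, b))
    at <- as.integer(rownames(acc_s))
    sums[at] <- acc_s[, 1]
    cnts[at] <- acc_n[, 1]
    comp <- array(0, dims)
    comp[at] <- sums[at] / cnts[at]
    J[, , , axis] <- comp
  }
  mag <- sqrt(J[, , , 1]^2 + J[, , , 2]^2 + J[, , , 3]^2)
  structure(list(J = J, magnitude = mag, potential = V, sigma = field$sigma,
                 conductive = field$conductive, faces = field$faces,
                 montage = field$montage, voxel_size_mm = field$voxel_size_mm,
                 diagnostics = field$diagnostics),
            class = "current_density_field")
}

#' Current-conservation report
#'
#' Checks, from the face currents of the discrete solution, that (i) the
#' net current leaving the anode voxels equals the injected dose, (ii) the
#' net current leaving the cathode voxels equals minus the dose, and
#' (iii) the net flux through an interior closed box is zero, all within
#' `rel_tol` of the injected current.
#'
#' @param field a `current_density_field` (or `potential_field`).
#' @param box optional logical voxel array defining the interior control
#'   volume; defaults to the central half-extent box minus electrode
#'   voxels.
#' @param rel_tol pass threshold relative to the injected current.
#' @return List with fluxes in mA, relative errors, and `pass`.
#' @export
check_conservation <- function(field, box = NULL, rel_tol = 1e-3) {
  stopifnot(inherits(field, c("current_density_field", "potential_field")))
  V <- field$potential
  fc <- field$faces
  montage <- field$montage
  inj_mA <- montage$current_mA
  dims <- dim(V)

  anode_mA <- set_outflow(V, fc, montage$anode_mask) * 1000
  cathode_mA <- set_outflow(V, fc, montage$cathode_mask) * 1000

  if (is.null(box)) {
    box <- array(FALSE, dims)
    qs <- lapply(dims, function(n) seq(floor(n / 4) + 1, ceiling(3 * n / 4)))
    box[qs[[1]], qs[[2]], qs[[3]]] <- TRUE
    box <- box & !montage$anode_mask & !montage$cathode_mask
  }
  box_mA <- set_outflow(V, fc, box) * 1000

  rel_anode <- abs(anode_mA - inj_mA) / inj_mA
  rel_cathode <- abs(cathode_mA + inj_mA) / inj_mA
  rel_box <- abs(box_mA) / inj_mA
  list(injected_mA = inj_mA, anode_mA = anode_mA, cathode_mA = cathode_mA,
       interior_box_mA = box_mA,
       rel_error_anode = rel_anode, rel_error_cathode = rel_cathode,
       rel_error_box = rel_box,
       pass = rel_anode <= rel_tol && rel_cathode <= rel_tol && rel_box <= rel_tol)
}

#' End-to-end solve on a phantom
#'
#' Hard-segments the phantom, assigns conductivities, solves the potential
#' for its electrode masks and returns the current-density field.
#'
#' @param phantom a `head_phantom` with electrode masks.
#' @param current_mA injected current (mA).
#' @param conductivities named conductivity vector (S/m).
#' @param ... passed to [solve_potential()].
#' @return A `current_density_field`.
#' @export
tdcs_solve <- function(phantom, current_mA = 1,
                       conductivities = tissue_conductivities(), ...) {
  labels <- hard_segment(phantom)
  montage <- montage_config(phantom$electrode_masks$anode,
                            phantom$electrode_masks$cathode,
                            current_mA = current_mA)
  pot <- solve_potential(labels, conductivities, montage,
                         phantom$voxel_size_mm, ...)
  current_density(pot)
}

# Rescale a solved field to a different dose; exact by linearity.
#' @keywords internal
#' @noRd
scale_field <- function(field, new_current_mA) {
  s <- new_current_mA / field$montage$current_mA
  field$J <- field$J * s
  field$magnitude <- field$magnitude * s
  field$potential <- field$potential * s
  field$montage$current_mA <- new_current_mA
  field
}
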