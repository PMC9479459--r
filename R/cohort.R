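# Seeded cohort generators. Two modes:
#   table mode  — Gaussian additive model for regional volumes plus a
#                 controllable correlation between one ROI's CSF volume
#                 and the target-ROI current density (no solver involved);
#   phantom mode — per-subject head phantoms with sampled CSF pockets are
#                 pushed through the finite-difference solver.

#' Cohort effect specification
#'
#' Defines the statistical structure of a synthetic cohort over the
#' 3 age-group x 2 sex between-subject design. Effects are expressed in
#' units of the within-cell noise SD, so `interaction_delta = 1` adds one
#' noise-SD of CSF volume to the focal x older cell of `interaction_roi`.
#'
#' DTDI values are drawn from truncated normals whose parent parameters
#' are moment-matched so the realized class moments track the requested
#' ones (defaults: focal 0.87 +/- 0.11 on [0.75, 1], non-focal
#' 0.56 +/- 0.18 on [0, 0.75), the group moments typical of 1 mA
#' montages). Dispersions near the theoretical bound for the truncation
#' interval are approached as closely as a unimodal family allows.
#'
#' @param n_per_cell subjects per age x sex cell (>= 2).
#' @param age_csf_slope CSF age trend, in noise-SD units per age level.
#' @param interaction_roi ROI (integer id or `roiNN` name) carrying the
#'   focality effect.
#' @param interaction_delta CSF effect (noise-SD units) added to the
#'   focal x older cell of `interaction_roi`.
#' @param target_density_corr desired correlation in (-1, 1) between the
#'   CSF volume of `interaction_roi` and the target-ROI current density.
#' @param noise_sd within-cell volume SD (ml).
#' @param seed master RNG seed.
#' @param n_rois number of ROIs in table mode.
#' @param p_focal marginal probability of the focal class in table mode.
#' @param focality_delta optional main-effect shift (noise-SD units) of
#'   `interaction_roi` CSF for all focal subjects.
#' @param dtdi_focal,dtdi_nonfocal mean/sd pairs of the truncated-normal
#'   DTDI generators for the two classes.
#' @param baseline_ml named baseline per-ROI volumes (ml) for csf/gm/wm.
#' @param density_mean,density_sd moments (mA/m^2) of the target-ROI
#'   current density.
#' @param pocket_base_ml,pocket_sd_ml phantom-mode CSF pocket volume model
#'   (base + SD; the age trend reuses `age_csf_slope`).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(n_per_cell = 50L,
                        age_csf_slope = 0.5,
                        interaction_roi = 5L,
                        interaction_delta = 0,
                        target_density_corr = 0,
                        noise_sd = 0.5,
                        seed = 1L,
                        n_rois = 12L,
                        p_focal = 0.5,
                        focality_delta = 0,
                        dtdi_focal = c(mean = 0.87, sd = 0.11),
                        dtdi_nonfocal = c(mean = 0.56, sd = 0.18),
                        baseline_ml = c(csf = 3, gm = 40, wm = 35),
                        density_mean = 80, density_sd = 20,
                        pocket_base_ml = 1, pocket_sd_ml = 0.5) {
  n_per_cell <- as.integer(n_per_cell)
  if (n_per_cell < 1L) stop_ff("config_error", "n_per_cell must be >= 1")
  if (abs(target_density_corr) >= 1)
    stop_ff("config_error", "|target_density_corr| must be < 1")
  if (noise_sd <= 0) stop_ff("config_error", "noise_sd must be positive")
  if (p_focal <= 0 || p_focal >= 1)
    stop_ff("config_error", "p_focal must lie in (0, 1)")
  structure(list(n_per_cell = n_per_cell, age_csf_slope = age_csf_slope,
                 interaction_roi = roi_id(interaction_roi),
                 interaction_delta = interaction_delta,
                 target_density_corr = target_density_corr,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_rois = as.integer(n_rois), p_focal = p_focal,
                 focality_delta = focality_delta,
                 dtdi_focal = dtdi_focal, dtdi_nonfocal = dtdi_nonfocal,
                 baseline_ml = baseline_ml,
                 density_mean = density_mean, density_sd = density_sd,
                 pocket_base_ml = pocket_base_ml, pocket_sd_ml = pocket_sd_ml),
            class = "effect_spec")
}

#' @keywords internal
#' @noRd
roi_id <- function(roi) {
  if (is.character(roi)) as.integer(sub("^roi0*", "", roi)) else as.integer(roi)
}

#' @keywords internal
#' @noRd
roi_col <- function(roi, tissue) sprintf("roi%02d_%s_ml", roi_id(roi), tissue)

AGE_LEVELS <- c("young", "middle", "older")
SEX_LEVELS <- c("M", "F")

#' Sample a table-mode cohort
#'
#' Draws per-subject regional CSF/GM/WM volumes from a Gaussian additive
#' model over the 3 x 2 design: an age main effect on every ROI's CSF
#' volume (`age_csf_slope` noise-SDs per age level), plus
#' `interaction_delta` noise-SDs added to the CSF volume of
#' `interaction_roi` for focal subjects in the older group. The target-ROI
#' current density is generated so that its correlation with the
#' standardized CSF volume of `interaction_roi` equals
#' `target_density_corr` in expectation. DTDI values are drawn
#' consistently with the focality class (>= 0.75 iff focal). Fully
#' reproducible from `effects$seed`.
#'
#' @param effects an [effect_spec()].
#' @return Cohort data.frame: `subject_id`, `age_group`, `sex`, `dtdi`,
#'   `focality`, `target_density_mA_m2`, then `roiNN_{csf,gm,wm}_ml`
#'   columns.
#' @export
sample_cohort_tables <- function(effects) {
  stopifnot(inherits(effects, "effect_spec"))
  with_seed(sub_seed(effects$seed, 1L), {
    cells <- expand.grid(age_group = AGE_LEVELS, sex = SEX_LEVELS,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(cells) * effects$n_per_cell
    age_group <- rep(cells$age_group, each = effects$n_per_cell)
    sex <- rep(cells$sex, each = effects$n_per_cell)
    age_code <- age_group_code(age_group)

    focal <- stats::runif(n) < effects$p_focal
    # parent parameters moment-matched so the realized class moments track
    # the requested ones as closely as hard truncation at 0.75 permits
    pf <- truncnorm_parent(effects$dtdi_focal[["mean"]],
                           effects$dtdi_focal[["sd"]], 0.75, 1)
    pn <- truncnorm_parent(effects$dtdi_nonfocal[["mean"]],
                           effects$dtdi_nonfocal[["sd"]], 0, 0.75)
    dtdi_val <- numeric(n)
    dtdi_val[focal] <- rtruncnorm(sum(focal), pf[["mean"]], pf[["sd"]],
                                  0.75, 1)
    dtdi_val[!focal] <- rtruncnorm(sum(!focal), pn[["mean"]], pn[["sd"]],
                                   0, 0.75 - 1e-9)
    focality <- classify_focality(dtdi_val)

    vols <- list()
    for (r in seq_len(effects$n_rois)) {
      for (t in BRAIN_TISSUES) {
        mu <- effects$baseline_ml[[t]]
        eff <- 0
        if (t == "csf") {
          eff <- effects$age_csf_slope * age_code
          if (r == effects$interaction_roi) {
            eff <- eff + effects$focality_delta * focal +
              effects$interaction_delta * (focal & age_group == "older")
          }
        }
        vols[[roi_col(r, t)]] <- mu + effects$noise_sd * (eff + stats::rnorm(n))
      }
    }

    csf_i <- vols[[roi_col(effects$interaction_roi, "csf")]]
    z <- as.vector(scale(csf_i))
    rho <- effects$target_density_corr
    density <- effects$density_mean + effects$density_sd *
      (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))

    out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      age_group = factor(age_group, levels = AGE_LEVELS),
                      sex = factor(sex, levels = SEX_LEVELS),
                      dtdi = dtdi_val, focality = focality,
                      target_density_mA_m2 = density,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(vols))
  })
}

#' Simulate a phantom-mode cohort
#'
#' For each subject in the 3 x 2 design, samples a CSF pocket volume for
#' `effects$interaction_roi` (base + age trend + noise, truncated to the
#' ROI's capacity), injects it into a fresh phantom, solves the current
#' flow, and records the ROI density table, DTDI, focality class and
#' regional volumes. The solve is performed once at 1 mA and rescaled to
#' `dose_mA` (exact by linearity), so DTDI is identical across doses.
#'
#' @param effects an [effect_spec()] (its `n_per_cell` should be small —
#'   each subject costs one sparse solve).
#' @param spec a [phantom_spec()]; keep grids at or below 48^3.
#' @param montage_geometry `"interhemispheric"` (electrodes 180 degrees
#'   apart) or `"intrahemispheric"` (60 degrees apart).
#' @param dose_mA injected current in mA.
#' @param target_roi target ROI id or name; defaults to the sector under
#'   the anode (ROI 1).
#' @return Cohort data.frame as in [sample_cohort_tables()], with an
#'   attribute `roi_tables` holding the per-subject ROI density tables.
#' @export
simulate_cohort <- function(effects, spec = phantom_spec(),
                            montage_geometry = c("interhemispheric",
                                                 "intrahemispheric"),
                            dose_mA = 1, target_roi = 1L) {
  stopifnot(inherits(effects, "effect_spec"), inherits(spec, "phantom_spec"))
  montage_geometry <- match.arg(montage_geometry)
  spec <- montage_spec(spec, montage_geometry)
  target_roi <- roi_id(target_roi)

  with_seed(sub_seed(effects$seed, 2L), {
    age_group <- rep(rep(AGE_LEVELS, each = effects$n_per_cell), times = 2)
    sex <- rep(SEX_LEVELS, each = 3 * effects$n_per_cell)
    n <- length(age_group)
    age_code <- age_group_code(age_group)
    pocket <- pmax(0, effects$pocket_base_ml + effects$pocket_sd_ml *
                     (effects$age_csf_slope * age_code + stats::rnorm(n)))

    base <- make_phantom(spec)
    parc <- phantom_parcellation(base)
    cap_ml <- local({
      idx <- base$labels == effects$interaction_roi
      (sum(base$fractions[, , , "gm"][idx]) +
         sum(base$fractions[, , , "wm"][idx])) * spec$voxel_size_mm^3 / 1000
    })
    pocket <- pmin(pocket, 0.9 * cap_ml)

    rows <- vector("list", n)
    roi_tables <- vector("list", n)
    for (i in seq_len(n)) {
      subject <- sprintf("S%03d", i)
      res <- tryCatch({
        ph <- inject_csf_pocket(base, effects$interaction_roi, pocket[i])
        field <- tdcs_solve(ph, current_mA = 1)
        field <- scale_field(field, dose_mA)
        dens <- roi_mean_density(field, parc)
        vols <- tiv_scale(regional_volumes(ph, parc))
        list(dens = dens, vols = vols)
      }, error = function(e) {
        stop_ff("solver_error", "subject %s: %s", subject, conditionMessage(e))
      })
      d <- dtdi(res$dens, target_roi)
      vw <- stats::setNames(
        c(res$vols$csf_ml, res$vols$gm_ml, res$vols$wm_ml),
        c(roi_col(res$vols$roi, "csf"), roi_col(res$vols$roi, "gm"),
          roi_col(res$vols$roi, "wm")))
      rows[[i]] <- c(list(subject_id = subject, age_group = age_group[i],
                          sex = sex[i], dtdi = d,
                          focality = classify_focality(d),
                          target_density_mA_m2 =
                            res$dens$mean_mA_m2[res$dens$roi == target_roi]),
                     as.list(vw))
      roi_tables[[i]] <- res$dens
    }
    out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
    out$age_group <- factor(out$age_group, levels = AGE_LEVELS)
    out$sex <- factor(out$sex, levels = SEX_LEVELS)
    rownames(out) <- NULL
    attr(out, "roi_tables") <- roi_tables
    out
  })
}

# Electrode placement for the two montage geometries: caps 180 degrees
# apart stand in for an inter-hemispheric montage, 60 degrees apart for an
# intra-hemispheric one.
#' @keywords internal
#' @noRd
montage_spec <- function(spec, geometry) {
  ang <- if (geometry == "interhemispheric") pi else pi / 3
  spec$electrode_centers <- list(anode = c(1, 0, 0),
                                 cathode = c(cos(ang), sin(ang), 0))
  phantom_spec(grid_shape = spec$grid_shape,
               voxel_size_mm = spec$voxel_size_mm,
               shell_radii_mm = spec$shell_radii_mm,
               n_rois = spec$n_rois,
               electrode_centers = spec$electrode_centers,
               electrode_radius_mm = spec$electrode_radius_mm)
}

#' Read / write a cohort table as TSV
#' @param cohort cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  out$age_group <- factor(out$age_group, levels = AGE_LEVELS)
  out$sex <- factor(out$sex, levels = SEX_LEVELS)
  out
}
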