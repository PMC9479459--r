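# Shared fixtures and independent oracles used across the test files.

# Homogeneous or layered cuboid with full-face plate electrodes on the
# z axis; sigma_by_z gives the conductivity of each z-slab.
make_slab <- function(n = 16L, size_mm = 10, sigma_by_z = rep(1, n)) {
  h <- size_mm / n
  sigma <- array(rep(sigma_by_z, each = n * n), c(n, n, n))
  anode <- array(FALSE, c(n, n, n)); anode[, , n] <- TRUE
  cathode <- array(FALSE, c(n, n, n)); cathode[, , 1] <- TRUE
  list(sigma = sigma, h = h, n = n,
       montage = montage_config(anode, cathode, current_mA = 1))
}

solve_slab <- function(slab, current_mA = 1) {
  slab$montage$current_mA <- current_mA
  current_density(solve_potential(slab$sigma, montage = slab$montage,
                                  voxel_size_mm = slab$h))
}

small_phantom_spec <- function(geometry = c("interhemispheric",
                                            "intrahemispheric"),
                               n = 32L, voxel = 2) {
  geometry <- match.arg(geometry)
  ang <- if (geometry == "interhemispheric") pi else pi / 3
  phantom_spec(grid_shape = c(n, n, n), voxel_size_mm = voxel,
               shell_radii_mm = c(wm = 12, gm = 18, csf = 20.5,
                                  skull = 23.5, skin = 26.5),
               electrode_centers = list(anode = c(1, 0, 0),
                                        cathode = c(cos(ang), sin(ang), 0)))
}

# Textbook balanced-design sums-of-squares decomposition from cell means;
# valid for balanced full factorials only. Independent of the package's
# QR-based Type-III path.
balanced_anova_oracle <- function(data, dv, factors) {
  y <- data[[dv]]
  fs <- lapply(data[factors], factor)
  cell <- interaction(fs, drop = FALSE)
  stopifnot(length(unique(table(cell))) == 1L)   # balanced
  grand <- mean(y)
  n <- length(y)
  effects <- list()
  # all non-empty factor subsets, in term order A, B, C, A:B, A:C, B:C, A:B:C
  combos <- unlist(lapply(seq_along(factors), function(k)
    combn(factors, k, simplify = FALSE)), recursive = FALSE)
  ss <- setNames(numeric(length(combos)),
                 vapply(combos, paste, "", collapse = ":"))
  df <- ss
  means_for <- function(subset) {
    idx <- interaction(fs[subset], drop = FALSE)
    ave(y, idx)
  }
  for (ci in seq_along(combos)) {
    subset <- combos[[ci]]
    m <- means_for(subset)
    # subtract grand mean and all lower-order effect estimates
    est <- m - grand
    for (cj in seq_len(ci - 1)) {
      if (all(combos[[cj]] %in% subset)) est <- est - effects[[cj]]
    }
    effects[[ci]] <- est
    ss[ci] <- sum(est^2)
    df[ci] <- prod(vapply(fs[subset], nlevels, 1L) - 1L)
  }
  resid <- y - means_for(factors)
  ss_res <- sum(resid^2)
  df_res <- n - prod(vapply(fs, nlevels, 1L))
  data.frame(effect = names(ss), df1 = as.integer(df), df2 = df_res,
             ss = unname(ss),
             F = unname((ss / df) / (ss_res / df_res)),
             stringsAsFactors = FALSE)
}

# Balanced 2x2x2 fixture: unit main effect of the first factor, within-cell
# deviations -0.5/+0.5, two replicates per cell.
balanced_222_fixture <- function() {
  g <- expand.grid(rep = 1:2,
                   age_group = c("young", "older"),
                   sex = c("M", "F"),
                   focality = c("focal", "nonfocal"),
                   stringsAsFactors = FALSE)
  g$y <- 1 * (g$age_group == "older") + ifelse(g$rep == 1, -0.5, 0.5)
  g
}

# Naive per-voxel triple loop for regional tissue volumes; the brute-force
# oracle for the vectorized implementation.
naive_regional_volumes <- function(phantom, parc) {
  dims <- dim(phantom$labels)
  vv_ml <- phantom$voxel_size_mm^3 / 1000
  rois <- sort(setdiff(unique(as.vector(parc$labels)), 0L))
  tissues <- c("csf", "gm", "wm")
  # gather per-voxel contributions ROI by ROI, walking the grid in memory
  # order (first index fastest), then reduce each with sum()
  parts <- array(list(), c(length(rois), 3),
                 dimnames = list(as.character(rois), tissues))
  for (ri in seq_along(rois)) for (t in tissues)
    parts[[ri, match(t, tissues)]] <- numeric(0)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      lab <- parc$labels[i, j, k]
      if (lab > 0L) {
        r <- as.character(lab)
        for (t in tissues)
          parts[[r, t]] <- c(parts[[r, t]],
                             phantom$fractions[i, j, k, t] * vv_ml)
      }
    }
  acc <- matrix(0, length(rois), 3, dimnames = list(as.character(rois), tissues))
  for (r in as.character(rois)) for (t in tissues)
    acc[r, t] <- sum(parts[[r, t]])
  acc
}

# Scan under whole-scan familywise control; used with the engineered sweep
# cohorts so incidental single-ROI noise does not enter the focal-ROI set.
scanwide_scan <- function(ch) focal_roi_scan(ch, family = "scanwide")$focal_rois

# Cohort engineered so the focal-ROI finding survives DTDI reclassification
# down to exactly `break_threshold` and disappears one step below it.
# Three strata: "high" subjects (DTDI >= break_threshold) carry +delta on
# ROI 5 CSF; a "cluster" just below the break carries a balancing negative
# offset sized so that once it floods the focal group the group difference
# cancels; a "low" tail carries nothing.
build_sweep_cohort <- function(break_threshold, seed = 7L,
                               n_high = 120L, n_cluster = 150L, n_low = 30L,
                               delta_sd = 1, noise_sd = 0.5, n_rois = 12L) {
  set.seed(seed)
  n <- n_high + n_cluster + n_low
  stratum <- rep(c("high", "cluster", "low"), c(n_high, n_cluster, n_low))
  dtdi <- c(runif(n_high, break_threshold, 1),
            runif(n_cluster, break_threshold - 0.009, break_threshold - 0.001),
            runif(n_low, 0.5, break_threshold - 0.02))
  offset <- c(high = delta_sd, cluster = -delta_sd * n_high / n_cluster,
              low = 0)[stratum] * noise_sd
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age_group = factor(rep_len(c("young", "middle", "older"), n),
                       levels = c("young", "middle", "older")),
    sex = factor(rep_len(c("M", "F"), n), levels = c("M", "F")),
    dtdi = dtdi,
    focality = classify_focality(dtdi),
    target_density_mA_m2 = rnorm(n, 80, 20))
  for (r in seq_len(n_rois)) for (t in c("csf", "gm", "wm")) {
    col <- sprintf("roi%02d_%s_ml", r, t)
    base <- c(csf = 3, gm = 40, wm = 35)[[t]]
    cohort[[col]] <- base + rnorm(n, 0, noise_sd) +
      if (r == 5L && t == "csf") offset else 0
  }
  cohort
}
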