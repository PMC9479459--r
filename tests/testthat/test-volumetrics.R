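# Partial-volume regional volumetrics, TIV scaling and residualization.

test_that("regional volumes match the naive per-voxel loop oracle bitwise", {
  set.seed(5)
  # random fraction map on a small grid: three brain tissues + background
  dims <- c(8L, 8L, 8L)
  raw <- array(stats::runif(prod(dims) * 3), c(dims, 3))
  tot <- raw[, , , 1] + raw[, , , 2] + raw[, , , 3]
  frac <- array(0, c(dims, 6), dimnames = list(NULL, NULL, NULL,
                c("skin", "skull", "csf", "gm", "wm", "air")))
  for (i in 1:3) frac[, , , 2 + i] <- raw[, , , i] / tot * 0.9
  frac[, , , "air"] <- 0.1
  labels <- array(sample(0:4, prod(dims), replace = TRUE), dims)
  ph <- structure(list(fractions = frac, labels = labels, voxel_size_mm = 1.5,
                       electrode_masks = NULL, spec = NULL),
                  class = "head_phantom")
  parc <- atlas_parcellation(labels, data.frame(label = 1:4,
                                                name = sprintf("r%d", 1:4)),
                             1.5)
  tab <- regional_volumes(ph, parc)
  oracle <- naive_regional_volumes(ph, parc)
  expect_identical(tab$csf_ml, unname(oracle[, "csf"]))
  expect_identical(tab$gm_ml, unname(oracle[, "gm"]))
  expect_identical(tab$wm_ml, unname(oracle[, "wm"]))
})

test_that("pure and evenly mixed ROIs give the textbook volumes", {
  dims <- c(10L, 10L, 13L)
  frac <- array(0, c(dims, 6), dimnames = list(NULL, NULL, NULL,
                c("skin", "skull", "csf", "gm", "wm", "air")))
  labels <- array(0L, dims)
  # ROI 1: 1000 voxels of pure GM at 1 mm^3 -> 1 ml
  frac[, , 1:10, "gm"] <- 1
  labels[, , 1:10] <- 1L
  # ROI 2: 300 voxels with 1/3 in each tissue -> 0.1 ml each
  frac[, , 11:13, c("csf", "gm", "wm")] <- 1 / 3
  labels[, , 11:13] <- 2L
  ph <- structure(list(fractions = frac, labels = labels, voxel_size_mm = 1),
                  class = "head_phantom")
  parc <- atlas_parcellation(labels, data.frame(label = 1:2,
                                                name = c("pure", "mixed")), 1)
  tab <- regional_volumes(ph, parc)
  expect_equal(tab$gm_ml, c(1, 0.1))
  expect_equal(tab$csf_ml, c(0, 0.1))
  expect_equal(tab$wm_ml, c(0, 0.1))
  # full coverage: regional volumes sum to TIV
  expect_equal(sum(tab$csf_ml + tab$gm_ml + tab$wm_ml),
               attr(tab, "tiv_ml"), tolerance = 1e-12)
})

test_that("TIV scaling normalizes to 1 and is invariant to grid rescaling", {
  ph <- make_phantom(small_phantom_spec())
  tab <- tiv_scale(regional_volumes(ph))
  expect_lt(abs(sum(tab$csf_s + tab$gm_s + tab$wm_s) - 1), 1e-9)

  # same fractions on a grid with 2x voxel volume: scaled table unchanged
  ph2 <- ph
  ph2$voxel_size_mm <- ph$voxel_size_mm * 2^(1 / 3)
  tab2 <- tiv_scale(regional_volumes(ph2))
  expect_equal(tab2$csf_s, tab$csf_s, tolerance = 1e-12)

  bad <- tab
  attr(bad, "tiv_ml") <- 0
  bad$tiv_ml <- NULL
  expect_error(tiv_scale(bad), class = "degenerate_input_error")
})

test_that("partial parcellation coverage yields volumes strictly below TIV", {
  ph <- make_phantom(small_phantom_spec())
  partial <- ph$labels
  partial[partial > 6L] <- 0L
  parc <- atlas_parcellation(partial, data.frame(label = 1:6,
                                                 name = sprintf("r%d", 1:6)),
                             ph$voxel_size_mm)
  tab <- regional_volumes(ph, parc)
  expect_lt(sum(tab$csf_ml + tab$gm_ml + tab$wm_ml), attr(tab, "tiv_ml"))
})

test_that("residualization removes covariate structure and is idempotent", {
  eff <- effect_spec(n_per_cell = 334, age_csf_slope = 2, seed = 3)
  cohort <- sample_cohort_tables(eff)
  age <- as.numeric(cohort$age_group) - 1

  res <- residualize_covariates(cohort)
  # a column built as 2 * age + noise must end up uncorrelated with age
  expect_lt(abs(cor(res$roi01_csf_ml, age)), 0.02)
  expect_lt(abs(mean(res$roi01_csf_ml)), 1e-10)

  # exact linear dependence -> all-zero residuals
  cohort$roi01_gm_ml <- 3 * age + 0.5 * (cohort$sex == "F")
  res2 <- residualize_covariates(cohort)
  expect_lt(max(abs(res2$roi01_gm_ml)), 1e-10)

  # idempotence
  twice <- residualize_covariates(res)
  vols <- grep("_ml$", names(cohort), value = TRUE)
  expect_equal(as.matrix(twice[vols]), as.matrix(res[vols]),
               tolerance = 1e-10)

  # column orthogonal to covariates: residuals are the centered values
  z <- rnorm(nrow(cohort))
  z_orth <- lm(z ~ age + I(cohort$sex == "F"))$residuals + 5
  cohort$roi02_wm_ml <- z_orth
  res3 <- residualize_covariates(cohort)
  expect_equal(res3$roi02_wm_ml, unname(z_orth - mean(z_orth)),
               tolerance = 1e-10)
})
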