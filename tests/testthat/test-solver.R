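# Finite-difference volume-conductor solver: closed-form oracles,
# conservation, linearity and symmetry.

test_that("hard segmentation picks the max-fraction tissue with the stated tie order", {
  spec <- small_phantom_spec()
  ph <- make_phantom(spec)
  # pure voxels
  seg <- hard_segment(ph)
  pure_gm <- ph$fractions[, , , "gm"] == 1
  expect_true(all(seg[pure_gm] == "gm"))
  # engineered ties / mixtures in a 1-voxel phantom-like object
  mix <- ph
  mix$fractions[1, 1, 1, ] <- c(0, 0, 0.5, 0.5, 0, 0)   # csf/gm tie -> csf
  mix$fractions[2, 1, 1, ] <- c(0, 0, 0.6, 0.4, 0, 0)   # csf majority
  mix$fractions[3, 1, 1, ] <- c(0.5, 0.5, 0, 0, 0, 0)   # skull beats skin
  seg <- hard_segment(mix)
  expect_identical(seg[1, 1, 1], "csf")
  expect_identical(seg[2, 1, 1], "csf")
  expect_identical(seg[3, 1, 1], "skull")
})

test_that("homogeneous cube with plate electrodes reproduces J = I/A", {
  slab <- make_slab(n = 16L, size_mm = 10, sigma_by_z = rep(1, 16))
  f <- solve_slab(slab)
  # 1 mA over 100 mm^2 -> 10,000 mA/m^2
  expect_lt(max(abs(f$magnitude - 10000)) / 10000, 0.005)
  # field aligned with the electrode axis
  expect_lt(max(abs(f$J[, , , "x"])) / 10000, 0.005)
  expect_lt(max(abs(f$J[, , , "y"])) / 10000, 0.005)
  expect_lte(f$diagnostics$relative_residual, 1e-8)
})

test_that("two-layer slab obeys the series-resistance closed form", {
  n <- 16L
  slab <- make_slab(n = n, size_mm = 10,
                    sigma_by_z = rep(c(0.276, 1.65), each = n / 2))
  f <- solve_slab(slab)
  # normal current continuous: |J| uniform through both layers
  expect_lt(diff(range(f$magnitude)) / mean(f$magnitude), 0.005)
  expect_lt(abs(mean(f$magnitude) - 10000) / 10000, 0.005)
  # potential gradient ratio between layer interiors = sigma_csf / sigma_gm
  vz <- apply(f$potential, 3, mean)
  gm_slope <- (vz[6] - vz[3]) / 3
  csf_slope <- (vz[14] - vz[11]) / 3
  expect_equal(gm_slope / csf_slope, 1.65 / 0.276, tolerance = 0.01)
  # flux through planes in both layers identical
  jz <- apply(f$J[, , , "z"], 3, mean)
  expect_lt(max(abs(jz - jz[1])) / abs(jz[1]), 0.005)
})

test_that("solution is exactly linear in the injected current", {
  slab <- make_slab(n = 12L, sigma_by_z = rep(c(0.3, 1.0, 0.5), each = 4))
  f1 <- solve_slab(slab, current_mA = 1)
  f2 <- solve_slab(slab, current_mA = 2)
  expect_equal(f2$magnitude, 2 * f1$magnitude, tolerance = 1e-12)
  expect_equal(f2$potential, 2 * f1$potential, tolerance = 1e-12)
})

test_that("conservation holds on every test geometry", {
  for (sig in list(rep(1, 12), rep(c(0.276, 1.65), each = 6),
                   rep(c(0.465, 0.01, 1.65, 0.276), each = 3))) {
    f <- solve_slab(make_slab(n = 12L, sigma_by_z = sig))
    cz <- check_conservation(f)
    expect_lt(cz$rel_error_anode, 1e-3)
    expect_lt(cz$rel_error_cathode, 1e-3)
    expect_lt(cz$rel_error_box, 1e-3)
    expect_true(cz$pass)
  }
})

test_that("air voxels carry no current and stay out of the system", {
  ph <- make_phantom(small_phantom_spec())
  f <- tdcs_solve(ph)
  seg <- hard_segment(ph)
  expect_true(all(f$magnitude[seg == "air"] < 1e-6))
  expect_true(all(is.finite(f$potential[f$conductive])))
})

test_that("disconnected electrodes raise a singular-system error", {
  n <- 12L
  sigma <- array(1, c(n, n, n))
  sigma[, , 6] <- 1e-14          # insulating plane splits the domain
  anode <- array(FALSE, c(n, n, n)); anode[, , n] <- TRUE
  cathode <- array(FALSE, c(n, n, n)); cathode[, , 1] <- TRUE
  expect_error(solve_potential(sigma, montage = montage_config(anode, cathode, 1),
                               voxel_size_mm = 1),
               class = "singular_system_error")
})

test_that("mirror-symmetric phantom yields a mirror-symmetric field", {
  ph <- make_phantom(small_phantom_spec("interhemispheric"))
  f <- tdcs_solve(ph)
  m <- f$magnitude
  # electrodes on +x/-x: field symmetric under y -> -y and z -> -z
  expect_lt(max(abs(m - m[, dim(m)[2]:1, ])) / max(m), 1e-6)
  expect_lt(max(abs(m - m[, , dim(m)[3]:1])) / max(m), 1e-6)
})

test_that("conductivity table carries the standard defaults and validates overrides", {
  sig <- tissue_conductivities()
  expect_equal(sig[["csf"]], 1.65)
  expect_equal(sig[["gm"]], 0.276)
  expect_equal(sig[["wm"]], 0.126)
  expect_equal(sig[["skull"]], 0.01)
  expect_equal(sig[["skin"]], 0.465)
  expect_equal(sig[["air"]], 2.5e-14)
  expect_equal(sig[["gel"]], 0.3)
  expect_equal(sig[["electrode"]], 5.9e7)
  expect_equal(tissue_conductivities(csf = 1.8)[["csf"]], 1.8)
  expect_error(tissue_conductivities(csf = -1), class = "config_error")
})

test_that("montage validation rejects empty or overlapping masks", {
  a <- array(FALSE, c(4, 4, 4)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[4, 4, 4] <- TRUE
  expect_s3_class(montage_config(a, b, 1), "montage_config")
  expect_error(montage_config(a, a, 1), class = "config_error")
  expect_error(montage_config(array(FALSE, c(4, 4, 4)), b, 1),
               class = "config_error")
})
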