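shim_grid <- function() list(dims = c(32L, 32L, 32L), vox = 4)

test_that("coil bases obey symmetry, linearity and harmonicity", {
  g <- shim_grid()
  sys <- generate_coil_basis(n_coils = 16, dims = g$dims, vox = g$vox)
  expect_identical(dim(sys$basis), c(g$dims, 16L))
  # doubling the dipole scale doubles every value
  sys2 <- generate_coil_basis(n_coils = 16, dims = g$dims, vox = g$vox,
                              dipole_scale = 6e7)
  expect_equal(sys2$basis, 2 * sys$basis, tolerance = 1e-12)
  # mirrored coils: the two-coil system is symmetric under x -> -x
  s2 <- generate_coil_basis(n_coils = 2, dims = g$dims, vox = g$vox,
                            length = 0)
  expect_equal(s2$coil_pos[1, 1:2], -s2$coil_pos[2, 1:2], tolerance = 1e-9)
  b1 <- s2$basis[, , , 1]
  b2 <- s2$basis[, , , 2]
  n <- g$dims[1]
  flipx <- b2[c(1, n:2), , ]   # mirror about the centre voxel (x -> -x)
  expect_equal(b1[2:n, , ], flipx[2:n, , ], tolerance = 1e-9)
  # sources outside the FOV: fields are discretely harmonic inside it
  for (i in c(1, 8, 16)) {
    b <- sys$basis[, , , i]
    expect_lt(max(abs(discrete_laplacian(b))), 1e-3 * max(abs(b)))
  }
  expect_warning(generate_coil_basis(n_coils = 4, radius = 30,
                                     dims = g$dims, vox = g$vox),
                 "intersects")
})

test_that("block-mean downsampling pools correctly and respects validity", {
  v <- vvol(array(as.numeric(1:8), c(2L, 2L, 2L)), 1, "Hz")
  d <- downsample_for_shim(v, 2)
  expect_equal(as.numeric(d$data), 4.5)
  expect_equal(d$vox, rep(2, 3))
  # factor 1 is the identity
  expect_identical(downsample_for_shim(v, 1), v)
  # constant volumes stay constant, including over partial trailing blocks
  cst <- vvol(array(3, c(5L, 5L, 5L)), 1, "Hz")
  dc <- downsample_for_shim(cst, 2)
  expect_true(all(dc$data == 3))
  # invalid voxels are excluded from the block means
  v2 <- vvol(array(as.numeric(1:8), c(2L, 2L, 2L)), 1, "Hz",
             valid = array(c(FALSE, rep(TRUE, 7)), c(2L, 2L, 2L)))
  d2 <- downsample_for_shim(v2, 2)
  expect_equal(as.numeric(d2$data), mean(2:8))
})

test_that("shim currents solve the constrained least-squares problem", {
  g <- shim_grid()
  sys <- generate_coil_basis(n_coils = 16, dims = g$dims, vox = g$vox)
  mask <- array(FALSE, g$dims); mask[10:22, 10:22, 12:24] <- TRUE
  # zero target -> zero currents
  s0 <- solve_shim_currents(vvol(array(0, g$dims), g$vox, "Hz"), mask, sys)
  expect_true(all(s0$currents == 0))
  expect_equal(s0$cost, 0)
  # in-span target within the limits is recovered exactly
  set.seed(7)
  c_true <- runif(16, -2, 2)
  c_true <- c_true * min(1, 20 / sum(abs(c_true)))
  tgt <- array(0, g$dims)
  for (i in 1:16) tgt <- tgt + c_true[i] * sys$basis[, , , i]
  sol <- solve_shim_currents(vvol(tgt, g$vox, "Hz"), mask, sys)
  expect_lt(max(abs(sol$currents - c_true)), 1e-3)
  expect_lt(sol$residual_sd, 1e-3)
  expect_lt(sol$kkt_residual, 1e-6)
  # 1-coil closed form: c = clip(<a~, b~>/<a~, a~>, +/- 4)
  sys1 <- generate_coil_basis(n_coils = 1, dims = g$dims, vox = g$vox)
  tgt1 <- vvol(10 * sys1$basis[, , , 1], g$vox, "Hz")
  sol1 <- solve_shim_currents(tgt1, mask, sys1)
  a <- sys1$basis[, , , 1][mask]; a <- a - mean(a)
  b <- tgt1$data[mask]; b <- b - mean(b)
  expect_equal(sol1$currents, min(4, sum(a * b) / sum(a^2)), tolerance = 1e-9)
  expect_equal(sol1$currents, 4, tolerance = 1e-9)
})

test_that("limits are honoured, feasible, and monotone under relaxation", {
  g <- shim_grid()
  sys <- generate_coil_basis(n_coils = 16, dims = g$dims, vox = g$vox)
  mask <- array(FALSE, g$dims); mask[10:22, 10:22, 12:24] <- TRUE
  set.seed(8)
  c_big <- runif(16, -4, 4)
  tgt <- array(0, g$dims)
  for (i in 1:16) tgt <- tgt + 3 * c_big[i] * sys$basis[, , , i]
  tv <- vvol(tgt, g$vox, "Hz")
  sol <- solve_shim_currents(tv, mask, sys)
  expect_lte(max(abs(sol$currents)), 4 + 1e-9)
  expect_lte(sum(abs(sol$currents)), 50 + 1e-9)
  # residual SD never exceeds the pre-shim SD (zero current is feasible)
  expect_lte(sol$residual_sd, stats::sd(tgt[mask]) + 1e-12)
  # relaxing the limits never worsens the objective
  relaxed <- sys; relaxed$limit_coil <- 8; relaxed$limit_total <- 100
  solr <- solve_shim_currents(tv, mask, relaxed)
  expect_lte(solr$cost, sol$cost + 1e-6)
})

test_that("cross-evaluation scores currents from one map on another", {
  g <- shim_grid()
  sys <- generate_coil_basis(n_coils = 16, dims = g$dims, vox = g$vox)
  tr <- tiny_phantom()
  meas <- measured_fm_of(tr)
  base <- solve_shim_currents(meas, tr$brain_mask, sys)
  ev0 <- evaluate_shim(meas, rep(0, 16), sys, tr$brain_mask)
  expect_equal(ev0$vol_sd_after_hz, ev0$vol_sd_before_hz)
  expect_true(all(ev0$residual$data == meas$data))
  evb <- evaluate_shim(meas, base$currents, sys, tr$brain_mask)
  expect_lte(evb$vol_sd_after_hz, evb$vol_sd_before_hz + 1e-9)
  expect_error(evaluate_shim(meas, rep(5, 16), sys, tr$brain_mask),
               "limits")
})

test_that("better predictions never shim worse on average over seeds", {
  g <- shim_grid()
  sys <- generate_coil_basis(n_coils = 16, dims = g$dims, vox = g$vox)
  T <- rigid_transform(rot_deg = c(0, 0, 6), trans_mm = c(1, 0, -1))
  diffs <- sapply(c(101L, 202L, 303L), function(sd) {
    tr <- generate_phantom(tiny_spec(seed = sd))
    ref <- reference_of(tr)
    moved <- apply_motion(tr, T)
    meas_new <- measured_fm_of(moved)
    pc <- predict_combined_fm(ref, T)
    sol <- solve_shim_currents(pc$fm, moved$brain_mask, sys)
    ev <- evaluate_shim(meas_new, sol$currents, sys, moved$brain_mask)
    bl <- solve_shim_currents(meas_new, moved$brain_mask, sys)
    evb <- evaluate_shim(meas_new, bl$currents, sys, moved$brain_mask)
    evb$pct_reduction - ev$pct_reduction
  })
  # predicted-map shimming tracks the measured-map baseline closely
  expect_true(all(diffs >= -1e-6))
  expect_lt(mean(diffs), 5)
})
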