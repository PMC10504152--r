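test_that("rigid transforms compose, invert and resample as declared", {
  T <- rigid_transform(rot_deg = c(4, -3, 7), trans_mm = c(2, -1, 3))
  expect_equal(det(T$R), 1, tolerance = 1e-12)
  Ti <- invert_transform(T)
  expect_equal(Ti$R %*% T$R, diag(3), tolerance = 1e-12)
  expect_equal(as.numeric(Ti$R %*% (T$R %*% c(1, 2, 3) + T$t) + Ti$t),
               c(1, 2, 3), tolerance = 1e-12)

  set.seed(5)
  dims <- c(20L, 20L, 20L); vox <- 2
  v <- vvol(array(rnorm(prod(dims)), dims), vox, "Hz")
  # identity is bit-exact
  expect_identical(transform_volume(v, rigid_transform(), "continuous"), v)
  # integer-voxel translation is an exact shifted copy
  tshift <- rigid_transform(trans_mm = c(2 * vox, 0, 0))
  sh <- transform_volume(v, tshift, "label")
  expect_equal(sh$data[3:20, , ], v$data[1:18, , ])
  expect_true(all(sh$data[1:2, , ] == 0))
  # smooth round trip error is bounded by the interpolation modulus
  ca <- b0predict:::coord_arrays(dims, rep(vox, 3))
  smooth <- vvol(sin(ca$x / 10) * cos(ca$y / 12) + ca$z / 40, vox, "Hz")
  Tz <- rigid_transform(rot_deg = c(0, 0, 9))
  back <- transform_volume(transform_volume(smooth, Tz, "continuous"),
                           rigid_transform(rot_deg = c(0, 0, -9)),
                           "continuous")
  m <- b0predict:::valid_mask(back)
  expect_gt(sum(m), prod(dims) / 2)
  expect_lt(max(abs(back$data[m] - smooth$data[m])), 0.05)
})

test_that("prediction strategies are exact at the identity transform", {
  tr <- tiny_phantom()
  ref <- reference_of(tr)
  idT <- rigid_transform()
  pt <- predict_transformed_fm(ref, idT)
  expect_identical(pt$fm$data, ref$measured$data)
  ps <- predict_simulated_fm(ref, idT)
  expect_identical(ps$fm$data, ref$simulated$data)
  pc <- predict_combined_fm(ref, idT)
  expect_identical(pc$fm$data, ref$measured$data)  # MMR identity, exact
  r <- score_prediction(pc$fm, ref$measured, tr$brain_mask, "combined")
  expect_identical(r$rmse_hz, 0)
})

test_that("rigid-only motion is predicted almost perfectly by simulation", {
  tr <- tiny_phantom_clean()
  ref <- reference_of(tr)
  T <- rigid_transform(rot_deg = c(6, 0, 3), trans_mm = c(1, -2, 1))
  moved <- apply_motion(tr, T)
  meas_new <- measured_fm_of(moved)
  ps <- predict_simulated_fm(ref, T)
  r <- score_prediction(ps$fm, meas_new, moved$brain_mask, "simulated")
  expect_lt(r$rmse_hz, 1)
  pc <- predict_combined_fm(ref, T)
  rc <- score_prediction(pc$fm, meas_new, moved$brain_mask, "combined")
  expect_lt(rc$rmse_hz, 1)
})

test_that("neck deformation favours the mask-updated strategies", {
  tr <- mid_phantom()   # the deformed neck needs a lattice finer than 4 mm
  ref <- reference_of(tr)
  T <- rigid_transform(rot_deg = c(8, 0, 0), trans_mm = c(0, 1, -1))
  moved <- apply_motion(tr, T, deform_neck = TRUE)
  meas_new <- measured_fm_of(moved)
  new_mask <- body_mask_from_magnitude(vvol(Mod(moved$echoes[[1]]),
                                            tr$spec$vox, "1"))
  rt <- score_prediction(predict_transformed_fm(ref, T)$fm, meas_new,
                         moved$brain_mask, "transformed")
  rs <- score_prediction(predict_simulated_fm(ref, T, new_mask)$fm, meas_new,
                         moved$brain_mask, "simulated+mask")
  rc <- score_prediction(predict_combined_fm(ref, T, new_mask)$fm, meas_new,
                         moved$brain_mask, "combined+mask")
  expect_lt(rs$rmse_hz, rt$rmse_hz)
  expect_lt(rc$rmse_hz, rt$rmse_hz)
})

test_that("geometry-mask update changes exactly the right voxels", {
  # cavity-free phantom: the only internal air is what the bulge adds, so
  # the changed set is exactly the bulge
  tr <- cached_fixture("tiny_nocav", generate_phantom(
    tiny_spec(cavities = list(list(center = c(0, 16, -8), radius = 0)))))
  chi <- tr$chi
  # transported mask equal to the old body: nothing changes
  same <- update_geometry_mask(chi, tr$body_mask, tr$brain_mask)
  expect_identical(same$data, chi$data)
  # posterior bulge: exactly those voxels flip from air to soft tissue
  ca <- b0predict:::coord_arrays(dim(chi$data), rep(tr$spec$vox, 3))
  bulge <- b0predict:::ellipsoid_mask(ca, c(0, -35, -45), c(18, 14, 16)) &
    !tr$body_mask
  upd <- update_geometry_mask(chi, tr$body_mask | bulge, tr$brain_mask)
  changed <- upd$data != chi$data
  expect_identical(which(changed), which(bulge & chi$data == 0))
  expect_true(all(upd$data[bulge & chi$data == 0] == -9.6))
  # a shrunk mask only removes tissue
  shrunk <- tr$body_mask & ca$z > -20
  upd2 <- update_geometry_mask(chi, shrunk, tr$brain_mask)
  expect_true(all(upd2$data[!shrunk] == 0))
  expect_identical(sum(upd2$data != 0 & chi$data == 0 & !tr$brain_mask &
                         !shrunk), 0L)
  expect_error(update_geometry_mask(chi, array(FALSE, dim(chi$data)),
                                    tr$brain_mask), "empty")
})

test_that("prediction scores follow their definitions", {
  dims <- c(4L, 4L, 4L)
  meas <- vvol(array(1, dims), 2, "Hz")
  mask <- array(FALSE, dims); mask[1:2, 1, 1] <- TRUE
  pred <- meas
  pred$data[1, 1, 1] <- 1      # errors {0, 2} over a two-voxel mask
  pred$data[2, 1, 1] <- 3
  r <- score_prediction(pred, meas, mask)
  expect_equal(r$rmse_hz, sqrt(2))
  # constant offset: RMSE = offset, Vol.sigmaB0 unchanged
  set.seed(2)
  m2 <- vvol(array(rnorm(prod(dims)), dims), 2, "Hz")
  r2 <- score_prediction(m2 + 3, m2, array(TRUE, dims))
  expect_equal(r2$rmse_hz, 3, tolerance = 1e-12)
  expect_equal(r2$vol_sd_predicted_hz, r2$vol_sd_measured_hz)
  expect_error(score_prediction(pred, meas, array(FALSE, dims)), "empty")
})

test_that("body masks extracted from magnitude images track the truth", {
  tr <- tiny_phantom()
  mask <- body_mask_from_magnitude(vvol(Mod(tr$echoes[[1]]), tr$spec$vox, "1"))
  jac <- sum(mask & tr$body_mask) / sum(mask | tr$body_mask)
  expect_gt(jac, 0.9)
})
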