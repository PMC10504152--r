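test_that("field map computation has its closed forms and flags aliasing", {
  dims <- c(8L, 8L, 8L)
  TE <- c(2.68e-3, 7.49e-3)
  dTE <- diff(TE)
  s1 <- array(complex(modulus = 1, argument = 0.3), dims)
  fm0 <- compute_field_map(s1, s1, TE, 2)
  expect_true(all(fm0$data == 0))
  # phase difference pi/2: f = (pi/2) / (2 pi dTE)
  s2 <- s1 * exp(1i * pi / 2)
  fm <- compute_field_map(s1, s2, TE, 2)
  expect_equal(fm$data[1, 1, 1], (pi / 2) / (2 * pi * dTE), tolerance = 1e-12)
  # a field just past the aliasing limit wraps negative
  f_true <- 1 / (2 * dTE) + 5
  s2w <- s1 * exp(2i * pi * f_true * dTE)
  fmw <- compute_field_map(s1, s2w, TE, 2)
  expect_lt(fmw$data[1, 1, 1], 0)
  expect_error(compute_field_map(s1, s1, c(3e-3, 3e-3), 2), "TE2")
  # low-magnitude voxels are flagged invalid
  s1[1, 1, 1] <- s1[1, 1, 1] * 1e-4
  fmv <- compute_field_map(s1, s1, TE, 2)
  expect_false(fmv$valid[1, 1, 1])
  expect_true(fmv$valid[2, 1, 1])
})

test_that("ky-shift estimation recovers a pure phase-encode ramp exactly", {
  dims <- c(24L, 24L, 24L); vox <- 4
  TE <- c(2.68e-3, 7.49e-3)
  a <- 200                                 # k-index / s
  G <- -a / (dims[2] * vox)                # Hz / mm along y
  ca <- b0predict:::coord_arrays(dims, rep(vox, 3))
  mag <- exp(-(ca$x^2 + ca$y^2 + ca$z^2) / (2 * 30^2))   # smooth envelope
  echoes <- lapply(TE, function(t)
    array(mag * exp(2i * pi * G * ca$y * t), dims))
  zerof <- vvol(array(0, dims), vox, "Hz")
  pe <- estimate_ky_shift(echoes, zerof, TE)
  expect_equal(pe$a, a, tolerance = 0.01 * a)
  expect_equal(pe$dk, -a * TE, tolerance = 1e-6)
  # Bk varies only along y and is zero at the FOV centre
  expect_equal(pe$Bk$data[1, , 1], G * ca$y[1, , 1], tolerance = 1e-9)
  expect_equal(pe$Bk$data[5, , 9], pe$Bk$data[1, , 1], tolerance = 1e-12)
  expect_equal(pe$Bk$data[1, dims[2] %/% 2 + 1, 1], 0)
  # magnitude invariance: globally rescaled echoes give the identical slope
  pe2 <- estimate_ky_shift(lapply(echoes, function(e) 7.3 * e), zerof, TE)
  expect_identical(pe2$a, pe$a)
  # no applied ramp
  pe0 <- estimate_ky_shift(lapply(TE, function(t) array(mag, dims)),
                           zerof, TE)
  expect_equal(pe0$a, 0, tolerance = 1e-9)
  expect_true(all(pe0$Bk$data == 0))
  expect_error(estimate_ky_shift(lapply(TE, function(t) array(0i, dims)),
                                 zerof, TE), "signal-free")
})

test_that("dipole fit recovers a generating source and handles constants", {
  dims <- c(32L, 32L, 32L); vox <- 4
  ca <- b0predict:::coord_arrays(dims, rep(vox, 3))
  mask <- (ca$x^2 / 30^2 + ca$y^2 / 35^2 + (ca$z - 10)^2 / 35^2) <= 1
  P <- 6e7; rd <- c(5, -10, -220); shift <- 3
  B <- point_dipole_field(P, rd, dims, vox) + shift
  fit <- fit_lower_body_dipole(B, mask)
  expect_equal(fit$dipole$P, P, tolerance = 0.02 * P)
  expect_lt(max(abs(fit$dipole$rd - rd)), vox)
  expect_equal(fit$b0_shift, shift, tolerance = 1e-3)
  expect_lt(fit$cost, 1e-6 * sqrt(mean(B$data[mask]^2)))
  # translation equivariance of the recovered position
  d <- c(8, -4, 12)
  B2 <- point_dipole_field(P, rd + d, dims, vox) + shift
  fit2 <- fit_lower_body_dipole(B2, mask)
  expect_lt(max(abs(fit2$dipole$rd - (rd + d))), vox)
  # constant input: no dipole needed, offset absorbs it
  Bc <- vvol(array(7.5, dims), vox, "Hz")
  fitc <- fit_lower_body_dipole(Bc, mask)
  u <- point_dipole_field(fitc$dipole$P, fitc$dipole$rd, dims, vox)
  expect_lt(max(abs(u$data[mask])), 1e-3 * 7.5)
  expect_equal(fitc$b0_shift, 7.5, tolerance = 1e-3)
})

test_that("reference decomposition reconstructs the measurement exactly", {
  tr <- tiny_phantom_clean()
  dec <- decompose_reference(tr$echoes, tr$TE, tr$fields$B_SH,
                             tr$fields$Bchi, tr$brain_mask, tr$spec$vox,
                             Bk = tr$fields$Bk)
  recon <- dec$B_SH + dec$Bchi + dec$Bk + dec$Bchi_p + dec$b0_shift + dec$SMR
  m <- tr$brain_mask
  expect_lt(max(abs(recon$data[m] - dec$measured$data[m])), 1e-9)
  # with the true 3-class susceptibility the residual vanishes
  m2 <- m & b0predict:::valid_mask(dec$SMR)
  expect_lt(sqrt(mean(dec$SMR$data[m2]^2)), 1e-6)
})

test_that("SMR is invariant to a global measurement offset (refit absorbs it)", {
  tr <- tiny_phantom_clean()
  meas <- measured_fm_of(tr)
  mkdec <- function(measured) {
    B_diff <- measured - tr$fields$B_SH - tr$fields$Bchi - tr$fields$Bk
    fit <- fit_lower_body_dipole(B_diff, tr$brain_mask)
    Bchi_p <- point_dipole_field(fit$dipole$P, fit$dipole$rd,
                                 dim(measured$data), tr$spec$vox)
    compute_smr(structure(list(measured = measured, B_SH = tr$fields$B_SH,
                               Bchi = tr$fields$Bchi, Bk = tr$fields$Bk,
                               Bchi_p = Bchi_p, b0_shift = fit$b0_shift,
                               brain_mask = tr$brain_mask),
                          class = "decomposition_result"))
  }
  s1 <- mkdec(meas)
  s2 <- mkdec(meas + 12)
  m <- tr$brain_mask
  expect_equal(s2$data[m], s1$data[m], tolerance = 1e-4)
})

test_that("a deliberately mis-set tissue model leaves a localised residual", {
  tr <- tiny_phantom_clean()
  wrong_chi <- tr$chi
  wrong_chi$data[tr$labels == 2L] <- -8    # bone mis-set from -11.4
  Bwrong <- susceptibility_to_field(wrong_chi, tr$spec$pad_factor, tr$spec$f0)
  dec <- decompose_reference(tr$echoes, tr$TE, tr$fields$B_SH, Bwrong,
                             tr$brain_mask, tr$spec$vox, Bk = tr$fields$Bk)
  m <- tr$brain_mask & b0predict:::valid_mask(dec$SMR)
  expect_gt(sqrt(mean(dec$SMR$data[m]^2)), 0.1)
})
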