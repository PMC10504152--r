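chifit_setup <- function() {
  cached_fixture("chifit_setup", {
    tr <- mid_phantom_clean()
    x <- neg_log_transform(tr$ute)
    fit <- fit_histogram_peaks(x)
    multi <- segment_multi_class(x, fit, tr$brain_mask)
    design <- build_design_basis(multi, tr$voi, tr$brain_mask,
                                 tr$spec$pad_factor, tr$spec$f0)
    list(tr = tr, multi = multi, design = design)
  })
}

test_that("single-pair basis columns equal the forward field of their voxels", {
  s <- chifit_setup()
  des <- s$design; tr <- s$tr
  p <- which.max(des$pairs$n_voxels)
  src <- array(0, dim(tr$labels))
  src[des$pair_voxels[[p]]] <- 1
  ref <- susceptibility_to_field(vvol(src, tr$spec$vox, "ppm"),
                                 tr$spec$pad_factor, tr$spec$f0)
  expect_equal(des$A[, p], ref$data[des$mask_idx], tolerance = 1e-10)
})

test_that("basis superposition: disjoint pairs add to their union", {
  s <- chifit_setup()
  des <- s$design; tr <- s$tr
  both <- c(des$pair_voxels[[1]], des$pair_voxels[[2]])
  expect_identical(anyDuplicated(both), 0L)      # pairs are disjoint
  src <- array(0, dim(tr$labels)); src[both] <- 1
  ref <- susceptibility_to_field(vvol(src, tr$spec$vox, "ppm"),
                                 tr$spec$pad_factor, tr$spec$f0)
  expect_equal(des$A[, 1] + des$A[, 2], ref$data[des$mask_idx],
               tolerance = 1e-10)
})

test_that("known per-pair susceptibilities are recovered exactly", {
  s <- chifit_setup()
  des <- s$design; tr <- s$tr
  set.seed(42)
  true_chi <- runif(nrow(des$pairs), -11, -1)
  Bsyn <- vvol(array(0, dim(tr$labels)), tr$spec$vox, "Hz")
  Bsyn$data[des$mask_idx] <- des$A %*% true_chi +
    des$fixed_field$data[des$mask_idx]
  rec <- fit_susceptibilities(Bsyn, tr$brain_mask, des)
  expect_lt(max(abs(rec$pairs$chi - true_chi)), 0.1)
  expect_lte(rec$cost_final, rec$cost_init)
  expect_true(all(diff(rec$cost_trace) <= 1e-12))
  expect_true(all(rec$pairs$chi >= rec$bounds[1] &
                    rec$pairs$chi <= rec$bounds[2]))
  # an already-optimal start is a fixed point
  rec2 <- fit_susceptibilities(Bsyn, tr$brain_mask, des, init = true_chi)
  expect_lt(max(abs(rec2$pairs$chi - true_chi)), 1e-3)
  expect_lt(abs(rec2$cost_final - rec$cost_final), 1e-6)
})

test_that("fitted multi-segment model beats the literature 3-class model", {
  s <- chifit_setup()
  tr <- s$tr
  meas <- measured_fm_of(tr)
  B_diff_m <- meas - tr$fields$B_SH - tr$fields$Bchi_p - tr$fields$Bk -
    tr$spec$b0_shift
  res <- fit_susceptibilities(B_diff_m, tr$brain_mask, s$design)
  x <- neg_log_transform(tr$ute)
  chi3 <- assign_literature_chi(segment_three_class(x, fit_histogram_peaks(x)))
  B3 <- susceptibility_to_field(chi3, tr$spec$pad_factor, tr$spec$f0)
  m <- tr$brain_mask & b0predict:::valid_mask(B_diff_m)
  cost3 <- sqrt(mean((B_diff_m$data[m] - B3$data[m])^2))
  expect_lte(res$cost_final, cost3)
})

test_that("regional susceptibility differences need regional VOIs", {
  spec <- mid_spec(noise_sd = 0, cavity_chi = c(NA, -4))
  tr <- generate_phantom(spec)
  x <- neg_log_transform(tr$ute)
  multi <- segment_multi_class(x, fit_histogram_peaks(x), tr$brain_mask)
  meas <- measured_fm_of(tr)
  B_diff_m <- meas - tr$fields$B_SH - tr$fields$Bchi_p - tr$fields$Bk -
    spec$b0_shift
  des8 <- build_design_basis(multi, tr$voi, tr$brain_mask, spec$pad_factor,
                             spec$f0)
  des1 <- build_design_basis(multi, phantom_voi_partition(tr, 1L),
                             tr$brain_mask, spec$pad_factor, spec$f0)
  f8 <- fit_susceptibilities(B_diff_m, tr$brain_mask, des8)
  f1 <- fit_susceptibilities(B_diff_m, tr$brain_mask, des1)
  expect_lt(f8$cost_final, f1$cost_final)
})

test_that("MMR is the exact complement of the simulated map", {
  s <- chifit_setup()
  tr <- s$tr
  meas <- measured_fm_of(tr)
  sim <- tr$fields$total
  mmr <- compute_mmr(meas, sim, tr$brain_mask)
  m <- tr$brain_mask & b0predict:::valid_mask(mmr)
  expect_lt(max(abs(mmr$data[m] + sim$data[m] - meas$data[m])), 1e-12)
  # simulated = measured gives an identically zero residual
  mmr0 <- compute_mmr(meas, meas, tr$brain_mask)
  expect_true(all(mmr0$data == 0))
  expect_error(compute_mmr(meas, downsample_for_shim(sim, 2), tr$brain_mask),
               "grid mismatch")
})

test_that("measurement noise propagates to the MMR at the expected scale", {
  spec <- mid_spec(noise_sd = 0.02)
  tr <- generate_phantom(spec)
  meas <- measured_fm_of(tr)
  mmr <- compute_mmr(meas, tr$fields$total, tr$brain_mask)
  m <- tr$brain_mask & b0predict:::valid_mask(mmr)
  # complex noise sd on unit magnitude -> phase sd ~ noise_sd per echo;
  # the difference over 2 pi dTE gives the field-map noise
  expected_sd <- sqrt(2) * spec$noise_sd / (2 * pi * diff(spec$TE))
  expect_lt(abs(mean(mmr$data[m])), 0.2)
  expect_equal(stats::sd(mmr$data[m]), expected_sd, tolerance = 0.25)
})
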