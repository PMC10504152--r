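#' Reference model for position prediction
#'
#' Bundles everything the three prediction strategies need at the reference
#' head position: the measured field map, the scanner-frame components (shim,
#' phase-error, out-of-FOV dipole, global offset), the susceptibility model
#' to transport, its forward field, the simulated field map and the
#' multi-model residual.
#'
#' @param measured measured field map ([vvol], Hz).
#' @param B_SH,Bk,Bchi_p scanner-frame component fields ([vvol], Hz).
#' @param b0_shift global offset, Hz.
#' @param chi_map susceptibility model to transport ([vvol], ppm) — the
#'   fitted multi-segment map, or a three-class map.
#' @param brain_mask,body_mask logical arrays at the reference position.
#' @param f0,pad_factor forward-model parameters.
#' @param Bchi_m optional precomputed forward field of `chi_map`.
#' @return a `b0_reference` list, including `simulated` and `MMR`.
#' @export
b0_reference <- function(measured, B_SH, Bk, Bchi_p, b0_shift, chi_map,
                         brain_mask, body_mask, f0 = 123.2e6, pad_factor = 3,
                         Bchi_m = NULL) {
  if (is.null(Bchi_m))
    Bchi_m <- susceptibility_to_field(chi_map, pad_factor, f0)
  simulated <- B_SH + Bchi_m + Bk + Bchi_p + b0_shift
  structure(list(measured = measured, B_SH = B_SH, Bk = Bk, Bchi_p = Bchi_p,
                 b0_shift = b0_shift, chi_map = chi_map, Bchi_m = Bchi_m,
                 simulated = simulated,
                 MMR = compute_mmr(measured, simulated, brain_mask),
                 brain_mask = brain_mask, body_mask = body_mask,
                 f0 = f0, pad_factor = pad_factor),
            class = "b0_reference")
}

#' Transformed-FM prediction
#'
#' Predicts the field map at a new position by rigid transport of the
#' measured reference map: the static shim field is first subtracted (it does
#' not move with the head), the remainder is resampled under the transform,
#' and the shim field is added back.
#'
#' @param ref a [b0_reference()].
#' @param T a [rigid_transform()].
#' @return list with `strategy` and the predicted [vvol] `fm`.
#' @export
predict_transformed_fm <- function(ref, T) {
  if (is.null(ref$B_SH)) stop("reference decomposition lacks B_SH")
  if (is_identity_transform(T))   # (m - B_SH) + B_SH == m, exactly
    return(list(strategy = "transformed", fm = ref$measured))
  moved <- transform_volume(ref$measured - ref$B_SH, T, "continuous")
  list(strategy = "transformed", fm = moved + ref$B_SH)
}

#' Simulated-FM prediction
#'
#' Predicts the field map at a new position by rigid transport of the
#' susceptibility model (nearest neighbour; out-of-support voxels become air)
#' and a fresh forward calculation, keeping the shim field, phase-error field,
#' out-of-FOV dipole field and global offset in the scanner frame. When a
#' body mask measured at the new position is supplied, the transported model
#' is first corrected with [update_geometry_mask()] (large-motion soft-tissue
#' deformation).
#'
#' @param ref a [b0_reference()].
#' @param T a [rigid_transform()].
#' @param new_body_mask optional logical array from the new position's
#'   magnitude image.
#' @return list with `strategy`, predicted `fm`, the transported `chi_map`
#'   and brain mask.
#' @export
predict_simulated_fm <- function(ref, T, new_body_mask = NULL) {
  chi_t <- transform_volume(ref$chi_map, T, "label", fill = 0)
  brain_t <- nn_transform_array(ref$brain_mask, ref$chi_map$vox, T, 0) > 0.5
  if (!is.null(new_body_mask))
    chi_t <- update_geometry_mask(chi_t, new_body_mask, brain_t)
  if (is_identity_transform(T) && is.null(new_body_mask)) {
    fm <- ref$simulated
    Bchi_t <- ref$Bchi_m
  } else {
    Bchi_t <- susceptibility_to_field(chi_t, ref$pad_factor, ref$f0)
    fm <- ref$B_SH + Bchi_t + ref$Bk + ref$Bchi_p + ref$b0_shift
  }
  list(strategy = "simulated", fm = fm, chi_map = chi_t,
       brain_mask = brain_t, Bchi = Bchi_t)
}

#' Combined-FM prediction
#'
#' The simulated field map at the new position plus the rigidly transported
#' multi-model residual from the reference position. At the identity
#' transform this reproduces the measured reference map exactly.
#'
#' @inheritParams predict_simulated_fm
#' @return list with `strategy`, predicted `fm`, and the simulated-FM parts.
#' @export
predict_combined_fm <- function(ref, T, new_body_mask = NULL) {
  sim <- predict_simulated_fm(ref, T, new_body_mask)
  if (is_identity_transform(T) && is.null(new_body_mask)) {
    # simulated + (measured - simulated) == measured, exactly
    fm <- ref$measured
    return(c(list(strategy = "combined", fm = fm),
             sim[c("chi_map", "brain_mask")]))
  }
  mmr_t <- transform_volume(ref$MMR, T, "continuous")
  fm <- sim$fm + mmr_t$data    # MMR transported as data; validity via sim fm
  fm$valid <- combine_valid(sim$fm$valid, NULL)
  c(list(strategy = "combined", fm = fm), sim[c("chi_map", "brain_mask")])
}

#' Update a transported susceptibility model with a new body mask
#'
#' Corrects soft-tissue geometry changes that rigid transport cannot capture:
#' voxels outside the new body mask become air (0 ppm); voxels inside the new
#' mask that were air and are outside the brain become soft tissue; all other
#' voxels keep their transported values.
#'
#' @param chi a transported susceptibility map ([vvol], ppm).
#' @param new_body_mask logical array from the new position's magnitude image.
#' @param brain_mask transported brain mask.
#' @param soft_chi soft-tissue susceptibility for gained voxels, ppm.
#' @return the updated [vvol].
#' @export
update_geometry_mask <- function(chi, new_body_mask, brain_mask,
                                 soft_chi = -9.6) {
  stopifnot(inherits(chi, "vvol"), identical(dim(new_body_mask), dim(chi$data)))
  if (!any(new_body_mask)) stop("empty body mask")
  out <- chi$data
  out[!new_body_mask] <- 0
  gained <- new_body_mask & chi$data == 0 & !brain_mask
  out[gained] <- soft_chi
  vvol(out, chi$vox, "ppm", chi$valid)
}

shift_logical <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ]
}

dilate_mask <- function(m, radius) {
  off <- ball_offsets(radius)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(off)))
    out <- out | shift_logical(m, off$dx[i], off$dy[i], off$dz[i])
  out
}

erode_mask <- function(m, radius) !dilate_mask(!m, radius)

largest_component <- function(m) {
  d <- dim(m)
  lab <- array(0, d)
  lab[m] <- seq_len(sum(m))
  repeat {
    nb <- lab
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      sh <- shift_array(lab, s[1], s[2], s[3])
      upd <- m & sh > 0 & (nb == 0 | sh < nb)
      nb[upd] <- sh[upd]
    }
    if (all(nb == lab)) break
    lab <- nb
  }
  tb <- tabulate(lab[m])
  lab == which.max(tb)
}

shift_array <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

#' Body mask from a magnitude image
#'
#' Thresholds at 10% of the robust (99th percentile) maximum, keeps the
#' largest 6-connected component and applies a morphological closing of
#' radius 2 voxels.
#'
#' @param mag a [vvol] magnitude image.
#' @param thresh_frac threshold fraction.
#' @param close_radius closing radius in voxels.
#' @return a logical array.
#' @export
body_mask_from_magnitude <- function(mag, thresh_frac = 0.1,
                                     close_radius = 2) {
  stopifnot(inherits(mag, "vvol"))
  thr <- thresh_frac * stats::quantile(mag$data, 0.99, names = FALSE)
  m <- mag$data >= thr
  if (!any(m)) stop("no voxels above threshold")
  m <- largest_component(m)
  erode_mask(dilate_mask(m, close_radius), close_radius)
}

#' Score a predicted field map against a measured one
#'
#' RMSE of (predicted - measured) and the volume standard deviations
#' (Vol.sigmaB0) of both maps over the brain mask; invalid voxels of either
#' map are excluded.
#'
#' @param predicted,measured [vvol]s in Hz.
#' @param brain_mask logical array.
#' @param strategy optional strategy name carried into the report.
#' @return a `prediction_report` list: `strategy`, `rmse_hz`,
#'   `vol_sd_measured_hz`, `vol_sd_predicted_hz`, `n_voxels`.
#' @export
score_prediction <- function(predicted, measured, brain_mask,
                             strategy = NA_character_) {
  if (!any(brain_mask)) stop("empty brain mask")
  m <- brain_mask & valid_mask(predicted) & valid_mask(measured)
  if (!any(m)) stop("prediction and measurement share no valid voxels")
  structure(list(strategy = strategy,
                 rmse_hz = sqrt(mean((predicted$data[m] - measured$data[m])^2)),
                 vol_sd_measured_hz = stats::sd(measured$data[m]),
                 vol_sd_predicted_hz = stats::sd(predicted$data[m]),
                 n_voxels = sum(m)),
            class = "prediction_report")
}
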