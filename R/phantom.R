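#' Digital head phantom specification
#'
#' Defines a seeded digital head phantom: an ellipsoidal head with scalp,
#' skull shell, brain compartment, air cavities and a neck/spine extension,
#' plus the simulated measurement conditions (UTE-like intensity statistics,
#' dual-echo GRE timing, shim coefficients, phase-error ramp, an out-of-FOV
#' dipole and complex noise). The defaults describe a 64^3 lattice at 2 mm
#' with literature tissue susceptibilities (air 0, soft tissue -9.6 ppm, bone
#' -11.4 ppm), echo times 2.68/7.49 ms and a 3 T Larmor frequency of
#' 123.2 MHz.
#'
#' @param n voxels per axis (isotropic grid; >= 32).
#' @param vox voxel size mm.
#' @param f0 Larmor frequency Hz.
#' @param head_center,head_semiaxes outer head ellipsoid (scalp surface), mm.
#' @param scalp_thickness soft-tissue layer outside the skull, mm.
#' @param skull_thickness bone shell thickness, mm.
#' @param brain_margin gap between inner skull surface and brain mask, mm.
#' @param cavity_margin minimum brain-mask clearance from cavity surfaces, mm
#'   (keeps the brain below the dual-echo aliasing limit).
#' @param cavities list of `list(center=, radius=)` air cavities, mm; a radius
#'   of 0 removes the cavity.
#' @param cavity_chi optional per-cavity susceptibility override in ppm
#'   (`NA` = air); used to emulate mucosa-filled cavities whose true chi
#'   differs regionally.
#' @param neck_radius,neck_center_xy,spine_radius neck cylinder geometry, mm.
#' @param chi named vector of class susceptibilities in ppm
#'   (`air`, `soft`, `bone`).
#' @param ute_mean,ute_sd named vectors (air/soft/bone) of the class means and
#'   SDs of the negative-log UTE intensity; soft maps to small values, air to
#'   large ones, giving the bimodal histogram the segmentation relies on.
#' @param gre_mag named vector of dual-echo GRE magnitudes per class.
#' @param TE echo times in s (TE2 > TE1 > 0).
#' @param pe_slope_a phase-error slope `a` in k-index/s; the equivalent field
#'   is linear along the first phase-encode (y) axis.
#' @param dipole `list(P=, rd=)` out-of-FOV dipole truth (Hz mm^3, mm).
#' @param sh length-9 spherical-harmonic shim coefficients
#'   (see [sh_shim_field()]).
#' @param b0_shift global frequency offset, Hz.
#' @param auto_shim emulate the scanner's whole-head 2nd-order shim: fit the
#'   SH basis against the tissue + out-of-FOV fields over the brain at the
#'   reference position and add it to `sh`. The effective coefficients are
#'   fixed once per phantom (stored as `sh_effective`) and reused unchanged at
#'   every moved position, as in an experiment where the subject moves after
#'   the shim calibration.
#' @param noise_sd SD of additive circular Gaussian noise per complex channel
#'   (GRE magnitudes are order 1).
#' @param deform posterior neck bulge geometry (`list(center=, semiaxes=)`)
#'   used by [apply_motion()] when `deform_neck = TRUE`.
#' @param pad_factor padding for the forward field computation.
#' @param seed RNG seed; the same spec and seed give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n = 64L, vox = 2, f0 = 123.2e6,
                         head_center = c(0, 0, 10),
                         head_semiaxes = c(40, 45, 48),
                         scalp_thickness = 5, skull_thickness = 4,
                         brain_margin = 4, cavity_margin = 10,
                         cavities = list(
                           list(center = c(0, 26, 18), radius = 7),
                           list(center = c(0, 16, -8), radius = 8)),
                         cavity_chi = NULL,
                         neck_radius = 22, neck_center_xy = c(0, -8),
                         spine_radius = 7,
                         chi = c(air = 0, soft = -9.6, bone = -11.4),
                         ute_mean = c(air = 4.0, soft = 0.5, bone = 1.8),
                         ute_sd = c(air = 0.45, soft = 0.18, bone = 0.15),
                         gre_mag = c(air = 0, soft = 1, bone = 0.35),
                         TE = c(2.68e-3, 7.49e-3),
                         pe_slope_a = 50,
                         dipole = list(P = 6e7, rd = c(5, -10, -220)),
                         sh = c(5, 0.05, -0.04, 0.06,
                                8e-4, 4e-4, -3e-4, 2.5e-4, 3e-4),
                         b0_shift = 3,
                         auto_shim = TRUE,
                         noise_sd = 0.02,
                         deform = list(center = c(0, -35, -45),
                                       semiaxes = c(18, 14, 16)),
                         pad_factor = 3,
                         seed = 1L) {
  if (n < 32L) stop("grid_shape must be >= 32 per axis")
  if (vox <= 0) stop("voxel size must be positive")
  if (!(TE[2] > TE[1] && TE[1] > 0)) stop("need TE2 > TE1 > 0")
  for (cls in c("air", "soft", "bone")) {
    if (is.na(chi[cls]) || is.na(ute_mean[cls]) || is.na(ute_sd[cls]) ||
        is.na(gre_mag[cls]))
      stop("class '", cls, "' is not fully defined")
  }
  if (!is.null(cavity_chi) && length(cavity_chi) != length(cavities))
    stop("cavity_chi must have one entry per cavity")
  spec <- as.list(environment())
  spec$cls <- NULL
  spec$n <- as.integer(n)
  class(spec) <- "phantom_spec"
  spec
}

ellipsoid_mask <- function(ca, center, semiaxes) {
  semiaxes <- pmax(semiaxes, 1e-9)
  ((ca$x - center[1]) / semiaxes[1])^2 +
    ((ca$y - center[2]) / semiaxes[2])^2 +
    ((ca$z - center[3]) / semiaxes[3])^2 <= 1
}

sphere_mask <- function(ca, center, radius) {
  if (radius <= 0) return(array(FALSE, dim(ca$x)))
  (ca$x - center[1])^2 + (ca$y - center[2])^2 + (ca$z - center[3])^2 <=
    radius^2
}

# label codes used throughout the package
LBL_AIR <- 0L
LBL_SOFT <- 1L
LBL_BONE <- 2L

build_phantom_labels <- function(spec, ca) {
  hs <- spec$head_semiaxes
  if (any(hs <= spec$scalp_thickness + spec$skull_thickness))
    stop("head: semi-axes smaller than scalp + skull thickness")
  g <- grid_coords(rep(spec$n, 3), spec$vox)
  lo <- c(min(g$x), min(g$y), min(g$z))
  hi <- c(max(g$x), max(g$y), max(g$z))
  if (any(spec$head_center - hs < lo) || any(spec$head_center + hs > hi))
    stop("head: ellipsoid does not fit inside the grid")

  head <- ellipsoid_mask(ca, spec$head_center, hs)
  skull_out <- ellipsoid_mask(ca, spec$head_center, hs - spec$scalp_thickness)
  skull_in <- ellipsoid_mask(ca, spec$head_center,
                             hs - spec$scalp_thickness - spec$skull_thickness)
  # neck: cylinder from the lower head down to the inferior grid edge
  zneck_top <- spec$head_center[3]
  neck <- ((ca$x - spec$neck_center_xy[1])^2 +
             (ca$y - spec$neck_center_xy[2])^2 <= spec$neck_radius^2) &
    ca$z <= zneck_top
  spine <- ((ca$x - spec$neck_center_xy[1])^2 +
              (ca$y - spec$neck_center_xy[2])^2 <= spec$spine_radius^2) &
    ca$z <= spec$head_center[3] - hs[3] / 2 & neck

  body <- head | neck
  labels <- array(LBL_AIR, dim(ca$x))
  labels[body] <- LBL_SOFT
  labels[skull_out & !skull_in] <- LBL_BONE
  labels[spine & !skull_in] <- LBL_BONE

  # air cavities must sit inside the inner skull
  cav_idx <- vector("list", length(spec$cavities))
  brain_ok <- array(TRUE, dim(ca$x))
  for (i in seq_along(spec$cavities)) {
    cv <- spec$cavities[[i]]
    if (cv$radius <= 0) { cav_idx[[i]] <- integer(0); next }
    inner <- hs - spec$scalp_thickness - spec$skull_thickness
    rel <- sum(((cv$center - spec$head_center) / (inner - cv$radius))^2)
    if (!is.finite(rel) || rel > 1)
      stop(sprintf("cavity %d: does not fit inside the inner skull", i))
    m <- sphere_mask(ca, cv$center, cv$radius)
    labels[m] <- LBL_AIR
    cav_idx[[i]] <- which(m)
    brain_ok <- brain_ok &
      !sphere_mask(ca, cv$center, cv$radius + spec$cavity_margin)
  }

  brain <- ellipsoid_mask(ca, spec$head_center,
                          hs - spec$scalp_thickness - spec$skull_thickness -
                            spec$brain_margin) & brain_ok
  brain <- brain & labels == LBL_SOFT
  list(labels = labels, body = body, brain = brain, cavity_voxels = cav_idx)
}

chi_map_from_labels <- function(labels, spec, cavity_voxels = NULL) {
  chi <- array(spec$chi["air"], dim(labels))
  chi[labels == LBL_SOFT] <- spec$chi["soft"]
  chi[labels == LBL_BONE] <- spec$chi["bone"]
  if (!is.null(spec$cavity_chi) && !is.null(cavity_voxels)) {
    for (i in seq_along(cavity_voxels)) {
      ov <- spec$cavity_chi[i]
      if (!is.na(ov)) chi[cavity_voxels[[i]]] <- ov
    }
  }
  chi
}

#' Axis-aligned VOI partition for a phantom
#'
#' Splits the head-and-neck bounding box (body mask dilated by two voxels into
#' the surrounding air) into 8 octant boxes around the head centre, mirroring
#' the role of anatomically drawn volumes of interest: regions within which
#' each tissue bin may take its own susceptibility. Voxels outside every VOI
#' get label 0 (unfitted).
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param n_vois 1 or 8.
#' @return integer array of VOI labels (0 = unfitted).
#' @export
phantom_voi_partition <- function(truth, n_vois = 8L) {
  spec <- truth$spec
  dims <- dim(truth$labels)
  ca <- coord_arrays(dims, spec$vox)
  idx <- which(truth$body_mask)
  stopifnot(length(idx) > 0)
  pad <- 2 * spec$vox
  inbox <- ca$x >= min(ca$x[idx]) - pad & ca$x <= max(ca$x[idx]) + pad &
    ca$y >= min(ca$y[idx]) - pad & ca$y <= max(ca$y[idx]) + pad &
    ca$z >= min(ca$z[idx]) - pad & ca$z <= max(ca$z[idx]) + pad
  voi <- array(0L, dims)
  if (n_vois == 1L) {
    voi[inbox] <- 1L
    return(voi)
  }
  cc <- spec$head_center
  oct <- 1L + (ca$x >= cc[1]) + 2L * (ca$y >= cc[2]) + 4L * (ca$z >= cc[3])
  voi[inbox] <- oct[inbox]
  voi
}

simulate_echoes <- function(labels, total_field, spec, noise_seed_offset) {
  mag <- array(spec$gre_mag["air"], dim(labels))
  mag[labels == LBL_SOFT] <- spec$gre_mag["soft"]
  mag[labels == LBL_BONE] <- spec$gre_mag["bone"]
  echoes <- vector("list", 2)
  nvox <- length(labels)
  set.seed(spec$seed + noise_seed_offset)
  for (k in 1:2) {
    s <- mag * exp(2i * pi * total_field * spec$TE[k])
    if (spec$noise_sd > 0)
      s <- s + complex(real = stats::rnorm(nvox, 0, spec$noise_sd),
                       imaginary = stats::rnorm(nvox, 0, spec$noise_sd))
    echoes[[k]] <- array(s, dim(labels))
  }
  echoes
}

phantom_component_fields <- function(chi, spec, sh = spec$sh) {
  dims <- dim(chi)
  B_SH <- sh_shim_field(sh, dims, spec$vox)
  Bchi <- susceptibility_to_field(vvol(chi, spec$vox, "ppm"),
                                  spec$pad_factor, spec$f0)
  ca <- coord_arrays(dims, spec$vox)
  G <- -spec$pe_slope_a / (dims[2] * spec$vox)
  Bk <- vvol(G * ca$y, spec$vox, "Hz")
  Bchi_p <- point_dipole_field(spec$dipole$P, spec$dipole$rd, dims, spec$vox)
  total <- vvol(B_SH$data + Bchi$data + Bk$data + Bchi_p$data + spec$b0_shift,
                spec$vox, "Hz")
  list(B_SH = B_SH, Bchi = Bchi, Bk = Bk, Bchi_p = Bchi_p,
       b0_shift = spec$b0_shift, total = total)
}

#' Generate a digital head phantom with simulated measurements
#'
#' Builds the label volume, true susceptibility map, brain/body masks, all
#' simulated field components (shim, tissue, phase-error, out-of-FOV dipole,
#' global offset), a UTE-like magnitude image whose negative-log histogram is
#' bimodal, and noisy dual-echo complex GRE volumes whose phase encodes the
#' total field. With zero noise the field map recomputed from the echoes
#' equals the component sum at every magnitude-valid, non-aliased voxel (the
#' literature air/tissue contrast wraps the dual-echo phase right at cavity
#' poles; `wrap_mask` flags those voxels, and the brain mask is kept clear of
#' them by construction).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth`: `spec`, `labels`, `chi`
#'   ([vvol] ppm), `brain_mask`, `body_mask`, `fields` (component [vvol]s and
#'   `total`), `echoes` (two complex arrays), `TE`, `ute` ([vvol]),
#'   `ute_neglog`, `wrap_mask`, `voi`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- rep(spec$n, 3L)
  ca <- coord_arrays(dims, spec$vox)
  geo <- build_phantom_labels(spec, ca)
  chi <- chi_map_from_labels(geo$labels, spec, geo$cavity_voxels)

  # UTE-like image: negative-log intensities drawn per class, I = exp(-x)
  set.seed(spec$seed)
  x <- array(0, dims)
  for (cls in c("air", "soft", "bone")) {
    lbl <- c(air = LBL_AIR, soft = LBL_SOFT, bone = LBL_BONE)[cls]
    sel <- geo$labels == lbl
    x[sel] <- stats::rnorm(sum(sel), spec$ute_mean[cls], spec$ute_sd[cls])
  }
  # Emulate the scanner's whole-head 2nd-order SH shim at the reference
  # position: fit the 9-term SH basis to the negative of the tissue and
  # out-of-FOV dipole fields over the brain, and add it to the requested
  # coefficients. The shim is set once here and held fixed at every moved
  # position, as in an experiment where the subject moves after shimming.
  # This also keeps the brain below the dual-echo aliasing limit.
  sh_eff <- spec$sh
  if (isTRUE(spec$auto_shim)) {
    f0pre <- phantom_component_fields(chi, spec, sh = rep(0, 9))
    tofit <- f0pre$Bchi$data + f0pre$Bchi_p$data
    ca2 <- coord_arrays(dims, spec$vox)
    X <- cbind(1, ca2$x[geo$brain], ca2$y[geo$brain], ca2$z[geo$brain],
               (2 * ca2$z^2 - ca2$x^2 - ca2$y^2)[geo$brain],
               (ca2$z * ca2$x)[geo$brain], (ca2$z * ca2$y)[geo$brain],
               (ca2$x^2 - ca2$y^2)[geo$brain], (ca2$x * ca2$y)[geo$brain])
    sh_eff <- spec$sh + as.numeric(stats::lm.fit(X, -tofit[geo$brain])$coefficients)
  }
  fields <- phantom_component_fields(chi, spec, sh = sh_eff)
  echoes <- simulate_echoes(geo$labels, fields$total$data, spec,
                            noise_seed_offset = 1L)
  wrap <- abs(fields$total$data) >= 0.98 / (2 * diff(spec$TE))

  truth <- structure(list(
    spec = spec,
    sh_effective = sh_eff,
    labels = geo$labels,
    chi = vvol(chi, spec$vox, "ppm"),
    brain_mask = geo$brain,
    body_mask = geo$body,
    fields = fields,
    echoes = echoes,
    TE = spec$TE,
    ute = vvol(exp(-x), spec$vox, "1"),
    ute_neglog = x,
    wrap_mask = wrap
  ), class = "phantom_truth")
  truth$voi <- phantom_voi_partition(truth, 8L)
  truth
}

bulge_mask <- function(spec, ca) {
  dims <- dim(ca$x)
  zthird <- min(ca$z) + (max(ca$z) - min(ca$z)) / 3
  ellipsoid_mask(ca, spec$deform$center, spec$deform$semiaxes) & ca$z <= zthird
}

#' Move a phantom to a new head position
#'
#' Rigidly transports the head (labels, susceptibility, masks and UTE
#' intensities, nearest-neighbour) to the new position and re-simulates the
#' measurement there. Scanner-frame components — the SH shim field, the
#' phase-error field and the out-of-FOV dipole — remain unchanged; only the
#' tissue-induced field is recomputed from the moved susceptibility map. With
#' `deform_neck = TRUE` a posterior soft-tissue bulge (fixed scanner-frame
#' geometry in the inferior third of the volume, emulating skin folding of
#' the neck under large nodding rotations) is added to the moved body, so
#' rigid transport of the reference susceptibility map is wrong there.
#'
#' @param truth a `phantom_truth`.
#' @param transform a [rigid_transform()].
#' @param deform_neck add the neck bulge?
#' @return a new `phantom_truth` at the moved position.
#' @export
apply_motion <- function(truth, transform, deform_neck = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(transform, "rigid_transform"))
  spec <- truth$spec
  if (is_identity_transform(transform) && !deform_neck) return(truth)
  dims <- dim(truth$labels)
  vox <- spec$vox
  ca <- coord_arrays(dims, vox)

  labels <- nn_transform_array(truth$labels, vox, transform, fill = LBL_AIR)
  chi <- nn_transform_array(truth$chi$data, vox, transform,
                            fill = spec$chi[["air"]])
  body <- nn_transform_array(truth$body_mask, vox, transform, fill = 0) > 0.5
  brain <- nn_transform_array(truth$brain_mask, vox, transform, fill = 0) > 0.5
  x <- nn_transform_array(truth$ute_neglog, vox, transform, fill = NA_real_)

  kept <- sum(body) / sum(truth$body_mask)
  if (kept < 0.5)
    stop("transform moves the head mostly outside the grid (",
         sprintf("%.0f%%", 100 * (1 - kept)), " of body voxels lost)")

  # newly exposed voxels: air, with fresh air-class UTE draws
  nas <- which(is.na(x))
  set.seed(spec$seed + 104729L)
  x[nas] <- stats::rnorm(length(nas), spec$ute_mean["air"], spec$ute_sd["air"])

  if (deform_neck) {
    bm <- bulge_mask(spec, ca) & !body
    labels[bm] <- LBL_SOFT
    chi[bm] <- spec$chi[["soft"]]
    body <- body | bm
    set.seed(spec$seed + 224737L)
    x[bm] <- stats::rnorm(sum(bm), spec$ute_mean["soft"], spec$ute_sd["soft"])
  }

  fields <- phantom_component_fields(chi, spec, sh = truth$sh_effective)
  echoes <- simulate_echoes(labels, fields$total$data, spec,
                            noise_seed_offset = 2L)
  wrap <- abs(fields$total$data) >= 0.98 / (2 * diff(spec$TE))

  out <- truth
  out$labels <- labels
  out$chi <- vvol(chi, vox, "ppm")
  out$brain_mask <- brain
  out$body_mask <- body
  out$fields <- fields
  out$echoes <- echoes
  out$ute <- vvol(exp(-x), vox, "1")
  out$ute_neglog <- x
  out$wrap_mask <- wrap
  out$voi <- truth$voi   # VOI boxes stay in the scanner frame
  out
}
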