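#' Field map from a dual-echo complex pair
#'
#' Computes the off-resonance frequency `f = Arg(conj(S1) S2) / (2 pi dTE)`
#' in Hz. Only the temporal principal value is taken (no spatial unwrapping),
#' so true fields beyond `1/(2 dTE)` alias. Voxels whose combined magnitude
#' `sqrt(|S1||S2|)` falls below 5% of the robust (99th percentile) maximum are
#' flagged invalid.
#'
#' @param e1,e2 complex 3-D arrays at the two echo times.
#' @param TE echo times in s (length 2, TE2 > TE1).
#' @param vox voxel size mm.
#' @param mag_thresh_frac validity threshold as a fraction of the robust
#'   magnitude maximum.
#' @return a [vvol] in Hz with a validity mask.
#' @export
compute_field_map <- function(e1, e2, TE, vox, mag_thresh_frac = 0.05) {
  stopifnot(identical(dim(e1), dim(e2)), length(TE) == 2L)
  dTE <- TE[2] - TE[1]
  if (dTE == 0) stop("TE2 must differ from TE1")
  fm <- Arg(Conj(e1) * e2) / (2 * pi * dTE)
  mag <- sqrt(Mod(e1) * Mod(e2))
  thr <- mag_thresh_frac * stats::quantile(mag, 0.99, names = FALSE)
  vvol(fm, vox, "Hz", valid = mag >= thr)
}

#' Estimate the k-space phase-error shift and its linear field
#'
#' After demodulating the known field contributions
#' (`exp(-i 2 pi demod_field TE_n)`), the residual linear phase ramp along the
#' first phase-encode (y) axis is measured per echo as the intensity-weighted
#' centroid shift of the k-space centre, computed — via Parseval — as the
#' phase of the magnitude-weighted lag-1 autocorrelation along y (wrap-around
#' pair excluded; exact for a pure ramp, magnitude invariant). A
#' slope `a` is then fitted through the origin to `dk_n = -a t_n`, and the
#' shift is re-expressed as the equivalent linear field: a shift of `dk`
#' cycles across `N_y` samples at echo time `t` corresponds to a gradient
#' `dk / (N_y * dy * t)` Hz/mm along y (zero at the FOV centre).
#'
#' @param echoes list of two complex arrays.
#' @param demod_field a [vvol] in Hz (the shim + tissue field estimate).
#' @param TE echo times s.
#' @return a `phase_error_model`: slope `a` (k-index/s), per-echo shifts
#'   `dk`, and the linear field `Bk` ([vvol], Hz).
#' @export
estimate_ky_shift <- function(echoes, demod_field, TE) {
  stopifnot(length(echoes) == 2L, inherits(demod_field, "vvol"))
  if (demod_field$units != "Hz") stop("demod_field must be in Hz")
  dims <- dim(echoes[[1]])
  if (sum(Mod(echoes[[1]])) == 0) stop("signal-free input")
  dk <- numeric(2)
  for (n in 1:2) {
    s <- echoes[[n]] * exp(-2i * pi * demod_field$data * TE[n])
    # linear (non-circular) lag-1 pairs: the wrap-around pair would carry the
    # full phase span across the FOV and bias sub-integer shifts
    corr <- sum(s[, 2:dims[2], , drop = FALSE] *
                  Conj(s[, 1:(dims[2] - 1L), , drop = FALSE]))
    dk[n] <- dims[2] * Arg(corr) / (2 * pi)
  }
  a <- -sum(dk * TE) / sum(TE^2)
  G <- -a / (dims[2] * demod_field$vox[2])
  ca <- coord_arrays(dims, demod_field$vox)
  structure(list(a = a, dk = dk,
                 Bk = vvol(G * ca$y, demod_field$vox, "Hz")),
            class = "phase_error_model")
}

#' Fit an out-of-volume dipole and global offset to a residual field
#'
#' Minimises the RMSE between `B_diff` and a single axial point dipole plus a
#' constant offset over the brain mask. Because the field is linear in the
#' strength `P` and the offset, these are profiled out by least squares at
#' each candidate position; the position is found by a coarse 5x5x5 grid
#' search around the initial guess (100 mm inferior to the FOV centre by
#' default — the lungs lie inferior) followed by derivative-free simplex
#' (Nelder-Mead) refinement with one restart.
#'
#' @param B_diff a [vvol] in Hz (measured minus shim, tissue and phase-error
#'   fields).
#' @param brain_mask logical array.
#' @param init optional initial position (mm).
#' @return list with `dipole` (`P`, `rd`), `b0_shift`, `cost` (the RMSE at
#'   the optimum), and `converged`.
#' @export
fit_lower_body_dipole <- function(B_diff, brain_mask, init = NULL) {
  stopifnot(inherits(B_diff, "vvol"))
  dims <- dim(B_diff$data)
  vox <- B_diff$vox
  m <- brain_mask & valid_mask(B_diff)
  if (!any(m)) stop("no valid voxels inside the brain mask")
  b <- B_diff$data[m]
  if (!all(is.finite(b))) stop("non-finite B_diff inside the mask")
  ca <- coord_arrays(dims, vox)
  mx <- ca$x[m]; my <- ca$y[m]; mz <- ca$z[m]
  halfvox <- min(vox) / 2

  unit_field <- function(pos) {
    dx <- mx - pos[1]; dy <- my - pos[2]; dz <- mz - pos[3]
    d <- pmax(sqrt(dx^2 + dy^2 + dz^2), halfvox)
    (3 * (dz / d)^2 - 1) / d^3
  }
  profile_cost <- function(pos) {
    u <- unit_field(pos)
    um <- mean(u); bm <- mean(b)
    denom <- sum((u - um)^2)
    P <- if (denom < 1e-300) 0 else sum((u - um) * (b - bm)) / denom
    s <- bm - P * um
    list(cost = sqrt(mean((b - P * u - s)^2)), P = P, shift = s)
  }
  cost_only <- function(pos) profile_cost(pos)$cost

  if (is.null(init)) init <- c(0, 0, -100)
  span <- max(dims * vox)
  offs <- seq(-span, span, length.out = 5)
  best <- list(cost = Inf, pos = init)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    pos <- init + c(ox, oy, oz)
    cc <- cost_only(pos)
    if (cc < best$cost) best <- list(cost = cc, pos = pos)
  }
  opt <- stats::optim(best$pos, cost_only, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-13,
                                     parscale = rep(max(vox) * 5, 3)))
  opt2 <- stats::optim(opt$par, cost_only, method = "Nelder-Mead",
                       control = list(maxit = 10000, reltol = 1e-13,
                                      parscale = rep(max(vox), 3)))
  converged <- opt2$convergence == 0
  if (!converged)
    warning("dipole fit did not fully converge; returning best-so-far")
  pc <- profile_cost(opt2$par)
  list(dipole = list(P = pc$P, rd = as.numeric(opt2$par)),
       b0_shift = pc$shift, cost = pc$cost, converged = converged)
}

#' Decompose a measured reference field map into its components
#'
#' Runs the reference-position decomposition: the field map is computed from
#' the dual-echo data; the phase-error field is estimated after demodulating
#' the shim and tissue fields; `B_diff = measured - B_SH - Bchi - Bk` is
#' formed, and a single dipole plus global offset are fitted to it over the
#' brain mask; the simple-model residual is what remains.
#'
#' @param echoes list of two complex arrays.
#' @param TE echo times s.
#' @param B_SH shim field ([vvol], Hz).
#' @param Bchi tissue-induced field from the 3-class susceptibility model
#'   ([vvol], Hz).
#' @param brain_mask logical array.
#' @param vox voxel size mm.
#' @param Bk optional known phase-error field; when supplied the k-space
#'   estimation step is skipped (used when the acquisition's ramp is known).
#' @return a `decomposition_result`: `measured`, `B_SH`, `Bchi`, `Bk`,
#'   `pe_model`, `Bchi_p`, `b0_shift`, `B_diff`, `SMR`, `dipole_fit`.
#' @export
decompose_reference <- function(echoes, TE, B_SH, Bchi, brain_mask, vox,
                                Bk = NULL) {
  measured <- compute_field_map(echoes[[1]], echoes[[2]], TE, vox)
  pe <- NULL
  if (is.null(Bk)) {
    pe <- estimate_ky_shift(echoes, B_SH + Bchi, TE)
    Bk <- pe$Bk
  }
  B_diff <- measured - B_SH - Bchi - Bk
  fit <- fit_lower_body_dipole(B_diff, brain_mask)
  Bchi_p <- point_dipole_field(fit$dipole$P, fit$dipole$rd, dim(measured$data),
                               vox)
  res <- structure(list(measured = measured, B_SH = B_SH, Bchi = Bchi,
                        Bk = Bk, pe_model = pe, Bchi_p = Bchi_p,
                        b0_shift = fit$b0_shift, B_diff = B_diff,
                        dipole_fit = fit, brain_mask = brain_mask),
                   class = "decomposition_result")
  res$SMR <- compute_smr(res)
  res
}

#' Simple-model residual field map (SMR)
#'
#' `SMR = measured - B_SH - Bchi - Bk - Bchi' - B0_shift`, masked to the
#' brain. By construction the components plus the SMR reconstruct the
#' measured field map exactly.
#'
#' @param result a `decomposition_result` (all components present).
#' @return a [vvol] in Hz, invalid outside the brain mask.
#' @export
compute_smr <- function(result) {
  for (nm in c("measured", "B_SH", "Bchi", "Bk", "Bchi_p"))
    check_same_grid(result$measured, result[[nm]], paste("measured and", nm))
  smr <- result$measured - result$B_SH - result$Bchi - result$Bk -
    result$Bchi_p - result$b0_shift
  smr$valid <- combine_valid(smr$valid, result$brain_mask)
  smr
}
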