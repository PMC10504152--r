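#' Lorentz-corrected dipole kernel on the DFT frequency lattice
#'
#' Builds the k-space scaling factor `1/3 - kz^2/(kx^2+ky^2+kz^2)` that maps
#' the Fourier transform of a susceptibility distribution to the Fourier
#' transform of the induced relative field shift. The 1/3 term is the Lorentz
#' sphere correction. The kernel is singular at k = 0; by convention the DC
#' value is set to 0, which makes the computed field mean-free over the
#' (padded) computational volume — any constant offset is absorbed downstream
#' by the fitted B0 shift.
#'
#' @param dims grid shape of the (already padded) lattice.
#' @param vox voxel size in mm (length 1 or 3); anisotropy enters only through
#'   the per-axis frequency spacing `k_i = n_i/(N_i * vox_i)`.
#' @return a numeric array of kernel values in `[-2/3, 1/3]`.
#' @export
dipole_kernel <- function(dims, vox) {
  if (length(vox) == 1L) vox <- rep(vox, 3L)
  fftfreq <- function(n, d) {
    ix <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
    ix / (n * d)
  }
  kx <- fftfreq(dims[1], vox[1])
  ky <- fftfreq(dims[2], vox[2])
  kz <- fftfreq(dims[3], vox[3])
  kx2 <- array(rep(kx^2, times = dims[2] * dims[3]), dim = dims)
  ky2 <- array(rep(rep(ky^2, each = dims[1]), times = dims[3]), dim = dims)
  kz2 <- array(rep(kz^2, each = dims[1] * dims[2]), dim = dims)
  k2 <- kx2 + ky2 + kz2
  k2[1, 1, 1] <- Inf
  K <- 1 / 3 - kz2 / k2
  K[1, 1, 1] <- 0               # DC convention: mean-free field
  K
}

pad_centered <- function(arr, pad_factor) {
  dims <- dim(arr)
  pd <- as.integer(round(dims * pad_factor))
  if (identical(pd, dims)) return(list(arr = arr, start = rep(1L, 3)))
  out <- array(0, dim = pd)
  st <- (pd - dims) %/% 2L + 1L
  out[st[1]:(st[1] + dims[1] - 1L),
      st[2]:(st[2] + dims[2] - 1L),
      st[3]:(st[3] + dims[3] - 1L)] <- arr
  list(arr = out, start = st)
}

crop_centered <- function(arr, dims, start) {
  arr[start[1]:(start[1] + dims[1] - 1L),
      start[2]:(start[2] + dims[2] - 1L),
      start[3]:(start[3] + dims[3] - 1L)]
}

#' Susceptibility-induced field by Fourier dipole approximation
#'
#' Computes the static field perturbation (in Hz) of a susceptibility
#' distribution: the susceptibility map is zero-padded (centred) by
#' `pad_factor` per axis, multiplied in k-space by the Lorentz-corrected
#' dipole kernel, inverse-transformed and cropped back to the field of view:
#' `B(r) = f0 * 1e-6 * IFFT{ kernel * FFT(chi_padded) }`.
#'
#' Padding keeps the periodic DFT images of the source from folding field back
#' into the FOV; a factor of 3 is the package default. The result is real up
#' to floating-point residue; an error is raised if the imaginary residue
#' exceeds 1e-8 of the maximum magnitude.
#'
#' @param chi a [vvol] in ppm.
#' @param pad_factor padding multiple per axis (>= 1).
#' @param f0 Larmor frequency in Hz.
#' @param kernel optional precomputed [dipole_kernel()] for the padded shape
#'   (useful when many maps share one lattice).
#' @return a [vvol] in Hz on the input grid.
#' @export
susceptibility_to_field <- function(chi, pad_factor = 3, f0 = 123.2e6,
                                    kernel = NULL) {
  stopifnot(inherits(chi, "vvol"))
  if (chi$units != "ppm") stop("susceptibility map must be in ppm")
  if (!all(is.finite(chi$data))) stop("non-finite susceptibility values")
  if (pad_factor < 1) stop("pad_factor must be >= 1")
  dims <- dim(chi$data)
  p <- pad_centered(chi$data, pad_factor)
  if (is.null(kernel)) kernel <- dipole_kernel(dim(p$arr), chi$vox)
  stopifnot(identical(dim(kernel), dim(p$arr)))
  f <- stats::fft(kernel * stats::fft(p$arr), inverse = TRUE) / length(p$arr)
  resid <- max(abs(Im(f))) / max(abs(f), 1e-300)
  if (resid > 1e-8)
    stop(sprintf("imaginary residue %.3g exceeds tolerance", resid))
  out <- crop_centered(Re(f), dims, p$start) * (f0 * 1e-6)
  vvol(out, chi$vox, "Hz")
}

#' Spherical-harmonic shim field
#'
#' Evaluates the scanner shim field from 9 coefficients over the unnormalised
#' real solid-harmonic basis, in scanner mm coordinates:
#' `{1, x, y, z, 2z^2 - x^2 - y^2, zx, zy, x^2 - y^2, xy}` (order 0 in Hz,
#' order 1 in Hz/mm, order 2 in Hz/mm^2). Each order-2 basis term is harmonic,
#' exactly so under the discrete 7-point Laplacian.
#'
#' @param coeffs numeric length-9 coefficient vector in the basis order above.
#' @param dims grid shape.
#' @param vox voxel size mm.
#' @return a [vvol] in Hz.
#' @export
sh_shim_field <- function(coeffs, dims, vox) {
  if (length(coeffs) != 9L || !all(is.finite(coeffs)))
    stop("coeffs must be 9 finite numbers")
  ca <- coord_arrays(dims, vox)
  x <- ca$x; y <- ca$y; z <- ca$z
  f <- coeffs[1] +
    coeffs[2] * x + coeffs[3] * y + coeffs[4] * z +
    coeffs[5] * (2 * z^2 - x^2 - y^2) +
    coeffs[6] * z * x + coeffs[7] * z * y +
    coeffs[8] * (x^2 - y^2) + coeffs[9] * x * y
  vvol(f, vox, "Hz")
}

#' Field of an axial point dipole
#'
#' Evaluates `B(r) = P/|r-rd|^3 * (3 ((r-rd).zhat / |r-rd|)^2 - 1)` per voxel.
#' This models the perturbing field of susceptibility sources outside the
#' imaging volume (e.g. the lungs) as a single z-oriented magnetic dipole.
#' `P` is defined so the result is in Hz with distances in mm (units
#' Hz mm^3). Distances are clipped at half the smallest voxel edge to avoid
#' the singularity when `rd` falls on the lattice.
#'
#' @param P dipole strength, Hz mm^3.
#' @param rd dipole position (x, y, z) in mm; may lie outside the FOV.
#' @param dims grid shape.
#' @param vox voxel size mm.
#' @return a [vvol] in Hz.
#' @export
point_dipole_field <- function(P, rd, dims, vox) {
  stopifnot(length(rd) == 3L, all(is.finite(rd)), is.finite(P))
  if (length(vox) == 1L) vox <- rep(vox, 3L)
  ca <- coord_arrays(dims, vox)
  dx <- ca$x - rd[1]; dy <- ca$y - rd[2]; dz <- ca$z - rd[3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  d <- pmax(d, min(vox) / 2)
  vvol(P / d^3 * (3 * (dz / d)^2 - 1), vox, "Hz")
}
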