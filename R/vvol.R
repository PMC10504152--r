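#' Voxel volumes
#'
#' A `vvol` is the carrier for every 3-D map in the package: a scalar lattice
#' with an isotropic-or-not voxel size in mm, a units tag, and an optional
#' per-voxel validity mask. The world frame is the scanner frame: x = partition
#' (right-left), y = first phase encode (anterior-posterior), z = B0/readout
#' (head-foot). World coordinates are in mm with the origin at the centre voxel
#' (0-based index `floor(N/2)` per axis), so the z = 0 plane passes through
#' lattice points exactly.
#'
#' @param data numeric 3-D array.
#' @param vox voxel edge lengths in mm (length 1 or 3).
#' @param units one of `"Hz"`, `"ppm"`, `"1"` (dimensionless).
#' @param valid optional logical array of the same shape; `NULL` means all
#'   voxels valid.
#' @return an object of class `vvol`.
#' @export
vvol <- function(data, vox, units = c("Hz", "ppm", "1"), valid = NULL) {
  units <- match.arg(units)
  if (length(dim(data)) != 3L) stop("vvol data must be a 3-D array")
  if (length(vox) == 1L) vox <- rep(vox, 3L)
  if (any(vox <= 0)) stop("voxel size must be positive")
  if (!is.null(valid)) {
    stopifnot(identical(dim(valid), dim(data)))
    storage.mode(valid) <- "logical"
  }
  structure(list(data = data, vox = as.numeric(vox), units = units,
                 valid = valid),
            class = "vvol")
}

#' @export
print.vvol <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vvol %dx%dx%d, %.3g mm, units=%s%s>\n", d[1], d[2], d[3],
              x$vox[1], x$units,
              if (is.null(x$valid)) "" else
                sprintf(", %d invalid", sum(!x$valid))))
  invisible(x)
}

#' World coordinates of the lattice
#'
#' @param dims integer length-3 grid shape.
#' @param vox voxel size in mm (length 1 or 3).
#' @return list with vectors `x`, `y`, `z` (mm) and the grid shape.
#' @export
grid_coords <- function(dims, vox) {
  if (length(vox) == 1L) vox <- rep(vox, 3L)
  co <- lapply(1:3, function(i) (seq_len(dims[i]) - 1L - dims[i] %/% 2L) * vox[i])
  list(x = co[[1]], y = co[[2]], z = co[[3]], dims = dims, vox = vox)
}

coord_arrays <- function(dims, vox) {
  g <- grid_coords(dims, vox)
  list(
    x = array(rep(g$x, times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep(g$y, each = dims[1]), times = dims[3]), dim = dims),
    z = array(rep(g$z, each = dims[1] * dims[2]), dim = dims)
  )
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) && isTRUE(all.equal(a$vox, b$vox))
}

check_same_grid <- function(a, b, what = "operands") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what)
  invisible(TRUE)
}

combine_valid <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  a & b
}

#' @export
Ops.vvol <- function(e1, e2) {
  if (nargs() == 1L) {
    return(vvol(get(.Generic)(e1$data), e1$vox, e1$units, e1$valid))
  }
  v1 <- inherits(e1, "vvol"); v2 <- inherits(e2, "vvol")
  if (v1 && v2) {
    check_same_grid(e1, e2)
    if (.Generic %in% c("+", "-") && e1$units != e2$units)
      stop(sprintf("unit mismatch: cannot combine '%s' and '%s' volumes",
                   e1$units, e2$units))
    units <- if (.Generic %in% c("+", "-")) e1$units else "1"
    vvol(get(.Generic)(e1$data, e2$data), e1$vox, units,
         combine_valid(e1$valid, e2$valid))
  } else if (v1) {
    vvol(get(.Generic)(e1$data, e2), e1$vox, e1$units, e1$valid)
  } else {
    vvol(get(.Generic)(e1, e2$data), e2$vox, e2$units, e2$valid)
  }
}

valid_mask <- function(v) {
  if (is.null(v$valid)) array(TRUE, dim(v$data)) else v$valid
}

#' Root-mean-square error between two volumes over a mask
#'
#' Invalid voxels of either volume are excluded.
#'
#' @param a,b `vvol`s on the same grid and in the same units.
#' @param mask logical array selecting voxels (e.g. the brain mask).
#' @return RMSE in the common units.
#' @export
rmse_over <- function(a, b, mask) {
  check_same_grid(a, b)
  if (a$units != b$units) stop("unit mismatch in rmse_over")
  m <- mask & valid_mask(a) & valid_mask(b)
  if (!any(m)) stop("no valid voxels in common inside the mask")
  sqrt(mean((a$data[m] - b$data[m])^2))
}

#' Volume standard deviation (Vol.sigmaB0) over a mask
#'
#' @param v a `vvol`.
#' @param mask logical array.
#' @return standard deviation of valid in-mask voxels.
#' @export
vol_sd <- function(v, mask) {
  m <- mask & valid_mask(v)
  if (!any(m)) stop("no valid voxels inside the mask")
  stats::sd(v$data[m])
}
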