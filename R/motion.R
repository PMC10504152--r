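#' Rigid 6-DOF transform
#'
#' Represents a proper rigid-body motion in the scanner frame. Rotations are
#' intrinsic, applied in the order `R = Rx %*% Ry %*% Rz` about the scanner
#' axes through the volume centre (the world origin), followed by the
#' translation: a head point at `p` moves to `R p + t`. The convention is
#' documented so 6-DOF estimates from external registration tools can be
#' converted.
#'
#' @param rot_deg rotations about scanner x, y, z in degrees.
#' @param trans_mm translations along scanner x, y, z in mm.
#' @return an object of class `rigid_transform` carrying the parameters and
#'   the 3x3 rotation matrix / translation vector.
#' @export
rigid_transform <- function(rot_deg = c(0, 0, 0), trans_mm = c(0, 0, 0)) {
  stopifnot(length(rot_deg) == 3L, length(trans_mm) == 3L,
            all(is.finite(rot_deg)), all(is.finite(trans_mm)))
  th <- rot_deg * pi / 180
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])),
              c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  structure(list(rot_deg = rot_deg, trans_mm = trans_mm,
                 R = R, t = as.numeric(trans_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform rot=(%.2f,%.2f,%.2f) deg, t=(%.2f,%.2f,%.2f) mm>\n",
              x$rot_deg[1], x$rot_deg[2], x$rot_deg[3],
              x$trans_mm[1], x$trans_mm[2], x$trans_mm[3]))
  invisible(x)
}

#' Inverse of a rigid transform
#' @param T a [rigid_transform()].
#' @return a `rigid_transform` whose matrix action is the inverse map (the
#'   stored Euler angles are those of the inverse rotation only when a single
#'   axis is involved; the matrix fields are always exact).
#' @export
invert_transform <- function(T) {
  out <- T
  out$R <- t(T$R)
  out$t <- as.numeric(-t(T$R) %*% T$t)
  out$rot_deg <- rep(NA_real_, 3)  # angles of the inverse not re-derived
  out$trans_mm <- out$t
  out
}

is_identity_transform <- function(T) {
  max(abs(T$R - diag(3))) < 1e-12 && max(abs(T$t)) < 1e-12
}

#' Resample a volume under a rigid transform
#'
#' Transports a volume to the moved position and resamples it onto the
#' original grid: the output voxel at world `w` takes the input value at
#' `T^{-1}(w)`. Continuous volumes use trilinear interpolation, labels and
#' masks nearest neighbour (no intermediate susceptibilities are invented at
#' interfaces). Out-of-support voxels are filled with `fill` (default 0, i.e.
#' air for susceptibility maps) and marked invalid for continuous volumes.
#' The identity transform returns the input unchanged, bit-exactly.
#'
#' @param vol a [vvol].
#' @param T a [rigid_transform()].
#' @param kind `"continuous"`, `"label"` or `"mask"`.
#' @param fill fill value for out-of-support voxels.
#' @return a [vvol] on the same grid.
#' @export
transform_volume <- function(vol, T, kind = c("continuous", "label", "mask"),
                             fill = 0) {
  stopifnot(inherits(vol, "vvol"), inherits(T, "rigid_transform"))
  kind <- match.arg(kind)
  if (is_identity_transform(T)) return(vol)
  dims <- dim(vol$data)
  ca <- coord_arrays(dims, vol$vox)
  # source point s = R^T (w - t), in mm, then to (1-based) voxel index
  wx <- as.numeric(ca$x) - T$t[1]
  wy <- as.numeric(ca$y) - T$t[2]
  wz <- as.numeric(ca$z) - T$t[3]
  Rt <- t(T$R)
  sx <- Rt[1, 1] * wx + Rt[1, 2] * wy + Rt[1, 3] * wz
  sy <- Rt[2, 1] * wx + Rt[2, 2] * wy + Rt[2, 3] * wz
  sz <- Rt[3, 1] * wx + Rt[3, 2] * wy + Rt[3, 3] * wz
  ix <- sx / vol$vox[1] + dims[1] %/% 2L + 1
  iy <- sy / vol$vox[2] + dims[2] %/% 2L + 1
  iz <- sz / vol$vox[3] + dims[3] %/% 2L + 1

  out <- rep(fill, length(wx))
  vmask <- valid_mask(vol)

  if (kind == "continuous") {
    x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
    fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
    inside <- x0 >= 1 & x0 < dims[1] & y0 >= 1 & y0 < dims[2] &
      z0 >= 1 & z0 < dims[3]
    idx <- which(inside)
    x0 <- x0[idx]; y0 <- y0[idx]; z0 <- z0[idx]
    fx <- fx[idx]; fy <- fy[idx]; fz <- fz[idx]
    lin <- function(a, b, c) ((c - 1) * dims[2] + (b - 1)) * dims[1] + a
    d <- vol$data
    val <-
      d[lin(x0,     y0,     z0)]     * (1 - fx) * (1 - fy) * (1 - fz) +
      d[lin(x0 + 1, y0,     z0)]     * fx       * (1 - fy) * (1 - fz) +
      d[lin(x0,     y0 + 1, z0)]     * (1 - fx) * fy       * (1 - fz) +
      d[lin(x0 + 1, y0 + 1, z0)]     * fx       * fy       * (1 - fz) +
      d[lin(x0,     y0,     z0 + 1)] * (1 - fx) * (1 - fy) * fz +
      d[lin(x0 + 1, y0,     z0 + 1)] * fx       * (1 - fy) * fz +
      d[lin(x0,     y0 + 1, z0 + 1)] * (1 - fx) * fy       * fz +
      d[lin(x0 + 1, y0 + 1, z0 + 1)] * fx       * fy       * fz
    out[idx] <- val
    # a voxel is valid only if all 8 source corners were valid and in support
    vok <-
      vmask[lin(x0, y0, z0)] & vmask[lin(x0 + 1, y0, z0)] &
      vmask[lin(x0, y0 + 1, z0)] & vmask[lin(x0 + 1, y0 + 1, z0)] &
      vmask[lin(x0, y0, z0 + 1)] & vmask[lin(x0 + 1, y0, z0 + 1)] &
      vmask[lin(x0, y0 + 1, z0 + 1)] & vmask[lin(x0 + 1, y0 + 1, z0 + 1)]
    newvalid <- rep(FALSE, length(wx))
    newvalid[idx] <- vok
    return(vvol(array(out, dims), vol$vox, vol$units,
                array(newvalid, dims)))
  }

  # nearest neighbour for labels/masks
  x0 <- round(ix); y0 <- round(iy); z0 <- round(iz)
  inside <- x0 >= 1 & x0 <= dims[1] & y0 >= 1 & y0 <= dims[2] &
    z0 >= 1 & z0 <= dims[3]
  idx <- which(inside)
  lin <- ((z0[idx] - 1) * dims[2] + (y0[idx] - 1)) * dims[1] + x0[idx]
  out[idx] <- vol$data[lin]
  vvol(array(out, dims), vol$vox, vol$units, NULL)
}

nn_transform_array <- function(arr, vox, T, fill = 0) {
  v <- transform_volume(vvol(arr * 1, vox, "1"), T, "label", fill = fill)
  v$data
}
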