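#' Synthetic multi-coil shim basis
#'
#' Places `n_coils` circular shim coils on a cylinder around the head (two
#' rings, angularly interleaved) and models each coil's per-ampere field as
#' the z-component of a magnetic point dipole at the coil centre, oriented
#' along the inward coil normal, scaled to Hz/A. Sources sit outside the FOV,
#' so every basis map is (discretely) harmonic inside it.
#'
#' @param n_coils number of coils (default 16).
#' @param radius cylinder radius mm.
#' @param length cylinder length mm (ring separation = length/2).
#' @param dims grid shape.
#' @param vox voxel size mm.
#' @param dipole_scale dipole moment scale, Hz mm^3 / A.
#' @param limit_coil per-coil current limit, A.
#' @param limit_total total current limit (sum of magnitudes), A.
#' @return a `shim_system`: `basis` (4-D array, coil axis last, Hz/A),
#'   `coil_pos`, `coil_normal`, limits, `vox`, `currents = NULL`.
#' @export
generate_coil_basis <- function(n_coils = 16L, radius = 140, length = 240,
                                dims = c(64L, 64L, 64L), vox = 2,
                                dipole_scale = 3e7,
                                limit_coil = 4, limit_total = 50) {
  stopifnot(n_coils >= 1L)
  if (length(vox) == 1L) vox <- rep(vox, 3L)
  g <- grid_coords(dims, vox)
  if (radius < max(abs(c(g$x, g$y))) * 0.999)
    warning("coil cylinder intersects the FOV head region")
  per_ring <- ceiling(n_coils / 2)
  ring <- rep(c(-1, 1), length.out = n_coils)
  idx_in_ring <- (seq_len(n_coils) - 1) %/% 2
  ang <- 2 * pi * idx_in_ring / per_ring + ifelse(ring > 0, pi / per_ring, 0)
  pos <- cbind(radius * cos(ang), radius * sin(ang), ring * length / 4)
  nrm <- cbind(-cos(ang), -sin(ang), 0)  # inward radial normal
  ca <- coord_arrays(dims, vox)
  basis <- array(0, c(dims, n_coils))
  for (i in seq_len(n_coils)) {
    dx <- ca$x - pos[i, 1]; dy <- ca$y - pos[i, 2]; dz <- ca$z - pos[i, 3]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    mdotr <- (nrm[i, 1] * dx + nrm[i, 2] * dy + nrm[i, 3] * dz) / d
    basis[, , , i] <- dipole_scale * 3 * mdotr * (dz / d) / d^3
  }
  structure(list(basis = basis, coil_pos = pos, coil_normal = nrm,
                 n_coils = as.integer(n_coils), vox = vox,
                 limit_coil = limit_coil, limit_total = limit_total,
                 currents = NULL),
            class = "shim_system")
}

#' Block-mean downsampling for shimming
#'
#' Pools `factor^3` blocks by their mean, excluding invalid voxels; trailing
#' partial blocks are averaged over the voxels they do contain. A block with
#' no valid voxel becomes invalid.
#'
#' @param vol a [vvol].
#' @param factor integer downsampling factor.
#' @return a [vvol] on the coarse grid (voxel size scaled by `factor`).
#' @export
downsample_for_shim <- function(vol, factor) {
  stopifnot(inherits(vol, "vvol"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  nd <- as.integer(ceiling(d / factor))
  vm <- valid_mask(vol)
  dat <- vol$data
  dat[!vm] <- 0
  bx <- (seq_len(d[1]) - 1L) %/% factor + 1L
  by <- (seq_len(d[2]) - 1L) %/% factor + 1L
  bz <- (seq_len(d[3]) - 1L) %/% factor + 1L
  f <- list(bx[slice.index(dat, 1)], by[slice.index(dat, 2)],
            bz[slice.index(dat, 3)])
  key <- (f[[3]] - 1L) * nd[1] * nd[2] + (f[[2]] - 1L) * nd[1] + f[[1]]
  sums <- tapply(as.numeric(dat), key, sum)
  cnts <- tapply(as.numeric(vm), key, sum)
  out <- array(NA_real_, nd); nv <- array(FALSE, nd)
  k <- as.integer(names(sums))
  out[k] <- as.numeric(sums) / pmax(as.numeric(cnts), 1)
  nv[k] <- as.numeric(cnts) > 0
  out[!nv] <- 0
  vvol(out, vol$vox * factor, vol$units, nv)
}

project_capped_simplex <- function(z, cap, total) {
  x <- pmin(pmax(z, 0), cap)
  if (sum(x) <= total + 1e-12) return(x)
  lo <- 0; hi <- max(z)
  for (i in 1:100) {
    lam <- (lo + hi) / 2
    s <- sum(pmin(pmax(z - lam, 0), cap))
    if (s > total) lo <- lam else hi <- lam
  }
  pmin(pmax(z - (lo + hi) / 2, 0), cap)
}

#' Solve constrained multi-coil shim currents
#'
#' Minimises the sum of squared residual field over the mask,
#' `sum_r (B0(r) - sum_i c_i basis_i(r))^2`, subject to per-coil limits
#' `|c_i| <= limit_coil` and the total-current limit
#' `sum_i |c_i| <= limit_total`. This is a small convex QP (one variable per
#' coil): it is solved by exact cyclic coordinate descent under the box
#' constraints, with the total-current constraint enforced through its
#' Lagrange multiplier — each coordinate update is a closed-form
#' soft-threshold-and-clip, and the multiplier is found by bisection on the
#' monotone map from multiplier to total current. A projected-gradient KKT
#' residual is reported. The global frequency offset is jointly minimised
#' (the order-0 term is not a shim channel and the homogeneity metric is
#' offset-insensitive): the constant component is projected out of the target
#' and the basis columns, and the removed target offset is reported. Zero
#' current is always feasible, so the residual SD never exceeds the pre-shim
#' SD.
#'
#' @param target_fm a [vvol] in Hz on the shim grid.
#' @param brain_mask logical array.
#' @param system a [generate_coil_basis()] result (or any `shim_system`).
#' @param max_sweeps,tol solver controls (coordinate-descent sweeps and
#'   convergence tolerance in A).
#' @return the `shim_system` with `currents`, `cost` (sum of squares),
#'   `residual_sd`, `offset_removed`, `kkt_residual`.
#' @export
solve_shim_currents <- function(target_fm, brain_mask, system,
                                max_sweeps = 10000L, tol = 1e-12) {
  stopifnot(inherits(system, "shim_system"), inherits(target_fm, "vvol"))
  dims <- dim(target_fm$data)
  stopifnot(identical(dims, dim(system$basis)[1:3]))
  m <- brain_mask & valid_mask(target_fm)
  if (!any(m)) stop("no valid voxels inside the mask")
  nc <- system$n_coils
  A <- matrix(system$basis, ncol = nc)[as.vector(m), , drop = FALSE]
  offset <- mean(target_fm$data[m])
  b <- target_fm$data[m] - offset
  # the global offset is re-optimised for every current vector (it is not a
  # shim channel and Vol.sigmaB0 ignores it): project the constant component
  # out of the target AND the basis columns
  A <- sweep(A, 2, colMeans(A))

  M <- crossprod(A)            # nc x nc
  v <- as.numeric(crossprod(A, b))
  dM <- diag(M)
  if (any(dM <= 0)) stop("degenerate shim basis")
  cap <- system$limit_coil; tot <- system$limit_total

  # exact coordinate descent for min ||b - A c||^2 + lam * sum|c|, |c_i|<=cap
  cd_solve <- function(lam, cstart) {
    cvec <- cstart
    Mc <- as.numeric(M %*% cvec)
    for (sw in seq_len(max_sweeps)) {
      delta <- 0
      for (i in seq_len(nc)) {
        t_i <- v[i] - (Mc[i] - dM[i] * cvec[i])
        ci <- sign(t_i) * max(abs(t_i) - lam / 2, 0) / dM[i]
        ci <- min(cap, max(-cap, ci))
        if (ci != cvec[i]) {
          Mc <- Mc + M[, i] * (ci - cvec[i])
          delta <- max(delta, abs(ci - cvec[i]))
          cvec[i] <- ci
        }
      }
      if (delta < tol) break
    }
    cvec
  }

  # unconstrained optimum first: if it is feasible it is THE optimum
  c_ls <- tryCatch(as.numeric(qr.coef(qr(A), b)), error = function(e) NULL)
  feasible <- function(cv) !is.null(cv) && all(is.finite(cv)) &&
    max(abs(cv)) <= cap + 1e-9 && sum(abs(cv)) <= tot + 1e-9
  if (feasible(c_ls)) {
    cvec <- c_ls
  } else {
    cvec <- cd_solve(0, rep(0, nc))
    if (sum(abs(cvec)) > tot + 1e-9) {
      lo <- 0; hi <- 2 * max(abs(v)) + 1
      for (k in 1:200) {
        lam <- (lo + hi) / 2
        cvec <- cd_solve(lam, cvec)
        s <- sum(abs(cvec))
        if (abs(s - tot) < 1e-10) break
        if (s > tot) lo <- lam else hi <- lam
        if (hi - lo < 1e-14 * (1 + hi)) break
      }
      if (sum(abs(cvec)) > tot) cvec <- cd_solve(hi, cvec)
    }
    # active-set polish: resolve the free coordinates exactly
    objective <- function(cv) sum((b - A %*% cv)^2)
    freei <- abs(cvec) < cap - 1e-6
    cand <- cvec
    if (any(freei)) {
      r <- b - A[, !freei, drop = FALSE] %*% cvec[!freei]
      if (sum(abs(cvec)) < tot - 1e-6) {
        cf <- tryCatch(as.numeric(qr.coef(qr(A[, freei, drop = FALSE]), r)),
                       error = function(e) NULL)
        if (!is.null(cf)) cand[freei] <- cf
      } else {
        # total limit active: equality-constrained LS with the CD signs
        s_f <- sign(cvec[freei]); s_f[s_f == 0] <- 1
        Af <- A[, freei, drop = FALSE]
        Mf <- crossprod(Af); vf <- as.numeric(crossprod(Af, r))
        t_rem <- tot - sum(abs(cvec[!freei]))
        K <- rbind(cbind(2 * Mf, s_f), c(s_f, 0))
        sol <- tryCatch(solve(K, c(2 * vf, t_rem)), error = function(e) NULL)
        if (!is.null(sol)) cand[freei] <- sol[seq_len(sum(freei))]
      }
      if (feasible(cand) && objective(cand) <= objective(cvec) + 1e-9)
        cvec <- cand
    }
  }

  # KKT check: projected-gradient residual at the solution (split currents)
  g <- as.numeric(2 * (M %*% cvec - v))
  L <- 4 * max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  eta <- 1 / L
  xsplit <- c(pmax(cvec, 0), pmax(-cvec, 0))
  xp <- project_capped_simplex(xsplit - eta * c(g, -g), cap, tot)
  kkt <- max(abs((xp[1:nc] - xp[nc + 1:nc]) - cvec)) / eta
  resid <- b - as.numeric(A %*% cvec)
  out <- system
  out$currents <- as.numeric(cvec)
  out$cost <- sum(resid^2)
  out$residual_sd <- stats::sd(resid)
  out$offset_removed <- offset
  out$kkt_residual <- kkt
  out
}

#' Evaluate shim currents against a measured field map
#'
#' Applies currents (typically solved on a PREDICTED map) to the coil basis
#' and scores the residual on the MEASURED map: the cross-evaluation protocol
#' for shimming without a measured field map at the new position.
#'
#' @param measured_fm a [vvol] in Hz.
#' @param currents per-coil currents in A (checked against the limits).
#' @param system the `shim_system` providing the basis.
#' @param brain_mask logical array.
#' @return list with `vol_sd_before_hz`, `vol_sd_after_hz`,
#'   `pct_reduction`, and the residual [vvol].
#' @export
evaluate_shim <- function(measured_fm, currents, system, brain_mask) {
  stopifnot(length(currents) == system$n_coils)
  if (any(abs(currents) > system$limit_coil + 1e-6) ||
      sum(abs(currents)) > system$limit_total + 1e-6)
    stop("currents violate the system limits")
  dims <- dim(measured_fm$data)
  shim_field <- array(0, dims)
  for (i in seq_len(system$n_coils))
    shim_field <- shim_field + currents[i] * system$basis[, , , i]
  residual <- vvol(measured_fm$data - shim_field, measured_fm$vox, "Hz",
                   measured_fm$valid)
  sd_before <- vol_sd(measured_fm, brain_mask)
  sd_after <- vol_sd(residual, brain_mask)
  list(vol_sd_before_hz = sd_before, vol_sd_after_hz = sd_after,
       pct_reduction = 100 * (1 - sd_after / sd_before),
       residual = residual)
}
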