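#' Negative-log transform of a UTE-like image
#'
#' Maps a proton-density UTE magnitude image to `x = -log(I / max(I))`, in
#' which soft tissue appears as small values, bone intermediate, and air/noise
#' as large values. Intensities are floored at the 0.01 percentile of nonzero
#' voxels before the log to avoid `-log(0)`.
#'
#' @param ute a [vvol] (dimensionless magnitude).
#' @return a [vvol] of negative-log intensities (dimensionless).
#' @export
neg_log_transform <- function(ute) {
  stopifnot(inherits(ute, "vvol"))
  I <- ute$data
  if (all(I == 0)) stop("all-zero UTE image")
  floorv <- stats::quantile(I[I > 0], 1e-4, names = FALSE)
  I <- pmax(I, floorv)
  vvol(-log(I / max(I)), ute$vox, "1", ute$valid)
}

gauss_sse <- function(par, xc, y) {
  sum((y - par[1] * exp(-(xc - par[2])^2 / (2 * par[3]^2)))^2)
}

fit_gauss_window <- function(xc, y) {
  pk <- which.max(y)
  amp0 <- y[pk]; mu0 <- xc[pk]
  # initial sigma from the half-width at half maximum around the peak,
  # which keeps the fit local when a secondary bump sits inside the window
  half <- amp0 / 2
  l <- pk; while (l > 1 && y[l] > half) l <- l - 1
  r <- pk; while (r < length(y) && y[r] > half) r <- r + 1
  hwhm <- max((xc[r] - xc[l]) / 2, xc[2] - xc[1])
  sd0 <- hwhm / sqrt(2 * log(2))
  fit <- stats::optim(c(amp0, mu0, sd0), gauss_sse, xc = xc, y = y,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- c(amp = fit$par[1], mu = fit$par[2], sigma = abs(fit$par[3]))
  span <- diff(range(xc))
  if (p["mu"] < min(xc) || p["mu"] > max(xc) || p["sigma"] > span ||
      !all(is.finite(p)))
    p <- c(amp = amp0, mu = mu0, sigma = sd0)  # degenerate fit: keep init
  p
}

#' Fit the two dominant peaks of a negative-log UTE histogram
#'
#' Histograms the negative-log intensities, smooths the counts (moving
#' average, 5 bins), locates the two highest local maxima separated by at
#' least 10 bins, and fits a Gaussian to each by least squares over a window
#' of half the inter-peak distance. The soft-tissue peak is the one at the
#' smaller value (chosen by position, never by height); the other is the
#' air/noise peak. `FWHM = 2 sqrt(2 ln 2) sigma`.
#'
#' @param x a [vvol] from [neg_log_transform()] (or a numeric array).
#' @param nbins histogram bin count.
#' @return a `histogram_fit` list: `center_soft`, `fwhm_soft`,
#'   `center_noise`, `fwhm_noise`, `bin_mids`, `counts`.
#' @export
fit_histogram_peaks <- function(x, nbins = 256L) {
  v <- if (inherits(x, "vvol")) x$data else x
  h <- graphics::hist(as.numeric(v), breaks = nbins, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  n <- length(counts)
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  is_peak <- logical(n)
  for (i in 2:(n - 1)) {
    is_peak[i] <- sm[i] > 0 && sm[i] >= sm[i - 1] && sm[i] >= sm[i + 1] &&
      (sm[i] > sm[i - 1] || sm[i] > sm[i + 1])
  }
  cand <- which(is_peak)[order(sm[is_peak], decreasing = TRUE)]
  if (length(cand) < 1) stop("histogram not bimodal")
  p1 <- cand[1]
  # second peak: far enough from the first, not a tail ripple, and separated
  # from the first by a genuine valley (otherwise noise maxima on the flank
  # of one broad peak would masquerade as a second mode)
  p2 <- NA_integer_
  for (p in cand[-1]) {
    if (abs(p - p1) < 10 || sm[p] < 0.05 * sm[p1]) next
    valley <- min(sm[min(p, p1):max(p, p1)])
    if (valley < 0.5 * min(sm[p], sm[p1])) { p2 <- p; break }
  }
  if (is.na(p2)) stop("histogram not bimodal")
  half <- max(3L, floor(abs(p2 - p1) / 2))
  fits <- lapply(c(p1, p2), function(p) {
    # cap the window at 2.5x the peak's own HWHM so a bone shoulder between
    # the peaks cannot pull the Gaussian off its peak
    amp <- sm[p]
    l <- p; while (l > 1 && sm[l] > amp / 2) l <- l - 1
    r <- p; while (r < n && sm[r] > amp / 2) r <- r + 1
    w <- min(half, max(3L, ceiling(2.5 * (r - l) / 2)))
    lo <- max(1L, p - w); hi <- min(n, p + w)
    fit_gauss_window(mids[lo:hi], counts[lo:hi])
  })
  ord <- order(c(mids[p1], mids[p2]))   # soft = lower position
  soft <- fits[[ord[1]]]; noise <- fits[[ord[2]]]
  k <- 2 * sqrt(2 * log(2))
  structure(list(center_soft = unname(soft["mu"]),
                 fwhm_soft = unname(k * soft["sigma"]),
                 center_noise = unname(noise["mu"]),
                 fwhm_noise = unname(k * noise["sigma"]),
                 bin_mids = mids, counts = counts),
            class = "histogram_fit")
}

#' Three-class threshold segmentation (air / bone / soft tissue)
#'
#' Applies the bone-interval rule to the negative-log intensities: soft tissue
#' below `center_soft + 1.4 * FWHM_soft`, air above
#' `center_noise - 1.4 * FWHM_noise`, bone in between.
#'
#' @param x a [vvol] of negative-log intensities.
#' @param fit a [fit_histogram_peaks()] result.
#' @return a `segmentation_model`: `mode = "three_class"`, integer `labels`
#'   (0 air, 1 soft, 2 bone), the bone `interval`, and the fit.
#' @export
segment_three_class <- function(x, fit) {
  stopifnot(inherits(fit, "histogram_fit"))
  lo <- fit$center_soft + 1.4 * fit$fwhm_soft
  hi <- fit$center_noise - 1.4 * fit$fwhm_noise
  if (!(lo < hi))
    stop(sprintf("inverted bone interval [%.3f, %.3f]: peaks overlap", lo, hi))
  v <- x$data
  labels <- array(LBL_BONE, dim(v))
  labels[v < lo] <- LBL_SOFT
  labels[v > hi] <- LBL_AIR
  structure(list(mode = "three_class", labels = labels,
                 interval = c(lo, hi), fit = fit, vox = x$vox,
                 x = v),
            class = "segmentation_model")
}

# multi-class label codes: 1 brain, 2 below-interval soft, 3 above-interval
# air, 10 + j for bin j (j = 0 .. nbins-1)
MC_BRAIN <- 1L
MC_SOFT <- 2L
MC_AIR <- 3L
MC_BIN0 <- 10L

#' Multiple-segment model of the head
#'
#' Voxels inside the brain mask are labelled brain (fixed soft-tissue
#' susceptibility). Voxels outside are binned by their negative-log intensity
#' over the linear interval
#' `[center_soft - 1.4 * FWHM_soft, center_noise]` with bin width 0.1;
#' below-interval voxels are labelled soft tissue, above-interval voxels air.
#'
#' @param x a [vvol] of negative-log intensities.
#' @param fit a [fit_histogram_peaks()] result.
#' @param brain_mask logical array aligned with `x`.
#' @param bin_width histogram-class width (0.1 by default).
#' @return a `segmentation_model`: `mode = "multi_class"`, `labels`,
#'   `interval`, `nbins`, `bin_width`, `classes` (a table describing every
#'   label code), the fit and the intensities.
#' @export
segment_multi_class <- function(x, fit, brain_mask, bin_width = 0.1) {
  stopifnot(inherits(fit, "histogram_fit"),
            identical(dim(brain_mask), dim(x$data)))
  if (!any(brain_mask)) warning("empty brain mask; no voxels fixed as brain")
  lo <- fit$center_soft - 1.4 * fit$fwhm_soft
  hi <- fit$center_noise
  if (!(lo < hi)) stop("degenerate multi-class interval")
  nbins <- as.integer(floor((hi - lo) / bin_width + 1e-9))
  v <- x$data
  labels <- array(MC_AIR, dim(v))
  labels[v < hi] <- MC_BIN0 + pmin(pmax(floor((v[v < hi] - lo) / bin_width),
                                        0), nbins - 1L)
  labels[v < lo] <- MC_SOFT
  labels[brain_mask] <- MC_BRAIN
  classes <- data.frame(
    code = c(MC_BRAIN, MC_SOFT, MC_AIR, MC_BIN0 + seq_len(nbins) - 1L),
    description = c("brain (fixed soft-tissue chi)",
                    "below interval: soft tissue",
                    "above interval: air",
                    sprintf("bin %d: x in [%.2f, %.2f)", seq_len(nbins) - 1L,
                            lo + bin_width * (seq_len(nbins) - 1L),
                            lo + bin_width * seq_len(nbins))))
  structure(list(mode = "multi_class", labels = labels,
                 interval = c(lo, hi), nbins = nbins, bin_width = bin_width,
                 classes = classes, fit = fit, vox = x$vox, x = v,
                 brain_mask = brain_mask),
            class = "segmentation_model")
}

#' Literature susceptibilities for a three-class model
#'
#' Assigns air 0 ppm (the reference), bone -11.4 ppm and soft tissue
#' -9.6 ppm to a three-class segmentation.
#'
#' @param model a three-class `segmentation_model`.
#' @param chi named values in ppm.
#' @return a [vvol] susceptibility map in ppm.
#' @export
assign_literature_chi <- function(model,
                                  chi = c(air = 0, soft = -9.6,
                                          bone = -11.4)) {
  stopifnot(inherits(model, "segmentation_model"))
  if (model$mode != "three_class") stop("expected a three-class model")
  lbl <- model$labels
  known <- lbl %in% c(LBL_AIR, LBL_SOFT, LBL_BONE)
  if (!all(known)) stop("unknown label in three-class model")
  out <- array(chi[["air"]], dim(lbl))
  out[lbl == LBL_SOFT] <- chi[["soft"]]
  out[lbl == LBL_BONE] <- chi[["bone"]]
  vvol(out, model$vox, "ppm")
}
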