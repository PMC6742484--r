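erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' Generate a synthetic fluorescence line scan
#'
#' Emulates the intensity profile of a fluorescently labelled filament
#' imaged with a Gaussian point spread function: a plateau whose ends
#' fall off as Gaussian error functions of combined width
#' \eqn{\sqrt{\sigma_{true}^2 + \sigma_{psf}^2}}.  The right-hand end
#' carries the taper width \code{sigma_true} (protofilament length
#' variability); the left end falls off with the PSF width alone.
#' Optional Poisson shot noise plus Gaussian read noise.
#'
#' @param sigma_true Tip standard deviation of the right end, nm (>= 0).
#' @param sigma_psf PSF sigma, nm.
#' @param length Filament length, nm.
#' @param pixel Pixel size, nm (default 64).
#' @param amplitude Plateau intensity, a.u.
#' @param background Background offset, a.u.
#' @param noise \code{"none"} or \code{"poisson-gaussian"}.
#' @param read_sd Gaussian read-noise SD, a.u.
#' @param pad Background padding on each side, nm.
#' @param channel Channel tag.
#' @return A \code{line_scan}: list with \code{positions} (nm, strictly
#'   increasing), \code{intensities}, \code{channel}, \code{pixel}.
#' @export
generate_synthetic_linescan <- function(sigma_true, sigma_psf = 120,
                                        length = 2500, pixel = 64,
                                        amplitude = 1000, background = 100,
                                        noise = c("none", "poisson-gaussian"),
                                        read_sd = 5, pad = 1500,
                                        channel = "filament") {
  stopifnot(sigma_true >= 0, sigma_psf >= 0, length > 0)
  noise <- match.arg(noise)
  x <- seq(-pad, length + pad, by = pixel)
  wL <- sigma_psf
  wR <- sqrt(sigma_true^2 + sigma_psf^2)
  profile <- 0.5 * (erf(x / (max(wL, 1e-6) * sqrt(2))) -
                    erf((x - length) / (max(wR, 1e-6) * sqrt(2))))
  y <- background + amplitude * profile
  if (noise == "poisson-gaussian") {
    y <- stats::rpois(base::length(y), y) +
      stats::rnorm(base::length(y), 0, read_sd)
  }
  structure(list(positions = x, intensities = y, channel = channel,
                 pixel = pixel,
                 truth = list(sigma_true = sigma_true,
                              sigma_psf = sigma_psf, length = length,
                              amplitude = amplitude,
                              background = background)),
            class = "line_scan")
}

#' Fit a Gaussian error function to a filament end
#'
#' Least-squares fit of
#' \eqn{I(x) = A/2 \cdot erfc((x - \mu)/(\sigma_{fit}\sqrt{2})) + bg}
#' to the intensity falloff at a filament end, initialized by moment
#' matching.  The tip standard deviation deconvolves the PSF in
#' quadrature: \eqn{\sigma_{tip}^2 = \max(\sigma_{fit}^2 -
#' \sigma_{psf}^2, 0)}; set \code{deconvolve = FALSE} to report the raw
#' fitted width instead.
#'
#' @param scan A \code{line_scan} (or list with positions/intensities)
#'   covering background on both sides of the end.
#' @param sigma_psf PSF sigma, nm (required for deconvolution).
#' @param end Which end to fit: \code{"right"} (falling) or
#'   \code{"left"}.
#' @param deconvolve Subtract the PSF width in quadrature (default).
#' @return A \code{tip_fit}: \code{mu}, \code{sigma_fit},
#'   \code{sigma_tip}, \code{amplitude}, \code{background},
#'   \code{covariance}.
#' @export
fit_tip_errorfunction <- function(scan, sigma_psf = 120,
                                  end = c("right", "left"),
                                  deconvolve = TRUE) {
  end <- match.arg(end)
  x <- scan$positions; y <- scan$intensities
  if (end == "left") { x <- rev(-x); y <- rev(y) }
  # restrict to the half of the scan containing this end
  mid <- stats::median(x)
  keep <- x >= mid - diff(range(x)) * 0.05
  xs <- x[keep]; ys <- y[keep]
  bg0 <- stats::quantile(ys, 0.05, names = FALSE)
  a0 <- stats::quantile(ys, 0.95, names = FALSE) - bg0
  half <- bg0 + a0 / 2
  mu0 <- xs[which.min(abs(ys - half))]
  # moment-matched width from the 25-75% crossing span
  x25 <- xs[which.min(abs(ys - (bg0 + 0.25 * a0)))]
  x75 <- xs[which.min(abs(ys - (bg0 + 0.75 * a0)))]
  s0 <- max(abs(x25 - x75) / 1.349, scan$pixel %||% 50)
  df <- data.frame(x = xs, y = ys)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bg + a / 2 * erfc((x - mu) / (sig * sqrt(2))),
      data = df,
      start = list(bg = bg0, a = a0, mu = mu0, sig = s0),
      lower = c(-Inf, 0, min(xs), 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("tip fit did not converge: ", conditionMessage(e),
           sprintf(" (starts: bg=%.3g a=%.3g mu=%.3g sig=%.3g)",
                   bg0, a0, mu0, s0)))
  co <- stats::coef(fit)
  sig_fit <- abs(co[["sig"]])
  sig_tip <- if (deconvolve) sqrt(max(sig_fit^2 - sigma_psf^2, 0)) else sig_fit
  structure(list(mu = if (end == "left") -co[["mu"]] else co[["mu"]],
                 sigma_fit = sig_fit, sigma_tip = sig_tip,
                 amplitude = co[["a"]], background = co[["bg"]],
                 covariance = tryCatch(stats::vcov(fit),
                                       error = function(e) NULL),
                 end = end, deconvolved = deconvolve),
            class = "tip_fit")
}

#' Align and average line scans
#'
#' Orients every two-channel scan so that the brighter binder end is on
#' the right (the binder-channel intensity summed over the last 9 pixels
#' of each end decides), rebins all scans to the mean filament length by
#' linear interpolation, and averages, returning per-point standard
#' errors.
#'
#' @param scans List of filaments; each element a list with
#'   \code{filament} and \code{binder} \code{line_scan}s sharing
#'   positions.
#' @param n_end_pixels Pixels summed at each end for orientation
#'   (default 9).
#' @return List with \code{positions} (rebinned common axis),
#'   \code{filament}, \code{binder} (mean intensities), \code{se_filament},
#'   \code{se_binder}, \code{flipped} (logical per scan).
#' @export
align_and_average_linescans <- function(scans, n_end_pixels = 9) {
  if (length(scans) < 2) stop("need at least 2 scans")
  npix <- vapply(scans, function(s) length(s$binder$intensities), integer(1))
  if (any(npix < 2 * n_end_pixels))
    stop("scans must have at least 2 x ", n_end_pixels, " pixels")
  oriented <- lapply(scans, function(s) {
    g <- s$binder$intensities
    left <- sum(g[seq_len(n_end_pixels)])
    right <- sum(g[seq(length(g) - n_end_pixels + 1, length(g))])
    flip <- left > right
    if (flip) {
      s$binder$intensities <- rev(s$binder$intensities)
      s$filament$intensities <- rev(s$filament$intensities)
    }
    s$flipped <- flip
    s
  })
  mean_len <- mean(vapply(oriented, function(s)
    diff(range(s$filament$positions)), numeric(1)))
  n_out <- round(mean(npix))
  xout <- seq(0, mean_len, length.out = n_out)
  rebin <- function(s, chan) {
    x <- s[[chan]]$positions - min(s[[chan]]$positions)
    stats::approx(x / max(x) * mean_len, s[[chan]]$intensities,
                  xout = xout, rule = 2)$y
  }
  fm <- vapply(oriented, rebin, numeric(n_out), chan = "filament")
  bm <- vapply(oriented, rebin, numeric(n_out), chan = "binder")
  list(positions = xout,
       filament = rowMeans(fm), binder = rowMeans(bm),
       se_filament = apply(fm, 1, stats::sd) / sqrt(ncol(fm)),
       se_binder = apply(bm, 1, stats::sd) / sqrt(ncol(bm)),
       flipped = vapply(oriented, `[[`, logical(1), "flipped"))
}

#' Binder/filament intensity ratio of one filament
#'
#' Background-normalized two-channel intensity ratio: the mean intensity
#' in a signal band of +/- 4 pixels about the centreline between the two
#' end points, divided by the mean background estimated 8-22 pixels above
#' and below the centreline, computed in each channel; the ratio of the
#' green (binder) normalized intensity to the red (filament) normalized
#' intensity is returned.
#'
#' @param green,red Numeric matrices (rows = y, cols = x), same shape.
#' @param ends 2 x 2 matrix; rows are the two clicked end points
#'   (x, y) in pixel coordinates (the filament is assumed roughly
#'   horizontal; the centreline y is interpolated between the clicks).
#' @param signal_halfwidth Half-width of the signal band, pixels.
#' @param bg_band Background band offsets from the centreline, pixels.
#' @return List with \code{ratio}, \code{green_over_bg},
#'   \code{red_over_bg}, and the pixel index sets used.
#' @export
intensity_ratio <- function(green, red, ends, signal_halfwidth = 4,
                            bg_band = c(8, 22)) {
  stopifnot(all(dim(green) == dim(red)))
  x1 <- round(ends[1, 1]); x2 <- round(ends[2, 1])
  if (x1 > x2) { tmp <- x1; x1 <- x2; x2 <- tmp; ends <- ends[2:1, ] }
  if (x1 < 1 || x2 > ncol(green)) stop("end points outside image")
  xs <- x1:x2
  yc <- stats::approx(ends[, 1], ends[, 2], xout = xs, rule = 2)$y
  sig_idx <- NULL; bg_idx <- NULL
  for (i in seq_along(xs)) {
    ys <- round(yc[i]) + (-signal_halfwidth:signal_halfwidth)
    yb <- round(yc[i]) + c(bg_band[1]:bg_band[2], -(bg_band[1]:bg_band[2]))
    if (any(yb < 1) || any(yb > nrow(green)))
      stop("background band outside image")
    ys <- ys[ys >= 1 & ys <= nrow(green)]
    sig_idx <- rbind(sig_idx, cbind(ys, xs[i]))
    bg_idx <- rbind(bg_idx, cbind(yb, xs[i]))
  }
  g_sig <- mean(green[sig_idx]); g_bg <- mean(green[bg_idx])
  r_sig <- mean(red[sig_idx]); r_bg <- mean(red[bg_idx])
  list(ratio = (g_sig / g_bg) / (r_sig / r_bg),
       green_over_bg = g_sig / g_bg, red_over_bg = r_sig / r_bg,
       signal_pixels = sig_idx, background_pixels = bg_idx)
}

#' Binder coverage fraction of the filaments in an image
#'
#' Binarizes the filament (red) channel to find the filament-positive
#' pixels, binarizes the binder (green) channel within that mask, and
#' returns occupied length / total filament length (pixel counts on the
#' binary masks).  Thresholds default to Otsu's method on each channel
#' and can be overridden.
#'
#' @param green,red Numeric matrices, same shape.
#' @param red_threshold,green_threshold Optional absolute thresholds; by
#'   default Otsu's threshold of each channel (requires the EBImage
#'   package).
#' @return List with \code{coverage}, \code{filament_pixels},
#'   \code{occupied_pixels}, and the thresholds used.
#' @export
coverage_fraction <- function(green, red, red_threshold = NULL,
                              green_threshold = NULL) {
  stopifnot(all(dim(green) == dim(red)))
  otsu_or_stop <- function(img) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("EBImage is needed for automatic Otsu thresholds; ",
           "pass explicit thresholds instead")
    rg <- range(img)
    EBImage::otsu(EBImage::Image((img - rg[1]) / max(rg[2] - rg[1], 1e-12)),
                  range = c(0, 1)) * (rg[2] - rg[1]) + rg[1]
  }
  if (is.null(red_threshold)) red_threshold <- otsu_or_stop(red)
  if (is.null(green_threshold)) green_threshold <- otsu_or_stop(green)
  mask <- red > red_threshold
  total <- sum(mask)
  if (total == 0) stop("no filament pixels above the red threshold")
  occ <- sum(green[mask] > green_threshold)
  list(coverage = occ / total, filament_pixels = total,
       occupied_pixels = occ,
       red_threshold = red_threshold, green_threshold = green_threshold)
}

#' Comet occupancy model
#'
#' Axial occupancy profile of a tip-tracking binder on a growing
#' microtubule end: complete occupancy of the edge sites along the
#' tapered tip region (at the edge-site density, 2 of 14 sites per
#' layer) plus an exponentially decaying occupancy of lattice sites
#' behind the closed-tube boundary, convolved with the imaging PSF.
#'
#' @param edge_occupancy Occupancy of edge sites in the taper, [0, 1].
#' @param decay_length Lattice occupancy decay length behind the
#'   boundary, nm (> 0).
#' @param sigma_psf PSF sigma, nm.
#' @param site_ratio Edge:total site densities per layer,
#'   default \code{c(edge = 2, total = 14)}.
#' @param taper_length Length of the tapered tip region, nm.
#' @param span Half-length of the computed profile, nm.
#' @param pixel Sample spacing, nm.
#' @return List of class \code{"comet_profile"}: \code{positions} (nm;
#'   0 = distal filament end, negative = toward the minus end),
#'   \code{occupancy} (pre-PSF), \code{intensity} (convolved),
#'   \code{peak_offset} (nm behind the distal end; positive = lagging),
#'   \code{degenerate} (flat-profile flag).
#' @export
simulate_comet_profile <- function(edge_occupancy = 1, decay_length = 100,
                                   sigma_psf = 120,
                                   site_ratio = c(edge = 2, total = 14),
                                   taper_length = 96, span = 2000,
                                   pixel = 4) {
  stopifnot(edge_occupancy >= 0, edge_occupancy <= 1, decay_length > 0)
  x <- seq(-span, span, by = pixel)
  dens_edge <- site_ratio[["edge"]] / site_ratio[["total"]]
  dens_lat <- 1 - dens_edge
  occ <- numeric(length(x))
  taper <- x <= 0 & x >= -taper_length
  occ[taper] <- dens_edge * edge_occupancy
  behind <- x < -taper_length
  occ[behind] <- dens_lat * exp((x[behind] + taper_length) / decay_length)
  # Gaussian PSF convolution on the dense grid
  half <- ceiling(4 * sigma_psf / pixel)
  kx <- (-half:half) * pixel
  kern <- exp(-kx^2 / (2 * sigma_psf^2))
  kern <- kern / sum(kern)
  intens <- stats::convolve(occ, rev(kern), type = "open")
  intens <- intens[(half + 1):(half + length(x))]
  # degenerate: uniform occupancy along the occupied domain (no comet);
  # the peak is then reported at the domain midpoint by convention
  occd <- occ[x <= 0]
  degenerate <- (max(occd) - min(occd)) < 1e-12 * max(occ, 1e-300)
  peak <- if (degenerate) span / 2 else -x[which.max(intens)]
  structure(list(positions = x, occupancy = occ, intensity = intens,
                 peak_offset = peak, degenerate = degenerate),
            class = "comet_profile")
}

#' Read / write images as TIFF
#'
#' Thin wrappers over the tiff package for two-channel microscopy images;
#' matrices are stored as 32-bit float TIFF.
#'
#' @param path TIFF file.
#' @return \code{read_image_tiff}: a numeric matrix.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF input")
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname read_image_tiff
#' @param image Numeric matrix.
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF output")
  rg <- range(image)
  scaled <- if (diff(rg) > 0) (image - rg[1]) / diff(rg) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  invisible(path)
}
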