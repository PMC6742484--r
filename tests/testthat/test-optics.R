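test_that("synthetic line scans match the closed-form profile", {
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  sc <- generate_synthetic_linescan(100, sigma_psf = 120, length = 2000,
                                    noise = "none")
  w <- sqrt(100^2 + 120^2)
  expected <- 100 + 1000 * 0.5 * (erf(sc$positions / (120 * sqrt(2))) -
                                  erf((sc$positions - 2000) / (w * sqrt(2))))
  expect_lt(max(abs(sc$intensities - expected) /
                  max(abs(expected))), 1e-6)
  # blunt end: falloff width equals the PSF exactly
  sc0 <- generate_synthetic_linescan(0, sigma_psf = 120, noise = "none")
  exp0 <- 100 + 1000 * 0.5 * (erf(sc0$positions / (120 * sqrt(2))) -
                              erf((sc0$positions - 2500) / (120 * sqrt(2))))
  expect_lt(max(abs(sc0$intensities - exp0)), 1e-6)
  # linearity: doubling the amplitude doubles the signal
  scA <- generate_synthetic_linescan(50, amplitude = 500, background = 0,
                                     noise = "none")
  scB <- generate_synthetic_linescan(50, amplitude = 1000, background = 0,
                                     noise = "none")
  expect_equal(scB$intensities, 2 * scA$intensities, tolerance = 1e-12)
})

test_that("tip fit recovers the generating taper width", {
  sc <- generate_synthetic_linescan(100, sigma_psf = 120, noise = "none")
  ft <- fit_tip_errorfunction(sc, sigma_psf = 120)
  expect_lt(abs(ft$sigma_tip - 100), 2)
  expect_lt(abs(ft$mu - 2500), 30)
  # blunt scan: tip standard deviation near zero
  sc0 <- generate_synthetic_linescan(0, sigma_psf = 120, noise = "none")
  ft0 <- fit_tip_errorfunction(sc0, sigma_psf = 120)
  expect_lt(ft0$sigma_tip, 10)
  # without deconvolution the raw width is reported
  ftr <- fit_tip_errorfunction(sc, sigma_psf = 120, deconvolve = FALSE)
  expect_equal(ftr$sigma_tip, ftr$sigma_fit)
  expect_lt(abs(ftr$sigma_fit - sqrt(100^2 + 120^2)), 3)
})

test_that("tip estimates increase with the true taper under noise", {
  set.seed(60)
  grid <- c(0, 60, 120, 200)
  med <- vapply(grid, function(s) {
    est <- replicate(12, {
      sc <- generate_synthetic_linescan(s, noise = "poisson-gaussian")
      fit_tip_errorfunction(sc, sigma_psf = 120)$sigma_tip
    })
    median(est)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("line-scan alignment orients bright binder ends right", {
  set.seed(61)
  mk <- function(flipit) {
    x <- seq(0, 2496, by = 64)
    fil <- rep(800, length(x))
    bind <- 100 + 500 * (x / max(x))       # bright on the right
    if (flipit) { fil <- rev(fil); bind <- rev(bind) }
    list(filament = list(positions = x, intensities = fil),
         binder = list(positions = x, intensities = bind))
  }
  scans <- c(lapply(1:3, function(i) mk(FALSE)),
             lapply(1:3, function(i) mk(TRUE)))
  avg <- align_and_average_linescans(scans)
  expect_equal(sum(avg$flipped), 3)
  # after orientation, the average binder profile increases to the right
  expect_gt(mean(avg$binder[avg$positions > 1800]),
            mean(avg$binder[avg$positions < 700]))
  # identical symmetric scans average to the input
  sym <- lapply(1:4, function(i) {
    x <- seq(0, 2496, by = 64)
    y <- 500 + 100 * sin(x / 400)
    y <- (y + rev(y)) / 2
    list(filament = list(positions = x, intensities = y),
         binder = list(positions = x, intensities = y))
  })
  avs <- align_and_average_linescans(sym)
  expect_equal(avs$filament, sym[[1]]$filament$intensities,
               tolerance = 1e-9)
  expect_true(all(avs$se_filament < 1e-9))
  expect_error(align_and_average_linescans(sym[1]), "at least 2")
})

test_that("rebinned intensity agrees with a linear-interpolation oracle", {
  set.seed(62)
  mk_len <- function(len) {
    x <- seq(0, len, length.out = 40)
    y <- 200 + 600 * exp(-((x - len / 2) / (len / 4))^2)
    list(filament = list(positions = x, intensities = y),
         binder = list(positions = x, intensities = y))
  }
  scans <- lapply(c(2200, 2500, 2800), mk_len)
  avg <- align_and_average_linescans(scans)
  mean_len <- mean(c(2200, 2500, 2800))
  oracle <- rowMeans(vapply(scans, function(s) {
    x <- s$filament$positions
    approx(x / max(x) * mean_len, s$filament$intensities,
           xout = avg$positions, rule = 2)$y
  }, numeric(length(avg$positions))))
  expect_equal(avg$filament, oracle, tolerance = 1e-9)
  # total intensity is preserved within 1 percent of the oracle
  expect_lt(abs(sum(avg$filament) / sum(oracle) - 1), 0.01)
})

test_that("intensity ratio uses the stated pixel bands", {
  ny <- 60; nx <- 80
  green <- matrix(100, ny, nx); red <- matrix(200, ny, nx)
  ends <- rbind(c(10, 30), c(70, 30))
  # equal channels everywhere: ratio 1
  r0 <- intensity_ratio(green, green, ends)
  expect_equal(r0$ratio, 1)
  # constructed: green signal 3x its background, red 1.5x
  green2 <- green; red2 <- red
  green2[26:34, 10:70] <- 300
  red2[26:34, 10:70] <- 300
  r2 <- intensity_ratio(green2, red2, ends)
  expect_equal(r2$ratio, 2, tolerance = 1e-9)
  # pixel-set membership vs a per-pixel geometric oracle
  sig <- r2$signal_pixels
  expect_true(all(abs(sig[, 1] - 30) <= 4))
  expect_true(all(sig[, 2] >= 10 & sig[, 2] <= 70))
  bg <- r2$background_pixels
  off <- abs(bg[, 1] - 30)
  expect_true(all(off >= 8 & off <= 22))
  # background band falling outside the image errors
  expect_error(intensity_ratio(green, red, rbind(c(10, 5), c(70, 5))),
               "outside")
  # gain invariance: scaling one channel leaves the ratio unchanged
  r3 <- intensity_ratio(green2 * 7.5, red2, ends)
  expect_equal(r3$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("coverage fraction matches the painted ground truth", {
  set.seed(63)
  ny <- 100; nx <- 200
  red <- matrix(rnorm(ny * nx, 50, 5), ny, nx)
  green <- matrix(rnorm(ny * nx, 40, 5), ny, nx)
  # three horizontal filaments; green paints 40% of their length
  rows <- c(20, 50, 80)
  painted <- 0; total <- 0
  for (r in rows) {
    red[r, 10:190] <- 500
    n_pix <- length(10:190)
    n_paint <- round(0.4 * n_pix)
    green[r, 10:(9 + n_paint)] <- 400
    painted <- painted + n_paint; total <- total + n_pix
  }
  cov <- coverage_fraction(green, red, red_threshold = 250,
                           green_threshold = 200)
  expect_equal(cov$coverage, painted / total, tolerance = 0.03)
  # full and empty coverage
  gfull <- green; gfull[red > 250] <- 1000
  expect_equal(coverage_fraction(gfull, red, 250, 200)$coverage, 1)
  gnone <- matrix(0, ny, nx)
  expect_equal(coverage_fraction(gnone, red, 250, 200)$coverage, 0)
  expect_error(coverage_fraction(green, red * 0, 250, 200), "no filament")
  # gain invariance through Otsu rethresholding of the scaled channel
  c1 <- coverage_fraction(green, red)
  c2 <- coverage_fraction(green * 3, red)
  expect_equal(c1$coverage, c2$coverage, tolerance = 1e-9)
})

test_that("comet profile peaks behind the distal end", {
  cp <- simulate_comet_profile()
  expect_false(cp$degenerate)
  expect_gt(cp$peak_offset, 0)
  # numerical profile equals a dense direct-convolution oracle
  x <- cp$positions
  kern_x <- seq(-4 * 120, 4 * 120, by = 4)
  oracle <- vapply(seq_along(x), function(i) {
    xi <- x[i] - kern_x
    occ <- numeric(length(xi))
    occ[xi <= 0 & xi >= -96] <- 2 / 14
    behind <- xi < -96
    occ[behind] <- (12 / 14) * exp((xi[behind] + 96) / 100)
    w <- exp(-kern_x^2 / (2 * 120^2))
    sum(occ * w) / sum(w)
  }, numeric(1))
  expect_lt(max(abs(cp$intensity - oracle)), 1e-8)
})

test_that("uniform occupancy is reported as degenerate", {
  # edge density x occupancy equal to the lattice density with no decay
  cp <- simulate_comet_profile(edge_occupancy = 1, decay_length = Inf,
                               site_ratio = c(edge = 7, total = 14))
  expect_true(cp$degenerate)
  expect_equal(cp$peak_offset, 1000)   # span/2 midpoint convention
})

test_that("TIFF image round trip preserves relative intensities", {
  img <- matrix(runif(600, 0, 500), 20, 30)
  f <- tempfile(fileext = ".tif")
  write_image_tiff(img, f)
  back <- read_image_tiff(f)
  expect_equal(dim(back), dim(img))
  expect_gt(cor(as.numeric(back), as.numeric(img)), 0.999999)
})
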