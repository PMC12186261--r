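test_that("complement and Gaussian window behave as documented", {
  img <- micrograph(matrix(runif(64 * 64), 64, 64), 1)
  # complement twice with no window is the identity
  back <- complement_and_mask(complement_and_mask(img, Inf), Inf)
  expect_equal(back$pixels, img$pixels, tolerance = 1e-15)
  # constant image becomes a radial Gaussian centred on the image
  flat <- micrograph(matrix(0.25, 65, 65), 1)
  cm <- complement_and_mask(flat, 0.25)
  expect_equal(cm$pixels[33, 33], 0.75)
  expect_equal(cm$pixels, t(cm$pixels), tolerance = 1e-12)   # radial symmetry
  expect_true(all(cm$pixels <= 0.75 + 1e-15))
  # windowing suppresses the axis-aligned cross that the non-periodic
  # image boundaries leak into the spectrum (oblique off-bin sinusoid:
  # all its true power sits at 37 degrees, none on the axes)
  n <- 128; x <- 0:(n - 1)
  obl <- 0.5 + 0.4 * outer(0.121 * x, 0.093 * x,
                           function(a, b) sin(2 * pi * (a + b)))
  sp_raw <- apply_bandpass(power_spectrum(micrograph(obl, 1)),
                           bandpass_spec(0.05, 0.4))
  sp_win <- apply_bandpass(power_spectrum(
    complement_and_mask(micrograph(obl, 1), 0.25)), bandpass_spec(0.05, 0.4))
  on_axes <- function(sp) {
    a <- polar_integrate(sp)
    sum(a$power[a$angle %in% c(0, 90, 180, 270)]) / sum(a$power)
  }
  expect_lt(on_axes(sp_win), 0.5 * on_axes(sp_raw))
})

test_that("power spectrum is normalized and locates sinusoid frequencies", {
  n <- 128
  f <- 8 / n                 # cycles per pixel -> um^-1 at 1 um/px
  sinu <- outer(rep(1, n), sin(2 * pi * f * (0:(n - 1))))
  sp <- power_spectrum(micrograph(0.5 + 0.4 * sinu, 1))
  expect_equal(sum(sp$power), 1, tolerance = 1e-12)
  pw <- sp$power
  pw[sp$fy == 0, sp$fx == 0] <- 0                  # drop the mean (DC) term
  pk <- which(pw > 0.1, arr.ind = TRUE)
  expect_equal(nrow(pk), 2)                        # two symmetric peaks
  expect_equal(sort(sp$fx[pk[, 2]]), c(-f, f))
  expect_equal(sp$fy[pk[, 1]], c(0, 0))
})

test_that("bandpass keeps 4-40 um elements and is idempotent", {
  b <- bandpass_spec(0.025, 0.25)
  expect_equal(1 / b$f_high, 4)
  expect_equal(1 / b$f_low, 40)
  img <- micrograph(matrix(runif(128 * 128), 128, 128), 1)
  sp <- power_spectrum(img)
  once <- apply_bandpass(sp, b)
  twice <- apply_bandpass(once, b)
  expect_equal(twice$power, once$power, tolerance = 1e-15)
  r <- sqrt(outer(once$fy^2, once$fx^2, `+`))
  expect_true(all(once$power[r < 0.025 | r > 0.25] == 0))
  # a band squeezed between two achievable bin radii holds no pixel
  expect_error(apply_bandpass(sp, bandpass_spec(1.05 / 128, 1.35 / 128)),
               "empty")
  expect_error(bandpass_spec(0.3, 0.2))
})

test_that("a ring artifact outside the default band is fully removed", {
  # image whose spectrum is a ring at 0.3 um^-1: plane cosines placed on
  # exact DFT bins (Pythagorean components of radius 30/100)
  n <- 100
  x <- 0:(n - 1)
  img <- matrix(0.5, n, n)
  for (k in list(c(30, 0), c(24, 18), c(18, 24), c(0, 30))) {
    img <- img + 0.05 * cos(2 * pi * outer(x * k[2] / n, x * k[1] / n, `+`))
  }
  sp <- apply_bandpass(power_spectrum(micrograph(img, 1)), bandpass_spec())
  r <- sqrt(outer(sp$fy^2, sp$fx^2, `+`))
  expect_true(all(sp$power[r > 0.29] == 0))
  expect_lt(sum(sp$power), 1e-12)  # nothing but DC and the ring was present
})

test_that("polar integration partitions power exactly", {
  img <- micrograph(matrix(runif(96 * 96), 96, 96), 1)
  sp <- apply_bandpass(power_spectrum(img), bandpass_spec())
  aps <- polar_integrate(sp)
  expect_equal(sum(aps$power), sum(sp$power), tolerance = 1e-14)
  expect_true(all(aps$power >= 0))
  expect_equal(aps$angle, 0:359)
  # real image: 180-degree point symmetry of the angular spectrum
  expect_equal(aps$power[aps$angle %in% 1:179],
               aps$power[aps$angle %in% 181:359],
               tolerance = 1e-10)
})

test_that("isotropic spectrum gives a flat profile; a sinusoid concentrates", {
  n <- 256
  sp <- structure(list(power = matrix(0, n, n),
                       fx = sort(fftshift_freqs(n)), fy = sort(fftshift_freqs(n)),
                       pixel_size = 1, band = NULL), class = "spectrum2d")
  r <- sqrt(outer(sp$fy^2, sp$fx^2, `+`))
  sp$power[r >= 0.1 & r <= 0.3] <- 1
  aps <- polar_integrate(sp)
  expect_lt(sd(aps$power) / mean(aps$power), 0.15)  # flat up to discretization
  # two-point spectrum of a zero-mean plane sinusoid on the exact bin
  # (20, 15)/256: angle atan2(15, 20) = 36.87 -> nearest degree 37
  img2 <- 0.2 * outer((0:(n - 1)) * 15 / n, (0:(n - 1)) * 20 / n,
                      function(a, b) sin(2 * pi * (a + b)))
  aps2 <- polar_integrate(power_spectrum(micrograph(img2, 1)))
  top <- sort(aps2$angle[order(aps2$power, decreasing = TRUE)][1:2])
  expect_equal(top, c(37, 217))
})

test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  aps <- polar_integrate(apply_bandpass(
    power_spectrum(micrograph(matrix(runif(64 * 64), 64, 64), 1)),
    bandpass_spec()))
  const <- aps; const$power <- rep(2, 360)
  expect_equal(smooth_angular(const)$power, rep(2, 360), tolerance = 1e-12)
  # a wrapped cubic segment: exact within the segment interior
  poly <- aps; poly$power <- 5 + 0.01 * (0:359) - 2e-5 * (0:359)^2
  sm <- smooth_angular(poly, window = 15, order = 3)
  interior <- 10:350
  expect_equal(sm$power[interior], poly$power[interior], tolerance = 1e-9)
  expect_error(smooth_angular(aps, window = 14), "odd")
  expect_error(smooth_angular(aps, window = 3, order = 3), "odd|greater")
  # smoothing reduces rms deviation from a noiseless truth
  truth <- 1 + 0.5 * cos(2 * (0:359) * pi / 180)
  noisy <- aps; noisy$power <- truth + rnorm(360, 0, 0.1)
  smn <- smooth_angular(noisy)
  expect_lt(sqrt(mean((smn$power - truth)^2)),
            sqrt(mean((noisy$power - truth)^2)))
})

test_that("inverse transform round-trips and removes out-of-band structure", {
  img <- micrograph(matrix(runif(64 * 64), 64, 64), 1)
  rt <- inverse_check(img, band = NULL)
  expect_lt(max(abs(rt$pixels - img$pixels)), 1e-9 * diff(range(img$pixels)))
  # a sinusoid outside the band disappears, one inside survives
  n <- 256; x <- 0:(n - 1)
  lowf <- 1 / 256          # 0.0039 um^-1, below f_low
  inf_ <- 0.125            # inside the band, on a DFT bin
  im2 <- micrograph(0.5 + 0.2 * outer(rep(1, n), sin(2 * pi * lowf * x)) +
                      0.2 * outer(rep(1, n), sin(2 * pi * inf_ * x)), 1)
  filt <- inverse_check(im2, bandpass_spec(0.025, 0.25))
  proj <- colMeans(filt$pixels)
  amp_low <- Mod(fft(proj))[1 + n * lowf] / n * 2
  amp_in <- Mod(fft(proj))[1 + n * inf_] / n * 2
  expect_lt(amp_low, 0.01 * 0.2)
  expect_gt(amp_in, 0.15)
})

test_that("anisotropy index: flat is 0, spike is 1, scaling invariant", {
  base <- polar_integrate(apply_bandpass(
    power_spectrum(micrograph(matrix(runif(64 * 64), 64, 64), 1)),
    bandpass_spec()))
  flat <- base; flat$power <- rep(1, 360)
  expect_equal(anisotropy_index(flat)$anisotropy, 0, tolerance = 1e-12)
  spike <- base; spike$power <- numeric(360); spike$power[78] <- 5
  ai <- anisotropy_index(spike)
  expect_equal(ai$anisotropy, 1)
  expect_equal(ai$preferred_angle, 77 %% 180)
  spike$power <- spike$power * 1e6
  expect_equal(anisotropy_index(spike)$preferred_angle, ai$preferred_angle)
  zero <- base; zero$power <- numeric(360)
  expect_error(anisotropy_index(zero), "zero")
})

test_that("rotating the micrograph by 90 degrees rotates the angular spectrum", {
  img <- simulate_micrograph(micrograph_sim_config(
    width = 256, height = 256, kappa = 4, n_platelets = 80, seed = 5L))
  rot <- micrograph(t(img$pixels)[ncol(img$pixels):1, ], img$pixel_size)
  a1 <- anisotropy_index(micrograph_aps(img, smooth = FALSE))
  a2 <- anisotropy_index(micrograph_aps(rot, smooth = FALSE))
  d <- abs(((a1$preferred_angle + 90) - a2$preferred_angle) %% 180)
  expect_lt(min(d, 180 - d), 5)
})

test_that("anisotropy increases with platelet orientation concentration", {
  ai <- vapply(c(0, 0.5, 1.5, 4, 10), function(k) {
    img <- simulate_micrograph(micrograph_sim_config(
      width = 256, height = 256, kappa = k, n_platelets = 120,
      band_contrast = 0, seed = 21L))
    anisotropy_index(micrograph_aps(img))$anisotropy
  }, numeric(1))
  expect_true(all(diff(ai) > 0))
})

test_that("preferred angle recovers the generating mean within 5 degrees", {
  # enough platelets that orientation-sampling noise is well below the
  # 5-degree recovery tolerance
  for (axis in c(0, 45, 90)) {
    img <- simulate_micrograph(micrograph_sim_config(
      width = 384, height = 384, kappa = 3, n_platelets = 500,
      band_contrast = 0, band_axis = axis, seed = 13L))
    ai <- anisotropy_index(micrograph_aps(img))
    # spectrum peaks perpendicular to the platelet long axis
    want <- (axis + 90) %% 180
    d <- abs(ai$preferred_angle - want) %% 180
    expect_lt(min(d, 180 - d), 5)
  }
})

test_that("micrograph generator: flat limit, band period, determinism", {
  flat <- simulate_micrograph(micrograph_sim_config(
    n_platelets = 0, band_contrast = 0, blur_sigma = 0, noise_sigma = 0))
  expect_equal(diff(range(flat$pixels)), 0)
  bands <- simulate_micrograph(micrograph_sim_config(
    width = 1024, height = 64, n_platelets = 0, noise_sigma = 0,
    blur_sigma = 0, band_contrast = 0.5, band_period = 300, band_axis = 90))
  lag <- acf_first_peak(colMeans(bands$pixels))
  expect_lte(abs(lag - 300), 2)
  a <- simulate_micrograph(micrograph_sim_config(seed = 9L))
  b <- simulate_micrograph(micrograph_sim_config(seed = 9L))
  expect_identical(a$pixels, b$pixels)
  expect_error(micrograph_sim_config(platelet_length = 1e5), "exceeds")
})
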