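#' Configuration for a synthetic bright-field micrograph
#'
#' Emulates the appearance of USW-structured oleogel micrographs: a
#' sinusoidal dark/light band shading (the nodal bands) plus elongated
#' dark platelet silhouettes with a controllable axial von Mises
#' orientation distribution, Gaussian blur, and additive gray-level
#' noise. Pixel values are clamped to `[0, 1]`.
#'
#' @param width,height image size in pixels.
#' @param pixel_size um per pixel (default 1; placeholder for a 5x
#'   objective, exposed here precisely because it is uncertain).
#' @param band_period band spacing in um (default 300, the nodal
#'   half-wavelength spacing).
#' @param band_axis orientation of the band stripes in degrees (default
#'   90: vertical bands, intensity modulated along x). Platelet
#'   orientations are drawn about this axis.
#' @param band_contrast relative shading amplitude in `[0, 1]`.
#' @param n_platelets number of platelets to render (>= 0).
#' @param platelet_length,platelet_width mean lengths/widths (um);
#'   individual sizes are lognormal about these with 20% spread.
#' @param platelet_depth gray-level darkening per platelet.
#' @param kappa axial von Mises concentration of platelet orientations
#'   (0 = uniform).
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param noise_sigma additive Gaussian gray-level noise sd (0 = none).
#' @param seed integer RNG seed.
#' @return A list of class `micrograph_sim_config`.
#' @export
micrograph_sim_config <- function(width = 512, height = 512, pixel_size = 1,
                                  band_period = 300, band_axis = 90,
                                  band_contrast = 0.3, n_platelets = 150,
                                  platelet_length = 20, platelet_width = 4,
                                  platelet_depth = 0.3, kappa = 3,
                                  blur_sigma = 1, noise_sigma = 0.02,
                                  seed = 1L) {
  cfg <- structure(as.list(environment()), class = "micrograph_sim_config")
  stopifnot(width >= 8, height >= 8, pixel_size > 0, band_period > 0,
            band_contrast >= 0, band_contrast <= 1, n_platelets >= 0,
            kappa >= 0, blur_sigma >= 0, noise_sigma >= 0)
  if (platelet_length / pixel_size > max(width, height))
    stop("platelet length exceeds the image extent")
  cfg
}

#' Simulate a bright-field micrograph
#'
#' Background level 0.7 with sinusoidal band shading of the configured
#' period and orientation; platelets are rendered as rotated dark
#' ellipses with long axes sampled from an axial von Mises law about
#' `band_axis`. Reproducible bit-for-bit under the config seed; with
#' `n_platelets = 0`, `band_contrast = 0`, `blur_sigma = 0` and
#' `noise_sigma = 0` the image is exactly flat.
#'
#' @param cfg a [micrograph_sim_config()].
#' @return A [micrograph()]; ground truth is attached as attribute
#'   `truth` (platelet table and the config).
#' @export
simulate_micrograph <- function(cfg) {
  stopifnot(inherits(cfg, "micrograph_sim_config"))
  h <- cfg$height; w <- cfg$width
  xs <- (seq_len(w) - 0.5) * cfg$pixel_size
  ys <- (seq_len(h) - 0.5) * cfg$pixel_size
  # coordinate along the normal to the band stripes
  nrm <- c(cos((cfg$band_axis + 90) * pi / 180),
           sin((cfg$band_axis + 90) * pi / 180))
  U <- outer(ys * nrm[2], xs * nrm[1], `+`)
  img <- 0.7 * (1 + cfg$band_contrast * cos(2 * pi * U / cfg$band_period)) /
    (1 + cfg$band_contrast)

  platelets <- NULL
  if (cfg$n_platelets > 0 || cfg$noise_sigma > 0) {
    img <- with_local_seed(cfg$seed, {
      if (cfg$n_platelets > 0) {
        n <- cfg$n_platelets
        platelets <- data.frame(
          cx = stats::runif(n, 0, w * cfg$pixel_size),
          cy = stats::runif(n, 0, h * cfg$pixel_size),
          len = stats::rlnorm(n, log(cfg$platelet_length), 0.2),
          wid = stats::rlnorm(n, log(cfg$platelet_width), 0.2),
          theta = (cfg$band_axis + 90 / pi * rvmises(n, 0, cfg$kappa)) %% 180)
        for (i in seq_len(cfg$n_platelets))
          img <- draw_platelet(img, platelets[i, ], cfg)
      }
      if (cfg$noise_sigma > 0)
        img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_sigma), h, w)
      img
    })
  }
  if (cfg$blur_sigma > 0) img <- blur_gaussian(img, cfg$blur_sigma)
  img <- pmin(pmax(img, 0), 1)
  out <- micrograph(img, cfg$pixel_size)
  attr(out, "truth") <- list(config = cfg, platelets = platelets)
  out
}

# Darken one elliptical platelet silhouette (units: um -> pixels).
draw_platelet <- function(img, p, cfg) {
  ps <- cfg$pixel_size
  a <- p$len / 2 / ps; b <- p$wid / 2 / ps
  cx <- p$cx / ps; cy <- p$cy / ps
  th <- p$theta * pi / 180
  half <- ceiling(a) + 1
  ix <- max(1, floor(cx - half)):min(ncol(img), ceiling(cx + half))
  iy <- max(1, floor(cy - half)):min(nrow(img), ceiling(cy + half))
  if (!length(ix) || !length(iy)) return(img)
  dx <- outer(rep(1, length(iy)), ix - cx)
  dy <- outer(iy - cy, rep(1, length(ix)))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img[iy, ix] <- img[iy, ix] - cfg$platelet_depth * inside
  img
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution
# on (-pi, pi]; kappa = 0 falls back to the uniform.
rvmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n); i <- 0
  while (i < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- (mu + sign(u3 - 0.5) * acos(f) + pi) %% (2 * pi) - pi
    }
  }
  out
}

# Gaussian blur by circular FFT convolution (periodic boundary; the
# kernel is a few pixels wide so wrap effects are negligible here).
blur_gaussian <- function(m, sigma) {
  h <- nrow(m); w <- ncol(m)
  gy <- stats::dnorm(fft_freq(h, 1) * h, sd = sigma)
  gx <- stats::dnorm(fft_freq(w, 1) * w, sd = sigma)
  k <- outer(gy, gx)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / (h * w)
}
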