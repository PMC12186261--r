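#' Micrograph container
#'
#' A grayscale bright-field micrograph: pixel values in `[0, 1]` (rows =
#' y, columns = x) with a known physical pixel size.
#'
#' @param pixels numeric matrix of finite gray levels.
#' @param pixel_size physical size of one pixel (um, > 0).
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size = 1) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), all(is.finite(pixels)), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px at %.3g um/px (%.0f x %.0f um)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              ncol(x$pixels) * x$pixel_size, nrow(x$pixels) * x$pixel_size))
  invisible(x)
}

#' Complement and Gaussian-window a micrograph
#'
#' First pre-processing step of the FFT orientation pipeline: invert the
#' gray levels about the representable maximum (1 for `[0, 1]` images),
#' then multiply by a centered circular Gaussian window with
#' `sigma = sigma_frac * min(height, width)` pixels. The window
#' suppresses the sharp image edges that otherwise put a bright
#' horizontal/vertical cross through the power spectrum.
#' `sigma_frac = Inf` disables the window.
#'
#' @param img a [micrograph()].
#' @param sigma_frac window sigma as a fraction of the smaller image
#'   dimension (default 0.25).
#' @return A [micrograph()].
#' @export
complement_and_mask <- function(img, sigma_frac = 0.25) {
  stopifnot(inherits(img, "micrograph"))
  px <- 1 - img$pixels
  if (is.finite(sigma_frac)) {
    h <- nrow(px); w <- ncol(px)
    sigma <- sigma_frac * min(h, w)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    r2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
    px <- px * exp(-r2 / (2 * sigma^2))
  }
  micrograph(px, img$pixel_size)
}

# Frequencies of an n-point DFT with sample spacing d, DFT order.
fft_freq <- function(n, d) {
  k <- c(seq.int(0, ceiling(n / 2) - 1), seq.int(-floor(n / 2), -1))
  k / (n * d)
}

# Move zero frequency to the center of a vector or matrix.
fft_shift <- function(x) {
  if (is.matrix(x)) {
    sr <- floor(nrow(x) / 2); sc <- floor(ncol(x) / 2)
    x[c((sr + 1):nrow(x), 1:sr), c((sc + 1):ncol(x), 1:sc)]
  } else {
    s <- floor(length(x) / 2)
    x[c((s + 1):length(x), 1:s)]
  }
}

#' Centered, normalized 2D power spectrum
#'
#' Squared magnitude of the 2D discrete Fourier transform, shifted so
#' zero frequency sits at the center, and normalized to unit total
#' power so angular profiles are comparable across images. Frequency
#' axes (um^-1) follow from the pixel size.
#'
#' @param img a [micrograph()].
#' @return A list of class `spectrum2d`: `power` (matrix, rows = fy,
#'   cols = fx), `fx`, `fy` (um^-1, centered), `pixel_size`, `band`
#'   (NULL until [apply_bandpass()]).
#' @export
power_spectrum <- function(img) {
  stopifnot(inherits(img, "micrograph"))
  P <- Mod(stats::fft(img$pixels))^2
  tot <- sum(P)
  if (tot > 0) P <- P / tot
  structure(list(power = fft_shift(P),
                 fx = sort(fft_freq(ncol(img$pixels), img$pixel_size)),
                 fy = sort(fft_freq(nrow(img$pixels), img$pixel_size)),
                 pixel_size = img$pixel_size, band = NULL),
            class = "spectrum2d")
}

#' Bandpass specification
#'
#' Radial spatial-frequency bounds for the sharp annular bandpass. The
#' default 0.025-0.25 um^-1 keeps structural elements between
#' `1/f_high` = 4 um and `1/f_low` = 40 um, excluding both the
#' low-frequency band shading / windowing artifacts and the ring
#' artifacts at 0.3 um^-1 and beyond.
#'
#' @param f_low,f_high bounds in um^-1, `0 <= f_low < f_high`.
#' @return A list of class `bandpass_spec`.
#' @export
bandpass_spec <- function(f_low = 0.025, f_high = 0.25) {
  stopifnot(f_low >= 0, f_low < f_high)
  structure(list(f_low = f_low, f_high = f_high), class = "bandpass_spec")
}

#' Apply a sharp annular bandpass to a 2D spectrum
#'
#' Binary mask on radial frequency: power is kept iff
#' `f_low <= |f| <= f_high`. Idempotent.
#'
#' @param spec a [power_spectrum()] result.
#' @param band a [bandpass_spec()].
#' @return The filtered `spectrum2d` (with `band` recorded).
#' @export
apply_bandpass <- function(spec, band = bandpass_spec()) {
  stopifnot(inherits(spec, "spectrum2d"), inherits(band, "bandpass_spec"))
  if (band$f_high > 1 / (2 * spec$pixel_size) + 1e-12)
    warning("f_high exceeds the Nyquist frequency of this image")
  r <- sqrt(outer(spec$fy^2, spec$fx^2, `+`))
  keep <- r >= band$f_low & r <= band$f_high
  if (!any(keep)) stop("empty annulus: no frequencies inside the band")
  spec$power <- spec$power * keep
  spec$band <- band
  spec
}

#' Integrate a 2D spectrum over polar angle
#'
#' Each spectrum element is assigned to the integer degree nearest its
#' polar angle about the zero-frequency center (0 degrees = +fx axis,
#' increasing counterclockwise) and powers are summed per degree. The
#' 360 bins exactly partition the pixels, so total in-band power is
#' conserved.
#'
#' @param spec a (typically bandpassed) `spectrum2d`.
#' @return A data frame of class `angular_power_spectrum` with columns
#'   `angle` (0-359) and `power`; attribute `smoothed = FALSE`.
#' @export
polar_integrate <- function(spec) {
  stopifnot(inherits(spec, "spectrum2d"))
  ang <- atan2(outer(spec$fy, rep(1, length(spec$fx))),
               outer(rep(1, length(spec$fy)), spec$fx)) * 180 / pi
  deg <- round(ang) %% 360
  pw <- rowsum(as.vector(spec$power), group = as.vector(deg))
  power <- numeric(360)
  power[as.integer(rownames(pw)) + 1L] <- pw
  out <- data.frame(angle = 0:359, power = power)
  class(out) <- c("angular_power_spectrum", "data.frame")
  attr(out, "smoothed") <- FALSE
  out
}

#' Savitzky-Golay smoothing of an angular power spectrum
#'
#' Polynomial smoothing with wrap-around boundary (the angle axis is
#' circular). Exactly reproduces profiles that are locally polynomial of
#' degree `<= order`.
#'
#' @param aps an [polar_integrate()] result.
#' @param window filter length in degrees (odd, > `order`; default 15).
#' @param order polynomial order (default 3).
#' @return The smoothed `angular_power_spectrum` (`smoothed = TRUE`).
#' @export
smooth_angular <- function(aps, window = 15, order = 3) {
  stopifnot(inherits(aps, "angular_power_spectrum"))
  if (window %% 2 != 1 || window <= order)
    stop("window must be odd and greater than order")
  n <- nrow(aps)
  pad <- (window - 1) / 2
  xp <- c(aps$power[(n - pad + 1):n], aps$power, aps$power[1:pad])
  yp <- signal::sgolayfilt(xp, p = order, n = window)
  aps$power <- yp[(pad + 1):(pad + n)]
  attr(aps, "smoothed") <- TRUE
  aps
}

#' Inverse-transform check of the bandpass
#'
#' Manual verification step: transform the (complemented, windowed)
#' image, zero the out-of-band complex coefficients, and transform back.
#' The returned real-space image contains only in-band structures. With
#' `band = NULL` (all-pass) the round trip reproduces the input to
#' numerical precision.
#'
#' @param img a [micrograph()] (already pre-processed as desired).
#' @param band a [bandpass_spec()], or NULL for all-pass.
#' @return A [micrograph()] with the filtered image.
#' @export
inverse_check <- function(img, band = NULL) {
  stopifnot(inherits(img, "micrograph"))
  F <- stats::fft(img$pixels)
  if (!is.null(band)) {
    stopifnot(inherits(band, "bandpass_spec"))
    fy <- fft_freq(nrow(F), img$pixel_size)
    fx <- fft_freq(ncol(F), img$pixel_size)
    r <- sqrt(outer(fy^2, fx^2, `+`))
    F <- F * (r >= band$f_low & r <= band$f_high)
  }
  out <- Re(stats::fft(F, inverse = TRUE)) / length(F)
  micrograph(out, img$pixel_size)
}

#' Anisotropy summary of an angular power spectrum
#'
#' Axial circular statistics on the doubled angle: the preferred angle is
#' half the power-weighted circular mean of `2 * angle`, and the degree
#' of anisotropy is the resultant length of that statistic — 0 for a
#' flat profile, 1 for a single-degree spike. Both are invariant under
#' power scaling.
#'
#' @param aps an `angular_power_spectrum`.
#' @return A list of class `anisotropy_index`: `preferred_angle` (degrees
#'   in `[0, 180)`), `anisotropy` in `[0, 1]`.
#' @export
anisotropy_index <- function(aps) {
  stopifnot(inherits(aps, "angular_power_spectrum"))
  w <- aps$power
  tot <- sum(w)
  if (tot <= 0) stop("zero spectrum: no power to summarize")
  th <- 2 * aps$angle * pi / 180
  z <- sum(w * exp(1i * th)) / tot
  structure(list(preferred_angle = (Arg(z) * 180 / pi / 2) %% 180,
                 anisotropy = Mod(z)),
            class = "anisotropy_index")
}

#' @export
print.anisotropy_index <- function(x, ...) {
  cat(sprintf("preferred angle %.1f deg, anisotropy %.3f\n",
              x$preferred_angle, x$anisotropy))
  invisible(x)
}

#' Full micrograph orientation pipeline
#'
#' Convenience wrapper chaining [complement_and_mask()],
#' [power_spectrum()], [apply_bandpass()], [polar_integrate()] and
#' [smooth_angular()].
#'
#' @param img a [micrograph()].
#' @param band a [bandpass_spec()].
#' @param sigma_frac Gaussian-window fraction (see
#'   [complement_and_mask()]).
#' @param smooth apply the Savitzky-Golay smoothing step.
#' @param window,order smoothing parameters.
#' @return An `angular_power_spectrum`.
#' @export
micrograph_aps <- function(img, band = bandpass_spec(), sigma_frac = 0.25,
                           smooth = TRUE, window = 15, order = 3) {
  aps <- polar_integrate(apply_bandpass(
    power_spectrum(complement_and_mask(img, sigma_frac)), band))
  if (smooth) aps <- smooth_angular(aps, window, order)
  aps
}
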