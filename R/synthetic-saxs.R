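#' Configuration for a synthetic SAXS pattern
#'
#' Forward model of one reduced 2D scattering image: a low-q power-law
#' background `B q^P`, a Gaussian lamellar ring at `q0` with fwhm
#' `delta_q` and azimuthal modulation, optional broad "Kapton" shoulder
#' in q = 0.04-0.08, periodic detector-gap masks, and optional Poisson
#' counting noise.
#'
#' The azimuthal weight is a 180-degree-periodic von Mises density in the
#' doubled angle, normalized to unit circular mean, so the azimuthally
#' averaged ring amplitude is `peak_amplitude` regardless of `kappa`
#' (platelet orientation is an axis, not a vector). `kappa = 0` gives an
#' isotropic ring.
#'
#' @param q_grid strictly increasing positive q values (1/Angstrom).
#' @param chi_grid azimuthal angles, degrees in `[0, 360)`.
#' @param q0 ring center (1/Angstrom); must lie inside `q_grid`.
#' @param delta_q ring full width at half maximum (1/Angstrom, > 0).
#' @param peak_amplitude azimuthal-mean ring amplitude (counts).
#' @param background_B,background_P power-law prefactor and (negative)
#'   exponent of the low-q background.
#' @param kappa orientation concentration (>= 0; 0 = isotropic).
#' @param chi_pref preferred azimuth of the ring maximum (degrees).
#' @param gap_period,gap_width detector-gap spacing and width (degrees);
#'   gaps are centered on multiples of `gap_period`. `gap_width = 0`
#'   disables masking.
#' @param shoulder_on add the broad spurious shoulder at q = 0.04-0.08.
#' @param noise apply Poisson sampling to the expected counts.
#' @param seed integer RNG seed used when `noise = TRUE`.
#' @return A list of class `saxs_sim_config`.
#' @export
saxs_sim_config <- function(q_grid = seq(0.005, 0.20, length.out = 150),
                            chi_grid = seq(0, 355, by = 5),
                            q0 = 0.1308, delta_q = 0.0045,
                            peak_amplitude = 1000,
                            background_B = 5e-6, background_P = -3.5,
                            kappa = 0, chi_pref = 0,
                            gap_period = 25, gap_width = 10,
                            shoulder_on = FALSE, noise = FALSE, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "saxs_sim_config")
  if (any(q_grid <= 0) || any(diff(q_grid) <= 0))
    stop("q_grid must be strictly increasing and positive")
  if (q0 < min(q_grid) || q0 > max(q_grid)) stop("q0 outside q_grid")
  if (delta_q <= 0) stop("delta_q must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  if (peak_amplitude < 0 || background_B < 0)
    stop("expected intensity would be negative")
  cfg
}

# Axial (180-deg periodic) von Mises weight with unit circular mean:
# g(chi) = exp(kappa cos(2(chi - chi_pref))) / I0(kappa).
vm_weight <- function(chi_deg, kappa, chi_pref) {
  if (kappa == 0) return(rep(1, length(chi_deg)))
  exp(kappa * cos(2 * (chi_deg - chi_pref) * pi / 180)) /
    besselI(kappa, 0, expon.scaled = FALSE)
}

# Detector-gap mask: FALSE strictly within gap_width/2 of any multiple
# of gap_period (open interval, so bins on the gap edge stay valid).
gap_mask <- function(chi_deg, gap_period, gap_width) {
  if (gap_width <= 0) return(rep(TRUE, length(chi_deg)))
  d <- abs(((chi_deg + gap_period / 2) %% gap_period) - gap_period / 2)
  d >= gap_width / 2
}

#' Simulate one SAXS pattern
#'
#' Expected intensity per bin is
#' `B q^P + A exp(-4 ln2 (q - q0)^2 / delta_q^2) g(chi)` (plus the
#' optional shoulder), with `g` the normalized axial von Mises weight.
#' Masked bins are flagged in the pattern mask, never zeroed. With
#' `noise = FALSE` the output equals the closed-form expectation exactly;
#' with `noise = TRUE` each bin is Poisson-sampled, reproducibly under
#' the config seed.
#'
#' @param cfg a [saxs_sim_config()].
#' @return A [scattering_pattern()] whose `meta` carries the ground-truth
#'   config.
#' @export
simulate_saxs_pattern <- function(cfg) {
  stopifnot(inherits(cfg, "saxs_sim_config"))
  mu <- saxs_expected_intensity(cfg)
  if (any(mu < 0)) stop("expected intensity negative; check config")
  if (isTRUE(cfg$noise)) {
    I <- with_local_seed(cfg$seed, {
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    })
  } else I <- mu
  mk <- matrix(gap_mask(cfg$chi_grid, cfg$gap_period, cfg$gap_width),
               length(cfg$q_grid), length(cfg$chi_grid), byrow = TRUE)
  scattering_pattern(I, cfg$q_grid, cfg$chi_grid, mask = mk,
                     meta = list(truth = cfg))
}

# Closed-form expected intensity matrix (q rows x chi columns).
saxs_expected_intensity <- function(cfg) {
  q <- cfg$q_grid
  bg <- cfg$background_B * q^cfg$background_P
  ring_q <- cfg$peak_amplitude *
    exp(-4 * log(2) * (q - cfg$q0)^2 / cfg$delta_q^2)
  if (isTRUE(cfg$shoulder_on)) {
    # broad nuisance bump centred in the 0.04-0.08 window
    amp <- 0.3 * cfg$background_B * 0.06^cfg$background_P
    bg <- bg + amp * exp(-4 * log(2) * (q - 0.06)^2 / 0.02^2)
  }
  g <- vm_weight(cfg$chi_grid, cfg$kappa, cfg$chi_pref)
  outer(bg, rep(1, length(g))) + outer(ring_q, g)
}

# Evaluate an expression with a temporarily-set RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for a synthetic raster scan
#'
#' Defines the spatial layout and band modulation of a simulated
#' scanning-SAXS acquisition: an `nx` x `ny` grid (default 101 x 101) at
#' `step` spacing (default 0.020 mm, i.e. 2 x 2 mm), with a sinusoidal
#' nodal-band profile of period `band_period` (default 0.3 mm — half the
#' 0.65 mm ultrasound wavelength) along the axis normal to the bands.
#'
#' Per point, every modulated parameter follows the contrast-scaled band
#' weight `w = (1 + band_contrast cos(2 pi u / period)) / 2` (`u` =
#' coordinate along `band_axis`): ring amplitude is scaled by `2 w`, the
#' orientation concentration is `kappa_in w` where `kappa_in` reproduces
#' `of_in_band`, and the correlation length interpolates
#' `xi_out_band -> xi_in_band` with `w`, setting the ring width via
#' `delta_q = 2 pi / xi`. At `band_contrast = 1` the in-band targets are
#' attained exactly at band centers; at 0 every map is constant (the
#' stated targets attenuate linearly with contrast). The ground-truth
#' band mask is `cos(2 pi u / period) > 0`, independent of contrast.
#'
#' @param nx,ny grid points per axis (>= 2).
#' @param step grid spacing (mm).
#' @param band_period nodal-band spacing (mm); must exceed `2 step`.
#' @param band_axis `"x"` or `"y"`: the direction *normal* to the bands
#'   (along which intensity is modulated).
#' @param band_contrast relative amplitude modulation in `[0, 1]`.
#' @param of_in_band target Hermans OF at band centers.
#' @param xi_in_band,xi_out_band correlation lengths (Angstrom) at band
#'   centers and between bands.
#' @param seed integer; all per-point noise streams derive from it.
#' @return A list of class `scan_sim_config`.
#' @export
scan_sim_config <- function(nx = 101, ny = 101, step = 0.020,
                            band_period = 0.3, band_axis = "x",
                            band_contrast = 0.5, of_in_band = 0.4,
                            xi_in_band = 1850, xi_out_band = 1460,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "scan_sim_config")
  if (nx < 2 || ny < 2) stop("grid must be at least 2 x 2")
  if (band_contrast < 0 || band_contrast > 1)
    stop("band_contrast must be in [0, 1]")
  if (band_period <= 2 * step)
    stop("band_period must exceed 2 * step (bands unresolvable)")
  if (band_period > (max(nx, ny) - 1) * step)
    stop("grid too small to hold one band period")
  if (!band_axis %in% c("x", "y")) stop("band_axis must be 'x' or 'y'")
  cfg
}

#' Simulate a raster scan with nodal-band structure
#'
#' Builds the per-point ground-truth parameter maps from
#' [scan_sim_config()] and attaches a base pattern config; patterns are
#' realized lazily with [realize_pattern()] (or all at once with
#' `materialize = TRUE`, for small scans). Per-point Poisson streams are
#' derived from the scan seed so patterns are independent and the whole
#' scan is reproducible bit-for-bit.
#'
#' @param scan_cfg a [scan_sim_config()].
#' @param saxs_cfg a [saxs_sim_config()] giving the out-of-band baseline
#'   pattern (its `peak_amplitude`, `kappa`, `delta_q` are modulated per
#'   point; its `chi_pref` is kept — the USW aligns plane normals with
#'   the horizontal axis, chi_pref = 0).
#' @param materialize realize every pattern now (memory-heavy for large
#'   grids).
#' @return A list of class `saxs_scan`: `positions` (data frame `ix`,
#'   `iy`, `x`, `y` in mm), `truth` (per-point `amplitude`, `kappa`,
#'   `delta_q`, `chi_pref`, `band_w`, `in_band`), the two configs,
#'   per-point seeds, and `patterns` (list or NULL).
#' @export
simulate_scan <- function(scan_cfg, saxs_cfg = saxs_sim_config(noise = TRUE),
                          materialize = FALSE) {
  stopifnot(inherits(scan_cfg, "scan_sim_config"),
            inherits(saxs_cfg, "saxs_sim_config"))
  x <- (seq_len(scan_cfg$nx) - 1) * scan_cfg$step
  y <- (seq_len(scan_cfg$ny) - 1) * scan_cfg$step
  pos <- expand.grid(ix = seq_len(scan_cfg$nx), iy = seq_len(scan_cfg$ny))
  pos$x <- x[pos$ix]; pos$y <- y[pos$iy]

  u <- if (scan_cfg$band_axis == "x") pos$x else pos$y
  phase <- 2 * pi * u / scan_cfg$band_period
  w <- (1 + scan_cfg$band_contrast * cos(phase)) / 2
  kappa_in <- if (scan_cfg$of_in_band > 0) kappa_from_of(scan_cfg$of_in_band) else 0
  xi <- scan_cfg$xi_out_band + (scan_cfg$xi_in_band - scan_cfg$xi_out_band) * w
  truth <- data.frame(
    amplitude = saxs_cfg$peak_amplitude * 2 * w,
    kappa = kappa_in * w,
    delta_q = 2 * pi / xi,
    chi_pref = saxs_cfg$chi_pref,
    band_w = w,
    in_band = cos(phase) > 0)

  n <- nrow(pos)
  point_seeds <- with_local_seed(scan_cfg$seed,
                                 sample.int(.Machine$integer.max, n))
  scan <- structure(list(positions = pos, truth = truth,
                         scan_cfg = scan_cfg, saxs_cfg = saxs_cfg,
                         point_seeds = point_seeds, patterns = NULL),
                    class = "saxs_scan")
  if (materialize)
    scan$patterns <- lapply(seq_len(n), function(i) realize_pattern(scan, i))
  scan
}

#' Realize the scattering pattern at one scan point
#'
#' @param scan a [simulate_scan()] result.
#' @param i point index (row of `scan$positions`).
#' @return A [scattering_pattern()] with the point's ground-truth config
#'   and position in `meta`.
#' @export
realize_pattern <- function(scan, i) {
  stopifnot(inherits(scan, "saxs_scan"))
  if (!is.null(scan$patterns)) return(scan$patterns[[i]])
  cfg <- scan$saxs_cfg
  tr <- scan$truth[i, ]
  cfg$peak_amplitude <- tr$amplitude
  cfg$kappa <- tr$kappa
  cfg$delta_q <- tr$delta_q
  cfg$seed <- scan$point_seeds[i]
  p <- simulate_saxs_pattern(cfg)
  p$meta$position_mm <- c(x = scan$positions$x[i], y = scan$positions$y[i])
  p
}

#' @export
print.saxs_scan <- function(x, ...) {
  cat(sprintf("<saxs_scan> %d x %d points, step %.3f mm, band period %.3f mm along %s\n",
              x$scan_cfg$nx, x$scan_cfg$ny, x$scan_cfg$step,
              x$scan_cfg$band_period, x$scan_cfg$band_axis))
  invisible(x)
}

#' Hermans OF of an axial von Mises azimuthal profile
#'
#' Forward map from orientation concentration `kappa` (about chi = 0) to
#' the OF that [hermans_of()] would report for a dense noiseless
#' profile; computed by fine-grid quadrature of the sin-weighted
#' integrals. Strictly increasing in `kappa`, from 0 (isotropic) towards
#' 1.
#'
#' @param kappa concentration (>= 0).
#' @param n quadrature grid size on `[0, 90]` degrees.
#' @return OF value.
#' @export
of_from_kappa <- function(kappa, n = 2001) {
  chi <- seq(0, 90, length.out = n)
  x <- chi * pi / 180
  I <- exp(kappa * cos(2 * x))
  cos2 <- trapz(x, I * sin(x) * cos(x)^2) / trapz(x, I * sin(x))
  (3 * cos2 - 1) / 2
}

#' @rdname of_from_kappa
#' @param of target OF in `(0, 1)`; inverted by root finding.
#' @export
kappa_from_of <- function(of, n = 2001) {
  stopifnot(of > 0, of < 1)
  stats::uniroot(function(k) of_from_kappa(k, n) - of,
                 c(1e-6, 500), tol = 1e-8)$root
}
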