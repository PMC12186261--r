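#' Scattering pattern on a (q, chi) grid
#'
#' Container for one scan point's reduced 2D scattering image: intensity
#' (counts) on a grid of scattering-vector magnitude `q` (rows, in inverse
#' Angstrom) by azimuthal angle `chi` (columns, degrees in `[0, 360)`),
#' plus a per-bin validity mask (`TRUE` = valid; detector gaps are
#' `FALSE`) and acquisition metadata.
#'
#' Masked bins are carried through, never zeroed: every downstream
#' statistic excludes them explicitly.
#'
#' @param intensity numeric matrix, `length(q)` x `length(chi)`, counts.
#'   Must be non-negative on valid bins.
#' @param q strictly increasing positive numeric vector (1/Angstrom).
#' @param chi strictly increasing numeric vector of azimuthal angles in
#'   degrees, spanning less than one full turn plus one step.
#' @param mask logical matrix of the same shape as `intensity`
#'   (`TRUE` = valid bin). Defaults to all-valid.
#' @param meta named list of metadata (e.g. `energy_keV`,
#'   `detector_distance_m`, `position_mm`).
#' @return An object of class `scattering_pattern`.
#' @export
scattering_pattern <- function(intensity, q, chi, mask = NULL, meta = list()) {
  intensity <- as.matrix(intensity)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  mask <- as.matrix(mask)
  obj <- structure(
    list(intensity = intensity, q = as.numeric(q), chi = as.numeric(chi),
         mask = mask, meta = meta),
    class = "scattering_pattern")
  validate_pattern(obj)
  obj
}

validate_pattern <- function(p, id = NULL) {
  where <- if (is.null(id)) "" else sprintf(" (point %s)", id)
  if (!is.matrix(p$intensity) || !is.numeric(p$intensity))
    stop("intensity must be a numeric matrix", where)
  if (nrow(p$intensity) != length(p$q))
    stop("intensity rows must match length(q)", where)
  if (ncol(p$intensity) != length(p$chi))
    stop("intensity columns must match length(chi)", where)
  if (!all(dim(p$mask) == dim(p$intensity)))
    stop("mask shape must match intensity", where)
  if (any(p$q <= 0) || any(diff(p$q) <= 0))
    stop("q grid must be strictly increasing and positive", where)
  if (any(diff(p$chi) <= 0))
    stop("chi grid must be strictly increasing", where)
  step <- if (length(p$chi) > 1) stats::median(diff(p$chi)) else 360
  if (diff(range(p$chi)) >= 360 + step)
    stop("chi grid spans more than a full turn", where)
  bad <- p$intensity[p$mask]
  if (any(!is.finite(bad)) || any(bad < 0))
    stop("intensity must be finite and non-negative on valid bins", where)
  invisible(p)
}

#' @export
print.scattering_pattern <- function(x, ...) {
  cat(sprintf("<scattering_pattern> %d q-bins [%.4g, %.4g] 1/A x %d chi-bins; %.1f%% masked\n",
              length(x$q), min(x$q), max(x$q), length(x$chi),
              100 * mean(!x$mask)))
  invisible(x)
}

#' Radial (azimuthally averaged) intensity profile
#'
#' Averages the pattern over azimuthal angle chi, per q bin, using valid
#' bins only. A q row with no valid bin yields `NA` (flagged, not zero).
#'
#' @param pattern a [scattering_pattern()].
#' @return A data frame of class `radial_profile` with columns `q`, `I`
#'   (mean counts per valid bin) and `n_valid` (bins contributing).
#' @export
radial_average <- function(pattern) {
  validate_pattern(pattern)
  n_valid <- rowSums(pattern$mask)
  Im <- pattern$intensity
  Im[!pattern$mask] <- NA_real_
  I <- rowMeans(Im, na.rm = TRUE)
  I[n_valid == 0] <- NA_real_
  structure(data.frame(q = pattern$q, I = I, n_valid = n_valid),
            class = c("radial_profile", "data.frame"))
}

#' Azimuthal intensity profile over a q band
#'
#' Averages the pattern over the q band (default 0.11-0.15 1/Angstrom,
#' bracketing the lamellar reflection near q = 0.13) to obtain intensity
#' versus azimuthal angle chi. Bin validity is propagated: a chi bin with
#' no valid (q, chi) cell in the band is marked invalid.
#'
#' @param pattern a [scattering_pattern()].
#' @param q_band numeric length-2 interval (1/Angstrom).
#' @return A data frame of class `azimuthal_profile` with columns `chi`,
#'   `I` and logical `valid`.
#' @export
azimuthal_profile <- function(pattern, q_band = c(0.11, 0.15)) {
  validate_pattern(pattern)
  sel <- pattern$q >= q_band[1] & pattern$q <= q_band[2]
  if (!any(sel)) stop("q_band does not overlap the pattern's q grid")
  Im <- pattern$intensity[sel, , drop = FALSE]
  Mm <- pattern$mask[sel, , drop = FALSE]
  Im[!Mm] <- NA_real_
  n <- colSums(Mm)
  I <- colMeans(Im, na.rm = TRUE)
  I[n == 0] <- NA_real_
  structure(data.frame(chi = pattern$chi, I = I, valid = n > 0),
            class = c("azimuthal_profile", "data.frame"))
}

#' Circular boxcar smoothing of an azimuthal profile
#'
#' Normalized moving average with wrap-around boundary, matching the
#' kernel-size-30 convolution used to make azimuthal intensity
#' distributions interpretable. Invalid bins are excluded from each
#' window's mean and stay invalid in the output. With an all-valid
#' profile the total intensity is conserved exactly.
#'
#' @param profile an [azimuthal_profile()].
#' @param kernel_size window length in bins (default 30).
#' @return A smoothed `azimuthal_profile`.
#' @export
smooth_azimuthal <- function(profile, kernel_size = 30) {
  stopifnot(inherits(profile, "azimuthal_profile"))
  n <- nrow(profile)
  k <- as.integer(kernel_size)
  if (k < 1) stop("kernel_size must be >= 1")
  if (k > n) stop("kernel wider than profile")
  if (k == 1) return(profile)
  # window offsets centered on the bin; even k leans one bin forward
  off <- seq.int(-((k - 1) %/% 2), k %/% 2)
  v <- ifelse(profile$valid, profile$I, NA_real_)
  out <- numeric(n)
  cnt <- numeric(n)
  for (d in off) {
    vd <- v[((seq_len(n) - 1 + d) %% n) + 1]
    ok <- !is.na(vd)
    out[ok] <- out[ok] + vd[ok]
    cnt <- cnt + ok
  }
  sm <- ifelse(cnt > 0, out / cnt, NA_real_)
  sm[!profile$valid] <- NA_real_
  structure(data.frame(chi = profile$chi, I = sm, valid = profile$valid),
            class = c("azimuthal_profile", "data.frame"))
}
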