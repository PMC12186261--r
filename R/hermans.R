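#' Hermans orientation factor from an azimuthal profile
#'
#' Computes the orientation factor (OF)
#' \deqn{f_2 = (3\langle\cos^2\chi\rangle - 1)/2}
#' with the sin-weighted moment
#' \deqn{\langle\cos^2\chi\rangle =
#'   \int_0^{\pi/2} I(\chi)\sin\chi\cos^2\chi\,d\chi \Big/
#'   \int_0^{\pi/2} I(\chi)\sin\chi\,d\chi}
#' evaluated by trapezoidal quadrature on the profile folded to
#' `[0, 90]` degrees. OF ranges from -0.5 (plane normal perpendicular to
#' the director), through 0 (isotropic), to 1 (parallel). The director is
#' chi = 0, the horizontal scan axis.
#'
#' Full-circle data are folded by averaging the four axis-symmetric bins
#' chi, 180-chi, 180+chi, 360-chi (platelet orientation is an axis, not a
#' vector). Masked bins are dropped, never interpolated.
#'
#' Degenerate limit: when all intensity sits in the chi = 0 bin, both
#' sin-weighted integrals vanish. The implementation then falls back to
#' the plain intensity-weighted mean of cos^2(chi), which is the limit of
#' the sin-weighted ratio for a distribution concentrating at 0 and gives
#' OF = 1 as required.
#'
#' @param profile an [azimuthal_profile()] (any chi span up to a full
#'   circle), or a data frame with columns `chi`, `I` and optionally
#'   `valid`.
#' @return A list of class `orientation_factor`: `of`, `cos2_mean`,
#'   `n_valid_bins`.
#' @export
hermans_of <- function(profile) {
  chi <- profile$chi
  I <- profile$I
  valid <- if (!is.null(profile$valid)) profile$valid & !is.na(I) else !is.na(I)
  chi <- chi[valid]; I <- I[valid]
  if (length(chi) == 0) stop("all bins masked")
  if (any(I < 0)) stop("negative intensities in azimuthal profile")

  f <- fold_chi(chi, I)
  if (nrow(f) < 2) stop("fewer than 2 valid bins after folding to [0, 90]")

  x <- f$chi * pi / 180
  w_den <- f$I * sin(x)
  w_num <- w_den * cos(x)^2
  den <- trapz(x, w_den)
  num <- trapz(x, w_num)
  tot <- trapz(x, f$I)
  if (tot <= 0) stop("profile carries no intensity")
  cos2 <- if (den > 1e-12 * tot) num / den else
    sum(f$I * cos(x)^2) / sum(f$I)
  of <- (3 * cos2 - 1) / 2
  structure(list(of = of, cos2_mean = cos2, n_valid_bins = nrow(f)),
            class = "orientation_factor")
}

#' @export
print.orientation_factor <- function(x, ...) {
  cat(sprintf("Hermans OF = %.4f  (<cos2 chi> = %.4f, %d folded bins)\n",
              x$of, x$cos2_mean, x$n_valid_bins))
  invisible(x)
}

# Fold full-circle azimuthal data onto [0, 90] by axis symmetry:
# chi, 180-chi, 180+chi and 360-chi are equivalent. Bins landing on the
# same folded angle (within 1e-9 deg) are averaged.
fold_chi <- function(chi, I) {
  cf <- chi %% 180
  cf <- ifelse(cf > 90, 180 - cf, cf)
  key <- round(cf / 1e-9)
  agg <- rowsum(cbind(I, 1), group = key)
  ang <- as.numeric(rownames(agg)) * 1e-9
  o <- order(ang)
  data.frame(chi = ang[o], I = (agg[, 1] / agg[, 2])[o])
}

# Trapezoidal quadrature on a (possibly nonuniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
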