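#' Low-q power-law (Porod regime) fit
#'
#' Fits `I(q) = B q^P` by exact least squares of `log I` on `log q` over
#' the low-q fit range (default 0.005-0.05 1/Angstrom, the linear region
#' of the double-logarithmic radial plot). The exponent magnitude |P|
#' between 3 and 4 indicates scattering from fractally rough surfaces,
#' with surface fractal dimension `D_s = 6 - |P|`.
#'
#' Non-positive intensities in the range are excluded with a warning; the
#' fit errors if fewer than 5 usable points remain.
#'
#' @param profile a [radial_average()] result.
#' @param fit_range numeric length-2 q interval (1/Angstrom).
#' @return A list of class `power_law_fit`: `B`, `P` (signed slope),
#'   `abs_P`, `D_s`, `fit_range`, `residual` (rms log residual), `n`.
#' @export
fit_power_law <- function(profile, fit_range = c(0.005, 0.05)) {
  sel <- profile$q >= fit_range[1] & profile$q <= fit_range[2] & !is.na(profile$I)
  q <- profile$q[sel]; I <- profile$I[sel]
  pos <- I > 0
  if (any(!pos)) {
    warning(sprintf("%d non-positive intensities excluded from power-law fit",
                    sum(!pos)))
    q <- q[pos]; I <- I[pos]
  }
  if (length(q) < 5) stop("fewer than 5 positive points in fit range")
  fit <- stats::lm(log(I) ~ log(q))
  P <- unname(stats::coef(fit)[2])
  B <- exp(unname(stats::coef(fit)[1]))
  structure(list(B = B, P = P, abs_P = abs(P), D_s = 6 - abs(P),
                 fit_range = fit_range,
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(q)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("I(q) = B q^P: B = %.4g, P = %.3f (|P| = %.3f, D_s = %.3f); rms log-residual %.3g (n = %d)\n",
              x$B, x$P, x$abs_P, x$D_s, x$residual, x$n))
  invisible(x)
}
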