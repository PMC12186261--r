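#' Fit the main lamellar diffraction peak
#'
#' Least-squares fit of a Gaussian plus linear baseline,
#' `I(q) = a exp(-(q - mu)^2 / (2 sigma^2)) + c0 + c1 q`,
#' inside a q window (default 0.10-0.16 1/Angstrom, bracketing the
#' monoglyceride lamellar reflection). Initial values come from the
#' discrete argmax and the background-subtracted second moment. The full
#' width at half maximum is `delta_q = 2 sqrt(2 ln 2) sigma`; the
#' interplanar distance follows Bragg's law `d = 2 pi / q_peak` and the
#' correlation length the Scherrer relation `xi = 2 pi / delta_q`
#' (both in Angstrom; divide by 10 for nm).
#'
#' @param profile a [radial_average()] result (columns `q`, `I`).
#' @param window numeric length-2 fit window (1/Angstrom).
#' @return A list of class `peak_fit`: `q_peak`, `delta_q`, `amplitude`,
#'   `baseline` (intercept, slope), `d`, `xi`, `fit_window`, `converged`,
#'   and `diagnostics` when the fit is flagged.
#' @export
fit_main_peak <- function(profile, window = c(0.10, 0.16)) {
  sel <- profile$q >= window[1] & profile$q <= window[2] & !is.na(profile$I)
  q <- profile$q[sel]; I <- profile$I[sel]
  if (length(q) < 6) stop("fewer than 6 valid points in the fit window")

  i0 <- which.max(I)
  if (i0 == 1L || i0 == length(q))
    return(failed_peak_fit(window, "no interior local maximum in window"))
  mu0 <- q[i0]
  n <- length(q)
  c1_0 <- (I[n] - I[1]) / (q[n] - q[1])
  c0_0 <- I[1] - c1_0 * q[1]
  resid0 <- pmax(I - (c0_0 + c1_0 * q), 0)
  a0 <- max(resid0)
  sig0 <- sqrt(sum(resid0 * (q - mu0)^2) / max(sum(resid0), .Machine$double.eps))
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- diff(window) / 10

  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ a * exp(-(q - mu)^2 / (2 * sig^2)) + c0 + c1 * q,
      start = list(a = a0, mu = mu0, sig = sig0, c0 = c0_0, c1 = c1_0),
      lower = c(a = 0, mu = window[1], sig = 1e-8, c0 = -Inf, c1 = -Inf),
      upper = c(a = Inf, mu = window[2], sig = diff(window), c0 = Inf, c1 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(failed_peak_fit(window, conditionMessage(fit)))

  cf <- stats::coef(fit)
  delta_q <- 2 * sqrt(2 * log(2)) * cf[["sig"]]
  at_bound <- cf[["mu"]] <= window[1] + 1e-12 || cf[["mu"]] >= window[2] - 1e-12 ||
    delta_q >= diff(window) * (1 - 1e-9)
  structure(list(
    q_peak = cf[["mu"]], delta_q = delta_q, amplitude = cf[["a"]],
    baseline = c(intercept = cf[["c0"]], slope = cf[["c1"]]),
    d = 2 * pi / cf[["mu"]], xi = 2 * pi / delta_q,
    fit_window = window, converged = !at_bound,
    diagnostics = if (at_bound) "estimate at window bound" else NULL),
    class = "peak_fit")
}

failed_peak_fit <- function(window, msg) {
  structure(list(q_peak = NA_real_, delta_q = NA_real_, amplitude = NA_real_,
                 baseline = c(intercept = NA_real_, slope = NA_real_),
                 d = NA_real_, xi = NA_real_, fit_window = window,
                 converged = FALSE, diagnostics = msg),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  if (!x$converged && is.na(x$q_peak)) {
    cat("<peak_fit> failed:", x$diagnostics, "\n"); return(invisible(x))
  }
  cat(sprintf("q_peak = %.4f 1/A (d = %.2f A = %.2f nm); fwhm = %.5f 1/A (xi = %.0f A)%s\n",
              x$q_peak, x$d, x$d / 10, x$delta_q, x$xi,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Percent change in correlation length between two peak widths
#'
#' The Scherrer correlation length is inversely proportional to the peak
#' fwhm, so the relative change in xi between two samples is
#' `100 (delta_q_a / delta_q_b - 1)` — independent of the unit convention
#' used for xi itself.
#'
#' @param delta_q_a,delta_q_b peak fwhm values (same units, > 0);
#'   `delta_q_b` belongs to the sample whose xi is in the numerator.
#' @return Percent change of correlation length (numeric, signed).
#' @export
scherrer_ratio <- function(delta_q_a, delta_q_b) {
  if (any(c(delta_q_a, delta_q_b) <= 0)) stop("peak widths must be > 0")
  100 * (delta_q_a / delta_q_b - 1)
}
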