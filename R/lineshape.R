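#' Pseudo-Voigt peak profile
#'
#' Evaluates a mixed Gaussian-Lorentzian lineshape on a chemical-shift grid.
#' The two shape terms share the centre `x0` and the width parameter `lw`,
#' and are mixed by the Gaussian fraction `a`:
#'
#' \deqn{y(x) = h \left[ a\, e^{-(x-x_0)^2 / (2\,lw^2)}
#'   + (1-a) \frac{1}{1 + ((x-x_0)/lw)^2} \right]}
#'
#' `lw` acts as the Gaussian standard deviation and as the Lorentzian
#' half-width at half maximum; both terms equal 1 at the apex, so the peak
#' height is exactly `h` for any mixing fraction.  The full width at half
#' maximum of the mixed profile is not analytic in `lw`; use
#' [peak_fwhm()] to obtain it numerically.
#'
#' @param x numeric vector, chemical-shift grid (ppm).
#' @param x0 peak centre (ppm).
#' @param h apex height (intensity units).
#' @param lw width parameter (ppm); must be positive.
#' @param a Gaussian fraction, in `[0, 1]`.
#' @return numeric vector of intensities, same length as `x`.
#' @examples
#' x <- seq(-0.05, 0.05, length.out = 401)
#' y <- pseudo_voigt(x, x0 = 0, h = 10, lw = 0.004, a = 0.5)
#' max(y) # 10 at the apex
#' @export
pseudo_voigt <- function(x, x0, h, lw, a) {
  if (!is.numeric(lw) || length(lw) != 1L || !is.finite(lw) || lw <= 0) {
    stop("'lw' must be a single positive number, got ", format(lw))
  }
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0 || a > 1) {
    stop("'a' (Gaussian fraction) must lie in [0, 1], got ", format(a))
  }
  d <- (x - x0) / lw
  h * (a * exp(-d^2 / 2) + (1 - a) / (1 + d^2))
}

#' Full width at half maximum of a pseudo-Voigt peak
#'
#' Solves numerically for the half-height width of the mixed profile.  For
#' `a = 1` this equals the Gaussian FWHM `2 sqrt(2 log 2) lw`; for `a = 0`
#' the Lorentzian FWHM `2 lw`.
#'
#' @param lw width parameter (ppm).
#' @param a Gaussian fraction in `[0, 1]`.
#' @return FWHM in ppm.
#' @export
peak_fwhm <- function(lw, a) {
  if (lw <= 0) stop("'lw' must be positive")
  if (a < 0 || a > 1) stop("'a' must lie in [0, 1]")
  g <- function(d) a * exp(-d^2 / 2) + (1 - a) / (1 + d^2) - 0.5
  # half-width lies between the Lorentzian (1) and Gaussian (1.1774) values
  2 * lw * stats::uniroot(g, c(0.5, 2), tol = 1e-12)$root
}

#' Analytic area of one fitted signal
#'
#' Each component peak of a signal integrates to
#' `h (a lw sqrt(2 pi) + (1 - a) pi lw)`; with component heights
#' `h = I w_i` and weights summing to one, the signal area is
#' `I lw (a sqrt(2 pi) + (1 - a) pi)`.
#'
#' @param I total signal intensity.
#' @param lw width parameter (ppm).
#' @param a Gaussian fraction.
#' @return area in intensity x ppm units.
#' @export
signal_area <- function(I, lw, a) {
  I * lw * (a * sqrt(2 * pi) + (1 - a) * pi)
}
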