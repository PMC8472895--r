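## Two-flux Kubelka-Munk model: closed-form forward solution and inversion.
##
## Conventions: all coefficients in cm^-1, thickness in cm; R_d and T_d are
## dimensionless fractions. The model is per-wavelength independent, so every
## function is vectorised over wavelength.
##
## The K/S <-> (mu_a, mu_s) bridge is the standard one for a slab with
## anisotropy g:
##   K = 2 mu_a,   S = (3 (1 - g) mu_s - mu_a) / 4
## and its inverse
##   mu_a = K / 2, mu_s = (4 S + mu_a) / (3 (1 - g)).

.Y_TOL <- 1e-9  # below this, y = sqrt(x^2-1) is treated as the K = 0 limit

#' Kubelka-Munk auxiliary variables
#'
#' Computes the dimensionless auxiliaries of the two-flux inversion,
#' \deqn{x = \frac{1 - T_d^2 + R_d^2}{2 R_d}, \qquad y = \sqrt{x^2 - 1}.}
#' A physically realisable passive measurement always gives \eqn{x \ge 1};
#' \eqn{x = 1} (hence \eqn{y = 0}) is the non-absorbing limit
#' \eqn{R_d + T_d = 1}.
#'
#' @param rd diffuse reflectance fraction(s), in (0, 1)
#' @param td diffuse transmittance fraction(s), in [0, 1)
#' @param tol tolerance below 1 accepted for x before the pair is declared
#'   an invalid measurement (absorbs rounding noise); such x are clamped to 1
#' @return list with numeric components \code{x} and \code{y}
#' @export
#'
#' @examples
#' kmAuxiliaries(0.3, 0.7)   # non-absorbing limit: x = 1, y = 0
kmAuxiliaries <- function(rd, td, tol = 1e-9) {
  stopifnot(length(rd) == length(td))
  if (any(!is.finite(rd)) || any(rd <= 0) || any(rd >= 1))
    stop("rd must lie strictly in (0, 1)")
  if (any(!is.finite(td)) || any(td < 0) || any(td >= 1))
    stop("td must lie in [0, 1)")
  x <- (1 - td^2 + rd^2) / (2 * rd)
  bad <- x < 1 - tol
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(paste0("invalid measurement: rd = %g, td = %g give x = %g",
                        " < 1 (rd + td exceeds 1 beyond tolerance)"),
                 rd[i], td[i], x[i]))
  }
  x <- pmax(x, 1)
  list(x = x, y = sqrt(x^2 - 1))
}

#' Forward two-flux model: slab reflectance and transmittance
#'
#' Closed-form solution of the two-flux (Kubelka-Munk) equations for a slab
#' of thickness \eqn{t}: with \eqn{a = (S + K)/S} and
#' \eqn{b = \sqrt{a^2 - 1}},
#' \deqn{R_d = \frac{\sinh(bSt)}{a\sinh(bSt) + b\cosh(bSt)}, \qquad
#'       T_d = \frac{b}{a\sinh(bSt) + b\cosh(bSt)}.}
#' The flux coefficients are obtained from the transport coefficients as
#' \eqn{K = 2\mu_a}, \eqn{S = (3(1-g)\mu_s - \mu_a)/4}. This is the exact
#' inverse of [kmInvert()], and serves as the reference the Monte Carlo
#' simulator is validated against.
#'
#' In the non-absorbing limit \eqn{\mu_a = 0} the formulas reduce to
#' \eqn{R_d = St/(1 + St)}, \eqn{T_d = 1/(1 + St)}, so \eqn{R_d + T_d = 1}.
#'
#' @param props an [OpticalProperties-class], or a numeric vector of
#'   absorption coefficients (cm^-1) when \code{muS} is given
#' @param thicknessT slab thickness, cm
#' @param muS,g scattering coefficient(s) (cm^-1) and anisotropy, used only
#'   when \code{props} is numeric
#' @return list with numeric components \code{rd} and \code{td}
#' @export
#'
#' @examples
#' kmForward(OpticalProperties(muA = 6.09, muS = 128.02, g = 0.9),
#'           thicknessT = 0.05)
kmForward <- function(props, thicknessT = 0.05, muS = NULL, g = 0.9) {
  if (is(props, "OpticalProperties")) {
    mua <- muA(props); mus <- muS(props); g <- anisotropy(props)
  } else {
    mua <- as.numeric(props); mus <- as.numeric(muS)
  }
  stopifnot(length(mua) == length(mus), abs(g) < 1, thicknessT > 0,
            all(mua >= 0), all(mus > 0))
  K <- 2 * mua
  S <- (3 * (1 - g) * mus - mua) / 4
  if (any(S <= 0))
    stop("conversion-domain error: mu_a too large relative to (1 - g) mu_s ",
         "(implied S <= 0)")
  a <- (S + K) / S
  b <- sqrt(pmax(a^2 - 1, 0))
  sh <- sinh(b * S * thicknessT)
  ch <- cosh(b * S * thicknessT)
  den <- a * sh + b * ch
  rd <- ifelse(K > 0, sh / den, S * thicknessT / (1 + S * thicknessT))
  td <- ifelse(K > 0, b / den, 1 / (1 + S * thicknessT))
  list(rd = rd, td = td)
}

#' Invert a measured spectrum with the Kubelka-Munk equations
#'
#' Per-wavelength inversion of diffuse reflectance/transmittance into flux
#' coefficients and transport-domain optical properties:
#' \deqn{S = \frac{1}{y\,t}\,\ln\!\frac{1 - R_d (x - y)}{T_d}, \qquad
#'       K = S (x - 1),}
#' \deqn{\mu_a = K/2, \qquad \mu_s = \frac{4S + \mu_a}{3 (1 - g)},}
#' with \eqn{x, y} from [kmAuxiliaries()]. The scattering-coefficient
#' expression \eqn{S} is the logarithmic closed form of the two-flux
#' solution; the round trip \code{kmInvert(kmForward(...))} is exact to
#' floating-point precision.
#'
#' Degenerate non-absorbing input (\eqn{R_d + T_d = 1}, hence \eqn{y = 0})
#' raises an error rather than silently returning \eqn{\mu_a = 0}; use the
#' \eqn{K = 0} limit of [kmForward()] directly in that regime.
#'
#' @param spectrum a [MeasuredSpectrum-class]
#' @param g anisotropy factor, |g| < 1; defaults to 0.9, the accepted value
#'   for strongly forward-scattering UHMWPE
#' @param n refractive index recorded on the returned properties (not used
#'   by the inversion itself)
#' @return a [KMInversion-class]
#' @export
#'
#' @examples
#' fw <- kmForward(OpticalProperties(muA = 1.67, muS = 29.72), 0.05)
#' sp <- MeasuredSpectrum(630, fw$rd, fw$td, thickness = 0.05, label = "P-30")
#' muA(opticalProperties(kmInvert(sp)))  # recovers 1.67
kmInvert <- function(spectrum, g = 0.9, n = 1.54) {
  stopifnot(is(spectrum, "MeasuredSpectrum"), abs(g) < 1)
  validObject(spectrum)
  rd <- spectrum@rd; td <- spectrum@td; t <- spectrum@thickness
  aux <- kmAuxiliaries(rd, td)
  if (any(aux$y < .Y_TOL)) {
    i <- which(aux$y < .Y_TOL)[1L]
    stop(sprintf(paste0("degenerate inversion at wavelength %g nm: ",
                        "rd + td = 1 within tolerance (y ~ 0); the sample ",
                        "is non-absorbing there -- use the K = 0 limit"),
                 spectrum@wavelength[i]))
  }
  arg <- (1 - rd * (aux$x - aux$y)) / td
  if (any(arg <= 0)) {
    i <- which(arg <= 0)[1L]
    stop(sprintf(paste0("invalid measurement at wavelength %g nm: ",
                        "log argument (1 - rd (x - y)) / td = %g <= 0"),
                 spectrum@wavelength[i], arg[i]))
  }
  s <- log(arg) / (aux$y * t)
  k <- s * (aux$x - 1)
  mua <- k / 2
  mus <- (4 * s + mua) / (3 * (1 - g))
  if (any(!is.finite(s)) || any(s <= 0) || any(mus < 0) || any(mua < 0))
    stop("inversion produced non-finite or negative coefficients")
  new("KMInversion",
      spectrum = spectrum,
      coefficients = KMCoefficients(spectrum@wavelength, s, k, aux$x, aux$y),
      properties = OpticalProperties(muA = mua, muS = mus, g = g, n = n,
                                     wavelength = spectrum@wavelength))
}
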