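## S4 class definitions, validity rules and constructors.

#' MeasuredSpectrum: wavelength-indexed diffuse reflectance/transmittance
#'
#' Container for an integrating-sphere measurement of a single slab sample:
#' diffuse reflectance \eqn{R_d} and diffuse transmittance \eqn{T_d} as
#' dimensionless fractions on a strictly increasing wavelength grid, plus the
#' sample thickness (cm) and a free-text dose label such as \code{"P-30"}.
#'
#' Validity requires, at every wavelength, \eqn{0 < R_d < 1},
#' \eqn{0 < T_d < 1} and \eqn{R_d + T_d \le 1} (energy cannot be created by
#' a passive sample), and a positive thickness.
#'
#' @slot wavelength numeric, nm, strictly increasing
#' @slot rd numeric, diffuse reflectance fraction per wavelength
#' @slot td numeric, diffuse transmittance fraction per wavelength
#' @slot thickness numeric(1), slab thickness in cm
#' @slot label character(1), sample/dose label
#' @slot metadata list, free-form provenance (e.g. generator ground truth)
#'
#' @aliases MeasuredSpectrum-class
#' @export MeasuredSpectrum
#' @exportClass MeasuredSpectrum
#'
#' @examples
#' sp <- MeasuredSpectrum(wavelength = c(630, 700, 800),
#'                        rd = c(0.18, 0.18, 0.18),
#'                        td = c(0.42, 0.39, 0.38),
#'                        thickness = 0.05, label = "P-0")
#' wavelengths(sp)
setClass("MeasuredSpectrum",
  representation(wavelength = "numeric", rd = "numeric", td = "numeric",
                 thickness = "numeric", label = "character",
                 metadata = "list"),
  prototype(thickness = 0.05, label = "sample", metadata = list()))

setValidity("MeasuredSpectrum", function(object) {
  msg <- character()
  n <- length(object@wavelength)
  if (length(object@rd) != n || length(object@td) != n)
    msg <- c(msg, "wavelength, rd and td must have equal length")
  if (n == 0L)
    msg <- c(msg, "spectrum must contain at least one wavelength")
  if (n > 1L && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(object@rd) == n && length(object@td) == n && n > 0L) {
    if (any(!is.finite(object@rd)) || any(!is.finite(object@td)))
      msg <- c(msg, "rd and td must be finite")
    else {
      if (any(object@rd <= 0 | object@rd >= 1))
        msg <- c(msg, "rd must satisfy 0 < rd < 1 at every wavelength")
      if (any(object@td <= 0 | object@td >= 1))
        msg <- c(msg, "td must satisfy 0 < td < 1 at every wavelength")
      if (any(object@rd + object@td > 1))
        msg <- c(msg, "rd + td must not exceed 1 (passive sample)")
    }
  }
  if (length(object@thickness) != 1L || !is.finite(object@thickness) ||
      object@thickness <= 0)
    msg <- c(msg, "thickness must be a single positive number (cm)")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' @param wavelength,rd,td,thickness,label,metadata see slot descriptions
#' @rdname MeasuredSpectrum-class
MeasuredSpectrum <- function(wavelength, rd, td, thickness = 0.05,
                             label = "sample", metadata = list()) {
  new("MeasuredSpectrum",
      wavelength = as.numeric(wavelength), rd = as.numeric(rd),
      td = as.numeric(td), thickness = as.numeric(thickness),
      label = as.character(label), metadata = metadata)
}

#' KMCoefficients: per-wavelength two-flux coefficients
#'
#' Kubelka-Munk flux coefficients obtained by inversion: the scattering flux
#' coefficient \eqn{S} and absorption flux coefficient \eqn{K} (both
#' cm\eqn{^{-1}}), together with the dimensionless auxiliaries
#' \eqn{x = (1 - T_d^2 + R_d^2) / (2 R_d)} and \eqn{y = \sqrt{x^2 - 1}}.
#'
#' @slot wavelength numeric, nm
#' @slot s numeric, scattering flux coefficient S, cm^-1, > 0
#' @slot k numeric, absorption flux coefficient K, cm^-1, >= 0
#' @slot x numeric, auxiliary, >= 1
#' @slot y numeric, auxiliary, sqrt(x^2 - 1) >= 0
#'
#' @aliases KMCoefficients-class
#' @export KMCoefficients
#' @exportClass KMCoefficients
setClass("KMCoefficients",
  representation(wavelength = "numeric", s = "numeric", k = "numeric",
                 x = "numeric", y = "numeric"))

setValidity("KMCoefficients", function(object) {
  msg <- character()
  n <- length(object@wavelength)
  if (any(lengths(list(object@s, object@k, object@x, object@y)) != n))
    msg <- c(msg, "all slots must have equal length")
  else if (n > 0L) {
    if (any(object@s <= 0)) msg <- c(msg, "s must be > 0")
    if (any(object@k < 0)) msg <- c(msg, "k must be >= 0")
    if (any(object@x < 1)) msg <- c(msg, "x must be >= 1")
    if (any(abs(object@y - sqrt(pmax(object@x^2 - 1, 0))) > 1e-8))
      msg <- c(msg, "y must equal sqrt(x^2 - 1)")
  }
  if (length(msg)) msg else TRUE
})

#' @param wavelength,s,k,x,y see slot descriptions
#' @rdname KMCoefficients-class
KMCoefficients <- function(wavelength, s, k, x, y) {
  new("KMCoefficients", wavelength = as.numeric(wavelength),
      s = as.numeric(s), k = as.numeric(k),
      x = as.numeric(x), y = as.numeric(y))
}

#' OpticalProperties: transport-domain optical coefficients
#'
#' Per-wavelength absorption coefficient \eqn{\mu_a} and scattering
#' coefficient \eqn{\mu_s} (cm\eqn{^{-1}}), with the scattering anisotropy
#' factor \eqn{g} (mean cosine of the single-scattering deflection; 0.9 for
#' UHMWPE, which scatters strongly forward) and the slab refractive index
#' \eqn{n} used for Fresnel boundary physics in the Monte Carlo simulator.
#'
#' @slot wavelength numeric, nm (NA when the properties are not spectral)
#' @slot muA numeric, absorption coefficient, cm^-1, >= 0
#' @slot muS numeric, scattering coefficient, cm^-1, >= 0
#' @slot g numeric(1), anisotropy factor, -1 < g < 1
#' @slot n numeric(1), refractive index, >= 1
#'
#' @aliases OpticalProperties-class
#' @export OpticalProperties
#' @exportClass OpticalProperties
#'
#' @examples
#' op <- OpticalProperties(muA = 6.09, muS = 128.02)
#' transportAlbedo(op)
setClass("OpticalProperties",
  representation(wavelength = "numeric", muA = "numeric", muS = "numeric",
                 g = "numeric", n = "numeric"),
  prototype(g = 0.9, n = 1.54))

setValidity("OpticalProperties", function(object) {
  msg <- character()
  nw <- length(object@muA)
  if (length(object@muS) != nw || length(object@wavelength) != nw)
    msg <- c(msg, "wavelength, muA and muS must have equal length")
  else if (nw > 0L) {
    if (any(!is.finite(object@muA)) || any(object@muA < 0))
      msg <- c(msg, "muA must be finite and >= 0")
    if (any(!is.finite(object@muS)) || any(object@muS < 0))
      msg <- c(msg, "muS must be finite and >= 0")
  }
  if (length(object@g) != 1L || !is.finite(object@g) || abs(object@g) >= 1)
    msg <- c(msg, "g must be a single value with |g| < 1")
  if (length(object@n) != 1L || !is.finite(object@n) || object@n < 1)
    msg <- c(msg, "n must be a single value >= 1")
  if (length(msg)) msg else TRUE
})

#' @param muA,muS,g,n,wavelength see slot descriptions
#' @rdname OpticalProperties-class
OpticalProperties <- function(muA, muS, g = 0.9, n = 1.54,
                              wavelength = rep(NA_real_, length(muA))) {
  new("OpticalProperties", wavelength = as.numeric(wavelength),
      muA = as.numeric(muA), muS = as.numeric(muS),
      g = as.numeric(g), n = as.numeric(n))
}

#' KMInversion: result of a Kubelka-Munk inversion
#'
#' Bundles the input spectrum with the inverted flux coefficients and
#' transport-domain optical properties. Use [kmCoefficients()] and
#' [opticalProperties()] to access the parts, or \code{as.data.frame()} for
#' a flat per-wavelength table.
#'
#' @slot spectrum the inverted [MeasuredSpectrum-class]
#' @slot coefficients the [KMCoefficients-class]
#' @slot properties the [OpticalProperties-class]
#'
#' @aliases KMInversion-class
#' @exportClass KMInversion
setClass("KMInversion",
  representation(spectrum = "MeasuredSpectrum",
                 coefficients = "KMCoefficients",
                 properties = "OpticalProperties"))

#' SlabGeometry: a single homogeneous slab and its surroundings
#'
#' Geometry for the Monte Carlo simulator: slab thickness (cm) and the
#' refractive indices of the slab and of the ambient media above (beam side)
#' and below it. Matched boundaries (all indices equal) disable Fresnel
#' reflection entirely.
#'
#' @slot thickness numeric(1), cm, > 0
#' @slot nSlab numeric(1), slab refractive index, >= 1
#' @slot nAbove numeric(1), ambient index on the illuminated side, >= 1
#' @slot nBelow numeric(1), ambient index on the transmission side, >= 1
#'
#' @aliases SlabGeometry-class
#' @export SlabGeometry
#' @exportClass SlabGeometry
#'
#' @examples
#' SlabGeometry()                 # 0.05 cm UHMWPE sheet in air
#' SlabGeometry(matched = TRUE)   # index-matched boundaries
setClass("SlabGeometry",
  representation(thickness = "numeric", nSlab = "numeric",
                 nAbove = "numeric", nBelow = "numeric"),
  prototype(thickness = 0.05, nSlab = 1.54, nAbove = 1, nBelow = 1))

setValidity("SlabGeometry", function(object) {
  msg <- character()
  ok1 <- function(v) length(v) == 1L && is.finite(v)
  if (!ok1(object@thickness) || object@thickness <= 0)
    msg <- c(msg, "thickness must be a single positive number (cm)")
  for (nm in c("nSlab", "nAbove", "nBelow"))
    if (!ok1(slot(object, nm)) || slot(object, nm) < 1)
      msg <- c(msg, paste(nm, "must be a single value >= 1"))
  if (length(msg)) msg else TRUE
})

#' @param thickness,nSlab,nAbove,nBelow see slot descriptions
#' @param matched logical; if TRUE, set all refractive indices to 1
#'   (no Fresnel reflection anywhere)
#' @rdname SlabGeometry-class
SlabGeometry <- function(thickness = 0.05, nSlab = 1.54, nAbove = 1,
                         nBelow = 1, matched = FALSE) {
  if (matched) nSlab <- nAbove <- nBelow <- 1
  new("SlabGeometry", thickness = as.numeric(thickness),
      nSlab = as.numeric(nSlab), nAbove = as.numeric(nAbove),
      nBelow = as.numeric(nBelow))
}

#' MCConfig: Monte Carlo run controls
#'
#' Photon budget, scoring grids, random seed and Russian-roulette settings
#' for [mcRun()]. Defaults follow the classic MCML conventions for a thin
#' sheet: 200 radial bins of 50 um, 30 polar bins on \eqn{[0, \pi/2]},
#' 48 azimuthal bins on \eqn{[0, 2\pi]}; the depth grid defaults to 100 bins
#' spanning the slab (dz resolved at run time as thickness/nz when NA).
#'
#' @slot nPhotons numeric(1), photon packets to launch, >= 1
#' @slot dr numeric(1), radial bin width, cm
#' @slot nr integer(1), number of radial bins (last bin collects overflow)
#' @slot dz numeric(1), depth bin width, cm, or NA to use thickness/nz
#' @slot nz integer(1), number of depth bins; nz*dz must cover the slab
#' @slot nTheta integer(1), polar-angle bins on [0, pi/2]
#' @slot nPhi integer(1), azimuthal bins on [0, 2*pi)
#' @slot seed numeric(1), RNG seed (non-negative integer-valued)
#' @slot rouletteThreshold numeric(1), packet weight below which roulette
#'   is played, in (0, 1)
#' @slot rouletteSurvival numeric(1), survival probability, in (0, 1)
#'
#' @aliases MCConfig-class
#' @export MCConfig
#' @exportClass MCConfig
setClass("MCConfig",
  representation(nPhotons = "numeric", dr = "numeric", nr = "integer",
                 dz = "numeric", nz = "integer", nTheta = "integer",
                 nPhi = "integer", seed = "numeric",
                 rouletteThreshold = "numeric", rouletteSurvival = "numeric"),
  prototype(nPhotons = 1e6, dr = 50e-4, nr = 200L, dz = NA_real_, nz = 100L,
            nTheta = 30L, nPhi = 48L, seed = 1,
            rouletteThreshold = 1e-4, rouletteSurvival = 0.1))

setValidity("MCConfig", function(object) {
  msg <- character()
  if (object@nPhotons < 1) msg <- c(msg, "nPhotons must be >= 1")
  if (!is.na(object@dz) && object@dz <= 0) msg <- c(msg, "dz must be > 0")
  if (object@dr <= 0) msg <- c(msg, "dr must be > 0")
  for (nm in c("nr", "nz", "nTheta", "nPhi"))
    if (slot(object, nm) < 1L) msg <- c(msg, paste(nm, "must be >= 1"))
  if (object@seed < 0 || object@seed != floor(object@seed))
    msg <- c(msg, "seed must be a non-negative integer value")
  if (object@rouletteThreshold <= 0 || object@rouletteThreshold >= 1)
    msg <- c(msg, "rouletteThreshold must be in (0, 1)")
  if (object@rouletteSurvival <= 0 || object@rouletteSurvival >= 1)
    msg <- c(msg, "rouletteSurvival must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param nPhotons,dr,nr,dz,nz,nTheta,nPhi,seed see slot descriptions
#' @param rouletteThreshold,rouletteSurvival see slot descriptions
#' @rdname MCConfig-class
MCConfig <- function(nPhotons = 1e6, dr = 50e-4, nr = 200, dz = NA, nz = 100,
                     nTheta = 30, nPhi = 48, seed = 1,
                     rouletteThreshold = 1e-4, rouletteSurvival = 0.1) {
  new("MCConfig", nPhotons = as.numeric(nPhotons), dr = as.numeric(dr),
      nr = as.integer(nr), dz = as.numeric(dz), nz = as.integer(nz),
      nTheta = as.integer(nTheta), nPhi = as.integer(nPhi),
      seed = as.numeric(seed),
      rouletteThreshold = as.numeric(rouletteThreshold),
      rouletteSurvival = as.numeric(rouletteSurvival))
}

#' MCResult: scored output of a Monte Carlo slab run
#'
#' Weight-bookkeeping output of [mcRun()]. All totals are fractions of the
#' launched weight; \code{aRZ} holds the absorbed weight fraction per
#' cylindrical (r, z) bin (rows = radial bins, columns = depth bins); the
#' angular matrices hold escaping weight fractions per (theta, phi) exit bin.
#' Validity enforces exact weight conservation,
#' \code{rSpecular + rDiffuse + tDiffuse + aTotal == 1} to 1e-9.
#'
#' @slot aRZ numeric matrix nr x nz, absorbed weight fraction per bin
#' @slot rSpecular numeric(1), specular reflection fraction
#' @slot rDiffuse numeric(1), total diffuse reflectance fraction
#' @slot tDiffuse numeric(1), total diffuse transmittance fraction
#' @slot aTotal numeric(1), total absorbed fraction
#' @slot rAngular numeric matrix nTheta x nPhi, reflected exit weight
#' @slot tAngular numeric matrix nTheta x nPhi, transmitted exit weight
#' @slot nPhotonsRun numeric(1), photons actually launched
#' @slot seedUsed numeric(1), RNG seed used
#' @slot config the [MCConfig-class] of the run (dz resolved)
#' @slot geometry the [SlabGeometry-class] of the run
#' @slot properties the [OpticalProperties-class] of the run
#'
#' @aliases MCResult-class
#' @exportClass MCResult
setClass("MCResult",
  representation(aRZ = "matrix", rSpecular = "numeric", rDiffuse = "numeric",
                 tDiffuse = "numeric", aTotal = "numeric",
                 rAngular = "matrix", tAngular = "matrix",
                 nPhotonsRun = "numeric", seedUsed = "numeric",
                 config = "MCConfig", geometry = "SlabGeometry",
                 properties = "OpticalProperties"))

setValidity("MCResult", function(object) {
  msg <- character()
  tot <- object@rSpecular + object@rDiffuse + object@tDiffuse + object@aTotal
  if (abs(tot - 1) > 1e-9)
    msg <- c(msg, sprintf("weight not conserved: totals sum to %.12f", tot))
  fr <- c(object@rSpecular, object@rDiffuse, object@tDiffuse, object@aTotal)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "all totals must be fractions in [0, 1]")
  if (any(object@aRZ < 0))
    msg <- c(msg, "aRZ entries must be >= 0")
  if (length(msg)) msg else TRUE
})
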