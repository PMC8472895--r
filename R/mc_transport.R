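## Monte Carlo photon-packet transport: R surface over the C++ engine.

#' Sample an exponential free path
#'
#' \eqn{s = -\ln(\xi)/\mu_t} for \eqn{\xi \in (0, 1]}: the free path between
#' interactions in a medium of total attenuation \eqn{\mu_t}.
#'
#' @param xi uniform deviates on (0, 1]; \eqn{\xi = 0} is rejected (the
#'   caller must resample rather than evaluate \eqn{\ln 0})
#' @param muT total attenuation coefficient, cm^-1, > 0
#' @return path length(s), cm
#' @export
#' @examples
#' sampleStep(exp(-1), 134.11)  # exactly one mean free path
sampleStep <- function(xi, muT) {
  stopifnot(muT > 0)
  if (any(xi <= 0) || any(xi > 1))
    stop("xi must lie in (0, 1]; resample instead of passing 0")
  -log(xi) / muT
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function:
#' for \eqn{g = 0}, \eqn{\cos\theta = 2\xi - 1} (isotropic); otherwise
#' \deqn{\cos\theta = \frac{1}{2g}\left[1 + g^2 -
#'   \left(\frac{1 - g^2}{1 - g + 2 g \xi}\right)^2\right].}
#' The mean of \eqn{\cos\theta} equals \eqn{g}.
#'
#' @param xi uniform deviates on [0, 1)
#' @param g anisotropy factor, |g| < 1
#' @return deflection cosine(s) in [-1, 1]
#' @export
#' @examples
#' sampleHG(0.75, g = 0)  # 0.5
sampleHG <- function(xi, g) {
  stopifnot(abs(g) < 1, all(xi >= 0), all(xi <= 1))
  .sample_hg_cpp(as.numeric(xi), g)
}

#' Unpolarised Fresnel reflectance
#'
#' Average of the s- and p-polarised Fresnel reflection coefficients for a
#' ray crossing from index \code{nI} to \code{nT} with incidence cosine
#' \code{cosI}. Beyond the critical angle (when \code{nI > nT}) the
#' reflectance is 1 (total internal reflection); matched indices give 0.
#'
#' @param nI,nT refractive indices of the incidence and transmission media
#' @param cosI cosine of the incidence angle, in [0, 1]
#' @return reflectance fraction in [0, 1]
#' @export
#' @examples
#' fresnelReflectance(1, 1.54, 1)  # ~0.0452 at normal incidence
fresnelReflectance <- function(nI, nT, cosI) {
  stopifnot(nI >= 1, nT >= 1, cosI >= 0, cosI <= 1)
  .fresnel_cpp(nI, nT, cosI)
}

.resolve_dz <- function(config, geometry) {
  if (is.na(config@dz)) config@dz <- geometry@thickness / config@nz
  if (config@nz * config@dz < geometry@thickness - 1e-12)
    stop("config error: depth grid (nz * dz) does not cover the slab")
  config
}

#' Run the Monte Carlo slab simulation
#'
#' Simulates photon-packet transport through a single homogeneous turbid
#' slab under an infinitely narrow, normally incident beam, MCML-style:
#' specular reflection at launch (Fresnel at normal incidence), exponential
#' free paths, fractional absorption deposits \eqn{\Delta w = w \mu_a/\mu_t}
#' scored on a cylindrical (r, z) grid, Henyey-Greenstein scattering,
#' Fresnel internal reflection at both faces, and energy-conserving Russian
#' roulette (a packet below the threshold weight survives with probability
#' \code{rouletteSurvival} keeping its weight, otherwise its residual weight
#' is deposited locally as absorbed). Weight bookkeeping therefore closes
#' exactly: specular + diffuse reflectance + transmittance + absorbed = 1.
#'
#' The run is fully deterministic given the config (including its seed):
#' identical inputs give a bit-identical [MCResult-class].
#'
#' @param props an [OpticalProperties-class] of length 1 (one wavelength)
#' @param geometry a [SlabGeometry-class]; defaults to a 0.05 cm slab of
#'   index 1.54 in air
#' @param config an [MCConfig-class]
#' @return an [MCResult-class]
#' @export
#'
#' @examples
#' res <- mcRun(OpticalProperties(muA = 6.09, muS = 128.02),
#'              SlabGeometry(matched = TRUE),
#'              MCConfig(nPhotons = 1e4, seed = 7))
#' res
mcRun <- function(props, geometry = SlabGeometry(), config = MCConfig()) {
  stopifnot(is(props, "OpticalProperties"), is(geometry, "SlabGeometry"),
            is(config, "MCConfig"))
  validObject(props); validObject(geometry); validObject(config)
  if (length(muA(props)) != 1L)
    stop("mcRun simulates one wavelength at a time; props must have length 1")
  if (muA(props) + muS(props) <= 0)
    stop("mu_t = mu_a + mu_s must be positive")
  config <- .resolve_dz(config, geometry)
  raw <- .mc_slab_cpp(muA(props), muS(props), anisotropy(props),
                      geometry@thickness, geometry@nSlab, geometry@nAbove,
                      geometry@nBelow,
                      config@nPhotons, config@dr, config@nr, config@dz,
                      config@nz, config@nTheta, config@nPhi, config@seed,
                      config@rouletteThreshold, config@rouletteSurvival)
  new("MCResult",
      aRZ = raw$a_rz, rSpecular = raw$r_specular,
      rDiffuse = raw$r_diffuse, tDiffuse = raw$t_diffuse,
      aTotal = raw$a_total, rAngular = raw$r_angular,
      tAngular = raw$t_angular, nPhotonsRun = raw$n_photons,
      seedUsed = raw$seed, config = config, geometry = geometry,
      properties = props)
}

#' Absorption map and iso-level penetration summary
#'
#' Returns the simulated absorption grid \eqn{A(r, z)} in one of three
#' normalizations, plus an iso-level summary of how deep absorption
#' extends: the deepest depth-bin centre at which any radial bin still
#' exceeds \code{isoLevel} times the grid's peak value. Radial bin centres
#' are at \eqn{(i_r + 1/2)\,dr}; the outermost bin is an overflow bin.
#'
#' Normalizations:
#' \describe{
#'   \item{\code{fraction}}{absorbed weight fraction of the launched
#'     photons per bin (sums to the run's total absorbed fraction).}
#'   \item{\code{per_area}}{absorbed photons per unit area,
#'     photons cm\eqn{^{-2}}: bin weight times the photon count divided by
#'     the annular bin area \eqn{2\pi (i_r + 1/2) dr^2}.}
#'   \item{\code{per_volume}}{absorbed photons per unit volume,
#'     photons cm\eqn{^{-3}} (\code{per_area} further divided by dz).}
#' }
#'
#' @param result an [MCResult-class]
#' @param normalization one of "fraction", "per_area", "per_volume"
#' @param isoLevel iso-level as a fraction of the peak grid value, in (0, 1)
#' @return list with \code{grid} (long data frame \code{r_cm, z_cm, value}),
#'   \code{normalization}, \code{isoLevel}, \code{peak},
#'   \code{isoDepthCm} (NA for an all-zero map) and \code{total} (the run's
#'   absorbed fraction)
#' @export
absorptionMap <- function(result,
                          normalization = c("fraction", "per_area",
                                            "per_volume"),
                          isoLevel = 0.01) {
  stopifnot(is(result, "MCResult"), isoLevel > 0, isoLevel < 1)
  normalization <- match.arg(normalization)
  cfg <- result@config
  a <- result@aRZ
  nr <- nrow(a); nz <- ncol(a)
  r_centres <- (seq_len(nr) - 0.5) * cfg@dr
  z_centres <- (seq_len(nz) - 0.5) * cfg@dz
  if (normalization != "fraction") {
    area <- 2 * pi * (seq_len(nr) - 0.5) * cfg@dr^2
    a <- a * result@nPhotonsRun / area
    if (normalization == "per_volume") a <- a / cfg@dz
  }
  grid <- data.frame(r_cm = rep(r_centres, times = nz),
                     z_cm = rep(z_centres, each = nr),
                     value = as.vector(a))
  peak <- max(a)
  iso_depth <- NA_real_
  if (peak > 0) {
    above <- which(a >= isoLevel * peak, arr.ind = TRUE)
    iso_depth <- max(z_centres[above[, 2]])
  }
  list(grid = grid, normalization = normalization, isoLevel = isoLevel,
       peak = peak, isoDepthCm = iso_depth, total = result@aTotal)
}

#' Validate the Monte Carlo simulator against the two-flux closed form
#'
#' Runs [mcRun()] and compares its total diffuse reflectance, transmittance
#' and absorbance against the forward two-flux model [kmForward()] at the
#' same optical properties (with \eqn{A = 1 - R_d - T_d}). The default
#' geometry is index-matched because the two-flux closed form contains no
#' boundary reflections; pass an unmatched [SlabGeometry-class] to quantify
#' the boundary effect instead. Only the diffuse (non-specular) reflectance
#' enters the comparison.
#'
#' @param props an [OpticalProperties-class] of length 1
#' @param geometry a [SlabGeometry-class]; default matched boundaries
#' @param config an [MCConfig-class]
#' @param threshold pass/fail threshold on the relative difference
#' @return data frame with one row per quantity (R, T, A) and columns
#'   \code{quantity, mc, twoflux, rel_diff, pass}, with the
#'   [MCResult-class] attached as attribute \code{"result"}
#' @export
#'
#' @examples
#' validateAgainstTwoFlux(OpticalProperties(muA = 6.09, muS = 128.02),
#'                        config = MCConfig(nPhotons = 2e4, seed = 1))
validateAgainstTwoFlux <- function(props,
                                   geometry = SlabGeometry(
                                     thickness = 0.05, matched = TRUE),
                                   config = MCConfig(),
                                   threshold = 0.05) {
  res <- mcRun(props, geometry, config)
  ref <- kmForward(props, thicknessT = geometry@thickness)
  ref_a <- 1 - ref$rd - ref$td
  mc <- c(R = res@rDiffuse, T = res@tDiffuse, A = res@aTotal)
  tf <- c(R = ref$rd, T = ref$td, A = ref_a)
  rel <- abs(mc - tf) / tf
  out <- data.frame(quantity = names(mc), mc = unname(mc),
                    twoflux = unname(tf), rel_diff = unname(rel),
                    pass = unname(rel <= threshold))
  attr(out, "result") <- res
  out
}
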