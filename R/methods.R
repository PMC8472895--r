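## Accessor and show methods.

#' @rdname uhmwpeOptics-generics
setMethod("wavelengths", "MeasuredSpectrum", function(object) object@wavelength)
#' @rdname uhmwpeOptics-generics
setMethod("reflectance", "MeasuredSpectrum", function(object) object@rd)
#' @rdname uhmwpeOptics-generics
setMethod("transmittance", "MeasuredSpectrum", function(object) object@td)
#' @rdname uhmwpeOptics-generics
setMethod("thickness", "MeasuredSpectrum", function(object) object@thickness)
#' @rdname uhmwpeOptics-generics
setMethod("doseLabel", "MeasuredSpectrum", function(object) object@label)
#' @rdname uhmwpeOptics-generics
setMethod("spectrumMetadata", "MeasuredSpectrum", function(object) object@metadata)

#' @rdname uhmwpeOptics-generics
setMethod("wavelengths", "KMCoefficients", function(object) object@wavelength)
#' @rdname uhmwpeOptics-generics
setMethod("wavelengths", "OpticalProperties", function(object) object@wavelength)
#' @rdname uhmwpeOptics-generics
setMethod("muA", "OpticalProperties", function(object) object@muA)
#' @rdname uhmwpeOptics-generics
setMethod("muS", "OpticalProperties", function(object) object@muS)
#' @rdname uhmwpeOptics-generics
setMethod("anisotropy", "OpticalProperties", function(object) object@g)
#' @rdname uhmwpeOptics-generics
setMethod("refractiveIndex", "OpticalProperties", function(object) object@n)

#' @rdname uhmwpeOptics-generics
setMethod("kmCoefficients", "KMInversion", function(object) object@coefficients)
#' @rdname uhmwpeOptics-generics
setMethod("opticalProperties", "KMInversion", function(object) object@properties)
#' @rdname uhmwpeOptics-generics
setMethod("thickness", "SlabGeometry", function(object) object@thickness)

setMethod("show", "MeasuredSpectrum", function(object) {
  wl <- object@wavelength
  cat("MeasuredSpectrum '", object@label, "': ", length(wl),
      " wavelengths [", min(wl), ", ", max(wl), "] nm, thickness ",
      object@thickness, " cm\n", sep = "")
  cat("  rd in [", signif(min(object@rd), 4), ", ", signif(max(object@rd), 4),
      "], td in [", signif(min(object@td), 4), ", ",
      signif(max(object@td), 4), "]\n", sep = "")
})

setMethod("show", "OpticalProperties", function(object) {
  cat("OpticalProperties: ", length(object@muA), " wavelength(s), g = ",
      object@g, ", n = ", object@n, "\n", sep = "")
  cat("  muA in [", signif(min(object@muA), 4), ", ",
      signif(max(object@muA), 4), "] cm^-1; muS in [",
      signif(min(object@muS), 4), ", ", signif(max(object@muS), 4),
      "] cm^-1\n", sep = "")
})

setMethod("show", "KMInversion", function(object) {
  cat("KMInversion of '", object@spectrum@label, "' (",
      length(object@spectrum@wavelength), " wavelengths)\n", sep = "")
  show(object@properties)
})

setMethod("show", "SlabGeometry", function(object) {
  cat("SlabGeometry: thickness ", object@thickness, " cm; n = ",
      object@nAbove, " / ", object@nSlab, " / ", object@nBelow,
      " (above/slab/below)\n", sep = "")
})

setMethod("show", "MCConfig", function(object) {
  cat("MCConfig: ", format(object@nPhotons, big.mark = ","),
      " photons, seed ", object@seed, "\n", sep = "")
  cat("  grid: ", object@nr, " x ", object@dr, " cm radial, ", object@nz,
      " x ", ifelse(is.na(object@dz), "auto", format(object@dz)),
      " cm depth; ", object@nTheta, " theta x ", object@nPhi,
      " phi exit bins\n", sep = "")
})

setMethod("show", "MCResult", function(object) {
  cat("MCResult (", format(object@nPhotonsRun, big.mark = ","),
      " photons, seed ", object@seedUsed, ")\n", sep = "")
  cat(sprintf("  R_spec = %.5f  R_diff = %.5f  T_diff = %.5f  A = %.5f\n",
              object@rSpecular, object@rDiffuse, object@tDiffuse,
              object@aTotal))
})

#' Flatten a KMInversion to a per-wavelength data frame
#'
#' @param x a [KMInversion-class]
#' @param row.names,optional,... passed on conventions of
#'   [base::as.data.frame()]; ignored
#' @return data frame with columns \code{wavelength, rd, td, x, y, s, k,
#'   mu_a, mu_s}
#' @method as.data.frame KMInversion
#' @export
as.data.frame.KMInversion <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(wavelength = x@spectrum@wavelength,
             rd = x@spectrum@rd, td = x@spectrum@td,
             x = x@coefficients@x, y = x@coefficients@y,
             s = x@coefficients@s, k = x@coefficients@k,
             mu_a = x@properties@muA, mu_s = x@properties@muS)
}

setMethod("as.data.frame", "KMInversion", as.data.frame.KMInversion)

#' Flatten a MeasuredSpectrum to a data frame
#'
#' @param x a [MeasuredSpectrum-class]
#' @param row.names,optional,... ignored
#' @return data frame with columns \code{wavelength_nm, r_d, t_d}
#' @method as.data.frame MeasuredSpectrum
#' @export
as.data.frame.MeasuredSpectrum <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(wavelength_nm = x@wavelength, r_d = x@rd, t_d = x@td)
}

setMethod("as.data.frame", "MeasuredSpectrum", as.data.frame.MeasuredSpectrum)
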