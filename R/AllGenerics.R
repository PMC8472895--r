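#' @name uhmwpeOptics-generics
#' @title Accessor generics
#' @description Accessor generics for the package's S4 classes.
#' @param object an object of one of the package's S4 classes
#' @param ... further arguments for methods
#' @return The slot value the accessor is named after.
NULL

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("wavelengths", function(object, ...) standardGeneric("wavelengths"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("reflectance", function(object, ...) standardGeneric("reflectance"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("transmittance", function(object, ...) standardGeneric("transmittance"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("thickness", function(object, ...) standardGeneric("thickness"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("doseLabel", function(object, ...) standardGeneric("doseLabel"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("spectrumMetadata", function(object, ...) standardGeneric("spectrumMetadata"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("muA", function(object, ...) standardGeneric("muA"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("muS", function(object, ...) standardGeneric("muS"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("anisotropy", function(object, ...) standardGeneric("anisotropy"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("refractiveIndex", function(object, ...) standardGeneric("refractiveIndex"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("kmCoefficients", function(object, ...) standardGeneric("kmCoefficients"))

#' @rdname uhmwpeOptics-generics
#' @export
setGeneric("opticalProperties", function(object, ...) standardGeneric("opticalProperties"))
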