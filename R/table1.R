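## Packaged reference table of UHMWPE optical coefficients.

#' Reference optical coefficients for pristine and irradiated UHMWPE
#'
#' Returns the packaged reference table of Kubelka-Munk-extracted absorption
#' and scattering coefficients for 0.05 cm UHMWPE sheets at gamma doses of
#' 0 kGy ("P-0"), 30 kGy ("P-30") and 100 kGy ("P-100"), on an 18-point
#' wavelength grid from 630 nm to 800 nm. The \code{mu_t_printed} column is
#' the attenuation coefficient exactly as published (it can differ from
#' \code{mu_a + mu_s} by rounding of unrounded intermediates, at most
#' 0.02 cm^-1).
#'
#' @param dose optional dose label(s) to filter to
#' @return data frame with columns \code{wavelength_nm, dose, mu_a, mu_s,
#'   mu_t_printed}
#' @export
#'
#' @examples
#' tab <- uhmwpeTable1()
#' subset(tab, wavelength_nm == 800)
uhmwpeTable1 <- function(dose = NULL) {
  path <- system.file("extdata", "table1.csv", package = "uhmwpeOptics",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$dose <- factor(tab$dose, levels = c("P-0", "P-30", "P-100"))
  if (!is.null(dose)) {
    stopifnot(all(dose %in% levels(tab$dose)))
    tab <- tab[tab$dose %in% dose, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Look up reference optical properties for one dose and wavelength
#'
#' Convenience accessor over [uhmwpeTable1()] returning an
#' [OpticalProperties-class] ready for [kmForward()] or [mcRun()].
#'
#' @param dose one of "P-0", "P-30", "P-100"
#' @param wavelength one or more of the tabulated wavelengths (nm)
#' @param g,n anisotropy and refractive index to attach
#' @return an [OpticalProperties-class]
#' @export
#'
#' @examples
#' table1Properties("P-0", 800)
table1Properties <- function(dose, wavelength, g = 0.9, n = 1.54) {
  tab <- uhmwpeTable1(dose = dose)
  i <- match(wavelength, tab$wavelength_nm)
  if (anyNA(i))
    stop("wavelength(s) not tabulated: ",
         paste(wavelength[is.na(i)], collapse = ", "))
  OpticalProperties(muA = tab$mu_a[i], muS = tab$mu_s[i], g = g, n = n,
                    wavelength = tab$wavelength_nm[i])
}
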