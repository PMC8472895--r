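## End-to-end orchestration: read spectra, invert, derive, simulate,
## validate, and write Table-style reports and absorption maps.

#' Read a spectrum CSV
#'
#' Reads the standard spectrum format: columns \code{wavelength_nm, r_d,
#' t_d} with values as fractions (not percent). Thickness and label are not
#' stored in the file and must be supplied.
#'
#' @param file path to the CSV
#' @param thicknessT slab thickness, cm
#' @param label dose/sample label; defaults to the file name
#' @return a [MeasuredSpectrum-class]
#' @export
readSpectrum <- function(file, thicknessT = 0.05, label = NULL) {
  if (!file.exists(file)) stop("spectrum file not found: ", file)
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "r_d", "t_d")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("spectrum CSV is empty (row count 0): ", file)
  if (is.null(label)) label <- sub("\\.csv$", "", basename(file))
  MeasuredSpectrum(df$wavelength_nm, df$r_d, df$t_d,
                   thickness = thicknessT, label = label)
}

#' Write a spectrum CSV
#'
#' @param spectrum a [MeasuredSpectrum-class]
#' @param file output path
#' @return the path, invisibly
#' @export
writeSpectrum <- function(spectrum, file) {
  stopifnot(is(spectrum, "MeasuredSpectrum"))
  write.csv(as.data.frame(spectrum), file, row.names = FALSE)
  invisible(file)
}

#' Extract optical properties from one or more spectra
#'
#' The inversion stage of the pipeline: each spectrum is inverted
#' per-wavelength with [kmInvert()] and the results are assembled into a
#' spectral table with all derived quantities via [buildSpectralTable()].
#' Wavelengths that fail inversion (degenerate or unphysical measurements)
#' are dropped from the table with a warning naming them, so one bad row
#' does not abort the run.
#'
#' @param spectra a [MeasuredSpectrum-class], a list of them, or a character
#'   vector of spectrum CSV paths
#' @param thicknessT thickness used when reading from files, cm
#' @param g anisotropy factor
#' @return spectral table data frame (see [buildSpectralTable()])
#' @export
#'
#' @examples
#' sp <- generateSpectrum("P-0", seq(630, 800, 10), noiseRelSd = 0, seed = 1)
#' head(runExtraction(sp))
runExtraction <- function(spectra, thicknessT = 0.05, g = 0.9) {
  if (is.character(spectra))
    spectra <- lapply(spectra, readSpectrum, thicknessT = thicknessT)
  if (is(spectra, "MeasuredSpectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(sp) {
    stopifnot(is(sp, "MeasuredSpectrum"))
    wl <- wavelengths(sp)
    per_wl <- lapply(seq_along(wl), function(i) {
      one <- MeasuredSpectrum(wl[i], reflectance(sp)[i], transmittance(sp)[i],
                              thickness = thickness(sp),
                              label = doseLabel(sp))
      tryCatch({
        inv <- kmInvert(one, g = g)
        data.frame(wavelength = wl[i], dose = doseLabel(sp),
                   mu_a = muA(opticalProperties(inv)),
                   mu_s = muS(opticalProperties(inv)))
      }, error = function(e) {
        warning(sprintf("dropping %s @ %g nm: %s", doseLabel(sp), wl[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    })
    do.call(rbind, per_wl)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no wavelength could be inverted")
  buildSpectralTable(tab, g = g)
}

#' Cross-validate simulated against two-flux totals at one wavelength
#'
#' For every dose present in the spectral table at the given wavelength,
#' runs the Monte Carlo simulator and compares total R/T/A against the
#' two-flux closed form ([validateAgainstTwoFlux()]), in matched-boundary
#' mode, mismatched mode (slab index \code{nSlab} in air), or both. Doses
#' missing at the wavelength are reported as gaps and skipped.
#'
#' @param table spectral table from [runExtraction()] or
#'   [buildSpectralTable()]
#' @param wavelength wavelength to validate at, nm
#' @param config an [MCConfig-class]; per-dose runs use consecutive seeds
#'   starting at \code{config@seed}
#' @param thicknessT slab thickness, cm
#' @param g,nSlab anisotropy and slab refractive index
#' @param boundary "matched", "mismatched", or "both"
#' @param threshold pass/fail threshold on relative differences
#' @return data frame with columns \code{dose, boundary, quantity, mc,
#'   twoflux, rel_diff, pass}
#' @export
runValidation <- function(table, wavelength = 800, config = MCConfig(),
                          thicknessT = 0.05, g = 0.9, nSlab = 1.54,
                          boundary = c("matched", "mismatched", "both"),
                          threshold = 0.05) {
  boundary <- match.arg(boundary)
  modes <- if (boundary == "both") c("matched", "mismatched") else boundary
  doses <- unique(as.character(table$dose))
  out <- list(); seed_offset <- 0
  for (dose in doses) {
    row <- table[table$wavelength == wavelength & table$dose == dose, ]
    if (nrow(row) == 0L) {
      warning("no entry for dose ", dose, " at ", wavelength, " nm; skipped")
      next
    }
    props <- OpticalProperties(muA = row$mu_a, muS = row$mu_s, g = g,
                               n = nSlab, wavelength = wavelength)
    for (mode in modes) {
      geo <- SlabGeometry(thickness = thicknessT, nSlab = nSlab,
                          matched = (mode == "matched"))
      cfg <- config
      cfg@seed <- config@seed + seed_offset
      seed_offset <- seed_offset + 1
      v <- validateAgainstTwoFlux(props, geo, cfg, threshold = threshold)
      v$dose <- dose; v$boundary <- mode
      out[[length(out) + 1L]] <- v
    }
  }
  if (!length(out)) stop("no dose could be validated at ", wavelength, " nm")
  res <- do.call(rbind, out)
  res[, c("dose", "boundary", "quantity", "mc", "twoflux", "rel_diff",
          "pass")]
}

#' Simulate per-dose absorption maps at one wavelength
#'
#' The light-distribution stage: for every dose in the table at the given
#' wavelength, runs the Monte Carlo simulator and returns the absorption
#' map with its iso-level penetration summary, annotated with the dose's
#' transport albedo.
#'
#' @inheritParams runValidation
#' @param normalization passed to [absorptionMap()]
#' @param isoLevel passed to [absorptionMap()]
#' @param matched logical; simulate with index-matched boundaries
#' @return named list (one element per dose) of lists with components
#'   \code{map} (see [absorptionMap()]), \code{albedo}, \code{result}
#' @export
runDistribution <- function(table, wavelength = 800, config = MCConfig(),
                            thicknessT = 0.05, g = 0.9, nSlab = 1.54,
                            matched = FALSE,
                            normalization = "per_area", isoLevel = 0.01) {
  doses <- unique(as.character(table$dose))
  out <- list(); seed_offset <- 0
  for (dose in doses) {
    row <- table[table$wavelength == wavelength & table$dose == dose, ]
    if (nrow(row) == 0L) {
      warning("no entry for dose ", dose, " at ", wavelength, " nm; skipped")
      next
    }
    props <- OpticalProperties(muA = row$mu_a, muS = row$mu_s, g = g,
                               n = nSlab, wavelength = wavelength)
    geo <- SlabGeometry(thickness = thicknessT, nSlab = nSlab,
                        matched = matched)
    cfg <- config
    cfg@seed <- config@seed + seed_offset
    seed_offset <- seed_offset + 1
    res <- mcRun(props, geo, cfg)
    out[[dose]] <- list(map = absorptionMap(res, normalization, isoLevel),
                        albedo = transportAlbedo(props),
                        result = res)
  }
  out
}

#' Write / read a spectral table
#'
#' CSV columns: \code{wavelength_nm, dose, mu_a, mu_s, mu_t, mu_eff,
#' delta_mm, albedo} (depth reported in mm). A JSON mirror is written next
#' to the CSV when \code{json = TRUE}. The reader restores the internal
#' representation (with \code{delta_cm}) so that write/read round-trips.
#'
#' @param table spectral table data frame
#' @param file output CSV path
#' @param json also write \code{<file>.json}
#' @return the CSV path, invisibly
#' @export
writeSpectralTable <- function(table, file, json = TRUE) {
  out <- data.frame(wavelength_nm = table$wavelength,
                    dose = as.character(table$dose),
                    mu_a = table$mu_a, mu_s = table$mu_s,
                    mu_t = table$mu_t, mu_eff = table$mu_eff,
                    delta_mm = table$delta_mm, albedo = table$albedo)
  write.csv(out, file, row.names = FALSE)
  if (json)
    jsonlite::write_json(out, paste0(file, ".json"), digits = NA,
                         dataframe = "rows")
  invisible(file)
}

#' @rdname writeSpectralTable
#' @export
readSpectralTable <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  data.frame(wavelength = df$wavelength_nm, dose = df$dose,
             mu_a = df$mu_a, mu_s = df$mu_s, mu_t = df$mu_t,
             mu_eff = df$mu_eff, delta_cm = df$delta_mm / 10,
             delta_mm = df$delta_mm, albedo = df$albedo)
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a pipeline run: inputs, physical
#' parameters, Monte Carlo configuration, seeds, package version and a
#' timestamp. Serializable with [jsonlite::write_json()].
#'
#' @param inputFiles character vector of input spectrum paths (may be empty
#'   for synthetic runs)
#' @param thicknessT,g,nSlab physical parameters of the run
#' @param mcWavelengths wavelengths selected for simulation, nm
#' @param config an [MCConfig-class]
#' @return a list with class \code{"runManifest"}
#' @export
runManifest <- function(inputFiles = character(), thicknessT = 0.05,
                        g = 0.9, nSlab = 1.54, mcWavelengths = 800,
                        config = MCConfig()) {
  stopifnot(is(config, "MCConfig"))
  structure(list(
    input_files = inputFiles,
    thickness_cm = thicknessT, g = g, n_slab = nSlab,
    mc_wavelengths_nm = mcWavelengths,
    mc_config = list(n_photons = config@nPhotons, dr_cm = config@dr,
                     nr = config@nr, dz_cm = config@dz, nz = config@nz,
                     n_theta = config@nTheta, n_phi = config@nPhi,
                     seed = config@seed,
                     roulette_threshold = config@rouletteThreshold,
                     roulette_survival = config@rouletteSurvival),
    package_version = as.character(packageVersion("uhmwpeOptics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "runManifest")
}
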