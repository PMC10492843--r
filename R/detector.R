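#' Camera detector efficiency profiles
#'
#' Quantum-efficiency weights of the three color channels over 350--750 nm.
#' The packaged default is a tri-Gaussian model (peaks 460/530/600 nm, FWHM
#' 80 nm, equal peak height); user-supplied curves with the same schema
#' (wavelength_nm, qy_b, qy_g, qy_r) are accepted.
#'
#' @param path Optional CSV with columns wavelength_nm, qy_b, qy_g, qy_r.
#' @return Object of class `detector_response`.
#' @export
detector_response <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "detector_response.csv",
                        package = "polgate", mustWork = TRUE)
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "qy_b", "qy_g", "qy_r")
  if (!all(need %in% names(tab)))
    stop("detector response file must have columns ",
         paste(need, collapse = ", "))
  if (any(tab[need[-1]] < 0)) stop("quantum efficiencies must be non-negative")
  structure(as.list(tab), class = "detector_response")
}

#' Integrate a reflectance spectrum into RGB channel values
#'
#' channel = sum spectrum(lambda) * illuminant(lambda) * qy(lambda) * dlambda,
#' after linear resampling of the spectrum onto the detector wavelength grid.
#' The default illuminant is flat white.
#'
#' @param wavelengths Wavelengths of the spectrum samples, nm.
#' @param spectrum Reflectance (or differential reflectance) per wavelength.
#' @param response A [detector_response()].
#' @param illuminant Spectral power at the detector grid wavelengths, or a
#'   single value for a flat illuminant (default 1).
#' @return Named numeric vector c(r, g, b) in linear arbitrary units.
#' @export
spectrum_to_rgb <- function(wavelengths, spectrum, response = detector_response(),
                            illuminant = 1) {
  stopifnot(inherits(response, "detector_response"))
  wl <- response$wavelength_nm
  if (min(wavelengths) > max(wl) || max(wavelengths) < min(wl))
    stop("spectrum wavelength grid does not overlap the detector range")
  sp <- stats::approx(wavelengths, spectrum, wl, rule = 1)$y
  keep <- !is.na(sp)
  if (!any(keep)) stop("spectrum wavelength grid does not overlap the detector range")
  sp[!keep] <- 0
  ill <- if (length(illuminant) == 1) rep(illuminant, length(wl)) else illuminant
  dl <- mean(diff(wl))
  c(r = sum(sp * ill * response$qy_r) * dl,
    g = sum(sp * ill * response$qy_g) * dl,
    b = sum(sp * ill * response$qy_b) * dl)
}
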