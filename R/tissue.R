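#' Packaged hemoglobin extinction table
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin
#' (cm^-1 / (mol/L)) on a 5 nm grid over 350--750 nm; a coarse transcription
#' of the standard public-domain compilation.
#'
#' @return data.frame with columns `wavelength_nm`, `eps_oxy`, `eps_deoxy`.
#' @export
hemoglobin_extinction <- function() {
  path <- system.file("extdata", "hemoglobin_extinction.csv",
                      package = "polgate", mustWork = TRUE)
  utils::read.csv(path)
}

#' Blood absorption model
#'
#' @param blood_volume_fraction Fraction of tissue volume occupied by whole
#'   blood, in \[0, 1\] (the simulation grid uses 0.4--0.9%).
#' @param hemoglobin_gdl Hemoglobin concentration in blood, g/dL (default 15).
#' @param oxygen_saturation Fraction of hemoglobin that is oxygenated
#'   (default 1: fully oxygenated, configurable).
#' @param extinction_table Optional replacement extinction table with the
#'   same columns as [hemoglobin_extinction()].
#' @return Object of class `blood_model`.
#' @export
blood_model <- function(blood_volume_fraction, hemoglobin_gdl = 15,
                        oxygen_saturation = 1,
                        extinction_table = hemoglobin_extinction()) {
  if (blood_volume_fraction < 0 || blood_volume_fraction > 1)
    stop("invalid parameter: blood_volume_fraction must be in [0, 1]")
  if (oxygen_saturation < 0 || oxygen_saturation > 1)
    stop("invalid parameter: oxygen_saturation must be in [0, 1]")
  if (any(extinction_table$eps_oxy < 0) || any(extinction_table$eps_deoxy < 0))
    stop("invalid parameter: extinction coefficients must be non-negative")
  structure(list(blood_volume_fraction = blood_volume_fraction,
                 hemoglobin_gdl = hemoglobin_gdl,
                 oxygen_saturation = oxygen_saturation,
                 extinction_table = extinction_table),
            class = "blood_model")
}

## molar concentration of hemoglobin in whole blood, mol/L
## (monomer molecular weight 64,500 g/mol)
hb_molar_concentration <- function(hemoglobin_gdl) {
  hemoglobin_gdl * 10 / 64500
}

#' Tissue absorption coefficient from blood content
#'
#' mu_a(lambda) = bvf * ln(10) * eps_Hb(lambda) * C_molar, with the extinction
#' coefficient linearly interpolated from the packaged table and mixed by
#' oxygen saturation.
#'
#' @param wavelength Wavelength(s) in nm, within the extinction table range.
#' @param blood A [blood_model()].
#' @return mu_a in cm^-1 (vectorized over `wavelength`).
#' @export
absorption_coefficient <- function(wavelength, blood) {
  stopifnot(inherits(blood, "blood_model"))
  tab <- blood$extinction_table
  rng <- range(tab$wavelength_nm)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop(sprintf("out of range: wavelength outside extinction table [%g, %g] nm",
                 rng[1], rng[2]))
  eps_oxy <- stats::approx(tab$wavelength_nm, tab$eps_oxy, wavelength)$y
  eps_deoxy <- stats::approx(tab$wavelength_nm, tab$eps_deoxy, wavelength)$y
  eps <- blood$oxygen_saturation * eps_oxy +
    (1 - blood$oxygen_saturation) * eps_deoxy
  blood$blood_volume_fraction * log(10) * eps *
    hb_molar_concentration(blood$hemoglobin_gdl)
}

#' Scattering coefficient from the reduced scattering coefficient
#'
#' mu_s = mu_s' / (1 - g).
#'
#' @param musp Reduced scattering coefficient, cm^-1.
#' @param g Scattering anisotropy (< 1).
#' @return mu_s in cm^-1.
#' @export
mus_from_musp <- function(musp, g) {
  if (any(g >= 1)) stop("invalid parameter: anisotropy g must be < 1")
  musp / (1 - g)
}

#' Optical depth of a slab
#'
#' tau = (mu_a + mu_s) * D. The simulated slab uses tau = 20, beyond which
#' the white-light signal saturates.
#'
#' @param mua,mus Absorption and scattering coefficients, cm^-1.
#' @param thickness Geometrical thickness D, cm.
#' @return Dimensionless optical depth.
#' @export
optical_depth <- function(mua, mus, thickness) {
  (mua + mus) * thickness
}

#' @rdname optical_depth
#' @param tau Target optical depth.
#' @export
thickness_for_depth <- function(tau, mua, mus) {
  tau / (mua + mus)
}

#' Wavelength-resolved tissue optical properties for one grid point
#'
#' Composes absorption from blood content and scattering from a monodisperse
#' sphere population. The sphere radius is chosen so its Mie scattering cross
#' section at the 550 nm reference equals `sigma_um2`; mu_s(lambda) takes its
#' spectral shape from the sphere's sigma_sca(lambda) and its amplitude from
#' `musp_ref` at 550 nm under the transport convention g = 0.9. The reduced
#' scattering spectrum mu_s' = mu_s * (1 - g_transport) is fitted for the
#' scattering power b.
#'
#' @param musp_ref Reduced scattering coefficient at 550 nm, cm^-1.
#' @param sigma_um2 Scattering cross section at 550 nm, um^2.
#' @param bvf Blood volume fraction.
#' @param wavelengths Wavelength grid, nm (default 350--750 by 10).
#' @param g_transport Transport anisotropy (default 0.9).
#' @param n_medium,n_particle Refractive indices.
#' @param oxygen_saturation Passed to [blood_model()].
#' @param radius Optional precomputed sphere radius (um), skips inversion.
#' @return Object of class `tissue_optical_properties` with spectra and
#'   scattering power `b`.
#' @export
tissue_optical_properties <- function(musp_ref, sigma_um2, bvf,
                                      wavelengths = seq(350, 750, by = 10),
                                      g_transport = 0.9,
                                      n_medium = 1.35, n_particle = 1.42,
                                      oxygen_saturation = 1,
                                      radius = NULL) {
  if (is.null(radius))
    radius <- radius_from_cross_section(sigma_um2, 550, n_particle, n_medium)
  sc <- sphere_scatterer(radius, n_particle, n_medium)
  cs <- lapply(wavelengths, function(l) mie_cross_sections(sc, l))
  sigma_sca <- vapply(cs, `[[`, numeric(1), "sigma_sca")
  g_mie <- vapply(cs, `[[`, numeric(1), "g")
  sigma_ref <- mie_cross_sections(sc, 550)$sigma_sca
  mus_ref <- mus_from_musp(musp_ref, g_transport)
  mus <- mus_ref * sigma_sca / sigma_ref
  musp <- mus * (1 - g_transport)
  blood <- blood_model(bvf, oxygen_saturation = oxygen_saturation)
  mua <- absorption_coefficient(wavelengths, blood)
  pw <- fit_scattering_power(wavelengths, musp)
  structure(list(wavelengths = wavelengths, mua = mua, mus = mus, musp = musp,
                 g_transport = g_transport, g_mie = g_mie,
                 n_medium = n_medium, scatterer = sc, blood = blood,
                 b = pw$b, fit_r2 = pw$fit_r2),
            class = "tissue_optical_properties")
}

#' Simulation parameter grid
#'
#' Cartesian grid of reduced scattering coefficients, scattering cross
#' sections and blood volume fractions spanning soft-tissue conditions.
#' The default reading of "10 to 35 cm^-1 with 5 equal steps" is 6 values
#' {10, 15, 20, 25, 30, 35}; set `musp_five_values = TRUE` for the 5-value
#' reading.
#'
#' @param musp_values Reduced scattering coefficients at 550 nm, cm^-1.
#' @param sigma_values Scattering cross sections at 550 nm, um^2.
#' @param bvf_values Blood volume fractions (fractions, not percent).
#' @param musp_five_values Use 5 equally spaced musp values instead of 6.
#' @return Object of class `parameter_grid`: a data.frame `points` with one
#'   row per grid point (musp, sigma, bvf, radius, b) plus the value lists.
#' @export
build_parameter_grid <- function(musp_values = NULL,
                                 sigma_values = seq(0.5, 8, by = 0.5),
                                 bvf_values = seq(0.004, 0.009, by = 0.001),
                                 musp_five_values = FALSE) {
  if (is.null(musp_values))
    musp_values <- if (musp_five_values) seq(10, 35, length.out = 5)
                   else seq(10, 35, by = 5)
  if (any(musp_values < 10 - 1e-9) || any(musp_values > 35 + 1e-9))
    stop("invalid parameter: musp_values must lie within [10, 35] cm^-1")
  radii <- vapply(sigma_values, radius_from_cross_section, numeric(1))
  b_by_sigma <- vapply(seq_along(sigma_values), function(i) {
    tissue_optical_properties(20, sigma_values[i], 0.006,
                              radius = radii[i])$b
  }, numeric(1))
  points <- expand.grid(musp = musp_values, sigma = sigma_values,
                        bvf = bvf_values, KEEP.OUT.ATTRS = FALSE)
  idx <- match(points$sigma, sigma_values)
  points$radius <- radii[idx]
  points$b <- b_by_sigma[idx]
  structure(list(points = points, musp_values = musp_values,
                 sigma_values = sigma_values, bvf_values = bvf_values,
                 radii = radii),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("parameter_grid: %d musp x %d sigma x %d bvf = %d points; b in [%.3f, %.3f]\n",
              length(x$musp_values), length(x$sigma_values),
              length(x$bvf_values), nrow(x$points),
              min(x$points$b), max(x$points$b)))
  invisible(x)
}
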