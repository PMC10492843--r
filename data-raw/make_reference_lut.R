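# Builds inst/extdata/lut_reference.csv: the packaged reduced reflectance
# lookup table (musp' = 20 cm^-1, bvf = 0.6%, six scattering cross sections)
# used by the phantom generators so fixtures build in seconds. Produced by
# the package's own Monte Carlo (4e4 photons per wavelength, 27 wavelengths,
# common-random-number seeding, fixed seed).
library(polgate)
set.seed(424242)
g <- build_parameter_grid(musp_values = 20,
                          sigma_values = c(0.5, 1, 2, 4, 6, 8),
                          bvf_values = 0.006)
lut <- build_lookup_table(g, n_photons = 4e4, seed = 424242)
write_lookup_table(lut, "inst/extdata/lut_reference.csv")
print(lut$points)
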