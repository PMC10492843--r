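# polgate

Analysis and simulation tools for **polarization-gated laparoscopy**:
label-free contrast enhancement of superficial peritoneal lesions from
co/cross-polarized RGB video frames.

## The problem and the method

A laparoscope that illuminates tissue with linearly polarized white light
and records co- and cross-polarized frames can separate superficial from
deep signal: light returned from the superficial layer keeps most of its
polarization (co-polarized), while deeper, multiply-scattered light is
depolarized and splits evenly between the two channels. With per-channel
intensities R∥, R⊥, …:

- **WLL** = (R∥+R⊥) + (G∥+G⊥) + (B∥+B⊥) — the white-light-equivalent image,
- **PEL** = (R∥−R⊥) + (G∥−G⊥) + (B∥−B⊥) — the polarization-gated image,

and the **mPEL** statistic is a color-weighted differential tuned to the
tissue *scattering power* b (the exponent in μs′(λ) ∝ λ⁻ᵇ, elevated where
collagen is sparse and fine, as in metastatic deposits):

    mPEL = a0 + a1 (R∥−R⊥) + a2 (G∥−G⊥) + a3 (B∥−B⊥)

The coefficients come from multiple regression of b on RGB differentials
simulated with a polarization-sensitive Monte Carlo model of photon
transport (Stokes vectors, Mie-sphere scattering, hemoglobin absorption) —
the published clinical set (0.4705, −0.0073, −0.0039, +0.1104) ships with
the package, and `fit_mpel()` refits it on any simulated lookup table.

The package covers the full workflow:

- `mie_amplitudes()`, `mie_solution()`, `radius_from_cross_section()`,
  `fit_scattering_power()` — Mie optics and scattering power;
- `build_parameter_grid()`, `tissue_optical_properties()` — tissue optics
  (μs′ 10–35 cm⁻¹, σs 0.5–8 µm², blood volume 0.4–0.9%, Hb 15 g/dL);
- `simulate_slab()`, `build_lookup_table()` — the polarized Monte Carlo and
  the co/cross reflectance lookup table (slab at optical depth 20);
- `spectrum_to_rgb()`, `detector_response()` — RGB integration through
  camera quantum-efficiency curves;
- `fit_mpel()`, `apply_mpel()`, `compute_wll()`, `compute_pel()` — the
  image statistics;
- `run_frame()`, `preprocess()`, `glare_mask()` — the Lab-domain
  pre-processing chain (Gaussian denoise σ 0.5 px, homomorphic illumination
  correction σ 15 px, 1%/1% contrast saturation, percentile-based specular
  glare exclusion);
- `roi_means()`, `weber_contrast()`, `anova_tukey()`, `ttest_two_sample()`,
  `fisher_exact_2x2()` — ROI quantification and the accompanying
  statistics;
- `segment_fibers()`, `local_orientation()`, `directional_variance()`,
  `area_fraction()` — collagen organization from SHG microscopy;
- `render_phantom()`, `render_fibers()`, `make_fixture_suite()` — synthetic
  phantoms with known ground truth for validation.

## Worked example

```r
library(polgate)

# a malignant-like phantom: lesion with higher scattering power than its
# background, vignette, noise; rendered from the packaged lookup table
ph  <- render_phantom(phantom_spec(size = c(96L, 96L), seed = 11))
cf  <- fit_mpel(reference_lut())
out <- run_frame(ph$pair, coeffs = cf)

rois <- matrix(0L, 96, 96); rois[ph$lesion_mask] <- 1L
for (mod in c("wll", "pel", "mpel")) {
  r <- contrast_records(out[[mod]], rois, out$excluded_mask, toupper(mod))
  cat(sprintf("%5s: I_f = %8.4f  I_b = %8.4f  C_W = %+.3f\n",
              toupper(mod), r$I_f, r$I_b, r$C_W))
}
#>   WLL: I_f =   2.4646  I_b =   2.2754  C_W = +0.083
#>   PEL: I_f =   0.0595  I_b =   0.0369  C_W = +0.612
#>  MPEL: I_f =   0.3941  I_b =   0.3833  C_W = +0.028
```

The lesion is faint in the white-light image (Weber contrast +0.08: the
depolarized deep signal dilutes it), but the polarization-gated image
suppresses that background and the contrast rises about 7-fold (+0.61);
mPEL maps the pixels onto the scattering-power scale, where the
higher-scattering-power lesion mean exceeds the background mean.

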