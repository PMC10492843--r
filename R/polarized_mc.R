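#' Slab geometry for the transport simulation
#'
#' Single-layer tissue slab, illuminated at normal incidence with linear
#' polarization along the lab x axis. The thickness is normally chosen so the
#' optical depth tau = (mua + mus) * D equals 20.
#'
#' @param thickness Slab thickness, cm (> 0).
#' @param n_inside,n_outside Refractive indices of the slab and surroundings.
#' @return Object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness, n_inside = 1.35, n_outside = 1.0) {
  if (thickness <= 0) stop("invalid parameter: thickness must be positive")
  structure(list(thickness = thickness, n_inside = n_inside,
                 n_outside = n_outside),
            class = "slab_geometry")
}

#' Launch a photon packet
#'
#' Photon at the origin of the top surface, travelling into the slab (+z),
#' fully x-linearly polarized: Stokes (1, 1, 0, 0), unit weight. The
#' reference frame (e1, e2) spans the lab x/y axes.
#'
#' @param geometry A [slab_geometry()] (unused beyond the contract; kept for
#'   interface symmetry).
#' @return List describing the launched `stokes_photon`.
#' @export
launch <- function(geometry = NULL) {
  list(position = c(0, 0, 0), direction = c(0, 0, 1),
       stokes = c(1, 1, 0, 0), weight = 1,
       e1 = c(1, 0, 0), e2 = c(0, 1, 0))
}

#' Sample an exponential free path
#'
#' @param mu_t Total attenuation coefficient, cm^-1 (> 0).
#' @param u Uniform(0,1) variate(s); defaults to fresh draws.
#' @return Step length(s) in cm, s = -log(u)/mu_t.
#' @export
sample_step <- function(mu_t, u = stats::runif(1)) {
  if (any(mu_t <= 0)) stop("invalid parameter: mu_t must be positive")
  -log(u) / mu_t
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized power reflectances at a planar
#' interface; 1 beyond the critical angle.
#'
#' @param cos_i Cosine of the angle of incidence (in the incident medium).
#' @param n_in,n_out Refractive indices of the incident and transmitting media.
#' @return Reflectance in \[0, 1\].
#' @export
fresnel_reflectance <- function(cos_i, n_in, n_out) {
  sin_i <- sqrt(pmax(0, 1 - cos_i^2))
  sin_t <- n_in / n_out * sin_i
  ifelse(sin_t >= 1, 1, {
    cos_t <- sqrt(pmax(0, 1 - pmin(sin_t, 1)^2))
    rs <- (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t)
    rp <- (n_in * cos_t - n_out * cos_i) / (n_in * cos_t + n_out * cos_i)
    0.5 * (rs^2 + rp^2)
  })
}

#' Single scattering update of a Stokes vector
#'
#' Pure Mueller algebra for one scattering event at given (theta, phi):
#' rotation of the reference frame into the scattering plane, application of
#' the sphere Mueller matrix, and renormalization to unit intensity. Exposed
#' for validation against closed-form single-scattering results.
#'
#' @param stokes Incident Stokes vector (I, Q, U, V), I > 0.
#' @param theta,phi Scattering and azimuth angles, radians.
#' @param m11,m12,m33,m34 Phase-matrix elements at `theta`.
#' @return Normalized scattered Stokes vector (I = 1).
#' @export
scatter_stokes <- function(stokes, theta, phi, m11, m12, m33, m34) {
  s <- stokes / stokes[1]
  c2 <- cos(2 * phi); s2 <- sin(2 * phi)
  q <- c2 * s[2] + s2 * s[3]
  u <- -s2 * s[2] + c2 * s[3]
  I2 <- m11 * s[1] + m12 * q
  Q2 <- m12 * s[1] + m11 * q
  U2 <- m33 * u + m34 * s[4]
  V2 <- -m34 * u + m33 * s[4]
  c(1, Q2 / I2, U2 / I2, V2 / I2)
}

#' Analyzer split of an exiting photon
#'
#' Contribution of an exiting photon packet to the co- and cross-polarized
#' detection channels, with Q expressed in the lab frame aligned to the
#' illumination polarization: co = w (I+Q)/(2I), cross = w (I-Q)/(2I).
#'
#' @param stokes Exit Stokes vector in the lab analyzer frame.
#' @param weight Survival weight.
#' @return Named vector with `co` and `cross` contributions (sum = weight).
#' @export
detect <- function(stokes, weight = 1) {
  I <- stokes[1]
  c(co = weight * (I + stokes[2]) / (2 * I),
    cross = weight * (I - stokes[2]) / (2 * I))
}

#' An isotropic, depolarizing phase table
#'
#' Flat m11, zero off-diagonal elements; useful for similarity-relation
#' checks and distribution tests.
#'
#' @param n_angles Number of angle samples.
#' @return A list shaped like a [mie_solution()] phase table.
#' @export
isotropic_phase <- function(n_angles = 1801L) {
  ang <- seq(0, pi, length.out = n_angles)
  list(angles = ang, m11 = rep(1, n_angles), m12 = rep(0, n_angles),
       m33 = rep(0, n_angles), m34 = rep(0, n_angles), g = 0)
}

#' Simulate polarized transport through a slab at one wavelength
#'
#' Runs the Stokes-vector Monte Carlo for `n_photons` packets and tallies
#' co/cross-polarized reflectance, transmittance and absorbed fractions.
#' Deterministic for a fixed seed. Weight-based absorption with Russian
#' roulette below 1e-4 (survival factor 10).
#'
#' @param mua,mus Absorption and scattering coefficients, cm^-1.
#' @param phase A [mie_solution()] (or [isotropic_phase()]) supplying the
#'   angle grid and phase-matrix elements.
#' @param geometry A [slab_geometry()].
#' @param n_photons Number of photon packets (>= 1).
#' @param seed Integer seed for the kernel RNG stream.
#' @param stokes Illumination Stokes vector (default x-linear (1,1,0,0)).
#' @param matched_boundary If TRUE, disable Fresnel reflection (index-matched
#'   boundaries); used by conservation oracles.
#' @param collect_exits If TRUE, also return per-exit-photon maximum depth,
#'   scattering-event count and co/cross weights.
#' @return List of class `reflectance_result`.
#' @export
simulate_slab <- function(mua, mus, phase, geometry, n_photons = 1e4,
                          seed = 1, stokes = c(1, 1, 0, 0),
                          matched_boundary = FALSE, collect_exits = FALSE) {
  stopifnot(inherits(geometry, "slab_geometry"), n_photons >= 1)
  if (mus <= 0 || mua < 0) stop("invalid parameter: need mus > 0, mua >= 0")
  res <- simulate_slab_cpp(mua, mus, geometry$thickness,
                           geometry$n_inside, geometry$n_outside,
                           phase$angles, phase$m11, phase$m12, phase$m33,
                           phase$m34, as.integer(n_photons), seed,
                           stokes, matched_boundary, collect_exits)
  class(res) <- "reflectance_result"
  res
}

#' @export
print.reflectance_result <- function(x, ...) {
  cat(sprintf("reflectance_result: R_co %.4f R_cross %.4f T %.4f A %.4f (n = %d)\n",
              x$R_co, x$R_cross, x$T_total, x$A_total, x$n_photons))
  invisible(x)
}

## default Monte Carlo wavelength set: 9 per RGB band, 27 total, spanning the
## detector sensitivity range
mc_wavelengths <- function() {
  c(seq(410, 510, length.out = 9),    # blue band
    seq(480, 580, length.out = 9),    # green band
    seq(550, 650, length.out = 9))    # red band
}

#' Build the co/cross reflectance lookup table
#'
#' Simulates every parameter-grid point at each wavelength (slab thickness
#' set per wavelength so tau = 20), converts the reflectance spectra to RGB
#' through the detector model, and tabulates the RGB differentials together
#' with WLL/PEL scalars and the true scattering power b. Per-point seeds are
#' derived as `seed + point index` and recorded, so results do not depend on
#' execution order.
#'
#' @param grid A [build_parameter_grid()] object.
#' @param wavelengths Simulation wavelengths, nm (default 27 values, 9 per
#'   RGB band).
#' @param n_photons Photon packets per wavelength and grid point.
#' @param seed Base seed.
#' @param detector A [detector_response()] (default packaged tri-Gaussian).
#' @param tau Slab optical depth (default 20).
#' @param g_scaling How the scattering amplitude is anchored to the grid's
#'   mus' at 550 nm: `"mie"` (default) uses each sphere's own anisotropy,
#'   mus = musp_ref / (1 - g_mie(550)), so the transport-equivalent reduced
#'   scattering is identical across sphere sizes (this is what makes the
#'   white-light signal insensitive to scattering power); `"transport"` uses
#'   the fixed g = 0.9 convention, mus = musp_ref / 0.1.
#' @param seed_mode `"common"` (default): every grid point reuses the same
#'   per-wavelength seed stream (common random numbers), so Monte Carlo noise
#'   is correlated across grid points and contrasts between points — the
#'   quantities the table exists for — have much lower variance;
#'   `"per_point"`: independent streams seeded `seed + point index`.
#'   Both modes are deterministic for a fixed base seed and independent of
#'   execution order.
#' @param slab `"shared"` (default): one geometrical thickness per
#'   (musp, bvf) pair, set so tau = (mua + mus') * D / (1 - 0.9) = 20 at
#'   550 nm under the g = 0.9 transport convention for mus — every sphere
#'   size is then simulated in the same physical slab (transport-equivalent
#'   depth ~2, where the white-light signal has saturated), so the
#'   white-light channel is insensitive to scattering power and the co/cross
#'   contrast isolates polarization memory; `"per_point"`: thickness
#'   recomputed per grid point and wavelength so tau = 20 with the
#'   Mie-consistent mus.
#' @return Object of class `reflectance_lut` with `points` (one row per grid
#'   point: musp, sigma, bvf, b, dR, dG, dB, WLL, PEL, seed) and `spectra`
#'   (long format: point, wavelength_nm, R_co, R_cross).
#' @export
build_lookup_table <- function(grid, wavelengths = mc_wavelengths(),
                               n_photons = 5e3, seed = 1,
                               detector = detector_response(), tau = 20,
                               g_scaling = c("mie", "transport"),
                               slab = c("shared", "per_point"),
                               seed_mode = c("common", "per_point")) {
  stopifnot(inherits(grid, "parameter_grid"))
  g_scaling <- match.arg(g_scaling)
  slab <- match.arg(slab)
  seed_mode <- match.arg(seed_mode)
  pts <- grid$points
  ## cache phase tables and cross-section spectra per unique radius
  radii <- grid$radii
  phase_cache <- lapply(radii, function(r) {
    sc <- sphere_scatterer(r)
    lapply(wavelengths, function(l) mie_solution(sc, l))
  })
  n_pts <- nrow(pts)
  spectra <- vector("list", n_pts)
  point_rows <- vector("list", n_pts)
  for (i in seq_len(n_pts)) {
    p <- pts[i, ]
    isig <- match(p$sigma, grid$sigma_values)
    phases <- phase_cache[[isig]]
    ## reference cross section and anisotropy at 550 nm for amplitude scaling
    cs550 <- mie_cross_sections(sphere_scatterer(radii[isig]), 550)
    sig550 <- cs550$sigma_sca
    blood <- blood_model(p$bvf)
    g_ref <- if (g_scaling == "mie") cs550$g else 0.9
    mus_ref <- mus_from_musp(p$musp, g_ref)
    R_co <- numeric(length(wavelengths))
    R_cross <- numeric(length(wavelengths))
    pt_seed <- if (seed_mode == "common") seed else seed + i
    D_shared <- thickness_for_depth(
      tau, absorption_coefficient(550, blood), mus_from_musp(p$musp, 0.9))
    for (k in seq_along(wavelengths)) {
      lam <- wavelengths[k]
      mus_l <- mus_ref * phases[[k]]$sigma_sca / sig550
      mua_l <- absorption_coefficient(lam, blood)
      D <- if (slab == "shared") D_shared
           else thickness_for_depth(tau, mua_l, mus_l)
      geom <- slab_geometry(D)
      res <- simulate_slab(mua_l, mus_l, phases[[k]], geom,
                           n_photons = n_photons,
                           seed = pt_seed * 64 + k)
      R_co[k] <- res$R_co
      R_cross[k] <- res$R_cross
    }
    rgb_co <- spectrum_to_rgb(wavelengths, R_co, detector)
    rgb_cross <- spectrum_to_rgb(wavelengths, R_cross, detector)
    d <- rgb_co - rgb_cross
    point_rows[[i]] <- data.frame(
      musp = p$musp, sigma = p$sigma, bvf = p$bvf, b = p$b,
      dR = d[["r"]], dG = d[["g"]], dB = d[["b"]],
      WLL = sum(rgb_co + rgb_cross), PEL = sum(d),
      co_r = rgb_co[["r"]], co_g = rgb_co[["g"]], co_b = rgb_co[["b"]],
      cross_r = rgb_cross[["r"]], cross_g = rgb_cross[["g"]],
      cross_b = rgb_cross[["b"]], seed = pt_seed)
    spectra[[i]] <- data.frame(point = i, wavelength_nm = wavelengths,
                               R_co = R_co, R_cross = R_cross)
  }
  structure(list(points = do.call(rbind, point_rows),
                 spectra = do.call(rbind, spectra),
                 wavelengths = wavelengths, n_photons = n_photons,
                 seed = seed),
            class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat(sprintf("reflectance_lut: %d grid points x %d wavelengths, %g photons each; b range [%.3f, %.3f]\n",
              nrow(x$points), length(x$wavelengths), x$n_photons,
              min(x$points$b), max(x$points$b)))
  invisible(x)
}

#' Write / read a lookup table as CSV
#'
#' @param lut A `reflectance_lut`.
#' @param path Output CSV path (point table; the per-wavelength spectra go to
#'   `<path>` with a `.spectra.csv` companion when `spectra = TRUE`).
#' @param spectra Also write the long-format spectra.
#' @export
write_lookup_table <- function(lut, path, spectra = FALSE) {
  utils::write.csv(lut$points, path, row.names = FALSE)
  if (spectra)
    utils::write.csv(lut$spectra, sub("\\.csv$", ".spectra.csv", path),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path) {
  pts <- utils::read.csv(path)
  structure(list(points = pts, spectra = NULL, wavelengths = NULL,
                 n_photons = NA, seed = NA),
            class = "reflectance_lut")
}
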