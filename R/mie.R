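#' Spherical scatterer description
#'
#' Homogeneous dielectric sphere embedded in tissue-like medium. The default
#' refractive indices (1.42 for the scatterer, 1.35 for the surrounding medium)
#' are representative of collagen-dominated soft tissue.
#'
#' @param radius Sphere radius in micrometres. `radius = 0` is accepted as the
#'   degenerate "no scatterer" limit; negative values are rejected.
#' @param n_particle Real refractive index of the sphere (>= 1).
#' @param n_medium Real refractive index of the surrounding medium (>= 1).
#' @return An object of class `sphere_scatterer`.
#' @export
sphere_scatterer <- function(radius, n_particle = 1.42, n_medium = 1.35) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius < 0)
    stop("invalid parameter: 'radius' must be a single non-negative number")
  if (n_particle < 1 || n_medium < 1)
    stop("invalid parameter: refractive indices must be real and >= 1")
  structure(list(radius = radius, n_particle = n_particle, n_medium = n_medium),
            class = "sphere_scatterer")
}

#' @export
print.sphere_scatterer <- function(x, ...) {
  cat(sprintf("sphere_scatterer: radius %.4g um, n_p %.3f, n_med %.3f (m = %.5f)\n",
              x$radius, x$n_particle, x$n_medium, x$n_particle / x$n_medium))
  invisible(x)
}

## Lorenz-Mie expansion coefficients a_n, b_n for a homogeneous sphere.
## x: size parameter, m: relative refractive index (real here).
## Truncation after Wiscombe: nmax = ceil(x + 4 x^{1/3} + 2).
mie_ab <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  ## logarithmic derivative D_n(mx) by downward recurrence
  mx <- m * x
  nstart <- max(nmax, ceiling(abs(mx))) + 16L
  D <- complex(length.out = nstart + 1L)  # D[n+1] = D_n
  for (n in nstart:1) {
    D[n] <- n / mx - 1 / (D[n + 1L] + n / mx)
  }
  n <- seq_len(nmax)
  ## Riccati-Bessel psi_n(x), chi_n(x) upward
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi_m1 <- cos(x); psi_0 <- sin(x)
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  pm2 <- psi_m1; pm1 <- psi_0; cm2 <- chi_m1; cm1 <- chi_0
  for (k in n) {
    psi[k] <- (2 * k - 1) / x * pm1 - pm2
    chi[k] <- (2 * k - 1) / x * cm1 - cm2
    pm2 <- pm1; pm1 <- psi[k]
    cm2 <- cm1; cm1 <- chi[k]
  }
  xi <- complex(real = psi, imaginary = -chi)
  xi_prev <- c(complex(real = psi_0, imaginary = -chi_0), xi[-nmax])
  psi_prev <- c(psi_0, psi[-nmax])
  Dn <- D[n + 1L]
  ta <- Dn / m + n / x
  tb <- Dn * m + n / x
  a <- (ta * psi - psi_prev) / (ta * xi - xi_prev)
  b <- (tb * psi - psi_prev) / (tb * xi - xi_prev)
  list(a = a, b = b, nmax = nmax)
}

## angular functions pi_n(mu), tau_n(mu) for a vector of mu = cos(theta);
## returns nmax x length(mu) matrices
mie_pitau <- function(mu, nmax) {
  nA <- length(mu)
  pi_m <- matrix(0, nmax, nA)
  tau_m <- matrix(0, nmax, nA)
  p_prev <- rep(0, nA)   # pi_0
  p_cur <- rep(1, nA)    # pi_1
  for (k in seq_len(nmax)) {
    if (k > 1) {
      p_new <- (2 * k - 1) / (k - 1) * mu * p_cur - k / (k - 1) * p_prev
      p_prev <- p_cur; p_cur <- p_new
    }
    pi_m[k, ] <- p_cur
    tau_m[k, ] <- k * mu * p_cur - (k + 1) * p_prev
  }
  list(pi = pi_m, tau = tau_m)
}

#' Mie scattering amplitude functions
#'
#' Complex amplitudes S1, S2 of the Lorenz-Mie series for a homogeneous
#' sphere, evaluated on an angle grid.
#'
#' @param scatterer A [sphere_scatterer()].
#' @param wavelength Vacuum wavelength in nanometres (> 0).
#' @param angles Scattering angles in radians, within \[0, pi\].
#' @return A list with `angles`, complex vectors `S1` and `S2`, the size
#'   parameter `x` and the truncation order `nmax`.
#' @export
mie_amplitudes <- function(scatterer, wavelength, angles) {
  stopifnot(inherits(scatterer, "sphere_scatterer"))
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("invalid parameter: 'wavelength' must be positive")
  if (any(angles < -1e-12) || any(angles > pi + 1e-12))
    stop("invalid parameter: angles must lie within [0, pi]")
  if (scatterer$radius == 0) {
    z <- complex(length.out = length(angles))
    return(list(angles = angles, S1 = z, S2 = z, x = 0, nmax = 0L))
  }
  x <- 2 * pi * scatterer$radius * scatterer$n_medium / (wavelength * 1e-3)
  m <- scatterer$n_particle / scatterer$n_medium
  ab <- mie_ab(x, m)
  pt <- mie_pitau(cos(angles), ab$nmax)
  n <- seq_len(ab$nmax)
  w <- (2 * n + 1) / (n * (n + 1))
  S1 <- as.vector(t(pt$pi) %*% (w * ab$a) + t(pt$tau) %*% (w * ab$b))
  S2 <- as.vector(t(pt$tau) %*% (w * ab$a) + t(pt$pi) %*% (w * ab$b))
  list(angles = angles, S1 = S1, S2 = S2, x = x, nmax = ab$nmax)
}

#' Mie cross sections and anisotropy
#'
#' Scattering and extinction cross sections (in square micrometres) and the
#' scattering anisotropy g = <cos theta> from the Lorenz-Mie series.
#'
#' @inheritParams mie_amplitudes
#' @return A list with `sigma_sca`, `sigma_ext` (um^2), `g`, `x`, `Qsca`, `Qext`.
#' @export
mie_cross_sections <- function(scatterer, wavelength) {
  stopifnot(inherits(scatterer, "sphere_scatterer"))
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("invalid parameter: 'wavelength' must be positive")
  if (scatterer$radius == 0)
    return(list(sigma_sca = 0, sigma_ext = 0, g = 0, x = 0, Qsca = 0, Qext = 0))
  x <- 2 * pi * scatterer$radius * scatterer$n_medium / (wavelength * 1e-3)
  m <- scatterer$n_particle / scatterer$n_medium
  ab <- mie_ab(x, m)
  n <- seq_len(ab$nmax)
  a <- ab$a; b <- ab$b
  Qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  Qext <- (2 / x^2) * sum((2 * n + 1) * Re(a + b))
  ## asymmetry parameter series
  a1 <- c(a[-1], 0 + 0i); b1 <- c(b[-1], 0 + 0i)
  gQ <- (4 / x^2) * (sum(n * (n + 2) / (n + 1) * Re(a * Conj(a1) + b * Conj(b1))) +
                     sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b))))
  geom <- pi * scatterer$radius^2
  list(sigma_sca = Qsca * geom, sigma_ext = Qext * geom,
       g = gQ / Qsca, x = x, Qsca = Qsca, Qext = Qext)
}

#' Full Mie solution on an angle grid
#'
#' Convenience wrapper bundling amplitudes, cross sections and the polarized
#' phase-matrix elements used by the Monte Carlo transport kernel.
#'
#' @inheritParams mie_amplitudes
#' @param n_angles Number of uniform angle samples over \[0, pi\] (default 1801).
#' @return An object of class `mie_solution` with fields `wavelength`,
#'   `size_parameter`, `sigma_sca`, `sigma_ext`, `g`, `angles`, `m11`, `m12`,
#'   `m33`, `m34`.
#' @export
mie_solution <- function(scatterer, wavelength, n_angles = 1801L) {
  angles <- seq(0, pi, length.out = n_angles)
  amp <- mie_amplitudes(scatterer, wavelength, angles)
  cs <- mie_cross_sections(scatterer, wavelength)
  pm <- phase_matrix(amp)
  structure(c(list(wavelength = wavelength, size_parameter = amp$x,
                   sigma_sca = cs$sigma_sca, sigma_ext = cs$sigma_ext,
                   g = cs$g, angles = angles), pm),
            class = "mie_solution")
}

#' Polarized phase-matrix elements of a sphere
#'
#' For spheres the single-scattering Mueller (phase) matrix is determined by
#' four elements: m11 = (|S1|^2+|S2|^2)/2, m12 = (|S2|^2-|S1|^2)/2,
#' m33 = Re(S1 S2*), m34 = Im(S1 S2*); m22 = m11 and m44 = m33 are implied.
#'
#' @param amplitudes Result of [mie_amplitudes()].
#' @return List with numeric vectors `m11`, `m12`, `m33`, `m34` per angle.
#' @export
phase_matrix <- function(amplitudes) {
  S1 <- amplitudes$S1; S2 <- amplitudes$S2
  cross <- S1 * Conj(S2)
  list(m11 = (Mod(S1)^2 + Mod(S2)^2) / 2,
       m12 = (Mod(S2)^2 - Mod(S1)^2) / 2,
       m33 = Re(cross),
       m34 = Im(cross))
}

#' Invert the scattering cross section for sphere radius
#'
#' Finds the radius whose Mie scattering cross section at a reference
#' wavelength equals a target value, restricted to the monotone-increasing
#' branch below the first maximum of sigma_sca(radius) so the inverse is
#' unique.
#'
#' @param sigma_target Target scattering cross section in um^2 (> 0).
#' @param wavelength_ref Reference wavelength in nm (default 550, mid-band of
#'   the 350--750 nm range).
#' @param n_particle,n_medium Refractive indices (defaults as in
#'   [sphere_scatterer()]).
#' @return Radius in micrometres.
#' @export
radius_from_cross_section <- function(sigma_target, wavelength_ref = 550,
                                      n_particle = 1.42, n_medium = 1.35) {
  if (!is.numeric(sigma_target) || sigma_target <= 0)
    stop("no solution: 'sigma_target' must be positive")
  sig_of_r <- function(r)
    mie_cross_sections(sphere_scatterer(r, n_particle, n_medium),
                       wavelength_ref)$sigma_sca
  ## coarse scan for the first local maximum of sigma_sca(r)
  r_grid <- seq(0.01, 6, by = 0.02)
  s_grid <- vapply(r_grid, sig_of_r, numeric(1))
  drops <- which(diff(s_grid) < 0)
  r_max <- if (length(drops)) r_grid[drops[1]] else r_grid[length(r_grid)]
  s_max <- sig_of_r(r_max)
  if (sigma_target > s_max)
    stop(sprintf(
      "no solution: sigma_target = %.3g um^2 outside attainable range (0, %.3g] um^2 on the monotone branch",
      sigma_target, s_max))
  root <- stats::uniroot(function(r) sig_of_r(r) - sigma_target,
                         lower = 1e-4, upper = r_max, tol = 1e-10)
  root$root
}

#' Scattering power from a reduced scattering spectrum
#'
#' Fits the power law mus'(lambda) ~ lambda^(-b) by least squares on the
#' log-log scale; `b` is the negative slope. Tissues dominated by small
#' scatterers have steeper spectra (larger b).
#'
#' @param wavelengths Wavelengths in nm (>= 3 samples).
#' @param musp Reduced scattering coefficients, same length, all > 0.
#' @return List with `b` and `fit_r2`.
#' @export
fit_scattering_power <- function(wavelengths, musp) {
  if (length(wavelengths) < 3L || length(musp) != length(wavelengths))
    stop("invalid spectrum: need >= 3 matched samples")
  if (any(!is.finite(musp)) || any(musp <= 0))
    stop("invalid spectrum: all reduced scattering values must be positive")
  fit <- stats::lm.fit(cbind(1, log(wavelengths)), log(musp))
  res <- fit$residuals
  tss <- sum((log(musp) - mean(log(musp)))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  list(b = -unname(fit$coefficients[2]), fit_r2 = r2)
}
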