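test_that("photon launch state matches linearly polarized normal incidence", {
  p <- launch(slab_geometry(0.1))
  expect_equal(p$stokes, c(1, 1, 0, 0))
  expect_equal(sum(p$direction * c(0, 0, 1)), 1)
  dop <- sqrt(sum(p$stokes[2:4]^2)) / p$stokes[1]
  expect_equal(dop, 1)
  expect_equal(p$weight, 1)
})

test_that("free-path sampling is exponential", {
  expect_equal(sample_step(7, u = 0.5), log(2) / 7)
  set.seed(4)
  s <- sample_step(3, u = runif(1e5))
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1 / 3), 3 * se)
  expect_equal(sample_step(6, u = 0.37), sample_step(3, u = 0.37) / 2)
  expect_error(sample_step(0), "mu_t")
})

test_that("Fresnel boundary reflectance matches closed forms", {
  expect_equal(fresnel_reflectance(1, 1.35, 1), ((1.35 - 1) / (1.35 + 1))^2,
               tolerance = 1e-12)
  expect_equal(fresnel_reflectance(1, 1.35, 1.35), 0, tolerance = 1e-12)
  ## beyond the critical angle: total internal reflection
  cos_c <- sqrt(1 - (1 / 1.35)^2)
  expect_equal(fresnel_reflectance(cos_c * 0.5, 1.35, 1), 1)
})

test_that("single-scattering Mueller algebra reproduces Rayleigh closed form", {
  ## Rayleigh at theta = pi/2: m11 = 1/2, m12 = -1/2, m33 = m34 = 0.
  ## x-polarized light scattered at phi = pi/2 stays fully polarized but is
  ## analyzed as cross-polarized.
  out <- scatter_stokes(c(1, 1, 0, 0), pi / 2, pi / 2,
                        m11 = 0.5, m12 = -0.5, m33 = 0, m34 = 0)
  expect_equal(out, c(1, -1, 0, 0), tolerance = 1e-12)
  ## physicality: I^2 >= Q^2 + U^2 + V^2 preserved under arbitrary events
  sc <- sphere_scatterer(radius_for_x(5))
  sol <- mie_solution(sc, 550)
  set.seed(9)
  for (i in 1:50) {
    th <- runif(1, 0, pi)
    k <- which.min(abs(sol$angles - th))
    s0 <- c(1, runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    s0[2:4] <- s0[2:4] / max(1, sqrt(sum(s0[2:4]^2)))
    s1 <- scatter_stokes(s0, th, runif(1, 0, 2 * pi),
                         sol$m11[k], sol$m12[k], sol$m33[k], sol$m34[k])
    expect_lte(sum(s1[2:4]^2), s1[1]^2 + 1e-9)
  }
})

test_that("scattering angle sampling matches the target distribution", {
  ## isotropic unpolarized limit: cos(theta) uniform on [-1, 1]
  ph <- isotropic_phase()
  draws <- polgate:::sample_scatter_cpp(ph$angles, ph$m11, ph$m12,
                                        c(1, 0, 0, 0), 1e5, 42)
  ks <- suppressWarnings(ks.test(cos(draws[, 1]), "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  ## phi uniform for unpolarized light
  ks2 <- suppressWarnings(ks.test(draws[, 2], "punif", 0, 2 * pi))
  expect_gt(ks2$p.value, 0.01)
  ## polarized light: azimuth density ~ 1 + (m12/m11) Q cos(2 phi); for
  ## Rayleigh-like m12 = -m11 at 90 deg the sampled phi avoids the incident
  ## polarization plane
  ang <- seq(0, pi, length.out = 1801)
  m11 <- rep(1, 1801); m12 <- rep(-0.9, 1801)
  d2 <- polgate:::sample_scatter_cpp(ang, m11, m12, c(1, 1, 0, 0), 4e4, 7)
  frac_pol_plane <- mean(abs(cos(2 * d2[, 2])) > 0.5 & cos(2 * d2[, 2]) > 0)
  frac_perp <- mean(abs(cos(2 * d2[, 2])) > 0.5 & cos(2 * d2[, 2]) < 0)
  expect_gt(frac_perp, frac_pol_plane)
})

test_that("analyzer split conserves weight and respects polarization", {
  expect_equal(unname(detect(c(1, 0, 0, 0), weight = 0.8)),
               c(0.4, 0.4))
  expect_equal(unname(detect(c(2, 2, 0, 0), weight = 1)), c(1, 0))
  set.seed(3)
  for (i in 1:20) {
    q <- runif(1, -1, 1)
    w <- runif(1)
    expect_equal(sum(detect(c(1, q, 0.1, 0), weight = w)), w,
                 tolerance = 1e-12)
  }
})

test_that("slab simulation conserves energy and is seed-deterministic", {
  sc <- sphere_scatterer(radius_from_cross_section(2))
  mie <- mie_solution(sc, 550)
  geom <- slab_geometry(20 / 202)
  ## no absorber: R + T = 1
  r0 <- simulate_slab(0, 200, mie, geom, n_photons = 5e3, seed = 2,
                      matched_boundary = TRUE)
  expect_lt(abs(r0$R_total + r0$T_total - 1), 3 / sqrt(5e3))
  ## with absorption and Fresnel boundaries: R + T + A = 1
  r1 <- simulate_slab(2, 200, mie, geom, n_photons = 5e3, seed = 2)
  expect_lt(abs(r1$R_total + r1$T_total + r1$A_total - 1), 3 / sqrt(5e3))
  expect_gte(r1$R_co, 0)
  expect_gte(r1$R_cross, 0)
  expect_equal(r1$R_total, r1$R_co + r1$R_cross, tolerance = 1e-12)
  ## determinism
  r2 <- simulate_slab(2, 200, mie, geom, n_photons = 5e3, seed = 2)
  expect_identical(r1$R_co, r2$R_co)
  expect_identical(r1$T_total, r2$T_total)
  ## unpolarized illumination: co/cross symmetric within sampling noise
  r3 <- simulate_slab(2, 200, mie, geom, n_photons = 2e4, seed = 5,
                      stokes = c(1, 0, 0, 0))
  se <- sqrt(r3$R_total / 2e4)
  expect_lt(abs(r3$R_co - r3$R_cross), 3 * se)
})

test_that("similarity relation: forward-peaked and isotropic phases agree on musp", {
  ## Henyey-Greenstein-shaped intensity phase function, g = 0.9
  g <- 0.9
  ang <- seq(0, pi, length.out = 1801)
  hg <- (1 - g^2) / (1 + g^2 - 2 * g * cos(ang))^1.5
  fwd <- list(angles = ang, m11 = hg, m12 = rep(0, 1801),
              m33 = rep(0, 1801), m34 = rep(0, 1801))
  iso <- isotropic_phase()
  musp <- 15
  D <- 2 / musp  # transport-equivalent thickness of 2 for both runs
  rf <- simulate_slab(0.5, musp / (1 - g), fwd, slab_geometry(D),
                      n_photons = 3e4, seed = 8, stokes = c(1, 0, 0, 0))
  ri <- simulate_slab(0.5, musp, iso, slab_geometry(D),
                      n_photons = 3e4, seed = 9, stokes = c(1, 0, 0, 0))
  expect_lt(abs(rf$R_total - ri$R_total) / ri$R_total, 0.05)
})

test_that("depolarization grows with scattering order and gates depth", {
  ## thin slab so low scattering orders are well populated among the exits
  sc <- sphere_scatterer(radius_from_cross_section(2))
  mie <- mie_solution(sc, 550)
  res <- simulate_slab(0.5, 100, mie, slab_geometry(0.05), n_photons = 4e6,
                       seed = 12, collect_exits = TRUE)
  ns <- res$exit_n_scatter
  ratio <- vapply(1:10, function(k) {
    sel <- ns == k
    sum(res$exit_co[sel]) / sum(res$exit_cross[sel])
  }, numeric(1))
  ## co/cross ratio decreases with the number of scattering events
  expect_true(all(diff(ratio) < 0))
  ## polarization-gated depth: the (co - cross) weighted mean maximum depth is
  ## shallower than the (co + cross) weighted one
  d_gated <- sum(res$exit_max_depth * (res$exit_co - res$exit_cross)) /
    sum(res$exit_co - res$exit_cross)
  d_total <- sum(res$exit_max_depth * (res$exit_co + res$exit_cross)) /
    sum(res$exit_co + res$exit_cross)
  expect_lt(d_gated, d_total)
})

test_that("lookup table construction is complete and reproducible", {
  g <- build_parameter_grid(musp_values = c(15, 30), sigma_values = c(1, 4),
                            bvf_values = 0.006)
  wl <- c(450, 550, 650)
  lut1 <- build_lookup_table(g, wavelengths = wl, n_photons = 500, seed = 3)
  expect_equal(nrow(lut1$points), 2 * 2 * 1)
  expect_equal(nrow(lut1$spectra), 4 * 3)
  expect_true(all(is.finite(as.matrix(lut1$points[sapply(lut1$points, is.numeric)]))))
  lut2 <- build_lookup_table(g, wavelengths = wl, n_photons = 500, seed = 3)
  expect_identical(lut1$points, lut2$points)
  expect_identical(lut1$spectra, lut2$spectra)
  ## round trip through CSV
  path <- tempfile(fileext = ".csv")
  write_lookup_table(lut1, path)
  lut3 <- read_lookup_table(path)
  expect_equal(lut3$points$dB, lut1$points$dB, tolerance = 1e-12)
})
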