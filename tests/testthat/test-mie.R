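test_that("Mie quantities match the arbitrary-precision series oracle", {
  for (case in mie_oracle_tissue) {
    r <- radius_for_x(case$x)
    sc <- sphere_scatterer(r)
    cs <- mie_cross_sections(sc, 550)
    expect_lt(abs(cs$Qsca - case$Qsca) / case$Qsca, 1e-8)
    expect_lt(abs(cs$g - case$g) / abs(case$g), 1e-8)
    mus <- as.numeric(names(case$S))
    amp <- mie_amplitudes(sc, 550, acos(mus))
    ## relative to the amplitude scale of the case (|S2(90 deg)| can be
    ## 10^4-fold smaller than |S1| through cancellation; element-wise
    ## relative error is not meaningful there)
    scale <- max(vapply(case$S, function(s) max(Mod(s$S1), Mod(s$S2)),
                        numeric(1)))
    for (i in seq_along(mus)) {
      expect_lt(Mod(amp$S1[i] - case$S[[i]]$S1) / scale, 1e-8)
      expect_lt(Mod(amp$S2[i] - case$S[[i]]$S2) / scale, 1e-8)
    }
  }
  ## low-contrast spheres, m = 1.05
  for (case in mie_oracle_m105) {
    r <- radius_for_x(case$x)
    sc <- sphere_scatterer(r, n_particle = 1.05 * 1.35, n_medium = 1.35)
    cs <- mie_cross_sections(sc, 550)
    expect_lt(abs(cs$Qsca - case$Qsca) / case$Qsca, 1e-8)
    mus <- as.numeric(names(case$S))
    amp <- mie_amplitudes(sc, 550, acos(mus))
    pm <- phase_matrix(amp)
    for (i in seq_along(mus)) {
      o <- case$S[[i]]
      expect_lt(Mod(amp$S1[i] - o$S1) / Mod(o$S1), 1e-8)
      expect_lt(Mod(amp$S2[i] - o$S2) / Mod(o$S2), 1e-8)
      if (!is.null(o$m11)) {
        expect_lt(abs(pm$m11[i] - o$m11) / o$m11, 1e-8)
        expect_lt(abs(pm$m12[i] - o$m12) / abs(o$m12), 1e-8)
        expect_lt(abs(pm$m33[i] - o$m33) / abs(o$m33), 1e-8)
        expect_lt(abs(pm$m34[i] - o$m34) / abs(o$m34), 1e-8)
      }
    }
  }
})

test_that("Rayleigh and degenerate limits behave", {
  ## x -> 0: amplitudes vanish, degree of linear polarization at 90 deg -> 1
  sc <- sphere_scatterer(radius_for_x(1e-3))
  amp <- mie_amplitudes(sc, 550, c(0, pi / 2, pi))
  expect_true(all(Mod(amp$S1) < 1e-8))
  expect_true(all(is.finite(Mod(amp$S1))) && all(is.finite(Mod(amp$S2))))
  pm <- phase_matrix(amp)
  expect_equal(-pm$m12[2] / pm$m11[2], 1, tolerance = 1e-4)
  ## Rayleigh anisotropy ~ 0
  expect_lt(abs(mie_cross_sections(sc, 550)$g), 1e-3)
  ## zero radius: no scatterer
  amp0 <- mie_amplitudes(sphere_scatterer(0), 550, c(0, 1, pi))
  expect_true(all(amp0$S1 == 0) && all(amp0$S2 == 0))
  ## invalid parameters
  expect_error(sphere_scatterer(-1), "radius")
  expect_error(mie_amplitudes(sc, -5, 0), "wavelength")
})

test_that("optical theorem and phase-function normalization hold", {
  for (x in c(0.5, 5, 20)) {
    sc <- sphere_scatterer(radius_for_x(x))
    cs <- mie_cross_sections(sc, 550)
    expect_lt(abs(cs$sigma_ext - cs$sigma_sca) / cs$sigma_sca, 1e-10)
  }
  ## sigma_sca equals the angular integral of m11 over the sphere
  sc <- sphere_scatterer(radius_for_x(5))
  sol <- mie_solution(sc, 550)
  k <- 2 * pi * 1.35 / (550 * 1e-3)  # per um
  integ <- 2 * pi / k^2 *
    sum((sol$m11 * sin(sol$angles))[-1] + (sol$m11 * sin(sol$angles))[-1801]) /
    2 * diff(sol$angles[1:2])
  expect_equal(integ, sol$sigma_sca, tolerance = 1e-4)
})

test_that("phase matrix elements satisfy sphere constraints", {
  sc <- sphere_scatterer(radius_for_x(3, n_medium = 1.35), 1.05 * 1.35, 1.35)
  sol <- mie_solution(sc, 550)
  expect_true(all(sol$m11 >= 0))
  expect_true(all(abs(sol$m12) <= sol$m11 + 1e-12))
  expect_true(all(abs(sol$m34) <= sol$m11 + 1e-12))
  ## forward scattering: S1(0) = S2(0) so m12(0) = 0
  expect_lt(abs(sol$m12[1]) / sol$m11[1], 1e-12)
})

test_that("cross-section inversion is a consistent round trip", {
  for (sig in c(0.5, 2, 8)) {
    r <- radius_from_cross_section(sig)
    achieved <- mie_cross_sections(sphere_scatterer(r), 550)$sigma_sca
    expect_lt(abs(achieved - sig), 1e-6)
  }
  ## dense-scan oracle for the smallest grid value
  r05 <- radius_from_cross_section(0.5)
  rs <- seq(0.3, 0.9, by = 0.001)
  ss <- vapply(rs, function(r)
    mie_cross_sections(sphere_scatterer(r), 550)$sigma_sca, numeric(1))
  r_scan <- rs[which.min(abs(ss - 0.5))]
  expect_lt(abs(r05 - r_scan), 2e-3)
  expect_error(radius_from_cross_section(-1), "no solution")
  expect_error(radius_from_cross_section(500), "no solution")
})

test_that("scattering power fit recovers exact power laws and is scale invariant", {
  wl <- seq(350, 750, by = 25)
  fit <- fit_scattering_power(wl, 3.2 * wl^-1.2)
  expect_equal(fit$b, 1.2, tolerance = 1e-12)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
  expect_equal(fit_scattering_power(wl, rep(4, length(wl)))$b, 0,
               tolerance = 1e-12)
  ## scale invariance
  musp <- 10 * wl^-0.7 * exp(0.1 * sin(wl / 50))
  expect_equal(fit_scattering_power(wl, musp)$b,
               fit_scattering_power(wl, 7.3 * musp)$b, tolerance = 1e-12)
  expect_error(fit_scattering_power(wl, c(-1, rep(1, length(wl) - 1))),
               "invalid spectrum")
  expect_error(fit_scattering_power(c(500, 600), c(1, 2)), "invalid spectrum")
  ## independent log-log regression oracle on a Mie spectrum
  r <- radius_from_cross_section(0.5)
  sc <- sphere_scatterer(r)
  sig <- vapply(wl, function(l) mie_cross_sections(sc, l)$sigma_sca, numeric(1))
  musp_mie <- 20 * sig / sig[wl == 550]
  x <- log(wl); y <- log(musp_mie)
  b_oracle <- -sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit_scattering_power(wl, musp_mie)$b, b_oracle,
               tolerance = 1e-10)
})
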