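test_that("phantom rendering passes lookup values through when artifact-free", {
  lut <- reference_lut()
  spec <- phantom_spec(size = c(32L, 32L), lesions = list(),
                       deep_fraction = 0, vignette_ratio = 1,
                       noise = list(read_sigma_dn = 0, shot_gain = 0),
                       gain_dn = 100, seed = 1)
  ph <- render_phantom(spec, lut)
  row <- lut$points[abs(lut$points$sigma - 6) < 1e-9 &
                      abs(lut$points$musp - 20) < 1e-9, ]
  expect_equal(ph$pair$co[1, 1, 1], 100 * row$co_r, tolerance = 1e-9)
  expect_equal(ph$pair$cross[5, 7, 3], 100 * row$cross_b, tolerance = 1e-9)
  expect_equal(length(unique(as.vector(ph$pair$co))), 3)  # one value per channel
  ## WLL/PEL of the constant frames match the tabulated scalars
  wll <- compute_wll(ph$pair)[1, 1] / 100
  pel <- compute_pel(ph$pair)[1, 1] / 100
  expect_equal(wll, row$WLL, tolerance = 1e-9)
  expect_equal(pel, row$PEL, tolerance = 1e-9)
})

test_that("phantom generation is deterministic per seed with fixed ground truth", {
  lut <- reference_lut()
  s1 <- phantom_spec(size = c(48L, 48L), seed = 5)
  ph_a <- render_phantom(s1, lut)
  ph_b <- render_phantom(s1, lut)
  expect_identical(ph_a$pair$co, ph_b$pair$co)
  s2 <- phantom_spec(size = c(48L, 48L), seed = 6)
  ph_c <- render_phantom(s2, lut)
  expect_false(identical(ph_a$pair$co, ph_c$pair$co))
  expect_identical(ph_a$lesion_mask, ph_c$lesion_mask)
  expect_identical(ph_a$b_map, ph_c$b_map)
})

test_that("noise-free phantoms satisfy co >= cross pixelwise", {
  lut <- reference_lut()
  spec <- phantom_spec(size = c(64L, 64L),
                       noise = list(read_sigma_dn = 0, shot_gain = 0),
                       seed = 2)
  ph <- render_phantom(spec, lut)
  expect_true(all(ph$pair$co >= ph$pair$cross))
  ## lesion has higher scattering power than background
  expect_gt(mean(ph$b_map[ph$lesion_mask]), mean(ph$b_map[!ph$lesion_mask]))
  ## unknown grid point is refused
  bad <- phantom_spec(background = list(musp = 20, sigma = 3.33, bvf = 0.006))
  expect_error(render_phantom(bad, lut), "extrapolation")
})

test_that("von Mises sampling spans alignment regimes", {
  ## near-degenerate concentration: all angles at the mean
  fb_tight <- render_fibers(fiber_spec(n_fibers = 100, kappa = 1e6, seed = 3))
  expect_lt(fb_tight$true_variance, 0.01)
  expect_lt(max(abs(sin(fb_tight$angles - pi / 6))), 0.05)
  ## kappa = 0: uniform axial angles, variance near 1
  fb_flat <- render_fibers(fiber_spec(n_fibers = 400, kappa = 0, seed = 4))
  expect_gt(fb_flat$true_variance, 0.85)
  ## distribution check against the analytic circular variance of a
  ## moderately concentrated von Mises (I1/I0 ratio)
  set.seed(7)
  psi <- rvonmises(2e4, 1.2, 2)
  R <- sqrt(mean(cos(psi))^2 + mean(sin(psi))^2)
  R_true <- besselI(2, 1) / besselI(2, 0)
  expect_lt(abs(R - R_true), 0.01)
  expect_error(rvonmises(5, 0, -1), "kappa")
})

test_that("single-fiber images count their own area", {
  fb <- render_fibers(fiber_spec(n_fibers = 1, background_noise = 0,
                                 length_range = c(40, 40), seed = 8))
  mask <- fb$image > 0.5
  expect_equal(area_fraction(mask), sum(mask) / prod(dim(fb$image)))
  expect_gt(sum(mask), 40)            # at least the fiber spine
  expect_lt(mean(mask), 0.01)         # sparse field
})

test_that("fixture suite is reproducible and matches its manifest", {
  lut <- reference_lut()
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  m1 <- make_fixture_suite(d1, seed = 3, lut = lut)
  m2 <- make_fixture_suite(d2, seed = 3, lut = lut)
  files <- c(vapply(m1$phantoms, `[[`, character(1), "co"),
             vapply(m1$phantoms, `[[`, character(1), "cross"),
             vapply(m1$fibers, `[[`, character(1), "file"))
  expect_true(all(file.exists(file.path(d1, files))))
  h1 <- tools::md5sum(file.path(d1, files))
  h2 <- tools::md5sum(file.path(d2, files))
  expect_true(all(unname(h1) == unname(h2)))
  expect_equal(length(m1$fibers), 3)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("glare exclusion protects lesion statistics", {
  lut <- reference_lut()
  cf <- fit_mpel(lut)
  lesion <- list(list(cx = 48, cy = 48, rx = 20, ry = 15, sigma = 1,
                      class = "malignant-like"))
  glare_in_lesion <- list(list(cx = 48, cy = 48, rx = 9, ry = 7))
  base_spec <- phantom_spec(size = c(96L, 96L), lesions = lesion, seed = 9)
  glare_spec <- phantom_spec(size = c(96L, 96L), lesions = lesion,
                             glare = glare_in_lesion, seed = 9)
  lesion_mean <- function(ph, glare_exclusion) {
    out <- run_frame(ph$pair, coeffs = cf, glare_exclusion = glare_exclusion)
    diffs <- out$co - out$cross
    m <- cf$a0 + cf$a1 * diffs[, , 1] + cf$a2 * diffs[, , 2] +
      cf$a3 * diffs[, , 3]
    sel <- ph$lesion_mask & !out$excluded_mask
    mean(m[sel])
  }
  ph0 <- render_phantom(base_spec, lut)
  ph1 <- render_phantom(glare_spec, lut)
  ref <- lesion_mean(ph0, TRUE)
  masked <- lesion_mean(ph1, TRUE)
  disabled <- lesion_mean(ph1, FALSE)
  expect_lt(abs(masked - ref) / abs(ref), 0.02)
  expect_gt(abs(disabled - ref) / abs(ref), 0.02)
})

test_that("a malignant-like phantom shows lesion mPEL and PEL contrast end-to-end", {
  lut <- reference_lut()
  cf <- fit_mpel(lut)
  ph <- render_phantom(phantom_spec(size = c(96L, 96L), seed = 11), lut)
  out <- run_frame(ph$pair, coeffs = cf)
  rois <- matrix(0L, 96, 96); rois[ph$lesion_mask] <- 1L
  rec_mpel <- contrast_records(out$mpel, rois, out$excluded_mask, "mPEL")
  expect_gt(rec_mpel$I_f, rec_mpel$I_b)
  ## polarization gating: the lesion's Weber contrast is stronger under PEL
  ## than under WLL (the depolarized deep term dilutes WLL)
  rec_pel <- contrast_records(out$pel, rois, out$excluded_mask, "PEL")
  rec_wll <- contrast_records(out$wll, rois, out$excluded_mask, "WLL")
  expect_gt(rec_pel$C_W, rec_wll$C_W)
})
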