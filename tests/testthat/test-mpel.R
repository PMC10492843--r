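make_pair <- function(co, cross) polarized_frame_pair(co, cross)

test_that("WLL and PEL images follow the channel sums and differences", {
  u <- array(1, c(4, 4, 3))
  pair <- make_pair(u, u)
  expect_equal(compute_wll(pair), matrix(6, 4, 4))
  expect_equal(compute_pel(pair), matrix(0, 4, 4))
  z <- array(0, c(4, 4, 3))
  expect_equal(compute_wll(make_pair(z, z)), matrix(0, 4, 4))
  ## cross = 0: fully polarization-preserving scene, PEL = WLL
  set.seed(1)
  co <- array(runif(48), c(4, 4, 3))
  p0 <- make_pair(co, z)
  expect_equal(compute_pel(p0), compute_wll(p0))
  ## algebraic identity WLL - PEL = 2 * sum of cross channels
  cross <- array(runif(48), c(4, 4, 3))
  pr <- make_pair(co, cross)
  expect_equal(compute_wll(pr) - compute_pel(pr),
               2 * (cross[, , 1] + cross[, , 2] + cross[, , 3]),
               tolerance = 1e-12)
  ## hand-computed 2x2 example
  co2 <- array(c(1, 2, 3, 4,  5, 6, 7, 8,  9, 10, 11, 12), c(2, 2, 3))
  cr2 <- array(c(0.5, 1, 1, 2,  2, 3, 3, 4,  4, 5, 5, 6), c(2, 2, 3))
  expect_equal(compute_pel(make_pair(co2, cr2)),
               matrix(c(1 - 0.5 + 5 - 2 + 9 - 4,
                        2 - 1 + 6 - 3 + 10 - 5,
                        3 - 1 + 7 - 3 + 11 - 5,
                        4 - 2 + 8 - 4 + 12 - 6), 2, 2))
  expect_error(make_pair(u, array(1, c(3, 4, 3))), "shape mismatch")
})

test_that("mPEL regression recovers linear relations", {
  set.seed(7)
  n <- 60
  X <- data.frame(dR = runif(n), dG = runif(n), dB = runif(n))
  ## noiseless: coefficients recovered to float precision (suppress the
  ## perfect-fit advisory from summary.lm)
  X$b <- 0.2 + 1.0 * X$dR - 0.5 * X$dG + 2.0 * X$dB
  cf <- suppressWarnings(fit_mpel(X))
  expect_equal(c(cf$a0, cf$a1, cf$a2, cf$a3), c(0.2, 1.0, -0.5, 2.0),
               tolerance = 1e-10)
  expect_equal(cf$r2, 1, tolerance = 1e-10)
  expect_identical(cf$provenance, "fitted")
  ## constant response: zero slopes, intercept = b
  X2 <- X; X2$b <- 0.7
  cf2 <- suppressWarnings(fit_mpel(X2))
  expect_equal(c(cf2$a0, cf2$a1, cf2$a2, cf2$a3), c(0.7, 0, 0, 0),
               tolerance = 1e-10)
  ## noisy: against an independent normal-equations oracle, within 3 SE
  set.seed(11)
  n <- 1000
  Xn <- data.frame(dR = runif(n), dG = runif(n), dB = runif(n))
  truth <- c(0.3, 0.8, -0.4, 1.5)
  Xn$b <- truth[1] + truth[2] * Xn$dR + truth[3] * Xn$dG + truth[4] * Xn$dB +
    rnorm(n, 0, 0.05)
  cfn <- fit_mpel(Xn)
  M <- cbind(1, Xn$dR, Xn$dG, Xn$dB)
  beta_oracle <- solve(t(M) %*% M, t(M) %*% Xn$b)
  expect_equal(c(cfn$a0, cfn$a1, cfn$a2, cfn$a3), as.vector(beta_oracle),
               tolerance = 1e-8)
  expect_true(all(abs(c(cfn$a0, cfn$a1, cfn$a2, cfn$a3) - truth) <
                    3 * cfn$se))
  ## degenerate designs are refused with the offending columns named
  Xr <- Xn; Xr$dG <- 2 * Xr$dR
  expect_error(fit_mpel(Xr), "collinear")
  expect_error(fit_mpel(Xn[1:4, ]), "at least 5")
})

test_that("published coefficient set evaluates the worked examples", {
  cf <- paper_coefficients()
  expect_identical(cf$provenance, "paper")
  expect_equal(apply_mpel(c(0, 0, 0), cf), 0.4705)
  expect_equal(apply_mpel(c(10, 10, 10), cf), 1.4625, tolerance = 1e-12)
  ## red channel weight isolated
  expect_equal(apply_mpel(c(1, 0, 0), cf) - apply_mpel(c(0, 0, 0), cf),
               -0.0073, tolerance = 1e-12)
})

test_that("mPEL application is affine and saturates rasters", {
  cf <- mpel_coefficients(0.1, -0.2, 0.3, 1.0)
  d1 <- c(0.5, 0.1, 0.9); d2 <- c(0.2, 0.8, 0.3)
  lam <- 0.3
  expect_equal(apply_mpel(lam * d1 + (1 - lam) * d2, cf),
               lam * apply_mpel(d1, cf) + (1 - lam) * apply_mpel(d2, cf),
               tolerance = 1e-12)
  ## raster path: outliers clipped at the 1%/99% quantiles
  set.seed(2)
  arr <- array(runif(30000), c(100, 100, 3))
  m_raw <- apply_mpel(arr, cf, saturate = FALSE)
  m_sat <- apply_mpel(arr, cf, saturate = TRUE)
  q <- quantile(m_raw, c(0.01, 0.99), names = FALSE)
  expect_equal(max(m_sat), q[2], tolerance = 1e-12)
  expect_equal(min(m_sat), q[1], tolerance = 1e-12)
  ## coefficient JSON round trip
  path <- tempfile(fileext = ".json")
  write_coefficients(cf, path)
  cf2 <- read_coefficients(path)
  expect_equal(cf2$a3, 1.0)
  expect_identical(cf2$provenance, "fitted")
})
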