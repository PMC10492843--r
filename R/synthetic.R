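#' Packaged reference lookup table
#'
#' A small pre-built co/cross reflectance lookup table (one musp and blood
#' volume fraction, six scattering cross sections), produced by the package's
#' own Monte Carlo at a fixed seed, so phantom fixtures build in seconds.
#'
#' @return A `reflectance_lut`.
#' @export
reference_lut <- function() {
  read_lookup_table(system.file("extdata", "lut_reference.csv",
                                package = "polgate", mustWork = TRUE))
}

#' Phantom specification
#'
#' Describes a synthetic co/cross-polarized frame pair: uniform background
#' tissue drawn from a lookup-table grid point, elliptical lesions with
#' different (typically higher) scattering power, a radial multiplicative
#' illumination vignette, specular glare ellipses (saturating the co frame,
#' near-extinguished in the cross frame), an additive depolarized deep-tissue
#' term (equal in co and cross), signal-dependent noise, and an optional
#' co/cross misregistration offset.
#'
#' @param size c(rows, cols) in pixels.
#' @param background list(musp, sigma, bvf) selecting the background grid point.
#' @param lesions list of lesions: list(cx, cy, rx, ry, sigma, class) in
#'   pixel units; class is "malignant-like" or "benign-like".
#' @param deep_fraction Depolarized additive term as a fraction of the mean
#'   background co signal (models deep-tissue light; equal in co and cross).
#' @param vignette_ratio Center-to-corner illumination ratio (1 = flat).
#' @param glare list of ellipses list(cx, cy, rx, ry).
#' @param noise list(read_sigma_dn, shot_gain): Gaussian read noise in DN and
#'   the Poisson-like shot-noise gain (variance = shot_gain * DN).
#' @param misregistration c(dy, dx) sub-pixel shift applied to the cross frame.
#' @param gain_dn Digital numbers per unit lookup-table reflectance signal
#'   (12-bit range; defaults to put the background co signal near 2000 DN).
#' @param seed Integer seed for the noise realization.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128L, 128L),
                         background = list(musp = 20, sigma = 6, bvf = 0.006),
                         lesions = list(list(cx = 64, cy = 64, rx = 22,
                                             ry = 16, sigma = 1,
                                             class = "malignant-like")),
                         deep_fraction = 0.5,
                         vignette_ratio = 1.5,
                         glare = list(),
                         noise = list(read_sigma_dn = 2, shot_gain = 1),
                         misregistration = c(0, 0),
                         gain_dn = NULL,
                         seed = 1L) {
  structure(list(size = size, background = background, lesions = lesions,
                 deep_fraction = deep_fraction,
                 vignette_ratio = vignette_ratio, glare = glare,
                 noise = noise, misregistration = misregistration,
                 gain_dn = gain_dn, seed = seed),
            class = "phantom_spec")
}

## look up one grid point's co/cross RGB triples in a lut, exact match
.lut_row <- function(lut, musp, sigma, bvf) {
  pts <- lut$points
  hit <- which(abs(pts$musp - musp) < 1e-9 & abs(pts$sigma - sigma) < 1e-9 &
               abs(pts$bvf - bvf) < 1e-9)
  if (length(hit) != 1L)
    stop(sprintf(
      "extrapolation error: grid point (musp=%g, sigma=%g, bvf=%g) not in lookup table",
      musp, sigma, bvf))
  pts[hit, ]
}

.ellipse_mask <- function(size, cx, cy, rx, ry) {
  row <- matrix(seq_len(size[1]), size[1], size[2])
  col <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  ((col - cx) / rx)^2 + ((row - cy) / ry)^2 <= 1
}

## bilinear sub-pixel translation, replicate boundary
.shift_image <- function(x, dy, dx) {
  if (dy == 0 && dx == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) - dy, 1), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1), nc)
  r0 <- floor(ri); r1 <- pmin(r0 + 1, nr); fr <- ri - r0
  c0 <- floor(ci); c1 <- pmin(c0 + 1, nc); fc <- ci - c0
  a <- x[r0, c0]; b <- x[r1, c0]; cc <- x[r0, c1]; d <- x[r1, c1]
  FR <- matrix(fr, nr, nc); FC <- matrix(fc, nr, nc, byrow = TRUE)
  (1 - FR) * (1 - FC) * a + FR * (1 - FC) * b + (1 - FR) * FC * cc + FR * FC * d
}

#' Render a synthetic co/cross-polarized phantom
#'
#' Builds a 12-bit frame pair from lookup-table reflectance triples plus the
#' acquisition artifacts described in the [phantom_spec()], together with the
#' pixelwise ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param lut A `reflectance_lut` covering the requested grid points
#'   (default: the packaged [reference_lut()]).
#' @return List: `pair` ([polarized_frame_pair()]), `b_map`, `lesion_mask`,
#'   `glare_mask`, `spec`.
#' @export
render_phantom <- function(spec = phantom_spec(), lut = reference_lut()) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$size
  bgrow <- .lut_row(lut, spec$background$musp, spec$background$sigma,
                    spec$background$bvf)
  co <- array(0, c(size, 3)); cross <- array(0, c(size, 3))
  b_map <- matrix(bgrow$b, size[1], size[2])
  lesion_mask <- matrix(FALSE, size[1], size[2])
  fill <- function(arr, mask, triple) {
    for (ch in 1:3) {
      pl <- arr[, , ch]
      pl[mask] <- triple[ch]
      arr[, , ch] <- pl
    }
    arr
  }
  all_px <- matrix(TRUE, size[1], size[2])
  co <- fill(co, all_px, c(bgrow$co_r, bgrow$co_g, bgrow$co_b))
  cross <- fill(cross, all_px, c(bgrow$cross_r, bgrow$cross_g, bgrow$cross_b))
  for (les in spec$lesions) {
    lrow <- .lut_row(lut, spec$background$musp, les$sigma, spec$background$bvf)
    m <- .ellipse_mask(size, les$cx, les$cy, les$rx, les$ry)
    lesion_mask <- lesion_mask | m
    b_map[m] <- lrow$b
    co <- fill(co, m, c(lrow$co_r, lrow$co_g, lrow$co_b))
    cross <- fill(cross, m, c(lrow$cross_r, lrow$cross_g, lrow$cross_b))
  }
  ## depolarized deep-tissue term: equal in co and cross
  deep <- spec$deep_fraction * mean(c(bgrow$co_r, bgrow$co_g, bgrow$co_b))
  co <- co + deep
  cross <- cross + deep
  ## digital-number scale and radial vignette
  gain <- if (is.null(spec$gain_dn)) 2000 / max(co) else spec$gain_dn
  row <- matrix(seq_len(size[1]), size[1], size[2])
  col <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  r2 <- ((row - (size[1] + 1) / 2)^2 + (col - (size[2] + 1) / 2)^2)
  vig <- 1 / (1 + (spec$vignette_ratio - 1) * r2 / max(r2))
  co <- co * gain; cross <- cross * gain
  for (ch in 1:3) {
    co[, , ch] <- co[, , ch] * vig
    cross[, , ch] <- cross[, , ch] * vig
  }
  ## specular glare: saturates co, extinguished in cross
  glare_mask <- matrix(FALSE, size[1], size[2])
  for (gl in spec$glare) {
    m <- .ellipse_mask(size, gl$cx, gl$cy, gl$rx, gl$ry)
    glare_mask <- glare_mask | m
  }
  if (any(glare_mask)) {
    for (ch in 1:3) {
      pl <- co[, , ch]; pl[glare_mask] <- 4095; co[, , ch] <- pl
      pl <- cross[, , ch]; pl[glare_mask] <- pl[glare_mask] * 0.02
      cross[, , ch] <- pl
    }
  }
  ## misregistration of the cross frame
  if (any(spec$misregistration != 0)) {
    for (ch in 1:3)
      cross[, , ch] <- .shift_image(cross[, , ch], spec$misregistration[1],
                                    spec$misregistration[2])
  }
  ## signal-dependent noise after all optics
  set.seed(spec$seed)
  n_px <- prod(size) * 3
  shot <- spec$noise$shot_gain
  co <- co + stats::rnorm(n_px, 0, sqrt(pmax(shot * co, 0))) +
    stats::rnorm(n_px, 0, spec$noise$read_sigma_dn)
  cross <- cross + stats::rnorm(n_px, 0, sqrt(pmax(shot * cross, 0))) +
    stats::rnorm(n_px, 0, spec$noise$read_sigma_dn)
  co <- pmin(pmax(co, 0), 4095)
  cross <- pmin(pmax(cross, 0), 4095)
  list(pair = polarized_frame_pair(co, cross, bit_depth = 12),
       b_map = b_map, lesion_mask = lesion_mask, glare_mask = glare_mask,
       spec = spec)
}

#' Sample von Mises angles
#'
#' Best-Fisher rejection sampler; kappa = 0 gives the uniform distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (>= 0).
#' @return Angles in \[0, 2 pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("invalid parameter: kappa must be >= 0")
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  bb <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + bb^2) / (2 * bb)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      i <- i + 1L
      out[i] <- (sign(u3 - 0.5) * acos(f) + mu) %% (2 * pi)
    }
  }
  out
}

#' Fiber image specification
#'
#' @param n_fibers Number of fiber segments (>= 1).
#' @param size c(rows, cols), px.
#' @param mean_orientation Mean fiber axis, radians in \[0, pi).
#' @param kappa von Mises concentration of the doubled axial angles
#'   (0 = uniform orientations, large = aligned).
#' @param length_range Segment length range, px.
#' @param width Gaussian half-width of the fiber profile, px.
#' @param background_noise Additive Gaussian noise sd (intensity units).
#' @param seed Integer seed.
#' @return Object of class `fiber_spec`.
#' @export
fiber_spec <- function(n_fibers = 200L, size = c(256L, 256L),
                       mean_orientation = pi / 6, kappa = 8,
                       length_range = c(30, 60), width = 1.5,
                       background_noise = 0.02, seed = 1L) {
  if (n_fibers < 1L) stop("invalid parameter: n_fibers must be >= 1")
  if (kappa < 0) stop("invalid parameter: kappa must be >= 0")
  structure(list(n_fibers = n_fibers, size = size,
                 mean_orientation = mean_orientation, kappa = kappa,
                 length_range = length_range, width = width,
                 background_noise = background_noise, seed = seed),
            class = "fiber_spec")
}

#' Render a synthetic SHG-like fiber image
#'
#' Anti-aliased line segments with von Mises-distributed axial orientations
#' (sampled on the doubled-angle scale). Returns the analytic ground truth:
#' the circular variance of the sampled doubled angles.
#'
#' @param spec A [fiber_spec()].
#' @return List: `image` (matrix), `angles` (axial, \[0, pi)),
#'   `true_variance` (1 - resultant length of the doubled angles).
#' @export
render_fibers <- function(spec = fiber_spec()) {
  stopifnot(inherits(spec, "fiber_spec"))
  set.seed(spec$seed)
  size <- spec$size
  psi <- rvonmises(spec$n_fibers, 2 * spec$mean_orientation, spec$kappa)
  theta <- (psi / 2) %% pi
  img <- matrix(0, size[1], size[2])
  for (i in seq_len(spec$n_fibers)) {
    len <- stats::runif(1, spec$length_range[1], spec$length_range[2])
    cx <- stats::runif(1, 1, size[2])
    cy <- stats::runif(1, 1, size[1])
    dx <- cos(theta[i]); dy <- sin(theta[i])
    x0 <- cx - dx * len / 2; x1 <- cx + dx * len / 2
    y0 <- cy - dy * len / 2; y1 <- cy + dy * len / 2
    pad <- ceiling(3 * spec$width)
    rr <- max(1, floor(min(y0, y1)) - pad):min(size[1], ceiling(max(y0, y1)) + pad)
    cc <- max(1, floor(min(x0, x1)) - pad):min(size[2], ceiling(max(x0, x1)) + pad)
    if (length(rr) == 0 || length(cc) == 0) next
    py <- matrix(rr, length(rr), length(cc))
    px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    ## distance from pixel to the segment
    vx <- x1 - x0; vy <- y1 - y0
    t <- pmin(pmax(((px - x0) * vx + (py - y0) * vy) / (vx^2 + vy^2), 0), 1)
    d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
    img[rr, cc] <- img[rr, cc] + exp(-d2 / (2 * spec$width^2))
  }
  img <- pmin(img, 1.5)
  if (spec$background_noise > 0)
    img <- pmax(img + matrix(stats::rnorm(prod(size), 0, spec$background_noise),
                             size[1], size[2]), 0)
  c2 <- mean(cos(psi)); s2 <- mean(sin(psi))
  list(image = img, angles = theta, true_variance = 1 - sqrt(c2^2 + s2^2))
}

#' Write the canonical fixture suite to disk
#'
#' Three phantoms (benign-like, malignant-like, glare-heavy), three fiber
#' images (kappa 0.5, 2, 8), 16-bit TIFF frames plus a JSON manifest with the
#' ground truth. Byte-reproducible for a fixed seed.
#'
#' @param outdir Writable directory (created if missing).
#' @param seed Base seed.
#' @param lut Lookup table for the phantoms.
#' @return Invisibly, the manifest list.
#' @export
make_fixture_suite <- function(outdir, seed = 1L, lut = reference_lut()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    benign = phantom_spec(lesions = list(list(cx = 64, cy = 64, rx = 22,
                                              ry = 16, sigma = 4,
                                              class = "benign-like")),
                          seed = seed),
    malignant = phantom_spec(seed = seed + 1L),
    glare = phantom_spec(glare = list(list(cx = 36, cy = 36, rx = 9, ry = 7),
                                      list(cx = 96, cy = 70, rx = 7, ry = 10)),
                         seed = seed + 2L))
  manifest <- list(seed = seed, phantoms = list(), fibers = list())
  write_frame <- function(img, path) {
    tiff::writeTIFF(img / 4095, path, bits.per.sample = 16L,
                    compression = "none")
  }
  for (nm in names(specs)) {
    ph <- render_phantom(specs[[nm]], lut)
    co_p <- file.path(outdir, paste0("phantom_", nm, "_co.tif"))
    cr_p <- file.path(outdir, paste0("phantom_", nm, "_cross.tif"))
    write_frame(ph$pair$co, co_p)
    write_frame(ph$pair$cross, cr_p)
    manifest$phantoms[[nm]] <- list(
      co = basename(co_p), cross = basename(cr_p),
      b_background = ph$b_map[1, 1],
      b_lesion = if (any(ph$lesion_mask)) ph$b_map[ph$lesion_mask][1] else NULL,
      n_lesion_px = sum(ph$lesion_mask), n_glare_px = sum(ph$glare_mask))
  }
  for (k in c(0.5, 2, 8)) {
    fb <- render_fibers(fiber_spec(kappa = k, seed = seed + round(10 * k)))
    p <- file.path(outdir, sprintf("fibers_kappa%s.tif", gsub("\\.", "p", k)))
    tiff::writeTIFF(fb$image / max(fb$image), p, bits.per.sample = 16L,
                    compression = "none")
    manifest$fibers[[sprintf("kappa%s", gsub("\\.", "p", k))]] <-
      list(file = basename(p), kappa = k, true_variance = fb$true_variance)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
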