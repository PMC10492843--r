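## ---- color space -----------------------------------------------------------

## sRGB (linear) <-> CIE Lab, D65 white point. Inputs are linear intensities
## in [0, 1]; no gamma companding is applied (the camera data are linear).
.M_RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041),
                     3, 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
.WHITE_D65 <- c(0.95047, 1.0, 1.08883)

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert linear RGB to CIE Lab (D65)
#'
#' @param rgb rows x cols x 3 array, linear intensities in \[0, 1\].
#' @return rows x cols x 3 array with L (0--100), a, b planes.
#' @export
rgb_to_lab <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("expected a rows x cols x 3 RGB array")
  dm <- dim(rgb)
  m <- matrix(rgb, ncol = 3L)
  xyz <- m %*% t(.M_RGB2XYZ)
  fx <- .lab_f(xyz[, 1] / .WHITE_D65[1])
  fy <- .lab_f(xyz[, 2] / .WHITE_D65[2])
  fz <- .lab_f(xyz[, 3] / .WHITE_D65[3])
  out <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  array(out, dm)
}

#' @rdname rgb_to_lab
#' @param lab rows x cols x 3 Lab array.
#' @export
lab_to_rgb <- function(lab) {
  if (length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    stop("expected a rows x cols x 3 Lab array")
  dm <- dim(lab)
  m <- matrix(lab, ncol = 3L)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.lab_finv(fx) * .WHITE_D65[1],
               .lab_finv(fy) * .WHITE_D65[2],
               .lab_finv(fz) * .WHITE_D65[3])
  rgb <- xyz %*% t(.M_XYZ2RGB)
  array(pmax(rgb, 0), dm)
}

## ---- separable Gaussian filtering with reflect padding ---------------------

.reflect_pad_idx <- function(n, k) {
  ## index vector implementing mirror (symmetric) padding of width k, by
  ## folding positions into [1, n] with period 2n; valid for any k
  p0 <- ((1 - k):(n + k) - 1) %% (2 * n)
  ifelse(p0 < n, p0 + 1, 2 * n - p0)
}

#' Gaussian smoothing of a matrix (reflect-padded)
#'
#' Separable convolution with a normalized Gaussian kernel truncated at
#' 3 standard deviations; boundaries are mirror-padded so the global mean is
#' preserved.
#'
#' @param x Numeric matrix.
#' @param sigma Kernel standard deviation in pixels (> 0).
#' @return Filtered matrix of the same dimension.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) stop("invalid parameter: sigma must be positive")
  k <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-k):k)^2 / (2 * sigma^2))
  w <- w / sum(w)
  nr <- nrow(x); nc <- ncol(x)
  ri <- .reflect_pad_idx(nr, k)
  xp <- x[ri, , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(w))
    out <- out + w[j] * xp[(j - 1) + seq_len(nr), , drop = FALSE]
  ci <- .reflect_pad_idx(nc, k)
  xp <- out[, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(w))
    out <- out + w[j] * xp[, (j - 1) + seq_len(nc), drop = FALSE]
  out
}

#' Homomorphic illumination correction
#'
#' Removes low-frequency multiplicative illumination: log-transform,
#' subtraction of a Gaussian low-pass (sigma in pixels), exponentiation.
#' A small epsilon (1e-6 of the maximum) guards zeros. The result is a
#' detail image fluctuating around 1.
#'
#' @param x Non-negative numeric matrix.
#' @param sigma Low-pass standard deviation in pixels (default 15).
#' @return Matrix of multiplicative detail.
#' @export
homomorphic_filter <- function(x, sigma = 15) {
  eps <- 1e-6 * max(x)
  if (eps <= 0) return(x / max(x, 1e-12))  # all-zero image
  lg <- log(x + eps)
  exp(lg - gaussian_smooth(lg, sigma))
}

## ---- pipeline configuration ------------------------------------------------

#' Image pipeline configuration
#'
#' Bundles the pre-processing constants: detector-noise smoothing sigma
#' (0.5 px), homomorphic low-pass sigma (15 px), 1%/1% contrast saturation,
#' the glare percentile rule (co-polarized upper 0.5th, cross-polarized lower
#' 0.5th) and the glare dilation radius.
#'
#' @param denoise_sigma Gaussian denoise sigma, px.
#' @param homomorphic_sigma Homomorphic low-pass sigma, px.
#' @param saturation_low,saturation_high Saturated tail fractions.
#' @param glare_co_percentile Upper percentile of the co frame (0--100).
#' @param glare_cross_percentile Lower percentile of the cross frame (0--100).
#' @param glare_dilation_radius Dilation radius of the glare mask, px.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(denoise_sigma = 0.5, homomorphic_sigma = 15,
                            saturation_low = 0.01, saturation_high = 0.01,
                            glare_co_percentile = 99.5,
                            glare_cross_percentile = 0.5,
                            glare_dilation_radius = 2L) {
  stopifnot(denoise_sigma > 0, homomorphic_sigma > 0,
            saturation_low > 0, saturation_low < 1,
            saturation_high > 0, saturation_high < 1,
            glare_co_percentile > 0, glare_co_percentile < 100,
            glare_cross_percentile > 0, glare_cross_percentile < 100)
  structure(list(denoise_sigma = denoise_sigma,
                 homomorphic_sigma = homomorphic_sigma,
                 saturation_low = saturation_low,
                 saturation_high = saturation_high,
                 glare_co_percentile = glare_co_percentile,
                 glare_cross_percentile = glare_cross_percentile,
                 glare_dilation_radius = glare_dilation_radius,
                 ## fixed processing order of the luminosity channel
                 order = c("rgb_to_lab", "gaussian_smooth",
                           "homomorphic_filter", "percentile_saturate",
                           "lab_to_rgb")),
            class = "pipeline_config")
}

## ---- pre-processing chain --------------------------------------------------

#' Pre-process one RGB frame
#'
#' The luminosity-only chain: RGB -> Lab (D65), then on L only Gaussian
#' smoothing (sigma 0.5), homomorphic illumination correction (sigma 15) and
#' 1%/1% percentile saturation with rescale; the a and b chroma planes are
#' untouched; finally Lab -> RGB.
#'
#' Pixels flagged in `exclude_mask` (typically specular glare) are replaced
#' by the median valid luminosity before filtering, so that the Gaussian
#' low-pass cannot smear their energy into a halo around them; they are
#' excluded from every downstream statistic anyway.
#'
#' @param image rows x cols x 3 linear RGB array in \[0, 1\].
#' @param config A [pipeline_config()].
#' @param exclude_mask Optional logical matrix of pixels to neutralize
#'   before filtering.
#' @return List with `rgb` (processed array) and `L` (processed luminosity).
#' @export
preprocess <- function(image, config = pipeline_config(),
                       exclude_mask = NULL) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected a rows x cols x 3 RGB array")
  lab <- rgb_to_lab(image)
  L <- lab[, , 1]
  if (!is.null(exclude_mask) && any(exclude_mask) && !all(exclude_mask))
    L[exclude_mask] <- stats::median(L[!exclude_mask])
  L1 <- gaussian_smooth(L, config$denoise_sigma)
  L2 <- homomorphic_filter(L1, config$homomorphic_sigma)
  q <- stats::quantile(L2, c(config$saturation_low, 1 - config$saturation_high),
                       na.rm = TRUE, names = FALSE)
  qL <- stats::quantile(L, c(config$saturation_low, 1 - config$saturation_high),
                        na.rm = TRUE, names = FALSE)
  if (q[2] > q[1] && qL[2] > qL[1]) {
    ## clamp the homomorphic detail to its percentile window and map that
    ## window onto the *original* luminosity's percentile window: the frame
    ## keeps its own absolute brightness scale (so co stays brighter than
    ## cross), and anchoring on percentiles at both ends keeps the result
    ## robust to saturated outliers such as specular glare
    L3 <- (pmin(pmax(L2, q[1]), q[2]) - q[1]) / (q[2] - q[1]) *
      (qL[2] - qL[1]) + qL[1]
  } else {
    L3 <- L  # flat field: nothing to correct
  }
  lab[, , 1] <- L3
  list(rgb = lab_to_rgb(lab), L = L3)
}

## ---- glare exclusion -------------------------------------------------------

## Canny edge detector on a 2D map: Gaussian smooth, Sobel gradients,
## non-maximum suppression, median-based double-threshold hysteresis.
canny_edges <- function(x, sigma = 1) {
  xs <- gaussian_smooth(x, sigma)
  nr <- nrow(xs); nc <- ncol(xs)
  pad <- function(m) m[.reflect_pad_idx(nr, 1L), .reflect_pad_idx(nc, 1L)]
  p <- pad(xs)
  ix <- seq_len(nr) + 1L; jx <- seq_len(nc) + 1L
  gx <- (p[ix - 1, jx + 1] + 2 * p[ix, jx + 1] + p[ix + 1, jx + 1] -
         p[ix - 1, jx - 1] - 2 * p[ix, jx - 1] - p[ix + 1, jx - 1])
  gy <- (p[ix + 1, jx - 1] + 2 * p[ix + 1, jx] + p[ix + 1, jx + 1] -
         p[ix - 1, jx - 1] - 2 * p[ix - 1, jx] - p[ix - 1, jx + 1])
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nr, nc))
  ## non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  mp <- mag[.reflect_pad_idx(nr, 1L), .reflect_pad_idx(nc, 1L)]
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    o <- offs[[s + 1]]
    n1 <- mp[ix + o[1], jx + o[2]]
    n2 <- mp[ix - o[1], jx - o[2]]
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }
  pos <- mag[mag > 0]
  hi <- stats::median(pos) * 2
  lo <- hi / 2
  strong <- nms & mag >= hi
  weak <- nms & mag >= lo
  ## hysteresis: keep weak edges connected to strong ones
  lab <- EBImage::bwlabel(weak * 1)
  keep <- unique(lab[strong & lab > 0])
  matrix(lab %in% keep & weak, nr, nc)
}

#' Specular glare mask
#'
#' Specular highlights are bright in the co-polarized frame (the polarizer
#' preserves surface reflections) and dark in the cross-polarized frame.
#' Candidate pixels are those at or above the co-frame's upper percentile AND
#' at or below the cross-frame's lower percentile; edges of the candidate map
#' delimit glare regions, which are filled and dilated.
#'
#' @param pair A [polarized_frame_pair()].
#' @param config A [pipeline_config()].
#' @return Logical matrix, TRUE = excluded glare pixel.
#' @export
glare_mask <- function(pair, config = pipeline_config()) {
  stopifnot(inherits(pair, "polarized_frame_pair"))
  co_lum <- pair$co[, , 1] + pair$co[, , 2] + pair$co[, , 3]
  cr_lum <- pair$cross[, , 1] + pair$cross[, , 2] + pair$cross[, , 3]
  q_co <- stats::quantile(co_lum, config$glare_co_percentile / 100,
                          names = FALSE)
  q_cr <- stats::quantile(cr_lum, config$glare_cross_percentile / 100,
                          names = FALSE)
  cand <- co_lum >= q_co & cr_lum <= q_cr
  if (!any(cand)) return(matrix(FALSE, nrow(co_lum), ncol(co_lum)))
  edges <- canny_edges(cand * 1)
  region <- cand | edges
  filled <- EBImage::fillHull(EBImage::bwlabel(region)) > 0
  r <- config$glare_dilation_radius
  if (r > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
    filled <- EBImage::dilate(filled * 1, brush) > 0
  }
  matrix(as.logical(filled), nrow(co_lum), ncol(co_lum))
}

## ---- full frame processing -------------------------------------------------

#' Run the full processing chain on a frame pair
#'
#' Normalizes digital numbers to \[0, 1\] by the source bit depth, builds the
#' glare exclusion mask from the raw frames, pre-processes the co and cross
#' frames independently, and computes the WLL, PEL and mPEL images on
#' non-excluded pixels (excluded pixels are NA).
#'
#' @param pair A [polarized_frame_pair()].
#' @param config A [pipeline_config()].
#' @param coeffs An [mpel_coefficients()] (default: the published set).
#' @param normalize Divide by `2^bit_depth - 1` before processing.
#' @param glare_exclusion Detect and exclude specular glare (default TRUE;
#'   FALSE runs the chain with no glare handling, for comparison studies).
#' @return Object of class `derived_images`: `wll`, `pel`, `mpel` matrices,
#'   `excluded_mask`, processed `co`/`cross` arrays, and the configuration
#'   used.
#' @export
run_frame <- function(pair, config = pipeline_config(),
                      coeffs = paper_coefficients(), normalize = TRUE,
                      glare_exclusion = TRUE) {
  stopifnot(inherits(pair, "polarized_frame_pair"))
  scale <- if (normalize) 2^pair$bit_depth - 1 else 1
  gm <- if (glare_exclusion) glare_mask(pair, config)
        else matrix(FALSE, dim(pair$co)[1], dim(pair$co)[2])
  excl <- gm | !pair$valid_mask
  co <- preprocess(pair$co / scale, config, excl)$rgb
  cross <- preprocess(pair$cross / scale, config, excl)$rgb
  proc <- polarized_frame_pair(co, cross, valid_mask = !excl, bit_depth = 0)
  wll <- compute_wll(proc)
  pel <- compute_pel(proc)
  diffs <- co - cross
  wll[excl] <- NA_real_
  pel[excl] <- NA_real_
  mpel <- apply_mpel_masked(diffs, coeffs, excl)
  structure(list(wll = wll, pel = pel, mpel = mpel, excluded_mask = excl,
                 co = co, cross = cross, config = config, coeffs = coeffs),
            class = "derived_images")
}

## apply mPEL with exclusions NA'd before the percentile saturation, so
## excluded pixels cannot influence the contrast stretch
apply_mpel_masked <- function(diffs, coeffs, excl) {
  m <- coeffs$a0 + coeffs$a1 * diffs[, , 1] + coeffs$a2 * diffs[, , 2] +
    coeffs$a3 * diffs[, , 3]
  m[excl] <- NA_real_
  percentile_saturate(m, 0.01, 0.99)
}

#' @export
print.derived_images <- function(x, ...) {
  cat(sprintf(
    "derived_images %dx%d: WLL mean %.4g, PEL mean %.4g, mPEL mean %.4g, %d px excluded\n",
    nrow(x$wll), ncol(x$wll), mean(x$wll, na.rm = TRUE),
    mean(x$pel, na.rm = TRUE), mean(x$mpel, na.rm = TRUE),
    sum(x$excluded_mask)))
  invisible(x)
}
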