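#' mPEL regression coefficients
#'
#' Linear coefficients mapping the three co-minus-cross RGB differentials to
#' the tissue scattering-power scale:
#' mPEL = a0 + a1 (R|| - R_|_) + a2 (G|| - G_|_) + a3 (B|| - B_|_).
#' Every coefficient set carries a provenance tag: `"paper"` for the
#' published clinical set, `"fitted"` for sets refitted on a Monte Carlo
#' lookup table.
#'
#' @param a0,a1,a2,a3 Regression coefficients (finite).
#' @param provenance `"paper"` or `"fitted"`.
#' @param r2 Optional R-squared of the fit.
#' @param se Optional coefficient standard errors (length 4).
#' @return Object of class `mpel_coefficients`.
#' @export
mpel_coefficients <- function(a0, a1, a2, a3,
                              provenance = c("fitted", "paper"),
                              r2 = NA_real_, se = NULL) {
  provenance <- match.arg(provenance)
  co <- c(a0 = a0, a1 = a1, a2 = a2, a3 = a3)
  if (any(!is.finite(co))) stop("coefficients must be finite")
  structure(list(a0 = a0, a1 = a1, a2 = a2, a3 = a3,
                 provenance = provenance, r2 = r2, se = se),
            class = "mpel_coefficients")
}

#' @export
print.mpel_coefficients <- function(x, ...) {
  cat(sprintf("mPEL = %.4f %+.4f dR %+.4f dG %+.4f dB  [%s%s]\n",
              x$a0, x$a1, x$a2, x$a3, x$provenance,
              if (is.na(x$r2)) "" else sprintf(", R2 = %.3f", x$r2)))
  invisible(x)
}

#' The published mPEL coefficient set
#'
#' Loads the packaged clinical coefficient set
#' (0.4705, -0.0073, -0.0039, 0.1104) with provenance `"paper"`.
#'
#' @return An `mpel_coefficients` object.
#' @export
paper_coefficients <- function() {
  path <- system.file("extdata", "coefficients_published.json",
                      package = "polgate", mustWork = TRUE)
  read_coefficients(path)
}

#' Read / write coefficient sets as JSON
#'
#' @param path JSON file with fields a0..a3 and provenance.
#' @export
read_coefficients <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mpel_coefficients(j$a0, j$a1, j$a2, j$a3, provenance = j$provenance,
                    r2 = if (!is.null(j$r2)) j$r2 else NA_real_)
}

#' @rdname read_coefficients
#' @param coeffs An `mpel_coefficients` object.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "mpel_coefficients"))
  jsonlite::write_json(
    list(a0 = coeffs$a0, a1 = coeffs$a1, a2 = coeffs$a2, a3 = coeffs$a3,
         provenance = coeffs$provenance, r2 = coeffs$r2),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Paired co/cross-polarized RGB frames
#'
#' @param co,cross Numeric arrays of identical dimension (rows x cols x 3),
#'   non-negative linear intensities.
#' @param valid_mask Optional logical matrix (rows x cols); FALSE pixels are
#'   excluded from analysis.
#' @param bit_depth Source bit depth (acquisition was 12-bit); used to
#'   normalize digital numbers to the \[0, 1\] reflectance-like scale.
#' @return Object of class `polarized_frame_pair`.
#' @export
polarized_frame_pair <- function(co, cross, valid_mask = NULL, bit_depth = 12) {
  if (!identical(dim(co), dim(cross)))
    stop("shape mismatch: co and cross images must have identical dimensions")
  if (length(dim(co)) != 3L || dim(co)[3] != 3L)
    stop("frames must be rows x cols x 3 RGB arrays")
  if (min(co, na.rm = TRUE) < 0 || min(cross, na.rm = TRUE) < 0)
    stop("intensities must be non-negative")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, dim(co)[1], dim(co)[2])
  structure(list(co = co, cross = cross, valid_mask = valid_mask,
                 bit_depth = bit_depth),
            class = "polarized_frame_pair")
}

#' White-light-equivalent (WLL) image
#'
#' Pixelwise sum of all co- and cross-polarized channels:
#' (R||+R_|_) + (G||+G_|_) + (B||+B_|_). Captures surface and deep signal.
#'
#' @param pair A [polarized_frame_pair()].
#' @return Numeric matrix.
#' @export
compute_wll <- function(pair) {
  stopifnot(inherits(pair, "polarized_frame_pair"))
  s <- pair$co + pair$cross
  s[, , 1] + s[, , 2] + s[, , 3]
}

#' Polarization-gated (PEL) image
#'
#' Pixelwise sum of channel differentials:
#' (R||-R_|_) + (G||-G_|_) + (B||-B_|_). The depolarized deep signal cancels,
#' leaving the superficial contribution.
#'
#' @inheritParams compute_wll
#' @return Numeric matrix.
#' @export
compute_pel <- function(pair) {
  stopifnot(inherits(pair, "polarized_frame_pair"))
  d <- pair$co - pair$cross
  d[, , 1] + d[, , 2] + d[, , 3]
}

#' Fit the mPEL regression on a lookup table
#'
#' Ordinary least squares of the scattering power b on the three RGB
#' differentials with intercept (no regularization, no interactions).
#'
#' @param lut A `reflectance_lut` (or a data.frame with columns b, dR, dG,
#'   dB).
#' @return An `mpel_coefficients` with provenance `"fitted"`, R-squared and
#'   coefficient standard errors.
#' @export
fit_mpel <- function(lut) {
  pts <- if (inherits(lut, "reflectance_lut")) lut$points else lut
  if (nrow(pts) < 5L) stop("need at least 5 lookup-table rows to fit")
  X <- as.matrix(pts[, c("dR", "dG", "dB")])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < 4L) {
    bad <- c("(intercept)", "dR", "dG", "dB")[qrX$pivot[(qrX$rank + 1):4]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(b ~ dR + dG + dB, data = pts)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  mpel_coefficients(cf[[1]], cf[[2]], cf[[3]], cf[[4]],
                    provenance = "fitted", r2 = sm$r.squared,
                    se = unname(sm$coefficients[, "Std. Error"]))
}

#' Apply mPEL coefficients to differentials
#'
#' For a differential triple (dR, dG, dB) returns the scalar
#' a0 + a1 dR + a2 dG + a3 dB. For a rows x cols x 3 raster of differentials
#' returns the mPEL raster, contrast-adjusted by saturating the bottom and
#' top 1% of pixel values (disable with `saturate = FALSE`).
#'
#' @param differentials Length-3 numeric vector or rows x cols x 3 array of
#'   co-minus-cross channel differentials (channel order R, G, B).
#' @param coeffs An [mpel_coefficients()].
#' @param saturate Apply the 1%/1% percentile saturation to rasters.
#' @return Scalar or numeric matrix.
#' @export
apply_mpel <- function(differentials, coeffs = paper_coefficients(),
                       saturate = TRUE) {
  stopifnot(inherits(coeffs, "mpel_coefficients"))
  if (is.null(dim(differentials))) {
    stopifnot(length(differentials) == 3L)
    return(coeffs$a0 + sum(c(coeffs$a1, coeffs$a2, coeffs$a3) * differentials))
  }
  stopifnot(length(dim(differentials)) == 3L, dim(differentials)[3] == 3L)
  m <- coeffs$a0 + coeffs$a1 * differentials[, , 1] +
    coeffs$a2 * differentials[, , 2] + coeffs$a3 * differentials[, , 3]
  if (saturate) m <- percentile_saturate(m, 0.01, 0.99)
  m
}

#' Percentile saturation (contrast clipping)
#'
#' Clamps values below the `lo` quantile and above the `hi` quantile.
#'
#' @param x Numeric vector/matrix (NAs ignored and preserved).
#' @param lo,hi Quantile bounds in (0, 1).
#' @param rescale If TRUE, linearly map \[q_lo, q_hi\] onto the original
#'   \[min, max\] range after clamping.
#' @return Same shape as `x`.
#' @export
percentile_saturate <- function(x, lo = 0.01, hi = 0.99, rescale = FALSE) {
  q <- stats::quantile(x, c(lo, hi), na.rm = TRUE, names = FALSE)
  if (!is.finite(q[1]) || q[2] <= q[1]) return(x)  # degenerate (flat) input
  y <- pmin(pmax(x, q[1]), q[2])
  if (rescale) {
    r <- range(x, na.rm = TRUE)
    y <- (y - q[1]) / (q[2] - q[1]) * (r[2] - r[1]) + r[1]
  }
  y
}
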