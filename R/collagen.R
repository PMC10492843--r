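#' Otsu threshold of a grayscale image
#'
#' Exhaustive maximization of the between-class variance over a 256-bin
#' intensity histogram.
#'
#' @param image Non-negative numeric matrix, non-constant.
#' @param nbins Number of histogram bins (default 256).
#' @return The threshold intensity (bin upper edge).
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  r <- range(image, na.rm = TRUE)
  if (r[1] == r[2])
    stop("degenerate threshold: image is constant")
  edges <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(image, edges, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_tot <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins)
  between[valid] <- (mu_tot * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(between)
  edges[k + 1L]
}

#' Segment fiber regions
#'
#' Above-Otsu-threshold mask of an SHG intensity image.
#'
#' @param image Grayscale matrix (SHG intensity, arbitrary units).
#' @return Logical matrix (TRUE = fiber).
#' @export
segment_fibers <- function(image) {
  image > otsu_threshold(image)
}

## Sobel gradients with reflect padding
.sobel <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  p <- x[.reflect_pad_idx(nr, 1L), .reflect_pad_idx(nc, 1L)]
  i <- seq_len(nr) + 1L; j <- seq_len(nc) + 1L
  gx <- (p[i - 1, j + 1] + 2 * p[i, j + 1] + p[i + 1, j + 1] -
         p[i - 1, j - 1] - 2 * p[i, j - 1] - p[i + 1, j - 1])
  gy <- (p[i + 1, j - 1] + 2 * p[i + 1, j] + p[i + 1, j + 1] -
         p[i - 1, j - 1] - 2 * p[i - 1, j] - p[i - 1, j + 1])
  list(gx = gx, gy = gy)
}

## box (moving-window) sum with reflect padding, window odd
.box_sum <- function(x, window) {
  k <- (window - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[.reflect_pad_idx(nr, k), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_len(window))
    out <- out + xp[(j - 1) + seq_len(nr), , drop = FALSE]
  xp <- out[, .reflect_pad_idx(nc, k), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_len(window))
    out <- out + xp[, (j - 1) + seq_len(nc), drop = FALSE]
  out
}

#' Local fiber orientation by weighted vector summation
#'
#' Gradient-derived axial orientation: per pixel the doubled-angle gradient
#' vector (structure-tensor components) is summed over a window with
#' gradient-energy weights; the fiber axis is perpendicular to the dominant
#' gradient. Angle doubling makes the average well-defined for axial data
#' (theta and theta + pi are the same fiber axis).
#'
#' Small windows (default 5 px) keep each pixel's estimate local to its own
#' fiber; larger windows average across fibers and bias the downstream
#' directional variance towards alignment.
#'
#' @param image Grayscale matrix.
#' @param fiber_mask Optional logical matrix restricting the output.
#' @param window Odd window size in pixels (default 5).
#' @return Object of class `orientation_field`: `theta` (radians in
#'   \[0, pi), NA off-mask), `coherence_weight` (summed gradient energy),
#'   `fiber_mask`.
#' @export
local_orientation <- function(image, fiber_mask = NULL, window = 5L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("invalid parameter: window must be odd and >= 3")
  if (window > min(dim(image)))
    stop("invalid parameter: window larger than image")
  g <- .sobel(image)
  ## doubled-angle gradient vector, weighted by gradient energy
  vx <- g$gx^2 - g$gy^2
  vy <- 2 * g$gx * g$gy
  sx <- .box_sum(vx, window)
  sy <- .box_sum(vy, window)
  wgt <- .box_sum(g$gx^2 + g$gy^2, window)
  theta_grad <- 0.5 * atan2(sy, sx)
  theta <- (theta_grad + pi / 2) %% pi   # fiber axis is normal to the gradient
  if (is.null(fiber_mask)) fiber_mask <- matrix(TRUE, nrow(image), ncol(image))
  theta[!fiber_mask] <- NA_real_
  structure(list(theta = theta, coherence_weight = wgt,
                 fiber_mask = fiber_mask, window = window),
            class = "orientation_field")
}

#' 2D directional variance of axial orientations
#'
#' Circular variance of the doubled angles:
#' 1 - |mean of unit vectors at angle 2 theta| (optionally weighted).
#' 0 for perfectly aligned fibers, -> 1 for uniformly random orientations.
#'
#' @param theta Axial orientations in radians (any range; treated mod pi).
#'   NAs are dropped.
#' @param weights Optional non-negative weights.
#' @return Variance in \[0, 1\].
#' @export
directional_variance <- function(theta, weights = NULL) {
  theta <- as.vector(theta)
  keep <- !is.na(theta)
  if (!is.null(weights)) {
    weights <- as.vector(weights)[keep]
  }
  theta <- theta[keep]
  if (length(theta) == 0L) stop("empty orientation set")
  if (is.null(weights)) weights <- rep(1, length(theta))
  c2 <- sum(weights * cos(2 * theta)) / sum(weights)
  s2 <- sum(weights * sin(2 * theta)) / sum(weights)
  1 - sqrt(c2^2 + s2^2)
}

#' Per-window directional variance map
#'
#' Local circular variance of the doubled angles over a moving window,
#' restricted to fiber pixels.
#'
#' @param field An [local_orientation()] result.
#' @param window Odd window size (default 33 px).
#' @return Matrix of local variance (NA where the window holds no fiber).
#' @export
directional_variance_map <- function(field, window = 33L) {
  th <- field$theta
  m <- field$fiber_mask * 1
  c2 <- cos(2 * th); c2[is.na(c2)] <- 0
  s2 <- sin(2 * th); s2[is.na(s2)] <- 0
  n <- .box_sum(m, window)
  rc <- .box_sum(c2, window)
  rs <- .box_sum(s2, window)
  v <- 1 - sqrt(rc^2 + rs^2) / n
  v[n == 0] <- NA_real_
  v
}

#' Collagen area fraction
#'
#' Fraction of the field occupied by segmented fiber pixels.
#'
#' @param fiber_mask Logical matrix.
#' @return Fraction in \[0, 1\].
#' @export
area_fraction <- function(fiber_mask) {
  mean(fiber_mask)
}

#' Full collagen analysis of an SHG image
#'
#' Otsu fiber segmentation, windowed orientation estimation, and the summary
#' statistics reported per region: mean directional variance over fiber
#' pixels and collagen area fraction. Multi-slice stacks should be reduced
#' by maximum-intensity projection first (see [max_intensity_projection()]).
#'
#' @param image Grayscale matrix.
#' @param orientation_window Per-pixel orientation window, px (default 5).
#' @return List: `fiber_mask`, `orientation` field, `directional_variance`
#'   (scalar, gradient-energy weighted over fiber pixels), `area_fraction`.
#' @export
analyze_collagen <- function(image, orientation_window = 5L) {
  mask <- segment_fibers(image)
  field <- local_orientation(image, mask, orientation_window)
  v <- directional_variance(field$theta[mask],
                            field$coherence_weight[mask])
  list(fiber_mask = mask, orientation = field,
       directional_variance = v, area_fraction = area_fraction(mask))
}

#' Maximum-intensity projection of an image stack
#'
#' @param stack 3D array (rows x cols x slices) or list of matrices.
#' @return Matrix of per-pixel maxima.
#' @export
max_intensity_projection <- function(stack) {
  if (is.list(stack)) stack <- simplify2array(stack)
  apply(stack, c(1, 2), max)
}
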