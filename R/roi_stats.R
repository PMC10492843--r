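#' Per-ROI mean intensities and shared background mean
#'
#' Background is the mean over all pixels that belong to no ROI and are not
#' excluded; every ROI is excluded from the background of every other ROI.
#'
#' @param image Numeric matrix (e.g. a WLL/PEL/mPEL raster; NAs ignored).
#' @param rois Integer label matrix: 0 = background, k > 0 = ROI k.
#' @param excluded_mask Optional logical matrix of pixels to drop everywhere.
#' @return List with `I_f` (named per-ROI means) and `I_b` (scalar).
#' @export
roi_means <- function(image, rois, excluded_mask = NULL) {
  if (!identical(dim(image), dim(rois)))
    stop("shape mismatch: image and ROI label raster differ")
  if (any(rois < 0)) stop("ROI labels must be non-negative integers")
  ok <- !is.na(image)
  if (!is.null(excluded_mask)) ok <- ok & !excluded_mask
  labels <- sort(unique(rois[rois > 0]))
  if (length(labels) == 0L) stop("empty ROI set")
  I_f <- vapply(labels, function(k) {
    sel <- rois == k & ok
    if (!any(sel)) stop(sprintf("ROI %d is empty after exclusions", k))
    mean(image[sel])
  }, numeric(1))
  names(I_f) <- labels
  bg <- rois == 0 & ok
  if (!any(bg)) stop("empty background after exclusions")
  list(I_f = I_f, I_b = mean(image[bg]))
}

#' Weber contrast
#'
#' C_W = (I_f - I_b) / I_b: the visibility of a target of mean intensity I_f
#' against a background of mean intensity I_b. Invariant to global linear
#' intensity rescaling.
#'
#' @param I_f Target (ROI) mean intensity.
#' @param I_b Background mean intensity (> 0).
#' @return Dimensionless contrast (vectorized over `I_f`).
#' @export
weber_contrast <- function(I_f, I_b) {
  if (any(I_b <= 0)) stop("undefined contrast: background intensity must be positive")
  (I_f - I_b) / I_b
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups Named list of numeric samples (>= 2 groups, each n >= 2).
#' @return List with `F`, `p` (omnibus) and `tukey` (data.frame of pairwise
#'   adjusted p-values and mean differences). Degenerate data with zero
#'   residual variance return p = 1 when all group means are equal and p = 0
#'   otherwise.
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups),
                                  vapply(groups, length, integer(1)))))
  if (stats::var(df$y) == 0)
    return(list(F = NaN, p = 1, tukey = NULL))
  means <- tapply(df$y, df$g, mean)
  resid_ss <- sum((df$y - means[df$g])^2)
  if (resid_ss == 0)  # groups are distinct constants: infinite F
    return(list(F = Inf, p = 0, tukey = NULL))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          row.names = NULL))
}

#' Two-sample t-test
#'
#' Classic pooled-variance two-sample t-test by default (`welch = TRUE`
#' switches to the unequal-variance form). Two-sided.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param welch Use the Welch correction.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_two_sample <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 in each sample")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of the
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  stats::fisher.test(table)$p.value
}

#' Contrast records for a set of ROIs on one modality raster
#'
#' Convenience wrapper: per-ROI mean intensity, shared background mean and
#' Weber contrast.
#'
#' @inheritParams roi_means
#' @param modality Label stored with the records ("WLL", "PEL" or "mPEL").
#' @return data.frame (roi, modality, I_f, I_b, C_W).
#' @export
contrast_records <- function(image, rois, excluded_mask = NULL,
                             modality = "WLL") {
  m <- roi_means(image, rois, excluded_mask)
  data.frame(roi = as.integer(names(m$I_f)), modality = modality,
             I_f = unname(m$I_f), I_b = m$I_b,
             C_W = weber_contrast(unname(m$I_f), m$I_b))
}
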