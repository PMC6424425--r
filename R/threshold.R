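#' Fixed-threshold binarization
#'
#' The recommended practice for comparing colocalization across conditions:
#' one fixed threshold per channel, applied identically to every image of an
#' experiment. Binarization is strictly greater-than, so `value` equal to the
#' image maximum yields an empty mask. The mask records its provenance
#' (source role, threshold used).
#'
#' @param image intensity matrix.
#' @param value threshold intensity.
#' @param role optional channel role recorded as provenance.
#' @return a `binary_mask`: logical matrix with attributes
#'   `threshold_used` and `source_channel`.
#' @export
fixed_threshold <- function(image, value, role = NA_character_) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  structure(image > value, threshold_used = value, source_channel = role,
            class = c("binary_mask", "matrix", "array"))
}

#' Background-derived fixed threshold
#'
#' Default fixed-threshold choice on simulated fields: mean + `k` standard
#' deviations of the pixels in a background region (e.g. outside all cell
#' masks). Real data should use a user-chosen per-channel constant instead.
#'
#' @param image intensity matrix.
#' @param background_mask logical matrix marking background pixels.
#' @param k number of standard deviations above the background mean.
#' @return a threshold intensity.
#' @export
background_threshold <- function(image, background_mask, k = 2) {
  v <- image[background_mask]
  if (length(v) < 2L) stop("background region too small", call. = FALSE)
  mean(v) + k * stats::sd(v)
}

#' Costes automatic joint threshold
#'
#' The auto-thresholding procedure this package exists to scrutinise. An
#' orthogonal (total least squares) regression `B ~ a*A + c` is fitted over
#' all pixels; candidate thresholds `T_A` are scanned downward from `max(A)`
#' in unit steps with `T_B = a*T_A + c`, and the scan stops at the highest
#' candidate for which the Pearson correlation of the pixels *below* both
#' thresholds (`A < T_A` and `B < T_B`, strict) first reaches <= 0. If the
#' below-threshold correlation never reaches 0 the minimum positive candidate
#' is returned with `converged = FALSE`. When one channel is dim and
#' dispersed (ER-resident enzyme) and the other bright and compact, the
#' thresholds settle near the bright population and the dim signal is
#' excluded from the supra-threshold analysis — the failure mode to test for.
#'
#' @param image_a,image_b intensity matrices of identical shape, each with at
#'   least two distinct values.
#' @return list with `t_a`, `t_b`, `slope`, `intercept`, `converged`.
#' @export
costes_threshold <- function(image_a, image_b) {
  if (!identical(dim(image_a), dim(image_b))) {
    stop("images must have identical shape (dimension error)", call. = FALSE)
  }
  a <- as.numeric(image_a); b <- as.numeric(image_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant channel: Costes regression undefined (degenerate input)",
         call. = FALSE)
  }
  n <- length(a)
  sxx <- stats::var(a); syy <- stats::var(b); sxy <- stats::cov(a, b)
  if (sxy == 0) {
    stop("zero covariance: Costes regression undefined (degenerate input)",
         call. = FALSE)
  }
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  intercept <- mean(b) - slope * mean(a)
  cands <- seq(max(1, floor(max(a))), 1)
  if (slope <= 0) {
    return(list(t_a = min(cands), t_b = slope * min(cands) + intercept,
                slope = slope, intercept = intercept, converged = FALSE))
  }
  # pixel i is below candidate T iff T > m_i, m_i = max(A_i, (B_i - c)/a)
  m <- pmax(a, (b - intercept) / slope)
  ord <- order(m)
  ms <- m[ord]; as_ <- a[ord]; bs <- b[ord]
  ca <- cumsum(as_); cb <- cumsum(bs)
  caa <- cumsum(as_^2); cbb <- cumsum(bs^2); cab <- cumsum(as_ * bs)
  # strict '<': count of m strictly below each candidate
  cnt <- findInterval(cands, ms, left.open = TRUE)
  r <- rep(NA_real_, length(cands))
  ok <- cnt >= 2L
  if (any(ok)) {
    k <- cnt[ok]
    sa <- ca[k]; sb <- cb[k]; saa <- caa[k]; sbb <- cbb[k]; sab <- cab[k]
    va <- saa - sa^2 / k
    vb <- sbb - sb^2 / k
    cv <- sab - sa * sb / k
    den <- sqrt(pmax(va, 0) * pmax(vb, 0))
    r[ok] <- ifelse(den > 0, cv / den, NA_real_)
  }
  hit <- which(!is.na(r) & r <= 0)
  if (length(hit)) {
    i <- hit[1L]   # candidates are in descending order: first = highest
    list(t_a = cands[i], t_b = slope * cands[i] + intercept,
         slope = slope, intercept = intercept, converged = TRUE)
  } else {
    list(t_a = min(cands), t_b = slope * min(cands) + intercept,
         slope = slope, intercept = intercept, converged = FALSE)
  }
}

#' Remove Golgi-localized signal using a Golgi-marker mask
#'
#' Zeroes every enzyme pixel inside the Golgi mask, leaving only the
#' out-of-Golgi (e.g. ER-resident) signal for downstream colocalization —
#' the key workflow step that makes a small relocated enzyme fraction
#' measurable against the dominant Golgi pool. Works slice-wise on 3-D
#' arrays (the 2-D mask is applied to every slice).
#'
#' @param enzyme_image intensity matrix or `[y, x, z]` array.
#' @param golgi_mask logical matrix (e.g. from [fixed_threshold()] on the
#'   Golgi-marker channel) matching the image's `(y, x)` shape.
#' @return image of identical shape with in-mask pixels set to zero.
#' @export
golgi_mask_removal <- function(enzyme_image, golgi_mask) {
  golgi_mask <- unclass_mask(golgi_mask)
  d <- dim(enzyme_image)
  if (!identical(d[1:2], dim(golgi_mask))) {
    stop("enzyme image and Golgi mask shapes differ (dimension error)",
         call. = FALSE)
  }
  out <- enzyme_image
  if (length(d) == 2L) {
    out[golgi_mask] <- 0
  } else {
    for (z in seq_len(d[3])) {
      slice <- out[, , z]
      slice[golgi_mask] <- 0
      out[, , z] <- slice
    }
  }
  out
}

unclass_mask <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "logical"
  m
}
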