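#' Pearson correlation of two channels
#'
#' Standard product-moment correlation over the pixels of a region (whole
#' image if no region is given). Sensitive to intensity changes, unlike the
#' Manders coefficients.
#'
#' @param image_a,image_b intensity matrices/arrays of identical shape.
#' @param region_mask optional logical mask selecting the pixels to use.
#' @return correlation in `[-1, 1]`.
#' @export
coloc_pearson <- function(image_a, image_b, region_mask = NULL) {
  if (!identical(dim(image_a), dim(image_b))) {
    stop("images must have identical shape (dimension error)", call. = FALSE)
  }
  a <- as.numeric(image_a); b <- as.numeric(image_b)
  if (!is.null(region_mask)) {
    keep <- as.logical(region_mask)
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 2L) {
    stop("fewer than 2 pixels in region (degenerate input)", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant channel in region: Pearson undefined (degenerate input)",
         call. = FALSE)
  }
  stats::cor(a, b)
}

#' Directional Manders colocalization coefficients
#'
#' `m1` is the fraction of channel-A intensity coincident with
#' supra-threshold channel-B signal, `m2` the converse — e.g. with A = enzyme
#' and B = Golgi marker, `m1` is the fraction of enzyme staining at the Golgi
#' (drops when enzyme relocates) while `m2` is the fraction of Golgi marker
#' covered by enzyme (stays flat as long as some enzyme remains at the
#' Golgi; intensity changes do not move it). The default is the thresholded
#' variant: the numerator of `m1` also requires `A > t_a` (thresholds are set
#' on both channels); `thresholded = FALSE` gives the classic variant summing
#' over all A pixels. All comparisons are strict. An empty supra-threshold
#' denominator yields `NA` with the matching `*_defined` flag set to `FALSE`
#' — never silently zero.
#'
#' @param image_a,image_b intensity matrices/arrays of identical shape.
#' @param t_a,t_b per-channel thresholds.
#' @param thresholded include the own-channel threshold in each numerator.
#' @return list with `m1`, `m2`, `m1_defined`, `m2_defined`, `n_a`, `n_b`,
#'   `n_overlap` (supra-threshold pixel counts), `t_a`, `t_b`.
#' @export
manders <- function(image_a, image_b, t_a, t_b, thresholded = TRUE) {
  if (!identical(dim(image_a), dim(image_b))) {
    stop("images must have identical shape (dimension error)", call. = FALSE)
  }
  a <- as.numeric(image_a); b <- as.numeric(image_b)
  above_a <- a > t_a; above_b <- b > t_b
  den1 <- if (thresholded) sum(a[above_a]) else sum(a)
  den2 <- if (thresholded) sum(b[above_b]) else sum(b)
  num1 <- if (thresholded) sum(a[above_a & above_b]) else sum(a[above_b])
  num2 <- if (thresholded) sum(b[above_a & above_b]) else sum(b[above_a])
  list(m1 = if (den1 > 0) num1 / den1 else NA_real_,
       m2 = if (den2 > 0) num2 / den2 else NA_real_,
       m1_defined = den1 > 0, m2_defined = den2 > 0,
       n_a = sum(above_a), n_b = sum(above_b),
       n_overlap = sum(above_a & above_b),
       t_a = t_a, t_b = t_b)
}

#' Full colocalization statistics for a channel pair
#'
#' Convenience wrapper returning Pearson plus both Manders coefficients with
#' threshold provenance. Pearson degenerate inputs (constant channel in the
#' region) propagate as `NA` rather than an error here, so per-cell tables
#' keep their rows.
#'
#' @inheritParams manders
#' @param role_a,role_b channel roles recorded as provenance.
#' @param region_mask optional logical mask restricting all statistics.
#' @param method provenance label for how thresholds were chosen
#'   (`"fixed"` or `"costes"`).
#' @return one-row data frame (class `coloc_result`).
#' @export
coloc_stats <- function(image_a, image_b, t_a, t_b,
                        role_a = NA_character_, role_b = NA_character_,
                        region_mask = NULL, thresholded = TRUE,
                        method = "fixed") {
  if (!is.null(region_mask)) {
    keep <- as.logical(region_mask)
    image_a <- as.numeric(image_a)[keep]
    image_b <- as.numeric(image_b)[keep]
  }
  m <- manders(image_a, image_b, t_a, t_b, thresholded = thresholded)
  r <- tryCatch(coloc_pearson(image_a, image_b), error = function(e) NA_real_)
  out <- data.frame(channel_a = role_a, channel_b = role_b,
                    pearson_r = r, m1 = m$m1, m2 = m$m2,
                    m1_defined = m$m1_defined, m2_defined = m$m2_defined,
                    n_pixels_a = m$n_a, n_pixels_b = m$n_b,
                    n_pixels_overlap = m$n_overlap,
                    t_a = t_a, t_b = t_b, threshold_method = method,
                    stringsAsFactors = FALSE)
  class(out) <- c("coloc_result", "data.frame")
  out
}

#' Normalize colocalization coefficients to a control condition
#'
#' Divides each coefficient by the mean coefficient of the control condition
#' (e.g. unstimulated cells at 0 h), so results are expressed as fold change
#' relative to control; the control condition's mean maps to 1 exactly.
#' Undefined (`NA`) values are excluded from control means.
#'
#' @param df data frame with a condition column and coefficient columns.
#' @param control the control condition's value in `condition_col`.
#' @param condition_col name of the condition column.
#' @param cols coefficient columns to normalize (defaults to those of
#'   [coloc_stats()] that are present).
#' @return `df` with added `<col>_rel` columns and attribute `control_id`.
#' @export
normalize_to_control <- function(df, control, condition_col = "condition",
                                 cols = intersect(c("m1", "m2", "pearson_r"),
                                                  names(df))) {
  if (!condition_col %in% names(df)) {
    stop("missing condition column '", condition_col, "'", call. = FALSE)
  }
  in_ctrl <- df[[condition_col]] == control
  if (!any(in_ctrl)) stop("control condition not present", call. = FALSE)
  for (cl in cols) {
    ctrl_mean <- mean(df[[cl]][in_ctrl], na.rm = TRUE)
    if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
      stop("control mean of '", cl,
           "' is zero or undefined (normalization error)", call. = FALSE)
    }
    df[[paste0(cl, "_rel")]] <- df[[cl]] / ctrl_mean
  }
  attr(df, "control_id") <- control
  df
}

#' Nuclei-seeded Voronoi cell regions
#'
#' Partitions the field into per-cell regions by assigning every pixel to the
#' nearest nucleus centroid — a reproducible stand-in for manual per-cell
#' cropping. Nuclei are detected as 8-connected supra-threshold components of
#' the nuclei channel.
#'
#' @param nuclei_image nuclei-channel intensity matrix.
#' @param threshold nuclei detection threshold.
#' @param min_size minimum nucleus area in pixels.
#' @param foreground optional logical mask; pixels outside it get label 0.
#' @return integer label matrix (0 = background) with attribute `centroids`
#'   (matrix of 0-based `(y, x)` nucleus centroids).
#' @export
segment_cells <- function(nuclei_image, threshold, min_size = 20,
                          foreground = NULL) {
  objs <- detect_objects(nuclei_image, threshold, min_size = min_size)
  if (nrow(objs) == 0L) stop("no nuclei detected", call. = FALSE)
  h <- nrow(nuclei_image); w <- ncol(nuclei_image)
  yy <- matrix(seq_len(h) - 1, h, w)
  xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  lab <- matrix(1L, h, w)
  best <- (yy - objs$centroid_y[1])^2 + (xx - objs$centroid_x[1])^2
  if (nrow(objs) > 1L) {
    for (i in 2:nrow(objs)) {
      d2 <- (yy - objs$centroid_y[i])^2 + (xx - objs$centroid_x[i])^2
      closer <- d2 < best
      lab[closer] <- i
      best[closer] <- d2[closer]
    }
  }
  if (!is.null(foreground)) lab[!as.logical(foreground)] <- 0L
  attr(lab, "centroids") <- cbind(y = objs$centroid_y, x = objs$centroid_x)
  lab
}

#' ER colocalization of the enzyme after Golgi-mask removal
#'
#' The composite workflow that makes partial Golgi-to-ER relocation
#' measurable: per field, max-project, binarize the Golgi-marker channel at a
#' fixed threshold, zero all enzyme signal inside that Golgi mask, then
#' compute per-cell thresholded Manders coefficients (and Pearson) between
#' the remaining out-of-Golgi enzyme signal and the ER-marker channel. With
#' A = enzyme-outside-Golgi and B = ER marker, `m2` is the fraction of ER
#' marker covered by relocated enzyme — near zero (or undefined) without
#' relocation and rising steeply with it. Cells whose supra-threshold sets
#' are empty yield `NA` coefficients with `*_defined = FALSE`.
#'
#' @param stack an [image_stack()] with enzyme, golgi_marker and er_marker
#'   roles.
#' @param thresholds named numeric vector/list with elements `enzyme`,
#'   `golgi_marker`, `er_marker`.
#' @param cell_labels integer label matrix of per-cell regions (e.g. from
#'   [segment_cells()] or ground-truth `cell_labels`).
#' @param use_projection analyse the maximum projection (default) or the full
#'   z-stack voxels.
#' @return data frame, one row per cell (columns of [coloc_stats()] plus
#'   `cell`).
#' @export
er_coloc_after_golgi_removal <- function(stack, thresholds, cell_labels,
                                         use_projection = TRUE) {
  for (role in c("enzyme", "golgi_marker", "er_marker")) {
    if (!role %in% stack$roles) {
      stop("stack lacks required role '", role, "' (configuration error)",
           call. = FALSE)
    }
  }
  thresholds <- unlist(thresholds)
  proj <- max_project(stack)
  gmask <- fixed_threshold(channel_image(proj, "golgi_marker"),
                           thresholds[["golgi_marker"]], role = "golgi_marker")
  if (use_projection) {
    enz <- channel_image(proj, "enzyme")
    erm <- channel_image(proj, "er_marker")
  } else {
    enz <- channel_image(stack, "enzyme", drop = FALSE)
    erm <- channel_image(stack, "er_marker", drop = FALSE)
  }
  enz2 <- golgi_mask_removal(enz, gmask)
  ids <- sort(unique(cell_labels[cell_labels > 0L]))
  if (length(ids) == 0L) stop("no cell regions supplied", call. = FALSE)
  rows <- lapply(ids, function(cc) {
    reg2d <- cell_labels == cc
    reg <- if (use_projection) reg2d else
      array(reg2d, dim(enz))  # broadcast region across z
    res <- coloc_stats(enz2, erm, thresholds[["enzyme"]],
                       thresholds[["er_marker"]],
                       role_a = "enzyme", role_b = "er_marker",
                       region_mask = reg, method = "fixed")
    cbind(cell = cc, res,
          analysis = if (use_projection) "projection" else "zstack")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("coloc_result", "data.frame")
  out
}
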