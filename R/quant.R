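#' Total supra-threshold intensity
#'
#' Sum of intensities over strictly supra-threshold pixels (equivalently the
#' supra-threshold pixel count times their mean intensity). The basic
#' per-image readout behind lectin (Tn) staining quantification.
#'
#' @param image intensity matrix or array.
#' @param threshold intensity threshold (strict greater-than).
#' @return intensity sum (0 when nothing is above threshold).
#' @export
total_masked_intensity <- function(image, threshold) {
  sum(image[image > threshold])
}

#' Count nuclei
#'
#' Number of 8-connected supra-threshold components of the nuclei channel
#' with area at least `min_size`.
#'
#' @param nuclei_image nuclei-channel intensity matrix.
#' @param threshold detection threshold.
#' @param min_size minimum nucleus area in pixels.
#' @return integer count.
#' @export
count_nuclei <- function(nuclei_image, threshold, min_size = 20) {
  nrow(detect_objects(nuclei_image, threshold, min_size = min_size,
                      role = "nuclei"))
}

#' Per-cell staining intensity
#'
#' Total supra-threshold image intensity normalized by the nuclei count —
#' the standard per-cell readout when individual cell boundaries are not
#' segmented.
#'
#' @param image intensity matrix (e.g. the glycan/HPL channel).
#' @param threshold intensity threshold.
#' @param nuclei_count number of nuclei in the field (>= 1).
#' @return mean intensity per cell.
#' @export
intensity_per_cell <- function(image, threshold, nuclei_count) {
  if (!is.numeric(nuclei_count) || nuclei_count < 1) {
    stop("nuclei_count must be >= 1 (quantification error)", call. = FALSE)
  }
  total_masked_intensity(image, threshold) / nuclei_count
}

#' Per-cell signal intensity within the Golgi region
#'
#' For each cell region, sums the signal channel over the Golgi area, defined
#' as the supra-threshold Golgi-marker mask intersected with the cell region
#' (e.g. phosphotyrosine staining within Giantin-demarcated Golgi). A cell
#' with an empty Golgi mask yields `NA`, flagged — not zero.
#'
#' @param signal_image intensity matrix of the signal channel.
#' @param golgi_marker_image intensity matrix of the Golgi-marker channel.
#' @param golgi_threshold threshold defining the Golgi mask.
#' @param cell_labels integer label matrix of cell regions.
#' @param signal_threshold optional threshold on the signal itself (default 0
#'   sums all positive signal in the region).
#' @return data frame: `cell`, `golgi_intensity`, `golgi_area`, `defined`.
#' @export
golgi_region_intensity <- function(signal_image, golgi_marker_image,
                                   golgi_threshold, cell_labels,
                                   signal_threshold = 0) {
  stopifnot(identical(dim(signal_image), dim(golgi_marker_image)),
            identical(dim(signal_image), dim(cell_labels)))
  gmask <- golgi_marker_image > golgi_threshold
  ids <- sort(unique(cell_labels[cell_labels > 0L]))
  res <- lapply(ids, function(cc) {
    m <- gmask & cell_labels == cc
    if (!any(m)) {
      return(data.frame(cell = cc, golgi_intensity = NA_real_,
                        golgi_area = 0L, defined = FALSE))
    }
    v <- signal_image[m]
    data.frame(cell = cc, golgi_intensity = sum(v[v > signal_threshold]),
               golgi_area = sum(m), defined = TRUE)
  })
  do.call(rbind, res)
}

#' Two-tailed paired t test
#'
#' The test used for all condition-versus-control comparisons: Student's t on
#' paired differences, two-sided p from the t distribution with `n - 1`
#' degrees of freedom. Pairs with a missing member are dropped (with the
#' retained `n` reported); identically zero-variance differences are a
#' degenerate-test error, not a p-value.
#'
#' @param values,control_values paired measurements of equal length.
#' @return list with `t`, `p`, `df`, `n`, `mean_difference`.
#' @export
paired_t_test <- function(values, control_values) {
  if (length(values) != length(control_values)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  keep <- is.finite(values) & is.finite(control_values)
  x <- values[keep]; y <- control_values[keep]
  if (length(x) < 2L) {
    stop("fewer than 2 complete pairs (degenerate test)", call. = FALSE)
  }
  if (stats::sd(x - y) == 0) {
    stop("paired differences have zero variance (degenerate test)",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n = length(x),
       mean_difference = unname(ht$estimate))
}

#' Condition-level fold changes with paired tests
#'
#' Summarises a per-cell (or per-replicate) value column into condition-level
#' mean fold changes versus a control condition, with a two-tailed paired t
#' test per condition (pairing by row order within condition; `NA` pairs
#' dropped). The control's fold versus itself is 1 by construction.
#'
#' @param df data frame with a condition column and a value column.
#' @param value_col,condition_col column names.
#' @param control control condition value.
#' @return data frame: `condition`, `mean_value`, `fold_vs_control`, `n`,
#'   `t`, `p`.
#' @export
fold_change_table <- function(df, value_col, condition_col = "condition",
                              control) {
  conds <- unique(df[[condition_col]])
  if (!control %in% conds) stop("control condition not present", call. = FALSE)
  ctrl <- df[[value_col]][df[[condition_col]] == control]
  ctrl_mean <- mean(ctrl, na.rm = TRUE)
  if (!is.finite(ctrl_mean) || ctrl_mean == 0) {
    stop("control mean is zero or undefined (normalization error)",
         call. = FALSE)
  }
  rows <- lapply(conds, function(cd) {
    v <- df[[value_col]][df[[condition_col]] == cd]
    tt <- if (cd == control) list(t = NA_real_, p = NA_real_, n = sum(is.finite(v)))
    else {
      k <- min(length(v), length(ctrl))
      tryCatch(paired_t_test(v[seq_len(k)], ctrl[seq_len(k)]),
               error = function(e) list(t = NA_real_, p = NA_real_,
                                        n = sum(is.finite(v))))
    }
    data.frame(condition = cd, mean_value = mean(v, na.rm = TRUE),
               fold_vs_control = mean(v, na.rm = TRUE) / ctrl_mean,
               n = tt$n, t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Estimate the relocation fraction from enzyme signal partitioning
#'
#' Parameter-recovery readout: the background-corrected enzyme intensity
#' outside the Golgi mask as a fraction of the background-corrected total,
#' clipped to `[0, 1]`. With a marker-derived Golgi mask this estimates the
#' fraction of enzyme relocated out of the Golgi.
#'
#' @param enzyme_image enzyme-channel intensity matrix (or `[y, x, z]`
#'   array; the 2-D mask is applied to every slice).
#' @param golgi_mask logical matrix of the Golgi region.
#' @param background scalar background level subtracted per pixel before
#'   summing (e.g. the extracellular median); negative corrected values are
#'   clipped at zero.
#' @return estimated fraction in `[0, 1]`.
#' @export
estimate_relocation_fraction <- function(enzyme_image, golgi_mask,
                                         background = 0) {
  golgi_mask <- unclass_mask(golgi_mask)
  d <- dim(enzyme_image)
  if (!identical(d[1:2], dim(golgi_mask))) {
    stop("enzyme image and Golgi mask shapes differ (dimension error)",
         call. = FALSE)
  }
  corr <- pmax(enzyme_image - background, 0)
  total <- sum(corr)
  if (total <= 0) {
    stop("non-positive total enzyme signal (estimation error)", call. = FALSE)
  }
  inside <- if (length(d) == 2L) sum(corr[golgi_mask]) else
    sum(apply(corr, 3L, function(s) sum(s[golgi_mask])))
  min(max((total - inside) / total, 0), 1)
}

#' Supra-threshold out-of-Golgi enzyme fraction
#'
#' The fraction of supra-threshold enzyme intensity lying outside the Golgi
#' mask. Because only pixels above the fixed threshold count, this is the
#' readout through which per-slice photobleaching visibly erodes the weak,
#' diluted ER-resident signal while the bright Golgi pool persists. Works on
#' 2-D images or full `[y, x, z]` stacks (2-D mask broadcast across z).
#'
#' @param enzyme_image intensity matrix or `[y, x, z]` array.
#' @param golgi_mask logical matrix.
#' @param threshold fixed intensity threshold (strict greater-than).
#' @return fraction in `[0, 1]` (`NA` if nothing is above threshold).
#' @export
supra_out_of_golgi_fraction <- function(enzyme_image, golgi_mask, threshold) {
  golgi_mask <- unclass_mask(golgi_mask)
  d <- dim(enzyme_image)
  if (!identical(d[1:2], dim(golgi_mask))) {
    stop("enzyme image and Golgi mask shapes differ (dimension error)",
         call. = FALSE)
  }
  total <- total_masked_intensity(enzyme_image, threshold)
  if (total <= 0) return(NA_real_)
  outside <- golgi_mask_removal(enzyme_image, golgi_mask)
  total_masked_intensity(outside, threshold) / total
}
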