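# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a small union-find pass.
label_components8 <- function(mask) {
  mask <- unclass_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  dr <- cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1]))   # down-right
  dl <- cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  pairs <- rbind(dr, dl)
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, integer(1))
    relab <- match(root, sort(unique(root)))
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

#' Detect discrete objects (puncta) in one channel
#'
#' Strict supra-threshold binarization, 8-connected component labelling,
#' removal of components smaller than `min_size`, and an intensity-weighted
#' sub-pixel centroid per remaining object. Centroids are 0-based `(y, x)`
#' pixel-centre coordinates.
#'
#' @param image intensity matrix.
#' @param threshold detection threshold (strict greater-than).
#' @param min_size minimum object area in pixels (>= 1).
#' @param role channel role recorded as provenance.
#' @return data frame of class `object_set`: `label`, `centroid_y`,
#'   `centroid_x`, `total_intensity`, `area`, with attributes `threshold`,
#'   `min_size`, `source_channel`. Zero rows when nothing is detected.
#' @examples
#' img <- matrix(0, 5, 5); img[2, 2:3] <- c(10, 30)
#' detect_objects(img, 1, min_size = 1)$centroid_x  # (0*10 + 1*30)/40
#' @export
detect_objects <- function(image, threshold, min_size = 4,
                           role = NA_character_) {
  stopifnot(min_size >= 1)
  lab <- label_components8(image > threshold)
  empty <- data.frame(label = integer(), centroid_y = numeric(),
                      centroid_x = numeric(), total_intensity = numeric(),
                      area = integer())
  out <- empty
  if (max(lab) > 0L) {
    idx <- which(lab > 0L)
    li <- lab[idx]
    inten <- image[idx]
    h <- nrow(image)
    y0 <- (idx - 1L) %% h          # 0-based row
    x0 <- (idx - 1L) %/% h         # 0-based col
    area <- tabulate(li)
    tot <- as.vector(rowsum(inten, li))
    cy <- as.vector(rowsum(inten * y0, li)) / tot
    cx <- as.vector(rowsum(inten * x0, li)) / tot
    keep <- which(area >= min_size)
    if (length(keep)) {
      out <- data.frame(label = seq_along(keep),
                        centroid_y = cy[keep], centroid_x = cx[keep],
                        total_intensity = tot[keep], area = area[keep])
    }
  }
  attr(out, "threshold") <- threshold
  attr(out, "min_size") <- min_size
  attr(out, "source_channel") <- role
  class(out) <- c("object_set", "data.frame")
  out
}

#' Object-based colocalization by centroid distance
#'
#' An object of set A counts as colocalized if some object of set B has an
#' intensity-weighted centroid strictly closer than `resolution_px` (the
#' microscope's resolution expressed in pixels); a distance exactly equal to
#' the resolution does not count. Matching is non-exclusive: one B object may
#' satisfy several A objects. The result is the percentage of A objects
#' colocalized; with no A objects the percentage is undefined (`NA`,
#' `defined = FALSE`).
#'
#' @param set_a,set_b [detect_objects()] results (query and reference).
#' @param resolution_px matching radius in pixels, > 0.
#' @param mode `"any"` (default, non-exclusive matching) or `"mutual"`:
#'   in mutual mode an A object only counts if it is also the nearest A
#'   object of its nearest B — a stricter pairing for sensitivity analysis.
#' @return list with `percent_a_colocalized`, `defined`, `n_objects_a`,
#'   `n_objects_b`, `resolution_px`, and `matches` (data frame: A label,
#'   nearest B label, distance, colocalized flag).
#' @export
object_coloc <- function(set_a, set_b, resolution_px,
                         mode = c("any", "mutual")) {
  stopifnot(is.numeric(resolution_px), resolution_px > 0)
  mode <- match.arg(mode)
  n_a <- nrow(set_a); n_b <- nrow(set_b)
  if (n_a == 0L) {
    return(list(percent_a_colocalized = NA_real_, defined = FALSE,
                n_objects_a = 0L, n_objects_b = n_b,
                resolution_px = resolution_px,
                matches = data.frame(label_a = integer(),
                                     nearest_b = integer(),
                                     distance = numeric(),
                                     colocalized = logical())))
  }
  if (n_b == 0L) {
    matches <- data.frame(label_a = set_a$label, nearest_b = NA_integer_,
                          distance = Inf, colocalized = FALSE)
  } else {
    dy <- outer(set_a$centroid_y, set_b$centroid_y, "-")
    dx <- outer(set_a$centroid_x, set_b$centroid_x, "-")
    d <- sqrt(dy^2 + dx^2)
    nearest <- apply(d, 1L, which.min)
    dist <- d[cbind(seq_len(n_a), nearest)]
    hit <- dist < resolution_px
    if (mode == "mutual") {
      back <- apply(d, 2L, which.min)      # nearest A of each B
      hit <- hit & back[nearest] == seq_len(n_a)
    }
    matches <- data.frame(label_a = set_a$label,
                          nearest_b = set_b$label[nearest],
                          distance = dist,
                          colocalized = hit)
  }
  list(percent_a_colocalized = 100 * sum(matches$colocalized) / n_a,
       defined = TRUE, n_objects_a = n_a, n_objects_b = n_b,
       resolution_px = resolution_px, matches = matches)
}

#' Microscope resolution in pixels from optics metadata
#'
#' Rayleigh criterion `0.61 * lambda / NA` converted to pixels.
#'
#' @param wavelength_um emission wavelength in micrometres.
#' @param numerical_aperture objective numerical aperture.
#' @param pixel_size_um micrometres per pixel.
#' @return resolution in pixels.
#' @export
rayleigh_resolution_px <- function(wavelength_um, numerical_aperture,
                                   pixel_size_um) {
  stopifnot(wavelength_um > 0, numerical_aperture > 0, pixel_size_um > 0)
  0.61 * wavelength_um / numerical_aperture / pixel_size_um
}

#' Per-cell object colocalization of punctate channels
#'
#' Runs [detect_objects()] on the max projections of a punctate query channel
#' (default ERGIC) and a reference channel (default enzyme) within each cell
#' region, then [object_coloc()] per cell. Used to quantify relocation as the
#' percentage of ERGIC structures whose centres fall within the microscope
#' resolution of an enzyme structure.
#'
#' @param stack an [image_stack()] containing both roles.
#' @param thresholds named vector/list with one detection threshold per role.
#' @param cell_labels integer label matrix of cell regions; `NULL` treats the
#'   whole field as one region.
#' @param resolution_px matching radius in pixels.
#' @param min_size minimum object area.
#' @param role_a,role_b query and reference channel roles.
#' @return data frame: one row per cell with `cell`, `percent_a_colocalized`,
#'   `defined`, `n_objects_a`, `n_objects_b`, `resolution_px`.
#' @export
ergic_coloc_pipeline <- function(stack, thresholds, cell_labels = NULL,
                                 resolution_px, min_size = 4,
                                 role_a = "ergic", role_b = "enzyme") {
  for (role in c(role_a, role_b)) {
    if (!role %in% stack$roles) {
      stop("stack lacks required role '", role, "' (configuration error)",
           call. = FALSE)
    }
  }
  thresholds <- unlist(thresholds)
  proj <- max_project(stack)
  img_a <- channel_image(proj, role_a)
  img_b <- channel_image(proj, role_b)
  if (is.null(cell_labels)) cell_labels <- matrix(1L, nrow(img_a), ncol(img_a))
  ids <- sort(unique(cell_labels[cell_labels > 0L]))
  rows <- lapply(ids, function(cc) {
    inreg <- cell_labels == cc
    a <- img_a; a[!inreg] <- 0
    b <- img_b; b[!inreg] <- 0
    oa <- detect_objects(a, thresholds[[role_a]], min_size, role = role_a)
    ob <- detect_objects(b, thresholds[[role_b]], min_size, role = role_b)
    oc <- object_coloc(oa, ob, resolution_px)
    data.frame(cell = cc, percent_a_colocalized = oc$percent_a_colocalized,
               defined = oc$defined, n_objects_a = oc$n_objects_a,
               n_objects_b = oc$n_objects_b, resolution_px = resolution_px)
  })
  do.call(rbind, rows)
}
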