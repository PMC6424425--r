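#' Multi-channel image stacks
#'
#' An `image_stack` holds a multi-channel fluorescence volume as an unsigned
#' integer-valued array indexed `[y, x, z, channel]`, together with the
#' micrometre pixel size, the bit depth (8 or 16) and one biological role per
#' channel. Roles name what was stained, not the fluorophore:
#' `"nuclei"`, `"golgi_marker"` (e.g. TGN46, Giantin), `"er_marker"`
#' (e.g. calnexin), `"enzyme"` (a GALNT), `"glycan"` (Tn lectin such as HPL),
#' `"phospho"` and `"ergic"` (ERGIC53, punctate).
#'
#' @param pixels numeric array `[y, x, z, channel]` (a `[y, x, channel]` array
#'   or a list of matrices is promoted to `z = 1`).
#' @param roles character vector of channel roles, one per channel, unique.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return an object of class `image_stack`.
#' @examples
#' px <- array(0, c(8, 8, 1, 2))
#' s <- image_stack(px, roles = c("nuclei", "enzyme"))
#' dim(channel_image(s, "enzyme"))
#' @export
image_stack <- function(pixels, roles, pixel_size = 0.1, bit_depth = 16) {
  if (is.list(pixels)) {
    pixels <- array(unlist(pixels, use.names = FALSE),
                    c(dim(pixels[[1]]), 1L, length(pixels)))
  }
  if (length(dim(pixels)) == 3L) {
    dim(pixels) <- c(dim(pixels)[1:2], 1L, dim(pixels)[3])
  }
  if (length(dim(pixels)) != 4L) {
    stop("'pixels' must be a [y, x, z, channel] array", call. = FALSE)
  }
  roles <- as.character(roles)
  known <- c("nuclei", "golgi_marker", "er_marker", "enzyme", "glycan",
             "phospho", "ergic")
  bad <- setdiff(roles, known)
  if (length(bad)) {
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         " (configuration error)", call. = FALSE)
  }
  if (anyDuplicated(roles)) stop("channel roles must be unique", call. = FALSE)
  if (length(roles) != dim(pixels)[4]) {
    stop("length(roles) must equal the channel count", call. = FALSE)
  }
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1) {
    stop("intensities outside [0, 2^bit_depth - 1]", call. = FALSE)
  }
  structure(list(pixels = pixels, roles = roles,
                 pixel_size = as.numeric(pixel_size),
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack: %d x %d px, %d z-slice(s), %d channel(s), %d-bit\n",
              d[1], d[2], d[3], d[4], x$bit_depth))
  cat("  roles:", paste(x$roles, collapse = ", "), "\n")
  cat(sprintf("  pixel size: %g um/px\n", x$pixel_size))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

#' Extract one channel from a stack
#'
#' @param stack an `image_stack`.
#' @param role a channel role present in the stack.
#' @param drop drop the z dimension when there is a single slice.
#' @return a `[y, x]` matrix (when `z = 1` and `drop = TRUE`) or a
#'   `[y, x, z]` array.
#' @export
channel_image <- function(stack, role, drop = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(role, stack$roles)
  if (is.na(i)) {
    stop("role '", role, "' not present in stack (configuration error)",
         call. = FALSE)
  }
  out <- stack$pixels[, , , i, drop = FALSE]
  dim(out) <- dim(stack$pixels)[1:3]
  if (drop && dim(out)[3] == 1L) dim(out) <- dim(out)[1:2]
  out
}

#' Write a stack as a multi-page TIFF
#'
#' Pages are written channel-major by default (all z slices of the first
#' channel, then the second channel, ...); `page_order = "z-major"` interleaves
#' channels within each slice instead. Intensities are rounded and clipped to
#' the stack's bit depth before writing.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @param page_order `"channel-major"` (default) or `"z-major"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, page_order = c("channel-major", "z-major")) {
  stopifnot(inherits(stack, "image_stack"))
  page_order <- match.arg(page_order)
  d <- dim(stack$pixels)
  maxv <- 2^stack$bit_depth - 1
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  if (page_order == "channel-major") {
    for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
      pages[[k]] <- round(stack$pixels[, , z, ch]) / maxv
      k <- k + 1L
    }
  } else {
    for (z in seq_len(d[3])) for (ch in seq_len(d[4])) {
      pages[[k]] <- round(stack$pixels[, , z, ch]) / maxv
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' The page count must be divisible by the number of declared roles; the
#' per-channel z depth is inferred as `pages / channels`. The page dialect
#' must match how the file was written (see [write_stack()]).
#'
#' @param path a multi-page TIFF file.
#' @param roles channel roles in file order.
#' @param pixel_size micrometres per pixel to attach.
#' @param page_order `"channel-major"` (default) or `"z-major"`.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, roles, pixel_size = 0.1,
                       page_order = c("channel-major", "z-major")) {
  page_order <- match.arg(page_order)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(roles)
  if (length(pages) %% n_ch != 0L) {
    stop(sprintf(
      "page count (%d) not divisible by declared channel count (%d) (format error)",
      length(pages), n_ch), call. = FALSE)
  }
  n_z <- length(pages) %/% n_ch
  vals <- unlist(pages, use.names = FALSE)
  bit_depth <- if (max(vals) > 255) 16L else 8L
  d <- dim(pages[[1]])
  px <- array(0, c(d[1], d[2], n_z, n_ch))
  k <- 1L
  if (page_order == "channel-major") {
    for (ch in seq_len(n_ch)) for (z in seq_len(n_z)) {
      px[, , z, ch] <- pages[[k]]; k <- k + 1L
    }
  } else {
    for (z in seq_len(n_z)) for (ch in seq_len(n_ch)) {
      px[, , z, ch] <- pages[[k]]; k <- k + 1L
    }
  }
  image_stack(px, roles, pixel_size = pixel_size, bit_depth = bit_depth)
}

#' Maximum intensity projection
#'
#' Collapses a z-stack to one 2-D image per channel by taking the per-pixel
#' maximum across slices, the standard way to pool serial confocal sections
#' before 2-D quantification. A single-slice input is returned unchanged.
#'
#' @param x an `image_stack`, a `[y, x, z]` array, or a matrix.
#' @return same kind of object with `z = 1` (matrix for array input).
#' @export
max_project <- function(x) UseMethod("max_project")

#' @export
max_project.image_stack <- function(x) {
  d <- dim(x$pixels)
  out <- array(0, c(d[1], d[2], 1L, d[4]))
  for (ch in seq_len(d[4])) {
    m <- x$pixels[, , 1L, ch]
    if (d[3] > 1L) for (z in 2:d[3]) m <- pmax(m, x$pixels[, , z, ch])
    out[, , 1L, ch] <- m
  }
  image_stack(out, x$roles, pixel_size = x$pixel_size, bit_depth = x$bit_depth)
}

#' @export
max_project.default <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  stopifnot(length(d) == 3L, d[3] >= 1L)
  m <- x[, , 1L]
  if (d[3] > 1L) for (z in 2:d[3]) m <- pmax(m, x[, , z])
  m
}

#' Grayscale inversion for display
#'
#' Returns `max_value - pixel` so that weak out-of-Golgi signal shows as dark
#' on white. Display-only: inverted images must never be fed back into
#' quantification.
#'
#' @param image matrix or array of intensities.
#' @param bit_depth bit depth defining `max_value = 2^bit_depth - 1`.
#' @return inverted image, same shape.
#' @export
invert_display <- function(image, bit_depth = 16) {
  stopifnot(bit_depth %in% c(8, 16))
  (2^bit_depth - 1) - image
}
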