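#' Parameters for the synthetic relocation-field simulator
#'
#' Bundles and validates every knob of [simulate_field()]. The defaults are
#' the study conditions used throughout this package's benchmarks: 20
#' HeLa-like cells per field, a bright compact perinuclear Golgi
#' (`golgi_peak`), a dim volume-filling reticular ER (`er_peak` well below
#' `golgi_peak`), Poisson photon noise plus Gaussian read noise, and a single
#' in-focus plane (`n_z_slices = 1`; axial sectioning and per-slice
#' photobleaching are enabled by raising `n_z_slices` and `bleach_rate`).
#'
#' @param n_cells number of cells per field (>= 1).
#' @param relocation_fraction fraction `f` in `[0, 1]` of each cell's enzyme
#'   photon budget redistributed from the Golgi to the ER.
#' @param tn_gain glycan amplification gain `g >= 0`: extra glycan signal per
#'   unit of ER-resident enzyme signal, modelling the large Tn increase that a
#'   small amount of relocated enzyme can produce on abundant ER substrates.
#' @param golgi_peak noise-free Golgi enzyme intensity (per pixel, `f = 0`).
#' @param er_peak noise-free ER-marker channel intensity; keep well below
#'   `golgi_peak` (the ER is dim and dispersed).
#' @param cell_radius cell radius in pixels.
#' @param field_shape `(height, width)` in pixels, or `NULL` to size the field
#'   from the cell grid.
#' @param pixel_size micrometres per pixel.
#' @param n_z_slices number of z slices (1 = single in-focus plane).
#' @param psf_sigma_xy,psf_sigma_z Gaussian blur sigmas (pixels / slices)
#'   applied by [apply_optics()]; 0 disables.
#' @param bleach_rate per-slice fractional photobleaching loss `b` in `[0, 1)`;
#'   slice `k` (0-based acquisition order) is attenuated by `(1 - b)^k`.
#' @param poisson_noise logical; Poisson photon noise.
#' @param read_noise_sd sd of additive zero-mean Gaussian read noise.
#' @param nuclei_peak,golgi_marker_peak,glycan_base_peak marker/baseline
#'   intensities for the nuclei, Golgi-marker and glycan channels.
#' @param bit_depth 8 or 16.
#' @param seed integer RNG seed; identical parameters (including seed) give
#'   bit-identical fields.
#' @return a validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_cells = 20,
                              relocation_fraction = 0,
                              tn_gain = 8,
                              golgi_peak = 3000,
                              er_peak = 300,
                              cell_radius = 26,
                              field_shape = NULL,
                              pixel_size = 0.1,
                              n_z_slices = 1,
                              psf_sigma_xy = 0,
                              psf_sigma_z = 0,
                              bleach_rate = 0,
                              poisson_noise = TRUE,
                              read_noise_sd = 2,
                              nuclei_peak = 1500,
                              golgi_marker_peak = golgi_peak,
                              glycan_base_peak = 0.3 * golgi_peak,
                              bit_depth = 16,
                              seed = 1) {
  p <- list(n_cells = as.integer(n_cells),
            relocation_fraction = relocation_fraction,
            tn_gain = tn_gain,
            golgi_peak = golgi_peak, er_peak = er_peak,
            cell_radius = cell_radius, field_shape = field_shape,
            pixel_size = pixel_size,
            n_z_slices = as.integer(n_z_slices),
            psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
            bleach_rate = bleach_rate,
            poisson_noise = isTRUE(poisson_noise),
            read_noise_sd = read_noise_sd,
            nuclei_peak = nuclei_peak,
            golgi_marker_peak = golgi_marker_peak,
            glycan_base_peak = glycan_base_peak,
            bit_depth = as.integer(bit_depth),
            seed = as.integer(seed))
  check <- function(ok, field, msg) {
    if (!ok) stop("invalid parameter '", field, "': ", msg, call. = FALSE)
  }
  check(p$n_cells >= 1L, "n_cells", "must be >= 1")
  check(p$relocation_fraction >= 0 && p$relocation_fraction <= 1,
        "relocation_fraction", "must be in [0, 1]")
  check(p$tn_gain >= 0, "tn_gain", "must be >= 0")
  check(p$bleach_rate >= 0 && p$bleach_rate < 1, "bleach_rate",
        "must be in [0, 1)")
  check(p$n_z_slices >= 1L, "n_z_slices", "must be >= 1")
  for (f in c("golgi_peak", "er_peak", "cell_radius", "pixel_size",
              "psf_sigma_xy", "psf_sigma_z", "read_noise_sd", "nuclei_peak",
              "golgi_marker_peak", "glycan_base_peak")) {
    check(is.numeric(p[[f]]) && length(p[[f]]) == 1L && p[[f]] >= 0, f,
          "must be a non-negative number")
  }
  check(p$bit_depth %in% c(8L, 16L), "bit_depth", "must be 8 or 16")
  if (!is.null(p$field_shape)) {
    check(length(p$field_shape) == 2L && all(p$field_shape >= 2 * p$cell_radius),
          "field_shape", "must be (height, width), each >= cell diameter")
  }
  class(p) <- "simulation_params"
  p
}

# Evaluate code under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gaussian z-profile of the axially compact Golgi, 0-based slice index.
golgi_z_profile <- function(n_z) {
  k <- seq_len(n_z) - 1
  exp(-(k - (n_z - 1) / 2)^2 / (2 * max(1, n_z / 12)^2))
}

#' Simulate a multi-cell relocation field with ground truth
#'
#' Renders a field of cells, each with a nucleus, a compact perinuclear Golgi
#' crescent (area at most ~10% of the cell) and a reticular ER filling the
#' cytoplasm (at least 5x the Golgi area), then distributes each cell's
#' enzyme photon budget between Golgi and ER according to the relocation
#' fraction `f`. The budget is conserved: the total noise-free enzyme signal
#' does not depend on `f`, only its location does, so relocation dilutes the
#' signal over the much larger ER at correspondingly lower per-pixel
#' brightness. The glycan channel is a Golgi baseline plus `tn_gain * f` times
#' the ER enzyme signal, so total glycan increases with relocation. With
#' `n_z_slices > 1` the Golgi is axially compact (Gaussian z-profile) while
#' nuclei, ER and cell body span all slices; budgets are conserved in 3-D, so
#' sectioning further dilutes the ER enzyme signal per voxel. Optics and noise
#' are then applied via [apply_optics()].
#'
#' @param params a [simulation_params()] object.
#' @return list with elements `stack` (an [image_stack()] with channels
#'   nuclei, golgi_marker, er_marker, enzyme, glycan) and `truth` (a
#'   `ground_truth` object: labelled compartment masks plus per-cell
#'   noise-free photon budgets; see [truth_mask()]).
#' @examples
#' sim <- simulate_field(simulation_params(n_cells = 4, seed = 1,
#'                                         poisson_noise = FALSE,
#'                                         read_noise_sd = 0))
#' sim$truth$cells$enzyme_in_er /
#'   (sim$truth$cells$enzyme_in_er + sim$truth$cells$enzyme_in_golgi)
#' @export
simulate_field <- function(params) {
  if (!inherits(params, "simulation_params")) {
    params <- do.call(simulation_params, params)
  }
  with_seed(params$seed, simulate_field_impl(params))
}

simulate_field_impl <- function(p) {
  r_cell <- p$cell_radius
  jit <- 4
  rows <- max(1L, floor(sqrt(p$n_cells)))
  cols <- ceiling(p$n_cells / rows)
  spacing <- ceiling(2 * r_cell + 2 * jit + 4)
  if (is.null(p$field_shape)) {
    h <- rows * spacing
    w <- cols * spacing
  } else {
    h <- p$field_shape[1]; w <- p$field_shape[2]
    if (floor(h / rows) < spacing || floor(w / cols) < spacing) {
      stop("invalid parameter 'field_shape': too small for ", p$n_cells,
           " non-overlapping cells of radius ", r_cell, call. = FALSE)
    }
  }
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)

  cell_lab <- matrix(0L, h, w)
  nuc_lab  <- matrix(0L, h, w)
  gol_lab  <- matrix(0L, h, w)
  er_lab   <- matrix(0L, h, w)

  # one smooth noise field drives every cell's reticular ER pattern
  noise_raw <- matrix(stats::rnorm(h * w), h, w)
  er_noise <- EBImage::imageData(EBImage::gblur(noise_raw, sigma = 2))

  n <- p$n_cells
  centers <- matrix(0, n, 2)
  nuc_cent <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    gi <- (i - 1L) %/% cols
    gj <- (i - 1L) %% cols
    cy <- (gi + 0.5) * (h / rows) + stats::runif(1, -jit, jit)
    cx <- (gj + 0.5) * (w / cols) + stats::runif(1, -jit, jit)
    centers[i, ] <- c(cy, cx)
    d2 <- (yy - cy)^2 + (xx - cx)^2
    cell <- d2 <= r_cell^2
    r_nuc <- 0.38 * r_cell
    off_a <- stats::runif(1, 0, 2 * pi)
    off_r <- stats::runif(1, 0, 0.1 * r_cell)
    ny <- cy + off_r * sin(off_a); nx <- cx + off_r * cos(off_a)
    nuc_cent[i, ] <- c(ny, nx)
    dn2 <- (yy - ny)^2 + (xx - nx)^2
    nuc <- dn2 <= r_nuc^2
    # compact crescent hugging the nucleus
    phi <- stats::runif(1, 0, 2 * pi)
    ang <- atan2(yy - ny, xx - nx)
    dang <- abs(((ang - phi + pi) %% (2 * pi)) - pi)
    gol <- dn2 > (r_nuc + 1)^2 & dn2 <= (r_nuc + 7)^2 & dang <= 55 * pi / 180 &
      cell & !nuc
    cyto <- cell & !nuc & !gol
    thr <- stats::quantile(er_noise[cyto], 0.40, names = FALSE)
    er <- cyto & er_noise > thr
    cell_lab[cell] <- i
    nuc_lab[nuc] <- i
    gol_lab[gol] <- i
    er_lab[er] <- i
  }

  garea <- tabulate(gol_lab[gol_lab > 0L], nbins = n)
  earea <- tabulate(er_lab[er_lab > 0L], nbins = n)
  if (any(garea == 0L) || any(earea == 0L)) {
    stop("degenerate geometry: empty Golgi or ER compartment", call. = FALSE)
  }

  f <- p$relocation_fraction
  budget <- p$golgi_peak * garea           # per-cell enzyme photon budget
  er_px_value <- f * budget / earea        # per-pixel ER enzyme intensity

  t_nuc <- p$nuclei_peak * (nuc_lab > 0L)
  t_gm  <- p$golgi_marker_peak * (gol_lab > 0L)
  t_erm <- p$er_peak * (er_lab > 0L)
  t_enz <- matrix(0, h, w)
  t_enz[gol_lab > 0L] <- (1 - f) * p$golgi_peak
  idx <- which(er_lab > 0L)
  t_enz[idx] <- er_px_value[er_lab[idx]]
  t_gly <- matrix(0, h, w)
  t_gly[gol_lab > 0L] <- p$glycan_base_peak
  t_gly[idx] <- p$tn_gain * er_px_value[er_lab[idx]]

  roles <- c("nuclei", "golgi_marker", "er_marker", "enzyme", "glycan")
  n_z <- p$n_z_slices
  px <- array(0, c(h, w, n_z, 5L))
  if (n_z == 1L) {
    px[, , 1L, ] <- c(t_nuc, t_gm, t_erm, t_enz, t_gly)
  } else {
    gz <- golgi_z_profile(n_z)
    gol_px <- gol_lab > 0L
    # ER sheets span much of the cell's axial extent (a band per pixel around
    # the mid-plane) while the Golgi is axially compact, so sectioning dilutes
    # the ER enzyme signal toward the detection floor.
    band <- max(1L, round(n_z * 0.4))
    ctr <- round((n_z + 1) / 2 + stats::rnorm(length(idx), 0, n_z / 8))
    start <- pmin(pmax(ctr - floor(band / 2), 1L), n_z - band + 1L)
    for (k in seq_len(n_z)) {
      # markers: nuclei span the stack, Golgi compact, ER in its bands
      px[, , k, 1L] <- t_nuc
      px[, , k, 2L] <- t_gm * (gz[k] / max(gz))
      in_band <- start <= k & k <= start + band - 1L
      erm_k <- matrix(0, h, w)
      erm_k[idx[in_band]] <- t_erm[idx[in_band]]
      px[, , k, 3L] <- erm_k
      # budget channels: 3-D photon budget conserved (column sums = template)
      enz_k <- matrix(0, h, w)
      enz_k[gol_px] <- t_enz[gol_px] * gz[k] / sum(gz)
      enz_k[idx[in_band]] <- t_enz[idx[in_band]] / band
      px[, , k, 4L] <- enz_k
      gly_k <- matrix(0, h, w)
      gly_k[gol_px] <- t_gly[gol_px] * gz[k] / sum(gz)
      gly_k[idx[in_band]] <- t_gly[idx[in_band]] / band
      px[, , k, 5L] <- gly_k
    }
  }
  stack <- image_stack(px, roles, pixel_size = p$pixel_size,
                       bit_depth = p$bit_depth)
  stack <- apply_optics(stack,
                        psf_sigma_xy = p$psf_sigma_xy,
                        psf_sigma_z = p$psf_sigma_z,
                        bleach_rate = p$bleach_rate,
                        poisson_noise = p$poisson_noise,
                        read_noise_sd = p$read_noise_sd)

  cells <- data.frame(
    cell = seq_len(n),
    center_y = centers[, 1] - 1, center_x = centers[, 2] - 1,
    nucleus_y = nuc_cent[, 1] - 1, nucleus_x = nuc_cent[, 2] - 1,
    cell_area = tabulate(cell_lab[cell_lab > 0L], nbins = n),
    golgi_area = garea, er_area = earea,
    enzyme_in_golgi = (1 - f) * budget,
    enzyme_in_er = f * budget,
    glycan_total = p$glycan_base_peak * garea + p$tn_gain * f * budget,
    f = f)
  truth <- structure(list(cell_labels = cell_lab, nucleus_labels = nuc_lab,
                          golgi_labels = gol_lab, er_labels = er_lab,
                          cells = cells, params = p),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d cell(s), f = %g, field %d x %d px\n",
              nrow(x$cells), x$cells$f[1], nrow(x$cell_labels),
              ncol(x$cell_labels)))
  invisible(x)
}

#' Extract a ground-truth compartment mask
#'
#' @param truth a `ground_truth` from [simulate_field()].
#' @param compartment one of `"cell"`, `"nucleus"`, `"golgi"`, `"er"`.
#' @param cell a cell id, or `NULL` for the union over all cells.
#' @return logical matrix.
#' @export
truth_mask <- function(truth, compartment = c("cell", "nucleus", "golgi", "er"),
                       cell = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  compartment <- match.arg(compartment)
  lab <- switch(compartment, cell = truth$cell_labels,
                nucleus = truth$nucleus_labels,
                golgi = truth$golgi_labels, er = truth$er_labels)
  if (is.null(cell)) lab > 0L else lab == cell
}

#' Apply acquisition optics and noise to a stack
#'
#' Models serial confocal acquisition: optional lateral and axial Gaussian
#' blur, per-slice photobleaching (slice `k`, 0-based acquisition order, is
#' attenuated by `(1 - bleach_rate)^k`, identically across channels), then
#' Poisson photon noise and additive Gaussian read noise, rounded and clipped
#' to the bit-depth range. With all effects disabled the stack is returned
#' unchanged.
#'
#' @param stack an [image_stack()].
#' @param psf_sigma_xy lateral Gaussian sigma in pixels (0 = off).
#' @param psf_sigma_z axial Gaussian sigma in slices (0 = off).
#' @param bleach_rate per-slice fractional loss in `[0, 1)`.
#' @param poisson_noise logical; Poisson noise on the photon signal.
#' @param read_noise_sd sd of zero-mean Gaussian read noise.
#' @return an [image_stack()] of identical shape.
#' @export
apply_optics <- function(stack, psf_sigma_xy = 0, psf_sigma_z = 0,
                         bleach_rate = 0, poisson_noise = FALSE,
                         read_noise_sd = 0) {
  stopifnot(inherits(stack, "image_stack"))
  if (bleach_rate < 0 || bleach_rate >= 1) {
    stop("invalid parameter 'bleach_rate': must be in [0, 1)", call. = FALSE)
  }
  px <- stack$pixels
  d <- dim(px)
  if (psf_sigma_xy > 0) {
    for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
      px[, , z, ch] <- EBImage::imageData(
        EBImage::gblur(px[, , z, ch], sigma = psf_sigma_xy))
    }
    px[px < 0] <- 0   # filter ringing must not create negative photon counts
  }
  if (psf_sigma_z > 0 && d[3] > 1L) {
    half <- ceiling(3 * psf_sigma_z)
    kern <- stats::dnorm(-half:half, sd = psf_sigma_z)
    for (ch in seq_len(d[4])) {
      old <- px[, , , ch, drop = FALSE]
      dim(old) <- d[1:3]
      for (z in seq_len(d[3])) {
        ks <- max(1L, z - half):min(d[3], z + half)
        wgt <- kern[ks - z + half + 1L]
        wgt <- wgt / sum(wgt)
        acc <- matrix(0, d[1], d[2])
        for (j in seq_along(ks)) acc <- acc + wgt[j] * old[, , ks[j]]
        px[, , z, ch] <- acc
      }
    }
  }
  if (bleach_rate > 0) {
    for (z in seq_len(d[3])) {
      px[, , z, ] <- px[, , z, ] * (1 - bleach_rate)^(z - 1L)
    }
  }
  noisy <- poisson_noise || read_noise_sd > 0
  if (poisson_noise) {
    px[] <- stats::rpois(length(px), lambda = px)
  }
  if (read_noise_sd > 0) {
    px <- px + stats::rnorm(length(px), sd = read_noise_sd)
  }
  if (noisy) {
    px <- round(pmin(pmax(px, 0), 2^stack$bit_depth - 1))
  }
  image_stack(px, stack$roles, pixel_size = stack$pixel_size,
              bit_depth = stack$bit_depth)
}

#' Simulate a two-channel punctate field
#'
#' Generates punctate ERGIC-like and enzyme-like channels for object-based
#' colocalization benchmarks: `n_b` reference puncta placed uniformly, and
#' `n_a` query puncta of which a fraction `coloc_fraction` is co-placed
#' exactly on randomly chosen reference puncta while the rest are placed
#' independently. Each punctum is a Gaussian spot.
#'
#' @param shape `(height, width)` in pixels.
#' @param n_a,n_b numbers of puncta in the query (first role) and reference
#'   (second role) channels.
#' @param coloc_fraction fraction of query puncta co-placed on reference
#'   puncta, in `[0, 1]`.
#' @param peak spot amplitude; `spot_sigma` its Gaussian sigma in pixels.
#' @param spot_sigma Gaussian sigma of each spot.
#' @param roles channel roles, query first.
#' @param min_sep minimum centre-to-centre separation within each channel, in
#'   pixels (keeps structures discrete so detection never merges them).
#' @param poisson_noise,read_noise_sd acquisition noise (off by default).
#' @param seed RNG seed.
#' @return list with `stack` (two-channel [image_stack()]) and `truth`
#'   (data frames `a` and `b` of placed 0-based centres).
#' @export
simulate_puncta_field <- function(shape = c(128, 128), n_a = 25, n_b = 25,
                                  coloc_fraction = 0, peak = 2000,
                                  spot_sigma = 1.2,
                                  roles = c("ergic", "enzyme"),
                                  min_sep = 6 * spot_sigma,
                                  poisson_noise = FALSE, read_noise_sd = 0,
                                  seed = 1) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1, n_a >= 0, n_b >= 0)
  with_seed(seed, {
    h <- shape[1]; w <- shape[2]; m <- 6
    place <- function(k) {
      pts <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(pts) < k && tries < 200L * max(k, 1L)) {
        cand <- c(stats::runif(1, m, h - m), stats::runif(1, m, w - m))
        if (nrow(pts) == 0L ||
            min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
              min_sep) {
          pts <- rbind(pts, cand)
        }
        tries <- tries + 1L
      }
      if (nrow(pts) < k) {
        stop("could not place ", k, " puncta at min_sep = ", min_sep,
             call. = FALSE)
      }
      colnames(pts) <- c("y", "x")
      pts
    }
    b_cent <- place(n_b)
    n_co <- round(coloc_fraction * n_a)
    a_cent <- place(n_a)
    if (n_co > 0 && n_b > 0) {
      a_cent[seq_len(n_co), ] <- b_cent[sample.int(n_b, n_co, replace = TRUE), ,
                                        drop = FALSE]
    }
    render <- function(cent) {
      img <- matrix(0, h, w)
      if (nrow(cent) == 0L) return(img)
      yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (i in seq_len(nrow(cent))) {
        img <- img + peak * exp(-((yy - cent[i, 1])^2 + (xx - cent[i, 2])^2) /
                                  (2 * spot_sigma^2))
      }
      img
    }
    px <- array(0, c(h, w, 1L, 2L))
    px[, , 1L, 1L] <- pmin(render(a_cent), 65535)
    px[, , 1L, 2L] <- pmin(render(b_cent), 65535)
    stack <- image_stack(px, roles, bit_depth = 16)
    if (poisson_noise || read_noise_sd > 0) {
      stack <- apply_optics(stack, poisson_noise = poisson_noise,
                            read_noise_sd = read_noise_sd)
    }
    list(stack = stack,
         truth = list(a = data.frame(y = a_cent[, 1] - 1, x = a_cent[, 2] - 1),
                      b = data.frame(y = b_cent[, 1] - 1, x = b_cent[, 2] - 1)))
  })
}
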