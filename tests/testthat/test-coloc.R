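test_that("Pearson handles linear relations and matches the sum formula", {
  set.seed(20)
  a <- matrix(stats::runif(64, 0, 100), 8, 8)
  expect_equal(coloc_pearson(a, 2 * a + 3), 1, tolerance = 1e-12)
  expect_equal(coloc_pearson(a, -a), -1, tolerance = 1e-12)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(64), 8, 8); y <- matrix(stats::rnorm(64), 8, 8)
    expect_equal(coloc_pearson(x, y), brute_pearson(x, y), tolerance = 1e-13)
  }
  expect_error(coloc_pearson(a, matrix(1, 8, 8)), "degenerate")
  expect_error(coloc_pearson(matrix(1, 2, 2), matrix(1, 2, 2),
                             region_mask = matrix(c(TRUE, rep(FALSE, 3)), 2)),
               "degenerate")
})

test_that("Manders coefficients match hand-computed sums", {
  a <- matrix(c(4, 0, 0, 4), 2, 2)
  b <- matrix(c(4, 0, 0, 0), 2, 2)
  m <- manders(a, b, 1, 1)
  expect_equal(m$m1, 0.5)
  expect_equal(m$m2, 1.0)
  expect_identical(m$n_a, 2L)
  expect_identical(m$n_overlap, 1L)
  # identity: A = B, threshold below minimum positive value
  m2 <- manders(a, a, 0.5, 0.5)
  expect_equal(m2$m1, 1); expect_equal(m2$m2, 1)
  # disjoint supra-threshold supports
  m3 <- manders(a, matrix(c(0, 4, 4, 0), 2, 2), 1, 1)
  expect_equal(m3$m1, 0); expect_equal(m3$m2, 0)
})

test_that("empty supra-threshold denominators are flagged NA, never zero", {
  a <- matrix(0, 3, 3)
  b <- matrix(5, 3, 3)
  m <- manders(a, b, 1, 1)
  expect_true(is.na(m$m1))
  expect_false(m$m1_defined)
  expect_true(m$m2_defined)
  expect_equal(m$m2, 0)   # defined: B has signal, none of it overlaps A
})

test_that("Manders is invariant under intensity rescaling, Pearson unchanged", {
  set.seed(21)
  a <- matrix(sample(0:500, 256, replace = TRUE), 16, 16)
  b <- matrix(sample(0:500, 256, replace = TRUE), 16, 16)
  m0 <- manders(a, b, 50, 80)
  for (c_scale in c(0.25, 3, 17.5)) {
    m1 <- manders(c_scale * a, b, c_scale * 50, 80)
    expect_equal(m1$m1, m0$m1, tolerance = 1e-12)
    expect_equal(m1$m2, m0$m2, tolerance = 1e-12)
    expect_equal(coloc_pearson(c_scale * a, b), coloc_pearson(a, b),
                 tolerance = 1e-12)
  }
})

test_that("thresholded and classic Manders differ as documented", {
  a <- matrix(c(10, 2, 0, 10), 2, 2)   # pixel of 2 below t_a
  b <- matrix(c(5, 5, 0, 0), 2, 2)
  th <- manders(a, b, 4, 1, thresholded = TRUE)
  cl <- manders(a, b, 4, 1, thresholded = FALSE)
  expect_equal(th$m1, 10 / 20)         # only supra-A pixels in denominator
  expect_equal(cl$m1, 12 / 22)         # all A intensity in denominator
})

test_that("normalization to control divides by the control mean", {
  df <- data.frame(condition = c("0h", "0h", "4h", "4h"),
                   m1 = c(0.9, 0.7, 0.5, 0.3),
                   m2 = c(1, 1, 1, 1))
  out <- normalize_to_control(df, "0h", cols = c("m1", "m2"))
  expect_equal(mean(out$m1_rel[out$condition == "0h"]), 1)
  expect_equal(out$m1_rel[3], 0.5 / 0.8)
  expect_equal(out$m2_rel, rep(1, 4))
  expect_identical(attr(out, "control_id"), "0h")
  # elementwise-division oracle over three conditions
  df3 <- data.frame(condition = rep(c("c", "a", "b"), each = 2),
                    m1 = c(0.8, 0.8, 0.4, 0.2, 0.6, 0.2))
  out3 <- normalize_to_control(df3, "c", cols = "m1")
  expect_equal(out3$m1_rel, df3$m1 / 0.8)
  expect_error(normalize_to_control(data.frame(condition = "c", m1 = 0), "c",
                                    cols = "m1"), "normalization")
  expect_error(normalize_to_control(df, "absent"), "control")
})

test_that("relocation leaves M2 flat while M1 falls (noise on)", {
  res <- lapply(c(0, 0.15, 0.3), function(f) {
    sim <- simulate_field(simulation_params(n_cells = 8,
                                            relocation_fraction = f, seed = 13))
    th <- field_thresholds(sim)
    proj <- max_project(sim$stack)
    m <- manders(channel_image(proj, "enzyme"),
                 channel_image(proj, "golgi_marker"),
                 th$enzyme, th$golgi_marker)
    c(m1 = m$m1, m2 = m$m2)
  })
  res <- do.call(rbind, res)
  expect_true(all(diff(res[, "m1"]) < 0))
  expect_lt(diff(range(res[, "m2"])) / mean(res[, "m2"]), 0.05)
})

test_that("ER coloc after Golgi removal is near zero without relocation", {
  sim <- simulate_field(noise_off(n_cells = 4, relocation_fraction = 0,
                                  seed = 3))
  res <- er_coloc_after_golgi_removal(
    sim$stack, c(enzyme = 5, golgi_marker = 5, er_marker = 5),
    sim$truth$cell_labels)
  expect_identical(nrow(res), 4L)
  # no out-of-Golgi enzyme: M1 undefined (flagged) or essentially zero
  expect_true(all(!res$m1_defined | res$m1 < 0.01))
  expect_true(all(!res$m2_defined | res$m2 < 0.01))
})

test_that("a Golgi mask covering the whole cell flags all coefficients", {
  px <- array(0, c(8, 8, 1, 3))
  px[, , 1, 1] <- 100   # golgi marker everywhere
  px[, , 1, 2] <- 50    # enzyme
  px[, , 1, 3] <- 20    # er marker
  s <- image_stack(px, c("golgi_marker", "enzyme", "er_marker"))
  res <- er_coloc_after_golgi_removal(
    s, c(enzyme = 1, golgi_marker = 1, er_marker = 1),
    matrix(1L, 8, 8))
  expect_false(res$m1_defined)   # all enzyme removed with the mask
  expect_true(is.na(res$m1))
  expect_true(is.na(res$pearson_r))   # constant channel propagates as NA
})

test_that("missing roles are a configuration error", {
  px <- array(0, c(4, 4, 1, 2))
  s <- image_stack(px, c("enzyme", "er_marker"))
  expect_error(er_coloc_after_golgi_removal(s, c(enzyme = 1), matrix(1L, 4, 4)),
               "golgi_marker")
})

test_that("full z-stack and projection analysis paths both run", {
  sim <- simulate_field(simulation_params(n_cells = 2, relocation_fraction = 0.3,
                                          n_z_slices = 5, seed = 5))
  th <- field_thresholds(sim)
  thr <- c(enzyme = th$enzyme, golgi_marker = th$golgi_marker,
           er_marker = th$er_marker)
  proj <- er_coloc_after_golgi_removal(sim$stack, thr, sim$truth$cell_labels)
  vox <- er_coloc_after_golgi_removal(sim$stack, thr, sim$truth$cell_labels,
                                      use_projection = FALSE)
  expect_identical(proj$analysis, rep("projection", 2))
  expect_identical(vox$analysis, rep("zstack", 2))
  expect_false(identical(proj$m2, vox$m2))
})
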