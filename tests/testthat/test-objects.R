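test_that("object detection finds centroids, areas and sizes correctly", {
  img <- matrix(0, 9, 9)
  img[3:5, 3:5] <- 10                      # uniform 3x3 blob
  o <- detect_objects(img, 1, min_size = 1)
  expect_identical(nrow(o), 1L)
  expect_equal(o$centroid_y, 3)            # 0-based centre of rows 3..5
  expect_equal(o$centroid_x, 3)
  expect_identical(o$area, 9L)
  expect_equal(o$total_intensity, 90)

  img2 <- matrix(0, 5, 5); img2[2, 2:3] <- 5
  expect_identical(nrow(detect_objects(img2, 1, min_size = 3)), 0L)

  # intensity-weighted sub-pixel centroid: 10 at x=0, 30 at x=1
  img3 <- matrix(0, 5, 5); img3[1, 1] <- 10; img3[1, 2] <- 30
  o3 <- detect_objects(img3, 1, min_size = 1)
  expect_equal(o3$centroid_x, 0.75)
  expect_equal(o3$centroid_y, 0)
})

test_that("components are 8-connected", {
  img <- matrix(0, 6, 6)
  img[cbind(1:5, 1:5)] <- 7        # diagonal chain
  expect_identical(nrow(detect_objects(img, 1, min_size = 1)), 1L)
  img[1, 5] <- 7                   # isolated pixel, not diagonal-adjacent
  expect_identical(nrow(detect_objects(img, 1, min_size = 1)), 2L)
})

test_that("centroid matching is strict and matches a brute-force check", {
  one <- object_coloc(mk_objset(0, 0), mk_objset(0, 2), resolution_px = 3)
  expect_equal(one$percent_a_colocalized, 100)
  boundary <- object_coloc(mk_objset(0, 0), mk_objset(0, 3), resolution_px = 3)
  expect_equal(boundary$percent_a_colocalized, 0)   # strict less-than

  a <- mk_objset(c(0, 0, 10, 10), c(0, 5, 0, 5))
  b <- mk_objset(c(0, 10), c(1, 6))
  got <- object_coloc(a, b, resolution_px = 2)
  expect_equal(got$percent_a_colocalized, 50)
  expect_equal(got$percent_a_colocalized,
               brute_object_percent(cbind(a$centroid_y, a$centroid_x),
                                    cbind(b$centroid_y, b$centroid_x), 2))
  # empty query set: undefined, flagged
  none <- object_coloc(mk_objset(numeric(0), numeric(0)), b, 2)
  expect_true(is.na(none$percent_a_colocalized))
  expect_false(none$defined)
  # empty reference set: defined zero
  zero <- object_coloc(a, mk_objset(numeric(0), numeric(0)), 2)
  expect_equal(zero$percent_a_colocalized, 0)
})

test_that("mutual matching is at most as permissive as non-exclusive", {
  # two A objects share the single B within range: only one is mutual
  a <- mk_objset(c(0, 0), c(0, 1.5))
  b <- mk_objset(0, 0.4)
  expect_equal(object_coloc(a, b, 3)$percent_a_colocalized, 100)
  expect_equal(object_coloc(a, b, 3, mode = "mutual")$percent_a_colocalized, 50)
  set.seed(31)
  ra <- mk_objset(stats::runif(15, 0, 40), stats::runif(15, 0, 40))
  rb <- mk_objset(stats::runif(10, 0, 40), stats::runif(10, 0, 40))
  expect_lte(object_coloc(ra, rb, 5, mode = "mutual")$percent_a_colocalized,
             object_coloc(ra, rb, 5)$percent_a_colocalized)
})

test_that("match percentage is monotone in the resolution radius", {
  set.seed(30)
  a <- mk_objset(stats::runif(20, 0, 50), stats::runif(20, 0, 50))
  b <- mk_objset(stats::runif(15, 0, 50), stats::runif(15, 0, 50))
  pc <- vapply(c(0.5, 1, 2, 4, 8, 16),
               function(r) object_coloc(a, b, r)$percent_a_colocalized,
               numeric(1))
  expect_true(all(diff(pc) >= 0))
})

test_that("percentage is invariant under joint intensity rescaling", {
  sim <- simulate_puncta_field(n_a = 15, n_b = 15, coloc_fraction = 0.5,
                               seed = 4)
  img_a <- channel_image(sim$stack, "ergic")
  img_b <- channel_image(sim$stack, "enzyme")
  run <- function(a, b, t) {
    object_coloc(detect_objects(a, t), detect_objects(b, t),
                 resolution_px = 2)$percent_a_colocalized
  }
  expect_equal(run(img_a, img_b, 100), run(3 * img_a, 3 * img_b, 300))
})

test_that("exactly co-placed puncta give 100% colocalization", {
  sim <- simulate_puncta_field(n_a = 12, n_b = 12, coloc_fraction = 1, seed = 6)
  tab <- ergic_coloc_pipeline(sim$stack, c(ergic = 100, enzyme = 100),
                              resolution_px = 2)
  expect_equal(tab$percent_a_colocalized, 100)
  expect_error(ergic_coloc_pipeline(sim$stack, c(ergic = 100, enzyme = 100),
                                    resolution_px = 2, role_a = "glycan"),
               "configuration")
})

test_that("independent puncta match at the analytic random-overlap rate", {
  # query/reference centres uniform over the placement window: the chance a
  # query has any of n_b references within r is 1 - (1 - pi r^2 / A)^n_b
  n_b <- 25; r <- 2.5; margin <- 6; shape <- c(128, 128)
  area <- prod(shape - 2 * margin)
  expected <- 100 * (1 - (1 - pi * r^2 / area)^n_b)
  pcts <- vapply(1:50, function(s) {
    sim <- simulate_puncta_field(shape, n_a = 25, n_b = n_b,
                                 coloc_fraction = 0, seed = s)
    oa <- detect_objects(channel_image(sim$stack, "ergic"), 100)
    ob <- detect_objects(channel_image(sim$stack, "enzyme"), 100)
    object_coloc(oa, ob, r)$percent_a_colocalized
  }, numeric(1))
  se <- stats::sd(pcts) / sqrt(length(pcts))
  expect_lt(abs(mean(pcts) - expected), 3 * se + 0.5)
})

test_that("raising the co-placement fraction raises the percentage", {
  fr <- c(0, 0.25, 0.5, 0.75, 1)
  pcts <- vapply(fr, function(cf) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_puncta_field(n_a = 20, n_b = 20, coloc_fraction = cf,
                                   seed = s)
      oa <- detect_objects(channel_image(sim$stack, "ergic"), 100)
      ob <- detect_objects(channel_image(sim$stack, "enzyme"), 100)
      object_coloc(oa, ob, 2)$percent_a_colocalized
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(pcts) > 0))
  expect_lt(pcts[1], 20)
  expect_gt(pcts[5], 95)
})

test_that("Rayleigh resolution converts optics metadata to pixels", {
  expect_equal(rayleigh_resolution_px(0.52, 1.4, 0.1), 0.61 * 0.52 / 1.4 / 0.1)
  expect_error(rayleigh_resolution_px(0, 1.4, 0.1))
})
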