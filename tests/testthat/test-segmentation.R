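test_that("noise-free phantom is segmented one-to-one at Jaccard >= 0.95", {
  spec <- phantom_spec(n_nuclei = 20L, field_size = c(1000L, 1000L),
                       shape_mix = c(normal = 0.7, blebs = 0.15,
                                     strings = 0.15),
                       noise = NULL, seed = 31)
  sim <- generate_field(spec)
  masks <- segment_nuclei_2d(sim$field)
  expect_length(masks, 20L)
  gt <- match_to_truth(masks, sim$truth$label_image)
  expect_false(anyNA(gt))
  expect_identical(sort(gt), 1:20)
  jac <- vapply(seq_along(masks), function(i)
    jaccard_vs_truth(masks[[i]], gt[i], sim$truth$label_image), numeric(1))
  expect_true(all(jac >= 0.95))
})

test_that("empty and two-blob images behave per contract", {
  blank <- image_field(list(dna = matrix(0, 120, 120)), pixel_size_um = 0.5)
  expect_length(segment_nuclei_2d(blank), 0L)

  img <- matrix(0, 160, 160)
  img[raster_disc(160, 25, centre = 50)] <- 100
  img[raster_ellipse(160, 60, 40, 0, centre = 115)] <- 100
  two <- image_field(list(dna = img), pixel_size_um = 0.5)
  masks <- segment_nuclei_2d(two, min_area_um2 = 10)
  expect_length(masks, 2L)
})

test_that("touching nuclei are split by the watershed", {
  img <- matrix(0, 200, 200)
  xy <- expand.grid(1:200, 1:200)
  d1 <- matrix((xy[, 1] - 100)^2 + (xy[, 2] - 75)^2 <= 30^2, 200, 200)
  d2 <- matrix((xy[, 1] - 100)^2 + (xy[, 2] - 128)^2 <= 30^2, 200, 200)
  img[d1 | d2] <- 100  # two discs fused across a neck
  f <- image_field(list(dna = img), pixel_size_um = 0.5)
  masks <- segment_nuclei_2d(f, min_area_um2 = 10, split_min_area_um2 = 300)
  expect_length(masks, 2L)
  areas <- vapply(masks, `[[`, numeric(1), "area_um2")
  expect_equal(areas[1] / areas[2], 1, tolerance = 0.15)
})

test_that("perimeter estimator matches closed forms", {
  d <- raster_disc(512, 200)
  expect_equal(measure_perimeter(d, 1), 2 * pi * 200, tolerance = 0.01)
  e <- raster_ellipse(512, 400, 200)
  expect_equal(measure_perimeter(e, 1), ramanujan_perimeter(200, 100),
               tolerance = 0.015)
  line <- matrix(FALSE, 5, 104)
  line[3, 3:102] <- TRUE
  p <- measure_perimeter(line, 1)
  expect_true(is.finite(p) && p > 0)
  expect_error(measure_perimeter(matrix(FALSE, 4, 4), 1), "empty")
})

test_that("major axis: construction, 3D sphere, rotation invariance", {
  px <- 0.2
  m <- generate_shape_mask("elongated", c(30, 9), px)
  expect_equal(measure_major_axis(m, px), 30, tolerance = px / 30 + 0.01)

  # 3D sphere of radius 12 vx (isotropic): principal-axis extent ~ 2r
  r <- 12
  n <- 31
  co <- expand.grid(1:n, 1:n, 1:n)
  sph <- array((co[, 1] - 16)^2 + (co[, 2] - 16)^2 + (co[, 3] - 16)^2 <= r^2,
               c(n, n, n))
  expect_equal(measure_major_axis(sph, 1, 1), 2 * r, tolerance = 0.1)

  m0 <- generate_shape_mask(character(0), c(18, 10), px, orientation = 0)
  m37 <- generate_shape_mask(character(0), c(18, 10), px,
                             orientation = 37 * pi / 180)
  expect_equal(measure_major_axis(m37, px), measure_major_axis(m0, px),
               tolerance = 0.02)
})

test_that("area is conserved and measurements are translation invariant", {
  px <- 0.3
  m <- generate_shape_mask("blebs", c(14, 10), px)
  n1 <- nucleus_mask(m, offset = c(5, 9), label_id = 1L, pixel_size_um = px)
  n2 <- nucleus_mask(m, offset = c(101, 57), label_id = 2L,
                     pixel_size_um = px)
  expect_identical(n1$area_um2, sum(m) * px^2)
  expect_identical(n1$perimeter_um, n2$perimeter_um)
  expect_identical(n1$major_axis_um, n2$major_axis_um)
  expect_equal(n2$centroid_um - n1$centroid_um, c(96, 48) * px)
})

test_that("border-touching nuclei are flagged", {
  img <- matrix(0, 150, 150)
  img[raster_disc(150, 25, centre = 75)] <- 100
  img[1:20, 60:100] <- 100  # blob cut by the field border
  f <- image_field(list(dna = img), pixel_size_um = 0.5)
  masks <- segment_nuclei_2d(f, min_area_um2 = 10)
  flags <- vapply(masks, `[[`, logical(1), "touches_border")
  expect_identical(sort(flags), c(FALSE, TRUE))
})

test_that("3D segmentation recovers stack phantoms and guards its inputs", {
  spec <- phantom_spec(n_nuclei = 4L, field_size = c(360L, 360L, 22L),
                       z_step_um = 0.5,
                       shape_mix = c(normal = 0.5, elongated = 0.5),
                       noise = NULL, seed = 13)
  sim <- generate_field(spec)
  masks <- segment_nuclei_3d(sim$field)
  expect_length(masks, 4L)
  gt <- match_to_truth(masks, sim$truth$label_image)
  tr <- sim$truth$nuclei[gt, ]
  meas <- vapply(masks, `[[`, numeric(1), "major_axis_um")
  expect_equal(meas, tr$major_axis_um, tolerance = 0.05)

  blank <- image_field(list(dna = array(0, c(50, 50, 5))),
                       pixel_size_um = 0.5, z_step_um = 1)
  expect_length(segment_nuclei_3d(blank), 0L)
  too_thin <- image_field(list(dna = array(10, c(50, 50, 2))),
                          pixel_size_um = 0.5, z_step_um = 1)
  expect_error(segment_nuclei_3d(too_thin), "3 planes")
  aniso <- image_field(list(dna = array(c(0, 60), c(40, 40, 6))),
                       pixel_size_um = 0.2, z_step_um = 4)
  expect_warning(segment_nuclei_3d(aniso), "anisotropy")
})
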