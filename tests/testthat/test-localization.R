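make_uniform_nucleus <- function(axes = c(15, 11), px = 0.2, value = 100) {
  m <- generate_shape_mask(character(0), axes, px)
  img <- matrix(0, nrow(m), ncol(m))
  img[m] <- value
  list(img = img, nm = nucleus_mask(m, c(1, 1), 1L, px))
}

test_that("peripheral ratio: uniform = 1, scale invariant, guarded", {
  u <- make_uniform_nucleus()
  expect_identical(peripheral_ratio(u$img, u$nm, 1.0), 1)
  expect_identical(peripheral_ratio(u$img * 7.3, u$nm, 1.0),
                   peripheral_ratio(u$img, u$nm, 1.0))
  expect_error(peripheral_ratio(u$img, u$nm, ring_width_um = 8),
               "too small for ring width")
})

test_that("injected rim ratios are recovered noise-free and monotonically", {
  measured <- vapply(c(0.5, 1.0, 1.5, 2.0, 3.0), function(r) {
    spec <- phantom_spec(n_nuclei = 2L, field_size = c(420L, 420L),
                         rim_ratio = r, noise = NULL, seed = 77)
    sim <- generate_field(spec)
    masks <- segment_nuclei_2d(sim$field)
    mean(localize_nuclei(sim$field, masks)$peripheral_ratio)
  }, numeric(1))
  expect_equal(measured, c(0.5, 1.0, 1.5, 2.0, 3.0), tolerance = 0.05)
  expect_true(all(diff(measured) > 0))
})

test_that("mid-stack projection selects 6 centred planes", {
  # plane k holds value k inside a central disc
  stack <- array(0, c(60, 60, 11))
  disc <- raster_disc(60, 18)
  for (k in 1:11) stack[, , k][disc] <- k
  proj <- mid_stack_projection(stack)
  # intensity-weighted mid-plane: sum(k^2)/sum(k) = 506/66 = 7.67 -> 5:10
  expect_identical(attr(proj, "planes"), 5:10)
  expect_identical(max(proj), 10)              # max of the selected values
  one <- array(5, c(10, 10, 1))
  expect_warning(p1 <- mid_stack_projection(one), "plane")
  expect_identical(p1[1, 1], 5)
})

test_that("3D projection reproduces the 2D peripheral ratio within 5%", {
  spec3 <- phantom_spec(n_nuclei = 3L, field_size = c(360L, 360L, 22L),
                        z_step_um = 0.5, rim_ratio = 2, noise = NULL,
                        seed = 55)
  sim3 <- generate_field(spec3)
  masks3 <- segment_nuclei_3d(sim3$field)
  r3 <- localize_nuclei(sim3$field, masks3)$peripheral_ratio
  expect_equal(r3, rep(2, length(r3)), tolerance = 0.05)
})

test_that("aggregate detectors fire on injected structure only", {
  px <- 0.2
  u <- make_uniform_nucleus(value = 100)
  cfg <- localization_config()
  res <- detect_aggregates(u$img, u$nm, cfg)
  expect_false(res$has_honeycomb)
  expect_false(res$has_foci)

  # inject three interior holes -> honeycomb
  holey <- u$img
  cen <- round(dim(holey) / 2)
  for (dc in c(-12, 0, 12))
    holey[raster_disc(nrow(holey), 5, centre = cen[1] + dc)] <- 5
  holey[!u$nm$mask] <- 0
  res <- detect_aggregates(holey, u$nm, cfg)
  expect_true(res$has_honeycomb)

  # inject one bright peripheral focus -> foci
  spot <- u$img
  ring <- nucmorph:::ring_partition(u$nm$mask, px, cfg$ring_width_um)$ring
  idx <- which(ring, arr.ind = TRUE)[10, ]
  dd <- sqrt((row(spot) - idx[1])^2 + (col(spot) - idx[2])^2) * px
  spot[dd <= 0.6 & u$nm$mask] <- 400
  res <- detect_aggregates(spot, u$nm, cfg)
  expect_true(res$has_foci)
  expect_identical(res$n_foci, 1L)

  # a large bright interior blob is a nucleolus, not a focus
  nuc <- u$img
  dd <- sqrt((row(nuc) - cen[1])^2 + (col(nuc) - cen[2])^2) * px
  nuc[dd <= 1.5 & u$nm$mask] <- 400   # area ~7 um^2 > max_focus_area
  res <- detect_aggregates(nuc, u$nm, cfg)
  expect_false(res$has_foci)
})

test_that("capping detector measures absent arcs", {
  px <- 0.2
  u <- make_uniform_nucleus(axes = c(14, 12), value = 100)
  cfg <- localization_config()
  res <- detect_capping(u$img, u$nm, cfg)
  expect_false(res$has_capping)
  expect_identical(res$capped_arc_fraction, 0)

  part <- nucmorph:::ring_partition(u$nm$mask, px, cfg$ring_width_um)
  cen <- colMeans(which(u$nm$mask, arr.ind = TRUE))
  ang <- atan2(col(u$img) - cen[2], row(u$img) - cen[1])
  capped <- u$img
  capped[part$ring & abs(ang) <= pi / 6] <- 2   # 60 degree cap
  res <- detect_capping(capped, u$nm, cfg)
  expect_true(res$has_capping)
  expect_equal(res$capped_arc_fraction, 60 / 360, tolerance = 0.25)

  full <- u$img
  full[part$ring] <- 2                          # 360 degree deletion
  res <- detect_capping(full, u$nm, cfg)
  expect_true(res$has_capping)
  expect_equal(res$capped_arc_fraction, 1)
})

test_that("emerin foci reuse the foci branch and stay quiet on uniform", {
  u <- make_uniform_nucleus()
  expect_false(detect_emerin_foci(u$img, u$nm)$has_emerin_foci)
  spot <- u$img
  ring <- nucmorph:::ring_partition(u$nm$mask, 0.2, 1.0)$ring
  idx <- which(ring, arr.ind = TRUE)[5, ]
  dd <- sqrt((row(spot) - idx[1])^2 + (col(spot) - idx[2])^2) * 0.2
  spot[dd <= 0.6 & u$nm$mask] <- 500
  expect_true(detect_emerin_foci(spot, u$nm)$has_emerin_foci)
})

test_that("detectors hold a low false-positive rate under default noise", {
  bat <- run_battery(n_fields = 2L, n_per_field = 30L, seed = 911L,
                     shape_mix = c(normal = 1),
                     misloc = c(honeycomb = 0, foci = 0, capping = 0,
                                emerin_foci = 0))
  fp <- c(bat$pred$has_honeycomb, bat$pred$has_foci, bat$pred$has_capping,
          bat$pred$has_emerin_foci)
  expect_lte(mean(fp), 0.02)
})
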