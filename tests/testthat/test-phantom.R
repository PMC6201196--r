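test_that("spec validation enforces the stated invariants", {
  expect_error(phantom_spec(shape_mix = c(normal = 0.5, blebs = 0.4)),
               "sum to 1")
  expect_error(phantom_spec(shape_mix = c(elongated = 1),
                            elongated_length_um = c(20, 24)),
               "strictly above 25")
  expect_error(phantom_spec(shape_mix = c(wiggly = 1)), "unknown shape label")
  expect_error(phantom_spec(base_axes_um = c(30, 11)), "25")
  expect_error(phantom_spec(field_size = c(200, 200, 10)), "z_step_um")
  expect_silent(phantom_spec(shape_mix = c("blebs+elongated" = 0.5,
                                           normal = 0.5)))
})

test_that("identity configuration: empty labels, uniform lamin intensity", {
  spec <- phantom_spec(n_nuclei = 4L, field_size = c(420L, 420L),
                       shape_mix = c(normal = 1), rim_ratio = 1,
                       noise = NULL, seed = 5)
  sim <- generate_field(spec)
  expect_true(all(sim$truth$nuclei$label_set == "normal"))
  expect_true(all(sim$truth$nuclei$is_normal))
  lac <- sim$field$channels$lamin_ac
  for (i in seq_len(4L)) {
    vals <- lac[sim$truth$label_image == i]
    expect_equal(sd(vals), 0)
  }
})

test_that("forced elongated mix fixes ground-truth length and label", {
  spec <- phantom_spec(n_nuclei = 5L, field_size = c(800L, 800L),
                       shape_mix = c(elongated = 1),
                       elongated_length_um = 30, noise = NULL, seed = 2)
  sim <- generate_field(spec)
  expect_equal(sim$truth$nuclei$major_axis_um, rep(30, 5))
  expect_true(all(sim$truth$nuclei$label_set == "elongated"))
})

test_that("label draw matches an independent replay of the seeded sampler", {
  mix <- c(normal = 0.6, elongated = 0.4)
  spec <- phantom_spec(n_nuclei = 100L, field_size = c(2200L, 2200L),
                       shape_mix = mix, noise = NULL, seed = 1)
  sim <- generate_field(spec)
  expect_identical(sim$truth$nuclei$label_set, replay_label_draw(mix, 100L, 1))
})

test_that("generation is deterministic for a fixed (spec, seed)", {
  spec <- phantom_spec(n_nuclei = 6L, field_size = c(500L, 500L),
                       shape_mix = c(normal = 0.7, blebs = 0.3),
                       misloc_fractions = c(foci = 0.5), seed = 9)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  c2 <- generate_field(spec, seed = 10)
  expect_false(identical(a$field$channels$dna, c2$field$channels$dna))
})

test_that("label frequencies converge to the mix (chi-square GOF)", {
  mix <- c(normal = 0.6, jellybean = 0.1, blebs = 0.1, strings = 0.1,
           elongated = 0.1)
  set.seed(42)
  draws <- nucmorph:::draw_shape_labels(mix, 10000L)
  counts <- table(factor(draws, levels = names(mix)))
  p <- stats::chisq.test(counts, p = mix)$p.value
  expect_gt(p, 0.01)
})

test_that("placement failure raises an explicit crowding error", {
  spec <- phantom_spec(n_nuclei = 30L, field_size = c(220L, 220L),
                       noise = NULL, seed = 1)
  expect_error(generate_field(spec), "field too crowded")
})

test_that("shape masks honour their geometric contracts", {
  px <- 0.2
  # normal ellipse: near-circular contour ratio against the closed form
  m <- generate_shape_mask(character(0), c(15, 12), px)
  nm <- nucleus_mask(m, c(1, 1), 1L, px)
  cr_oracle <- 4 * pi * (pi * 7.5 * 6) / ramanujan_perimeter(7.5, 6)^2
  expect_equal(contour_ratio(nm$area_um2, nm$perimeter_um), cr_oracle,
               tolerance = 0.01)

  # elongated: measured major axis within one pixel of the request
  m <- generate_shape_mask("elongated", c(26, 9), px)
  expect_lt(abs(measure_major_axis(m, px) - 26), px + 1e-9)

  # blebs strictly lower the solidity of the matching plain ellipse
  sol <- function(mm) {
    nmm <- nucleus_mask(mm, c(1, 1), 1L, px)
    shape_metrics(nmm)$solidity
  }
  expect_lt(sol(generate_shape_mask("blebs", c(15, 11), px)),
            sol(generate_shape_mask(character(0), c(15, 11), px)))

  # every class yields a single 4-connected, hole-free mask
  for (lbl in SHAPE_LABELS) {
    axes <- if (lbl == "elongated") c(28, 9) else c(16, 11)
    m <- generate_shape_mask(lbl, axes, px, orientation = 0.7)
    lab <- nucmorph:::label_components(m, 4L)
    expect_identical(max(lab), 1L)
    expect_identical(sum(nucmorph:::fill_holes(m)), sum(m))
  }
  expect_error(generate_shape_mask("octopus", c(15, 11), px), "unknown")
})

test_that("myotube context places multinucleated tubes with exclusion", {
  spec <- phantom_spec(n_nuclei = 12L, field_size = c(800L, 800L),
                       myotube_fraction = 0.5, noise = NULL, seed = 21)
  sim <- generate_field(spec)
  tr <- sim$truth$nuclei
  expect_true("marker" %in% names(sim$field$channels))
  expect_equal(sum(tr$in_myotube), 6L)
  # every occupied tube is multinucleated
  expect_true(all(table(tr$tube_id[!is.na(tr$tube_id)]) >= 2L))
  # marker is excluded from member nuclei relative to the tube interior
  mk <- sim$field$channels$marker
  inside <- mk[sim$truth$label_image > 0 & sim$truth$tube_image > 0]
  tube_only <- mk[sim$truth$label_image == 0 & sim$truth$tube_image > 0]
  expect_lt(mean(inside), 0.5 * mean(tube_only))
})

test_that("3D generation produces stacks with per-plane geometry", {
  spec <- phantom_spec(n_nuclei = 3L, field_size = c(300L, 300L, 20L),
                       z_step_um = 0.5, noise = NULL, seed = 4)
  sim <- generate_field(spec)
  expect_identical(dim(sim$field$channels$dna), c(300L, 300L, 20L))
  # each nucleus spans several planes and vanishes at the poles
  for (i in 1:3) {
    planes <- apply(sim$truth$label_image == i, 3, any)
    expect_gt(sum(planes), 8)
    expect_lt(sum(planes), 20)
  }
})
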