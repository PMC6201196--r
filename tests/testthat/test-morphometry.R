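test_that("contour ratio: analytic anchors and input guards", {
  expect_identical(contour_ratio(pi, 2 * pi), 1)            # unit circle
  expect_equal(contour_ratio(4, 8), pi / 4)                 # square, side 2
  expect_error(contour_ratio(0, 1), "strictly positive")
  expect_error(contour_ratio(1, -2), "strictly positive")
  # monotone decreasing in perimeter at fixed area
  p <- seq(2 * pi, 4 * pi, length.out = 10)
  expect_true(all(diff(contour_ratio(pi, p)) < 0))
})

test_that("a 2:1 oval sits inside the normal circular/oval band", {
  # 30 x 15 um ellipse at 0.2 um/px; closed-form oracle ~0.84
  m <- raster_ellipse(200, 150, 75)
  nm <- nucleus_mask(m, c(1, 1), 1L, 0.2)
  cr <- contour_ratio(nm$area_um2, nm$perimeter_um)
  oracle <- 4 * pi * (pi * 15 * 7.5) / ramanujan_perimeter(15, 7.5)^2
  expect_equal(cr, oracle, tolerance = 0.02)
  expect_gte(cr, 0.79)
  expect_lte(cr, 1.02)
})

test_that("elongation rule is sharp at the 25 um threshold", {
  px <- 0.2
  mk <- function(len) {
    m <- generate_shape_mask(if (len > 25) "elongated" else character(0),
                             c(len, 9), px, orientation = 0.3)
    nucleus_mask(m, c(1, 1), 1L, px)
  }
  below <- mk(24.9)
  above <- mk(25.1)
  labs_below <- classify_shape(below)
  labs_above <- classify_shape(above)
  expect_false("elongated" %in% labs_below)
  expect_true("elongated" %in% labs_above)
  # nothing else differs between the two
  expect_identical(setdiff(labs_above, "elongated"), labs_below)
})

test_that("contour ratio is scale invariant on rasterized shapes", {
  m1 <- raster_ellipse(140, 100, 60)
  m2 <- raster_ellipse(280, 200, 120)
  cr <- function(m, px) {
    nm <- nucleus_mask(m, c(1, 1), 1L, px)
    contour_ratio(nm$area_um2, nm$perimeter_um)
  }
  expect_equal(cr(m1, 1), cr(m2, 1), tolerance = 0.01)
  # physical rescale via pixel size cancels exactly (A ~ px^2, P ~ px)
  expect_equal(cr(m1, 0.2), cr(m1, 1))
})

test_that("protrusions never increase the contour ratio", {
  px <- 0.2
  base <- generate_shape_mask(character(0), c(16, 11), px)
  cr_of <- function(lbls, params = list()) {
    m <- generate_shape_mask(lbls, c(16, 11), px, params = params)
    nm <- nucleus_mask(m, c(1, 1), 1L, px)
    contour_ratio(nm$area_um2, nm$perimeter_um)
  }
  cr0 <- cr_of(character(0))
  expect_lt(cr_of("blebs"), cr0)
  expect_lt(cr_of("strings"), cr0)
  expect_lt(cr_of(c("blebs", "strings")), cr0)
})

test_that("each generated class maps to exactly its own label", {
  px <- 0.2
  cases <- list(
    list(lbl = character(0), axes = c(15, 12)),
    list(lbl = "jellybean", axes = c(16, 11)),
    list(lbl = "severely_deformed", axes = c(16, 11)),
    list(lbl = "blebs", axes = c(16, 11)),
    list(lbl = "strings", axes = c(16, 11)),
    list(lbl = "elongated", axes = c(28, 9)))
  for (cs in cases) {
    m <- generate_shape_mask(cs$lbl, cs$axes, px, orientation = 0.9)
    nm <- nucleus_mask(m, c(1, 1), 1L, px)
    expect_identical(sort(classify_shape(nm)), sort(cs$lbl),
                     info = paste("class:", format_label_set(cs$lbl)))
  }
})

test_that("degenerate masks fall back to severely_deformed with a warning", {
  thin <- matrix(FALSE, 6, 40)
  thin[3, 3:38] <- TRUE  # too thin to support the smoothed iso-level
  nm <- nucleus_mask(thin, c(1, 1), 7L, 0.2)
  expect_warning(labs <- classify_shape(nm), "degenerate")
  expect_identical(labs, "severely_deformed")
})

test_that("pooling jellybean + severe reproduces the deformed tally", {
  set.seed(7)
  n <- 500
  tab <- data.frame(jellybean = runif(n) < 0.2,
                    severely_deformed = runif(n) < 0.25)
  n_deformed <- sum(tab$jellybean | tab$severely_deformed)
  expect_identical(n_deformed,
                   sum(tab$jellybean) + sum(tab$severely_deformed) -
                     sum(tab$jellybean & tab$severely_deformed))
})

test_that("multi-label sets classify as all their parts", {
  px <- 0.2
  m <- generate_shape_mask(c("blebs", "elongated"), c(28, 9), px,
                           orientation = 0.2,
                           params = list(bleb_angle = pi / 2))
  nm <- nucleus_mask(m, c(1, 1), 1L, px)
  labs <- classify_shape(nm)
  expect_true(all(c("blebs", "elongated") %in% labs))
})
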