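## Parametric nucleus-shape constructions. The five abnormality classes are
## built so that each is unambiguous ground truth for the rule classifier:
##   jellybean         - ellipse bent along a circular arc (one dominant bend)
##   severely_deformed - ellipse with >= 2 deep boundary bites (concavities)
##   blebs             - ellipse plus an attached round protrusion
##   strings           - ellipse plus a thin (<= 1 um) long (>= 3 um) process
##   elongated         - ellipse with major axis > 25 um

#' Rasterize a nucleus shape mask
#'
#' Builds a binary mask realizing a shape-label set. The geometry is
#' deterministic given the arguments; stochastic choices (angles, sizes) are
#' resolved by the caller and passed through `params`.
#'
#' @param label_set character vector of labels (subset of [SHAPE_LABELS]);
#'   empty for a normal ellipse.
#' @param axes_um `c(major, minor)` full axis lengths in um of the body
#'   ellipse (for elongated shapes pass the elongated length as major).
#' @param pixel_size_um um per pixel.
#' @param orientation rotation of the major axis, radians.
#' @param params optional list overriding the geometric parameters:
#'   `bend_deg` (jellybean arc, default 150), `jellybean_lengthen`,
#'   `jellybean_thin`, `n_bites`, `bite_angles`, `bite_radius_frac` (of the
#'   minor semi-axis, default 0.45), `bleb_diameter_um`, `bleb_angle`,
#'   `string_length_um`, `string_width_um`, `string_angle`.
#' @return logical matrix; 4-connected, hole-free, with a 3 px margin.
#' @export
generate_shape_mask <- function(label_set, axes_um, pixel_size_um,
                                orientation = 0, params = list()) {
  stopifnot(pixel_size_um > 0, length(axes_um) == 2L, all(axes_um > 0))
  bad <- setdiff(label_set, SHAPE_LABELS)
  if (length(bad)) stop("unknown shape label(s): ", paste(bad, collapse = ", "))
  p <- modifyList(list(
    bend_deg = 150, jellybean_lengthen = 1.15, jellybean_thin = 0.6,
    n_bites = 2L, bite_angles = c(0.4, 2.8), bite_radius_frac = 0.45,
    bleb_diameter_um = 2.4, bleb_angle = pi / 3,
    string_length_um = 4.5, string_width_um = 0.8, string_angle = -pi / 2),
    params)

  a <- axes_um[1] / 2
  b <- axes_um[2] / 2
  if ("jellybean" %in% label_set) {
    # a hook is longer and thinner than the ellipse it replaces, so the
    # bend produces a single deep concavity rather than a pinched blob
    a <- a * p$jellybean_lengthen
    b <- b * p$jellybean_thin
  }
  extra <- 0
  if ("blebs" %in% label_set) extra <- max(extra, p$bleb_diameter_um * 1.6)
  if ("strings" %in% label_set) extra <- max(extra, p$string_length_um + 1)
  half_um <- a + extra + 1
  half_px <- ceiling(half_um / pixel_size_um) + 3L
  n <- 2L * half_px + 1L
  ctr <- half_px + 1L
  # coordinates in um, rotated into the shape frame (u = major, v = minor)
  row_um <- (seq_len(n) - ctr) * pixel_size_um
  col_um <- row_um
  rr <- matrix(row_um, n, n)
  cc <- matrix(col_um, n, n, byrow = TRUE)
  u <- cc * cos(orientation) + rr * sin(orientation)
  v <- -cc * sin(orientation) + rr * cos(orientation)

  if ("jellybean" %in% label_set) {
    beta <- p$bend_deg * pi / 180          # total bend angle of the arc
    R <- 2 * a / beta                      # arc radius preserving arc length
    rad <- sqrt(u^2 + (v + R)^2)
    phi <- atan2(u, v + R)
    s <- R * phi                           # arc-length coordinate
    d <- rad - R
    mask <- (s / a)^2 + (d / b)^2 <= 1
  } else {
    mask <- (u / a)^2 + (v / b)^2 <= 1
  }

  if ("severely_deformed" %in% label_set) {
    rho <- p$bite_radius_frac * b
    for (k in seq_len(p$n_bites)) {
      t0 <- p$bite_angles[((k - 1L) %% length(p$bite_angles)) + 1L]
      bx <- a * cos(t0); by <- b * sin(t0)
      mask <- mask & ((u - bx)^2 + (v - by)^2 > rho^2)
    }
  }

  if ("blebs" %in% label_set) {
    t0 <- p$bleb_angle
    rho <- p$bleb_diameter_um / 2
    bx <- a * cos(t0); by <- b * sin(t0)
    nrm <- c(cos(t0) / a, sin(t0) / b)
    nrm <- nrm / sqrt(sum(nrm^2))
    cx <- bx + 0.8 * rho * nrm[1]; cy <- by + 0.8 * rho * nrm[2]
    mask <- mask | ((u - cx)^2 + (v - cy)^2 <= rho^2)
  }

  if ("strings" %in% label_set) {
    t0 <- p$string_angle
    bx <- a * cos(t0); by <- b * sin(t0)
    nrm <- c(cos(t0) / a, sin(t0) / b)
    nrm <- nrm / sqrt(sum(nrm^2))
    q0 <- c(bx, by) - 0.8 * nrm            # anchor just inside the body
    q1 <- c(bx, by) + p$string_length_um * nrm
    seg <- q1 - q0
    len2 <- sum(seg^2)
    tt <- pmin(1, pmax(0, ((u - q0[1]) * seg[1] + (v - q0[2]) * seg[2]) / len2))
    d2 <- (u - (q0[1] + tt * seg[1]))^2 + (v - (q0[2] + tt * seg[2]))^2
    mask <- mask | (d2 <= (p$string_width_um / 2)^2)
  }

  mask <- fill_holes(mask)
  lab <- label_components(mask, 4L)
  if (max(lab) > 1L) {  # keep the largest piece should a bite disconnect
    keep <- which.max(tabulate(lab[lab > 0L]))
    mask <- lab == keep
  }
  mask
}

#' Maximum extent (Feret diameter) of mask pixel centres, in um
#' @keywords internal
pixel_feret_um <- function(mask, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  if (nrow(idx) == 1L) return(pixel_size_um)
  h <- grDevices::chull(idx[, 1], idx[, 2])
  pts <- idx[h, , drop = FALSE]
  max(dist(pts)) * pixel_size_um
}
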