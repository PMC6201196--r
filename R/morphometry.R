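## Nuclear contour ratio and the multi-label shape classification.
## The contour ratio 4*pi*A/P^2 is 1 for a perfect circle and decreases
## with deformity; nuclei of control cells typically fall in [0.79, 1]
## (circular/oval band). Only the elongation rule (major axis > 25 um) and
## that band are quantitative in the original scoring protocol; the other
## operators are rule-based surrogates for by-eye classification, with all
## thresholds exposed in `classifier_config()`.

#' Nuclear contour ratio
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, lower for
#' deformed outlines.
#'
#' @param area_um2 area in um^2 (strictly positive).
#' @param perimeter_um perimeter in um (strictly positive).
#' @return dimensionless ratio.
#' @export
contour_ratio <- function(area_um2, perimeter_um) {
  if (any(!is.finite(area_um2)) || any(!is.finite(perimeter_um)) ||
      any(area_um2 <= 0) || any(perimeter_um <= 0))
    stop("area and perimeter must be strictly positive")
  4 * pi * area_um2 / perimeter_um^2
}

#' Shape-classifier configuration
#'
#' @param elongation_threshold_um major-axis cut-off above which a nucleus
#'   is labelled elongated (strict inequality).
#' @param normal_cr_floor lower edge of the normal circular/oval
#'   contour-ratio band; used for reporting/QC only, never as a
#'   classification rule.
#' @param bleb_min_diameter_um minimum width of a round protrusion counted
#'   as a bleb.
#' @param bleb_open_radius_um disc radius of the morphological opening that
#'   separates protrusions from the nuclear body.
#' @param bleb_min_protrusion_um minimum outward extent of a bleb beyond
#'   the body (rejects rasterization slivers at high-curvature tips).
#' @param string_max_width_um,string_min_length_um a thin protrusion at
#'   most this wide and at least this long is a string.
#' @param concavity_min_depth_um,concavity_min_area_um2 a convexity defect
#'   of the protrusion-free body counts as a deep concavity above these.
#' @param jellybean_bend_depth_um minimum depth of the single dominant bend
#'   concavity of a jellybean.
#' @param severe_concavity_count deep concavities at or above which the
#'   nucleus is severely deformed.
#' @param severe_solidity_max solidity bound accompanying the severe rule.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(elongation_threshold_um = 25,
                              normal_cr_floor = 0.79,
                              bleb_min_diameter_um = 1.3,
                              bleb_open_radius_um = 1.7,
                              bleb_min_protrusion_um = 1.0,
                              string_max_width_um = 1.2,
                              string_min_length_um = 3.0,
                              concavity_min_depth_um = 1.0,
                              concavity_min_area_um2 = 1.5,
                              jellybean_bend_depth_um = 1.2,
                              severe_concavity_count = 2L,
                              severe_solidity_max = 0.95) {
  stopifnot(elongation_threshold_um > 0, normal_cr_floor > 0,
            normal_cr_floor < 1, bleb_min_diameter_um > 0,
            string_max_width_um > 0, string_min_length_um > 0)
  structure(as.list(environment()), class = "classifier_config")
}

## Convex hull of the sub-pixel contour: polygon (row, col), its area, and
## a rasterization over the crop grid.
hull_of_contour <- function(pts, dims) {
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  # ensure counter-clockwise orientation for the half-plane test
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  area2 <- sum(poly[, 1] * poly[nxt, 2] - poly[nxt, 1] * poly[, 2])
  if (area2 < 0) { poly <- poly[n:1, , drop = FALSE]; area2 <- -area2 }
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  inside <- matrix(TRUE, dims[1], dims[2])
  nxt <- c(2:nrow(poly), 1L)
  for (e in seq_len(nrow(poly))) {
    ex <- poly[nxt[e], 1] - poly[e, 1]
    ey <- poly[nxt[e], 2] - poly[e, 2]
    inside <- inside &
      (ex * (cc - poly[e, 2]) - ey * (rr - poly[e, 1]) >= -1e-9)
  }
  list(poly = poly, area_px2 = area2 / 2, raster = inside)
}

#' Shape metrics of a nucleus mask
#'
#' Computes the descriptors consumed by [classify_shape()]: contour ratio,
#' major axis, solidity, deep-concavity census of the protrusion-free body,
#' and per-protrusion width/extent descriptors.
#'
#' @param mask a 2D [nucleus_mask()].
#' @param config a [classifier_config()].
#' @return list with `contour_ratio`, `major_axis_um`, `solidity`,
#'   `n_concavities`, `max_concavity_depth_um`, `protrusions` (data frame
#'   with `width_um`, `extent_um`, `area_um2`), and `degenerate`.
#' @export
shape_metrics <- function(mask, config = classifier_config()) {
  stopifnot(inherits(mask, "nucleus_mask"))
  px <- mask$pixel_size_um
  m <- mask$mask
  if (length(dim(m)) == 3L) m <- max_area_slice(m)
  contours <- mask_contours(m)
  if (length(contours) == 0L)
    return(list(contour_ratio = NA_real_, major_axis_um = NA_real_,
                solidity = NA_real_, n_concavities = NA_integer_,
                max_concavity_depth_um = NA_real_,
                protrusions = data.frame(), degenerate = TRUE))
  area_um2 <- sum(m) * px^2
  perim_um <- polygon_length(contours) * px
  cr <- contour_ratio(area_um2, perim_um)
  pts <- do.call(rbind, contours)
  hull_full <- hull_of_contour(pts, dim(m))
  solidity <- sum(m) / hull_full$area_px2

  # protrusions: what a disc opening removes. Only components wide enough
  # for a bleb or long enough for a string qualify; rasterization slivers
  # shed at high-curvature boundary stretches are ignored.
  body <- binary_open(m, config$bleb_open_radius_um, px)
  resid <- m & !body
  dist_to_body <- distance_map(!body, px)
  prot <- data.frame(width_um = numeric(0), extent_um = numeric(0),
                     area_um2 = numeric(0))
  qualifying <- array(FALSE, dim(m))
  if (any(resid) && any(body)) {
    rl <- label_components(resid, 4L)
    for (l in seq_len(max(rl))) {
      comp <- rl == l
      w <- 2 * max(distance_map(comp, px))
      ext <- max(dist_to_body[comp])
      prot <- rbind(prot, data.frame(width_um = w, extent_um = ext,
                                     area_um2 = sum(comp) * px^2))
      is_bleb <- w >= config$bleb_min_diameter_um &&
        ext >= config$bleb_min_protrusion_um
      is_string <- w <= config$string_max_width_um &&
        ext >= config$string_min_length_um
      if (is_bleb || is_string) qualifying <- qualifying | comp
    }
  }

  # deep concavities of the protrusion-free mask. The census runs on the
  # original mask minus the qualifying protrusions - not on the opened
  # body, whose boundary recession flattens concavity depth.
  body2 <- m & !qualifying
  bpts_l <- mask_contours(body2)
  n_conc <- 0L; max_depth <- 0
  if (length(bpts_l)) {
    hull_body <- hull_of_contour(do.call(rbind, bpts_l), dim(m))
    defects <- hull_body$raster & !body2
    if (any(defects)) {
      depth_map <- distance_map(hull_body$raster, px)
      dl <- label_components(defects, 4L)
      for (l in seq_len(max(dl))) {
        comp <- dl == l
        if (sum(comp) * px^2 < config$concavity_min_area_um2) next
        dep <- max(depth_map[comp])
        if (dep >= config$concavity_min_depth_um) {
          n_conc <- n_conc + 1L
          max_depth <- max(max_depth, dep)
        }
      }
    }
  }

  list(contour_ratio = cr,
       major_axis_um = mask$major_axis_um,
       solidity = solidity,
       n_concavities = n_conc,
       max_concavity_depth_um = max_depth,
       protrusions = prot,
       degenerate = FALSE)
}

max_area_slice <- function(m3) {
  areas <- apply(m3, 3L, sum)
  m3[, , which.max(areas)]
}

#' Classify the shape of a nucleus
#'
#' Multi-label rules, applied independently:
#' * `elongated`: major axis strictly greater than the threshold (25 um).
#' * `blebs`: a protrusion at least `bleb_min_diameter_um` wide extending
#'   at least `bleb_min_protrusion_um` beyond the body.
#' * `strings`: a protrusion at most `string_max_width_um` wide and at
#'   least `string_min_length_um` long.
#' * `jellybean`: exactly one deep concavity of the protrusion-free body,
#'   at least `jellybean_bend_depth_um` deep (the bend).
#' * `severely_deformed`: at least `severe_concavity_count` deep
#'   concavities with solidity below `severe_solidity_max`.
#'
#' An empty result means a normal (circular/oval) nucleus. Degenerate masks
#' that support no contour fall back to `severely_deformed` with a warning.
#'
#' @param mask a [nucleus_mask()] (2D, or 3D - elongation then uses the 3D
#'   principal-axis length and the remaining operators run on the
#'   largest-area z-slice).
#' @param metrics optional precomputed [shape_metrics()].
#' @param config a [classifier_config()].
#' @return character vector of labels (empty for normal).
#' @export
classify_shape <- function(mask, metrics = NULL, config = classifier_config()) {
  stopifnot(inherits(mask, "nucleus_mask"), inherits(config, "classifier_config"))
  if (is.null(metrics)) metrics <- shape_metrics(mask, config)
  if (isTRUE(metrics$degenerate)) {
    warning("degenerate mask #", mask$label_id,
            ": falling back to severely_deformed")
    return("severely_deformed")
  }
  labels <- character(0)
  if (metrics$major_axis_um > config$elongation_threshold_um)
    labels <- c(labels, "elongated")
  pr <- metrics$protrusions
  if (nrow(pr)) {
    if (any(pr$width_um >= config$bleb_min_diameter_um &
            pr$extent_um >= config$bleb_min_protrusion_um))
      labels <- c(labels, "blebs")
    if (any(pr$width_um <= config$string_max_width_um &
            pr$extent_um >= config$string_min_length_um))
      labels <- c(labels, "strings")
  }
  if (metrics$n_concavities >= config$severe_concavity_count &&
      metrics$solidity < config$severe_solidity_max)
    labels <- c(labels, "severely_deformed")
  else if (metrics$n_concavities == 1L &&
           metrics$max_concavity_depth_um >= config$jellybean_bend_depth_um)
    labels <- c(labels, "jellybean")
  intersect(SHAPE_LABELS, labels)
}

#' Classify a list of nucleus masks into a per-nucleus table
#'
#' @param masks list of [nucleus_mask()] objects.
#' @param config a [classifier_config()].
#' @param field_id optional field identifier.
#' @return [nuclei_table()] extended with `contour_ratio`, `solidity`, one
#'   logical column per shape label, `label_set` and `is_normal`.
#' @export
classify_nuclei <- function(masks, config = classifier_config(),
                            field_id = NA) {
  tab <- nuclei_table(masks, field_id = field_id)
  tab$contour_ratio <- NA_real_
  tab$solidity <- NA_real_
  for (lbl in SHAPE_LABELS) tab[[lbl]] <- logical(nrow(tab))
  tab$label_set <- character(nrow(tab))
  for (i in seq_along(masks)) {
    met <- shape_metrics(masks[[i]], config)
    labs <- classify_shape(masks[[i]], met, config)
    tab$contour_ratio[i] <- met$contour_ratio
    tab$solidity[i] <- met$solidity
    for (lbl in labs) tab[[lbl]][i] <- TRUE
    tab$label_set[i] <- format_label_set(labs)
  }
  tab$is_normal <- tab$label_set == "normal"
  tab
}
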