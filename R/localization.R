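## Lamina-protein localization: mid-nucleus maximum projection,
## peripheral/nucleoplasm intensity ratio, and detectors for Lamin A/C
## honeycomb and foci, Lamin B1 capping, and emerin foci.
##
## Ratio orientation: periphery / nucleoplasm, so that values above 1 mean
## peripheral enrichment (the usual lamin distribution). Detector
## thresholds use robust statistics (median/MAD) on intensities normalized
## by the regional (ring vs nucleoplasm) median, so a bright rim is not
## itself called a focus.

#' Localization-detector configuration
#'
#' @param ring_width_um width of the peripheral ring (erosion depth
#'   separating periphery from nucleoplasm). Default 1 um, about the
#'   lateral confocal resolution envelope.
#' @param k_low,k_high MAD multipliers for the low (honeycomb) and high
#'   (foci) intensity thresholds.
#' @param mad_floor_frac lower bound on the MAD as a fraction of the
#'   regional median, so noise-free images have a finite threshold.
#' @param min_patch_area_um2 minimum area of a signal-absent interior patch.
#' @param min_focus_area_um2 minimum area of a bright focus.
#' @param max_focus_area_um2 interior bright patches larger than this are
#'   treated as nucleoli and excluded from foci calls.
#' @param min_holes_honeycomb interior absent patches needed for honeycomb.
#' @param cap_k ring-intensity fraction (of the ring median) below which an
#'   angular bin counts as signal-absent.
#' @param min_arc_deg minimum contiguous absent arc for a capping call.
#' @param arc_bin_deg angular bin width used to unwrap the ring.
#' @return object of class `localization_config`.
#' @export
localization_config <- function(ring_width_um = 1.0, k_low = 3, k_high = 3,
                                mad_floor_frac = 0.05,
                                min_patch_area_um2 = 0.5,
                                min_focus_area_um2 = 0.3,
                                max_focus_area_um2 = 4,
                                min_holes_honeycomb = 2L,
                                cap_k = 0.5, min_arc_deg = 30,
                                arc_bin_deg = 5) {
  stopifnot(ring_width_um > 0, k_low > 0, k_high > 0, cap_k > 0, cap_k < 1,
            min_arc_deg > 0, arc_bin_deg > 0)
  structure(as.list(environment()), class = "localization_config")
}

## Crop an intensity channel to a nucleus_mask's bounding box.
crop_to_mask <- function(image, mask) {
  d <- dim(mask$mask)
  off <- mask$offset
  if (length(d) == 2L)
    image[off[1]:(off[1] + d[1] - 1L), off[2]:(off[2] + d[2] - 1L)]
  else
    image[off[1]:(off[1] + d[1] - 1L), off[2]:(off[2] + d[2] - 1L),
          off[3]:(off[3] + d[3] - 1L)]
}

## Ring / nucleoplasm partition of a 2D mask.
ring_partition <- function(m, px, ring_width_um) {
  edt <- distance_map(m, px)
  npl <- edt > ring_width_um
  list(ring = m & !npl, nucleoplasm = npl)
}

#' Mid-nucleus maximum-intensity projection
#'
#' Selects the 6 planes centred on the intensity-weighted mid-plane of the
#' nucleus and returns their per-pixel maximum, emulating a 3.5 um
#' mid-nucleus sub-stack. Stacks with fewer than 6 planes are projected
#' whole, with a warning.
#'
#' @param stack 3D intensity array (or an [image_field()] plus `channel`).
#' @param nucleus a 3D [nucleus_mask()] locating the nucleus, or `NULL` to
#'   use the whole stack's intensity profile.
#' @param channel channel role when `stack` is an `image_field`.
#' @param n_planes number of planes in the sub-stack (default 6).
#' @return 2D matrix with attribute `planes` (the plane indices used).
#' @export
mid_stack_projection <- function(stack, nucleus = NULL, channel = "lamin_ac",
                                 n_planes = 6L) {
  if (inherits(stack, "image_field")) stack <- get_channel(stack, channel)
  stopifnot(length(dim(stack)) == 3L)
  np <- dim(stack)[3L]
  if (np < n_planes) {
    warning("stack has ", np, " plane(s); projecting all of them")
    sel <- seq_len(np)
  } else {
    w <- if (!is.null(nucleus)) {
      stopifnot(inherits(nucleus, "nucleus_mask"))
      pl <- nucleus$offset[3L] + seq_len(dim(nucleus$mask)[3L]) - 1L
      prof <- numeric(np)
      crop <- crop_to_mask(stack, nucleus)
      prof[pl] <- vapply(seq_along(pl), function(k)
        sum(crop[, , k][nucleus$mask[, , k]]), numeric(1))
      prof
    } else apply(stack, 3L, sum)
    mid <- sum(w * seq_len(np)) / sum(w)
    first <- round(mid - n_planes / 2 + 0.5)
    first <- min(max(first, 1L), np - n_planes + 1L)
    sel <- first:(first + n_planes - 1L)
  }
  out <- apply(stack[, , sel, drop = FALSE], c(1L, 2L), max)
  attr(out, "planes") <- sel
  out
}

#' Peripheral localization ratio
#'
#' Mean intensity over the peripheral ring divided by the mean over the
#' nucleoplasm (nucleus eroded by the ring width). Values above 1 indicate
#' more signal at the nuclear periphery than in the nucleoplasm.
#'
#' @param image 2D intensity matrix covering the nucleus crop, or a
#'   full-field matrix when `nucleus` carries offsets into it.
#' @param nucleus a 2D [nucleus_mask()].
#' @param ring_width_um ring width in um; must leave a non-empty
#'   nucleoplasm.
#' @return dimensionless ratio.
#' @export
peripheral_ratio <- function(image, nucleus, ring_width_um = 1.0) {
  stopifnot(inherits(nucleus, "nucleus_mask"), ring_width_um > 0)
  m <- nucleus$mask
  if (!identical(dim(image), dim(m))) image <- crop_to_mask(image, nucleus)
  if (length(dim(m)) == 3L)
    stop("peripheral_ratio expects a 2D mask; project the stack first")
  part <- ring_partition(m, nucleus$pixel_size_um, ring_width_um)
  if (!any(part$nucleoplasm))
    stop("nucleus too small for ring width ", ring_width_um, " um")
  mean(image[part$ring]) / mean(image[part$nucleoplasm])
}

## Regional-median normalization shared by the patch detectors.
relative_intensity <- function(image, m, part) {
  rel <- array(NA_real_, dim(image))
  med_ring <- median(image[part$ring])
  med_np <- if (any(part$nucleoplasm)) median(image[part$nucleoplasm]) else med_ring
  rel[part$ring] <- image[part$ring] / med_ring
  rel[part$nucleoplasm] <- image[part$nucleoplasm] / med_np
  rel
}

#' Detect Lamin A/C aggregates (honeycomb and foci)
#'
#' Honeycomb: two or more interior patches where staining is absent
#' (relative intensity below `1 - k_low * MAD`), each at least
#' `min_patch_area_um2`. Foci: bright patches (above `1 + k_high * MAD`) of
#' at least `min_focus_area_um2`; interior bright patches larger than
#' `max_focus_area_um2` are treated as nucleoli and excluded.
#'
#' @param image 2D lamin intensity (crop or full field).
#' @param nucleus a 2D [nucleus_mask()].
#' @param config a [localization_config()].
#' @return list `has_honeycomb`, `has_foci`, `n_foci`, `n_holes`.
#' @export
detect_aggregates <- function(image, nucleus, config = localization_config()) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  m <- nucleus$mask
  if (!identical(dim(image), dim(m))) image <- crop_to_mask(image, nucleus)
  px <- nucleus$pixel_size_um
  part <- ring_partition(m, px, config$ring_width_um)
  rel <- relative_intensity(image, m, part)
  vals <- rel[m]
  s <- max(mad(vals, center = 1), config$mad_floor_frac)

  low <- m & !is.na(rel) & rel < 1 - config$k_low * s
  low <- low & part$nucleoplasm          # honeycomb is an interior pattern
  n_holes <- 0L
  if (any(low)) {
    ll <- label_components(low, 4L)
    sz <- tabulate(ll[ll > 0L])
    n_holes <- sum(sz * px^2 >= config$min_patch_area_um2)
  }

  high <- m & !is.na(rel) & rel > 1 + config$k_high * s
  n_foci <- 0L
  if (any(high)) {
    hl <- label_components(high, 4L)
    for (l in seq_len(max(hl))) {
      comp <- hl == l
      a <- sum(comp) * px^2
      if (a < config$min_focus_area_um2) next
      interior_only <- !any(comp & part$ring)
      if (interior_only && a > config$max_focus_area_um2) next  # nucleolus
      n_foci <- n_foci + 1L
    }
  }
  list(has_honeycomb = n_holes >= config$min_holes_honeycomb,
       has_foci = n_foci >= 1L, n_foci = n_foci, n_holes = n_holes)
}

#' Detect Lamin B1 capping
#'
#' Unwraps the peripheral ring by boundary angle and looks for a contiguous
#' angular arc of absent signal (bin mean below `cap_k` times the ring
#' median) of at least `min_arc_deg`.
#'
#' @inheritParams detect_aggregates
#' @return list `has_capping`, `capped_arc_fraction`.
#' @export
detect_capping <- function(image, nucleus, config = localization_config()) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  m <- nucleus$mask
  if (!identical(dim(image), dim(m))) image <- crop_to_mask(image, nucleus)
  px <- nucleus$pixel_size_um
  part <- ring_partition(m, px, config$ring_width_um)
  idx <- which(part$ring, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(has_capping = FALSE, capped_arc_fraction = 0))
  cen <- colMeans(which(m, arr.ind = TRUE))
  ang <- atan2(idx[, 2] - cen[2], idx[, 1] - cen[1])  # (-pi, pi]
  nb <- max(8L, round(360 / config$arc_bin_deg))
  bin <- pmin(nb, 1L + as.integer((ang + pi) / (2 * pi) * nb))
  vals <- image[part$ring]
  bin_mean <- vapply(seq_len(nb), function(b) {
    v <- vals[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  # reference level: the brighter of ring and nucleoplasm medians, so a
  # fully capped (signal-free) rim is still recognized as absent
  ref <- max(median(vals),
             if (any(part$nucleoplasm)) median(image[part$nucleoplasm]) else 0)
  if (ref <= 0)
    return(list(has_capping = FALSE, capped_arc_fraction = 0))
  absent <- !is.na(bin_mean) & bin_mean < config$cap_k * ref
  if (!any(absent))
    return(list(has_capping = FALSE, capped_arc_fraction = 0))
  frac <- mean(absent)
  # longest contiguous run on the circle
  x <- rep(absent, 2L)
  best <- 0L; run <- 0L
  for (v in x) { run <- if (v) run + 1L else 0L; best <- max(best, run) }
  best <- min(best, nb)
  arc_deg <- best * 360 / nb
  list(has_capping = arc_deg >= config$min_arc_deg,
       capped_arc_fraction = frac)
}

#' Detect emerin foci
#'
#' The foci branch of [detect_aggregates()]; the emerin signal is too weak
#' for a reliable honeycomb call, so only bright patches are scored.
#'
#' @inheritParams detect_aggregates
#' @return list `has_emerin_foci`, `n_foci`.
#' @export
detect_emerin_foci <- function(image, nucleus, config = localization_config()) {
  res <- detect_aggregates(image, nucleus, config)
  list(has_emerin_foci = res$has_foci, n_foci = res$n_foci)
}

#' Localization metrics for a list of nuclei
#'
#' Runs the peripheral ratio and all detectors over the channels present in
#' the field. For 3D fields each nucleus is first reduced to its
#' mid-nucleus maximum projection and the 2D machinery is applied to the
#' projected crop.
#'
#' @param field an [image_field()].
#' @param masks list of [nucleus_mask()] objects from the segmenter.
#' @param config a [localization_config()].
#' @return data frame, one row per nucleus: `peripheral_ratio` (Lamin A/C),
#'   `peripheral_ratio_b1`, `has_honeycomb`, `has_foci`, `n_foci`,
#'   `has_capping`, `capped_arc_fraction`, `has_emerin_foci`.
#' @export
localize_nuclei <- function(field, masks, config = localization_config()) {
  stopifnot(inherits(field, "image_field"))
  n <- length(masks)
  out <- data.frame(label_id = vapply(masks, `[[`, integer(1), "label_id"),
                    peripheral_ratio = rep(NA_real_, n),
                    peripheral_ratio_b1 = rep(NA_real_, n),
                    has_honeycomb = rep(NA, n), has_foci = rep(NA, n),
                    n_foci = rep(NA_integer_, n), has_capping = rep(NA, n),
                    capped_arc_fraction = rep(NA_real_, n),
                    has_emerin_foci = rep(NA, n))
  if (!n) return(out)
  is3d <- length(dim(masks[[1L]]$mask)) == 3L
  for (i in seq_len(n)) {
    nuc <- masks[[i]]
    nuc2 <- nuc
    get_crop <- function(role) {
      ch <- field$channels[[role]]
      if (is.null(ch)) return(NULL)
      if (is3d) {
        proj <- mid_stack_projection(crop_to_mask(ch, nuc), NULL)
        attr(proj, "planes") <- NULL
        proj
      } else crop_to_mask(ch, nuc)
    }
    if (is3d) {
      sel_planes <- attr(mid_stack_projection(crop_to_mask(
        get_channel(field, "dna"), nuc), NULL), "planes")
      m2 <- apply(nuc$mask[, , sel_planes, drop = FALSE], c(1L, 2L), any)
      if (!any(m2)) m2 <- apply(nuc$mask, c(1L, 2L), any)
      nuc2 <- nucleus_mask(m2, offset = nuc$offset[1:2],
                           label_id = nuc$label_id,
                           pixel_size_um = nuc$pixel_size_um,
                           touches_border = nuc$touches_border)
    }
    lac <- get_crop("lamin_ac")
    if (!is.null(lac)) {
      out$peripheral_ratio[i] <-
        tryCatch(peripheral_ratio(lac, nuc2, config$ring_width_um),
                 error = function(e) NA_real_)
      agg <- detect_aggregates(lac, nuc2, config)
      out$has_honeycomb[i] <- agg$has_honeycomb
      out$has_foci[i] <- agg$has_foci
      out$n_foci[i] <- agg$n_foci
    }
    lb1 <- get_crop("lamin_b1")
    if (!is.null(lb1)) {
      out$peripheral_ratio_b1[i] <-
        tryCatch(peripheral_ratio(lb1, nuc2, config$ring_width_um),
                 error = function(e) NA_real_)
      cap <- detect_capping(lb1, nuc2, config)
      out$has_capping[i] <- cap$has_capping
      out$capped_arc_fraction[i] <- cap$capped_arc_fraction
    }
    eme <- get_crop("emerin")
    if (!is.null(eme))
      out$has_emerin_foci[i] <- detect_emerin_foci(eme, nuc2, config)$has_emerin_foci
  }
  out
}
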