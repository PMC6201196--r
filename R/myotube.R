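## Myotube context: segment marker-positive (MyHC/eMyHC/titin) structures
## and assign each nucleus to the myotube or non-myotube compartment using
## three criteria: (1) the nucleus lies within a marker-positive structure,
## (2) that structure is multinucleated, and (3) the marker signal is
## excluded from the nucleus.

#' Segment myotube structures from a myogenic-marker channel
#'
#' Threshold plus connected components. A field whose marker channel shows
#' no real structure (foreground not clearly brighter than background)
#' yields zero structures.
#'
#' @param marker 2D/3D intensity image, or an [image_field()].
#' @param pixel_size_um lateral pixel size (taken from the field if given).
#' @param z_step_um z spacing for stacks.
#' @param channel channel role when a field is given.
#' @param min_area_um2 minimum structure footprint.
#' @param threshold optional fixed threshold overriding Otsu.
#' @return integer label image of structures (0 = background).
#' @export
segment_myotubes <- function(marker, pixel_size_um = NULL, z_step_um = NULL,
                             channel = "marker", min_area_um2 = 100,
                             threshold = NULL) {
  if (inherits(marker, "image_field")) {
    pixel_size_um <- marker$pixel_size_um
    z_step_um <- marker$z_step_um
    marker <- get_channel(marker, channel)
  }
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
  nd <- length(dim(marker))
  thr <- if (is.null(threshold)) otsu_threshold(marker) else threshold
  fg <- marker > thr
  # reject pseudo-structures in marker-negative fields: foreground must be
  # clearly brighter than background
  if (!any(fg) || mean(marker[fg]) < 2 * max(mean(marker[!fg]), 1e-12))
    return(array(0L, dim(marker)))
  # nuclear exclusion of the marker punches holes into the tubes; fill them
  fg <- fill_holes(fg)
  lab <- label_components(fg, if (nd == 3L) 6L else 4L)
  sizes <- tabulate(lab[lab > 0L])
  unit <- pixel_size_um^2
  keep <- which(sizes * unit >= min_area_um2)
  out <- array(0L, dim(marker))
  out[lab > 0L & lab %in% keep] <- match(lab[lab > 0L & lab %in% keep], keep)
  out
}

#' Assign nuclei to myotube / non-myotube compartments
#'
#' Criterion 1: at least `min_overlap` of the nucleus area lies inside one
#' structure. Criterion 2: that structure contains at least two such
#' nuclei. Criterion 3: the mean marker intensity inside the nucleus is
#' below `k_excl` times the mean in the surrounding structure shell
#' (nuclear exclusion). `in_myotube` requires all three.
#'
#' @param masks list of [nucleus_mask()] objects.
#' @param structures integer label image from [segment_myotubes()], or
#'   `NULL` / all-zero when no marker channel exists (every assignment is
#'   then FALSE).
#' @param marker marker intensity image (same geometry), needed for
#'   criterion 3.
#' @param min_overlap area fraction for criterion 1.
#' @param k_excl exclusion ratio for criterion 3.
#' @param shell_width_um width of the structure shell sampled around each
#'   nucleus.
#' @return data frame: `label_id`, `in_myotube`, `crit_inside`,
#'   `crit_multinucleated`, `crit_exclusion`, `structure_id` (NA outside).
#' @export
assign_myonuclei <- function(masks, structures, marker = NULL,
                             min_overlap = 0.8, k_excl = 0.5,
                             shell_width_um = 2.0) {
  n <- length(masks)
  out <- data.frame(label_id = vapply(masks, `[[`, integer(1), "label_id"),
                    in_myotube = logical(n), crit_inside = logical(n),
                    crit_multinucleated = logical(n),
                    crit_exclusion = logical(n),
                    structure_id = rep(NA_integer_, n))
  if (!n) return(out)
  if (is.null(structures) || !any(structures > 0L)) {
    if (is.null(structures))
      warning("no marker structures provided; all nuclei assigned non-myotube")
    return(out)
  }
  nuclei_px <- array(FALSE, dim(structures))
  for (i in seq_len(n)) {
    nuc <- masks[[i]]
    sub <- crop_to_mask(structures, nuc)
    vals <- sub[nuc$mask]
    tab <- table(vals[vals > 0L])
    if (length(tab)) {
      best <- as.integer(names(tab)[which.max(tab)])
      frac <- max(tab) / sum(nuc$mask)
      if (frac >= min_overlap) {
        out$crit_inside[i] <- TRUE
        out$structure_id[i] <- best
      }
    }
    d <- dim(nuc$mask); off <- nuc$offset
    if (length(d) == 2L) {
      nuclei_px[off[1]:(off[1] + d[1] - 1L),
                off[2]:(off[2] + d[2] - 1L)] <-
        nuclei_px[off[1]:(off[1] + d[1] - 1L),
                  off[2]:(off[2] + d[2] - 1L)] | nuc$mask
    } else {
      nuclei_px[off[1]:(off[1] + d[1] - 1L), off[2]:(off[2] + d[2] - 1L),
                off[3]:(off[3] + d[3] - 1L)] <-
        nuclei_px[off[1]:(off[1] + d[1] - 1L), off[2]:(off[2] + d[2] - 1L),
                  off[3]:(off[3] + d[3] - 1L)] | nuc$mask
    }
  }
  counts <- table(out$structure_id[out$crit_inside])
  multi <- as.integer(names(counts)[counts >= 2L])
  out$crit_multinucleated <- out$crit_inside & out$structure_id %in% multi

  if (!is.null(marker)) {
    fd <- dim(structures)
    for (i in which(out$crit_inside)) {
      nuc <- masks[[i]]
      is3 <- length(dim(nuc$mask)) == 3L
      px <- nuc$pixel_size_um
      spacing <- if (is3) c(px, px, nuc$z_step_um) else px
      # window enlarged by the shell width so dilation is not truncated
      grow <- ceiling(shell_width_um / c(px, px,
                                         if (is3) nuc$z_step_um else px))
      nd <- length(dim(nuc$mask))
      lo <- pmax(nuc$offset - grow[seq_len(nd)], 1L)
      hi <- pmin(nuc$offset + dim(nuc$mask) - 1L + grow[seq_len(nd)],
                 fd[seq_len(nd)])
      win <- function(a) {
        if (nd == 2L) a[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE]
        else a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      }
      big <- array(FALSE, hi - lo + 1L)
      rel <- lapply(seq_len(nd), function(k)
        (nuc$offset[k] - lo[k] + 1L):(nuc$offset[k] - lo[k] + dim(nuc$mask)[k]))
      if (nd == 2L) big[rel[[1]], rel[[2]]] <- nuc$mask
      else big[rel[[1]], rel[[2]], rel[[3]]] <- nuc$mask
      shell <- binary_dilate(big, shell_width_um, spacing) & !big
      shell <- shell & win(structures) == out$structure_id[i] &
        !win(nuclei_px)
      if (!any(shell)) next
      mk <- win(marker)
      out$crit_exclusion[i] <-
        mean(mk[big]) < k_excl * mean(mk[shell])
    }
  }
  out$in_myotube <- out$crit_inside & out$crit_multinucleated &
    out$crit_exclusion
  out
}
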