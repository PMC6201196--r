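## Synthetic field assembly: places nucleus phantoms without overlap, paints
## the DNA / Lamin A/C / Lamin B1 / Emerin / myogenic-marker channels from
## the staining model, applies Poisson+Gaussian noise, and returns the field
## together with per-nucleus ground truth.

# Per-nucleus RNG substream seeds, kept below 2^31.
nucleus_seed <- function(seed, i, salt) {
  as.integer((abs(as.numeric(seed)) %% 65011) * 32749 + i * 7919 + salt) %% 2147483646L + 1L
}

restore_rng <- function() {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a phantom field with ground truth
#'
#' Realizes a [phantom_spec()]: draws shape-label sets and mislocalization
#' flags, builds and places the nucleus masks without overlap (bounded
#' retries; a field that cannot host its nuclei raises a "field too crowded"
#' error), paints all channels, and applies the noise model. Deterministic
#' for a fixed (spec, seed).
#'
#' @param spec a [phantom_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return list with elements `field` (an [image_field()] with channels
#'   `dna`, `lamin_ac`, `lamin_b1`, `emerin` and - when
#'   `myotube_fraction > 0` - `marker`) and `truth` (list with `nuclei`, a
#'   one-row-per-nucleus data frame; `label_image`, integer ground-truth
#'   labels; `tube_image`, integer tube labels or `NULL`).
#' @export
generate_field <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(seed)) seed <- spec$seed
  on.exit(restore_rng()(), add = TRUE)
  set.seed(seed)

  px <- spec$pixel_size_um
  is3d <- length(spec$field_size) == 3L
  nr <- spec$field_size[1L]; nc <- spec$field_size[2L]
  np <- if (is3d) spec$field_size[3L] else 1L
  zs <- if (is3d) spec$z_step_um else NA_real_
  n <- spec$n_nuclei

  labels_str <- draw_shape_labels(spec$shape_mix, max(n, 1L))[seq_len(n)]
  mf <- spec$misloc_fractions
  fl_honey <- runif(n) < mf[["honeycomb"]]
  fl_foci <- runif(n) < mf[["foci"]]
  fl_cap <- runif(n) < mf[["capping"]]
  fl_emer <- runif(n) < mf[["emerin_foci"]]

  ## ---- myotube layout -----------------------------------------------------
  n_tube <- round(spec$myotube_fraction * n)
  if (n_tube < 2L) n_tube <- 0L
  tube_members <- if (n_tube > 0L) sort(sample.int(n, n_tube)) else integer(0)
  per_tube <- 5L
  k_tubes <- if (n_tube > 0L) ceiling(n_tube / per_tube) else 0L
  tube_of <- integer(n)  # 0 = none
  if (k_tubes > 0L)  # balanced split so every tube is multinucleated
    tube_of[tube_members] <- sort(rep_len(seq_len(k_tubes), n_tube))
  tube_h_px <- round(18 / px)
  tube_gap_px <- round(8 / px)
  tube_rows <- vector("list", k_tubes)
  if (k_tubes > 0L) {
    need <- k_tubes * (tube_h_px + tube_gap_px) + tube_gap_px
    if (need > nr)
      stop("field too crowded: not enough rows for ", k_tubes, " myotubes")
    for (t in seq_len(k_tubes)) {
      r0 <- tube_gap_px + (t - 1L) * (tube_h_px + tube_gap_px) + 1L
      tube_rows[[t]] <- c(r0, r0 + tube_h_px - 1L)
    }
  }

  ## ---- build nucleus masks ------------------------------------------------
  masks <- vector("list", n)
  feret_um <- numeric(n)
  major_true <- numeric(n)
  pure_ellipse <- logical(n)
  for (i in seq_len(n)) {
    set.seed(nucleus_seed(seed, i, 1L))
    ls <- parse_label_set(labels_str[i])
    if ("elongated" %in% ls) {
      major <- runif(1, spec$elongated_length_um[1], spec$elongated_length_um[2])
      minor <- spec$elongated_minor_um * runif(1, 0.92, 1.08)
    } else {
      jit <- runif(2, -spec$axes_jitter, spec$axes_jitter)
      major <- spec$base_axes_um[1] * (1 + jit[1])
      minor <- spec$base_axes_um[2] * (1 + jit[2])
      if (minor > major) { tmp <- major; major <- minor; minor <- tmp }
    }
    orient <- if (tube_of[i] > 0L) runif(1, -0.15, 0.15) else runif(1, 0, pi)
    base_ang <- runif(1, 0, 2 * pi)
    params <- list(
      bend_deg = runif(1, 130, 170),
      n_bites = sample(2:3, 1),
      bite_angles = (base_ang + c(0, 2.15, 4.3) + runif(3, -0.25, 0.25)) %% (2 * pi),
      bite_radius_frac = runif(1, 0.4, 0.5),
      bleb_diameter_um = max(1.7, runif(1, 0.16, 0.26) * minor),
      bleb_angle = runif(1, 0, 2 * pi),
      string_length_um = runif(1, 3.5, 6),
      string_width_um = runif(1, 0.6, 0.9),
      string_angle = runif(1, 0, 2 * pi))
    for (try in 1:5) {
      m <- generate_shape_mask(ls, c(major, minor), px, orient, params)
      fer <- pixel_feret_um(m, px)
      if ("elongated" %in% ls && fer <= 25.3) major <- major * 1.1
      else if (!("elongated" %in% ls) && fer > 24.5) {
        major <- major * 0.9; minor <- minor * 0.9
      } else break
    }
    # trim to tight bounding box plus 2 px background pad
    rs <- range(which(rowSums(m) > 0)); cs <- range(which(colSums(m) > 0))
    crop <- matrix(FALSE, diff(rs) + 5L, diff(cs) + 5L)
    crop[3:(diff(rs) + 3L), 3:(diff(cs) + 3L)] <-
      m[rs[1]:rs[2], cs[1]:cs[2]]
    masks[[i]] <- crop
    feret_um[i] <- fer
    pure_ellipse[i] <- length(ls) == 0L || identical(ls, "elongated")
    major_true[i] <- if (pure_ellipse[i]) major else fer
  }

  ## ---- placement ----------------------------------------------------------
  set.seed(nucleus_seed(seed, 0L, 2L))
  ctr_row <- numeric(n); ctr_col <- numeric(n); ctr_pl <- rep(1, n)
  rad_px <- vapply(seq_len(n), function(i)
    ceiling((feret_um[i] / 2 + 1.2) / px), numeric(1))
  if (is3d) {
    c_um <- spec$z_semi_axis_um
    z_half <- c_um / zs
    if (np < 2 * z_half + 2)
      stop("field too crowded: stack too shallow for the nucleus z extent")
  }
  in_tube_band <- function(row, r) {
    if (k_tubes == 0L) return(FALSE)
    any(vapply(tube_rows, function(tr)
      row + r >= tr[1] - tube_gap_px / 2 && row - r <= tr[2] + tube_gap_px / 2,
      logical(1)))
  }
  placed <- integer(0)
  free <- setdiff(seq_len(n), tube_members)
  ord <- c(tube_members, free[order(rad_px[free], decreasing = TRUE)])
  tube_cursor <- rep(NA_real_, max(k_tubes, 1L))
  for (i in ord) {
    r <- rad_px[i]
    ok <- FALSE
    for (try in seq_len(300L)) {
      if (tube_of[i] > 0L) {
        t <- tube_of[i]
        tr <- tube_rows[[t]]
        row <- mean(tr) + runif(1, -2, 2)
        if (is.na(tube_cursor[t])) tube_cursor[t] <- r + 3 + runif(1, 0, 10)
        col <- tube_cursor[t] + r
      } else {
        row <- runif(1, r + 2, nr - r - 1)
        if (in_tube_band(row, r)) next
        col <- runif(1, r + 2, nc - r - 1)
      }
      if (col > nc - r - 1 || row < r + 2 || row > nr - r - 1)
        break  # tube ran out of columns -> crowded
      sep_ok <- TRUE
      for (j in placed) {
        if ((ctr_row[j] - row)^2 + (ctr_col[j] - col)^2 <
            (rad_px[j] + r + 2)^2) { sep_ok <- FALSE; break }
      }
      if (!sep_ok) next
      ctr_row[i] <- round(row); ctr_col[i] <- round(col)
      if (tube_of[i] > 0L)
        tube_cursor[tube_of[i]] <- col + r + 4 + runif(1, 0, 8)
      if (is3d)
        ctr_pl[i] <- round(runif(1, z_half + 1.5, np - z_half - 0.5))
      ok <- TRUE
      break
    }
    if (!ok)
      stop("field too crowded: could not place nucleus ", i,
           " after bounded retries")
    placed <- c(placed, i)
  }

  ## ---- rasterize label image ----------------------------------------------
  dims <- if (is3d) c(nr, nc, np) else c(nr, nc)
  lab <- array(0L, dims)
  crop_index <- vector("list", n)   # field index ranges per nucleus
  crops3d <- vector("list", n)      # 3D crop masks when is3d
  for (i in seq_len(n)) {
    m <- masks[[i]]
    hr <- (nrow(m) - 1L) %/% 2L; hc <- (ncol(m) - 1L) %/% 2L
    rows <- (ctr_row[i] - hr):(ctr_row[i] - hr + nrow(m) - 1L)
    cols <- (ctr_col[i] - hc):(ctr_col[i] - hc + ncol(m) - 1L)
    keep_r <- rows >= 1L & rows <= nr
    keep_c <- cols >= 1L & cols <= nc
    m <- m[keep_r, keep_c, drop = FALSE]
    rows <- rows[keep_r]; cols <- cols[keep_c]
    if (is3d) {
      set.seed(nucleus_seed(seed, i, 3L))
      c_um <- spec$z_semi_axis_um
      edt2 <- distance_map(m, px)
      pls <- seq_len(np)
      dz <- (pls - ctr_pl[i]) * zs
      # flattened (super-ellipsoidal, q = 4) z profile: adherent nuclei are
      # pancake-like with steep walls, so a mid-nucleus sub-stack sees an
      # almost constant in-plane outline
      sq <- 1 - (dz / c_um)^4
      keep_p <- sq > 0
      pls <- pls[keep_p]
      m3 <- array(FALSE, c(nrow(m), ncol(m), length(pls)))
      recede <- feret_um[i] / 4
      for (k in seq_along(pls)) {
        depth <- recede * (1 - sq[keep_p][k]^0.25)
        m3[, , k] <- m & (edt2 > depth)
      }
      crops3d[[i]] <- m3
      crop_index[[i]] <- list(rows = rows, cols = cols, planes = pls)
      sub <- lab[rows, cols, pls]
      sub[m3] <- i
      lab[rows, cols, pls] <- sub
    } else {
      crop_index[[i]] <- list(rows = rows, cols = cols)
      sub <- lab[rows, cols]
      sub[m] <- i
      lab[rows, cols] <- sub
      masks[[i]] <- m
    }
  }

  ## ---- paint channels -----------------------------------------------------
  bg <- spec$background_level
  ch_dna <- array(bg, dims)
  ch_lac <- array(bg, dims)
  ch_lb1 <- array(bg, dims)
  ch_eme <- array(bg, dims)
  npl_lv <- spec$nucleoplasm_level
  spacing <- if (is3d) c(px, px, zs) else c(px, px)

  n_foci_true <- integer(n)
  for (i in seq_len(n)) {
    set.seed(nucleus_seed(seed, i, 4L))
    m <- if (is3d) crops3d[[i]] else masks[[i]]
    ci <- crop_index[[i]]
    edt <- distance_map(m, spacing)
    rim <- m & edt <= spec$rim_width_um
    # physical coordinates of the crop, centred on the nucleus centroid
    idx <- which(m, arr.ind = TRUE)
    cen <- colMeans(idx)
    d <- dim(m)
    co_r <- (slice.index(array(0, d), 1L) - cen[1]) * px
    co_c <- (slice.index(array(0, d), 2L) - cen[2]) * px
    co_z <- if (is3d) (slice.index(array(0, d), 3L) - cen[3]) * zs else 0

    v_lac <- array(0, d); v_lb1 <- array(0, d); v_eme <- array(0, d)
    v_lac[m] <- npl_lv; v_lac[rim] <- spec$rim_ratio * npl_lv
    v_lb1[m] <- npl_lv; v_lb1[rim] <- spec$rim_ratio * npl_lv
    v_eme[m] <- 0.7 * npl_lv; v_eme[rim] <- 0.7 * spec$rim_ratio * npl_lv

    put_blob <- function(v, centre_idx, radius_um, value) {
      dd <- sqrt((co_r - (centre_idx[1] - cen[1]) * px)^2 +
                 (co_c - (centre_idx[2] - cen[2]) * px)^2 +
                 (if (is3d) (co_z - (centre_idx[3] - cen[3]) * zs)^2 else 0))
      v[dd <= radius_um & m] <- value
      v
    }

    if (fl_honey[i]) {
      elig <- which(edt > spec$rim_width_um + 1.3, arr.ind = TRUE)
      k <- min(spec$n_holes, nrow(elig))
      if (k >= 2L) {
        pick <- elig[sample.int(nrow(elig), k), , drop = FALSE]
        for (h in seq_len(k))
          v_lac <- put_blob(v_lac, pick[h, ], runif(1, 0.8, 1.2), 0.05 * npl_lv)
      } else fl_honey[i] <- FALSE
    }
    if (fl_foci[i]) {
      elig <- which(rim, arr.ind = TRUE)
      k <- min(spec$n_foci, nrow(elig))
      if (k >= 1L) {
        pick <- elig[sample.int(nrow(elig), k), , drop = FALSE]
        for (h in seq_len(k))
          v_lac <- put_blob(v_lac, pick[h, ], runif(1, 0.45, 0.65), 4 * npl_lv)
        n_foci_true[i] <- k
      } else fl_foci[i] <- FALSE
    }
    if (fl_cap[i]) {
      ang <- atan2(co_c, co_r)
      phi0 <- runif(1, -pi, pi)
      half <- spec$capping_arc_deg / 2 * pi / 180
      dphi <- abs(((ang - phi0 + pi) %% (2 * pi)) - pi)
      v_lb1[rim & dphi <= half] <- 0.1 * npl_lv
    }
    if (fl_emer[i]) {
      elig <- which(rim, arr.ind = TRUE)
      k <- min(spec$n_foci, nrow(elig))
      if (k >= 1L) {
        pick <- elig[sample.int(nrow(elig), k), , drop = FALSE]
        for (h in seq_len(k))
          v_eme <- put_blob(v_eme, pick[h, ], runif(1, 0.45, 0.65),
                            4 * 0.7 * npl_lv)
      } else fl_emer[i] <- FALSE
    }

    poke <- function(field_arr, v) {
      if (is3d) {
        sub <- field_arr[ci$rows, ci$cols, ci$planes]
        sub[m] <- v[m]
        field_arr[ci$rows, ci$cols, ci$planes] <- sub
      } else {
        sub <- field_arr[ci$rows, ci$cols]
        sub[m] <- v[m]
        field_arr[ci$rows, ci$cols] <- sub
      }
      field_arr
    }
    v_dna <- array(0, d); v_dna[m] <- spec$dna_level
    ch_dna <- poke(ch_dna, v_dna)
    ch_lac <- poke(ch_lac, v_lac)
    ch_lb1 <- poke(ch_lb1, v_lb1)
    ch_eme <- poke(ch_eme, v_eme)
  }

  ## ---- marker channel and tube image --------------------------------------
  tube_img <- NULL
  ch_mark <- NULL
  if (k_tubes > 0L) {
    tube_img <- array(0L, dims)
    ch_mark <- array(bg, dims)
    mark_lv <- 150
    for (t in seq_len(k_tubes)) {
      tr <- tube_rows[[t]]
      members <- which(tube_of == t)
      x0 <- max(1, min(ctr_col[members]) - max(rad_px[members]) - 5)
      x1 <- min(nc, max(ctr_col[members]) + max(rad_px[members]) + 5)
      if (is3d) {
        tube_img[tr[1]:tr[2], x0:x1, ] <- t
        ch_mark[tr[1]:tr[2], x0:x1, ] <- mark_lv
      } else {
        tube_img[tr[1]:tr[2], x0:x1] <- t
        ch_mark[tr[1]:tr[2], x0:x1] <- mark_lv
      }
    }
    # nuclear exclusion of the marker inside member nuclei
    ch_mark[lab > 0 & tube_img > 0] <- 0.15 * 150
  }

  ## ---- noise --------------------------------------------------------------
  chans <- list(dna = ch_dna, lamin_ac = ch_lac, lamin_b1 = ch_lb1,
                emerin = ch_eme)
  if (!is.null(ch_mark)) chans$marker <- ch_mark
  if (!is.null(spec$noise)) {
    set.seed(nucleus_seed(seed, 0L, 5L))
    g <- spec$noise$poisson_gain
    for (nm in names(chans)) {
      v <- chans[[nm]]
      dyn <- max(v)
      noisy <- rpois(length(v), lambda = g * as.numeric(v)) / g +
        rnorm(length(v), 0, spec$noise$gaussian_sd_frac * dyn)
      noisy[noisy < 0] <- 0
      chans[[nm]] <- array(noisy, dims)
    }
  }

  truth_df <- data.frame(
    id = seq_len(n),
    label_set = labels_str,
    major_axis_um = major_true,
    centroid_row_um = ctr_row * px,
    centroid_col_um = ctr_col * px,
    centroid_plane = if (is3d) ctr_pl else NA_real_,
    rim_ratio = rep(spec$rim_ratio, n),
    has_honeycomb = fl_honey,
    has_foci = fl_foci,
    n_foci = n_foci_true,
    has_capping = fl_cap,
    has_emerin_foci = fl_emer,
    in_myotube = tube_of > 0L,
    tube_id = ifelse(tube_of > 0L, tube_of, NA_integer_),
    stringsAsFactors = FALSE)
  for (lbl in SHAPE_LABELS)
    truth_df[[lbl]] <- vapply(truth_df$label_set,
                              function(s) lbl %in% parse_label_set(s),
                              logical(1), USE.NAMES = FALSE)
  truth_df$is_normal <- truth_df$label_set == "normal"

  field <- image_field(chans, pixel_size_um = px,
                       z_step_um = if (is3d) zs else NULL)
  list(field = field,
       truth = list(nuclei = truth_df, label_image = lab,
                    tube_image = tube_img))
}
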