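## Independent oracles and fixture builders. Everything here is written
## against the mathematical definitions, not against the package's code
## paths: the marching-squares tracer below shares no code with
## grDevices::contourLines or the package's smoothing.

# Ramanujan's closed-form ellipse perimeter (semi-axes a, b)
ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# Rasterize a filled (rotated) ellipse; axes are FULL lengths in pixels.
raster_ellipse <- function(n, major_px, minor_px, theta = 0,
                           centre = (n + 1) / 2) {
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  u <- (xy$col - centre) * cos(theta) + (xy$row - centre) * sin(theta)
  v <- -(xy$col - centre) * sin(theta) + (xy$row - centre) * cos(theta)
  matrix((u / (major_px / 2))^2 + (v / (minor_px / 2))^2 <= 1, n, n)
}

raster_disc <- function(n, r_px, centre = (n + 1) / 2) {
  raster_ellipse(n, 2 * r_px, 2 * r_px, 0, centre)
}

## ---- independent sub-pixel contour oracle ---------------------------------
## Smooths the padded mask with its own Gaussian (shift-and-add), walks every
## 2x2 cell of the smoothed field, interpolates the 0.5 crossings, orients
## each segment by bilinear sampling, and accumulates perimeter (segment
## lengths) and area (Green's theorem / per-edge shoelace terms).

oracle_contour_metrics <- function(mask, sigma = 1.5, level = 0.5) {
  r <- ceiling(3 * sigma)
  pad <- r + 2L
  nr <- nrow(mask) + 2L * pad
  nc <- ncol(mask) + 2L * pad
  mp <- matrix(0, nr, nc)
  mp[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- as.numeric(mask)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  s <- matrix(0, nr, nc)
  for (di in (-r):r) for (dj in (-r):r) {
    w <- k[di + r + 1] * k[dj + r + 1]
    rows_src <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cols_src <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    # zero-extension: out-of-range shifts contribute nothing
    src <- matrix(0, nr, nc)
    ok_r <- seq_len(nr) + di >= 1L & seq_len(nr) + di <= nr
    ok_c <- seq_len(nc) + dj >= 1L & seq_len(nc) + dj <= nc
    src[ok_r, ok_c] <- mp[seq_len(nr)[ok_r] + di, seq_len(nc)[ok_c] + dj]
    s <- s + w * src
  }

  interp <- function(p1, v1, p2, v2) {
    t <- (level - v1) / (v2 - v1)
    p1 + t * (p2 - p1)
  }
  bilinear <- function(v00, v01, v10, v11, fx, fy) {
    # fx along columns, fy along rows, in [0,1]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  }

  perim <- 0
  area2 <- 0
  for (i in seq_len(nr - 1L)) {
    row_i <- s[i, ]
    row_i1 <- s[i + 1L, ]
    for (j in seq_len(nc - 1L)) {
      v00 <- row_i[j]; v01 <- row_i[j + 1L]
      v10 <- row_i1[j]; v11 <- row_i1[j + 1L]
      b <- c(v00, v01, v10, v11) >= level
      if (all(b) || !any(b)) next
      # crossings in (x = col, y = row) coordinates local to the cell corner
      pts <- list()
      if (xor(b[1], b[2])) pts$top <- c(interp(0, v00, 1, v01), 0)
      if (xor(b[3], b[4])) pts$bottom <- c(interp(0, v10, 1, v11), 1)
      if (xor(b[1], b[3])) pts$left <- c(0, interp(0, v00, 1, v10))
      if (xor(b[2], b[4])) pts$right <- c(1, interp(0, v01, 1, v11))
      segs <- if (length(pts) == 2L) {
        list(c(pts[[1]], pts[[2]]))
      } else {
        centre_in <- mean(c(v00, v01, v10, v11)) >= level
        # saddle: centre decides which diagonal the contour hugs
        if ((b[1] && centre_in) || (!b[1] && !centre_in))
          list(c(pts$top, pts$right), c(pts$bottom, pts$left))
        else
          list(c(pts$top, pts$left), c(pts$bottom, pts$right))
      }
      for (sg in segs) {
        x1 <- sg[1]; y1 <- sg[2]; x2 <- sg[3]; y2 <- sg[4]
        mx <- (x1 + x2) / 2; my <- (y1 + y2) / 2
        # left normal of (P1 -> P2)
        nx <- -(y2 - y1); ny <- x2 - x1
        nl <- sqrt(nx^2 + ny^2)
        if (nl == 0) next
        eps <- 0.05
        px <- min(max(mx + eps * nx / nl, 0), 1)
        py <- min(max(my + eps * ny / nl, 0), 1)
        if (bilinear(v00, v01, v10, v11, px, py) < level) {
          tmp <- c(x1, y1); x1 <- x2; y1 <- y2; x2 <- tmp[1]; y2 <- tmp[2]
        }
        gx1 <- j + x1; gy1 <- i + y1; gx2 <- j + x2; gy2 <- i + y2
        perim <- perim + sqrt((x2 - x1)^2 + (y2 - y1)^2)
        area2 <- area2 + (gx1 * gy2 - gx2 * gy1)
      }
    }
  }
  list(perimeter_px = perim, area_px2 = abs(area2) / 2)
}

## ---- independent replay of the label sampler ------------------------------
## Same uniform stream, different implementation (explicit cumulative loop).
replay_label_draw <- function(shape_mix, n, seed) {
  set.seed(seed)
  u <- runif(n)
  cs <- cumsum(shape_mix)
  out <- character(n)
  for (i in seq_len(n)) {
    k <- 1L
    while (u[i] > cs[k]) k <- k + 1L
    out[i] <- names(shape_mix)[k]
  }
  out
}

## ---- ground-truth matching ------------------------------------------------
match_to_truth <- function(masks, label_image) {
  vapply(masks, function(m) {
    sub <- nucmorph:::crop_to_mask(label_image, m)
    v <- sub[m$mask]
    v <- v[v > 0]
    if (!length(v)) NA_integer_
    else as.integer(names(which.max(table(v))))
  }, integer(1))
}

jaccard_vs_truth <- function(mask, gt_id, label_image) {
  sub <- nucmorph:::crop_to_mask(label_image, mask)
  inter <- sum(sub == gt_id & mask$mask)
  union <- sum(mask$mask) + sum(label_image == gt_id) - inter
  inter / union
}

## ---- phantom battery ------------------------------------------------------
## The stated recovery world: 60% normal, 8% each abnormal class, 25%
## mislocalization fractions, default Poisson+Gaussian noise.
battery_mix <- c(normal = 0.6, jellybean = 0.08, severely_deformed = 0.08,
                 blebs = 0.08, strings = 0.08, elongated = 0.08)
battery_misloc <- c(honeycomb = 0.25, foci = 0.25, capping = 0.25,
                    emerin_foci = 0.25)

run_battery <- function(n_fields, n_per_field = 40L, seed = 2024L,
                        shape_mix = battery_mix,
                        misloc = battery_misloc, noise = "default") {
  pred_all <- NULL
  truth_all <- NULL
  for (f in seq_len(n_fields)) {
    spec <- phantom_spec(
      n_nuclei = n_per_field, field_size = c(1100L, 1100L),
      shape_mix = shape_mix, misloc_fractions = misloc,
      noise = if (identical(noise, "default"))
        list(poisson_gain = 1, gaussian_sd_frac = 0.02) else noise,
      seed = seed + f)
    sim <- generate_field(spec)
    masks <- segment_nuclei_2d(sim$field)
    tab <- classify_nuclei(masks, field_id = f)
    loc <- localize_nuclei(sim$field, masks)
    tab <- cbind(tab, loc[, setdiff(names(loc), "label_id"), drop = FALSE])
    gt <- sim$truth$nuclei[match_to_truth(masks, sim$truth$label_image), ]
    pred_all <- rbind(pred_all, tab)
    truth_all <- rbind(truth_all, gt)
  }
  list(pred = pred_all, truth = truth_all)
}

recall_precision <- function(pred, truth) {
  tp <- sum(pred & truth)
  c(recall = tp / sum(truth), precision = tp / sum(pred))
}
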