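## Minimal baseline TIFF codec (uncompressed, grayscale, 8/16-bit,
## little- or big-endian, multi-page). Covers what the pipeline needs:
## multi-channel fields and z-stacks with pixel-size metadata, written so
## that standard readers (Fiji, tifffile) open them, plus a JSON payload in
## ImageDescription carrying the channel-role map and z spacing.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)  # BYTE..DOUBLE

#' Write a multi-page TIFF
#'
#' @param pages list of numeric matrices (one per page), values clamped to
#'   the unsigned range of `bits`.
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @param description optional ASCII string stored in the first page's
#'   ImageDescription tag.
#' @param pixel_size_um optional pixel size; stored as X/YResolution in
#'   pixels per centimetre.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, bits = 16L, description = NULL,
                       pixel_size_um = NULL) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))),
            bits %in% c(8L, 16L))
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wb(42L, 2)
  wb(8L, 4)  # first IFD immediately after the header
  pos <- 8

  n_pages <- length(pages)
  for (p in seq_len(n_pages)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    maxval <- 2^bits - 1
    v <- as.integer(pmin(pmax(round(t(m)), 0), maxval))  # row-major

    entries <- list()  # tag, type, count, value (integer vector) or raw
    add <- function(tag, type, count, value)
      entries[[length(entries) + 1L]] <<- list(tag = tag, type = type,
                                               count = count, value = value)
    add(256L, 4L, 1L, w)            # ImageWidth
    add(257L, 4L, 1L, h)            # ImageLength
    add(258L, 3L, 1L, bits)         # BitsPerSample
    add(259L, 3L, 1L, 1L)           # Compression: none
    add(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    desc_raw <- NULL
    if (p == 1L && !is.null(description)) {
      desc_raw <- c(charToRaw(enc2utf8(description)), as.raw(0L))
      add(270L, 2L, length(desc_raw), desc_raw)
    }
    add(273L, 4L, 1L, NA)           # StripOffsets, patched below
    add(277L, 3L, 1L, 1L)           # SamplesPerPixel
    add(278L, 4L, 1L, h)            # RowsPerStrip
    add(279L, 4L, 1L, length(v) * bits / 8)  # StripByteCounts
    res_raw <- NULL
    if (!is.null(pixel_size_um)) {
      ppcm <- 1e4 / pixel_size_um  # pixels per centimetre
      num <- round(ppcm * 1000); den <- 1000L
      res_raw <- c(int_to_raw_le(num, 4), int_to_raw_le(den, 4))
      add(282L, 5L, 1L, res_raw)    # XResolution (RATIONAL)
      add(283L, 5L, 1L, res_raw)    # YResolution
      add(296L, 3L, 1L, 3L)         # ResolutionUnit: centimetre
    }
    add(339L, 3L, 1L, 1L)           # SampleFormat: unsigned

    n_ent <- length(entries)
    ifd_size <- 2 + 12 * n_ent + 4
    # layout: IFD | external values | pixel data
    ext_pos <- pos + ifd_size
    ext <- raw(0)
    for (i in seq_len(n_ent)) {
      e <- entries[[i]]
      sz <- TIFF_TYPE_SIZES[e$type] * e$count
      if (sz > 4) {
        entries[[i]]$offset <- ext_pos + length(ext)
        ext <- c(ext, as.raw(e$value))
        if (length(ext) %% 2 == 1) ext <- c(ext, as.raw(0L))
      }
    }
    data_pos <- ext_pos + length(ext)
    strip_idx <- which(vapply(entries, function(e) e$tag == 273L, logical(1)))
    entries[[strip_idx]]$value <- data_pos

    wb(n_ent, 2)
    for (e in entries[order(vapply(entries, `[[`, integer(1), "tag"))]) {
      wb(e$tag, 2); wb(e$type, 2); wb(e$count, 4)
      sz <- TIFF_TYPE_SIZES[e$type] * e$count
      if (sz > 4) {
        wb(e$offset, 4)
      } else if (e$type == 3L) {        # SHORT packed left-justified
        wb(c(e$value, 0L), 2)
      } else {
        wb(e$value, 4)
      }
    }
    next_ifd <- if (p < n_pages) data_pos + length(v) * bits / 8 else 0
    wb(next_ifd, 4)
    if (length(ext)) writeBin(ext, con)
    writeBin(v, con, size = bits / 8, endian = "little")
    pos <- next_ifd
  }
  invisible(path)
}

int_to_raw_le <- function(x, n) {
  out <- raw(n)
  x <- as.numeric(x)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_to_int_le <- function(r, endian) {
  if (endian == "big") r <- rev(r)
  sum(as.numeric(r) * 256^(seq_along(r) - 1))
}

#' Read a multi-page TIFF
#'
#' Supports uncompressed grayscale 8/16-bit baseline TIFFs (either byte
#' order, any strip layout).
#'
#' @param path file to read.
#' @return list with `pages` (list of numeric matrices), `description`
#'   (string or NULL) and `pixel_size_um` (from the resolution tags, or
#'   NULL).
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
  else stop("not a TIFF file: ", path)
  rint <- function(off, n) raw_to_int_le(raw_all[(off + 1):(off + n)],
                                         endian = if (endian == "little") "little" else "big")
  if (rint(2, 2) != 42) stop("not a TIFF file: ", path)
  ifd_off <- rint(4, 4)
  pages <- list()
  description <- NULL
  pixel_size_um <- NULL
  while (ifd_off != 0) {
    n_ent <- rint(ifd_off, 2)
    tags <- list()
    for (i in seq_len(n_ent)) {
      base <- ifd_off + 2 + (i - 1) * 12
      tag <- rint(base, 2); type <- rint(base + 2, 2)
      count <- rint(base + 4, 4)
      sz <- TIFF_TYPE_SIZES[type] * count
      val_off <- if (sz > 4) rint(base + 8, 4) else base + 8
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        offset = val_off)
    }
    gv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      unit <- TIFF_TYPE_SIZES[t$type]
      vapply(seq_len(t$count), function(k)
        rint(t$offset + (k - 1) * unit, unit), numeric(1))
    }
    w <- gv(256); h <- gv(257)
    bits <- gv(258, 8); comp <- gv(259, 1)
    if (comp != 1) stop("unsupported TIFF compression scheme: ", comp)
    if (!bits[1] %in% c(8, 16)) stop("unsupported bit depth: ", bits[1])
    if (!is.null(tags[["270"]]) && is.null(description)) {
      t <- tags[["270"]]
      d <- raw_all[(t$offset + 1):(t$offset + t$count)]
      description <- rawToChar(d[d != as.raw(0)])
    }
    if (!is.null(tags[["282"]]) && is.null(pixel_size_um)) {
      t <- tags[["282"]]
      num <- rint(t$offset, 4); den <- rint(t$offset + 4, 4)
      unit_code <- gv(296, 2)
      if (num > 0 && den > 0) {
        per_len <- num / den
        scale <- if (unit_code == 3) 1e4 else if (unit_code == 2) 25400 else NA
        if (!is.na(scale)) pixel_size_um <- scale / per_len
      }
    }
    offs <- gv(273); counts <- gv(279)
    rows_per_strip <- gv(278, h)
    npx <- w * h
    vals <- numeric(npx)
    got <- 0
    for (s in seq_along(offs)) {
      n_this <- counts[s] / (bits[1] / 8)
      seg <- readBin(raw_all[(offs[s] + 1):(offs[s] + counts[s])],
                     "integer", n = n_this, size = bits[1] / 8,
                     signed = FALSE, endian = endian)
      vals[(got + 1):(got + n_this)] <- seg
      got <- got + n_this
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd_off <- rint(ifd_off + 2 + 12 * n_ent, 4)
  }
  list(pages = pages, description = description,
       pixel_size_um = pixel_size_um)
}
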