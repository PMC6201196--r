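#' Multi-channel image field
#'
#' Container for one acquired or simulated field: named channel arrays plus
#' physical calibration. Channels are matrices (2D fields) or 3D arrays
#' `[row, col, plane]` (z-stacks), all of identical dimensions. Canonical
#' channel roles are `dna`, `lamin_ac`, `lamin_b1`, `emerin` and `marker`
#' (myogenic marker such as MyHC or titin).
#'
#' @param channels named list of numeric matrices/arrays.
#' @param pixel_size_um lateral pixel size in um/px.
#' @param z_step_um z spacing in um (3D only).
#' @param field_id optional identifier carried into result tables.
#' @return object of class `image_field`.
#' @export
image_field <- function(channels, pixel_size_um, z_step_um = NULL,
                        field_id = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  dims <- lapply(channels, function(ch) dim(ch))
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same dimensions")
  nd <- length(dims[[1L]])
  if (!nd %in% c(2L, 3L)) stop("channels must be 2D matrices or 3D arrays")
  if (nd == 3L && is.null(z_step_um))
    stop("z_step_um is required for a 3D field")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, field_id = field_id),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("image_field: %s px, %.3g um/px%s\n",
              paste(d, collapse = " x "), x$pixel_size_um,
              if (!is.null(x$z_step_um))
                sprintf(", z step %.3g um", x$z_step_um) else ""))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of z planes of a field (1 for 2D)
#' @keywords internal
field_planes <- function(field) {
  d <- dim(field$channels[[1L]])
  if (length(d) == 3L) d[3L] else 1L
}

#' Fetch a channel by role, with an informative error
#' @keywords internal
get_channel <- function(field, role) {
  if (!role %in% names(field$channels))
    stop(sprintf("channel '%s' is not present in the field (have: %s)",
                 role, paste(names(field$channels), collapse = ", ")))
  field$channels[[role]]
}
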