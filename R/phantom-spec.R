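## Phantom specification: a stated imaging world (geometry, staining model,
## noise) from which fields with per-nucleus ground truth are generated.

#' Shape abnormality labels
#'
#' The five nuclear shape-abnormality classes scored by the pipeline. A
#' nucleus can carry several labels at once; the empty set means a normal
#' (circular/oval) nucleus.
#' @export
SHAPE_LABELS <- c("jellybean", "severely_deformed", "blebs", "strings",
                  "elongated")

#' Parse a shape-label-set string
#'
#' Label sets are serialized as `"normal"` (empty set) or `"+"`-joined label
#' names, e.g. `"blebs+elongated"`.
#' @param x character scalar.
#' @return character vector of labels (length 0 for normal).
#' @export
parse_label_set <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x == "normal" || x == "") return(character(0))
  labs <- strsplit(x, "+", fixed = TRUE)[[1L]]
  bad <- setdiff(labs, SHAPE_LABELS)
  if (length(bad)) stop("unknown shape label(s): ", paste(bad, collapse = ", "))
  labs
}

#' Serialize a label set
#' @param labels character vector of labels (possibly empty).
#' @return `"normal"` or `"+"`-joined labels in canonical order.
#' @export
format_label_set <- function(labels) {
  labels <- intersect(SHAPE_LABELS, labels)
  if (!length(labels)) "normal" else paste(labels, collapse = "+")
}

#' Phantom field specification
#'
#' Describes one synthetic field of nucleus phantoms: how many nuclei, their
#' shape-class mix, the lamina staining model (peripheral rim over a
#' nucleoplasmic level, plus optional honeycomb holes, bright foci, Lamin B1
#' capping arcs and emerin foci), myotube context, and the noise model.
#'
#' Geometry defaults emulate a 63x confocal field: 0.2 um/px, normal nuclei
#' with a 16 x 11 um elliptical envelope (major axis safely below the 25 um
#' elongation cut-off), elongated nuclei sampled above it.
#'
#' @param n_nuclei number of nuclei to place.
#' @param field_size field size in pixels, `c(rows, cols)` for a 2D field or
#'   `c(rows, cols, planes)` for a z-stack.
#' @param pixel_size_um lateral pixel size, um/px.
#' @param z_step_um z spacing in um (required for 3D fields).
#' @param shape_mix named probability vector over label-set strings (see
#'   [parse_label_set()]); must sum to 1.
#' @param base_axes_um major/minor axes (um) of a typical normal nucleus;
#'   jittered per nucleus by `axes_jitter`.
#' @param axes_jitter fractional uniform jitter applied to the base axes.
#' @param elongated_length_um range (um) from which major-axis lengths of
#'   elongated nuclei are drawn; must lie strictly above 25.
#' @param elongated_minor_um minor axis (um) of elongated nuclei.
#' @param z_semi_axis_um z semi-axis (um) of 3D nuclei.
#' @param rim_ratio true peripheral/nucleoplasm intensity ratio of the lamin
#'   channels; 1 gives spatially uniform staining.
#' @param rim_width_um width of the bright peripheral rim (um). Matches the
#'   default measurement ring width so that noise-free recovery is exact.
#' @param nucleoplasm_level nucleoplasmic intensity (photon counts).
#' @param dna_level DNA-channel intensity inside nuclei.
#' @param background_level field background intensity.
#' @param misloc_fractions named vector of per-nucleus probabilities for
#'   `honeycomb`, `foci`, `capping`, `emerin_foci` (independent Bernoulli).
#' @param n_foci bright lamin A/C foci injected per affected nucleus.
#' @param n_holes honeycomb holes injected per affected nucleus (at least 2).
#' @param capping_arc_deg angular size of the Lamin B1 signal-free arc.
#' @param myotube_fraction fraction of nuclei placed inside multinucleated
#'   marker-positive tubes.
#' @param noise `NULL` for noise-free output, or a list with
#'   `poisson_gain` (photon gain; Poisson shot noise) and `gaussian_sd_frac`
#'   (read noise sd as a fraction of the dynamic range).
#' @param seed integer RNG seed; generation is deterministic given
#'   (spec, seed).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_nuclei = 30L,
                         field_size = c(900L, 900L),
                         pixel_size_um = 0.2,
                         z_step_um = NULL,
                         shape_mix = c(normal = 1),
                         base_axes_um = c(16, 11),
                         axes_jitter = 0.08,
                         elongated_length_um = c(27, 34),
                         elongated_minor_um = 9,
                         z_semi_axis_um = 3.5,
                         rim_ratio = 2,
                         rim_width_um = 1.0,
                         nucleoplasm_level = 120,
                         dna_level = 160,
                         background_level = 5,
                         misloc_fractions = c(honeycomb = 0, foci = 0,
                                              capping = 0, emerin_foci = 0),
                         n_foci = 2L,
                         n_holes = 4L,
                         capping_arc_deg = 60,
                         myotube_fraction = 0,
                         noise = list(poisson_gain = 1, gaussian_sd_frac = 0.02),
                         seed = 1L) {
  stopifnot(n_nuclei >= 0, pixel_size_um > 0,
            length(field_size) %in% c(2L, 3L),
            length(base_axes_um) == 2L, all(base_axes_um > 0),
            base_axes_um[1] >= base_axes_um[2],
            rim_ratio >= 0, rim_width_um > 0,
            myotube_fraction >= 0, myotube_fraction <= 1)
  if (length(field_size) == 3L && is.null(z_step_um))
    stop("z_step_um is required for a 3D field")
  elongated_length_um <- rep_len(elongated_length_um, 2L)
  if (is.null(names(shape_mix)) || any(!nzchar(names(shape_mix))))
    stop("shape_mix must be a named probability vector")
  if (abs(sum(shape_mix) - 1) > 1e-9)
    stop("shape_mix probabilities must sum to 1")
  sets <- lapply(names(shape_mix), parse_label_set)  # validates names
  has_elong <- any(vapply(sets, function(s) "elongated" %in% s, logical(1)))
  if (has_elong && min(elongated_length_um) <= 25)
    stop("elongated_length_um must lie strictly above 25 um")
  if (base_axes_um[1] * (1 + axes_jitter) > 25)
    stop("base major axis (with jitter) must stay at or below 25 um")
  mf <- c(honeycomb = 0, foci = 0, capping = 0, emerin_foci = 0)
  mf[names(misloc_fractions)] <- misloc_fractions
  if (any(mf < 0 | mf > 1)) stop("misloc_fractions must be in [0, 1]")
  if (!is.null(noise))
    stopifnot(is.list(noise), noise$poisson_gain > 0,
              noise$gaussian_sd_frac >= 0)
  structure(list(
    n_nuclei = as.integer(n_nuclei), field_size = as.integer(field_size),
    pixel_size_um = pixel_size_um, z_step_um = z_step_um,
    shape_mix = shape_mix, base_axes_um = base_axes_um,
    axes_jitter = axes_jitter, elongated_length_um = elongated_length_um,
    elongated_minor_um = elongated_minor_um, z_semi_axis_um = z_semi_axis_um,
    rim_ratio = rim_ratio, rim_width_um = rim_width_um,
    nucleoplasm_level = nucleoplasm_level, dna_level = dna_level,
    background_level = background_level, misloc_fractions = mf,
    n_foci = as.integer(n_foci), n_holes = as.integer(n_holes),
    capping_arc_deg = capping_arc_deg, myotube_fraction = myotube_fraction,
    noise = noise, seed = as.integer(seed)), class = "phantom_spec")
}

#' Draw shape-label sets from the mix
#'
#' Uses an explicit inverse-CDF draw (`runif` + `findInterval`) so that the
#' sampling is replayable by an independent implementation consuming the
#' same uniform stream.
#' @param shape_mix named probability vector.
#' @param n number of draws.
#' @return character vector of label-set strings.
#' @keywords internal
draw_shape_labels <- function(shape_mix, n) {
  u <- runif(n)
  names(shape_mix)[findInterval(u, cumsum(shape_mix), left.open = TRUE) + 1L]
}

#' @export
print.phantom_spec <- function(x, ...) {
  dim_str <- paste(x$field_size, collapse = " x ")
  cat(sprintf("phantom_spec: %d nuclei in a %s px field (%.3g um/px)\n",
              x$n_nuclei, dim_str, x$pixel_size_um))
  cat("  shape mix:",
      paste(sprintf("%s=%.3g", names(x$shape_mix), x$shape_mix),
            collapse = ", "), "\n")
  cat(sprintf("  rim ratio %.3g (rim %.3g um), myotube fraction %.3g, %s\n",
              x$rim_ratio, x$rim_width_um, x$myotube_fraction,
              if (is.null(x$noise)) "noise-free" else "Poisson+Gaussian noise"))
  invisible(x)
}
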