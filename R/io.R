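## Field-level I/O and the end-to-end pipeline driver. Fields travel as
## multi-page TIFF (pages = channels, channel-major x z for stacks) with a
## JSON payload in ImageDescription recording the channel-role map, pixel
## size and z spacing; per-nucleus results travel as CSV and lengths are
## always serialized in um, never pixels.

#' Write an image field to TIFF
#'
#' @param field an [image_field()].
#' @param path output TIFF path.
#' @param bits bits per sample (default 16).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, bits = 16L) {
  stopifnot(inherits(field, "image_field"))
  d <- dim(field$channels[[1L]])
  pages <- list()
  for (ch in field$channels) {
    if (length(d) == 2L) pages <- c(pages, list(ch))
    else pages <- c(pages, lapply(seq_len(d[3L]), function(k) ch[, , k]))
  }
  meta <- list(nucmorph = as.character(utils::packageVersion("nucmorph")),
               channels = names(field$channels), dims = d,
               pixel_size_um = field$pixel_size_um,
               z_step_um = field$z_step_um, field_id = field$field_id)
  write_tiff(pages, path, bits = bits,
             description = jsonlite::toJSON(meta, auto_unbox = TRUE,
                                            null = "null", digits = NA),
             pixel_size_um = field$pixel_size_um)
  invisible(path)
}

#' Read an image field from TIFF
#'
#' Channel roles and calibration come from the embedded JSON metadata when
#' present; otherwise from `config` (channel names, in page order) and the
#' TIFF resolution tags. A `config` pixel size always wins, with a warning
#' when it conflicts with the file metadata.
#'
#' @param path TIFF file.
#' @param config optional list with `channels` (character vector of channel
#'   roles in page order), `pixel_size_um`, `z_step_um`, `n_planes`.
#' @return an [image_field()].
#' @export
read_field <- function(path, config = list()) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  tf <- read_tiff(path)
  meta <- NULL
  if (!is.null(tf$description))
    meta <- tryCatch(jsonlite::fromJSON(tf$description),
                     error = function(e) NULL)
  px <- config$pixel_size_um
  file_px <- if (!is.null(meta$pixel_size_um)) meta$pixel_size_um
  else tf$pixel_size_um
  if (is.null(px)) px <- file_px
  else if (!is.null(file_px) && abs(px - file_px) / file_px > 1e-3)
    warning(sprintf(
      "config pixel size (%.4g um) overrides file metadata (%.4g um)",
      px, file_px))
  if (is.null(px))
    stop("pixel size unavailable: not in file metadata and not in config")

  ch_names <- config$channels
  dims <- NULL
  if (!is.null(meta$channels)) {
    if (is.null(ch_names)) ch_names <- meta$channels
    dims <- meta$dims
  }
  n_pages <- length(tf$pages)
  if (is.null(ch_names)) ch_names <- if (n_pages == 1L) "dna"
  else paste0("ch", seq_len(n_pages))
  n_ch <- length(ch_names)
  n_planes <- if (!is.null(dims) && length(dims) == 3L) dims[3L]
  else if (!is.null(config$n_planes)) config$n_planes
  else if (n_pages %% n_ch == 0L) n_pages %/% n_ch else 1L
  if (n_ch * n_planes != n_pages)
    stop(sprintf("page count (%d) does not match %d channel(s) x %d plane(s)",
                 n_pages, n_ch, n_planes))
  zs <- config$z_step_um
  if (is.null(zs) && !is.null(meta$z_step_um)) zs <- meta$z_step_um

  chans <- list()
  for (c_i in seq_len(n_ch)) {
    if (n_planes == 1L) {
      chans[[ch_names[c_i]]] <- tf$pages[[c_i]]
    } else {
      first <- (c_i - 1L) * n_planes
      d2 <- dim(tf$pages[[1L]])
      arr <- array(0, c(d2, n_planes))
      for (k in seq_len(n_planes)) arr[, , k] <- tf$pages[[first + k]]
      chans[[ch_names[c_i]]] <- arr
    }
  }
  if (!"dna" %in% names(chans))
    stop("mandatory 'dna' channel missing; provide config$channels")
  image_field(chans, pixel_size_um = px, z_step_um = zs,
              field_id = if (!is.null(meta$field_id)) meta$field_id else
                tools::file_path_sans_ext(basename(path)))
}

#' Write phantom ground truth alongside a simulated field
#' @param truth the `truth` element of [generate_field()].
#' @param spec the [phantom_spec()] used.
#' @param dir output directory.
#' @param stem file stem (default "phantom").
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, spec, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_csv <- file.path(dir, paste0(stem, "_truth.csv"))
  write.csv(truth$nuclei, p_csv, row.names = FALSE)
  p_json <- file.path(dir, paste0(stem, "_spec.json"))
  sp <- unclass(spec)
  sp$shape_mix <- as.list(sp$shape_mix)
  sp$misloc_fractions <- as.list(sp$misloc_fractions)
  jsonlite::write_json(sp, p_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(p_csv, p_json))
}

#' Run the full analysis pipeline
#'
#' Segments every input field, classifies shapes, scores localization,
#' assigns myotube context, aggregates per repeat and - when the design
#' allows - runs the group comparisons, writing the per-nucleus CSV and the
#' report files.
#'
#' @param config list with:
#'   * `inputs`: data frame with columns `path` (TIFF) or `field`
#'     (in-memory [image_field()] in a list-column), plus `line`,
#'     `condition`, `repeat_id` and optionally `field_id`;
#'   * `out_dir`: output directory;
#'   * optional `read`: config passed to [read_field()];
#'   * optional `classifier`: a [classifier_config()];
#'   * optional `localization`: a [localization_config()];
#'   * optional `myotube`: list of [assign_myonuclei()] arguments;
#'   * optional `design`, `metrics` for [compare_groups()].
#' @return list with `per_nucleus`, `summaries`, `comparisons`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$inputs), !is.null(config$out_dir))
  inputs <- config$inputs
  if (nrow(inputs) == 0L) stop("no input fields in config$inputs")
  ccfg <- config$classifier %||% classifier_config()
  lcfg <- config$localization %||% localization_config()

  tabs <- vector("list", nrow(inputs))
  for (i in seq_len(nrow(inputs))) {
    field <- if ("field" %in% names(inputs)) inputs$field[[i]]
    else read_field(inputs$path[i], config$read %||% list())
    fid <- if ("field_id" %in% names(inputs)) inputs$field_id[i]
    else field$field_id %||% paste0("field", i)
    is3d <- length(dim(field$channels[[1L]])) == 3L
    masks <- if (is3d) segment_nuclei_3d(field) else segment_nuclei_2d(field)
    tab <- classify_nuclei(masks, ccfg, field_id = fid)
    loc <- localize_nuclei(field, masks, lcfg)
    tab <- cbind(tab, loc[, setdiff(names(loc), "label_id"), drop = FALSE])
    if ("marker" %in% names(field$channels)) {
      structures <- segment_myotubes(field)
      args <- config$myotube %||% list()
      asg <- do.call(assign_myonuclei,
                     c(list(masks = masks, structures = structures,
                            marker = get_channel(field, "marker")), args))
      tab$in_myotube <- asg$in_myotube
      tab$structure_id <- asg$structure_id
    } else {
      tab$in_myotube <- FALSE
      tab$structure_id <- NA_integer_
    }
    for (col in c("line", "condition", "repeat_id"))
      if (col %in% names(inputs)) tab[[col]] <- inputs[[col]][i]
    tabs[[i]] <- tab
  }
  per_nucleus <- do.call(rbind, tabs)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p_nuc <- file.path(config$out_dir, "per_nucleus.csv")
  write.csv(per_nucleus, p_nuc, row.names = FALSE)

  summaries <- NULL
  comparisons <- list()
  grouping <- intersect(c("line", "condition", "repeat_id"),
                        names(per_nucleus))
  if (length(grouping)) {
    summaries <- summarize_repeat(per_nucleus, grouping)
    write.csv(summaries, file.path(config$out_dir, "repeat_summaries.csv"),
              row.names = FALSE)
    metrics <- config$metrics %||% "mean_contour_ratio"
    design <- config$design %||%
      if ("condition" %in% grouping &&
          length(unique(summaries$condition)) > 1L) "two_way" else "one_way"
    can_compare <- "line" %in% grouping &&
      length(unique(summaries$line)) >= 2L &&
      min(table(summaries$line)) >= 2L
    if (can_compare)
      for (m in intersect(metrics, names(summaries)))
        comparisons[[m]] <- compare_groups(summaries, m, design = design)
  }
  paths <- render_report(per_nucleus, summaries, comparisons, config$out_dir)
  list(per_nucleus = per_nucleus, summaries = summaries,
       comparisons = comparisons, paths = c(p_nuc, paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
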