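#' Multi-channel image container
#'
#' A `channel_stack` holds co-registered 2D fluorescence channels keyed by
#' their biological role together with the pixel size. Recognised roles are
#' `membrane_marker` (e.g. SGCA immunostain or DiD dye), `target` (the protein
#' of interest, or the reconstituted Venus reporter), `nucleus` (DAPI or
#' Hoechst) and `transfection_control` (e.g. mRFP); reporter channels may use
#' free-form names such as `popdc1`/`popdc2`. Any subset of roles is allowed.
#'
#' @param channels named list of numeric matrices, all of identical dimension,
#'   with non-negative intensities in arbitrary units.
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @param image_id identifier carried into per-object records.
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = 1, image_id = "image") {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("'channels' must be a non-empty named list of matrices", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1)))) {
    stop("every channel must be a numeric matrix", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 image_id = as.character(image_id)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack '%s'> %d x %d px (%.3g um/px)\n",
              x$image_id, d[1], d[2], x$pixel_size_um))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

get_channel <- function(stack, role) {
  ch <- stack$channels[[role]]
  if (is.null(ch)) {
    stop(sprintf("channel role '%s' not present in stack '%s'",
                 role, stack$image_id), call. = FALSE)
  }
  ch
}

has_channel <- function(stack, role) !is.null(stack$channels[[role]])

#' Write a channel stack as a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit page per channel; intensities are quantized as
#' `round(pmax(pmin(x / scale, 1), 0) * 65535)`. The sidecar
#' (`<file>.json`) records the channel role for each page, the pixel size and
#' the quantization scale so [read_channel_stack()] round-trips the object.
#'
#' @param stack a [channel_stack()].
#' @param file output TIFF path.
#' @param scale intensity corresponding to the 16-bit full scale.
#' @return `file`, invisibly.
#' @export
write_channel_stack <- function(stack, file, scale = NULL) {
  if (is.null(scale)) {
    scale <- max(1, max(vapply(stack$channels, max, numeric(1))))
  }
  pages <- lapply(stack$channels, function(m) {
    round(pmax(pmin(m / scale, 1), 0) * 65535) / 65535
  })
  tiff::writeTIFF(pages, file, bits.per.sample = 16L, compression = "none")
  meta <- list(image_id = stack$image_id,
               pixel_size_um = stack$pixel_size_um,
               scale = scale,
               channels = as.list(names(stack$channels)))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a channel stack written by [write_channel_stack()]
#'
#' @param file TIFF path (expects `<file>.json` sidecar alongside).
#' @return a [channel_stack()].
#' @export
read_channel_stack <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file, all = TRUE)
  if (length(pages) != length(meta$channels)) {
    stop("TIFF page count does not match sidecar channel map", call. = FALSE)
  }
  channels <- lapply(pages, function(p) p * meta$scale)
  names(channels) <- meta$channels
  channel_stack(channels, pixel_size_um = meta$pixel_size_um,
                image_id = meta$image_id)
}

#' Read a channel-role map from a YAML or JSON configuration file
#'
#' The file maps channel roles to 1-based page indices and gives the pixel
#' size, e.g. `{"pixel_size_um": 0.5, "channels": {"membrane_marker": 1,
#' "target": 2}}`.
#'
#' @param path configuration file (`.yml`/`.yaml`/`.json`).
#' @return list with elements `channels` (named integer vector) and
#'   `pixel_size_um`.
#' @export
read_channel_map <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  idx <- unlist(cfg$channels)
  if (is.null(idx) || anyDuplicated(idx)) {
    stop("channel map must assign a unique page index to every role", call. = FALSE)
  }
  list(channels = idx, pixel_size_um = cfg$pixel_size_um %||% 1)
}

#' Assemble a channel stack from a plain multi-page TIFF plus a channel map
#'
#' @param file multi-page TIFF.
#' @param channel_map result of [read_channel_map()] or an equivalent list.
#' @param image_id identifier; defaults to the file name.
#' @param scale intensity corresponding to TIFF full scale (applied to the
#'   `[0, 1]` values returned by the reader).
#' @return a [channel_stack()].
#' @export
read_tiff_stack <- function(file, channel_map, image_id = basename(file),
                            scale = 65535) {
  pages <- tiff::readTIFF(file, all = TRUE)
  idx <- channel_map$channels
  if (any(idx < 1 | idx > length(pages))) {
    stop("channel map indexes pages missing from the TIFF", call. = FALSE)
  }
  channels <- lapply(idx, function(i) pages[[i]] * scale)
  names(channels) <- names(idx)
  channel_stack(channels, pixel_size_um = channel_map$pixel_size_um,
                image_id = image_id)
}
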