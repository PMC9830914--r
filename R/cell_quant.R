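#' Subtract background fluorescence from every channel
#'
#' The background of each channel is estimated as the median intensity over
#' pixels outside all supplied cell masks; when no mask pixels (or no masks)
#' are available the 5th percentile of the whole channel is used instead,
#' with a warning. The estimate is subtracted and intensities floored at 0.
#'
#' @param stack a [channel_stack()].
#' @param cell_masks optional logical or label matrix marking cell pixels.
#' @return the background-subtracted [channel_stack()]; per-channel estimates
#'   are stored in attribute `background`.
#' @export
subtract_background <- function(stack, cell_masks = NULL) {
  outside <- NULL
  if (!is.null(cell_masks)) outside <- !(cell_masks > 0)
  if (is.null(outside) || !any(outside)) {
    if (!is.null(cell_masks)) warning("no pixels outside cell masks; falling back to 5th percentile")
    bg <- vapply(stack$channels, function(ch) unname(stats::quantile(ch, 0.05)), numeric(1))
  } else {
    bg <- vapply(stack$channels, function(ch) stats::median(ch[outside]), numeric(1))
  }
  stack$channels <- Map(function(ch, b) pmax(ch - b, 0), stack$channels, bg)
  attr(stack, "background") <- bg
  stack
}

# rasterize a closed polygon boundary onto the pixel grid (rows y, cols x)
rasterize_polygon <- function(poly, h, w) {
  ys <- poly[, 1]; xs <- poly[, 2]
  n <- nrow(poly)
  pts_y <- pts_x <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    steps <- max(2, ceiling(2 * sqrt((ys[j] - ys[i])^2 + (xs[j] - xs[i])^2)))
    tt <- seq(0, 1, length.out = steps)
    pts_y <- c(pts_y, ys[i] + tt * (ys[j] - ys[i]))
    pts_x <- c(pts_x, xs[i] + tt * (xs[j] - xs[i]))
  }
  py <- pmin(pmax(round(pts_y), 1), h)
  px <- pmin(pmax(round(pts_x), 1), w)
  unique(cbind(py, px))
}

dilate_pixels <- function(pix, radius, h, w) {
  off <- disk_offsets(radius^2)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(off))) {
    yy <- pix[, 1] + off$dy[i]; xx <- pix[, 2] + off$dx[i]
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    out[cbind(yy[ok], xx[ok])] <- TRUE
  }
  out
}

# interior of a closed pixel curve by flood fill from the seed point
# (EBImage's first image dimension corresponds to matrix rows, hence x = row)
fill_inside <- function(curve_mask, seed_y, seed_x) {
  img <- EBImage::Image(curve_mask * 1)
  if (curve_mask[seed_y, seed_x]) stop("flood seed lies on the boundary", call. = FALSE)
  filled <- EBImage::floodFill(img, data.frame(x = seed_y, y = seed_x), col = 2)
  inside <- EBImage::imageData(filled) == 2
  if (inside[1, 1] || inside[nrow(inside), ncol(inside)]) {
    stop("boundary polygon does not close: flood fill escaped to the frame", call. = FALSE)
  }
  inside
}

#' Segment one cell into membrane and cytoplasm compartments
#'
#' With an operator-supplied closed boundary polygon (the faithful path,
#' mirroring manual outlining on the membrane-dye channel), the plasma
#' membrane mask is the rasterized boundary dilated by `band_px`; the
#' cytoplasm is the enclosed area minus the membrane band (plus a small guard
#' margin) and minus the thresholded nucleus. Without a polygon, the
#' membrane-dye channel is thresholded (Otsu) to extract the membrane ring
#' automatically and the enclosed area is recovered by hole filling.
#'
#' @param stack a [channel_stack()] (roles `membrane_marker`, optionally
#'   `nucleus`).
#' @param roi_polygon optional closed polygon, matrix with columns `(y, x)`
#'   in 0-based or 1-based pixel coordinates (values are rounded onto the
#'   grid).
#' @param band_px dilation radius of the membrane band (default 1 px).
#' @param cyto_margin_px guard margin excluded between membrane band and
#'   cytoplasm (default 1 px).
#' @return list with logical `membrane_mask`, `cytoplasm_mask`,
#'   `nucleus_mask` and a `flag` (`""`, or `"empty_cytoplasm"` when the
#'   nucleus covers the whole enclosed area).
#' @export
segment_cell <- function(stack, roi_polygon = NULL, band_px = 1L,
                         cyto_margin_px = 1L) {
  h <- nrow(stack$channels[[1]]); w <- ncol(stack$channels[[1]])
  if (!is.null(roi_polygon)) {
    curve <- rasterize_polygon(roi_polygon, h, w)
    membrane <- dilate_pixels(curve, band_px, h, w)
    curve_mask <- matrix(FALSE, h, w); curve_mask[curve] <- TRUE
    seed <- c(round(mean(roi_polygon[, 1])), round(mean(roi_polygon[, 2])))
    inside <- fill_inside(curve_mask, seed[1], seed[2])
    guard <- dilate_pixels(curve, band_px + cyto_margin_px, h, w)
    cyto <- inside & !guard & !curve_mask
  } else {
    did <- get_channel(stack, "membrane_marker")
    mx <- max(did)
    thr <- if (mx <= 0) Inf else EBImage::otsu(EBImage::Image(did / mx), range = c(0, 1)) * mx
    membrane <- did > thr
    filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(membrane * 1))) > 0
    cyto <- filled & !membrane
  }
  nucleus <- matrix(FALSE, h, w)
  if (has_channel(stack, "nucleus")) {
    nuc <- get_channel(stack, "nucleus")
    mx <- max(nuc)
    if (mx > 0) {
      thr <- EBImage::otsu(EBImage::Image(nuc / mx), range = c(0, 1)) * mx
      nucleus <- nuc > thr
    }
    cyto <- cyto & !nucleus
  }
  flag <- if (!any(cyto)) "empty_cytoplasm" else ""
  if (flag != "") warning("cytoplasm mask is empty for this cell")
  list(membrane_mask = membrane, cytoplasm_mask = cyto,
       nucleus_mask = nucleus, flag = flag)
}

#' Quantify reporter localization in one cell
#'
#' Mean intensity of every reporter channel over the membrane and cytoplasm
#' masks, and the plasma-membrane localization ratio
#' (membrane mean / cytoplasm mean) per reporter.
#'
#' @param stack a [channel_stack()] (reporter channels = all channels other
#'   than `membrane_marker`, `nucleus`, `transfection_control`).
#' @param masks result of [segment_cell()].
#' @param cell_id identifier for the record.
#' @return one-row data frame of class `cell_record` with columns
#'   `membrane_mean_<rep>`, `cytoplasm_mean_<rep>`, `ratio_<rep>`, `flag`.
#' @export
quantify_cell <- function(stack, masks, cell_id = 1L) {
  reporters <- setdiff(names(stack$channels),
                       c("membrane_marker", "nucleus", "transfection_control"))
  if (length(reporters) == 0L) stop("no reporter channels present", call. = FALSE)
  flag <- masks$flag
  if (!any(masks$membrane_mask)) flag <- "empty_membrane"
  out <- data.frame(image_id = stack$image_id, cell_id = cell_id)
  for (r in reporters) {
    ch <- stack$channels[[r]]
    mm <- if (any(masks$membrane_mask)) mean(ch[masks$membrane_mask]) else NA_real_
    cm <- if (any(masks$cytoplasm_mask)) mean(ch[masks$cytoplasm_mask]) else NA_real_
    out[[paste0("membrane_mean_", r)]] <- mm
    out[[paste0("cytoplasm_mean_", r)]] <- cm
    out[[paste0("ratio_", r)]] <- if (is.na(cm) || cm <= 0) NA_real_ else mm / cm
  }
  out$flag <- flag
  class(out) <- c("cell_record", "data.frame")
  out
}

#' Quantify every cell of a synthetic or ROI-annotated field
#'
#' Convenience wrapper: subtracts background (using the union of ROIs as the
#' cell region), then segments and quantifies each supplied ROI polygon.
#'
#' @param stack a [channel_stack()].
#' @param rois list of closed boundary polygons (matrices `(y, x)`).
#' @param band_px,cyto_margin_px see [segment_cell()].
#' @return data frame with one row per cell.
#' @export
quantify_cell_field <- function(stack, rois, band_px = 1L, cyto_margin_px = 1L) {
  h <- nrow(stack$channels[[1]]); w <- ncol(stack$channels[[1]])
  allcells <- matrix(FALSE, h, w)
  for (p in rois) {
    curve <- rasterize_polygon(p, h, w)
    cm <- matrix(FALSE, h, w); cm[curve] <- TRUE
    allcells <- allcells | dilate_pixels(curve, band_px, h, w) |
      fill_inside(cm, round(mean(p[, 1])), round(mean(p[, 2])))
  }
  stack <- subtract_background(stack, allcells)
  rows <- lapply(seq_along(rois), function(k) {
    m <- segment_cell(stack, rois[[k]], band_px = band_px,
                      cyto_margin_px = cyto_margin_px)
    quantify_cell(stack, m, cell_id = k)
  })
  do.call(rbind, rows)
}
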