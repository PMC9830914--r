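#' Segmentation configuration for muscle-fiber images
#'
#' @param threshold_method `"otsu"` (default) thresholds the membrane-marker
#'   channel automatically; `"fixed"` uses `fixed_threshold`.
#' @param fixed_threshold threshold in the channel's intensity units
#'   (required when `threshold_method = "fixed"`).
#' @param min_fiber_area_um2 connected components smaller than this are
#'   discarded.
#' @param exclude_border drop fibers touching the image frame.
#' @param dilation_radius_px disk radius used to dilate fiber outlines into
#'   the sarcolemma ring compartment.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_fiber_area_um2 = 100,
                                exclude_border = FALSE,
                                dilation_radius_px = 3L) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold required when threshold_method = 'fixed'", call. = FALSE)
  }
  if (dilation_radius_px < 1) stop("dilation_radius_px must be >= 1", call. = FALSE)
  if (min_fiber_area_um2 < 0) stop("min_fiber_area_um2 must be >= 0", call. = FALSE)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_fiber_area_um2 = min_fiber_area_um2,
                 exclude_border = isTRUE(exclude_border),
                 dilation_radius_px = as.integer(dilation_radius_px)),
            class = "segmentation_config")
}

#' Segment muscle fiber interiors from the membrane-marker channel
#'
#' Thresholds the membrane-marker channel (Otsu by default); fiber interiors
#' are the connected components of the sub-threshold region. Components
#' smaller than `min_fiber_area_um2`, and border-touching components when
#' `exclude_border`, are removed; surviving labels are renumbered `1..K`.
#'
#' @param stack a [channel_stack()] with a `membrane_marker` channel.
#' @param cfg a [segmentation_config()].
#' @return integer label matrix (0 = background/sarcolemma network), with the
#'   threshold used stored in attribute `threshold`.
#' @export
segment_fibers <- function(stack, cfg = segmentation_config()) {
  marker <- get_channel(stack, "membrane_marker")
  thr <- switch(cfg$threshold_method,
    otsu = {
      mx <- max(marker)
      if (mx <= 0) 0 else EBImage::otsu(EBImage::Image(marker / mx), range = c(0, 1)) * mx
    },
    fixed = cfg$fixed_threshold)
  sub <- marker < thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(sub * 1)))
  storage.mode(lab) <- "integer"
  if (max(lab) == 0L) {
    warning("no fiber interiors found (all pixels above threshold)")
    return(structure(matrix(0L, nrow(marker), ncol(marker)), threshold = thr))
  }
  min_px <- cfg$min_fiber_area_um2 / stack$pixel_size_um^2
  sz <- tabulate(lab, nbins = max(lab))
  drop <- which(sz < min_px)
  if (cfg$exclude_border) {
    h <- nrow(lab); w <- ncol(lab)
    border_labels <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
    drop <- union(drop, border_labels[border_labels > 0L])
  }
  keep <- setdiff(seq_len(max(lab)), drop)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  if (max(lab) == 0L) warning("all fiber candidates removed by size/border filters")
  structure(lab, threshold = thr)
}

# outline = interior pixels with a 4-neighbour outside the fiber
# (out-of-image counts as outside)
fiber_outline_idx <- function(member, h, w) {
  idx <- which(member)
  ys <- (idx - 1L) %% h + 1L
  xs <- (idx - 1L) %/% h + 1L
  nb_out <- (ys == 1L) | (ys == h) | (xs == 1L) | (xs == w)
  look <- function(dy, dx) {
    yy <- pmin(pmax(ys + dy, 1L), h)
    xx <- pmin(pmax(xs + dx, 1L), w)
    !member[cbind(yy, xx)]
  }
  nb_out <- nb_out | look(-1L, 0L) | look(1L, 0L) | look(0L, -1L) | look(0L, 1L)
  idx[nb_out]
}

#' Per-fiber sarcolemma-ring and cytoplasm masks
#'
#' For each fiber the outline (boundary pixels of its interior) is dilated by
#' a Euclidean disk of radius `dilation_radius_px`; the resulting ring claims
#' pixels by exact squared distance, and a pixel within reach of several
#' fibers' outlines is assigned to the nearest one (ties to the lower fiber
#' id). The cytoplasm mask is the fiber interior minus every ring, so rings
#' and interiors are disjoint within and across fibers.
#'
#' @param labels integer label matrix from [segment_fibers()].
#' @param dilation_radius_px disk radius in pixels.
#' @return list with `ring` and `interior` (integer label matrices aligned
#'   with `labels`) and `skipped` (ids of fibers whose cytoplasm vanished;
#'   these are dropped from both matrices).
#' @export
compartment_masks <- function(labels, dilation_radius_px = 3L) {
  h <- nrow(labels); w <- ncol(labels)
  K <- max(labels)
  r2max <- dilation_radius_px^2
  off <- disk_offsets(r2max)
  best_d2 <- matrix(Inf, h, w)
  owner <- matrix(0L, h, w)
  for (k in seq_len(K)) {
    ol <- fiber_outline_idx(labels == k, h, w)
    if (length(ol) == 0L) next
    ys <- (ol - 1L) %% h + 1L
    xs <- (ol - 1L) %/% h + 1L
    y0 <- max(1L, min(ys) - dilation_radius_px); y1 <- min(h, max(ys) + dilation_radius_px)
    x0 <- max(1L, min(xs) - dilation_radius_px); x1 <- min(w, max(xs) + dilation_radius_px)
    lh <- y1 - y0 + 1L; lw <- x1 - x0 + 1L
    d2 <- matrix(Inf, lh, lw)
    for (i in seq_len(nrow(off))) {
      yy <- ys + off$dy[i]; xx <- xs + off$dx[i]
      ok <- yy >= y0 & yy <= y1 & xx >= x0 & xx <= x1
      if (!any(ok)) next
      lin <- cbind(yy[ok] - y0 + 1L, xx[ok] - x0 + 1L)
      d2[lin] <- pmin(d2[lin], off$d2[i])
    }
    cand <- which(is.finite(d2))
    if (length(cand) == 0L) next
    gy <- (cand - 1L) %% lh + y0
    gx <- (cand - 1L) %/% lh + x0
    gidx <- cbind(gy, gx)
    upd <- d2[cand] < best_d2[gidx]   # strict: ties stay with the lower id
    if (any(upd)) {
      best_d2[gidx[upd, , drop = FALSE]] <- d2[cand][upd]
      owner[gidx[upd, , drop = FALSE]] <- k
    }
  }
  interior <- labels
  interior[owner > 0L] <- 0L
  skipped <- setdiff(seq_len(K), unique(interior[interior > 0L]))
  if (length(skipped)) {
    message(sprintf("compartment_masks: %d fiber(s) skipped (cytoplasm emptied by ring): %s",
                    length(skipped), paste(skipped, collapse = ", ")))
    owner[owner %in% skipped] <- 0L
    interior[interior %in% skipped] <- 0L
  }
  list(ring = owner, interior = interior, labels = labels, skipped = skipped)
}

#' Quantify per-fiber compartment intensities and morphology
#'
#' For every fiber, the mean intensity of each channel over the sarcolemma
#' ring and the cytoplasm, the fiber cross-sectional area (the full
#' segmented interior, before ring subtraction), the
#' marker-normalized sarcolemmal signal (`target` ring mean divided by
#' `membrane_marker` ring mean) and the sarcolemma/cytoplasm enrichment of
#' the target are recorded.
#'
#' @param stack a [channel_stack()].
#' @param masks result of [compartment_masks()].
#' @return data frame of class `fiber_records` with one row per fiber
#'   (columns `image_id`, `fiber_id`, `area_um2`, `ring_mean_<role>`,
#'   `interior_mean_<role>`, `sgca_norm_sarcolemma`, `enrichment`, `flag`).
#'   Fibers whose marker ring mean is zero carry `NA` ratios and
#'   `flag = "undefined_ratio"`; callers exclude flagged rows from summaries.
#' @export
quantify_fibers <- function(stack, masks) {
  K <- max(masks$ring, masks$interior)
  roles <- names(stack$channels)
  ring_means <- interior_means <- matrix(NA_real_, K, length(roles),
                                         dimnames = list(NULL, roles))
  ring_f <- factor(masks$ring, levels = seq_len(K))
  int_f <- factor(masks$interior, levels = seq_len(K))
  for (r in roles) {
    ch <- stack$channels[[r]]
    ring_means[, r] <- tapply(ch[masks$ring > 0L], ring_f[masks$ring > 0L], mean)[seq_len(K)]
    interior_means[, r] <- tapply(ch[masks$interior > 0L], int_f[masks$interior > 0L], mean)[seq_len(K)]
  }
  area_src <- if (!is.null(masks$labels)) masks$labels else masks$interior
  area_px <- tabulate(area_src[area_src > 0L], nbins = K)
  out <- data.frame(image_id = stack$image_id, fiber_id = seq_len(K),
                    area_um2 = area_px * stack$pixel_size_um^2)
  for (r in roles) out[[paste0("ring_mean_", r)]] <- ring_means[, r]
  for (r in roles) out[[paste0("interior_mean_", r)]] <- interior_means[, r]
  if (all(c("membrane_marker", "target") %in% roles)) {
    marker_ring <- ring_means[, "membrane_marker"]
    out$sgca_norm_sarcolemma <- ifelse(is.finite(marker_ring) & marker_ring > 0,
                                       ring_means[, "target"] / marker_ring, NA_real_)
  } else out$sgca_norm_sarcolemma <- NA_real_
  if ("target" %in% roles) {
    ti <- interior_means[, "target"]
    out$enrichment <- ifelse(is.finite(ti) & ti > 0,
                             ring_means[, "target"] / ti, NA_real_)
  } else out$enrichment <- NA_real_
  out$flag <- ifelse(out$fiber_id %in% masks$skipped, "skipped",
                     ifelse(is.na(out$sgca_norm_sarcolemma), "undefined_ratio", ""))
  out <- out[!(out$fiber_id %in% masks$skipped), , drop = FALSE]
  class(out) <- c("fiber_records", "data.frame")
  out
}
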