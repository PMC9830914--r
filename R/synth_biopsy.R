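#' Specification for a synthetic muscle biopsy cross-section
#'
#' Defines a seeded generator emulating a transverse immunofluorescence image
#' of skeletal muscle: border-sharing polygonal fibers whose sarcolemma forms
#' a bright ring network in the membrane-marker channel, with a target-protein
#' channel carrying per-fiber ring and interior intensities.
#'
#' Default intensities encode the strong sarcolemmal enrichment of
#' sarcolemma-resident proteins in such stains (ring:interior about 25:1,
#' faint background); the group effect acts multiplicatively on the target
#' ring intensity only, mirroring a trafficking defect that depletes the
#' membrane pool.
#'
#' @param n_fibers number of fibers to place.
#' @param field_size_px `(height, width)` in pixels; `NULL` picks a square
#'   field sized to hold `n_fibers` fibers of the requested median area.
#' @param pixel_size_um pixel edge length, micrometres.
#' @param area_lognormal `(meanlog, sdlog)` of fiber cross-sectional area in
#'   square micrometres.
#' @param ring_thickness_px half-width (in px) of the sarcolemma ring network
#'   separating fiber interiors; integer `>= 1`.
#' @param marker_ring_intensity,target_ring_intensity,target_interior_intensity
#'   noise-free intensities (arbitrary units) of the membrane marker on the
#'   ring, and of the target protein on ring and interior.
#' @param group_effect multiplicative factor applied to
#'   `target_ring_intensity` (control = 1).
#' @param intensity_cv per-fiber multiplicative lognormal heterogeneity
#'   (coefficient of variation), applied to both target compartments.
#' @param noise_sd additive Gaussian noise SD (clipped at 0).
#' @param background additive background level (a.u.).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `biopsy_spec`.
#' @export
biopsy_spec <- function(n_fibers = 150,
                        field_size_px = NULL,
                        pixel_size_um = 1,
                        area_lognormal = c(log(3000), 0.3),
                        ring_thickness_px = 3L,
                        marker_ring_intensity = 200,
                        target_ring_intensity = 200,
                        target_interior_intensity = 5,
                        group_effect = 1,
                        intensity_cv = 0.1,
                        noise_sd = 3,
                        background = 2,
                        seed = 1L) {
  stopifnot_scalar_pos(n_fibers, "n_fibers")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(group_effect, "group_effect")
  stopifnot_scalar_pos(marker_ring_intensity, "marker_ring_intensity", strict = FALSE)
  stopifnot_scalar_pos(target_ring_intensity, "target_ring_intensity", strict = FALSE)
  stopifnot_scalar_pos(target_interior_intensity, "target_interior_intensity", strict = FALSE)
  stopifnot_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  stopifnot_scalar_pos(background, "background", strict = FALSE)
  stopifnot_scalar_pos(intensity_cv, "intensity_cv", strict = FALSE)
  if (ring_thickness_px < 1) stop("ring_thickness_px must be >= 1", call. = FALSE)
  if (length(area_lognormal) != 2L || area_lognormal[2] < 0) {
    stop("area_lognormal must be (meanlog, sdlog) with sdlog >= 0", call. = FALSE)
  }
  structure(list(n_fibers = as.integer(n_fibers),
                 field_size_px = field_size_px,
                 pixel_size_um = pixel_size_um,
                 area_lognormal = area_lognormal,
                 ring_thickness_px = as.integer(ring_thickness_px),
                 marker_ring_intensity = marker_ring_intensity,
                 target_ring_intensity = target_ring_intensity,
                 target_interior_intensity = target_interior_intensity,
                 group_effect = group_effect,
                 intensity_cv = intensity_cv,
                 noise_sd = noise_sd,
                 background = background,
                 seed = as.integer(seed)),
            class = "biopsy_spec")
}

# Windowed power-diagram (Laguerre) labelling: pixel -> argmin_k (d^2 - r_k^2),
# restricted to a window around each seed for speed. Returns integer matrix.
power_partition <- function(h, w, cy, cx, r2) {
  best <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  win <- pmax(ceiling(2.2 * sqrt(pmax(r2, 1))), 8)
  for (k in seq_along(cy)) {
    y0 <- max(1L, floor(cy[k] - win[k])); y1 <- min(h, ceiling(cy[k] + win[k]))
    x0 <- max(1L, floor(cx[k] - win[k])); x1 <- min(w, ceiling(cx[k] + win[k]))
    dy2 <- ((y0:y1) - cy[k])^2
    dx2 <- ((x0:x1) - cx[k])^2
    pd <- outer(dy2, dx2, "+") - r2[k]
    sub_best <- best[y0:y1, x0:x1]
    upd <- pd < sub_best
    if (any(upd)) {
      sub_lab <- lab[y0:y1, x0:x1]
      sub_best[upd] <- pd[upd]
      sub_lab[upd] <- k
      best[y0:y1, x0:x1] <- sub_best
      lab[y0:y1, x0:x1] <- sub_lab
    }
  }
  if (any(lab == 0L)) {
    # windows missed a few pixels: assign by full power distance
    miss <- which(lab == 0L)
    ys <- (miss - 1L) %% h + 1L
    xs <- (miss - 1L) %/% h + 1L
    for (i in seq_along(miss)) {
      pd <- (ys[i] - cy)^2 + (xs[i] - cx)^2 - r2
      lab[miss[i]] <- which.min(pd)
    }
  }
  lab
}

# Pixels whose 4-neighbour carries a different label (image edge is not a
# boundary, so border cells keep interiors that touch the frame).
partition_boundary <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  b <- matrix(FALSE, h, w)
  d <- lab[-h, ] != lab[-1, ]
  b[-h, ] <- b[-h, ] | d
  b[-1, ] <- b[-1, ] | d
  d <- lab[, -w] != lab[, -1]
  b[, -w] <- b[, -w] | d
  b[, -1] <- b[, -1] | d
  b
}

# Remove label from pixels within Euclidean distance < t of the boundary set
# (exact: strips offsets with d^2 <= t^2 - 1 around boundary pixels).
erode_by_boundary <- function(lab, boundary, t) {
  h <- nrow(lab); w <- ncol(lab)
  interior <- lab
  interior[boundary] <- 0L
  if (t > 1) {
    off <- disk_offsets(t^2 - 1)
    idx <- which(boundary)
    ys <- (idx - 1L) %% h + 1L
    xs <- (idx - 1L) %/% h + 1L
    for (i in seq_len(nrow(off))) {
      if (off$d2[i] == 0) next
      yy <- ys + off$dy[i]; xx <- xs + off$dx[i]
      ok <- yy >= 1L & yy <= h & xx >= 1L & xx <= w
      interior[cbind(yy[ok], xx[ok])] <- 0L
    }
  }
  interior
}

#' Generate a synthetic biopsy image with ground truth
#'
#' Places fiber seed points by dart throwing, partitions the field by a
#' weighted nearest-seed (power diagram) rule so fibers tile without overlap
#' with areas following the requested lognormal law, and erodes each cell by
#' the ring half-width to carve the bright sarcolemma network. The membrane
#' marker is bright only on that network; the target channel carries per-fiber
#' ring/interior means (ring scaled by `group_effect`) plus background and
#' clipped Gaussian noise.
#'
#' @param spec a [biopsy_spec()].
#' @return list with elements `stack` (a [channel_stack()] with channels
#'   `membrane_marker` and `target`) and `truth` (class `biopsy_truth`:
#'   `interior_labels`, `ring_labels` matrices; per-fiber noise-free
#'   `ring_mean`/`interior_mean` per channel, areas in um^2, seeds).
#' @export
generate_biopsy <- function(spec) {
  stopifnot(inherits(spec, "biopsy_spec"))
  with_seed(spec$seed, {
    psz2 <- spec$pixel_size_um^2
    areas_um2 <- stats::rlnorm(spec$n_fibers, spec$area_lognormal[1], spec$area_lognormal[2])
    a_int_px <- areas_um2 / psz2
    t <- spec$ring_thickness_px
    # inflate targets so the post-erosion interiors land near the drawn areas
    a_cell_px <- a_int_px + 3.8 * sqrt(a_int_px) * t
    if (is.null(spec$field_size_px)) {
      side <- ceiling(sqrt(sum(a_cell_px) * 1.05))
      fs <- c(side, side)
    } else fs <- spec$field_size_px
    h <- fs[1]; w <- fs[2]
    if (h * w < sum(a_cell_px) * 0.95) {
      stop(sprintf("field %dx%d px too small for %d fibers of the requested area",
                   h, w, spec$n_fibers), call. = FALSE)
    }
    rad <- sqrt(a_cell_px / pi)
    ord <- order(rad, decreasing = TRUE)   # place big fibers first
    cy <- cx <- numeric(spec$n_fibers)
    placed <- integer(0)
    for (k in ord) {
      ok <- FALSE
      for (try in seq_len(400)) {
        py <- stats::runif(1, 1, h); px <- stats::runif(1, 1, w)
        if (length(placed) == 0 ||
            all((py - cy[placed])^2 + (px - cx[placed])^2 >=
                (0.7 * (rad[k] + rad[placed]))^2)) {
          cy[k] <- py; cx[k] <- px; ok <- TRUE; break
        }
      }
      if (!ok) {
        stop(sprintf("field %dx%d px too small: could not place fiber %d of %d",
                     h, w, length(placed) + 1L, spec$n_fibers), call. = FALSE)
      }
      placed <- c(placed, k)
    }
    # area-balancing iterations on the power-diagram weights
    r2 <- rad^2
    lab <- power_partition(h, w, cy, cx, r2)
    for (it in seq_len(5)) {
      sz <- tabulate(lab, nbins = spec$n_fibers)
      r2 <- pmax(r2 + 0.9 * (a_cell_px - sz) / pi, 1)
      lab <- power_partition(h, w, cy, cx, r2)
    }
    boundary <- partition_boundary(lab)
    interior <- erode_by_boundary(lab, boundary, t)

    # drop fibers whose interior vanished, renumber contiguously
    keep <- sort(unique(interior[interior > 0L]))
    remap <- integer(spec$n_fibers)
    remap[keep] <- seq_along(keep)
    interior_lab <- matrix(0L, h, w)
    nz <- interior > 0L
    interior_lab[nz] <- remap[interior[nz]]
    ring_lab <- matrix(0L, h, w)
    rz <- !nz & lab > 0L & lab %in% keep
    ring_lab[rz] <- remap[lab[rz]]
    K <- length(keep)

    fac <- rlnorm_cv1(spec$n_fibers, spec$intensity_cv)[keep]
    ring_val <- spec$background + spec$target_ring_intensity * spec$group_effect * fac
    int_val <- spec$background + spec$target_interior_intensity * fac

    marker <- matrix(spec$background, h, w)
    marker[interior_lab == 0L] <- spec$background + spec$marker_ring_intensity
    target <- matrix(spec$background, h, w)
    target[nz] <- int_val[interior_lab[nz]]
    in_ring <- ring_lab > 0L
    target[in_ring] <- ring_val[ring_lab[in_ring]]

    stack <- channel_stack(
      list(membrane_marker = matrix(add_noise(marker, spec$noise_sd), h, w),
           target = matrix(add_noise(target, spec$noise_sd), h, w)),
      pixel_size_um = spec$pixel_size_um,
      image_id = sprintf("biopsy_seed%d", spec$seed))

    truth <- structure(list(
      interior_labels = interior_lab,
      ring_labels = ring_lab,
      n_fibers = K,
      ring_mean = data.frame(fiber_id = seq_len(K),
                             membrane_marker = spec$background + spec$marker_ring_intensity,
                             target = ring_val),
      interior_mean = data.frame(fiber_id = seq_len(K),
                                 membrane_marker = spec$background,
                                 target = int_val),
      area_um2 = tabulate(interior_lab[nz], nbins = K) * psz2,
      seeds = cbind(y = cy[keep], x = cx[keep])),
      class = "biopsy_truth")
    list(stack = stack, truth = truth)
  })
}
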