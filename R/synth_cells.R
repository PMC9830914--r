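#' Specification for a synthetic transfected-cell field
#'
#' Emulates confocal images of cells carrying a lipophilic membrane dye
#' (DiD-like ring), a nuclear stain, and one or more fluorescent reporters
#' whose noise-free membrane:cytoplasm intensity ratio is set per reporter.
#'
#' @param n_cells number of cells to place.
#' @param field_size_px `(height, width)` in pixels.
#' @param cell_radius_px `(min, max)` outer cell radius range, pixels.
#' @param nucleus_radius_px nucleus radius, pixels.
#' @param membrane_ring_px width of the plasma-membrane ring, pixels (`>= 1`).
#' @param reporter_ratios named numeric vector, membrane:cytoplasm intensity
#'   ratio per reporter channel (all `> 0`).
#' @param reporter_cyto_intensity noise-free cytoplasm intensity (a.u.) of
#'   each reporter.
#' @param did_intensity membrane-dye ring intensity (a.u.).
#' @param nucleus_intensity nuclear-stain intensity (a.u.).
#' @param intensity_cv per-cell multiplicative lognormal variability of the
#'   reporter expression level.
#' @param noise_sd additive Gaussian noise SD (clipped at 0).
#' @param background additive background (a.u.).
#' @param seed integer RNG seed.
#' @return an object of class `cell_field_spec`.
#' @export
cell_field_spec <- function(n_cells = 30,
                            field_size_px = c(512, 512),
                            cell_radius_px = c(32, 44),
                            nucleus_radius_px = 13,
                            membrane_ring_px = 3L,
                            reporter_ratios = c(popdc1 = 4.5, popdc2 = 4.5),
                            reporter_cyto_intensity = 60,
                            did_intensity = 180,
                            nucleus_intensity = 150,
                            intensity_cv = 0.1,
                            noise_sd = 3,
                            background = 4,
                            seed = 1L) {
  if (membrane_ring_px < 1) stop("membrane_ring_px must be >= 1", call. = FALSE)
  if (any(reporter_ratios <= 0)) stop("reporter ratios must be > 0", call. = FALSE)
  if (is.null(names(reporter_ratios)) || any(!nzchar(names(reporter_ratios)))) {
    stop("reporter_ratios must be a named vector", call. = FALSE)
  }
  stopifnot_scalar_pos(n_cells, "n_cells")
  structure(list(n_cells = as.integer(n_cells), field_size_px = field_size_px,
                 cell_radius_px = cell_radius_px,
                 nucleus_radius_px = nucleus_radius_px,
                 membrane_ring_px = as.integer(membrane_ring_px),
                 reporter_ratios = reporter_ratios,
                 reporter_cyto_intensity = reporter_cyto_intensity,
                 did_intensity = did_intensity,
                 nucleus_intensity = nucleus_intensity,
                 intensity_cv = intensity_cv, noise_sd = noise_sd,
                 background = background, seed = as.integer(seed)),
            class = "cell_field_spec")
}

# dart-throw non-overlapping circle centres; capacity error after bounded retries
place_circles <- function(n, h, w, radii, margin = 2, tries_per = 400) {
  cy <- cx <- numeric(n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(tries_per)) {
      py <- stats::runif(1, radii[k] + margin, h - radii[k] - margin)
      px <- stats::runif(1, radii[k] + margin, w - radii[k] - margin)
      prev <- seq_len(k - 1L)
      if (k == 1L || all((py - cy[prev])^2 + (px - cx[prev])^2 >
                         (radii[k] + radii[prev] + margin)^2)) {
        cy[k] <- py; cx[k] <- px; ok <- TRUE; break
      }
    }
    if (!ok) stop(sprintf("could not place cell %d of %d without overlap; field too small",
                          k, n), call. = FALSE)
  }
  cbind(y = cy, x = cx)
}

radial_masks <- function(h, w, cy, cx) {
  function(rmin, rmax) {
    y0 <- max(1L, floor(cy - rmax)); y1 <- min(h, ceiling(cy + rmax))
    x0 <- max(1L, floor(cx - rmax)); x1 <- min(w, ceiling(cx + rmax))
    d2 <- outer(((y0:y1) - cy)^2, ((x0:x1) - cx)^2, "+")
    sel <- d2 >= rmin^2 & d2 < rmax^2
    idx <- which(sel)
    cbind((idx - 1L) %% nrow(sel) + y0, (idx - 1L) %/% nrow(sel) + x0)
  }
}

# closed polygon (n-gon) approximating the circle of given radius
circle_polygon <- function(cy, cx, r, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(y = cy + r * sin(th), x = cx + r * cos(th))
}

#' Generate a synthetic cell field with ground truth
#'
#' Each cell is a disc with a membrane ring of the configured width, a
#' central nucleus, and reporter channels whose noise-free
#' membrane:cytoplasm ratio equals `spec$reporter_ratios`. Ground truth
#' carries per-cell membrane/cytoplasm/nucleus masks, true compartment means
#' and a closed mid-membrane boundary polygon per cell (the manual-ROI
#' analysis path).
#'
#' @param spec a [cell_field_spec()].
#' @return list with `stack` (channels: `membrane_marker`, `nucleus`, one per
#'   reporter) and `truth` (class `cell_field_truth`).
#' @export
generate_cell_field <- function(spec) {
  stopifnot(inherits(spec, "cell_field_spec"))
  with_seed(spec$seed, {
    h <- spec$field_size_px[1]; w <- spec$field_size_px[2]
    radii <- stats::runif(spec$n_cells, spec$cell_radius_px[1], spec$cell_radius_px[2])
    ctr <- place_circles(spec$n_cells, h, w, radii, margin = 3)
    reps <- names(spec$reporter_ratios)
    chans <- c("membrane_marker", "nucleus", reps)
    imgs <- lapply(chans, function(.) matrix(spec$background, h, w))
    names(imgs) <- chans
    labels <- matrix(0L, h, w)
    mem_lab <- cyto_lab <- nuc_lab <- matrix(0L, h, w)
    fac <- rlnorm_cv1(spec$n_cells, spec$intensity_cv)
    truth_rows <- vector("list", spec$n_cells)
    polys <- vector("list", spec$n_cells)
    wring <- spec$membrane_ring_px
    for (k in seq_len(spec$n_cells)) {
      sel <- radial_masks(h, w, ctr[k, 1], ctr[k, 2])
      R <- radii[k]
      ring <- sel(R - wring, R)
      cyto <- sel(spec$nucleus_radius_px, R - wring)
      nuc <- sel(0, spec$nucleus_radius_px)
      body <- sel(0, R)
      labels[body] <- k
      mem_lab[ring] <- k; cyto_lab[cyto] <- k; nuc_lab[nuc] <- k
      imgs$membrane_marker[ring] <- spec$background + spec$did_intensity
      imgs$nucleus[nuc] <- spec$background + spec$nucleus_intensity
      cmeans <- mmeans <- numeric(length(reps))
      for (j in seq_along(reps)) {
        cv <- spec$reporter_cyto_intensity * fac[k]
        mv <- cv * spec$reporter_ratios[[j]]
        imgs[[reps[j]]][cyto] <- spec$background + cv
        imgs[[reps[j]]][nuc] <- spec$background + cv       # reporters fill the cell body
        imgs[[reps[j]]][ring] <- spec$background + mv
        cmeans[j] <- cv; mmeans[j] <- mv
      }
      truth_rows[[k]] <- data.frame(cell_id = k, reporter = reps,
                                    membrane_mean = spec$background + mmeans,
                                    cytoplasm_mean = spec$background + cmeans,
                                    true_ratio = unname(spec$reporter_ratios))
      polys[[k]] <- circle_polygon(ctr[k, 1], ctr[k, 2], R - wring / 2)
    }
    noisy <- lapply(imgs, function(m) matrix(add_noise(m, spec$noise_sd), h, w))
    stack <- channel_stack(noisy, pixel_size_um = 1,
                           image_id = sprintf("cells_seed%d", spec$seed))
    truth <- structure(list(labels = labels, membrane_labels = mem_lab,
                            cytoplasm_labels = cyto_lab, nucleus_labels = nuc_lab,
                            centers = ctr, radii = radii,
                            polygons = polys,
                            means = do.call(rbind, truth_rows),
                            n_cells = spec$n_cells),
                       class = "cell_field_truth")
    list(stack = stack, truth = truth)
  })
}

#' Specification for a synthetic BiFC field
#'
#' Emulates low-magnification confocal fields of 50-100 cells where a
#' transfection-control channel (mRFP-like) marks a configurable subset of
#' cells and the interaction-reporter channel (reconstituted Venus) carries
#' `efficiency` times the control intensity in transfected cells;
#' untransfected cells are dark in both.
#'
#' @param n_cells cells per field.
#' @param field_size_px `(height, width)` pixels.
#' @param cell_radius_px `(min, max)` cell radius, pixels.
#' @param nucleus_radius_px nucleus radius, pixels.
#' @param transfected_fraction fraction of cells expressing the control.
#' @param efficiency interaction-reporter intensity as a fraction of the
#'   control intensity (the complementation efficiency; wild-type pair = 1).
#' @param mrfp_intensity control-channel intensity in transfected cells.
#' @param nucleus_intensity nuclear-stain intensity.
#' @param intensity_cv per-cell lognormal expression variability.
#' @param noise_sd additive Gaussian noise SD.
#' @param background additive background.
#' @param seed integer RNG seed.
#' @return an object of class `bifc_field_spec`.
#' @export
bifc_field_spec <- function(n_cells = 80,
                            field_size_px = c(400, 400),
                            cell_radius_px = c(9, 13),
                            nucleus_radius_px = 4,
                            transfected_fraction = 1,
                            efficiency = 1,
                            mrfp_intensity = 120,
                            nucleus_intensity = 150,
                            intensity_cv = 0.1,
                            noise_sd = 3,
                            background = 4,
                            seed = 1L) {
  if (efficiency < 0) stop("efficiency must be >= 0", call. = FALSE)
  if (transfected_fraction < 0 || transfected_fraction > 1) {
    stop("transfected_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), field_size_px = field_size_px,
                 cell_radius_px = cell_radius_px,
                 nucleus_radius_px = nucleus_radius_px,
                 transfected_fraction = transfected_fraction,
                 efficiency = efficiency, mrfp_intensity = mrfp_intensity,
                 nucleus_intensity = nucleus_intensity,
                 intensity_cv = intensity_cv, noise_sd = noise_sd,
                 background = background, seed = as.integer(seed)),
            class = "bifc_field_spec")
}

#' Generate a synthetic BiFC field with ground truth
#'
#' @param spec a [bifc_field_spec()].
#' @return list with `stack` (channels `transfection_control`, `target`
#'   i.e. the interaction reporter, and `nucleus`) and `truth` (class
#'   `bifc_field_truth`: cell label matrix, transfected flags, nucleus
#'   labels, per-cell noise-free intensities).
#' @export
generate_bifc_field <- function(spec) {
  stopifnot(inherits(spec, "bifc_field_spec"))
  with_seed(spec$seed, {
    h <- spec$field_size_px[1]; w <- spec$field_size_px[2]
    radii <- stats::runif(spec$n_cells, spec$cell_radius_px[1], spec$cell_radius_px[2])
    ctr <- place_circles(spec$n_cells, h, w, radii, margin = 2)
    n_tr <- round(spec$transfected_fraction * spec$n_cells)
    transfected <- seq_len(spec$n_cells) %in% sample.int(spec$n_cells, n_tr)
    fac <- rlnorm_cv1(spec$n_cells, spec$intensity_cv)
    control <- target <- nucleus <- matrix(spec$background, h, w)
    labels <- nuc_lab <- matrix(0L, h, w)
    mrfp_true <- venus_true <- numeric(spec$n_cells)
    for (k in seq_len(spec$n_cells)) {
      sel <- radial_masks(h, w, ctr[k, 1], ctr[k, 2])
      body <- sel(0, radii[k])
      nuc <- sel(0, spec$nucleus_radius_px)
      labels[body] <- k
      nuc_lab[nuc] <- k
      nucleus[nuc] <- spec$background + spec$nucleus_intensity
      if (transfected[k]) {
        mrfp_true[k] <- spec$mrfp_intensity * fac[k]
        venus_true[k] <- spec$efficiency * mrfp_true[k]
        control[body] <- spec$background + mrfp_true[k]
        target[body] <- spec$background + venus_true[k]
      }
    }
    stack <- channel_stack(
      list(transfection_control = matrix(add_noise(control, spec$noise_sd), h, w),
           target = matrix(add_noise(target, spec$noise_sd), h, w),
           nucleus = matrix(add_noise(nucleus, spec$noise_sd), h, w)),
      pixel_size_um = 1, image_id = sprintf("bifc_seed%d", spec$seed))
    truth <- structure(list(labels = labels, nucleus_labels = nuc_lab,
                            transfected = transfected,
                            mrfp_true = spec$background + mrfp_true,
                            venus_true = spec$background + venus_true,
                            n_cells = spec$n_cells),
                       class = "bifc_field_truth")
    list(stack = stack, truth = truth)
  })
}
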