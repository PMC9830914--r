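# fiber segmentation, compartment masks and per-fiber quantification

test_that("segmentation recovers ground-truth interiors on a noise-free biopsy", {
  g <- generate_biopsy(tiny_biopsy(n_fibers = 2, seed = 21))
  lab <- segment_fibers(g$stack, segmentation_config(min_fiber_area_um2 = 50))
  expect_equal(max(lab), 2)
  tr <- g$truth
  # flood-fill oracle: each segmented fiber equals the region grown from the
  # ground-truth interior, independently of the labelling implementation
  for (k in seq_len(2)) {
    idx <- which(tr$interior_labels == k)
    seed_i <- idx[1]
    h <- nrow(lab)
    region <- flood_fill_region(tr$interior_labels == k,
                                (seed_i - 1) %% h + 1, (seed_i - 1) %/% h + 1)
    seg_label <- lab[seed_i]
    expect_gt(seg_label, 0)
    expect_identical(unname(which(lab == seg_label)), which(region))
  }
})

test_that("segmentation edge rules: uniform marker, border exclusion, missing channel", {
  st <- channel_stack(list(membrane_marker = matrix(100, 40, 40)))
  expect_warning(lab <- segment_fibers(st), "no fiber interiors")
  expect_equal(max(lab), 0)

  # a fiber clipped by the frame disappears under exclude_border
  m <- matrix(200, 60, 60)
  m[1:20, 10:30] <- 0          # touches row 1
  m[35:50, 20:40] <- 0         # interior fiber
  st2 <- channel_stack(list(membrane_marker = m))
  lab_all <- segment_fibers(st2, segmentation_config(min_fiber_area_um2 = 10))
  lab_nb <- segment_fibers(st2, segmentation_config(min_fiber_area_um2 = 10,
                                                    exclude_border = TRUE))
  expect_equal(max(lab_all), 2)
  expect_equal(max(lab_nb), 1)
  expect_true(all(lab_nb[1, ] == 0))

  expect_error(segment_fibers(channel_stack(list(target = m))), "membrane_marker")
})

test_that("compartment masks equal the brute-force Euclidean-distance oracle", {
  # disk fiber: ring = all pixels within the radius of the outline,
  # computed exhaustively
  h <- 60; w <- 60
  d2 <- outer((1:h - 30)^2, (1:w - 30)^2, "+")
  labels <- matrix(0L, h, w); labels[d2 <= 20^2] <- 1L
  m <- compartment_masks(labels, 3L)
  expect_identical(m$ring, brute_force_rings(labels, 3))
  expect_true(all(m$ring * m$interior == 0))

  # adjacent synthetic fibers: nearest-fiber contention, oracle equality
  g <- generate_biopsy(tiny_biopsy(n_fibers = 4, seed = 31))
  lab <- segment_fibers(g$stack, segmentation_config(min_fiber_area_um2 = 50))
  m2 <- compartment_masks(lab, 3L)
  expect_identical(m2$ring, brute_force_rings(lab, 3))
  # rings disjoint across fibers by construction of the ownership matrix;
  # interiors do not intersect any ring
  expect_true(all(m2$interior[m2$ring > 0] == 0))
})

test_that("a radius-1 dilation reduces the ring to the outline band", {
  labels <- matrix(0L, 20, 20); labels[5:15, 5:15] <- 1L
  m <- compartment_masks(labels, 1L)
  oracle <- brute_force_rings(labels, 1)
  expect_identical(m$ring, oracle)
})

test_that("quantification reproduces constructed intensities and ratios", {
  # uniform target of value c: ring mean = interior mean = c, enrichment 1
  labels <- matrix(0L, 40, 40); labels[10:30, 10:30] <- 1L
  st <- channel_stack(list(membrane_marker = matrix(100, 40, 40),
                           target = matrix(7, 40, 40)))
  m <- compartment_masks(labels, 2L)
  rec <- quantify_fibers(st, m)
  expect_equal(rec$ring_mean_target, 7)
  expect_equal(rec$interior_mean_target, 7)
  expect_equal(rec$enrichment, 1)
  expect_equal(rec$sgca_norm_sarcolemma, 0.07)
  expect_equal(rec$area_um2, sum(labels == 1))

  # zero marker ring: ratio undefined and flagged
  st0 <- channel_stack(list(membrane_marker = matrix(0, 40, 40),
                            target = matrix(7, 40, 40)))
  rec0 <- quantify_fibers(st0, m)
  expect_true(is.na(rec0$sgca_norm_sarcolemma))
  expect_equal(rec0$flag, "undefined_ratio")
})

test_that("noisy per-fiber ring means recover ground truth within 3 SE", {
  g <- generate_biopsy(biopsy_spec(n_fibers = 60, noise_sd = 5, intensity_cv = 0,
                                   area_lognormal = c(log(900), 0.2), seed = 12))
  lab <- segment_fibers(g$stack)
  m <- suppressMessages(compartment_masks(lab, 3L))
  target <- g$stack$channels$target
  # oracle: recompute means over the measurement masks from the noise-free image
  tr <- g$truth
  noise_free <- matrix(3, nrow(target), ncol(target))
  nz <- tr$interior_labels > 0
  noise_free[nz] <- tr$interior_mean$target[tr$interior_labels[nz]]
  rz <- tr$ring_labels > 0
  noise_free[rz] <- tr$ring_mean$target[tr$ring_labels[rz]]
  rec <- quantify_fibers(g$stack, m)
  ok <- 0
  for (i in seq_len(nrow(rec))) {
    k <- rec$fiber_id[i]
    npx <- sum(m$ring == k)
    se <- 5 / sqrt(npx)
    expected <- mean(noise_free[m$ring == k])
    ok <- ok + (abs(rec$ring_mean_target[i] - expected) <= 3 * se)
  }
  expect_gte(ok / nrow(rec), 0.97)
})

test_that("marker normalization is invariant to global intensity scaling", {
  g <- generate_biopsy(tiny_biopsy(n_fibers = 4, seed = 8, noise_sd = 2,
                                   intensity_cv = 0.1))
  lab <- segment_fibers(g$stack)
  m <- suppressMessages(compartment_masks(lab, 3L))
  rec1 <- quantify_fibers(g$stack, m)
  scaled <- g$stack
  scaled$channels$target <- scaled$channels$target * 3.7
  scaled$channels$membrane_marker <- scaled$channels$membrane_marker * 3.7
  rec2 <- quantify_fibers(scaled, m)
  expect_equal(rec2$sgca_norm_sarcolemma, rec1$sgca_norm_sarcolemma)
  expect_equal(rec2$area_um2, rec1$area_um2)
})

test_that("measured median area tracks ground truth on noise-free geometry", {
  g <- generate_biopsy(tiny_biopsy(n_fibers = 12, seed = 14))
  lab <- segment_fibers(g$stack, segmentation_config(min_fiber_area_um2 = 50))
  m <- suppressMessages(compartment_masks(lab, 3L))
  rec <- quantify_fibers(g$stack, m)
  expect_equal(median(rec$area_um2), median(g$truth$area_um2), tolerance = 0.05)
})
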