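# synthetic-data generators: determinism, ground-truth consistency,
# and distributional properties

test_that("biopsy generator is deterministic and honours the zero-noise contract", {
  sp <- tiny_biopsy(n_fibers = 5, seed = 42)
  g1 <- generate_biopsy(sp)
  g2 <- generate_biopsy(sp)
  expect_identical(g1$stack$channels, g2$stack$channels)
  expect_identical(g1$truth$interior_labels, g2$truth$interior_labels)

  # noise 0, cv 0, group_effect 1: target ring mean is exactly ring + background
  tr <- g1$truth
  target <- g1$stack$channels$target
  for (k in seq_len(tr$n_fibers)) {
    expect_equal(mean(target[tr$ring_labels == k]), 200 + 2)
    expect_equal(mean(target[tr$interior_labels == k]), 5 + 2)
  }
})

test_that("ground-truth masks are disjoint and recover specified means with heterogeneity", {
  g <- generate_biopsy(tiny_biopsy(n_fibers = 6, seed = 9, intensity_cv = 0.2,
                                   group_effect = 0.6))
  tr <- g$truth
  expect_true(all((tr$ring_labels > 0) + (tr$interior_labels > 0) <= 1))
  target <- g$stack$channels$target   # noise-free (noise_sd = 0)
  for (k in seq_len(tr$n_fibers)) {
    expect_equal(mean(target[tr$ring_labels == k]), tr$ring_mean$target[k])
    expect_equal(mean(target[tr$interior_labels == k]), tr$interior_mean$target[k])
  }
})

test_that("ground-truth fiber areas follow the requested lognormal law", {
  # Monte-Carlo oracle: the median of lognormal(log 3000, 0.3) areas,
  # estimated from independent draws
  set.seed(99)
  oracle_median <- median(rlnorm(1e5, log(3000), 0.3))
  g <- generate_biopsy(biopsy_spec(n_fibers = 200, seed = 5,
                                   area_lognormal = c(log(3000), 0.3)))
  expect_equal(median(g$truth$area_um2), oracle_median, tolerance = 0.10)
})

test_that("biopsy generator raises a capacity error when the field is too small", {
  expect_error(generate_biopsy(biopsy_spec(n_fibers = 60, field_size_px = c(60, 60),
                                           seed = 1)),
               "too small")
})

test_that("cell-field generator encodes the requested membrane:cytoplasm ratios", {
  sp <- cell_field_spec(n_cells = 5, field_size_px = c(300, 300),
                        reporter_ratios = c(rep1 = 1, rep2 = 5),
                        intensity_cv = 0, noise_sd = 0, background = 0, seed = 2)
  g <- generate_cell_field(sp)
  tr <- g$truth
  expect_equal(tr$n_cells, 5)
  expect_equal(max(tr$labels), 5)
  for (k in seq_len(5)) {
    m1 <- mean(g$stack$channels$rep1[tr$membrane_labels == k])
    c1 <- mean(g$stack$channels$rep1[tr$cytoplasm_labels == k])
    m2 <- mean(g$stack$channels$rep2[tr$membrane_labels == k])
    c2 <- mean(g$stack$channels$rep2[tr$cytoplasm_labels == k])
    expect_equal(m1 / c1, 1)
    expect_equal(m2 / c2, 5)
  }
  expect_identical(generate_cell_field(sp)$stack$channels, g$stack$channels)
})

test_that("bifc generator gates interaction signal on transfection and efficiency", {
  # efficiency 0: interaction channel is flat background everywhere
  g0 <- generate_bifc_field(bifc_field_spec(n_cells = 20, efficiency = 0,
                                            noise_sd = 0, seed = 3))
  expect_true(all(g0$stack$channels$target == 4))

  # efficiency 1, no noise: per-cell Venus/mRFP ratio is 1 in transfected cells
  g1 <- generate_bifc_field(bifc_field_spec(n_cells = 20, efficiency = 1,
                                            noise_sd = 0, background = 0, seed = 3))
  tr <- g1$truth
  for (k in which(tr$transfected)) {
    sel <- tr$labels == k
    expect_equal(mean(g1$stack$channels$target[sel]) /
                   mean(g1$stack$channels$transfection_control[sel]), 1)
  }

  # transfected count matches the spec fraction; untransfected cells dark
  gh <- generate_bifc_field(bifc_field_spec(n_cells = 40, transfected_fraction = 0.5,
                                            noise_sd = 0, background = 0, seed = 6))
  expect_equal(sum(gh$truth$transfected), 20)
  dark <- which(!gh$truth$transfected)
  expect_true(all(gh$stack$channels$transfection_control[gh$truth$labels %in% dark] == 0))
})

test_that("bret titration simulation matches the closed-form ideal curves", {
  # saturation limit: n = 2, acceptor fraction -> 1 drives BRET to bmax
  sp <- bret_sim_spec(stoichiometry_n = 2, bmax = 0.5, noise_sd = 0,
                      expr_noise_cv = 0, background_bret = 0,
                      donor_fractions = c(0.5, 0.01), seed = 1)
  sim <- generate_bret_titration(sp)
  expect_equal(sim$bret_corr[sim$acceptor_fraction > 0.98], 0.5 * 0.99)
  expect_equal(attr(sim, "truth")$bret_specific[2], 0.5 * 0.99)

  # monomer: saturating component identically zero
  spm <- bret_sim_spec(stoichiometry_n = 1, bystander_slope = 0, noise_sd = 0,
                       expr_noise_cv = 0, background_bret = 0.1, seed = 1)
  simm <- generate_bret_titration(spm)
  expect_true(all(simm$bret_corr == 0))

  # closed-form oracle: higher order saturates faster at fixed f
  f <- 0.25
  o2 <- 1 - (1 - f)^1
  o4 <- 1 - (1 - f)^3
  expect_equal(ideal_bret(f, 2, bmax = 1), o2)
  expect_equal(ideal_bret(f, 4, bmax = 1), o4)
  expect_gt(ideal_bret(f, 4, bmax = 0.5), ideal_bret(f, 2, bmax = 0.5))

  # total expression constant across points up to expression noise
  spn <- bret_sim_spec(stoichiometry_n = 2, expr_noise_cv = 0, seed = 2)
  simn <- generate_bret_titration(spn)
  expect_equal(simn$total_expr, rep(1000, nrow(simn)))
})

test_that("generator specs validate their invariants", {
  expect_error(biopsy_spec(ring_thickness_px = 0), "ring_thickness")
  expect_error(biopsy_spec(group_effect = 0), "group_effect")
  expect_error(cell_field_spec(reporter_ratios = c(a = -1)), "ratios")
  expect_error(bret_sim_spec(donor_fractions = c(0, 0.5)), "donor_fractions")
  expect_error(bret_sim_spec(bmax = -1), "bmax")
})
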