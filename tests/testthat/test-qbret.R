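# type-1 qBRET: correction, filtering, expression F-test, ideal curves, fit

test_that("plate correction pairs backgrounds and derives expression columns", {
  sim <- generate_bret_titration(bret_sim_spec(stoichiometry_n = 2, seed = 31))
  plate <- bret_plate_table(sim)
  tit <- correct_and_normalize(plate)
  # bret_raw == background gives corrected BRET of exactly 0
  plate0 <- plate
  plate0$bret_ratio[!plate0$is_background] <-
    plate0$bret_ratio[plate0$is_background]
  expect_true(all(correct_and_normalize(plate0)$bret_corr == 0))
  # equal expression gives f = 0.5 and ratio 1
  plate5 <- data.frame(well = c("A1", "B1"), pair_id = 1,
                       is_background = c(FALSE, TRUE),
                       donor_lum = 500, acceptor_fluor = c(500, 0),
                       bret_ratio = c(0.3, 0.1))
  t5 <- correct_and_normalize(plate5)
  expect_equal(t5$acceptor_fraction, 0.5)
  expect_equal(t5$ratio, 1)
  expect_equal(t5$bret_corr, 0.2)
  # recovered fractions track the simulation ground truth
  expect_equal(tit$acceptor_fraction, attr(sim, "truth")$acceptor_fraction,
               tolerance = 0.05)
  # missing background pair drops the point
  plate_miss <- plate[!(plate$is_background & plate$pair_id == 3), ]
  expect_message(tm <- correct_and_normalize(plate_miss), "dropping 1")
  expect_false(3 %in% tm$point)
})

test_that("ratio filter applies the strict predicate", {
  tit <- data.frame(bret_raw = 0, bret_background = 0,
                    donor_lum = c(2, 1, 1), acceptor_fluor = c(2, 2, 3))
  tit$bret_ratio <- 0
  t <- popdcquant:::finish_titration(data.frame(
    point = 1:3, donor_lum = c(2, 1, 1), acceptor_fluor = c(2, 2, 3),
    bret_raw = 0, bret_background = 0))
  f <- filter_by_ratio(t, min_ratio = 2)
  expect_identical(f$pass_ratio_filter, c(FALSE, FALSE, TRUE))  # strict: ratio 2 excluded
  f0 <- filter_by_ratio(t, min_ratio = 0)
  expect_true(all(f0$pass_ratio_filter))
  # brute-force predicate oracle on a simulated titration
  sim <- generate_bret_titration(bret_sim_spec(
    donor_fractions = seq(0.1, 0.95, length.out = 12) * 0 +
      seq(0.1, 0.9, length.out = 12), seed = 32))
  fs <- filter_by_ratio(sim, 2)
  expect_identical(fs$pass_ratio_filter,
                   sim$acceptor_fluor / sim$donor_lum > 2)
})

test_that("constant-expression F-test behaves at the boundaries and under trend", {
  t_const <- popdcquant:::finish_titration(data.frame(
    point = 1:6, donor_lum = 6:1 * 100, acceptor_fluor = 1:6 * 100,
    bret_raw = 0, bret_background = 0))
  ft <- constant_expression_ftest(t_const)
  expect_equal(ft$F, 0)
  expect_equal(ft$p, 1)
  expect_error(constant_expression_ftest(t_const[1:2, ]), "3 points")

  # strong linear trend in total expression is detected decisively
  set.seed(5)
  t_trend <- popdcquant:::finish_titration(data.frame(
    point = 1:12, donor_lum = seq(900, 100, length.out = 12),
    acceptor_fluor = seq(100, 2000, length.out = 12),
    bret_raw = 0, bret_background = 0))
  t_trend$total_expr <- t_trend$total_expr + rnorm(12, 0, 5)
  expect_lt(constant_expression_ftest(t_trend)$p, 0.001)
})

test_that("F-test type-I rate is calibrated under the constant-total design", {
  reject <- vapply(1:500, function(s) {
    sim <- generate_bret_titration(bret_sim_spec(stoichiometry_n = 2,
                                                 expr_noise_cv = 0.05,
                                                 seed = 5000 + s))
    sim <- filter_by_ratio(sim, 0)   # keep all 12 points for the null check
    constant_expression_ftest(sim)$p < 0.05
  }, logical(1))
  expect_equal(mean(reject), 0.05, tolerance = 0.03 / 0.05)
})

test_that("ideal curves match closed forms and the occupancy enumeration oracle", {
  for (n in 1:4) expect_equal(ideal_bret(0, n, bmax = 1, bystander_slope = 1), 0)
  expect_equal(ideal_bret(0.5, 2, bmax = 0.6), 0.30)
  # enumeration oracle for the tetramer: P(>=1 acceptor among 3 partner
  # slots), summed over all 2^3 occupancy patterns
  f <- 0.5
  patterns <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  p_pattern <- apply(patterns, 1, function(s) prod(ifelse(s == 1, f, 1 - f)))
  p_any <- sum(p_pattern[rowSums(patterns) >= 1])
  expect_equal(ideal_bret(0.5, 4, bmax = 0.6), 0.6 * p_any)
  expect_equal(0.6 * p_any, 0.525)
  # monotone in f and in n; saturation limits
  fgrid <- seq(0.05, 0.95, by = 0.05)
  for (n in 2:4) {
    expect_true(all(diff(ideal_bret(fgrid, n, bmax = 0.5)) > 0))
    expect_equal(ideal_bret(1, n, bmax = 0.5), 0.5)
  }
  expect_true(all(vapply(3:4, function(n) ideal_bret(0.4, n, bmax = 0.5),
                         numeric(1)) > ideal_bret(0.4, 2, bmax = 0.5)))
  expect_error(ideal_bret(1.2, 2), "\\[0, 1\\]")
})

test_that("noise-free dimer titration is classified exactly", {
  sim <- generate_bret_titration(bret_sim_spec(stoichiometry_n = 2, bmax = 0.5,
                                               noise_sd = 0, expr_noise_cv = 0,
                                               background_bret = 0, seed = 1))
  fit <- fit_stoichiometry(sim)
  expect_equal(fit$classification, 2L)
  expect_equal(unname(coef(fit)["bmax"]), 0.5, tolerance = 1e-12)
  expect_equal(residuals(fit), rep(0, 12), tolerance = 1e-12)
  expect_equal(predict(fit, 0.5), 0.25, tolerance = 1e-12)
})

test_that("stoichiometry classification is reliable at realistic noise", {
  cls <- vapply(1:60, function(s) {
    sim <- generate_bret_titration(bret_sim_spec(stoichiometry_n = 2, bmax = 0.5,
                                                 noise_sd = 0.02, seed = 600 + s))
    fit_stoichiometry(sim)$classification
  }, integer(1))
  expect_gte(mean(cls == 2L), 0.95)

  mono <- vapply(1:60, function(s) {
    sim <- generate_bret_titration(bret_sim_spec(stoichiometry_n = 1,
                                                 bystander_slope = 0.05,
                                                 noise_sd = 0.02, seed = 700 + s))
    fit_stoichiometry(sim)$classification
  }, integer(1))
  expect_gte(mean(mono == 1L), 0.90)
})

test_that("narrow fraction span refuses classification; caveat flags higher orders", {
  sim <- generate_bret_titration(bret_sim_spec(
    stoichiometry_n = 2, donor_fractions = seq(0.4, 0.6, length.out = 6), seed = 2))
  fit <- fit_stoichiometry(sim)
  expect_false(fit$classified)
  expect_true(is.na(fit$classification))

  simt <- generate_bret_titration(bret_sim_spec(
    stoichiometry_n = 4, bmax = 0.5, noise_sd = 0.005,
    donor_fractions = seq(0.1, 0.65, length.out = 8), seed = 3))
  fitt <- fit_stoichiometry(simt)
  expect_gte(fitt$classification, 3L)
  expect_true(fitt$rapid_saturation_caveat)
})
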