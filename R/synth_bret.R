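#' Specification for a simulated type-1 BRET titration
#'
#' Emulates the type-1 quantitative BRET design: donor- and acceptor-tagged
#' constructs co-expressed at a range of plasmid ratios while the total
#' expression is held constant, with a dye-free control providing the
#' background BRET.
#'
#' @param stoichiometry_n complex order of the simulated species (1 =
#'   monomer, i.e. bystander-only; `n >= 2` = n-mer under random assembly).
#' @param bmax saturating BRET amplitude (dimensionless).
#' @param bystander_slope linear bystander BRET per unit acceptor fraction
#'   (the monomer model's only component; default 0).
#' @param total_expression total donor + acceptor expression (a.u.), held
#'   constant across titration points.
#' @param donor_fractions donor expression fractions in (0, 1), one per
#'   titration point.
#' @param expr_noise_cv per-well expression variability (cell-count and
#'   pipetting variation): a shared lognormal factor multiplying both the
#'   luminescence and fluorescence reads of a well, so the acceptor:donor
#'   ratio is untouched while the apparent total fluctuates.
#' @param noise_sd additive Gaussian noise on the BRET ratio.
#' @param background_bret background BRET (subtracted via the dye-free
#'   control).
#' @param seed integer RNG seed.
#' @return an object of class `bret_sim_spec`.
#' @export
bret_sim_spec <- function(stoichiometry_n = 2L,
                          bmax = 0.5,
                          bystander_slope = 0,
                          total_expression = 1000,
                          donor_fractions = seq(0.1, 0.9, length.out = 12),
                          expr_noise_cv = 0.02,
                          noise_sd = 0.02,
                          background_bret = 0.05,
                          seed = 1L) {
  if (stoichiometry_n < 1) stop("stoichiometry_n must be >= 1", call. = FALSE)
  if (bmax < 0) stop("bmax must be >= 0", call. = FALSE)
  if (any(donor_fractions <= 0 | donor_fractions >= 1)) {
    stop("donor_fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  stopifnot_scalar_pos(total_expression, "total_expression")
  structure(list(stoichiometry_n = as.integer(stoichiometry_n), bmax = bmax,
                 bystander_slope = bystander_slope,
                 total_expression = total_expression,
                 donor_fractions = donor_fractions,
                 expr_noise_cv = expr_noise_cv, noise_sd = noise_sd,
                 background_bret = background_bret, seed = as.integer(seed)),
            class = "bret_sim_spec")
}

#' Simulate a type-1 BRET titration
#'
#' Per point, donor luminescence is proportional to the donor fraction of the
#' (constant) total expression and acceptor fluorescence to its complement;
#' the noise-free BRET follows the ideal stoichiometry curve
#' ([ideal_bret()]) plus the background, then Gaussian noise is added.
#'
#' @param spec a [bret_sim_spec()].
#' @return a `bret_titration` data frame (see [correct_and_normalize()] for
#'   the column contract) with attribute `truth` holding the noise-free
#'   curve, true fractions and model parameters.
#' @export
generate_bret_titration <- function(spec) {
  stopifnot(inherits(spec, "bret_sim_spec"))
  with_seed(spec$seed, {
    fd <- spec$donor_fractions
    fa <- 1 - fd
    donor_true <- fd * spec$total_expression
    acceptor_true <- fa * spec$total_expression
    bret_true <- ideal_bret(fa, spec$stoichiometry_n, spec$bmax,
                            spec$bystander_slope)
    n <- length(fd)
    well_factor <- rlnorm_cv1(n, spec$expr_noise_cv)
    donor_lum <- donor_true * well_factor
    acceptor_fluor <- acceptor_true * well_factor
    bret_raw <- bret_true + spec$background_bret + stats::rnorm(n, sd = spec$noise_sd)
    out <- data.frame(point = seq_len(n),
                      donor_lum = donor_lum,
                      acceptor_fluor = acceptor_fluor,
                      bret_raw = bret_raw,
                      bret_background = spec$background_bret)
    out <- finish_titration(out, calibration = c(donor = 1, acceptor = 1))
    attr(out, "truth") <- list(acceptor_fraction = fa,
                               bret_specific = bret_true,
                               model_n = spec$stoichiometry_n,
                               bmax = spec$bmax,
                               bystander_slope = spec$bystander_slope)
    out
  })
}

#' Expand a simulated titration into a raw plate table
#'
#' Produces the plate-reader-shaped CSV contract consumed by
#' [correct_and_normalize()]: one dye well and one matched dye-free (DMSO)
#' background well per titration point, sharing a `pair_id`.
#'
#' @param titration result of [generate_bret_titration()].
#' @return data frame with columns `well`, `pair_id`, `is_background`,
#'   `donor_lum`, `acceptor_fluor`, `bret_ratio`.
#' @export
bret_plate_table <- function(titration) {
  n <- nrow(titration)
  meas <- data.frame(well = sprintf("A%02d", seq_len(n)), pair_id = seq_len(n),
                     is_background = FALSE,
                     donor_lum = titration$donor_lum,
                     acceptor_fluor = titration$acceptor_fluor,
                     bret_ratio = titration$bret_raw)
  bgd <- data.frame(well = sprintf("B%02d", seq_len(n)), pair_id = seq_len(n),
                    is_background = TRUE,
                    donor_lum = titration$donor_lum,
                    acceptor_fluor = 0,
                    bret_ratio = titration$bret_background)
  rbind(meas, bgd)
}
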