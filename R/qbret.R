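#' Ideal type-1 BRET saturation curves
#'
#' Under random assembly of an n-mer at acceptor fraction `f`, the specific
#' BRET is proportional to the probability that a donor's complex contains at
#' least one acceptor among its `n - 1` partner slots:
#' `bmax * (1 - (1 - f)^(n - 1))`. The dimer therefore gives `bmax * f`
#' (hyperbolic when re-plotted against the acceptor:donor ratio), and higher
#' orders saturate faster. The monomer has no saturating (specific)
#' component at all; its only signal is non-saturating bystander BRET from
#' random proximity, which scales with the acceptor:donor expression ratio:
#' `bystander_slope * f / (1 - f)`. Against the acceptor:donor ratio the
#' dimer model is a saturating hyperbola while the bystander term is a
#' straight line, which is what makes the two distinguishable in a type-1
#' titration at constant total expression (against `f` itself, a linear
#' bystander would be confounded with the dimer curve `bmax * f`).
#'
#' @param f acceptor fraction(s) in `[0, 1]` (`f < 1` required for the
#'   monomer model).
#' @param model_n complex order (integer `>= 1`).
#' @param bmax saturating amplitude (ignored for `model_n = 1`).
#' @param bystander_slope bystander BRET per unit acceptor:donor ratio
#'   (used only for `model_n = 1`).
#' @return predicted specific BRET, same length as `f`.
#' @export
ideal_bret <- function(f, model_n, bmax = 1, bystander_slope = 0) {
  if (any(f < 0 | f > 1)) stop("acceptor fraction must lie in [0, 1]", call. = FALSE)
  if (model_n < 1) stop("model_n must be >= 1", call. = FALSE)
  if (model_n == 1) {
    if (any(f >= 1)) stop("monomer bystander model needs f < 1", call. = FALSE)
    bystander_slope * f / (1 - f)
  } else bmax * (1 - (1 - f)^(model_n - 1))
}

finish_titration <- function(df, calibration = c(donor = 1, acceptor = 1)) {
  df$bret_corr <- df$bret_raw - df$bret_background
  df$donor_norm <- df$donor_lum * calibration[["donor"]]
  df$acceptor_norm <- df$acceptor_fluor * calibration[["acceptor"]]
  df$total_expr <- df$donor_norm + df$acceptor_norm
  df$acceptor_fraction <- df$acceptor_norm / df$total_expr
  df$ratio <- df$acceptor_norm / df$donor_norm
  class(df) <- c("bret_titration", "data.frame")
  df
}

#' Background-correct and normalize a raw BRET plate table
#'
#' Dye wells are paired with their dye-free (DMSO) background wells by
#' `pair_id`; background BRET is subtracted from the raw BRET ratio, and
#' luminescence/fluorescence readings are put on a common expression scale by
#' the user-supplied calibration factors. Points lacking a background pair
#' are dropped with a message.
#'
#' @param plate data frame with columns `pair_id`, `is_background`,
#'   `donor_lum`, `acceptor_fluor`, `bret_ratio`.
#' @param calibration named factors `c(donor = , acceptor = )` converting
#'   luminescence and fluorescence onto a common expression scale.
#' @return a `bret_titration` data frame with derived columns `bret_corr`,
#'   `donor_norm`, `acceptor_norm`, `total_expr`, `acceptor_fraction`,
#'   `ratio`.
#' @export
correct_and_normalize <- function(plate, calibration = c(donor = 1, acceptor = 1)) {
  stopifnot(all(c("pair_id", "is_background", "donor_lum", "acceptor_fluor",
                  "bret_ratio") %in% names(plate)))
  meas <- plate[!plate$is_background, , drop = FALSE]
  bgd <- plate[plate$is_background, , drop = FALSE]
  has_bg <- meas$pair_id %in% bgd$pair_id
  if (any(!has_bg)) {
    message(sprintf("correct_and_normalize: dropping %d point(s) without a background pair",
                    sum(!has_bg)))
    meas <- meas[has_bg, , drop = FALSE]
  }
  if (nrow(meas) == 0L) stop("no measurement wells with matched background", call. = FALSE)
  bg_of <- stats::setNames(bgd$bret_ratio, bgd$pair_id)
  out <- data.frame(point = meas$pair_id,
                    donor_lum = meas$donor_lum,
                    acceptor_fluor = meas$acceptor_fluor,
                    bret_raw = meas$bret_ratio,
                    bret_background = unname(bg_of[as.character(meas$pair_id)]))
  finish_titration(out, calibration)
}

#' Flag titration points by acceptor:donor expression ratio
#'
#' Marks points whose acceptor:donor expression ratio exceeds `min_ratio`
#' (strict inequality). The constant-total-expression F-test uses only the
#' flagged points, as recommended for type-1 designs; curve fitting keeps the
#' full set.
#'
#' @param titration a `bret_titration`.
#' @param min_ratio minimum acceptor:donor ratio (default 2).
#' @return the titration with a logical `pass_ratio_filter` column; warns if
#'   no point passes.
#' @export
filter_by_ratio <- function(titration, min_ratio = 2.0) {
  titration$pass_ratio_filter <- titration$ratio > min_ratio
  if (!any(titration$pass_ratio_filter)) {
    warning("no titration points with acceptor:donor ratio above the cutoff; expression test will be skipped")
  }
  titration
}

#' F-test for constant total expression across the titration
#'
#' Fits total expression against the acceptor:donor ratio with a horizontal
#' (mean-only) and a straight-line model and compares them by a nested-model
#' F-test; `p > 0.05` is read as constant total expression over the
#' titration, the design assumption of type-1 BRET.
#'
#' @param titration a `bret_titration`, ideally after [filter_by_ratio()]
#'   (only flagged points enter the test when the flag column is present).
#' @return list `(F, p, df1, df2, n)`.
#' @export
constant_expression_ftest <- function(titration) {
  d <- titration
  if (!is.null(d$pass_ratio_filter)) d <- d[d$pass_ratio_filter, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 points for the expression F-test", call. = FALSE)
  if (stats::var(d$total_expr) == 0) {
    return(list(F = 0, p = 1, df1 = 1, df2 = nrow(d) - 2, n = nrow(d)))
  }
  m0 <- stats::lm(total_expr ~ 1, data = d)
  m1 <- stats::lm(total_expr ~ ratio, data = d)
  a <- stats::anova(m0, m1)
  list(F = a$F[2], p = a$`Pr(>F)`[2], df1 = a$Df[2], df2 = a$Res.Df[2], n = nrow(d))
}

#' Fit ideal stoichiometry models to a BRET titration
#'
#' Least-squares fit of each candidate model over the acceptor fraction:
#' the monomer model (bystander only, linear in the acceptor:donor ratio,
#' see [ideal_bret()]) and n-mer saturation models
#' (`bret = bmax * (1 - (1 - f)^(n - 1))`); each has one free amplitude
#' parameter with a closed-form least-squares solution. The
#' complex order is classified as the model with the lowest AICc. When the
#' best model has `n >= 3` but the titration poorly covers the low-f region,
#' a rapid-saturation caveat is flagged, as rapidly saturating curves make
#' the order of higher complexes hard to pin down.
#'
#' @param titration a `bret_titration` with `bret_corr` and
#'   `acceptor_fraction`.
#' @param candidate_ns integer candidate complex orders (default 1:4).
#' @param min_span minimum acceptor-fraction span required to classify.
#' @return an object of class `stoich_fit`.
#' @export
fit_stoichiometry <- function(titration, candidate_ns = 1:4, min_span = 0.4) {
  f <- titration$acceptor_fraction
  y <- titration$bret_corr
  npts <- length(y)
  if (npts < 5) stop("need at least 5 corrected points to fit", call. = FALSE)
  span <- max(f) - min(f)
  fits <- lapply(candidate_ns, function(n) {
    g <- if (n == 1) f / (1 - f) else 1 - (1 - f)^(n - 1)
    amp <- sum(g * y) / sum(g * g)
    pred <- amp * g
    rss <- sum((y - pred)^2)
    K <- 2  # amplitude + residual variance
    aicc <- npts * log(max(rss, .Machine$double.xmin) / npts) + 2 * K +
      2 * K * (K + 1) / (npts - K - 1)
    list(model_n = n, amplitude = amp, rss = rss, aicc = aicc, fitted = pred)
  })
  tab <- data.frame(model_n = vapply(fits, `[[`, integer(1), "model_n"),
                    amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
                    rss = vapply(fits, `[[`, numeric(1), "rss"),
                    aicc = vapply(fits, `[[`, numeric(1), "aicc"))
  classify <- span >= min_span
  best <- tab$model_n[which.min(tab$aicc)]
  caveat <- classify && best >= 3 && sum(f < 0.3) < 3
  structure(list(models = tab,
                 classification = if (classify) best else NA_integer_,
                 span = span, classified = classify,
                 rapid_saturation_caveat = caveat,
                 data = data.frame(acceptor_fraction = f, bret_corr = y),
                 fitted_best = fits[[which.min(tab$aicc)]]$fitted),
            class = "stoich_fit")
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat("Type-1 BRET stoichiometry fit\n")
  cat(sprintf("  points: %d, acceptor-fraction span: %.2f\n",
              nrow(x$data), x$span))
  if (x$classified) {
    lab <- c("monomer (bystander only)", "dimer", "trimer", "tetramer")
    nm <- if (x$classification <= 4) lab[x$classification]
          else sprintf("%d-mer", x$classification)
    cat(sprintf("  classification: n = %d (%s)\n", x$classification, nm))
  } else {
    cat("  classification refused: acceptor-fraction span too narrow\n")
  }
  if (x$rapid_saturation_caveat) {
    cat("  caveat: rapid saturation with sparse low-f coverage; higher-order\n",
        "  stoichiometries are hard to distinguish\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.stoich_fit <- function(object, ...) {
  cat("Candidate models (amplitude = bmax, or bystander slope for n = 1):\n")
  tab <- object$models
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  print(tab, row.names = FALSE, digits = 4)
  print(object)
  invisible(tab)
}

#' @export
coef.stoich_fit <- function(object, ...) {
  i <- match(object$models$model_n[which.min(object$models$aicc)],
             object$models$model_n)
  amp <- object$models$amplitude[i]
  n <- object$models$model_n[i]
  stats::setNames(c(n, amp), c("model_n", if (n == 1) "bystander_slope" else "bmax"))
}

#' @export
predict.stoich_fit <- function(object, newdata = NULL, model_n = NULL, ...) {
  f <- if (is.null(newdata)) object$data$acceptor_fraction
       else if (is.data.frame(newdata)) newdata$acceptor_fraction else newdata
  tab <- object$models
  n <- model_n %||% tab$model_n[which.min(tab$aicc)]
  amp <- tab$amplitude[match(n, tab$model_n)]
  if (is.na(amp)) stop("model_n was not among the fitted candidates", call. = FALSE)
  if (n == 1) ideal_bret(f, 1, bystander_slope = amp)
  else ideal_bret(f, n, bmax = amp)
}

#' @export
residuals.stoich_fit <- function(object, ...) {
  object$data$bret_corr - object$fitted_best
}

#' @export
fitted.stoich_fit <- function(object, ...) object$fitted_best

#' Plot a BRET titration with the fitted stoichiometry curves
#'
#' @param x a `stoich_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stoich_fit <- function(x, ...) {
  graphics::plot(x$data$acceptor_fraction, x$data$bret_corr,
                 xlab = "acceptor fraction", ylab = "corrected BRET",
                 pch = 19, ...)
  fgrid <- seq(0, 1, length.out = 200)
  for (i in seq_len(nrow(x$models))) {
    graphics::lines(fgrid, predict(x, fgrid, model_n = x$models$model_n[i]),
                    lty = i, col = i + 1)
  }
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("n = %d%s", x$models$model_n,
                                    ifelse(x$models$model_n == x$classification &
                                             x$classified, " (best)", "")),
                   lty = seq_len(nrow(x$models)), col = seq_len(nrow(x$models)) + 1)
  invisible(x)
}
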