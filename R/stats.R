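#' Normalize values to the median of matched controls
#'
#' Divides every value by the control median, so the control group's own
#' normalized median is exactly 1. This is the per-biopsy normalization used
#' before pooling fibers or cells across groups.
#'
#' @param values numeric vector to normalize.
#' @param control_values numeric vector of matched control measurements.
#' @return `values / median(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  control_values <- control_values[is.finite(control_values)]
  if (length(control_values) == 0L) stop("empty control group", call. = FALSE)
  m <- stats::median(control_values)
  if (!is.finite(m) || m <= 0) stop("control median must be positive", call. = FALSE)
  values / m
}

#' Distribution-free confidence interval for the median
#'
#' Order-statistic (binomial) interval: the widest symmetric pair of order
#' statistics `(x_(k), x_(n+1-k))` whose exact binomial coverage is at least
#' `level`. For very small samples (`n < 6`), where the order-statistic
#' interval degenerates to the sample range without reaching the nominal
#' level, a seeded bootstrap percentile interval (2000 resamples) is used and
#' a wide-interval warning is emitted.
#'
#' @param values numeric sample.
#' @param level confidence level (default 0.95).
#' @param boot_seed seed for the small-sample bootstrap fallback.
#' @return list `(median, lo, hi, n, method)`.
#' @export
median_ci <- function(values, level = 0.95, boot_seed = 1L) {
  x <- sort(values[is.finite(values)])
  n <- length(x)
  if (n == 0L) stop("no finite values", call. = FALSE)
  med <- stats::median(x)
  alpha <- 1 - level
  if (n >= 6) {
    # largest k with coverage 1 - 2*pbinom(k-1, n, 1/2) >= level
    ks <- seq_len(floor(n / 2))
    valid <- 2 * stats::pbinom(ks - 1, n, 0.5) <= alpha
    k <- if (any(valid)) max(ks[valid]) else 1L
    lo <- x[k]; hi <- x[n + 1 - k]
    method <- "order_statistic"
  } else {
    warning("n < 6: order-statistic interval unreliable; using seeded bootstrap (interval may be wide)")
    bs <- with_seed(boot_seed, {
      vapply(seq_len(2000), function(i) stats::median(sample(x, n, replace = TRUE)),
             numeric(1))
    })
    qs <- stats::quantile(bs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
    method <- "bootstrap"
  }
  list(median = med, lo = lo, hi = hi, n = n, method = method)
}

new_comparison <- function(test, statistic, p, comparisons = NULL, flag = "") {
  structure(list(test = test, statistic = statistic, p = p,
                 comparisons = comparisons, flag = flag),
            class = "popdc_comparison")
}

#' @export
print.popdc_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$test, x$statistic, x$p,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value for small tie-free samples, normal approximation otherwise
#' (the default sample-size rule of [stats::wilcox.test()]). Fully tied,
#' degenerate data return `p = 1` with a flag instead of an error.
#'
#' @param a,b numeric samples (each `n >= 3`).
#' @return a `popdc_comparison` (statistic = Mann-Whitney U of `a`).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop("both groups need n >= 3", call. = FALSE)
  if (length(unique(c(a, b))) == 1L) {
    return(new_comparison("mann_whitney", statistic = length(a) * length(b) / 2,
                          p = 1, flag = "degenerate_all_tied"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  new_comparison("mann_whitney", statistic = unname(wt$statistic), p = wt$p.value)
}

# Dunn's post hoc z statistic between groups i and j after a Kruskal-Wallis
# ranking of the pooled data, with the standard tie correction.
dunn_z <- function(ranks, groups, gi, gj) {
  N <- length(ranks)
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  ri <- mean(ranks[groups == gi]); rj <- mean(ranks[groups == gj])
  ni <- sum(groups == gi); nj <- sum(groups == gj)
  se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
  (ri - rj) / se
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Rank-based many-group comparison: Kruskal-Wallis H (with tie correction)
#' across all groups, followed by Dunn's z-test for the requested pairs with
#' Holm adjustment of the two-sided p-values.
#'
#' @param groups named list of numeric vectors (`>= 3` groups; with two
#'   groups use [mann_whitney()]).
#' @param comparisons either `NULL` (all pairs), a character control label
#'   (many-to-one), or a list of 2-element character vectors.
#' @return a `popdc_comparison`; `comparisons` holds columns `comparison`,
#'   `z`, `p`, `p_adj`.
#' @export
kruskal_dunn <- function(groups, comparisons = NULL) {
  if (length(groups) < 3) {
    stop("kruskal_dunn needs >= 3 groups; use mann_whitney() for two", call. = FALSE)
  }
  labs <- names(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, lengths(groups)), levels = labs)
  kw <- stats::kruskal.test(x, g)
  pairs <- if (is.null(comparisons)) {
    utils::combn(labs, 2, simplify = FALSE)
  } else if (is.character(comparisons) && length(comparisons) == 1L) {
    lapply(setdiff(labs, comparisons), function(l) c(comparisons, l))
  } else comparisons
  r <- rank(x)
  z <- vapply(pairs, function(p) dunn_z(r, g, p[1], p[2]), numeric(1))
  praw <- 2 * stats::pnorm(-abs(z))
  cmp <- data.frame(comparison = vapply(pairs, paste, character(1), collapse = " vs "),
                    z = z, p = praw, p_adj = stats::p.adjust(praw, "holm"))
  new_comparison("kruskal_dunn", statistic = unname(kw$statistic),
                 p = kw$p.value, comparisons = cmp)
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Classical one-way ANOVA across groups followed by Dunnett's test of every
#' group against the named control, with single-step (multivariate-t)
#' adjusted p-values.
#'
#' @param groups named list of numeric vectors including the control.
#' @param control_label name of the control group.
#' @return a `popdc_comparison`; `comparisons` holds columns `comparison`,
#'   `estimate`, `t`, `p_adj`. Data with zero within-group variance
#'   everywhere return a degenerate flag instead of a fit.
#' @export
anova_dunnett <- function(groups, control_label) {
  if (!control_label %in% names(groups)) stop("control group absent", call. = FALSE)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  labs <- c(control_label, setdiff(names(groups), control_label))
  d <- data.frame(value = unlist(groups[labs], use.names = FALSE),
                  group = factor(rep(labs, lengths(groups[labs])), levels = labs))
  if (all(vapply(groups, function(v) stats::var(v) == 0 || length(v) < 2, logical(1)))) {
    return(new_comparison("anova_dunnett", statistic = NA_real_, p = NA_real_,
                          flag = "degenerate_zero_variance"))
  }
  fit <- stats::aov(value ~ group, data = d)
  Fv <- summary(fit)[[1]][["F value"]][1]
  pv <- summary(fit)[[1]][["Pr(>F)"]][1]
  cmp <- NULL
  if (length(labs) > 1) {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    cmp <- data.frame(comparison = names(sm$test$coefficients),
                      estimate = unname(sm$test$coefficients),
                      t = unname(sm$test$tstat),
                      p_adj = unname(as.numeric(sm$test$pvalues)))
  }
  new_comparison("anova_dunnett", statistic = Fv, p = pv, comparisons = cmp)
}

#' Group summary with control-median normalization
#'
#' Normalizes every group to the control median ([normalize_to_control()])
#' and reports each group's normalized median with its 95% order-statistic
#' confidence interval.
#'
#' @param groups named list of numeric vectors.
#' @param control_label name of the control group.
#' @param level confidence level.
#' @return data frame with columns `group`, `n`, `median_normalized`,
#'   `ci_low`, `ci_high`.
#' @export
group_summary <- function(groups, control_label, level = 0.95) {
  if (!control_label %in% names(groups)) stop("control group absent", call. = FALSE)
  ctl <- groups[[control_label]]
  rows <- lapply(names(groups), function(l) {
    v <- normalize_to_control(groups[[l]], ctl)
    ci <- median_ci(v, level = level)
    data.frame(group = l, n = ci$n, median_normalized = ci$median,
               ci_low = ci$lo, ci_high = ci$hi)
  })
  do.call(rbind, rows)
}
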