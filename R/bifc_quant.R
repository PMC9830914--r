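#' Select transfected-cell pixels in a BiFC field
#'
#' Pixels whose transfection-control (mRFP) intensity lies above background
#' are selected, excluding non-transfected cells; nuclei (thresholded nucleus
#' channel) are removed from the mask. The default threshold is the
#' background estimate (channel median, most pixels being background at this
#' magnification) plus `k_mad` times the median absolute deviation.
#'
#' @param stack a [channel_stack()] with a `transfection_control` channel.
#' @param mrfp_threshold explicit intensity threshold; overrides the
#'   background + MAD rule.
#' @param k_mad multiplier of the MAD above the background estimate.
#' @return logical pixel mask, or `NULL` (with a warning) when no pixel
#'   passes, in which case the image is excluded from analysis.
#' @export
select_transfected <- function(stack, mrfp_threshold = NULL, k_mad = 3) {
  ctl <- get_channel(stack, "transfection_control")
  if (is.null(mrfp_threshold)) {
    mrfp_threshold <- stats::median(ctl) + k_mad * stats::mad(ctl)
  }
  mask <- ctl > mrfp_threshold
  if (has_channel(stack, "nucleus")) {
    nuc <- get_channel(stack, "nucleus")
    mx <- max(nuc)
    if (mx > 0) {
      thr <- EBImage::otsu(EBImage::Image(nuc / mx), range = c(0, 1)) * mx
      mask <- mask & !(nuc > thr)
    }
  }
  if (!any(mask)) {
    warning(sprintf("image '%s': no transfected pixels above threshold; image excluded",
                    stack$image_id))
    return(NULL)
  }
  mask
}

#' Per-image BiFC signal
#'
#' Median Venus (interaction reporter, role `target`) and median mRFP
#' (`transfection_control`) over the transfected-cell mask; the BiFC signal
#' is their ratio, normalizing the complementation signal to transfection
#' efficiency.
#'
#' @param stack a [channel_stack()].
#' @param mask pixel mask from [select_transfected()].
#' @return one-row data frame (`image_id`, `median_venus`, `median_mrfp`,
#'   `bifc_signal`), or `NULL` when the mRFP median is zero (image excluded
#'   with a warning).
#' @export
bifc_image_signal <- function(stack, mask) {
  if (is.null(mask) || !any(mask)) stop("mask must be non-empty", call. = FALSE)
  mv <- stats::median(get_channel(stack, "target")[mask])
  mr <- stats::median(get_channel(stack, "transfection_control")[mask])
  if (mr <= 0) {
    warning(sprintf("image '%s': zero mRFP median; image excluded", stack$image_id))
    return(NULL)
  }
  data.frame(image_id = stack$image_id, median_venus = mv, median_mrfp = mr,
             bifc_signal = mv / mr)
}

#' Summarize BiFC signals by group and compare to the wild-type pair
#'
#' Group means of the per-image BiFC signals are normalized so that the
#' wild-type pair equals 1 exactly; groups are compared on the per-image
#' values (the replication unit) by one-way ANOVA followed by Dunnett's
#' many-to-one test against the wild type.
#'
#' @param per_image data frame with columns `image_id`, `group`,
#'   `bifc_signal`.
#' @param wildtype_label group label of the wild-type pair.
#' @return list of class `bifc_groups`: `groups` (label, n_images, mean
#'   signal, normalized value) and `comparison` (a [anova_dunnett()] result,
#'   `NULL` with a single group).
#' @export
summarize_bifc_groups <- function(per_image, wildtype_label = "WT") {
  stopifnot(all(c("group", "bifc_signal") %in% names(per_image)))
  if (!wildtype_label %in% per_image$group) {
    stop(sprintf("wild-type group '%s' absent", wildtype_label), call. = FALSE)
  }
  if (sum(per_image$group == wildtype_label) < 2) {
    stop("wild-type group needs >= 2 images", call. = FALSE)
  }
  means <- tapply(per_image$bifc_signal, per_image$group, mean)
  ns <- tapply(per_image$bifc_signal, per_image$group, length)
  labs <- names(means)
  groups <- data.frame(group = labs, n_images = as.integer(ns[labs]),
                       mean_signal = as.numeric(means[labs]),
                       normalized = as.numeric(means[labs] / means[[wildtype_label]]),
                       row.names = NULL)
  comparison <- NULL
  if (length(labs) > 1) {
    glist <- split(per_image$bifc_signal, per_image$group)
    comparison <- anova_dunnett(glist, control_label = wildtype_label)
  }
  structure(list(groups = groups, wildtype = wildtype_label,
                 comparison = comparison), class = "bifc_groups")
}

#' @export
print.bifc_groups <- function(x, ...) {
  cat("BiFC group summary (normalized to", x$wildtype, "= 1)\n")
  print(x$groups, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("\n")
    print(x$comparison)
  }
  invisible(x)
}
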