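#' End-to-end biopsy study: fibers, normalization, statistics
#'
#' Runs fiber segmentation and compartment quantification on every patient
#' and control image, pools per-fiber marker-normalized sarcolemmal values by
#' arm, normalizes to the control median (set to 1), and compares the arms
#' with a Mann-Whitney test. Fiber cross-sectional areas are summarized and
#' compared the same way. Flagged fibers (undefined ratios) are excluded from
#' the summaries and counted.
#'
#' @param patient_stacks,control_stacks lists of [channel_stack()] objects
#'   (both arms non-empty).
#' @param config a [segmentation_config()].
#' @return list of class `biopsy_study`: `fibers` (pooled per-fiber records
#'   with an `arm` column), `per_image` (fiber counts and exclusions),
#'   `summary` (normalized medians with 95% CIs per arm),
#'   `area_summary`, `test`, `area_test`, and the `config`.
#' @export
run_biopsy_study <- function(patient_stacks, control_stacks,
                             config = segmentation_config()) {
  if (length(patient_stacks) == 0L || length(control_stacks) == 0L) {
    stop("both study arms must contain at least one image", call. = FALSE)
  }
  quant_arm <- function(stacks, arm) {
    rows <- lapply(stacks, function(st) {
      lab <- segment_fibers(st, config)
      m <- suppressMessages(compartment_masks(lab, config$dilation_radius_px))
      rec <- quantify_fibers(st, m)
      rec$arm <- arm
      rec
    })
    do.call(rbind, rows)
  }
  fib <- rbind(quant_arm(patient_stacks, "patient"),
               quant_arm(control_stacks, "control"))
  per_image <- do.call(rbind, lapply(split(fib, fib$image_id), function(d) {
    data.frame(image_id = d$image_id[1], arm = d$arm[1],
               n_fibers = nrow(d), n_flagged = sum(d$flag != ""))
  }))
  rownames(per_image) <- NULL
  usable <- fib[fib$flag == "" & is.finite(fib$sgca_norm_sarcolemma), , drop = FALSE]
  vals <- split(usable$sgca_norm_sarcolemma, usable$arm)
  if (length(vals$patient %||% numeric(0)) == 0L ||
      length(vals$control %||% numeric(0)) == 0L) {
    stop("a study arm has zero usable fibers; aborting run", call. = FALSE)
  }
  summary <- group_summary(list(control = vals$control, patient = vals$patient),
                           control_label = "control")
  test <- mann_whitney(vals$patient, vals$control)
  areas <- split(fib$area_um2, fib$arm)
  area_summary <- do.call(rbind, lapply(names(areas), function(l) {
    ci <- median_ci(areas[[l]])
    data.frame(group = l, n = ci$n, median_um2 = ci$median,
               ci_low = ci$lo, ci_high = ci$hi)
  }))
  area_test <- mann_whitney(areas$patient, areas$control)
  structure(list(fibers = fib, per_image = per_image, summary = summary,
                 test = test, area_summary = area_summary,
                 area_test = area_test, config = config),
            class = "biopsy_study")
}

#' @export
print.biopsy_study <- function(x, ...) {
  cat("Biopsy study:", nrow(x$fibers), "fibers across",
      nrow(x$per_image), "images\n")
  cat("Marker-normalized sarcolemmal signal (control median = 1):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  print(x$test)
  cat("Fiber cross-sectional area (um^2):\n")
  print(x$area_summary, row.names = FALSE, digits = 4)
  print(x$area_test)
  invisible(x)
}

#' Cross-biopsy comparison of fold changes
#'
#' Pools the per-fiber control-normalized values of several biopsy pairs and
#' compares the fold-change distributions across biopsies with
#' Kruskal-Wallis followed by Dunn's test (all pairs by default).
#'
#' @param normalized_by_biopsy named list: per biopsy, the patient arm's
#'   control-normalized per-fiber values.
#' @param comparisons see [kruskal_dunn()].
#' @return a `popdc_comparison`.
#' @export
compare_fold_changes <- function(normalized_by_biopsy, comparisons = NULL) {
  kruskal_dunn(normalized_by_biopsy, comparisons = comparisons)
}

#' End-to-end co-transfection study: cell localization ratios vs wild type
#'
#' Quantifies every cell (background subtraction, ROI-guided membrane /
#' cytoplasm segmentation, localization ratios), pools per-cell ratios per
#' reporter and group, normalizes to the wild-type median, and compares
#' groups with Kruskal-Wallis followed by Dunn's test against the wild-type
#' pair. Absolute membrane and cytoplasm means are summarized as well.
#'
#' @param group_fields named list; per group, a list of `list(stack, rois)`
#'   entries (one per image).
#' @param wildtype_label group label of the wild-type pair.
#' @param band_px,cyto_margin_px see [segment_cell()].
#' @return list of class `cotransfection_study`: `cells`, per-reporter
#'   `summary` (normalized medians + CIs) and `test`, and absolute
#'   compartment summaries.
#' @export
run_cotransfection_study <- function(group_fields, wildtype_label = "WT",
                                     band_px = 1L, cyto_margin_px = 1L) {
  if (!wildtype_label %in% names(group_fields)) {
    stop(sprintf("wild-type group '%s' absent", wildtype_label), call. = FALSE)
  }
  if (any(lengths(group_fields) == 0L)) stop("empty group supplied", call. = FALSE)
  cells <- do.call(rbind, lapply(names(group_fields), function(gname) {
    do.call(rbind, lapply(group_fields[[gname]], function(fld) {
      d <- quantify_cell_field(fld$stack, fld$rois, band_px = band_px,
                               cyto_margin_px = cyto_margin_px)
      d$group <- gname
      d
    }))
  }))
  reporters <- sub("^ratio_", "", grep("^ratio_", names(cells), value = TRUE))
  per_rep <- lapply(reporters, function(rep) {
    col <- paste0("ratio_", rep)
    ok <- cells$flag == "" & is.finite(cells[[col]])
    vals <- split(cells[[col]][ok], cells$group[ok])
    summ <- group_summary(vals, control_label = wildtype_label)
    test <- if (length(vals) >= 3) {
      kruskal_dunn(vals, comparisons = wildtype_label)
    } else if (length(vals) == 2) {
      mann_whitney(vals[[setdiff(names(vals), wildtype_label)]],
                   vals[[wildtype_label]])
    } else NULL
    abs_summ <- do.call(rbind, lapply(c("membrane_mean_", "cytoplasm_mean_"), function(pre) {
      v <- split(cells[[paste0(pre, rep)]][ok], cells$group[ok])
      do.call(rbind, lapply(names(v), function(l) {
        ci <- median_ci(v[[l]])
        data.frame(compartment = sub("_mean_$", "", pre), group = l, n = ci$n,
                   median = ci$median, ci_low = ci$lo, ci_high = ci$hi)
      }))
    }))
    list(reporter = rep, summary = summ, test = test, absolute = abs_summ)
  })
  names(per_rep) <- reporters
  structure(list(cells = cells, reporters = per_rep,
                 wildtype = wildtype_label),
            class = "cotransfection_study")
}

#' @export
print.cotransfection_study <- function(x, ...) {
  cat("Co-transfection study:", nrow(x$cells), "cells;",
      "wild type =", x$wildtype, "\n")
  for (rep in names(x$reporters)) {
    cat(sprintf("\nReporter '%s' localization ratio (wild-type median = 1):\n", rep))
    print(x$reporters[[rep]]$summary, row.names = FALSE, digits = 4)
    if (!is.null(x$reporters[[rep]]$test)) print(x$reporters[[rep]]$test)
  }
  invisible(x)
}

# serialize nested study results to plain lists for JSON
report_to_list <- function(x) {
  if (inherits(x, "popdc_comparison")) {
    return(list(test = x$test, statistic = x$statistic, p = x$p,
                comparisons = x$comparisons, flag = x$flag))
  }
  if (inherits(x, "segmentation_config")) return(unclass(x))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), report_to_list))
  x
}

#' Write a study report to disk
#'
#' Writes the per-object records as CSV and the summaries, tests and
#' configuration as a JSON report; output is byte-deterministic for a fixed
#' input, so seeded runs reproduce identical files.
#'
#' @param study a `biopsy_study` or `cotransfection_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  objects <- if (inherits(study, "biopsy_study")) study$fibers else study$cells
  csv <- file.path(dir, "records.csv")
  utils::write.csv(objects, csv, row.names = FALSE)
  rep <- report_to_list(study)
  rep$fibers <- NULL; rep$cells <- NULL
  json <- file.path(dir, "report.json")
  jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  invisible(c(records = csv, report = json))
}

#' Read back a JSON study report
#'
#' @param dir directory written by [write_study_report()].
#' @return list with `report` (parsed JSON) and `records` (data frame).
#' @export
read_study_report <- function(dir) {
  list(report = jsonlite::read_json(file.path(dir, "report.json"),
                                    simplifyVector = TRUE),
       records = utils::read.csv(file.path(dir, "records.csv")))
}
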