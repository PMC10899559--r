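#' Longest-diameter of a box-annotated lesion
#'
#' RECIST measures the longest in-plane diameter; for a box annotation this
#' is the longer box side times the in-plane pixel spacing.
#'
#' @param width,height Box sides in pixels.
#' @param spacing_mm In-plane pixel spacing, mm/pixel.
#' @return Diameter in mm (vectorised).
#' @export
lesion_diameter <- function(width, height, spacing_mm = 1) {
  pmax(width, height) * spacing_mm
}

assert_annotations <- function(ann) {
  req <- c("patient_id", "lesion_id", "site", "timepoint", "slice_index",
           "x", "y", "width", "height", "phase")
  miss <- setdiff(req, names(ann))
  if (length(miss)) abort(paste("annotation table lacks columns:", toString(miss)))
  bad <- which(ann$width <= 0 | ann$height <= 0)
  if (length(bad)) {
    abort(sprintf("annotation row %d (patient %s, lesion %s, timepoint %d) has a degenerate box.",
                  bad[1], ann$patient_id[bad[1]], ann$lesion_id[bad[1]],
                  ann$timepoint[bad[1]]))
  }
  if (any(ann$timepoint < 0 | ann$timepoint > 4)) {
    abort("`timepoint` must lie in 0..4 (0 = baseline).")
  }
  sizes <- ann |>
    group_by(.data$patient_id, .data$lesion_id) |>
    summarise(n_sizes = dplyr::n_distinct(paste(.data$width, .data$height)),
              .groups = "drop")
  if (any(sizes$n_sizes > 1)) {
    off <- sizes[sizes$n_sizes > 1, ][1, ]
    abort(sprintf("lesion %s of patient %s changes box size across timepoints; boxes must stay constant to preserve scale.",
                  off$lesion_id, off$patient_id))
  }
  invisible(ann)
}

# Contrast-phase policy: liver lesions use the venous phase only; other
# sites prefer venous and fall back to arterial.
select_phase <- function(ann) {
  pick <- function(df) {
    if (any(df$phase == "venous")) return(df[df$phase == "venous", , drop = FALSE])
    if (df$site[1] == "liver") return(df[0, , drop = FALSE])
    df[df$phase == "arterial", , drop = FALSE]
  }
  ann |>
    group_by(.data$patient_id, .data$lesion_id, .data$timepoint) |>
    dplyr::group_modify(~ pick(.x)) |>
    ungroup()
}

#' Load a cohort from annotation, image, marker and clinical files
#'
#' Assembles `patient_record` objects from the on-disk representation
#' written by [write_cohort()] (or produced by any annotation workflow using
#' the same schema). Lesions are ordered deterministically (primary first,
#' i.e. `lesion_id` 0, then by `lesion_id`); missing follow-ups and markers
#' are flagged, never imputed. An annotation pointing to an absent volume,
#' or a patient without baseline boxes, is a hard error.
#'
#' @param annotation_csv Path to the annotation CSV (schema as in
#'   [annotations_table()]).
#' @param image_dir Directory holding `<patient_id>_t<timepoint>.nii.gz`.
#' @param marker_csv Optional path to the long marker CSV
#'   (`patient_id`, `timepoint`, `marker`, `value`).
#' @param clinical_csv Path to the clinical CSV
#'   (`patient_id`, `sex`, `her2_status`, `therapy_line`, `os_months`, `event`).
#' @param n_timepoints_max Number of timepoint slots to allocate.
#' @return List of `patient_record` objects.
#' @export
load_cohort <- function(annotation_csv, image_dir, marker_csv = NULL,
                        clinical_csv, n_timepoints_max = 5) {
  ann <- readr::read_csv(annotation_csv, show_col_types = FALSE)
  assert_annotations(ann)
  ann <- select_phase(ann)
  clin <- readr::read_csv(clinical_csv, show_col_types = FALSE)
  mk <- if (!is.null(marker_csv) && file.exists(marker_csv)) {
    readr::read_csv(marker_csv, show_col_types = FALSE)
  } else {
    tibble(patient_id = character(), timepoint = integer(),
           marker = character(), value = double())
  }
  records <- list()
  for (pid in unique(ann$patient_id)) {
    pa <- ann[ann$patient_id == pid, ]
    if (!any(pa$timepoint == 0)) {
      abort(sprintf("patient %s has no baseline boxes.", pid))
    }
    tps <- sort(unique(pa$timepoint))
    present <- rep(FALSE, n_timepoints_max)
    present[tps + 1L] <- TRUE
    vols <- vector("list", n_timepoints_max)
    spacing <- 1
    for (t0 in tps) {
      f <- file.path(image_dir, sprintf("%s_t%d.nii.gz", pid, t0))
      if (!file.exists(f)) {
        abort(sprintf("annotation references missing volume '%s'.", f))
      }
      img <- RNifti::readNifti(f)
      spacing <- RNifti::pixdim(img)[1]
      vols[[t0 + 1L]] <- as.array(img)
    }
    les_meta <- pa |>
      distinct(.data$lesion_id, .data$site, .data$slice_index, .data$x,
               .data$y, .data$width, .data$height, .data$phase) |>
      arrange(.data$lesion_id)
    lesions <- lapply(seq_len(nrow(les_meta)), function(i) {
      m <- les_meta[i, ]
      list(lesion_id = m$lesion_id, site = m$site,
           is_primary = m$lesion_id == 0L, phase = m$phase,
           box = c(x = m$x, y = m$y, width = m$width, height = m$height),
           slice_index = m$slice_index)
    })
    crow <- clin[clin$patient_id == pid, ]
    if (nrow(crow) != 1) abort(sprintf("patient %s missing from clinical table.", pid))
    pm <- mk[!is.na(mk$patient_id) & mk$patient_id == pid & !is.na(mk$timepoint), ]
    records[[length(records) + 1L]] <- new_patient_record(
      pid,
      tibble(sex = crow$sex, her2_status = crow$her2_status,
             therapy_line = crow$therapy_line),
      crow$os_months, crow$event, present, lesions,
      select(pm, "timepoint", "marker", "value"),
      vols, dim(vols[[1]])[1], spacing)
  }
  records
}

#' Per-marker normalisation statistics
#'
#' Mean and standard deviation per marker over the non-missing entries;
#' compute these on the training cohort only and apply them everywhere.
#'
#' @param marker_table Long tibble with `marker` and `value` columns.
#' @return Tibble with `marker`, `mean`, `sd`.
#' @export
marker_stats <- function(marker_table) {
  marker_table |>
    filter(!is.na(.data$value)) |>
    group_by(.data$marker) |>
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              .groups = "drop")
}

#' Normalise marker values with training-cohort statistics
#'
#' Applies `(value - mean) / sd` per marker; missing entries stay missing.
#' A marker with zero variance in the statistics is an error (it carries no
#' information and would divide by zero).
#'
#' @param marker_table Long tibble with `marker` and `value` columns.
#' @param stats Per-marker statistics from [marker_stats()], computed on the
#'   training cohort.
#' @return `marker_table` with `value` replaced by its z-score.
#' @export
normalize_markers <- function(marker_table, stats) {
  bad <- stats$marker[is.na(stats$sd) | stats$sd <= 0]
  if (length(bad)) {
    abort(sprintf("marker '%s' has zero variance in the training statistics.", bad[1]))
  }
  unknown <- setdiff(unique(marker_table$marker), stats$marker)
  if (length(unknown)) {
    abort(sprintf("no training statistics for marker '%s'.", unknown[1]))
  }
  marker_table |>
    left_join(stats, by = "marker") |>
    mutate(value = (.data$value - .data$mean) / .data$sd) |>
    select(-"mean", -"sd")
}

#' Select target lesions from baseline annotations
#'
#' Keeps lesions whose baseline longest diameter exceeds 10 mm; if more than
#' `max_targets` qualify, the largest `max_targets` are kept (ties broken by
#' ascending `lesion_id`). The primary lesion (`lesion_id` 0) is always kept
#' regardless of size and does not count against the target budget.
#'
#' @param baseline_annotations Annotation tibble restricted to (or
#'   containing) `timepoint == 0` rows; may cover several patients.
#' @param spacing_mm Pixel spacing used to convert box sides to mm.
#' @param max_targets Maximum number of target lesions (default 5).
#' @param min_diameter_mm Measurability threshold (default 10 mm, exclusive).
#' @return The selected baseline annotation rows, with a `diameter_mm`
#'   column, ordered primary-first then by decreasing diameter.
#' @export
select_target_lesions <- function(baseline_annotations, spacing_mm = 1,
                                  max_targets = 5, min_diameter_mm = 10) {
  bl <- baseline_annotations |>
    filter(.data$timepoint == 0) |>
    mutate(diameter_mm = lesion_diameter(.data$width, .data$height, spacing_mm))
  pick <- function(df) {
    primary <- df[df$lesion_id == 0L, , drop = FALSE]
    targets <- df[df$lesion_id != 0L & df$diameter_mm > min_diameter_mm, , drop = FALSE]
    targets <- targets[order(-targets$diameter_mm, targets$lesion_id), , drop = FALSE]
    targets <- head(targets, max_targets)
    bind_rows(primary, targets)
  }
  bl |>
    group_by(.data$patient_id) |>
    dplyr::group_modify(~ pick(.x)) |>
    ungroup()
}
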