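#' RECIST v1.1 response category from target-lesion diameter sums
#'
#' Classifies the change in the sum of target-lesion longest diameters
#' between baseline and a follow-up: `CR` when the follow-up sum is zero,
#' `PD` when the sum increased by at least 20% AND at least 5 mm absolute,
#' or a new lesion appeared; `PR` when the sum decreased by at least 30%;
#' otherwise `SD`. Vectorised.
#'
#' @param diameter_sum_base Baseline diameter sum, mm (> 0).
#' @param diameter_sum_follow Follow-up diameter sum, mm (>= 0).
#' @param new_lesion Logical: unequivocal new lesion present (an input
#'   flag, not detected from images).
#' @return Factor with levels `CR`, `PR`, `SD`, `PD`.
#' @export
recist_classify <- function(diameter_sum_base, diameter_sum_follow,
                            new_lesion = FALSE) {
  if (any(diameter_sum_base <= 0)) abort("baseline diameter sum must be positive.")
  if (any(diameter_sum_follow < 0)) abort("diameters cannot be negative.")
  n <- max(length(diameter_sum_base), length(diameter_sum_follow))
  b <- rep_len(diameter_sum_base, n)
  f <- rep_len(diameter_sum_follow, n)
  nl <- rep_len(new_lesion, n)
  pct <- 100 * (f - b) / b
  out <- rep("SD", n)
  out[pct <= -30] <- "PR"
  out[f == 0] <- "CR"
  out[(pct >= 20 & (f - b) >= 5) | nl] <- "PD"
  factor(out, levels = c("CR", "PR", "SD", "PD"))
}

#' Tumour-burden change between two scans
#'
#' Percentage change of the summed target-lesion area:
#' `100 * (sum(follow) - sum(base)) / sum(base)`. Scale-invariant in the
#' areas.
#'
#' @param areas_base Baseline target-lesion areas, mm^2 (sum > 0).
#' @param areas_follow Follow-up areas, mm^2.
#' @return Percent change (scalar).
#' @export
tb_delta <- function(areas_base, areas_follow) {
  if (length(areas_base) == 0 || sum(areas_base) <= 0) {
    abort("baseline areas must be nonempty with positive sum.")
  }
  100 * (sum(areas_follow) - sum(areas_base)) / sum(areas_base)
}

# 3x3 box blur (edge-replicated) used to stabilise the half-way threshold
# against HU noise before measuring lesion extent.
blur3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  up <- function(i, n) pmin(pmax(i, 1), n)
  acc <- matrix(0, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    acc <- acc + m[up(seq_len(n1) + di, n1), up(seq_len(n2) + dj, n2)]
  }
  acc / 9
}

measure_one <- function(volume, les, t, spacing) {
  slice <- volume[, , les$slice_index]
  # a wide context (2.5-fold the box) so the border stays background even
  # for lesions that have outgrown their baseline box
  box <- expand_box(les$box, factor = 2.5, image_bounds = dim(slice))
  roi <- blur3(blur3(crop_box(slice, box)))
  n1 <- nrow(roi); n2 <- ncol(roi)
  # background from the ROI border; foreground at the strongest central
  # response (box rounding can shift the nominal centre by a pixel)
  bg <- median(c(roi[1, ], roi[n1, ], roi[, 1], roi[, n2]))
  ii <- max(1, round(n1 / 3)):min(n1, round(2 * n1 / 3))
  jj <- max(1, round(n2 / 3)):min(n2, round(2 * n2 / 3))
  dev <- abs(roi[ii, jj] - bg)
  pk <- which(dev == max(dev), arr.ind = TRUE)[1, ]
  ci <- ii[pk[1]]; cj <- jj[pk[2]]
  fg <- roi[ci, cj]
  if (abs(fg - bg) < 10) {
    # centre indistinguishable from background: lesion below measurability
    return(tibble(diameter_mm = 0, area_mm2 = 0))
  }
  mask <- abs(roi - fg) < abs(roi - bg)
  # lesion extents along the central cross-sections (the lesion is centred
  # in its box), with subpixel interpolation of the half-contrast crossing
  thr <- (fg + bg) / 2
  half_width <- function(v, c0, step) {
    k <- c0
    while (TRUE) {
      nk <- k + step
      if (nk < 1 || nk > length(v)) return(abs(k - c0) + 0.5)
      inside_k <- (v[k] - thr) * (fg - bg) > 0
      inside_nk <- (v[nk] - thr) * (fg - bg) > 0
      if (inside_k && !inside_nk) {
        frac <- (thr - v[k]) / (v[nk] - v[k])
        return(abs(k - c0) + max(min(frac, 1), 0))
      }
      if (!inside_k) return(abs(k - c0))
      k <- nk
    }
  }
  ext1 <- half_width(roi[, cj], ci, -1L) + half_width(roi[, cj], ci, 1L)
  ext2 <- half_width(roi[ci, ], cj, -1L) + half_width(roi[ci, ], cj, 1L)
  tibble(diameter_mm = max(ext1, ext2) * spacing,
         area_mm2 = sum(mask) * spacing^2)
}

#' Measure lesion extent on the images at every available timepoint
#'
#' Bounding boxes keep their baseline size across timepoints to preserve
#' scale information, so response must be measured on the image itself:
#' inside 1.5-fold the box, pixels are classified as lesion when closer to
#' the centre (foreground) HU than to the border (background) HU after a
#' 3x3 smoothing, and the longest in-plane extent and pixel area of that
#' mask are returned in mm / mm^2.
#'
#' @param records List of `patient_record` objects with volumes.
#' @return Tibble: `patient_id`, `lesion_id`, `site`, `timepoint`,
#'   `diameter_mm`, `area_mm2`.
#' @export
measure_lesions <- function(records) {
  rows <- list()
  for (rec in records) {
    for (les in rec$lesions) {
      for (t in which(rec$timepoints_present)) {
        m <- measure_one(rec$volumes[[t]], les, t, rec$spacing_mm)
        rows[[length(rows) + 1L]] <- tibble(
          patient_id = rec$patient_id, lesion_id = les$lesion_id,
          site = les$site, timepoint = t - 1L,
          diameter_mm = m$diameter_mm, area_mm2 = m$area_mm2)
      }
    }
  }
  bind_rows(rows)
}

#' RECIST and tumour-burden assessment for each patient
#'
#' Compares baseline with the second follow-up when available, otherwise
#' with the first follow-up (recorded in `reference_timepoint`); patients
#' with no follow-up get `NA` assessments and a flag. Target lesions are
#' the baseline-selected measurable lesions (longest diameter > 10 mm, at
#' most five, plus the primary).
#'
#' @param measurements Tibble from [measure_lesions()] (or the same schema
#'   from any measurement source), optionally with a logical `new_lesion`
#'   column per patient-timepoint.
#' @param max_targets Passed to the target-lesion rule.
#' @return Tibble: `patient_id`, `recist`, `tb_delta`,
#'   `reference_timepoint` (`"1F"`/`"2F"`/`NA`).
#' @export
assess_response <- function(measurements, max_targets = 5) {
  res <- list()
  for (pid in unique(measurements$patient_id)) {
    pm <- measurements[measurements$patient_id == pid, ]
    bl <- pm[pm$timepoint == 0, ]
    if (nrow(bl) == 0) abort(sprintf("patient %s has no baseline measurements.", pid))
    bl_np <- bl[bl$lesion_id != 0 & bl$diameter_mm > 10, ]
    bl_np <- bl_np[order(-bl_np$diameter_mm, bl_np$lesion_id), ]
    targets <- c(bl$lesion_id[bl$lesion_id == 0], head(bl_np$lesion_id, max_targets))
    ref <- if (any(pm$timepoint == 2)) 2L else if (any(pm$timepoint == 1)) 1L else NA_integer_
    if (is.na(ref)) {
      res[[length(res) + 1L]] <- tibble(patient_id = pid,
                                        recist = factor(NA, levels = c("CR", "PR", "SD", "PD")),
                                        tb_delta = NA_real_,
                                        reference_timepoint = NA_character_)
      next
    }
    fu <- pm[pm$timepoint == ref & pm$lesion_id %in% targets, ]
    bl_t <- bl[bl$lesion_id %in% targets, ]
    new_les <- if ("new_lesion" %in% names(pm)) any(pm$new_lesion[pm$timepoint == ref]) else FALSE
    res[[length(res) + 1L]] <- tibble(
      patient_id = pid,
      recist = recist_classify(sum(bl_t$diameter_mm), sum(fu$diameter_mm), new_les),
      tb_delta = tb_delta(bl_t$area_mm2, fu$area_mm2),
      reference_timepoint = sprintf("%dF", ref))
  }
  bind_rows(res)
}
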