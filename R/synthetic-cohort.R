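#' Default anatomic-site palette for the phantom cohort
#'
#' Background/foreground HU statistics and sampling probabilities for the
#' four most frequent metastatic sites in HER2-positive gastric cancer:
#' stomach (the primary, never sampled as a target), lymph node, liver and
#' lung. Liver metastases are rendered hypodense against bright parenchyma;
#' lung lesions sit on an air background near -800 HU.
#'
#' @return A tibble with columns `site`, `bg_mean`, `bg_sd`, `fg_mean`,
#'   `fg_sd`, `prob` (target-site sampling probability).
#' @export
default_site_palette <- function() {
  tibble(
    site    = c("stomach", "lymph_node", "liver", "lung"),
    bg_mean = c(0, -90, 70, -800),   # lumen/fluid, perinodal fat, parenchyma, air
    bg_sd   = c(12, 12, 10, 40),
    fg_mean = c(60, 50, 40, 45),
    fg_sd   = c(8, 8, 8, 8),
    prob    = c(0, 0.55, 0.40, 0.05)
  )
}

#' Configuration for the phantom cohort generator
#'
#' Defines the study conditions the simulator emulates: 1-5 target lesions
#' plus one primary per patient, up to 5 timepoints (baseline + 4
#' follow-ups), baseline longest diameters above 10 mm, monotone missing
#' follow-ups, site-dependent background HU, noisy longitudinal tumour
#' markers, and right-censored Weibull survival whose log-hazard is
#' proportional to a latent per-patient risk.
#'
#' @param n_patients Number of patients.
#' @param n_timepoints_max Scans per patient including baseline (<= 5).
#' @param lesion_count_range Min/max number of target lesions (max <= 5);
#'   one primary is always added.
#' @param baseline_diameter_range Baseline longest-diameter range in mm;
#'   minimum must exceed 10 mm.
#' @param followup_missing_prob Per-visit probability that a follow-up is
#'   missed; missingness is monotone (a missed visit ends the series).
#' @param censoring_rate Target marginal fraction of censored patients; an
#'   exponential censoring rate is calibrated against the drawn survival
#'   times to hit it.
#' @param hazard_coef Effect of the latent risk on the log hazard.
#' @param growth_coef Per-timepoint log-diameter drift per unit latent risk
#'   (high risk grows, low risk shrinks under treatment).
#' @param growth_sd Per-step log-diameter noise.
#' @param mean_drift Average per-step log-diameter drift (slightly negative:
#'   treatment shrinks the average lesion).
#' @param baseline_risk_effect Log-diameter shift per unit latent risk at
#'   baseline (weak baseline-burden signal).
#' @param image_size In-plane side of rendered volumes, pixels.
#' @param spacing_mm In-plane pixel spacing, mm/pixel.
#' @param noise_sd HU noise added to rendered slices.
#' @param n_markers Number of tumour-marker channels.
#' @param marker_missing_prob Extra per-entry marker missingness.
#' @param weibull_shape,weibull_scale Baseline Weibull survival parameters
#'   (months); scale 14 and shape 1.3 put the median OS near 12 months at
#'   average risk.
#' @param site_palette Site palette, see [default_site_palette()].
#' @param seed Integer seed; cohorts are bit-reproducible given the seed.
#' @return A `phantom_config` object (validated list).
#' @export
phantom_config <- function(n_patients = 100,
                           n_timepoints_max = 5,
                           lesion_count_range = c(1, 5),
                           baseline_diameter_range = c(12, 40),
                           followup_missing_prob = 0.2,
                           censoring_rate = 0.25,
                           hazard_coef = 1.0,
                           growth_coef = 0.18,
                           growth_sd = 0.06,
                           mean_drift = -0.04,
                           baseline_risk_effect = 0.08,
                           image_size = 64,
                           spacing_mm = 2.5,
                           noise_sd = 12,
                           n_markers = 3,
                           marker_missing_prob = 0.1,
                           weibull_shape = 1.3,
                           weibull_scale = 14,
                           site_palette = default_site_palette(),
                           seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 1) abort("`n_patients` must be positive.")
  if (cfg$n_timepoints_max < 1 || cfg$n_timepoints_max > 5) {
    abort("`n_timepoints_max` must be between 1 and 5.")
  }
  if (cfg$lesion_count_range[2] > 5) {
    abort("at most 5 target lesions are supported (plus the primary).")
  }
  if (cfg$lesion_count_range[1] < 1) abort("`lesion_count_range` minimum must be >= 1.")
  for (p in c("followup_missing_prob", "censoring_rate", "marker_missing_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(sprintf("`%s` must be in [0, 1].", p))
  }
  if (cfg$baseline_diameter_range[1] <= 10) {
    abort("baseline diameters must exceed 10 mm (measurable target lesions).")
  }
  structure(cfg, class = "phantom_config")
}

#' Render one phantom lesion as a 3-slice HU mini-volume
#'
#' Draws an elliptical soft blob with site-appropriate foreground HU on a
#' noisy site-appropriate background (lung near -800 HU, abdominal sites
#' near 0-100 HU). The central slice carries the full cross-section; the two
#' neighbouring slices a reduced one. Blob pixel count scales with the
#' squared diameter. Uses the current RNG state; identical states give
#' identical arrays.
#'
#' @param diameter_mm Longest in-plane diameter, mm; must be positive.
#' @param site Site name present in `palette`.
#' @param noise_sd Background HU noise standard deviation.
#' @param size_px Slice side in pixels.
#' @param spacing_mm Pixel spacing mm/pixel.
#' @param eccentricity Ratio of short to long ellipse axis in (0, 1]; drawn
#'   uniformly from `[0.7, 1]` when `NULL`.
#' @param palette Site palette, see [default_site_palette()].
#' @return Integer HU array `size_px x size_px x 3`.
#' @export
render_lesion_patch <- function(diameter_mm, site, noise_sd = 12,
                                size_px = 64, spacing_mm = 2.5,
                                eccentricity = NULL,
                                palette = default_site_palette()) {
  if (!is.numeric(diameter_mm) || diameter_mm <= 0) {
    abort("`diameter_mm` must be positive.")
  }
  row <- palette[palette$site == site, ]
  if (nrow(row) != 1) abort(sprintf("unknown anatomic site '%s'.", site))
  if (is.null(eccentricity)) eccentricity <- runif(1, 0.7, 1)
  a <- diameter_mm / 2 / spacing_mm
  b <- a * eccentricity
  cx <- (size_px + 1) / 2
  cy <- (size_px + 1) / 2
  gx <- matrix(seq_len(size_px), size_px, size_px)
  gy <- t(gx)
  bg <- rnorm(1, row$bg_mean, row$bg_sd / 4)
  fg <- rnorm(1, row$fg_mean, row$fg_sd)
  out <- array(0L, c(size_px, size_px, 3))
  scale_k <- c(0.72, 1, 0.72)  # partial-volume shrink on neighbouring slices
  for (k in 1:3) {
    r2 <- ((gx - cx) / (a * scale_k[k]))^2 + ((gy - cy) / (b * scale_k[k]))^2
    blob <- 1 / (1 + exp((r2 - 1) * 6))  # soft ellipse edge
    hu <- bg + (fg - bg) * blob + rnorm(size_px * size_px, 0, noise_sd)
    out[, , k] <- as.integer(round(hu))
  }
  out
}

# Exponential censoring rate calibrated so that the expected censored
# fraction over the drawn survival times matches the target.
calibrate_censoring_rate <- function(surv_times, target) {
  if (target <= 0) return(0)
  f <- function(r) mean(1 - exp(-r * surv_times)) - target
  uniroot(f, lower = 1e-8, upper = 1e4, tol = 1e-10)$root
}

new_patient_record <- function(patient_id, clinical, os_months, event,
                               timepoints_present, lesions, markers, volumes,
                               image_size, spacing_mm) {
  structure(list(patient_id = patient_id, clinical = clinical,
                 os_months = os_months, event = event,
                 timepoints_present = timepoints_present,
                 lesions = lesions, markers = markers, volumes = volumes,
                 image_size = image_size, spacing_mm = spacing_mm),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %d lesions, %d/%d timepoints, OS %.1f mo (event=%d)\n",
              x$patient_id, length(x$lesions), sum(x$timepoints_present),
              length(x$timepoints_present), x$os_months, x$event))
  invisible(x)
}

#' Simulate a phantom cohort with known latent risk
#'
#' Generates `n_patients` phantom patients: a latent risk `z ~ N(0, 1)`
#' drives (i) a Weibull proportional-hazards survival time with log-hazard
#' `hazard_coef * z`, (ii) per-lesion multiplicative diameter dynamics
#' (growth at high risk, shrinkage at low risk), and (iii) monotone noisy
#' tumour-marker trajectories. Each patient gets one primary (stomach) plus
#' 1-5 target lesions; follow-ups drop out monotonically; censoring is
#' calibrated to the requested marginal rate.
#'
#' @param config A [phantom_config()].
#' @return A list with `records` (list of `patient_record`) and `truth`
#'   (tibble: `patient_id`, `latent_risk`, `true_survival_time`,
#'   `censoring_time`, `os_months`, `event`, `growth_rates` list-column).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  z <- rnorm(n)
  u <- runif(n)
  # Weibull PH: S(t) = exp(-(t/scale)^shape * exp(beta z))
  t_true <- cfg$weibull_scale *
    (-log(u) / exp(cfg$hazard_coef * z))^(1 / cfg$weibull_shape)
  cens_rate <- calibrate_censoring_rate(t_true, cfg$censoring_rate)
  c_time <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  os <- pmin(t_true, c_time)
  event <- as.integer(t_true < c_time)

  tp_max <- cfg$n_timepoints_max
  pal <- cfg$site_palette
  target_sites <- pal$site[pal$prob > 0]
  target_prob <- pal$prob[pal$prob > 0]

  records <- vector("list", n)
  growth_list <- vector("list", n)
  for (p in seq_len(n)) {
    pid <- sprintf("P%04d", p)
    clinical <- tibble(
      sex = sample(c("male", "female"), 1, prob = c(0.77, 0.23)),
      her2_status = sample(c("3+", "2+/FISH+"), 1, prob = c(0.75, 0.25)),
      therapy_line = sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
    )
    present <- rep(FALSE, tp_max)
    present[1] <- TRUE
    for (t in seq_len(tp_max - 1) + 1) {
      if (!present[t - 1]) break
      present[t] <- runif(1) > cfg$followup_missing_prob
    }
    n_target <- sample(seq(cfg$lesion_count_range[1], cfg$lesion_count_range[2]), 1)
    sites <- c("stomach",
               sample(target_sites, n_target, replace = TRUE, prob = target_prob))
    n_les <- length(sites)
    lesions <- vector("list", n_les)
    rates <- numeric(n_les)
    vols <- vector("list", tp_max)
    for (t in which(present)) {
      vols[[t]] <- array(0L, c(cfg$image_size, cfg$image_size, 3L * n_les))
    }
    rng <- cfg$baseline_diameter_range
    for (l in seq_len(n_les)) {
      d0 <- exp(runif(1, log(rng[1]), log(rng[2]))) *
        exp(cfg$baseline_risk_effect * z[p])
      d0 <- min(max(d0, rng[1]), rng[2])
      rate <- cfg$mean_drift + cfg$growth_coef * z[p]
      rates[l] <- rate
      d <- numeric(tp_max)
      d[1] <- d0
      for (t in 2:tp_max) {
        # growth slows as lesions approach ~75 mm (saturating, Gompertz-like)
        eff <- if (rate > 0) rate * max(0, 1 - d[t - 1] / 75) else rate
        d[t] <- exp(log(d[t - 1]) + eff + rnorm(1, 0, cfg$growth_sd))
      }
      ecc <- runif(1, 0.7, 1)
      w_px <- max(3L, as.integer(round(d0 / cfg$spacing_mm)))
      h_px <- max(3L, as.integer(round(d0 * ecc / cfg$spacing_mm)))
      box <- c(x = (cfg$image_size - w_px) / 2,
               y = (cfg$image_size - h_px) / 2,
               width = w_px, height = h_px)
      for (t in which(present)) {
        band <- render_lesion_patch(d[t], sites[l], noise_sd = cfg$noise_sd,
                                    size_px = cfg$image_size,
                                    spacing_mm = cfg$spacing_mm,
                                    eccentricity = ecc, palette = pal)
        vols[[t]][, , (3L * (l - 1L) + 1L):(3L * l)] <- band
      }
      lesions[[l]] <- list(lesion_id = l - 1L, site = sites[l],
                           is_primary = l == 1L, phase = "venous",
                           eccentricity = ecc, box = box,
                           slice_index = 3L * (l - 1L) + 2L,
                           diameters_mm = ifelse(present, d, NA_real_))
    }
    growth_list[[p]] <- rates
    mk <- list()
    base_level <- runif(cfg$n_markers, 0.5, 1.5)
    slope <- runif(cfg$n_markers, 0.35, 0.65)
    for (t in which(present)) {
      for (m in seq_len(cfg$n_markers)) {
        val <- if (runif(1) < cfg$marker_missing_prob) NA_real_ else
          exp(base_level[m] + slope[m] * z[p] * (0.4 + 0.15 * (t - 1)) +
                rnorm(1, 0, 0.25))
        mk[[length(mk) + 1L]] <- tibble(timepoint = t - 1L,
                                        marker = sprintf("marker_%d", m),
                                        value = val)
      }
    }
    markers <- if (length(mk)) bind_rows(mk) else
      tibble(timepoint = integer(), marker = character(), value = double())
    records[[p]] <- new_patient_record(pid, clinical, os[p], event[p],
                                       present, lesions, markers, vols,
                                       cfg$image_size, cfg$spacing_mm)
  }
  truth <- tibble(
    patient_id = map(records, "patient_id") |> unlist(),
    latent_risk = z,
    true_survival_time = t_true,
    censoring_time = c_time,
    os_months = os,
    event = event,
    growth_rates = growth_list
  )
  list(records = records, truth = truth)
}

#' Annotation table for a set of patient records
#'
#' One row per lesion per available timepoint: the bounding box (constant
#' across timepoints for a given lesion, preserving scale information), the
#' anatomic site, the 1-based slice index of the lesion's central slice and
#' the contrast phase. Timepoints are 0-based (0 = baseline, 1 = first
#' follow-up, ...).
#'
#' @param records List of `patient_record` objects.
#' @return A tibble with columns `patient_id`, `lesion_id`, `site`,
#'   `timepoint`, `slice_index`, `x`, `y`, `width`, `height`, `phase`.
#' @export
annotations_table <- function(records) {
  rows <- list()
  for (rec in records) {
    for (les in rec$lesions) {
      for (t in which(rec$timepoints_present)) {
        rows[[length(rows) + 1L]] <- tibble(
          patient_id = rec$patient_id, lesion_id = les$lesion_id,
          site = les$site, timepoint = t - 1L,
          slice_index = les$slice_index,
          x = les$box[["x"]], y = les$box[["y"]],
          width = les$box[["width"]], height = les$box[["height"]],
          phase = les$phase)
      }
    }
  }
  bind_rows(rows)
}

#' @rdname annotations_table
#' @details `markers_table()` and `clinical_table()` extract the long
#'   marker table and the per-patient clinical/outcome table in the same
#'   schemas that [write_cohort()] writes.
#' @export
markers_table <- function(records) {
  bind_rows(lapply(records, function(rec) {
    if (nrow(rec$markers) == 0) {
      tibble(patient_id = rec$patient_id, timepoint = NA_integer_,
             marker = NA_character_, value = NA_real_)
    } else {
      mutate(rec$markers, patient_id = rec$patient_id, .before = 1)
    }
  }))
}

#' @rdname annotations_table
#' @export
clinical_table <- function(records) {
  bind_rows(lapply(records, function(rec) {
    tibble(patient_id = rec$patient_id,
           sex = rec$clinical$sex, her2_status = rec$clinical$her2_status,
           therapy_line = rec$clinical$therapy_line,
           os_months = rec$os_months, event = rec$event)
  }))
}

#' Write a phantom cohort to disk
#'
#' Writes per-patient per-timepoint NIfTI volumes (`images/<pid>_t<t>.nii.gz`,
#' int16 HU), `annotations.csv`, `markers.csv`, `clinical.csv` and, when
#' ground truth is supplied, `truth.csv`. The file set round-trips through
#' [load_cohort()].
#'
#' @param records List of `patient_record` objects (nonempty).
#' @param out_dir Output directory (created if needed).
#' @param truth Optional truth tibble from [simulate_cohort()].
#' @return Invisibly, `out_dir`.
#' @export
write_cohort <- function(records, out_dir, truth = NULL) {
  if (length(records) == 0) abort("`records` must be nonempty.")
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) abort(sprintf("cannot create '%s'.", img_dir))
  for (rec in records) {
    for (t in which(rec$timepoints_present)) {
      f <- file.path(img_dir, sprintf("%s_t%d.nii.gz", rec$patient_id, t - 1L))
      img <- RNifti::asNifti(rec$volumes[[t]])
      RNifti::pixdim(img) <- c(rec$spacing_mm, rec$spacing_mm, 1)
      RNifti::writeNifti(img, f, datatype = "int16")
    }
  }
  readr::write_csv(annotations_table(records), file.path(out_dir, "annotations.csv"))
  readr::write_csv(markers_table(records), file.path(out_dir, "markers.csv"))
  readr::write_csv(clinical_table(records), file.path(out_dir, "clinical.csv"))
  if (!is.null(truth)) {
    readr::write_csv(select(truth, -"growth_rates"), file.path(out_dir, "truth.csv"))
  }
  invisible(out_dir)
}
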