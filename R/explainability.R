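#' Attention importance report for a cohort
#'
#' Summarises the last attention layer of each level: per-timepoint
#' importance (how much valid queries attend to each timepoint, averaged
#' over heads and lesions, renormalised to sum to 1) and a site-by-site
#' matrix of mean inter-lesion attention (rows renormalised over the
#' lesion tokens, so a single-lesion patient yields a 1x1 entry of 1).
#' Reported separately for the high- and low-risk groups defined by the
#' frozen cutoff. Extraction is a pure read-out of the forward pass: the
#' risks returned here are bit-identical to [predict_cohort()].
#'
#' @param model A trained [risk_model()].
#' @param records Cohort records (or supply `feats`).
#' @param cutoff Risk cutoff defining high/low groups (default 0.5).
#' @param horizon Follow-up horizon, as in [predict_cohort()].
#' @param stats Marker statistics for marker models.
#' @param feats Optional precomputed [cohort_features()].
#' @return An `attention_report`: `temporal` (tibble `group`, `timepoint`,
#'   `weight`), `organ` (tibble `group`, `site_from`, `site_to`, `weight`),
#'   `per_patient` (tibble with `patient_id`, `risk`, `group`).
#' @export
extract_attention <- function(model, records = NULL, cutoff = 0.5,
                              horizon = "2F", stats = NULL, feats = NULL) {
  if (is.null(feats)) feats <- cohort_features(model, records, stats = stats)
  fr <- truncate_features(feats, horizon_to_followups(horizon))
  fwd <- model_forward(model, fr$F, fr$obj_mask, fr$tp_mask)
  P <- fwd$dims$P; O <- fwd$dims$O; T <- fwd$dims$T
  H <- model$config$n_heads
  group <- ifelse(fwd$risk > cutoff, "high", "low")
  m2 <- fr$tp_mask; dim(m2) <- c(P * O, T)
  # temporal importance: attention received by each timepoint, averaged
  # over heads and valid queries of every valid lesion, per patient
  th <- fwd$th_attn  # (P*O, T, T, H)
  temp_pp <- matrix(0, P, T)
  for (p in seq_len(P)) {
    acc <- numeric(T); wt <- 0
    for (o in which(fr$obj_mask[p, ])) {
      n <- (o - 1L) * P + p
      for (i in which(m2[n, ])) for (h in seq_len(H)) {
        acc <- acc + th[n, i, , h]
        wt <- wt + 1
      }
    }
    if (wt > 0) temp_pp[p, ] <- acc / sum(acc)
  }
  temporal <- bind_rows(lapply(unique(group), function(gv) {
    w <- colMeans(temp_pp[group == gv, , drop = FALSE])
    tibble(group = gv, timepoint = seq_len(T) - 1L, weight = w / sum(w))
  }))
  # organ matrix: OH last layer, object-to-object attention renormalised
  # over object tokens, averaged over heads, pooled by site pair
  oh <- fwd$oh_attn  # (P, O+1, O+1, H)
  rows <- list()
  for (p in seq_len(P)) {
    vo <- which(fr$obj_mask[p, ])
    for (i in vo) {
      wrow <- rep(0, O)
      for (h in seq_len(H)) wrow <- wrow + oh[p, i + 1L, 1L + seq_len(O), h]
      wrow <- wrow[vo]
      if (sum(wrow) > 0) wrow <- wrow / sum(wrow)
      for (k in seq_along(vo)) {
        rows[[length(rows) + 1L]] <- tibble(
          group = group[p], site_from = feats$sites[p, i],
          site_to = feats$sites[p, vo[k]], weight = wrow[k])
      }
    }
  }
  organ <- bind_rows(rows) |>
    group_by(.data$group, .data$site_from, .data$site_to) |>
    summarise(weight = mean(.data$weight), .groups = "drop")
  structure(list(temporal = temporal, organ = organ,
                 per_patient = tibble(patient_id = feats$patient_id,
                                      risk = fwd$risk, group = group),
                 cutoff = cutoff),
            class = "attention_report")
}

#' @export
print.attention_report <- function(x, ...) {
  cat(sprintf("<attention_report> %d patients (%d high-risk at cutoff %.3f)\n",
              nrow(x$per_patient), sum(x$per_patient$group == "high"), x$cutoff))
  invisible(x)
}

#' Grad-CAM heatmap for one lesion patch
#'
#' Gradient-weighted class activation map: the gradient of the chosen class
#' logit with respect to the final convolutional feature maps weights those
#' maps channel-wise; the rectified weighted sum is upsampled to the patch
#' size and max-normalised to `[0, 1]`. High-response regions mark pixels
#' the model's risk output depends on. The patch is scored as a
#' single-lesion forward pass at its own timepoint so the gradient path
#' includes both attention levels.
#'
#' @param model A trained image [risk_model()].
#' @param patch An `image_patch` from [build_patch()].
#' @param target_class `"poor"` (default) or `"good"`.
#' @return A `heatmap`: list with `array` (patch-sized, in `[0, 1]`),
#'   `lesion_id`, `timepoint`, `all_zero` flag.
#' @export
gradcam <- function(model, patch, target_class = c("poor", "good")) {
  target_class <- match.arg(target_class)
  stopifnot(inherits(patch, "image_patch"))
  cfg <- model$config
  ex <- extract_features(model, patch, return_maps = TRUE)
  T <- cfg$n_timepoints
  t_idx <- min(max(1L, as.integer(patch$timepoint %||% 0) + 1L), T)
  F <- array(0, c(1, 1, T, cfg$d_feat))
  F[1, 1, t_idx, ] <- ex$feat
  tp_mask <- array(FALSE, c(1, 1, T)); tp_mask[1, 1, t_idx] <- TRUE
  fwd <- model_forward(model, F, matrix(TRUE, 1, 1), tp_mask, collect = TRUE)
  dlog <- matrix(0, 1, 2)
  dlog[1, if (target_class == "poor") 1 else 2] <- 1
  g <- model_backward(model, fwd, dlog, want_dF = TRUE)
  hw <- prod(dim(ex$maps)[1:2])
  alpha <- g$dF[1, 1, t_idx, ] / hw    # d logit / d feature-map pixel
  cam <- matrix(0, dim(ex$maps)[1], dim(ex$maps)[2])
  for (k in seq_len(dim(ex$maps)[3])) cam <- cam + alpha[k] * ex$maps[, , k]
  cam <- pmax(cam, 0)
  all_zero <- max(cam) <= 0
  if (all_zero) {
    warn("Grad-CAM map is identically zero (no positive gradient response).")
  }
  up <- pmax(resize_bilinear(cam, dim(patch$array)[1]), 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(array = up, lesion_id = patch$lesion_id,
                 timepoint = patch$timepoint, all_zero = all_zero),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap> lesion %s, timepoint %s, %d x %d%s\n",
              x$lesion_id, x$timepoint, nrow(x$array), ncol(x$array),
              if (x$all_zero) " (all zero)" else ""))
  invisible(x)
}
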