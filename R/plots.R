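#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- object |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x[c("time", "surv")])) |>
    ungroup()
  cens <- dplyr::filter(object, .data$n_censor > 0)
  ggplot(steps, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    geom_point(data = cens, shape = 3, show.legend = FALSE) +
    ylim(0, 1) +
    labs(x = "Time (months)", y = "Overall survival", colour = "Risk group") +
    theme_minimal()
}

#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$pred_surv, y = .data$obs_surv)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    geom_point(aes(size = .data$n), show.legend = FALSE) +
    ylim(0, 1) +
    labs(x = "Predicted 1-year survival", y = "Observed 1-year survival (KM)") +
    theme_minimal()
}

#' @export
autoplot.attention_report <- function(object, which = c("temporal", "organ"), ...) {
  which <- match.arg(which)
  if (which == "temporal") {
    ggplot(object$temporal,
           aes(x = factor(.data$timepoint), y = .data$weight, fill = .data$group)) +
      ggplot2::geom_col(position = "dodge") +
      labs(x = "Timepoint (0 = baseline)", y = "Attention weight",
           fill = "Risk group") +
      theme_minimal()
  } else {
    ggplot(object$organ,
           aes(x = .data$site_to, y = .data$site_from, fill = .data$weight)) +
      geom_tile() +
      scale_fill_viridis_c() +
      ggplot2::facet_wrap(~ .data$group) +
      labs(x = "Attended lesion site", y = "Attending lesion site",
           fill = "Mean attention") +
      theme_minimal()
  }
}

#' @export
autoplot.heatmap <- function(object, ...) {
  df <- expand.grid(x = seq_len(nrow(object$array)),
                    y = seq_len(ncol(object$array)))
  df$value <- as.vector(object$array)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_equal() +
    labs(fill = "Grad-CAM") +
    theme_minimal()
}
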