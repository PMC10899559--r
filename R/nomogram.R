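#' Fit a Cox-regression nomogram fusing model scores and clinical covariates
#'
#' Combines the imaging deep-learning score, optionally the marker
#' deep-learning score, the RECIST category and clinical covariates (sex,
#' HER2 status) in a Cox proportional-hazards fit on the training cohort,
#' and derives the nomogram machinery: the Breslow baseline one-year
#' survival and an affine 0-100 point scale per covariate (100 points span
#' the widest coefficient-times-range contribution).
#'
#' @param data Training tibble with columns `os_months`, `event`,
#'   `ldlm_score`, optionally `tdlm_score`, `recist` (factor
#'   `CR`/`PR`/`SD`/`PD`), `sex`, `her2_status`.
#' @param use_tdlm Include the marker score; `FALSE` gives the
#'   without-marker variant used when a cohort has no marker data
#'   (refitted coefficients, not imputation).
#' @param covariates Character vector of additional covariate columns
#'   (default `c("recist", "sex", "her2_status")`); set to `character()`
#'   for score-only fusion.
#' @return A `nomogram_model`: coefficients, baseline 1-year survival,
#'   training mean linear predictor, point scale, and the underlying
#'   `coxph` fit.
#' @export
fit_nomogram <- function(data, use_tdlm = TRUE,
                         covariates = c("recist", "sex", "her2_status")) {
  vars <- c("ldlm_score", if (use_tdlm) "tdlm_score", covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) abort(paste("missing covariate columns:", toString(miss)))
  if (anyNA(data[vars])) abort("training covariates must be complete.")
  df <- as.data.frame(data)
  for (v in vars) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  if ("recist" %in% vars && !is.factor(df$recist)) {
    df$recist <- factor(df$recist, levels = c("CR", "PR", "SD", "PD"))
  }
  if ("recist" %in% vars) df$recist <- droplevels(df$recist)
  fml <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                                 paste(vars, collapse = " + ")))
  flagged <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, x = TRUE),
    warning = function(w) {
      flagged <<- c(flagged, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(coef(fit)))) abort("Cox fit did not converge (infinite coefficient).")
  if (any(abs(coef(fit)) > 15)) {
    flagged <- c(flagged, "very large coefficient: possible separation")
  }
  bh <- survival::basehaz(fit, centered = TRUE)
  i12 <- which(bh$time <= 12)
  s0_12 <- if (length(i12)) exp(-bh$hazard[max(i12)]) else 1
  X <- fit$x
  beta <- coef(fit)
  contrib <- sweep(X, 2, beta, "*")
  lo <- apply(contrib, 2, min)
  hi <- apply(contrib, 2, max)
  widest <- max(hi - lo)
  structure(list(
    fit = fit, terms = stats::delete.response(stats::terms(fit)),
    xlevels = fit$xlevels, coefficients = beta,
    lp_mean = sum(beta * fit$means),
    baseline_survival_1yr = s0_12,
    point_scale = list(lo = lo, widest = widest),
    variant = if (use_tdlm) "with-marker-score" else "without-marker-score",
    flagged = flagged, n = nrow(df), n_events = sum(df$event)),
    class = "nomogram_model")
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat(sprintf("<nomogram_model> %s, n=%d (%d events), baseline 1-yr survival %.3f\n",
              x$variant, x$n, x$n_events, x$baseline_survival_1yr))
  print(round(x$coefficients, 4))
  if (length(x$flagged)) cat("flagged:", paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.nomogram_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "coef"],
         hr = sm[, "exp(coef)"], std_error = sm[, "se(coef)"],
         statistic = sm[, "z"], p_value = sm[, "Pr(>|z|)"])
}

#' @export
glance.nomogram_model <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         c_index = unname(summary(x$fit)$concordance["C"]),
         baseline_survival_1yr = x$baseline_survival_1yr,
         variant = x$variant)
}

nomogram_design <- function(model, data) {
  df <- as.data.frame(data)
  for (v in names(model$xlevels)) {
    if (!v %in% names(df)) abort(paste("missing covariate:", v))
    bad <- setdiff(unique(as.character(df[[v]])), model$xlevels[[v]])
    if (length(bad)) {
      abort(sprintf("unseen level '%s' for covariate '%s'.", bad[1], v))
    }
    df[[v]] <- factor(df[[v]], levels = model$xlevels[[v]])
  }
  mm <- stats::model.matrix(model$terms, data = df, xlev = model$xlevels)
  mm[, names(model$coefficients), drop = FALSE]
}

#' Score patients with a fitted nomogram
#'
#' The linear predictor is exactly the coefficient-weighted covariate sum;
#' total points are its affine rescale onto the 0-100-per-widest-covariate
#' nomogram scale; the predicted one-year survival is
#' `baseline_survival_1yr ^ exp(lp - mean training lp)`.
#'
#' @param model A [fit_nomogram()] result.
#' @param data Tibble with the covariates of the fitted variant.
#' @return Tibble: `lp`, `points`, `surv_1yr`.
#' @export
nomo_score <- function(model, data) {
  X <- nomogram_design(model, data)
  lp <- as.numeric(X %*% model$coefficients)
  contrib <- sweep(X, 2, model$coefficients, "*")
  pts <- sweep(contrib, 2, model$point_scale$lo, "-") /
    model$point_scale$widest * 100
  tibble(lp = lp, points = unname(rowSums(pts)),
         surv_1yr = model$baseline_survival_1yr ^ exp(lp - model$lp_mean))
}

points_to_lp <- function(model, points) {
  unname(points / 100 * model$point_scale$widest + sum(model$point_scale$lo))
}

#' Hosmer-Lemeshow goodness-of-fit for predicted one-year survival
#'
#' Groups patients into bins of predicted event probability and compares
#' observed with expected events; the statistic is referred to a chi-square
#' distribution with `g - 2` degrees of freedom. With censoring the
#' observed per-bin event fraction comes from the Kaplan-Meier estimate at
#' the horizon.
#'
#' @param predicted_surv Predicted survival probabilities at the horizon.
#' @param time,event Observed survival data.
#' @param n_bins Number of probability bins (default 10); bins emptied by
#'   tied predictions are merged and a message is emitted.
#' @param horizon_months Landmark (default 12).
#' @return List with `curve` (tibble `bin`, `n`, `pred_surv`, `obs_surv`)
#'   and `test` (tibble `statistic`, `df`, `p_value`), class
#'   `calibration_curve`.
#' @export
calibration_curve <- function(predicted_surv, time, event, n_bins = 10,
                              horizon_months = 12) {
  n <- length(predicted_surv)
  if (n < 20) abort("calibration needs n >= 20.")
  br <- unique(quantile(predicted_surv, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) - 1 < n_bins) {
    inform(sprintf("merged %d empty calibration bins.", n_bins - (length(br) - 1)))
  }
  bin <- cut(predicted_surv, breaks = br, include.lowest = TRUE, labels = FALSE)
  g <- length(unique(bin))
  rows <- lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    fit <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    idx <- which(fit$time <= horizon_months)
    obs <- if (length(idx)) fit$surv[max(idx)] else 1
    tibble(bin = b, n = sum(i), pred_surv = mean(predicted_surv[i]),
           obs_surv = obs)
  })
  curve <- bind_rows(rows)
  p_ev <- 1 - curve$pred_surv
  O <- curve$n * (1 - curve$obs_surv)
  E <- curve$n * p_ev
  denom <- curve$n * p_ev * (1 - p_ev)
  ok <- denom > 0
  stat <- sum((O[ok] - E[ok])^2 / denom[ok])
  df <- max(g - 2, 1)
  structure(list(curve = curve,
                 test = tibble(statistic = stat, df = df,
                               p_value = pchisq(stat, df, lower.tail = FALSE))),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d bins, Hosmer-Lemeshow chi2=%.3f (df=%d), p=%.3f\n",
              nrow(x$curve), x$test$statistic, x$test$df, x$test$p_value))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) x$curve

#' @export
glance.calibration_curve <- function(x, ...) x$test
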