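#' Harrell's concordance index with bootstrap confidence interval
#'
#' Probability that, of a comparable patient pair, the patient with the
#' higher risk score fails first; tied scores count one half. Comparable
#' pairs follow the usual censoring rule (the shorter time must be an
#' event). The confidence interval is a seeded patient-level percentile
#' bootstrap.
#'
#' @param data Data frame with score, time and event columns.
#' @param score,time,event Column names (tidy-eval; defaults `score`,
#'   `os_months`, `event`).
#' @param n_boot Bootstrap replicates (default 2000; 0 skips the CI).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Bootstrap seed.
#' @return One-row tibble: `c_index`, `conf_low`, `conf_high`, `n`,
#'   `n_events`.
#' @export
c_index <- function(data, score = score, time = os_months, event = event,
                    n_boot = 2000, conf_level = 0.95, seed = 1L) {
  s <- dplyr::pull(data, {{ score }})
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  cc <- function(s, t, e) {
    fit <- survival::concordance(survival::Surv(t, e) ~ s, reverse = TRUE)
    unname(fit$concordance)
  }
  est <- cc(s, t, e)
  if (!is.finite(est)) abort("no comparable pairs.")
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    reps <- withr::with_seed(seed, {
      replicate(n_boot, {
        i <- sample.int(length(s), replace = TRUE)
        cc(s[i], t[i], e[i])
      })
    })
    alpha <- (1 - conf_level) / 2
    qs <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble(c_index = est, conf_low = lo, conf_high = hi,
         n = length(s), n_events = sum(e))
}

#' One-year AUC for predicting death within 12 months
#'
#' Binary AUC of the risk score for (death before 12 months) versus
#' (survival beyond 12 months); patients censored before 12 months are
#' excluded because their one-year status is unknown. Equivalent to the
#' Mann-Whitney statistic; invariant to strictly monotone transforms of the
#' score. Confidence interval by seeded percentile bootstrap.
#'
#' @inheritParams c_index
#' @param horizon_months Landmark (default 12).
#' @return One-row tibble: `auc`, `conf_low`, `conf_high`, `n_cases`,
#'   `n_controls`, `n_excluded`.
#' @export
auc_one_year <- function(data, score = score, time = os_months, event = event,
                         horizon_months = 12, n_boot = 2000,
                         conf_level = 0.95, seed = 1L) {
  s <- dplyr::pull(data, {{ score }})
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  excl <- t < horizon_months & e == 0
  lab <- ifelse(t < horizon_months, 1, 0)[!excl]
  sc <- s[!excl]
  if (length(unique(lab)) < 2) {
    abort("one-year AUC undefined: a class is empty after exclusions.")
  }
  auc1 <- function(sc, lab) {
    as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c(0, 1),
                                   direction = "<", quiet = TRUE)))
  }
  est <- auc1(sc, lab)
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    reps <- withr::with_seed(seed, {
      replicate(n_boot, {
        i <- sample.int(length(sc), replace = TRUE)
        if (length(unique(lab[i])) < 2) NA_real_ else auc1(sc[i], lab[i])
      })
    })
    alpha <- (1 - conf_level) / 2
    qs <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble(auc = est, conf_low = lo, conf_high = hi,
         n_cases = sum(lab == 1), n_controls = sum(lab == 0),
         n_excluded = sum(excl))
}

#' Youden-index cutoff on the training cohort
#'
#' Scans every midpoint between adjacent distinct scores and returns the
#' threshold maximising sensitivity + specificity - 1, where a patient is
#' called positive when the score exceeds the threshold. Ties are broken
#' towards the lower threshold. The cutoff is chosen once on the training
#' cohort and then frozen for every validation cohort.
#'
#' @param data Data frame with score and binary label columns.
#' @param score Score column (tidy-eval; default `score`).
#' @param label Binary label column (1 = positive/poor; default `y`).
#' @return The cutoff (scalar), with the achieved Youden index as attribute
#'   `youden`.
#' @export
youden_cutoff <- function(data, score = score, label = y) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ label }})
  keep <- !is.na(y) & !is.na(s)
  s <- s[keep]; y <- y[keep]
  if (length(unique(y)) < 2) abort("both classes are required to place a cutoff.")
  us <- sort(unique(s))
  if (length(us) < 2) abort("degenerate input: a single distinct score.")
  cand <- (us[-1] + us[-length(us)]) / 2
  jvals <- vapply(cand, function(cut) {
    sens <- mean(s[y == 1] > cut)
    spec <- mean(s[y == 0] <= cut)
    sens + spec - 1
  }, numeric(1))
  best <- cand[which.max(jvals)]  # which.max takes the first (lowest) on ties
  structure(best, youden = max(jvals))
}

#' Kaplan-Meier survival curve(s)
#'
#' Product-limit estimator, optionally per group, as a tidy step-function
#' table with censoring marks. The curve starts at 1 and is non-increasing.
#'
#' @inheritParams c_index
#' @param group Optional grouping column.
#' @return A `km_curve` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_curve <- function(data, time = os_months, event = event, group = NULL) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g <- if (rlang::quo_is_null(rlang::enquo(group))) {
    rep("all", length(t))
  } else {
    as.character(dplyr::pull(data, {{ group }}))
  }
  out <- lapply(unique(g), function(gv) {
    i <- g == gv
    fit <- survival::survfit(survival::Surv(t[i], e[i]) ~ 1)
    tibble(group = gv, time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv)
  })
  structure(bind_rows(out), class = c("km_curve", "tbl_df", "tbl", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square comparing the survival of the groups, with
#' the p-value from a chi-square distribution on `k - 1` degrees of
#' freedom.
#'
#' @inheritParams km_curve
#' @param group Grouping column (>= 2 nonempty groups).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, time = os_months, event = event, group = group) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g <- dplyr::pull(data, {{ group }})
  if (length(unique(g)) < 2) abort("log-rank needs >= 2 nonempty groups.")
  if (sum(e) < 1) abort("log-rank needs >= 1 event.")
  fit <- survival::survdiff(survival::Surv(t, e) ~ g)
  df <- length(fit$n) - 1
  tibble(statistic = fit$chisq, df = df,
         p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Evaluate risk scores on a cohort
#'
#' Computes the full evaluation suite: concordance index, one-year AUC,
#' risk groups from a frozen cutoff, per-group Kaplan-Meier curves, the
#' log-rank test, and the hazard ratio of high vs low risk from a
#' univariate Cox fit.
#'
#' @param data Tibble with `patient_id`, score, time and event columns.
#' @param cutoff Risk-group cutoff, typically [youden_cutoff()] from the
#'   training cohort.
#' @inheritParams c_index
#' @return A `cohort_result`: list with `per_patient` (tibble incl.
#'   `risk_group`), `c_index`, `auc_1yr`, `hazard_ratio`, `logrank`,
#'   `km` (a [km_curve()] per group) and `cutoff`.
#' @export
evaluate_cohort <- function(data, cutoff, score = score, time = os_months,
                            event = event, n_boot = 2000, seed = 1L) {
  s <- dplyr::pull(data, {{ score }})
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  per <- tibble(patient_id = data$patient_id, score = s, os_months = t,
                event = e,
                risk_group = ifelse(s > cutoff, "high", "low"))
  ci <- c_index(per, score, os_months, event, n_boot = n_boot, seed = seed)
  auc <- tryCatch(
    auc_one_year(per, score, os_months, event, n_boot = n_boot, seed = seed),
    error = function(c) tibble(auc = NA_real_, conf_low = NA_real_,
                               conf_high = NA_real_, n_cases = NA_integer_,
                               n_controls = NA_integer_, n_excluded = NA_integer_))
  both <- length(unique(per$risk_group)) == 2
  hr <- tibble(hr = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
               p_value = NA_real_)
  lr <- tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  if (both) {
    fit <- survival::coxph(survival::Surv(per$os_months, per$event) ~
                             I(per$risk_group == "high"))
    sm <- summary(fit)
    hr <- tibble(hr = unname(sm$conf.int[1, "exp(coef)"]),
                 conf_low = unname(sm$conf.int[1, "lower .95"]),
                 conf_high = unname(sm$conf.int[1, "upper .95"]),
                 p_value = unname(sm$coefficients[1, "Pr(>|z|)"]))
    lr <- logrank_test(per, os_months, event, risk_group)
  }
  structure(list(per_patient = per, c_index = ci, auc_1yr = auc,
                 hazard_ratio = hr, logrank = lr,
                 km = km_curve(per, os_months, event, risk_group),
                 cutoff = as.numeric(cutoff)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> n=%d, C-index %.3f (%.3f-%.3f), 1-yr AUC %s, log-rank p %s\n",
              nrow(x$per_patient), x$c_index$c_index, x$c_index$conf_low,
              x$c_index$conf_high,
              ifelse(is.na(x$auc_1yr$auc), "NA", sprintf("%.3f", x$auc_1yr$auc)),
              ifelse(is.na(x$logrank$p_value), "NA",
                     format.pval(x$logrank$p_value, digits = 3))))
  invisible(x)
}

#' @export
tidy.cohort_result <- function(x, ...) x$per_patient

#' @export
glance.cohort_result <- function(x, ...) {
  tibble(n = nrow(x$per_patient), n_events = sum(x$per_patient$event),
         c_index = x$c_index$c_index,
         c_index_low = x$c_index$conf_low, c_index_high = x$c_index$conf_high,
         auc_1yr = x$auc_1yr$auc, auc_1yr_low = x$auc_1yr$conf_low,
         auc_1yr_high = x$auc_1yr$conf_high,
         hr = x$hazard_ratio$hr, hr_p = x$hazard_ratio$p_value,
         logrank_p = x$logrank$p_value, cutoff = x$cutoff)
}
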