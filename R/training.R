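#' Binary survival labels for the classification loss
#'
#' The classification head targets poor overall survival (< 12 months).
#' Patients who died before the threshold are `poor`; patients observed
#' beyond it (event or censored) are `good`; patients censored before the
#' threshold have an undefined binary class (`indeterminate`) — they are
#' excluded from the cross-entropy loss but still inform the ranking loss.
#'
#' @param os_months Observed survival time in months.
#' @param event Event indicator (1 = death observed).
#' @param threshold_months Class boundary, default 12.
#' @return Tibble with `os_months`, `event`, `class`
#'   (`poor`/`good`/`indeterminate`) and `y` (1 = poor, NA if
#'   indeterminate).
#' @export
survival_labels <- function(os_months, event, threshold_months = 12) {
  cls <- dplyr::case_when(
    event == 1 & os_months < threshold_months ~ "poor",
    os_months >= threshold_months ~ "good",
    TRUE ~ "indeterminate"
  )
  tibble(os_months = os_months, event = event, class = cls,
         y = dplyr::if_else(cls == "poor", 1, dplyr::if_else(cls == "good", 0, NA_real_)))
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Cross-entropy loss over the poor/good classes
#'
#' Mean binary cross-entropy of the predicted poor-OS probability against
#' the binary class; `indeterminate` patients (censored before the
#' threshold) are skipped.
#'
#' @param risks Predicted poor-OS probabilities in `[0, 1]`.
#' @param labels A [survival_labels()] tibble (or anything with `y`).
#' @return Scalar loss.
#' @export
ce_loss <- function(risks, labels) {
  y <- labels$y
  keep <- !is.na(y)
  if (!any(keep)) abort("no poor/good patients in the batch (all indeterminate).")
  r <- risks[keep]; y <- y[keep]
  -mean(xlogy(y, r) + xlogy(1 - y, 1 - r))
}

# Breslow risk-set sums and per-sample gradient weights for the Cox
# partial likelihood of scores s. Shared by loss and gradient.
cox_parts <- function(s, time, event) {
  n <- length(s)
  ord <- order(time)
  u <- time[ord]
  es <- exp(s[ord] - max(s))
  total <- sum(es)
  cs <- cumsum(es)
  # first/last index of each tie group in sorted order
  first <- cummax(ifelse(!duplicated(u), seq_len(n), 0L))
  last <- rev(cummin(rev(ifelse(!duplicated(u, fromLast = TRUE), seq_len(n), n))))
  R <- total - ifelse(first > 1, cs[pmax(first - 1L, 1L)], 0)  # sum over t_k >= t_i
  ev <- event[ord] == 1
  list(ord = ord, u = u, es = es, R = R, ev = ev, first = first, last = last,
       smax = max(s))
}

#' Cox partial-likelihood ranking loss
#'
#' Negative Cox partial log-likelihood (Breslow tie handling) of the risk
#' scores over a mini-batch, averaged over events. This is the canonical
#' loss that orders all samples by risk: higher score must precede failure.
#' Invariant to adding a constant to all scores.
#'
#' @param risks Risk scores (any real scale; higher = worse prognosis).
#' @param os_months Observed times.
#' @param events Event indicators; at least one event is required.
#' @return Scalar loss.
#' @export
surv_loss <- function(risks, os_months, events) {
  if (sum(events) < 1) {
    abort("survival loss needs >= 1 event in the batch; increase surv_batch_size.")
  }
  cp <- cox_parts(risks, os_months, events)
  s_sorted <- risks[cp$ord] - cp$smax
  -sum((s_sorted - log(cp$R))[cp$ev]) / sum(cp$ev)
}

# Gradient of surv_loss w.r.t. the scores (original order).
surv_loss_grad <- function(risks, os_months, events) {
  cp <- cox_parts(risks, os_months, events)
  n <- length(risks)
  E <- sum(cp$ev)
  w <- ifelse(cp$ev, 1 / cp$R, 0)
  cumw <- cumsum(w)
  W <- cumw[cp$last]                     # events with t_i <= t_j (ties share risk sets)
  g_sorted <- -(as.numeric(cp$ev) - cp$es * W) / E
  g <- numeric(n)
  g[cp$ord] <- g_sorted
  g
}

#' Train a risk model with the combined loss
#'
#' Optimises `l_ce + l_surv` (unit weights by default; either term can be
#' switched off for ablation) with Adam over mini-batches of patients.
#' Training uses scans up to `max_followups` follow-ups (default 4); the
#' evaluation horizon is chosen independently at prediction time. Runs are
#' deterministic given the seed. The frozen convolutional extractor is not
#' updated; the projection, temporal position embedding, both attention
#' levels, the aggregation token and the head are.
#'
#' @param model A [risk_model()].
#' @param records List of `patient_record`s (used when `feats` is NULL and
#'   for outcomes).
#' @param feats Optional precomputed [cohort_features()].
#' @param outcomes Tibble `patient_id`, `os_months`, `event`; defaults to
#'   the records' clinical outcomes.
#' @param stats Marker statistics for marker models.
#' @param use_ce,use_surv Enable the cross-entropy / survival loss (at least
#'   one must be on).
#' @param ce_weight,surv_weight Loss weights (1 and 1, an unweighted sum).
#' @param epochs Training epochs.
#' @param batch_size Patients per mini-batch; batches without any event skip
#'   the survival term for that step.
#' @param lr Adam learning rate.
#' @param average_tail Fraction of final optimisation steps whose weights
#'   are averaged into the returned model (Polyak-Ruppert tail averaging;
#'   default 0.4, stabilising the stochastic-gradient endpoint; 0 disables).
#' @param max_followups Follow-ups used during training (default 4).
#' @param augment Random rotation augmentation at feature extraction.
#' @param seed Seed for shuffling.
#' @param verbose Print per-epoch losses.
#' @return The trained `risk_model`, with `$fit` holding the per-epoch loss
#'   history (`epoch`, `ce`, `surv`, `total`).
#' @export
train_risk_model <- function(model, records = NULL, feats = NULL,
                             outcomes = NULL, stats = NULL,
                             use_ce = TRUE, use_surv = TRUE,
                             ce_weight = 1, surv_weight = 1,
                             epochs = 10, batch_size = 32, lr = 3e-3,
                             average_tail = 0.4, max_followups = 4,
                             augment = FALSE, seed = 1L, verbose = FALSE) {
  if (!use_ce && !use_surv) abort("enable at least one loss.")
  if (is.null(feats)) {
    feats <- cohort_features(model, records, stats = stats, augment = augment)
  }
  feats <- truncate_features(feats, max_followups)
  if (is.null(outcomes)) {
    outcomes <- tibble(patient_id = map(records, "patient_id") |> unlist(),
                       os_months = map_dbl(records, "os_months"),
                       event = map_dbl(records, "event"))
  }
  stopifnot(identical(outcomes$patient_id, feats$patient_id))
  if (is.null(model$feat_stats)) {
    # per-dimension z-scoring over the observed training slots; frozen into
    # the model so validation cohorts reuse the training statistics
    df <- dim(feats$F)[4]
    F2 <- feats$F; dim(F2) <- c(length(F2) / df, df)
    valid <- as.vector(feats$tp_mask)
    mu <- colMeans(F2[valid, , drop = FALSE])
    sdv <- apply(F2[valid, , drop = FALSE], 2, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    model$feat_stats <- list(mean = mu, sd = sdv)
  }
  labels <- survival_labels(outcomes$os_months, outcomes$event)
  P <- length(feats$patient_id)
  state <- adam_init(model$par)
  history <- vector("list", epochs)
  total_steps <- epochs * ceiling(P / batch_size)
  avg_start <- ceiling((1 - average_tail) * total_steps)
  step <- 0L; avg_par <- NULL; n_avg <- 0L
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(P)
      ce_sum <- 0; surv_sum <- 0; nb_ce <- 0L; nb_surv <- 0L
      for (start in seq(1, P, by = batch_size)) {
        bi <- perm[start:min(start + batch_size - 1, P)]
        fb <- list(F = feats$F[bi, , , , drop = FALSE],
                   obj_mask = feats$obj_mask[bi, , drop = FALSE],
                   tp_mask = feats$tp_mask[bi, , , drop = FALSE])
        fwd <- model_forward(model, fb$F, fb$obj_mask, fb$tp_mask, collect = TRUE)
        nb <- length(bi)
        dlog <- matrix(0, nb, 2)
        lb <- labels[bi, ]
        keep <- !is.na(lb$y)
        if (use_ce && any(keep)) {
          lce <- ce_loss(fwd$risk, lb)
          ce_sum <- ce_sum + lce; nb_ce <- nb_ce + 1L
          dce <- (fwd$prob[keep, , drop = FALSE] -
                    cbind(lb$y[keep], 1 - lb$y[keep])) / sum(keep)
          dlog[keep, ] <- dlog[keep, ] + ce_weight * dce
        }
        if (use_surv && sum(lb$event) >= 1) {
          s <- fwd$logits[, 1] - fwd$logits[, 2]
          lsv <- surv_loss(s, lb$os_months, lb$event)
          surv_sum <- surv_sum + lsv; nb_surv <- nb_surv + 1L
          ds <- surv_loss_grad(s, lb$os_months, lb$event)
          dlog[, 1] <- dlog[, 1] + surv_weight * ds
          dlog[, 2] <- dlog[, 2] - surv_weight * ds
        }
        if (all(dlog == 0)) next
        g <- model_backward(model, fwd, dlog)
        st <- adam_step(model$par, g, state, lr = lr)
        model$par <- st$par
        state <- st$state
        step <- step + 1L
        if (average_tail > 0 && step > avg_start) {
          n_avg <- n_avg + 1L
          if (is.null(avg_par)) {
            avg_par <- model$par
          } else {
            for (nm in names(avg_par)) {
              avg_par[[nm]] <- avg_par[[nm]] +
                (model$par[[nm]] - avg_par[[nm]]) / n_avg
            }
          }
        }
      }
      ep_ce <- if (nb_ce > 0) ce_sum / nb_ce else NA_real_
      ep_surv <- if (nb_surv > 0) surv_sum / nb_surv else NA_real_
      ep_tot <- sum(c(if (use_ce) ce_weight * ep_ce,
                      if (use_surv) surv_weight * ep_surv), na.rm = TRUE)
      if (!is.finite(ep_tot)) {
        abort(sprintf("training diverged at epoch %d (ce=%g, surv=%g); lower the learning rate.",
                      ep, ep_ce, ep_surv))
      }
      history[[ep]] <- tibble(epoch = ep, ce = ep_ce, surv = ep_surv,
                              total = ep_tot)
      if (verbose) {
        inform(sprintf("epoch %d: ce=%.4f surv=%.4f total=%.4f",
                       ep, ep_ce, ep_surv, ep_tot))
      }
    }
  })
  if (!is.null(avg_par)) model$par <- avg_par
  model$fit <- list(history = bind_rows(history),
                    loss_config = list(use_ce = use_ce, use_surv = use_surv,
                                       ce_weight = ce_weight,
                                       surv_weight = surv_weight,
                                       epochs = epochs, batch_size = batch_size,
                                       lr = lr, max_followups = max_followups,
                                       seed = seed))
  model
}

#' @export
tidy.risk_model <- function(x, ...) {
  if (is.null(x$fit)) {
    abort("model has no training history; run train_risk_model() first.")
  }
  x$fit$history
}

#' @export
glance.risk_model <- function(x, ...) {
  cfg <- x$config
  tibble(input = cfg$input, d_model = cfg$d_model, n_heads = cfg$n_heads,
         n_layers = cfg$n_layers,
         n_parameters = sum(map_int(x$par, length)),
         trained = !is.null(x$fit),
         final_loss = if (!is.null(x$fit)) tail(x$fit$history$total, 1) else NA_real_)
}
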