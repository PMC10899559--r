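#' Construct a two-level attention risk model
#'
#' The model fuses, for each patient, every lesion's (or tumour-marker
#' channel's) time series with a temporal attention encoder, then fuses the
#' resulting object vectors through a second attention encoder that reads
#' its output at a learnable aggregation token, so one patient yields one
#' vector regardless of lesion count. A two-layer perceptron with softmax
#' turns that vector into the predicted probability of poor overall survival
#' (< 12 months). Masking makes absent timepoints and padded objects carry
#' exactly zero attention weight.
#'
#' Image models extract per-patch features with a small strided residual-style
#' CNN whose weights are fixed at construction (seeded); training updates the
#' projection, both attention levels, the aggregation token, the temporal
#' position embedding and the head. Marker models embed each marker channel's
#' scalar series directly.
#'
#' @param input `"image"` for CT patches or `"marker"` for tumour-marker
#'   series.
#' @param d_model Transformer width (default 64).
#' @param n_heads Attention heads per level (default 4; must divide
#'   `d_model`).
#' @param n_layers Encoder depth per level (default 2).
#' @param d_ff Feed-forward width (default `2 * d_model`).
#' @param d_feat Feature dimension entering the projection: CNN channels for
#'   image models; forced to `n_markers + 1` for marker models.
#' @param n_timepoints Maximum scans per patient (default 5: baseline + 4
#'   follow-ups).
#' @param patch_px Expected patch side in pixels for image models.
#' @param n_markers Marker channels for marker models.
#' @param use_temporal_embedding Add the learned temporal position embedding
#'   (TRUE by default; disabling it makes the temporal stage order-blind).
#' @param d_head_hidden Hidden width of the MLP head.
#' @param seed Integer seed for weight initialisation.
#' @return A `risk_model` object.
#' @export
risk_model <- function(input = c("image", "marker"), d_model = 64,
                       n_heads = 4, n_layers = 2, d_ff = 2 * d_model,
                       d_feat = 64, n_timepoints = 5, patch_px = 64,
                       n_markers = 3, use_temporal_embedding = TRUE,
                       d_head_hidden = 32, seed = 1L) {
  input <- match.arg(input)
  if (d_model %% n_heads != 0) abort("`n_heads` must divide `d_model`.")
  if (input == "marker") d_feat <- n_markers + 1L
  config <- list(input = input, d_model = d_model, n_heads = n_heads,
                 n_layers = n_layers, d_ff = d_ff, d_feat = d_feat,
                 n_timepoints = n_timepoints, patch_px = patch_px,
                 n_markers = n_markers,
                 use_temporal_embedding = use_temporal_embedding,
                 d_head_hidden = d_head_hidden, seed = seed)
  withr::with_seed(seed, {
    par <- list()
    par[["emb.W"]] <- matrix(rnorm(d_feat * d_model, 0, 1 / sqrt(d_feat)),
                             d_feat, d_model)
    par[["emb.b"]] <- rep(0, d_model)
    par[["pos"]] <- matrix(rnorm(n_timepoints * d_model, 0, 0.05),
                           n_timepoints, d_model)
    par[["agg"]] <- rnorm(d_model, 0, 0.05)
    for (l in seq_len(n_layers)) {
      blk <- nn_init_block(d_model, d_ff)
      for (nm in names(blk)) par[[sprintf("th%d.%s", l, nm)]] <- blk[[nm]]
      blk <- nn_init_block(d_model, d_ff)
      for (nm in names(blk)) par[[sprintf("oh%d.%s", l, nm)]] <- blk[[nm]]
    }
    par[["head.W1"]] <- matrix(rnorm(d_model * d_head_hidden, 0, 1 / sqrt(d_model)),
                               d_model, d_head_hidden)
    par[["head.b1"]] <- rep(0, d_head_hidden)
    par[["head.W2"]] <- matrix(rnorm(d_head_hidden * 2, 0, 1 / sqrt(d_head_hidden)),
                               d_head_hidden, 2)
    par[["head.b2"]] <- rep(0, 2)
    extractor <- if (input == "image") init_extractor(d_feat) else NULL
  })
  structure(list(config = config, par = par, extractor = extractor),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<risk_model> %s input, d=%d, %d heads, %d layers/level, %d timepoints, temporal embedding %s\n",
              cfg$input, cfg$d_model, cfg$n_heads, cfg$n_layers,
              cfg$n_timepoints, if (cfg$use_temporal_embedding) "on" else "off"))
  invisible(x)
}

level_pars <- function(par, level, n_layers) {
  keys <- c("ln1.g", "ln1.b", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
            "ln2.g", "ln2.b", "W1", "b1", "W2", "b2")
  lapply(seq_len(n_layers), function(l) {
    setNames(lapply(keys, function(k) par[[sprintf("%s%d.%s", level, l, k)]]), keys)
  })
}

# ---- frozen convolutional feature extractor -----------------------------

init_extractor <- function(d_feat) {
  ch <- c(3L, 8L, 16L, 32L, d_feat)
  strides <- c(2L, 2L, 2L, 1L)
  layers <- vector("list", 4)
  for (l in 1:4) {
    fan_in <- 9L * ch[l]
    layers[[l]] <- list(W = matrix(rnorm(fan_in * ch[l + 1], 0, sqrt(2 / fan_in)),
                                   fan_in, ch[l + 1]),
                        b = rep(0, ch[l + 1]), stride = strides[l])
  }
  layers
}

im2col <- function(x, stride) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- (H + 2L - 3L) %/% stride + 1L
  Wo <- (W + 2L - 3L) %/% stride + 1L
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  rows <- seq.int(1L, by = stride, length.out = Ho)
  cols <- seq.int(1L, by = stride, length.out = Wo)
  out <- matrix(0, Ho * Wo, 9L * C)
  k <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    out[, k] <- xp[rows + di, cols + dj, c]
  }
  list(col = out, Ho = Ho, Wo = Wo)
}

conv_stack <- function(layers, x) {
  for (l in seq_along(layers)) {
    ic <- im2col(x, layers[[l]]$stride)
    y <- nn_linear(ic$col, layers[[l]]$W, layers[[l]]$b)
    y <- pmax(y, 0)
    x <- array(y, c(ic$Ho, ic$Wo, ncol(y)))
  }
  x
}

#' Extract a feature vector from one image patch
#'
#' Runs the model's frozen convolutional extractor over a 3-channel patch
#' and global-average-pools the final feature maps into a `d_feat` vector.
#' Deterministic given the model.
#'
#' @param model An image-input [risk_model()].
#' @param patch An `image_patch` or a bare `patch_px x patch_px x 3` array.
#' @param return_maps Also return the final convolutional feature maps
#'   (needed by [gradcam()]).
#' @return A numeric `d_feat` vector, or a list `(feat, maps)` when
#'   `return_maps = TRUE`.
#' @export
extract_features <- function(model, patch, return_maps = FALSE) {
  stopifnot(inherits(model, "risk_model"))
  if (model$config$input != "image") abort("model does not take image input.")
  arr <- if (inherits(patch, "image_patch")) patch$array else patch
  px <- model$config$patch_px
  if (length(dim(arr)) != 3 || !all(dim(arr) == c(px, px, 3))) {
    abort(sprintf("patch must be %d x %d x 3 for this model.", px, px))
  }
  maps <- conv_stack(model$extractor, arr)
  feat <- apply(maps, 3, mean)
  if (return_maps) list(feat = feat, maps = maps) else feat
}

# ---- batched forward / backward ----------------------------------------

# F: [P, O, T, d_feat]; obj_mask: [P, O]; tp_mask: [P, O, T].
model_forward <- function(model, F, obj_mask, tp_mask, collect = FALSE) {
  cfg <- model$config
  par <- model$par
  dm <- dim(F)
  P <- dm[1]; O <- dm[2]; T <- dm[3]; df <- dm[4]
  d <- cfg$d_model
  if (!is.null(model$feat_stats)) {
    F2s <- F; dim(F2s) <- c(P * O * T, df)
    F2s <- sweep(sweep(F2s, 2, model$feat_stats$mean, "-"), 2,
                 model$feat_stats$sd, "/")
    F <- array(F2s, c(P, O, T, df))
  }
  mnum <- array(as.numeric(tp_mask), c(P, O, T, d))
  Fm <- F * array(as.numeric(tp_mask), dim(F))
  F2 <- Fm; dim(F2) <- c(P * O * T, df)
  E2 <- nn_linear(F2, par[["emb.W"]], par[["emb.b"]])
  E <- array(E2, c(P, O, T, d))
  if (cfg$use_temporal_embedding) {
    for (t in seq_len(T)) {
      E[, , t, ] <- E[, , t, ] + rep(par[["pos"]][t, ], each = P * O)
    }
  }
  E <- E * mnum  # masked slots carry the zero sentinel embedding
  X <- E; dim(X) <- c(P * O, T, d)
  m2 <- tp_mask; dim(m2) <- c(P * O, T)
  th <- nn_encoder_fwd(X, m2, level_pars(par, "th", cfg$n_layers), cfg$n_heads)
  nv <- rowSums(m2)
  pooled <- matrix(0, P * O, d)
  for (t in seq_len(T)) pooled <- pooled + th$Y[, t, ] * m2[, t]
  pooled <- pooled / ifelse(nv > 0, nv, 1)
  pooled[nv == 0, ] <- 0
  L <- array(pooled, c(P, O, d))
  Xo <- array(0, c(P, O + 1L, d))
  Xo[, 1, ] <- rep(par[["agg"]], each = P)
  Xo[, 2:(O + 1L), ] <- L
  om <- cbind(rep(TRUE, P), obj_mask)
  oh <- nn_encoder_fwd(Xo, om, level_pars(par, "oh", cfg$n_layers), cfg$n_heads)
  pv <- oh$Y[, 1, , drop = FALSE]; dim(pv) <- c(P, d)
  h1 <- pmax(nn_linear(pv, par[["head.W1"]], par[["head.b1"]]), 0)
  logits <- nn_linear(h1, par[["head.W2"]], par[["head.b2"]])
  pr <- softmax_rows(logits)
  out <- list(risk = pr[, 1], prob = pr, logits = logits,
              th_attn = th$attn_last, oh_attn = oh$attn_last,
              dims = list(P = P, O = O, T = T, df = df))
  if (collect) {
    out$cache <- list(F2 = F2, mnum = mnum, m2 = m2, nv = nv, th = th,
                      om = om, oh = oh, pv = pv, h1 = h1, pooled = pooled)
  }
  out
}

softmax_rows <- function(z) {
  mx <- apply(z, 1, max)
  e <- exp(z - mx)
  e / rowSums(e)
}

# dlogits: [P, 2]. Returns flat gradient list over model$par and, when
# want_dF, the gradient w.r.t. the input features.
model_backward <- function(model, fwd, dlogits, want_dF = FALSE) {
  cfg <- model$config
  par <- model$par
  ch <- fwd$cache
  P <- fwd$dims$P; O <- fwd$dims$O; T <- fwd$dims$T; df <- fwd$dims$df
  d <- cfg$d_model
  g <- list()
  l2 <- nn_linear_bwd(dlogits, ch$h1, par[["head.W2"]])
  g[["head.W2"]] <- l2$dW; g[["head.b2"]] <- l2$db
  dh1 <- l2$dX * (ch$h1 > 0)
  l1 <- nn_linear_bwd(dh1, ch$pv, par[["head.W1"]])
  g[["head.W1"]] <- l1$dW; g[["head.b1"]] <- l1$db
  dXo <- array(0, c(P, O + 1L, d))
  dXo[, 1, ] <- l1$dX
  ohp <- level_pars(par, "oh", cfg$n_layers)
  ob <- nn_encoder_bwd(dXo, ch$oh$caches, ch$om, ohp, cfg$n_heads)
  for (l in seq_len(cfg$n_layers)) {
    for (nm in names(ob$grads[[l]])) {
      g[[sprintf("oh%d.%s", l, nm)]] <- ob$grads[[l]][[nm]]
    }
  }
  g[["agg"]] <- colSums(matrix(ob$dX[, 1, ], P, d))
  dL <- ob$dX[, 2:(O + 1L), , drop = FALSE]
  dpooled <- dL; dim(dpooled) <- c(P * O, d)
  nv <- ch$nv
  dY <- array(0, c(P * O, T, d))
  sc <- 1 / ifelse(nv > 0, nv, 1) * (nv > 0)
  for (t in seq_len(T)) dY[, t, ] <- dpooled * sc * ch$m2[, t]
  thp <- level_pars(par, "th", cfg$n_layers)
  tb <- nn_encoder_bwd(dY, ch$th$caches, ch$m2, thp, cfg$n_heads)
  for (l in seq_len(cfg$n_layers)) {
    for (nm in names(tb$grads[[l]])) {
      g[[sprintf("th%d.%s", l, nm)]] <- tb$grads[[l]][[nm]]
    }
  }
  dE <- tb$dX; dim(dE) <- c(P, O, T, d)
  dE <- dE * ch$mnum
  if (cfg$use_temporal_embedding) {
    dpos <- matrix(0, T, d)
    for (t in seq_len(T)) {
      dEt <- dE[, , t, ]; dim(dEt) <- c(P * O, d)
      dpos[t, ] <- colSums(dEt)
    }
    if (T < cfg$n_timepoints) {
      dpos <- rbind(dpos, matrix(0, cfg$n_timepoints - T, d))
    }
    g[["pos"]] <- dpos
  }
  dE2 <- dE; dim(dE2) <- c(P * O * T, d)
  le <- nn_linear_bwd(dE2, ch$F2, par[["emb.W"]])
  g[["emb.W"]] <- le$dW; g[["emb.b"]] <- le$db
  if (want_dF) {
    mv <- ch$mnum; dim(mv) <- c(P * O * T, d)
    dF <- le$dX * mv[, 1]
    if (!is.null(model$feat_stats)) {
      dF <- sweep(dF, 2, model$feat_stats$sd, "/")
    }
    dim(dF) <- c(P, O, T, df)
    g$dF <- dF
  }
  g
}

#' Temporal attention pooling of one object's time series
#'
#' Runs the temporal encoder over token sequences and masked-mean-pools the
#' valid positions, giving one fused vector per object. Masked timepoints
#' receive exactly zero attention and do not enter the pool, so the output
#' of a sequence with one valid timepoint is independent of what the masked
#' slots contain. With the temporal position embedding disabled the
#' operation is invariant to timepoint order.
#'
#' @param model A [risk_model()].
#' @param E Embedding array `n_seq x n_timepoints x d_model`.
#' @param mask Logical `n_seq x n_timepoints`; each sequence needs >= 1
#'   valid timepoint.
#' @param add_positions Override the model's temporal-embedding switch.
#' @return List with `pooled` (`n_seq x d_model`) and `attention`
#'   (last-layer weights, `n_seq x T x T x n_heads`).
#' @export
temporal_pool <- function(model, E, mask, add_positions = NULL) {
  stopifnot(inherits(model, "risk_model"), length(dim(E)) == 3)
  cfg <- model$config
  if (any(rowSums(mask) == 0)) abort("every sequence needs >= 1 valid timepoint.")
  addp <- add_positions %||% cfg$use_temporal_embedding
  N <- dim(E)[1]; T <- dim(E)[2]; d <- dim(E)[3]
  if (addp) {
    for (t in seq_len(T)) E[, t, ] <- E[, t, ] + rep(model$par[["pos"]][t, ], each = N)
  }
  E <- E * array(as.numeric(mask), dim(E))
  th <- nn_encoder_fwd(E, mask, level_pars(model$par, "th", cfg$n_layers),
                       cfg$n_heads)
  nv <- rowSums(mask)
  pooled <- matrix(0, N, d)
  for (t in seq_len(T)) pooled <- pooled + th$Y[, t, ] * mask[, t]
  list(pooled = pooled / nv, attention = th$attn_last)
}

#' Aggregate object vectors into one patient vector
#'
#' Prepends the learnable aggregation token to the object vectors, runs the
#' object-level encoder (no positional embedding over objects), and reads
#' the output at the aggregation position. The result is invariant to object
#' order and to appended masked padding objects.
#'
#' @param model A [risk_model()].
#' @param L Object-vector array `n_patients x n_objects x d_model`.
#' @param obj_mask Logical `n_patients x n_objects`; >= 1 valid object per
#'   patient.
#' @return List with `vector` (`n_patients x d_model`) and `attention`
#'   (last-layer weights over `1 + n_objects` tokens).
#' @export
lesion_pool <- function(model, L, obj_mask) {
  stopifnot(inherits(model, "risk_model"), length(dim(L)) == 3)
  if (any(rowSums(obj_mask) == 0)) abort("every patient needs >= 1 valid object.")
  cfg <- model$config
  P <- dim(L)[1]; O <- dim(L)[2]; d <- dim(L)[3]
  L <- L * array(as.numeric(obj_mask), dim(L))
  Xo <- array(0, c(P, O + 1L, d))
  Xo[, 1, ] <- rep(model$par[["agg"]], each = P)
  Xo[, 2:(O + 1L), ] <- L
  om <- cbind(rep(TRUE, P), obj_mask)
  oh <- nn_encoder_fwd(Xo, om, level_pars(model$par, "oh", cfg$n_layers),
                       cfg$n_heads)
  pv <- oh$Y[, 1, , drop = FALSE]; dim(pv) <- c(P, d)
  list(vector = pv, attention = oh$attn_last)
}

#' Risk head: patient vector to poor-OS probability
#'
#' Applies the MLP + softmax head. The risk is the probability of the
#' poor-OS class (overall survival < 12 months); a risk above the frozen
#' Youden cutoff assigns the high-risk group.
#'
#' @param model A [risk_model()].
#' @param patient_vector Numeric matrix `n x d_model` (or a single vector).
#' @return Tibble with `risk` (in `[0, 1]`), `logit_poor`, `logit_good`.
#' @export
predict_risk <- function(model, patient_vector) {
  if (is.null(dim(patient_vector))) patient_vector <- matrix(patient_vector, 1)
  if (any(!is.finite(patient_vector))) abort("patient vector must be finite.")
  par <- model$par
  h1 <- pmax(nn_linear(patient_vector, par[["head.W1"]], par[["head.b1"]]), 0)
  logits <- nn_linear(h1, par[["head.W2"]], par[["head.b2"]])
  pr <- softmax_rows(logits)
  tibble(risk = pr[, 1], logit_poor = logits[, 1], logit_good = logits[, 2])
}

# ---- cohort feature assembly -------------------------------------------

horizon_to_followups <- function(horizon) {
  if (is.numeric(horizon)) return(as.integer(horizon))
  switch(toupper(horizon),
         "BS" = 0L, "1F" = 1L, "2F" = 2L, "3F" = 3L, "4F" = 4L,
         abort("`horizon` must be BS, 1F, 2F, 3F, 4F or a follow-up count."))
}

#' Assemble the feature tensor for a cohort
#'
#' For image models, builds every lesion's 3-channel patch at each available
#' timepoint with [build_patch()] and extracts CNN features; for marker
#' models, embeds each normalised marker channel's series. Returns the
#' padded feature array together with the object and timepoint masks that
#' downstream attention uses.
#'
#' @param model A [risk_model()].
#' @param records List of `patient_record` objects.
#' @param stats Marker statistics ([marker_stats()]) required for marker
#'   models; computed on the training cohort.
#' @param augment Apply random rotation augmentation to each patch
#'   (training only).
#' @return List with `F` (`P x O x T x d_feat`), `obj_mask`, `tp_mask`,
#'   `patient_id`, `sites` (`P x O` character).
#' @export
cohort_features <- function(model, records, stats = NULL, augment = FALSE) {
  cfg <- model$config
  P <- length(records)
  T <- cfg$n_timepoints
  if (cfg$input == "image") {
    O <- max(map_int(records, ~ length(.x$lesions)))
  } else {
    if (is.null(stats)) abort("marker models need training `stats` (see marker_stats()).")
    O <- cfg$n_markers
  }
  F <- array(0, c(P, O, T, cfg$d_feat))
  obj_mask <- matrix(FALSE, P, O)
  tp_mask <- array(FALSE, c(P, O, T))
  sites <- matrix(NA_character_, P, O)
  for (p in seq_len(P)) {
    rec <- records[[p]]
    if (cfg$input == "image") {
      for (o in seq_along(rec$lesions)) {
        les <- rec$lesions[[o]]
        obj_mask[p, o] <- TRUE
        sites[p, o] <- les$site
        for (t in which(rec$timepoints_present[seq_len(T)])) {
          ann <- list(lesion_id = les$lesion_id, site = les$site,
                      timepoint = t - 1L, slice_index = les$slice_index,
                      x = les$box[["x"]], y = les$box[["y"]],
                      width = les$box[["width"]], height = les$box[["height"]])
          patch <- build_patch(rec$volumes[[t]], ann, out_size = cfg$patch_px)
          if (augment) patch <- augment_rotation(patch)
          F[p, o, t, ] <- extract_features(model, patch)
          tp_mask[p, o, t] <- TRUE
        }
      }
      bl <- F[p, , 1, , drop = FALSE]; dim(bl) <- c(O, cfg$d_feat)
      if (anyDuplicated(bl[obj_mask[p, ], , drop = FALSE])) {
        inform(sprintf("patient %s has duplicate lesion features at baseline.",
                       rec$patient_id))
      }
    } else {
      mk <- normalize_markers(rec$markers, stats)
      for (m in seq_len(cfg$n_markers)) {
        nm <- sprintf("marker_%d", m)
        rows <- mk[mk$marker == nm & !is.na(mk$value), ]
        if (nrow(rows) == 0) next
        obj_mask[p, m] <- TRUE
        sites[p, m] <- nm
        for (i in seq_len(nrow(rows))) {
          t <- rows$timepoint[i] + 1L
          if (t > T) next
          F[p, m, t, 1] <- rows$value[i]
          F[p, m, t, 1 + m] <- 1
          tp_mask[p, m, t] <- TRUE
        }
      }
      if (!any(obj_mask[p, ])) {
        # no usable marker anywhere: keep one masked-risk-free sentinel
        obj_mask[p, 1] <- TRUE
        tp_mask[p, 1, 1] <- TRUE
      }
    }
  }
  list(F = F, obj_mask = obj_mask, tp_mask = tp_mask,
       patient_id = map(records, "patient_id") |> unlist(), sites = sites)
}

truncate_features <- function(feats, max_followups) {
  keep <- seq_len(dim(feats$tp_mask)[3]) <= (max_followups + 1L)
  tp <- feats$tp_mask
  tp[, , !keep] <- FALSE
  obj <- feats$obj_mask & (apply(tp, c(1, 2), any))
  # a patient with no observed object inside the horizon (possible for
  # marker series measured late) keeps one zero-information token so the
  # model falls back to its prior instead of erroring
  empty <- rowSums(obj) == 0
  if (any(empty)) {
    obj[empty, 1] <- TRUE
    tp[empty, 1, 1] <- TRUE
    feats$F[empty, 1, 1, ] <- 0
  }
  feats$tp_mask <- tp
  feats$obj_mask <- obj
  feats
}

#' Score patients with a risk model
#'
#' Truncates each record to the requested follow-up horizon (BS = baseline
#' only, 1F/2F/... = baseline plus that many follow-ups), masks whatever the
#' horizon requests but the record lacks, and runs the full
#' extract-features, temporal-attention, object-attention, head pipeline. A
#' patient missing a follow-up inside the horizon is scored identically to
#' the shorter horizon — masking, never imputation.
#'
#' @param model A trained [risk_model()].
#' @param records List of `patient_record` objects (each with a baseline).
#' @param horizon `"BS"`, `"1F"`, `"2F"`, `"3F"`, `"4F"` or an integer
#'   follow-up count.
#' @param stats Marker statistics for marker models.
#' @param feats Optional precomputed [cohort_features()] (skips extraction).
#' @return Tibble with `patient_id` and `risk`.
#' @export
predict_cohort <- function(model, records = NULL, horizon = "2F",
                           stats = NULL, feats = NULL) {
  if (is.null(feats)) feats <- cohort_features(model, records, stats = stats)
  fr <- truncate_features(feats, horizon_to_followups(horizon))
  if (any(rowSums(fr$obj_mask) == 0)) abort("every record needs a baseline scan.")
  fwd <- model_forward(model, fr$F, fr$obj_mask, fr$tp_mask)
  tibble(patient_id = feats$patient_id, risk = fwd$risk)
}

#' Save / load a risk model checkpoint
#'
#' Single-file archive containing weights, the frozen extractor, the
#' configuration (including the seed) and any training history attached by
#' [train_risk_model()].
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @return `load_risk_model()` returns the model; `save_risk_model()` the
#'   path, invisibly.
#' @export
save_risk_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "risk_model"))
  m
}
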