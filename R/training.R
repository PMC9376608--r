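# Self-supervised pretraining, downstream fine-tuning with the
# delta/gamma-weighted ensemble, baseline modes (fully supervised, embedding
# fusion, margin classifier, unimodal), cross-validation, and metrics.

#' Training configuration
#'
#' SGD with momentum at an initial learning rate of 0.01; the learning rate
#' halves after `lr_halving_patience` epochs of validation-loss plateau, and
#' training stops early after `early_stop_patience` epochs without
#' improvement (best-epoch weights are restored).
#'
#' @param lr0 initial learning rate
#' @param momentum SGD momentum
#' @param lr_halving_patience epochs of plateau before the LR halves
#' @param early_stop_patience epochs of plateau before stopping
#' @param batch_size minibatch size
#' @param max_epochs maximum epochs
#' @param val_fraction validation fraction when no explicit fold is given
#' @param seed RNG seed controlling init, shuffling and dropout
#' @return list of class `ssml_train_config`
#' @export
train_config <- function(lr0 = 0.01, momentum = 0.9, lr_halving_patience = 25,
                         early_stop_patience = 10, batch_size = 64,
                         max_epochs = 200, val_fraction = 0.1, seed = 1) {
  stopifnot(lr0 > 0, batch_size >= 2, max_epochs >= 1)
  structure(list(lr0 = lr0, momentum = momentum,
                 lr_halving_patience = lr_halving_patience,
                 early_stop_patience = early_stop_patience,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "ssml_train_config")
}

#' Cross-validation plan
#'
#' One stratified holdout split, then `n_folds` disjoint validation folds
#' over the remaining pool.
#'
#' @param holdout_fraction fraction held out as the final test set
#' @param n_folds number of cross-validation folds
#' @param fold_val_fraction validation fraction within each fold (implied by
#'   the fold partition; recorded for audit)
#' @param seed RNG seed for the splits
#' @return list of class `ssml_cv_plan`
#' @export
cv_plan <- function(holdout_fraction = 0.10, n_folds = 10,
                    fold_val_fraction = 0.10, seed = 1) {
  structure(list(holdout_fraction = holdout_fraction,
                 n_folds = as.integer(n_folds),
                 fold_val_fraction = fold_val_fraction,
                 seed = as.integer(seed)),
            class = "ssml_cv_plan")
}

take_batches <- function(n, batch_size, shuffle_order) {
  split(shuffle_order, ceiling(seq_len(n) / batch_size))
}

onehot_grad <- function(p, y) {
  # d(mean NLL)/d logits for softmax + cross-entropy
  g <- p
  g[cbind(y + 1L, seq_len(ncol(p)))] <- g[cbind(y + 1L, seq_len(ncol(p)))] - 1
  g / ncol(p)
}

# ---- self-supervised pretraining -------------------------------------------

#' Self-supervised pretraining of both encoders
#'
#' Jointly optimises the AU and EEG encoders under the total pretext loss:
#' paradigm classification on the EEG embedding, transformation and window
#' identification on the AU embedding, and the KL alignment term pulling the
#' AU embedding toward the (gradient-stopped) EEG embedding.
#'
#' @param trialset unlabeled `ssml_trialset`
#' @param variant encoder variant "A", "B" or "C"
#' @param n_samples number of pretext samples to draw from the trial set
#' @param loss_config an [pretext_loss_config()]
#' @param config an [train_config()]
#' @return checkpoint: list with `encoder_au`, `encoder_eeg`, the three
#'   pretext heads, `variant` and `history` (per-epoch train/validation loss)
#' @export
pretrain <- function(trialset, variant = "A", n_samples = 10 * length(trialset),
                     loss_config = pretext_loss_config(),
                     config = train_config()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  ds <- build_pretext_dataset(trialset, n_samples, seed = config$seed)
  n <- length(ds$y_para)
  n_val <- max(2L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)

  enc_au <- build_encoder(encoder_config(variant, "AU"))
  enc_eeg <- build_encoder(encoder_config(variant, "EEG"))
  head_para <- build_heads("pretext_eeg")
  head_st <- build_heads("pretext_au_st")
  head_win <- build_heads("pretext_au_win")

  vel <- list(au = NULL, eeg = NULL, para = NULL, st = NULL, win = NULL)
  lr <- config$lr0
  best <- list(val = Inf, epoch = 0L, nets = NULL)
  plateau <- 0L
  history <- data.frame()

  val_losses <- function() {
    zau <- encode(enc_au, ds$au[, , , val_idx, drop = FALSE])
    zeeg <- encode(enc_eeg, ds$eeg[, , , val_idx, drop = FALSE])
    p_para <- softmax_cols(nn_forward(head_para, zeeg)$out)
    p_st <- softmax_cols(nn_forward(head_st, zau)$out)
    p_win <- softmax_cols(nn_forward(head_win, zau)$out)
    L_para <- paradigm_loss(p_para, ds$y_para[val_idx])
    tl <- transformation_losses(p_st, ds$y_st[val_idx], p_win, ds$y_win[val_idx])
    L_KLD <- alignment_loss(zau, zeeg, loss_config)
    list(L_para = L_para, L_st = tl$L_st, L_win = tl$L_win, L_KLD = L_KLD,
         total = total_pretext_loss(L_para, tl$L_win, tl$L_st, L_KLD, loss_config))
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    batches <- take_batches(length(ord), config$batch_size, ord)
    tr_loss <- 0
    for (b in batches) {
      if (length(b) < 2) next
      fa <- nn_forward(enc_au, ds$au[, , , b, drop = FALSE], training = TRUE)
      fe <- nn_forward(enc_eeg, ds$eeg[, , , b, drop = FALSE], training = TRUE)
      enc_au <- fa$net; enc_eeg <- fe$net
      zau <- fa$out; zeeg <- fe$out
      hp <- nn_forward(head_para, zeeg, training = TRUE); head_para <- hp$net
      hs <- nn_forward(head_st, zau, training = TRUE); head_st <- hs$net
      hw <- nn_forward(head_win, zau, training = TRUE); head_win <- hw$net
      p_para <- softmax_cols(hp$out)
      p_st <- softmax_cols(hs$out)
      p_win <- softmax_cols(hw$out)
      L_para <- paradigm_loss(p_para, ds$y_para[b])
      tl <- transformation_losses(p_st, ds$y_st[b], p_win, ds$y_win[b])
      L_KLD <- alignment_loss(zau, zeeg, loss_config)
      tr_loss <- tr_loss + length(b) *
        total_pretext_loss(L_para, tl$L_win, tl$L_st, L_KLD, loss_config)

      bp <- nn_backward(head_para, hp$caches, onehot_grad(p_para, ds$y_para[b]))
      bs <- nn_backward(head_st, hs$caches,
                        loss_config$beta * onehot_grad(p_st, ds$y_st[b]))
      bw <- nn_backward(head_win, hw$caches,
                        loss_config$alpha * onehot_grad(p_win, ds$y_win[b]))
      d_zau <- bs$dx + bw$dx + alignment_loss_grad_zau(zau, zeeg, loss_config)
      d_zeeg <- bp$dx                      # no KLD gradient into the target side
      ba <- nn_backward(enc_au, fa$caches, d_zau)
      be <- nn_backward(enc_eeg, fe$caches, d_zeeg)

      up <- nn_update_sgd(enc_au, ba$grads, lr, vel$au, config$momentum)
      enc_au <- up$net; vel$au <- up$vel
      up <- nn_update_sgd(enc_eeg, be$grads, lr, vel$eeg, config$momentum)
      enc_eeg <- up$net; vel$eeg <- up$vel
      up <- nn_update_sgd(head_para, bp$grads, lr, vel$para, config$momentum)
      head_para <- up$net; vel$para <- up$vel
      up <- nn_update_sgd(head_st, bs$grads, lr, vel$st, config$momentum)
      head_st <- up$net; vel$st <- up$vel
      up <- nn_update_sgd(head_win, bw$grads, lr, vel$win, config$momentum)
      head_win <- up$net; vel$win <- up$vel
    }
    tr_loss <- tr_loss / length(tr_idx)
    if (!is.finite(tr_loss)) stop("pretraining diverged (non-finite loss)")
    vl <- val_losses()
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         val_loss = vl$total, val_L_st = vl$L_st,
                                         val_L_win = vl$L_win,
                                         val_L_para = vl$L_para,
                                         val_L_KLD = vl$L_KLD, lr = lr))
    if (vl$total < best$val - 1e-6) {
      best <- list(val = vl$total, epoch = epoch,
                   nets = list(enc_au, enc_eeg, head_para, head_st, head_win))
      plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau %% config$lr_halving_patience == 0L) lr <- lr / 2
      if (plateau >= config$early_stop_patience) break
    }
  }
  if (!is.null(best$nets)) {
    enc_au <- best$nets[[1]]; enc_eeg <- best$nets[[2]]
    head_para <- best$nets[[3]]; head_st <- best$nets[[4]]; head_win <- best$nets[[5]]
  }
  list(encoder_au = enc_au, encoder_eeg = enc_eeg, head_para = head_para,
       head_st = head_st, head_win = head_win, variant = variant,
       loss_config = loss_config, history = history)
}

# ---- downstream ------------------------------------------------------------

#' Weighted-ensemble prediction
#'
#' The final probability of upcoming stuttered speech is a sigmoid of the
#' weighted sum of the two branch logits:
#' `sigmoid(delta * y_eeg + gamma * y_au)`.
#'
#' @param y_eeg_logit,y_au_logit pre-sigmoid logits of the EEG and AU
#'   downstream heads (vectors)
#' @param weights list with nonnegative `delta` and `gamma`
#' @return probability vector in (0, 1)
#' @export
ensemble_predict <- function(y_eeg_logit, y_au_logit, weights) {
  stopifnot(weights$delta >= 0, weights$gamma >= 0)
  sigmoid(weights$delta * y_eeg_logit + weights$gamma * y_au_logit)
}

# binary-cross-entropy fine-tuning of one (encoder, head) branch
train_binary_branch <- function(encoder, head, x, y, tr_idx, val_idx, config, lr0 = NULL) {
  vel_e <- NULL; vel_h <- NULL
  lr <- if (is.null(lr0)) config$lr0 else lr0
  best <- list(val = Inf, nets = list(encoder, head))
  plateau <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    for (b in take_batches(length(ord), config$batch_size, ord)) {
      if (length(b) < 2) next
      fe <- nn_forward(encoder, x[, , , b, drop = FALSE], training = TRUE)
      encoder <- fe$net
      fh <- nn_forward(head, fe$out, training = TRUE)
      head <- fh$net
      p <- sigmoid(fh$out)
      dz <- (p - matrix(y[b], 1)) / length(b)
      bh <- nn_backward(head, fh$caches, dz)
      be <- nn_backward(encoder, fe$caches, bh$dx)
      up <- nn_update_sgd(encoder, be$grads, lr, vel_e, config$momentum)
      encoder <- up$net; vel_e <- up$vel
      up <- nn_update_sgd(head, bh$grads, lr, vel_h, config$momentum)
      head <- up$net; vel_h <- up$vel
    }
    zl <- branch_logits(encoder, head, x, val_idx)
    pv <- sigmoid(zl)
    vl <- -mean(y[val_idx] * log(pmax(pv, PROB_EPS)) +
                  (1 - y[val_idx]) * log(pmax(1 - pv, PROB_EPS)))
    if (!is.finite(vl)) stop("downstream training diverged (non-finite loss)")
    if (vl < best$val - 1e-6) {
      best <- list(val = vl, nets = list(encoder, head)); plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau %% config$lr_halving_patience == 0L) lr <- lr / 2
      if (plateau >= config$early_stop_patience) break
    }
  }
  list(encoder = best$nets[[1]], head = best$nets[[2]], val_loss = best$val)
}

branch_logits <- function(encoder, head, x, idx) {
  z <- encode(encoder, x[, , , idx, drop = FALSE])
  as.vector(nn_forward(head, z)$out)
}

# head-only binary training on frozen (cached) embeddings
train_head_binary <- function(head, z, y, tr_idx, val_idx, config) {
  vel <- NULL
  lr <- config$lr0
  best <- list(val = Inf, head = head)
  plateau <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    for (b in take_batches(length(ord), config$batch_size, ord)) {
      if (length(b) < 2) next
      fh <- nn_forward(head, z[, b, drop = FALSE], training = TRUE)
      head <- fh$net
      p <- sigmoid(fh$out)
      dz <- (p - matrix(y[b], 1)) / length(b)
      bh <- nn_backward(head, fh$caches, dz)
      up <- nn_update_sgd(head, bh$grads, lr, vel, config$momentum)
      head <- up$net; vel <- up$vel
    }
    pv <- sigmoid(as.vector(nn_forward(head, z[, val_idx, drop = FALSE])$out))
    vl <- -mean(y[val_idx] * log(pmax(pv, PROB_EPS)) +
                  (1 - y[val_idx]) * log(pmax(1 - pv, PROB_EPS)))
    if (!is.finite(vl)) stop("head training diverged (non-finite loss)")
    if (vl < best$val - 1e-6) {
      best <- list(val = vl, head = head); plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau %% config$lr_halving_patience == 0L) lr <- lr / 2
      if (plateau >= config$early_stop_patience) break
    }
  }
  best$head
}

# grid search for the ensemble multipliers on validation accuracy;
# ties broken toward the smallest delta + gamma, then the smallest delta
search_ensemble_weights <- function(z_eeg, z_au, y, grid = seq(0, 2, by = 0.1)) {
  cand <- expand.grid(delta = grid, gamma = grid)
  cand <- cand[cand$delta + cand$gamma > 0, ]   # (0,0) is a constant classifier
  acc <- vapply(seq_len(nrow(cand)), function(i) {
    p <- sigmoid(cand$delta[i] * z_eeg + cand$gamma[i] * z_au)
    mean((p > 0.5) == y)
  }, numeric(1))
  ord <- order(-acc, cand$delta + cand$gamma, cand$delta)
  list(delta = cand$delta[ord[1]], gamma = cand$gamma[ord[1]],
       val_accuracy = acc[ord[1]])
}

#' Train the downstream fluency classifier
#'
#' Modes: `ssml_ensemble` keeps the pretrained encoders frozen and trains a
#' per-branch downstream head (3 dense layers to one logit) on the cached
#' embeddings under binary cross-entropy, then selects the ensemble
#' multipliers delta and gamma by validation grid search; `fsml` trains the
#' same architecture end to end from random initialisation (fully
#' supervised); `fusion` trains one head on the concatenated 128-dim frozen
#' embedding; `margin_classifier` fits an RBF support-vector machine on the
#' frozen embeddings; `unimodal_eeg`/`unimodal_au` use one frozen branch
#' only.
#'
#' @param checkpoint a [pretrain()] checkpoint (ignored with mode "fsml",
#'   where encoders start from random weights and are trained end to end)
#' @param labeled a balanced `ssml_trialset` of fluent/stuttered trials
#' @param config an [train_config()]
#' @param mode training mode, see above
#' @param val_idx optional explicit validation indices (e.g. a CV fold);
#'   otherwise a stratified `val_fraction` split is drawn
#' @param strict_balance error if the labeled classes are unbalanced
#' @return an `ssml_model` with branch networks, `weights` (delta, gamma),
#'   and `metrics_val` on the validation split
#' @export
train_downstream <- function(checkpoint, labeled,
                             config = train_config(),
                             mode = c("ssml_ensemble", "fsml", "fusion",
                                      "margin_classifier", "unimodal_eeg",
                                      "unimodal_au"),
                             val_idx = NULL, strict_balance = TRUE) {
  mode <- match.arg(mode)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  tens <- trialset_tensors(labeled)
  if (!all(tens$fluency %in% c("fluent", "stuttered")))
    stop("downstream set may contain only fluent/stuttered trials")
  y <- as.integer(tens$fluency == "stuttered")
  if (strict_balance && sum(y == 0) != sum(y == 1))
    stop("unbalanced downstream set: ", sum(y == 0), " fluent vs ",
         sum(y == 1), " stuttered; balance first (balance_trialset)")
  n <- length(y)
  if (is.null(val_idx)) {
    n_val <- max(2L, round(config$val_fraction * n))
    val_idx <- stratified_sample(y, n_val)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  variant <- if (!is.null(checkpoint)) checkpoint$variant else "A"
  if (mode != "fsml" && is.null(checkpoint))
    stop("mode '", mode, "' requires a pretrained checkpoint; ",
         "use mode 'fsml' for fully supervised training from scratch")

  model <- list(mode = mode, variant = variant, config = config)
  if (mode == "fsml") {
    # fully supervised: both branches end to end from random initialisation
    br_e <- train_binary_branch(build_encoder(encoder_config(variant, "EEG")),
                                build_heads("downstream"),
                                tens$eeg, y, tr_idx, val_idx, config)
    br_a <- train_binary_branch(build_encoder(encoder_config(variant, "AU")),
                                build_heads("downstream"),
                                tens$au, y, tr_idx, val_idx, config)
    z_e <- branch_logits(br_e$encoder, br_e$head, tens$eeg, val_idx)
    z_a <- branch_logits(br_a$encoder, br_a$head, tens$au, val_idx)
    w <- search_ensemble_weights(z_e, z_a, y[val_idx])
    model$encoder_eeg <- br_e$encoder; model$head_eeg <- br_e$head
    model$encoder_au <- br_a$encoder; model$head_au <- br_a$head
    model$weights <- list(delta = w$delta, gamma = w$gamma)
    p_val <- ensemble_predict(z_e, z_a, model$weights)
  } else if (mode == "ssml_ensemble") {
    # frozen pretrained encoders; heads trained on cached embeddings
    ze <- encode(checkpoint$encoder_eeg, tens$eeg)
    za <- encode(checkpoint$encoder_au, tens$au)
    h_e <- train_head_binary(build_heads("downstream"), ze, y, tr_idx, val_idx, config)
    h_a <- train_head_binary(build_heads("downstream"), za, y, tr_idx, val_idx, config)
    z_e <- as.vector(nn_forward(h_e, ze[, val_idx, drop = FALSE])$out)
    z_a <- as.vector(nn_forward(h_a, za[, val_idx, drop = FALSE])$out)
    w <- search_ensemble_weights(z_e, z_a, y[val_idx])
    model$encoder_eeg <- checkpoint$encoder_eeg; model$head_eeg <- h_e
    model$encoder_au <- checkpoint$encoder_au; model$head_au <- h_a
    model$weights <- list(delta = w$delta, gamma = w$gamma)
    p_val <- ensemble_predict(z_e, z_a, model$weights)
  } else if (mode == "unimodal_eeg" || mode == "unimodal_au") {
    enc <- if (mode == "unimodal_eeg") checkpoint$encoder_eeg else checkpoint$encoder_au
    z <- encode(enc, if (mode == "unimodal_eeg") tens$eeg else tens$au)
    h <- train_head_binary(build_heads("downstream"), z, y, tr_idx, val_idx, config)
    model$encoder <- enc; model$head <- h
    p_val <- sigmoid(as.vector(nn_forward(h, z[, val_idx, drop = FALSE])$out))
  } else if (mode == "fusion") {
    zf <- rbind(encode(checkpoint$encoder_eeg, tens$eeg),
                encode(checkpoint$encoder_au, tens$au))
    h <- train_head_binary(build_heads("fusion"), zf, y, tr_idx, val_idx, config)
    model$encoder_eeg <- checkpoint$encoder_eeg
    model$encoder_au <- checkpoint$encoder_au
    model$head <- h
    p_val <- sigmoid(as.vector(nn_forward(h, zf[, val_idx, drop = FALSE])$out))
  } else { # margin_classifier on frozen embeddings
    z <- rbind(encode(checkpoint$encoder_eeg, tens$eeg),
               encode(checkpoint$encoder_au, tens$au))
    fit <- e1071::svm(x = t(z[, tr_idx, drop = FALSE]), y = factor(y[tr_idx]),
                      kernel = "radial", scale = TRUE)
    model$svm <- fit
    model$encoder_eeg <- checkpoint$encoder_eeg
    model$encoder_au <- checkpoint$encoder_au
    dv <- attr(stats::predict(fit, t(z[, val_idx, drop = FALSE]),
                              decision.values = TRUE), "decision.values")
    sgn <- if (colnames(dv)[1] == "0/1") -1 else 1
    p_val <- sigmoid(sgn * as.vector(dv))
    model$dv_sign <- sgn
  }
  model$metrics_val <- evaluate_metrics(p_val, y[val_idx])
  model$val_idx <- val_idx
  class(model) <- "ssml_model"
  model
}

stratified_sample <- function(y, n_val) {
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  k0 <- max(1L, round(n_val * length(idx0) / length(y)))
  k1 <- max(1L, n_val - k0)
  sort(c(sample(idx0, min(k0, length(idx0))), sample(idx1, min(k1, length(idx1)))))
}

#' Predict stuttering probability for new trials
#'
#' @param object an `ssml_model`
#' @param trialset an `ssml_trialset` (or a `trialset_tensors()` list)
#' @param ... unused
#' @return vector of probabilities of "stuttered"
#' @export
predict.ssml_model <- function(object, trialset, ...) {
  tens <- if (inherits(trialset, "ssml_trialset")) trialset_tensors(trialset)
          else trialset
  n <- dim(tens$au)[4]
  idx <- seq_len(n)
  switch(object$mode,
    ssml_ensemble = ,
    fsml = {
      z_e <- branch_logits(object$encoder_eeg, object$head_eeg, tens$eeg, idx)
      z_a <- branch_logits(object$encoder_au, object$head_au, tens$au, idx)
      ensemble_predict(z_e, z_a, object$weights)
    },
    unimodal_eeg = sigmoid(branch_logits(object$encoder, object$head, tens$eeg, idx)),
    unimodal_au = sigmoid(branch_logits(object$encoder, object$head, tens$au, idx)),
    fusion = {
      z <- rbind(encode(object$encoder_eeg, tens$eeg),
                 encode(object$encoder_au, tens$au))
      sigmoid(as.vector(nn_forward(object$head, z)$out))
    },
    margin_classifier = {
      z <- rbind(encode(object$encoder_eeg, tens$eeg),
                 encode(object$encoder_au, tens$au))
      dv <- attr(stats::predict(object$svm, t(z), decision.values = TRUE),
                 "decision.values")
      sigmoid(object$dv_sign * as.vector(dv))
    })
}

# ---- metrics and cross-validation ------------------------------------------

#' Classification metrics: AUC, F1, accuracy
#'
#' AUC by the rank (Wilcoxon) statistic; F1 with "stuttered" (label 1) as the
#' positive class at a 0.5 threshold; accuracy in percent.
#'
#' @param scores predicted probabilities of the positive class
#' @param labels 0/1 vector (or fluent/stuttered factor/character)
#' @return list of class `ssml_metrics` with `auc`, `f1`, `accuracy_percent`
#' @export
evaluate_metrics <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "stuttered")
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores > 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(auc = auc, f1 = f1,
                 accuracy_percent = 100 * mean(pred == labels),
                 n = length(labels)),
            class = "ssml_metrics")
}

#' @export
print.ssml_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f | F1 %.3f | accuracy %.1f%% (n=%d)\n",
              x$auc, x$f1, x$accuracy_percent, x$n))
  invisible(x)
}

#' Cross-validated downstream evaluation
#'
#' One stratified holdout split (subjects represented where possible), then
#' `n_folds` disjoint validation folds over the pool; per-fold models are
#' trained with [train_downstream()] and the holdout is scored with the model
#' of the best-validation fold.
#'
#' @param labeled balanced `ssml_trialset`
#' @param plan an [cv_plan()]
#' @param config an [train_config()]
#' @param checkpoint optional [pretrain()] checkpoint
#' @param mode passed to [train_downstream()]
#' @return list with `per_fold` (data.frame of fold metrics), `aggregate`
#'   (mean and sd), `holdout` (`ssml_metrics`), and `best_model`
#' @export
cross_validate <- function(labeled, plan = cv_plan(), config = train_config(),
                           checkpoint = NULL, mode = "ssml_ensemble") {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(plan$seed)
  tens_labels <- vapply(labeled$trials, `[[`, "", "fluency")
  y <- as.integer(tens_labels == "stuttered")
  n <- length(y)
  min_needed <- plan$n_folds * 2L
  if (sum(y == 1) < min_needed / 2 || sum(y == 0) < min_needed / 2)
    stop("too few trials for ", plan$n_folds, "-fold CV: need at least ",
         min_needed, " (", min_needed / 2, " per class)")
  n_hold <- max(2L, round(plan$holdout_fraction * n))
  hold_idx <- stratified_sample(y, n_hold)
  pool_idx <- setdiff(seq_len(n), hold_idx)
  folds <- make_folds(y[pool_idx], plan$n_folds)

  per_fold <- data.frame()
  best <- list(acc = -Inf, model = NULL)
  for (f in seq_len(plan$n_folds)) {
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    m <- train_downstream(checkpoint, labeled[pool_idx], fold_cfg, mode = mode,
                          val_idx = which(folds == f), strict_balance = FALSE)
    mv <- m$metrics_val
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, auc = mv$auc, f1 = mv$f1,
                                 accuracy_percent = mv$accuracy_percent))
    if (mv$accuracy_percent > best$acc) best <- list(acc = mv$accuracy_percent, model = m)
  }
  hold_p <- predict(best$model, labeled[hold_idx])
  list(per_fold = per_fold,
       aggregate = data.frame(
         metric = c("auc", "f1", "accuracy_percent"),
         mean = c(mean(per_fold$auc), mean(per_fold$f1),
                  mean(per_fold$accuracy_percent)),
         sd = c(stats::sd(per_fold$auc), stats::sd(per_fold$f1),
                stats::sd(per_fold$accuracy_percent))),
       holdout = evaluate_metrics(hold_p, y[hold_idx]),
       holdout_idx = hold_idx,
       best_model = best$model)
}

make_folds <- function(y, n_folds) {
  f <- integer(length(y))
  classes <- sort(unique(y))
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    # alternate the fold fill order per class so per-class remainders land on
    # different folds and the combined fold sizes stay as equal as possible
    levels <- if (ci %% 2 == 1) seq_len(n_folds) else rev(seq_len(n_folds))
    f[idx] <- sample(rep_len(levels, length(idx)))
  }
  f
}
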