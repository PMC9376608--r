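# Multimodal Shapley explanations: per-trial attribution maps for each
# modality via DeepLIFT rescale-rule multipliers against a population-matched
# reference set, an exact-Shapley brute-force oracle for validation, and
# completeness (additivity) reporting.

#' Select population-matched reference trials
#'
#' References are sampled without replacement from trials sharing the
#' explained trial's subject, session and paradigm, excluding the trial
#' itself; both fluency outcomes may appear.
#'
#' @param trialset an `ssml_trialset`
#' @param trial_index index of the explained trial within `trialset`
#' @param k number of references (default 20)
#' @param seed RNG seed for the draw
#' @return list of class `ssml_reference_set` with `indices`, `trials`, and
#'   the matching `policy`
#' @export
select_references <- function(trialset, trial_index, k = 20, seed = 1) {
  tr <- trialset$trials[[trial_index]]
  lab <- trialset_labels(trialset)
  eligible <- which(lab$subject == tr$subject_id &
                      lab$session == tr$session_id &
                      lab$paradigm == tr$paradigm)
  eligible <- setdiff(eligible, trial_index)
  if (length(eligible) < k)
    stop("not enough matched reference trials (", length(eligible),
         " eligible, ", k, " requested)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx <- sample(eligible, k)
  structure(list(indices = idx, trials = trialset$trials[idx],
                 policy = list(subject = tr$subject_id, session = tr$session_id,
                               paradigm = tr$paradigm, k = k, seed = seed)),
            class = "ssml_reference_set")
}

# stack a list of trials into branch tensors
stack_trials <- function(trials) {
  n <- length(trials)
  au <- array(0, c(1, N_AU_ROWS, N_AU_FRAMES, n))
  eeg <- array(0, c(1, N_EEG_CHANNELS, N_EEG_SAMPLES, n))
  for (i in seq_len(n)) {
    au[1, , , i] <- trials[[i]]$au
    eeg[1, , , i] <- trials[[i]]$eeg
  }
  list(au = au, eeg = eeg)
}

# replicate one trial k times along the batch axis
rep_trial <- function(x, k) {
  d <- dim(x)
  array(rep(x, k), c(d[1:3], k))
}

#' Explain one trial against a reference set
#'
#' Produces one attribution map per modality by backpropagating DeepLIFT
#' rescale-rule multipliers from the model output (the post-sigmoid stuttering
#' probability) to each input, once per reference, and averaging the
#' single-reference attributions over the reference set. The base value is
#' the mean model output over the references, so the two maps satisfy the
#' completeness property: `sum(e_au) + sum(e_eeg) = f(trial) - base_value`
#' (exact for the average-pooling variant-A networks; approximate through max
#' pooling in variants B/C).
#'
#' @param model a differentiable `ssml_model` (any mode except
#'   `margin_classifier`)
#' @param trial an `ssml_trial`
#' @param refs an `ssml_reference_set` (or list of `ssml_trial`)
#' @return list of class `ssml_explanation` with `e_au` (17 x 87), `e_eeg`
#'   (62 x 192), `base_value`, and `f_x`
#' @export
explain_trial <- function(model, trial, refs) {
  if (model$mode == "margin_classifier")
    stop("the margin classifier has no gradient access; explanations need a ",
         "differentiable model")
  trials_r <- if (inherits(refs, "ssml_reference_set")) refs$trials else refs
  k <- length(trials_r)
  stopifnot(k >= 1)
  xr <- stack_trials(trials_r)
  xx <- list(au = rep_trial(stack_trials(list(trial))$au, k),
             eeg = rep_trial(stack_trials(list(trial))$eeg, k))

  branch <- function(enc, head, x, r) {
    fx_e <- nn_forward(enc, x, training = FALSE)
    fr_e <- nn_forward(enc, r, training = FALSE)
    fx_h <- nn_forward(head, fx_e$out, training = FALSE)
    fr_h <- nn_forward(head, fr_e$out, training = FALSE)
    list(zx = as.vector(fx_h$out), zr = as.vector(fr_h$out),
         mult = function(m_logit) {
       m <- nn_multipliers(head, fx_h$caches, fr_h$caches, matrix(m_logit, 1, k))
       nn_multipliers(enc, fx_e$caches, fr_e$caches, m)
     })
  }

  if (model$mode %in% c("ssml_ensemble", "fsml")) {
    br_e <- branch(model$encoder_eeg, model$head_eeg, xx$eeg, xr$eeg)
    br_a <- branch(model$encoder_au, model$head_au, xx$au, xr$au)
    s_x <- model$weights$delta * br_e$zx + model$weights$gamma * br_a$zx
    s_r <- model$weights$delta * br_e$zr + model$weights$gamma * br_a$zr
    m_s <- sigmoid_mult(s_x, s_r)
    m_eeg <- br_e$mult(model$weights$delta * m_s)
    m_au <- br_a$mult(model$weights$gamma * m_s)
    f_x <- sigmoid(s_x[1]); f_r <- sigmoid(s_r)
  } else if (model$mode %in% c("unimodal_eeg", "unimodal_au")) {
    x1 <- if (model$mode == "unimodal_eeg") xx$eeg else xx$au
    r1 <- if (model$mode == "unimodal_eeg") xr$eeg else xr$au
    br <- branch(model$encoder, model$head, x1, r1)
    m_s <- sigmoid_mult(br$zx, br$zr)
    m1 <- br$mult(m_s)
    f_x <- sigmoid(br$zx[1]); f_r <- sigmoid(br$zr)
    if (model$mode == "unimodal_eeg") {
      m_eeg <- m1; m_au <- array(0, dim(xx$au))
    } else {
      m_au <- m1; m_eeg <- array(0, dim(xx$eeg))
    }
  } else { # fusion
    fe_x <- nn_forward(model$encoder_eeg, xx$eeg, training = FALSE)
    fe_r <- nn_forward(model$encoder_eeg, xr$eeg, training = FALSE)
    fa_x <- nn_forward(model$encoder_au, xx$au, training = FALSE)
    fa_r <- nn_forward(model$encoder_au, xr$au, training = FALSE)
    zx <- rbind(fe_x$out, fa_x$out); zr <- rbind(fe_r$out, fa_r$out)
    fh_x <- nn_forward(model$head, zx, training = FALSE)
    fh_r <- nn_forward(model$head, zr, training = FALSE)
    sx <- as.vector(fh_x$out); sr <- as.vector(fh_r$out)
    m_s <- sigmoid_mult(sx, sr)
    m_z <- nn_multipliers(model$head, fh_x$caches, fh_r$caches, matrix(m_s, 1, k))
    m_eeg <- nn_multipliers(model$encoder_eeg, fe_x$caches, fe_r$caches,
                            m_z[seq_len(EMBED_DIM), , drop = FALSE])
    m_au <- nn_multipliers(model$encoder_au, fa_x$caches, fa_r$caches,
                           m_z[EMBED_DIM + seq_len(EMBED_DIM), , drop = FALSE])
    f_x <- sigmoid(sx[1]); f_r <- sigmoid(sr)
  }

  phi_eeg <- m_eeg * (xx$eeg - xr$eeg)       # per-reference contribution maps
  phi_au <- m_au * (xx$au - xr$au)
  e_eeg <- apply(phi_eeg[1, , , , drop = FALSE], c(2, 3), mean)
  e_au <- apply(phi_au[1, , , , drop = FALSE], c(2, 3), mean)
  rownames(e_au) <- rownames(trial$au) %||% au_default_names()
  rownames(e_eeg) <- rownames(trial$eeg) %||% channel_whitelist_62()
  structure(list(e_au = e_au, e_eeg = e_eeg, base_value = mean(f_r), f_x = f_x),
            class = "ssml_explanation")
}

# rescale-rule multiplier through the final sigmoid (scalar per reference)
sigmoid_mult <- function(s_x, s_r) {
  ds <- s_x - s_r
  ifelse(abs(ds) > 1e-9,
         (sigmoid(s_x) - sigmoid(s_r)) / ds,
         sigmoid(s_x) * (1 - sigmoid(s_x)))
}

#' Explain many trials with the population-matched reference policy
#'
#' @param model a differentiable `ssml_model`
#' @param trialset an `ssml_trialset`
#' @param indices trials to explain (default all)
#' @param k references per trial
#' @param seed base RNG seed (each trial uses `seed + index`)
#' @return list with `explanations` (list of `ssml_explanation`) and
#'   `labels` (fluency per explained trial)
#' @export
explain_trialset <- function(model, trialset, indices = seq_along(trialset$trials),
                             k = 20, seed = 1) {
  ex <- vector("list", length(indices))
  for (j in seq_along(indices)) {
    i <- indices[j]
    refs <- select_references(trialset, i, k = k, seed = seed + i)
    ex[[j]] <- explain_trial(model, trialset$trials[[i]], refs)
  }
  list(explanations = ex,
       labels = vapply(trialset$trials[indices], `[[`, "", "fluency"))
}

#' Exact Shapley values by coalition enumeration
#'
#' Brute-force oracle for validating attribution methods on small models:
#' enumerates all 2^n feature coalitions, with missing features set to the
#' reference value, and computes the exact Shapley value of every feature.
#'
#' @param f vectorised model: a function taking a matrix (rows = inputs) and
#'   returning a numeric vector
#' @param x feature vector to explain (at most 20 features)
#' @param reference reference feature vector
#' @return numeric vector of exact Shapley attributions; satisfies
#'   `sum(phi) = f(x) - f(reference)`
#' @export
exact_shapley_oracle <- function(f, x, reference) {
  n <- length(x)
  stopifnot(length(reference) == n)
  if (n > 20) stop("too many features for exact enumeration: ", n, " > 20")
  n_coal <- 2^n
  masks <- 0:(n_coal - 1)
  inmask <- matrix(FALSE, n_coal, n)
  for (i in seq_len(n)) inmask[, i] <- bitwAnd(masks, 2^(i - 1)) > 0
  X <- matrix(reference, n_coal, n, byrow = TRUE)
  for (i in seq_len(n)) X[inmask[, i], i] <- x[i]
  v <- f(X)
  stopifnot(length(v) == n_coal)
  sizes <- rowSums(inmask)
  w <- factorial(0:(n - 1)) * factorial(n - 1 - (0:(n - 1))) / factorial(n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    without <- which(!inmask[, i])
    s <- sizes[without]
    phi[i] <- sum(w[s + 1] * (v[without + 2^(i - 1)] - v[without]))
  }
  phi
}

#' Completeness (additivity) report over a sample of trials
#'
#' For each trial, compares the summed attribution of both maps with
#' `f(trial) - base_value` and reports absolute and relative residuals with
#' summary quantiles. For average-pooling architectures the residuals are at
#' numerical precision; max-pooling layers make the rescale-rule
#' approximation visible here.
#'
#' @param model a differentiable `ssml_model`
#' @param trialset an `ssml_trialset`
#' @param indices trials to audit
#' @param k references per trial
#' @param seed base RNG seed
#' @return list with `per_trial` (data.frame) and `quantiles` of the relative
#'   residual
#' @export
additivity_report <- function(model, trialset, indices = seq_along(trialset$trials),
                              k = 20, seed = 1) {
  rows <- lapply(indices, function(i) {
    refs <- select_references(trialset, i, k = k, seed = seed + i)
    ex <- explain_trial(model, trialset$trials[[i]], refs)
    total <- sum(ex$e_au) + sum(ex$e_eeg)
    target <- ex$f_x - ex$base_value
    data.frame(trial = i, phi_sum = total, target = target,
               abs_residual = abs(total - target),
               rel_residual = abs(total - target) / max(abs(target), 1e-8))
  })
  per_trial <- do.call(rbind, rows)
  list(per_trial = per_trial,
       quantiles = stats::quantile(per_trial$rel_residual,
                                   c(0.25, 0.5, 0.75, 0.9, 1)))
}
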