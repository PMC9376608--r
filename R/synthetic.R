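# Synthetic multimodal trial generator with planted, recoverable structure,
# and a Monte-Carlo Bayes-optimal reference oracle computed from the planted
# likelihoods (closed-form Gaussian class means and noise covariances).

#' Synthetic dataset configuration
#'
#' Defaults describe the emulated study conditions: 7 subjects, 3 sessions
#' each, 400 trials per session, the four S1-S2 paradigms in equal mixture,
#' and an equal fluent/stuttered split. `effect_size` scales every planted
#' fluency difference (in units of the marginal noise SD); `noise_sd` is the
#' marginal SD of the AU and EEG noise processes.
#'
#' @param n_subjects,sessions_per_subject,trials_per_session cohort shape
#' @param paradigm_mix probabilities over WG, WAG, CW, CAW (sum to 1)
#' @param stutter_rate probability that a trial is stuttered
#' @param effect_size nonnegative scalar scaling all planted class differences
#' @param noise_sd marginal noise standard deviation
#' @param plant_au,plant_eeg plant the fluency signal in the AU / EEG modality
#' @param occurrence_prob probability that a trial actually expresses each of
#'   its class's planted bursts (upper-face, lower-face, and EEG markers are
#'   drawn independently); microexpression bursts do not occur on every trial,
#'   and this is what makes the class-specific attribution *timing*
#'   recoverable by the explanation ANOVA
#' @param seed integer seed; all generator randomness flows from it
#' @return list of class `ssml_synthetic_config`
#' @export
synthetic_config <- function(n_subjects = 7, sessions_per_subject = 3,
                             trials_per_session = 400,
                             paradigm_mix = c(WG = 0.25, WAG = 0.25,
                                              CW = 0.25, CAW = 0.25),
                             stutter_rate = 0.5, effect_size = 1,
                             noise_sd = 1, plant_au = TRUE, plant_eeg = TRUE,
                             occurrence_prob = 0.75, seed = 1) {
  stopifnot(abs(sum(paradigm_mix) - 1) < 1e-8, effect_size >= 0, noise_sd > 0,
            stutter_rate >= 0, stutter_rate <= 1,
            occurrence_prob > 0, occurrence_prob <= 1)
  if (is.null(names(paradigm_mix))) names(paradigm_mix) <- PARADIGM_LEVELS
  structure(list(n_subjects = n_subjects,
                 sessions_per_subject = sessions_per_subject,
                 trials_per_session = trials_per_session,
                 paradigm_mix = paradigm_mix, stutter_rate = stutter_rate,
                 effect_size = effect_size, noise_sd = noise_sd,
                 plant_au = plant_au, plant_eeg = plant_eeg,
                 occurrence_prob = occurrence_prob,
                 seed = as.integer(seed)),
            class = "ssml_synthetic_config")
}

gauss_bump <- function(n, center, sd) exp(-0.5 * ((seq_len(n) - center) / sd)^2)

# Fixed generator internals shared by the sampler and the Bayes oracle.
# AU noise: unit-marginal-SD smoothed Gaussian (banded smoothing matrix K,
# covariance sigma^2 K K'). EEG noise: circulant 1/f-shaped Gaussian with
# known spectrum. Fluency effects are fixed bump patterns scaled by
# effect_size; paradigm components and session offsets are class-independent.
synth_model <- function(config) {
  nf <- N_AU_FRAMES; ns <- N_EEG_SAMPLES
  # AU smoothing matrix: Gaussian kernel, rows scaled to unit L2 norm
  k <- stats::dnorm(-6:6, sd = 2)
  K <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    j <- pmin(pmax(i + (-6:6), 1), nf)
    idx <- (i - 6):(i + 6)
    ok <- idx >= 1 & idx <= nf
    K[i, idx[ok]] <- K[i, idx[ok]] + k[ok]
  }
  K <- K / sqrt(rowSums(K^2))
  bump_e <- gauss_bump(nf, center = 15, sd = 6)    # ~250 ms at 58 frames/s
  bump_l <- gauss_bump(nf, center = 73, sd = 6)    # ~1,250 ms
  au_names <- au_default_names()
  upper_planted <- c("AU01", "AU02", "AU04", "AU06")
  lower_planted <- c("AU14", "AU15", "AU20")

  # EEG circulant 1/f spectrum, scaled to unit marginal SD
  f <- pmin(seq_len(ns) - 1, ns - (seq_len(ns) - 1)) * 128 / ns
  g <- 1 / sqrt(pmax(f, 1))
  g <- g / sqrt(mean(g^2))
  ch <- channel_whitelist_62()
  eeg_bump_e <- gauss_bump(ns, center = 32, sd = 10)    # ~250 ms at 128 Hz
  eeg_bump_l <- gauss_bump(ns, center = 160, sd = 10)   # ~1,250 ms

  # paradigm components (62 x 192 each), class-independent
  tms <- (seq_len(ns) - 1) / 128 * 1000
  word_resp <- -gauss_bump(ns, 0.15 * 128 + 1, 0.04 * 128) +
    gauss_bump(ns, 0.30 * 128 + 1, 0.06 * 128)
  ramp <- pmax(0, (tms - 500) / 1000)
  tone_resp <- gauss_bump(ns, 0.70 * 128 + 1, 0.05 * 128)
  mk_comp <- function(channels, wave) {
    m <- matrix(0, length(ch), ns, dimnames = list(ch, NULL))
    m[channels, ] <- matrix(wave, length(channels), ns, byrow = TRUE)
    m
  }
  amp <- 1.0
  comp_word <- mk_comp(c("FZ", "FCZ", "CZ", "F1", "F2", "FC1", "FC2"),
                       amp * word_resp)
  comp_cue <- mk_comp(c("CZ", "CPZ", "C1", "C2"), amp * ramp)
  comp_tone <- mk_comp(c("FCZ", "CZ", "T7", "T8"), amp * tone_resp)
  para_comp <- list(WG = comp_word, WAG = comp_word + comp_tone,
                    CW = comp_cue, CAW = comp_cue + comp_tone)

  list(K = K, bump_e = bump_e, bump_l = bump_l, au_names = au_names,
       upper_planted = upper_planted, lower_planted = lower_planted,
       au_baseline = 3.0, g = g, ch = ch,
       eeg_bump_e = eeg_bump_e, eeg_bump_l = eeg_bump_l,
       para_comp = para_comp, offset_sd = 0.2 * config$noise_sd,
       zones = time_zones())
}

# Per-class planted burst patterns. Each class has an upper-face marker, a
# lower-face marker (time-reversed between classes), and an EEG marker; a
# trial expresses each of its class's markers with probability
# occurrence_prob (independent Bernoulli draws).
synth_class_means <- function(config, model) {
  E <- config$effect_size
  zero_au <- matrix(0, N_AU_ROWS, N_AU_FRAMES,
                    dimnames = list(model$au_names, NULL))
  mk_au <- function(rows, bump) {
    m <- zero_au
    m[rows, ] <- matrix(E * bump, length(rows), N_AU_FRAMES, byrow = TRUE)
    m
  }
  zero_eeg <- matrix(0, N_EEG_CHANNELS, N_EEG_SAMPLES,
                     dimnames = list(model$ch, NULL))
  mk_eeg <- function(chan, bump) { m <- zero_eeg; m[chan, ] <- E * bump; m }
  out <- list(
    # stuttered: upper-face early, lower-face late, left-temporal early
    au_s_upper = if (config$plant_au) mk_au(model$upper_planted, model$bump_e) else zero_au,
    au_s_lower = if (config$plant_au) mk_au(model$lower_planted, model$bump_l) else zero_au,
    eeg_s = if (config$plant_eeg) mk_eeg("T7", model$eeg_bump_e) else zero_eeg,
    # fluent: the time-reversed facial pattern, right-frontal late
    au_f_upper = if (config$plant_au) mk_au(model$upper_planted, model$bump_l) else zero_au,
    au_f_lower = if (config$plant_au) mk_au(model$lower_planted, model$bump_e) else zero_au,
    eeg_f = if (config$plant_eeg) mk_eeg("FP2", model$eeg_bump_l) else zero_eeg)
  # full-expression class means (every marker present), used by the oracle
  out$au_s <- out$au_s_upper + out$au_s_lower
  out$au_f <- out$au_f_upper + out$au_f_lower
  out
}

# one draw of the 1/f EEG noise (62 x 192), unit marginal SD times noise_sd
synth_eeg_noise <- function(model, noise_sd) {
  z <- matrix(stats::rnorm(N_EEG_SAMPLES * N_EEG_CHANNELS), N_EEG_SAMPLES)
  y <- Re(stats::mvfft(stats::mvfft(z) * model$g, inverse = TRUE)) / N_EEG_SAMPLES
  t(y) * noise_sd
}

synth_au_noise <- function(model, noise_sd) {
  t(model$K %*% matrix(stats::rnorm(N_AU_FRAMES * N_AU_ROWS), N_AU_FRAMES)) * noise_sd
}

#' Generate a synthetic multimodal trial set with known ground truth
#'
#' Every trial satisfies the fixed trial-tensor invariants. EEG carries a
#' paradigm-dependent component (stimulus-locked response at S1 for WG/WAG, an
#' S2-locked anticipation ramp for CW/CAW, and a tone-locked burst at 600 ms
#' for WAG/CAW) on top of 1/f-shaped noise with per-session channel offsets.
#' The fluency signal: stuttered trials receive Gaussian-bump activations in
#' the upper-face AUs (1, 2, 4, 6) centred in the 0-500 ms zone and in the
#' lower-face AUs (14, 15, 20) in the 1,000-1,500 ms zone; fluent trials the
#' time-reversed pattern. In EEG, stuttered trials shift the left-temporal
#' channel (T7) early and fluent trials the right-frontal channel (FP2) late.
#' All fluency effects are scaled by `effect_size`.
#'
#' @param config an [synthetic_config()]
#' @return list with `trialset` (an `ssml_trialset`) and `ground_truth`
#'   (per-trial labels plus planted-effect bookkeeping)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "ssml_synthetic_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  model <- synth_model(config)
  means <- synth_class_means(config, model)
  trials <- list()
  gt_rows <- list()
  idx <- 0L
  for (s in seq_len(config$n_subjects)) {
    subject <- sprintf("S%02d", s)
    for (ses in seq_len(config$sessions_per_subject)) {
      session <- sprintf("%s_sess%d", subject, ses)
      offset <- stats::rnorm(N_EEG_CHANNELS, 0, model$offset_sd)
      for (tr in seq_len(config$trials_per_session)) {
        idx <- idx + 1L
        paradigm <- sample(names(config$paradigm_mix), 1,
                           prob = config$paradigm_mix)
        stuttered <- stats::runif(1) < config$stutter_rate
        fluency <- if (stuttered) "stuttered" else "fluent"
        occ <- stats::runif(3) < config$occurrence_prob   # upper, lower, eeg
        au <- model$au_baseline + synth_au_noise(model, config$noise_sd)
        rownames(au) <- model$au_names
        if (stuttered) {
          if (occ[1]) au <- au + means$au_s_upper
          if (occ[2]) au <- au + means$au_s_lower
        } else {
          if (occ[1]) au <- au + means$au_f_upper
          if (occ[2]) au <- au + means$au_f_lower
        }
        au <- pmax(au, 0)
        eeg <- synth_eeg_noise(model, config$noise_sd) + offset +
          model$para_comp[[paradigm]] +
          (if (occ[3]) { if (stuttered) means$eeg_s else means$eeg_f }
           else 0)
        rownames(eeg) <- model$ch
        trials[[idx]] <- new_trial(subject, session, paradigm, fluency,
                                   au, eeg, s1_time = (tr - 1) * 4000)
        gt_rows[[idx]] <- data.frame(trial = idx, subject = subject,
                                     session = session, paradigm = paradigm,
                                     fluency = fluency,
                                     occ_upper = occ[1], occ_lower = occ[2],
                                     occ_eeg = occ[3], stringsAsFactors = FALSE)
      }
    }
  }
  ts <- new_trialset(trials, provenance = list(seed = config$seed,
                                               config = unclass(config)))
  gt <- list(labels = do.call(rbind, gt_rows),
             planted = list(
               au = data.frame(
                 au = c(model$upper_planted, model$lower_planted),
                 region = c(rep("upper", length(model$upper_planted)),
                            rep("lower", length(model$lower_planted))),
                 zone_stuttered = c(rep("0-500", length(model$upper_planted)),
                                    rep("1000-1500", length(model$lower_planted))),
                 zone_fluent = c(rep("1000-1500", length(model$upper_planted)),
                                 rep("0-500", length(model$lower_planted))),
                 stringsAsFactors = FALSE),
               eeg = data.frame(channel = c("T7", "FP2"),
                                class_with_shift = c("stuttered", "fluent"),
                                zone = c("0-500", "1000-1500"),
                                stringsAsFactors = FALSE)),
             config = unclass(config))
  list(trialset = ts, ground_truth = gt)
}

# quadratic forms against the known noise covariances --------------------------

# u' Sigma_eeg^{-1} v via the circulant spectrum
eeg_qform <- function(model, noise_sd, u, v) {
  n <- length(u)
  U <- stats::fft(u); V <- stats::fft(v)
  Re(sum(Conj(U) * V / (model$g^2 * noise_sd^2))) / n
}

#' Bayes-optimal reference accuracy of the synthetic generator
#'
#' Monte-Carlo estimate of the accuracy of the Bayes rule given the planted
#' class likelihoods. Each class likelihood is a finite Gaussian mixture over
#' the Bernoulli burst-occurrence indicators (upper-face, lower-face, EEG
#' markers, each present with `occurrence_prob`); the log-likelihood ratio is
#' evaluated exactly over the planted AU rows and EEG channels, conditioning
#' on the class-independent nuisance terms (session offsets, paradigm
#' components). AU clipping at zero is ignored (negligible at the default
#' baseline of 3 noise SDs). The always-present Mahalanobis distance between
#' the class means is reported as `d_prime`; the implied closed-form accuracy
#' `pnorm(d_prime / 2)` equals the Bayes accuracy only when
#' `occurrence_prob = 1` (it is `NA` otherwise). No trained model can beat
#' the oracle accuracy except by Monte-Carlo error.
#'
#' @param config an [synthetic_config()]
#' @param n_mc number of Monte-Carlo trials
#' @param seed RNG seed for the Monte-Carlo draw (default derived from config)
#' @return list with `accuracy`, `se` (binomial standard error), `n_mc`,
#'   `d_prime`, and `accuracy_closed_form`
#' @export
bayes_reference_accuracy <- function(config, n_mc = 4000,
                                     seed = config$seed + 7919L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  model <- synth_model(config)
  means <- synth_class_means(config, model)
  p_occ <- config$occurrence_prob

  Sinv <- chol2inv(chol(tcrossprod(model$K) * config$noise_sd^2))
  q_au <- function(v) sum(v * (Sinv %*% v))
  q_eeg <- function(v) eeg_qform(model, config$noise_sd, v, v)

  up <- model$upper_planted; lo <- model$lower_planted
  au_rows <- c(up, lo)
  # always-present discriminability (Mahalanobis distance of the full means)
  d2 <- 0
  if (config$plant_au)
    for (r in au_rows) d2 <- d2 + q_au(means$au_s[r, ] - means$au_f[r, ])
  if (config$plant_eeg) {
    d2 <- d2 + q_eeg(means$eeg_s["T7", ]) + q_eeg(means$eeg_f["FP2", ])
  }
  d_prime <- sqrt(d2)

  lse2 <- function(a, b) { m <- pmax(a, b); m + log(exp(a - m) + exp(b - m)) }
  # mixture log-likelihood of one marker: quadratic terms only (constants
  # shared by both mixture components and both classes cancel in the LLR)
  mix_ll <- function(ll_with, ll_without) {
    if (p_occ == 1) ll_with
    else lse2(log(p_occ) + ll_with, log(1 - p_occ) + ll_without)
  }
  region_ll <- function(x_rows, mu_with) {
    ll_w <- -0.5 * sum(vapply(seq_len(nrow(x_rows)), function(i)
      q_au(x_rows[i, ] - mu_with[i, ]), numeric(1)))
    ll_0 <- -0.5 * sum(vapply(seq_len(nrow(x_rows)), function(i)
      q_au(x_rows[i, ]), numeric(1)))
    mix_ll(ll_w, ll_0)
  }

  log_prior <- log(config$stutter_rate / (1 - config$stutter_rate))
  correct <- logical(n_mc)
  for (m in seq_len(n_mc)) {
    stuttered <- stats::runif(1) < config$stutter_rate
    occ <- stats::runif(3) < p_occ
    llr <- log_prior
    if (config$plant_au) {
      noise <- synth_au_noise(model, config$noise_sd)
      rownames(noise) <- model$au_names
      xs_up <- noise[up, , drop = FALSE] +
        (if (stuttered && occ[1]) means$au_s_upper[up, , drop = FALSE]
         else if (!stuttered && occ[1]) means$au_f_upper[up, , drop = FALSE]
         else 0)
      xs_lo <- noise[lo, , drop = FALSE] +
        (if (stuttered && occ[2]) means$au_s_lower[lo, , drop = FALSE]
         else if (!stuttered && occ[2]) means$au_f_lower[lo, , drop = FALSE]
         else 0)
      ll_s <- region_ll(xs_up, means$au_s_upper[up, , drop = FALSE]) +
        region_ll(xs_lo, means$au_s_lower[lo, , drop = FALSE])
      ll_f <- region_ll(xs_up, means$au_f_upper[up, , drop = FALSE]) +
        region_ll(xs_lo, means$au_f_lower[lo, , drop = FALSE])
      llr <- llr + ll_s - ll_f
    }
    if (config$plant_eeg) {
      noise <- synth_eeg_noise(model, config$noise_sd)
      rownames(noise) <- model$ch
      x_t7 <- noise["T7", ] +
        (if (stuttered && occ[3]) means$eeg_s["T7", ] else 0)
      x_fp2 <- noise["FP2", ] +
        (if (!stuttered && occ[3]) means$eeg_f["FP2", ] else 0)
      ll_s <- mix_ll(-0.5 * q_eeg(x_t7 - means$eeg_s["T7", ]),
                     -0.5 * q_eeg(x_t7)) + (-0.5 * q_eeg(x_fp2))
      ll_f <- (-0.5 * q_eeg(x_t7)) +
        mix_ll(-0.5 * q_eeg(x_fp2 - means$eeg_f["FP2", ]),
               -0.5 * q_eeg(x_fp2))
      llr <- llr + ll_s - ll_f
    }
    correct[m] <- (llr > 0) == stuttered
  }
  acc <- mean(correct)
  list(accuracy = acc, se = sqrt(acc * (1 - acc) / n_mc), n_mc = n_mc,
       d_prime = d_prime,
       accuracy_closed_form = if (p_occ == 1) stats::pnorm(d_prime / 2)
                              else NA_real_)
}
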