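# Epoch extraction, rational resampling, per-session normalization, and trial
# assembly: continuous recordings -> fixed-shape S1-S2 trial matrices.

#' Preprocessing configuration
#'
#' @param epoch_ms epoch duration in ms (S2 follows S1 by 1,500 ms)
#' @param eeg_target_rate EEG analysis rate in Hz after resampling
#' @param channel_whitelist 62 channel names, ordered; defines EEG row order
#' @param normalization `"per_session_constant"` (divide by one robust scale
#'   per session) or `"none"`
#' @param au_fps AU video frame rate (frames/s)
#' @return list of class `ssml_preprocess_config`
#' @export
preprocess_config <- function(epoch_ms = 1500,
                              eeg_target_rate = 128,
                              channel_whitelist = channel_whitelist_62(),
                              normalization = c("per_session_constant", "none"),
                              au_fps = 58) {
  stopifnot(epoch_ms > 0, eeg_target_rate > 0, au_fps > 0)
  normalization <- match.arg(normalization)
  structure(list(epoch_ms = epoch_ms, eeg_target_rate = eeg_target_rate,
                 channel_whitelist = channel_whitelist,
                 normalization = normalization, au_fps = au_fps),
            class = "ssml_preprocess_config")
}

#' Extract S1-S2 epochs from a continuous session
#'
#' For an EEG recording, returns epochs at the source rate covering the
#' half-open window `[s1, s1 + epoch_ms)`. For an AU frame stream (output of
#' [read_au_table()]), returns the frames whose timestamps fall in the window,
#' padded by repeating the final frame or truncated at the end so every AU
#' epoch has exactly `round(epoch_ms * au_fps / 1000)` frames (87 at the
#' defaults) despite frame-timing jitter.
#'
#' @param session an `ssml_recording`, or a list with `au` and `timestamps_ms`
#' @param s1_times numeric vector of S1 onsets (ms from session start)
#' @param config an `ssml_preprocess_config`
#' @return list of epoch matrices (channels/AUs x time)
#' @export
extract_epochs <- function(session, s1_times, config = preprocess_config()) {
  if (inherits(session, "ssml_recording")) {
    n <- round(config$epoch_ms * session$sfreq / 1000)
    total <- ncol(session$data)
    starts <- round(s1_times * session$sfreq / 1000)
    bad <- s1_times[starts < 0 | (starts + n) > total]
    if (length(bad))
      stop("epoch exceeds recording bounds for s1 = ",
           paste(bad, collapse = ", "), " ms")
    lapply(starts, function(s0) session$data[, s0 + seq_len(n), drop = FALSE])
  } else if (is.list(session) && !is.null(session$au)) {
    n_frames <- round(config$epoch_ms * config$au_fps / 1000)
    ts <- session$timestamps_ms
    lapply(s1_times, function(s1) {
      sel <- which(ts >= s1 & ts < s1 + config$epoch_ms)
      if (length(sel) == 0)
        stop("no AU frames in epoch at s1 = ", s1, " ms")
      ep <- session$au[, sel, drop = FALSE]
      if (ncol(ep) > n_frames) ep <- ep[, seq_len(n_frames), drop = FALSE]
      while (ncol(ep) < n_frames) ep <- cbind(ep, ep[, ncol(ep)])
      ep
    })
  } else {
    stop("session must be an ssml_recording or an AU frame list")
  }
}

# windowed-sinc anti-aliasing kernel for rational polyphase resampling
resample_kernel <- function(p, q, taps_per_phase = 16) {
  mpq <- max(p, q)
  half <- taps_per_phase * mpq
  n <- seq(-half, half)
  fc <- 1 / mpq
  h <- fc * ifelse(n == 0, 1, sin(pi * fc * n) / (pi * fc * n))
  i <- seq_along(n) - 1
  L <- length(n)
  w <- 0.42 - 0.5 * cos(2 * pi * i / (L - 1)) + 0.08 * cos(4 * pi * i / (L - 1))
  p * h * w
}

#' Resample an EEG epoch to a lower rate
#'
#' Rational polyphase FIR resampling (zero-stuff by p, windowed-sinc
#' anti-aliasing low-pass, pick every q-th sample) with edge-replication
#' padding. For a 1,500 ms epoch at 1,000 Hz and a 128 Hz target the output
#' has exactly 192 columns.
#'
#' @param epoch channels x samples matrix (or vector) at `source_rate`
#' @param target_rate target rate in Hz
#' @param source_rate source rate in Hz
#' @return matrix at the target rate with `round(ncol/source*target)` columns
#' @export
resample_epoch_eeg <- function(epoch, target_rate, source_rate) {
  vec_in <- is.null(dim(epoch))
  if (vec_in) epoch <- matrix(epoch, 1)
  if (!all(is.finite(epoch))) stop("non-finite values in epoch")
  if (target_rate > source_rate) stop("target rate above source rate")
  if (target_rate == source_rate) return(if (vec_in) drop(epoch) else epoch)
  g <- rational_gcd(target_rate, source_rate)
  p <- as.integer(round(target_rate / g)); q <- as.integer(round(source_rate / g))
  h <- resample_kernel(p, q)
  half <- (length(h) - 1L) %/% 2L
  n_in <- ncol(epoch)
  n_out <- round(n_in * p / q)
  pad <- ceiling(half / p) + 1L            # source-domain edge padding
  xp <- cbind(epoch[, rep(1L, pad), drop = FALSE], epoch,
              epoch[, rep(n_in, pad), drop = FALSE])
  np <- ncol(xp)
  # zero-stuffed upsampled signal, all channels at once (rows)
  up <- matrix(0, nrow(epoch), np * p)
  up[, (seq_len(np) - 1L) * p + 1L] <- xp
  nfft <- stats::nextn(ncol(up) + length(h) - 1L, 2)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Y <- t(stats::mvfft(t(cbind(up, matrix(0, nrow(up), nfft - ncol(up))))))
  Yf <- Y * rep(H, each = nrow(Y))
  yf <- Re(t(stats::mvfft(t(Yf), inverse = TRUE))) / nfft
  # output sample j (0-based) sits at upsampled index pad*p + j*q, plus the
  # kernel group delay `half`; +1 for R indexing
  pick <- half + pad * p + (seq_len(n_out) - 1L) * q + 1L
  out <- yf[, pick, drop = FALSE]
  rownames(out) <- rownames(epoch)
  if (vec_in) drop(out) else out
}

rational_gcd <- function(a, b) {
  # gcd for rates that may be non-integer (e.g. 58 frames/s vs 128 Hz)
  a <- round(a * 1000); b <- round(b * 1000)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a / 1000
}

#' Normalize all EEG epochs of one session by a single robust constant
#'
#' The session constant is the median absolute deviation (scaled by 1.4826)
#' of all concatenated EEG samples of the session; every epoch is divided by
#' it. With `method = "none"` the epochs are returned unchanged and the
#' constant is 1.
#'
#' @param epochs list of EEG epoch matrices from one session
#' @param method `"per_session_constant"` or `"none"`
#' @return list with `epochs` (scaled) and `constant` (for audit)
#' @export
normalize_session <- function(epochs, method = c("per_session_constant", "none")) {
  method <- match.arg(method)
  stopifnot(length(epochs) >= 1)
  if (method == "none") return(list(epochs = epochs, constant = 1))
  const <- stats::mad(unlist(epochs))
  if (!is.finite(const) || const <= 0)
    stop("degenerate session constant: ", const)
  list(epochs = lapply(epochs, function(e) e / const), constant = const)
}

#' Assemble a preprocessed trial
#'
#' Selects and orders EEG rows by the 62-name channel whitelist, checks the
#' fixed trial-tensor shapes (17 x 87 AU, 62 x 192 EEG) and wraps everything
#' in an [new_trial()] object.
#'
#' @param au_epoch 17 x 87 AU epoch (rows ordered as the AU name set)
#' @param eeg_epoch resampled, normalized EEG epoch with channel rownames
#' @param labels list with `subject`, `session`, `paradigm`, `fluency`,
#'   and optionally `s1_ms`
#' @param config an `ssml_preprocess_config`
#' @return an `ssml_trial`
#' @export
assemble_trial <- function(au_epoch, eeg_epoch, labels,
                           config = preprocess_config()) {
  wl <- config$channel_whitelist
  if (length(wl) != N_EEG_CHANNELS)
    stop("channel whitelist must have ", N_EEG_CHANNELS, " names, got ",
         length(wl))
  miss <- setdiff(wl, rownames(eeg_epoch))
  if (length(miss))
    stop("whitelisted channels missing from recording: ",
         paste(miss, collapse = ", "))
  eeg <- eeg_epoch[wl, , drop = FALSE]
  if (ncol(eeg) != N_EEG_SAMPLES)
    stop("eeg epoch has ", ncol(eeg), " samples, expected ", N_EEG_SAMPLES)
  if (nrow(au_epoch) != N_AU_ROWS)
    stop("au epoch has ", nrow(au_epoch), " rows, expected ", N_AU_ROWS)
  if (ncol(au_epoch) != N_AU_FRAMES)
    stop("au epoch has ", ncol(au_epoch), " frames, expected ", N_AU_FRAMES)
  new_trial(labels$subject, labels$session, labels$paradigm, labels$fluency,
            au_epoch, eeg, s1_time = if (is.null(labels$s1_ms)) 0 else labels$s1_ms)
}
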