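# Self-supervised pretext machinery: AU signal transformations with
# pseudo-labels, pretext dataset construction, and the four loss terms
# (paradigm cross-entropy, window and transformation identification,
# cross-modal KL embedding alignment).

# joint (kind, theta) class table: 4 scaling + 5 gaussian-noise + zero_fill +
# none = 11 classes
transformation_table <- function() {
  data.frame(
    st_class = 0:10,
    kind = c(rep("scale", 4), rep("gaussian_noise", 5), "zero_fill", "none"),
    theta = c(0.25, 0.5, 1.25, 1.75, 0.1, 0.25, 0.5, 0.75, 0.9, NA, NA),
    stringsAsFactors = FALSE)
}

N_ST_CLASSES <- 11L
N_WINDOWS <- 14L           # 100 ms windows (6 frames at 58 frames/s), frames 1..84
WINDOW_LEN <- 6L
N_WIN_CLASSES <- 15L       # 14 windows + "no-window" for kind = none

#' Construct a pretext transformation specification
#'
#' @param kind one of "scale", "gaussian_noise", "zero_fill", "none"
#' @param theta transformation parameter: one of {0.25, 0.5, 1.25, 1.75} for
#'   scaling, {0.1, 0.25, 0.5, 0.75, 0.9} for gaussian noise; absent otherwise
#' @param window_index 0-based window index in 0..13, or `"no-window"`
#'   (required for kind "none")
#' @param region facial region the transformation touches: "upper" or "lower"
#' @return list of class `ssml_transformation`
#' @export
transformation_spec <- function(kind, theta = NA, window_index = "no-window",
                                region = c("upper", "lower")) {
  region <- match.arg(region)
  tab <- transformation_table()
  legal <- tab[tab$kind == kind, ]
  if (nrow(legal) == 0) stop("unknown transformation kind: ", kind)
  if (kind %in% c("scale", "gaussian_noise")) {
    if (!isTRUE(theta %in% legal$theta))
      stop("illegal theta ", theta, " for kind ", kind, "; legal: ",
           paste(legal$theta, collapse = ", "))
  } else theta <- NA
  if (kind == "none") {
    if (!identical(window_index, "no-window"))
      stop("kind 'none' requires window_index = 'no-window'")
  } else {
    if (!(is.numeric(window_index) && window_index %in% 0:(N_WINDOWS - 1)))
      stop("window_index must be in 0..", N_WINDOWS - 1)
  }
  st_class <- if (kind == "none") 10L
  else if (kind == "zero_fill") 9L
  else tab$st_class[tab$kind == kind & tab$theta == theta]
  structure(list(kind = kind, theta = theta, window_index = window_index,
                 region = region, st_class = as.integer(st_class),
                 window_class = if (identical(window_index, "no-window")) 14L
                 else as.integer(window_index)),
            class = "ssml_transformation")
}

#' Sample a random transformation specification
#'
#' The joint (kind, theta) class is uniform over its 11 legal values, the
#' window uniform over the 14 tiling windows (forced to "no-window" for kind
#' "none"), and the face region uniform over upper/lower. Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @return an `ssml_transformation`
#' @export
sample_transformation <- function() {
  tab <- transformation_table()
  row <- tab[sample.int(N_ST_CLASSES, 1), ]
  win <- if (row$kind == "none") "no-window" else sample.int(N_WINDOWS, 1) - 1L
  transformation_spec(row$kind, row$theta, win,
                      region = sample(c("upper", "lower"), 1))
}

# frame columns of a window (1-based), and AU rows of a region
window_cols <- function(window_index) window_index * WINDOW_LEN + seq_len(WINDOW_LEN)

region_rows <- function(region, au_names = au_default_names()) {
  which(au_region_map(au_names) == region)
}

#' Apply a pretext transformation to an AU matrix
#'
#' Only the entries in (region rows) x (window columns) change: scaling
#' multiplies them by theta, zero-fill sets them to 0, gaussian noise adds
#' N(0, theta^2) draws, and "none" returns the input unchanged.
#'
#' @param au 17 x 87 AU matrix
#' @param spec an `ssml_transformation`
#' @return transformed matrix of the same shape
#' @export
apply_transformation <- function(au, spec) {
  stopifnot(inherits(spec, "ssml_transformation"), all(is.finite(au)))
  if (spec$kind == "none") return(au)
  rows <- region_rows(spec$region, rownames(au) %||% au_default_names())
  cols <- window_cols(spec$window_index)
  block <- au[rows, cols, drop = FALSE]
  au[rows, cols] <- switch(spec$kind,
    scale = block * spec$theta,
    zero_fill = 0,
    gaussian_noise = block + stats::rnorm(length(block), 0, spec$theta))
  au
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a self-supervised pretext dataset
#'
#' Samples trials with replacement (fluency labels are not needed), applies a
#' fresh random transformation to each trial's AU matrix, and carries the
#' trial's paradigm class as the EEG pseudo-label. EEG matrices are never
#' transformed.
#'
#' @param trialset an `ssml_trialset`
#' @param n_samples number of pretext samples to draw
#' @param seed RNG seed
#' @return list of class `ssml_pretext_dataset` with arrays `au`
#'   (1 x 17 x 87 x n), `eeg` (1 x 62 x 192 x n) and integer label vectors
#'   `y_para` (0-3), `y_st` (0-10), `y_win` (0-14)
#' @export
build_pretext_dataset <- function(trialset, n_samples, seed = 1) {
  if (length(trialset) == 0) stop("empty trial set")
  if (n_samples <= 0) stop("n_samples must be positive")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- as.integer(n_samples)
  pick <- sample.int(length(trialset), n, replace = TRUE)
  au <- array(0, c(1, N_AU_ROWS, N_AU_FRAMES, n))
  eeg <- array(0, c(1, N_EEG_CHANNELS, N_EEG_SAMPLES, n))
  y_para <- integer(n); y_st <- integer(n); y_win <- integer(n)
  region <- character(n)
  for (i in seq_len(n)) {
    tr <- trialset$trials[[pick[i]]]
    spec <- sample_transformation()
    au[1, , , i] <- apply_transformation(tr$au, spec)
    eeg[1, , , i] <- tr$eeg
    y_para[i] <- paradigm_class(tr$paradigm)
    y_st[i] <- spec$st_class
    y_win[i] <- spec$window_class
    region[i] <- spec$region
  }
  structure(list(au = au, eeg = eeg, y_para = y_para, y_st = y_st,
                 y_win = y_win, region = region, trial_index = pick),
            class = "ssml_pretext_dataset")
}

# ---- losses ----------------------------------------------------------------

PROB_EPS <- 1e-12

#' Pretext loss configuration
#'
#' @param alpha weight of the window-identification loss
#' @param beta weight of the transformation-identification loss
#' @param temperature softmax temperature for the embedding distributions in
#'   the alignment loss
#' @return list of class `ssml_pretext_loss_config`
#' @export
pretext_loss_config <- function(alpha = 1, beta = 1, temperature = 1) {
  if (alpha < 0 || beta < 0) stop("loss weights must be nonnegative")
  structure(list(alpha = alpha, beta = beta, temperature = temperature),
            class = "ssml_pretext_loss_config")
}

nll_loss <- function(p, y) {
  # p: classes x n matrix (or vector), y: 0-based class labels
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  stopifnot(all(p >= -1e-9), all(abs(colSums(p) - 1) < 1e-6))
  -mean(log(pmax(p[cbind(y + 1L, seq_len(ncol(p)))], PROB_EPS)))
}

#' Paradigm-classification pretext loss
#'
#' Cross-entropy of the predicted paradigm distribution against the true
#' paradigm pseudo-label (batch mean when batched).
#'
#' @param p_para 4-vector of predicted probabilities, or 4 x n matrix
#' @param y_para true class(es), 0-3
#' @return scalar loss, nonnegative
#' @export
paradigm_loss <- function(p_para, y_para) nll_loss(p_para, y_para)

#' Transformation- and window-identification losses
#'
#' Negative log-probability of the true joint (kind, theta) class (11 levels)
#' and of the true window class (14 windows + "no-window").
#'
#' @param p_st 11-vector (or 11 x n matrix) of class probabilities
#' @param y_st true transformation class(es), 0-10
#' @param p_win 15-vector (or 15 x n matrix)
#' @param y_win true window class(es), 0-14
#' @return list with `L_st` and `L_win`
#' @export
transformation_losses <- function(p_st, y_st, p_win, y_win) {
  list(L_st = nll_loss(p_st, y_st), L_win = nll_loss(p_win, y_win))
}

#' Cross-modal embedding alignment loss
#'
#' KL divergence between the temperature-softmaxed EEG embedding (target;
#' gradients are never propagated into it) and the softmaxed AU embedding:
#' `KL(softmax(z_eeg/T) || softmax(z_au/T))`. Zero iff the softmaxed
#' embeddings coincide.
#'
#' @param z_au,z_eeg 64-vectors (or 64 x n matrices) of embeddings
#' @param config an [pretext_loss_config()]
#' @return scalar loss, nonnegative (batch mean when batched)
#' @export
alignment_loss <- function(z_au, z_eeg, config = pretext_loss_config()) {
  if (is.null(dim(z_au))) { z_au <- matrix(z_au); z_eeg <- matrix(z_eeg) }
  p <- softmax_cols(z_eeg, config$temperature)   # target side
  q <- softmax_cols(z_au, config$temperature)
  mean(colSums(p * (log(pmax(p, PROB_EPS)) - log(pmax(q, PROB_EPS)))))
}

# gradient of alignment_loss wrt z_au (none flows into z_eeg)
alignment_loss_grad_zau <- function(z_au, z_eeg, config = pretext_loss_config()) {
  p <- softmax_cols(z_eeg, config$temperature)
  q <- softmax_cols(z_au, config$temperature)
  (q - p) / (config$temperature * ncol(q))
}

#' Total self-supervised pretext loss
#'
#' `L = L_para + alpha * L_win + beta * L_st + L_KLD`.
#'
#' @param L_para,L_win,L_st,L_KLD the component losses (finite, nonnegative)
#' @param config an [pretext_loss_config()] supplying alpha and beta
#' @return scalar total loss
#' @export
total_pretext_loss <- function(L_para, L_win, L_st, L_KLD,
                               config = pretext_loss_config()) {
  comps <- c(L_para, L_win, L_st, L_KLD)
  stopifnot(all(is.finite(comps)), all(comps >= 0))
  L_para + config$alpha * L_win + config$beta * L_st + L_KLD
}
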