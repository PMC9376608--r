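# Trial containers and session-level I/O: AU intensity tables (CSV), EEG
# recordings (EDF or HDF5), event/label tables, and the HDF5 trial store.

#' Construct a single multimodal trial
#'
#' One S1-S2 speech-preparation epoch holding a paired AU intensity matrix
#' (AUs x frames) and EEG matrix (channels x samples) with paradigm and
#' fluency labels.
#'
#' @param subject_id,session_id identifiers
#' @param paradigm paradigm code ("WG", "WAG", "CW", "CAW")
#' @param fluency fluency code ("fluent", "stuttered", "other_disfluency",
#'   "missed")
#' @param au numeric matrix, 17 x 87 (AUs x frames at 58 frames/s)
#' @param eeg numeric matrix, 62 x 192 (channels x samples at 128 Hz)
#' @param s1_time S1 onset in ms relative to session start
#' @return object of class `ssml_trial`
#' @export
new_trial <- function(subject_id, session_id, paradigm, fluency, au, eeg,
                      s1_time = 0) {
  tr <- structure(list(subject_id = as.character(subject_id),
                       session_id = as.character(session_id),
                       paradigm = paradigm, fluency = fluency,
                       au = au, eeg = eeg, s1_time = s1_time),
                  class = "ssml_trial")
  validate_trial(tr)
}

#' @rdname new_trial
#' @param trial an `ssml_trial`
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "ssml_trial"))
  if (!trial$paradigm %in% PARADIGM_LEVELS)
    stop("unknown paradigm code: ", trial$paradigm)
  if (!trial$fluency %in% FLUENCY_LEVELS)
    stop("unknown fluency code: ", trial$fluency)
  if (!is.matrix(trial$au) || !identical(dim(trial$au), c(N_AU_ROWS, N_AU_FRAMES)))
    stop("au matrix must be ", N_AU_ROWS, " x ", N_AU_FRAMES, ", got ",
         paste(dim(trial$au), collapse = " x "))
  if (!is.matrix(trial$eeg) ||
      !identical(dim(trial$eeg), c(N_EEG_CHANNELS, N_EEG_SAMPLES)))
    stop("eeg matrix must be ", N_EEG_CHANNELS, " x ", N_EEG_SAMPLES, ", got ",
         paste(dim(trial$eeg), collapse = " x "))
  if (!all(is.finite(trial$au))) stop("non-finite values in au matrix")
  if (!all(is.finite(trial$eeg))) stop("non-finite values in eeg matrix")
  trial
}

#' Construct a trial set
#'
#' @param trials list of `ssml_trial` objects
#' @param provenance list recording how the set was produced (config, seed)
#' @return object of class `ssml_trialset`
#' @export
new_trialset <- function(trials, provenance = list()) {
  stopifnot(is.list(trials))
  structure(list(trials = trials, provenance = provenance),
            class = "ssml_trialset")
}

#' @export
length.ssml_trialset <- function(x) length(x$trials)

#' @export
`[.ssml_trialset` <- function(x, i) {
  new_trialset(x$trials[i], x$provenance)
}

#' @export
print.ssml_trialset <- function(x, ...) {
  fl <- vapply(x$trials, `[[`, "", "fluency")
  cat("ssml_trialset:", length(x$trials), "trials (",
      paste(sprintf("%s=%d", names(table(fl)), table(fl)), collapse = ", "),
      ")\n")
  invisible(x)
}

trialset_labels <- function(ts) {
  data.frame(subject = vapply(ts$trials, `[[`, "", "subject_id"),
             session = vapply(ts$trials, `[[`, "", "session_id"),
             paradigm = vapply(ts$trials, `[[`, "", "paradigm"),
             fluency = vapply(ts$trials, `[[`, "", "fluency"),
             s1_ms = vapply(ts$trials, `[[`, 0, "s1_time"),
             stringsAsFactors = FALSE)
}

# stack trial matrices into (1, H, W, N) arrays for the network engine
trialset_tensors <- function(ts) {
  n <- length(ts)
  au <- array(0, c(1, N_AU_ROWS, N_AU_FRAMES, n))
  eeg <- array(0, c(1, N_EEG_CHANNELS, N_EEG_SAMPLES, n))
  for (i in seq_len(n)) {
    au[1, , , i] <- ts$trials[[i]]$au
    eeg[1, , , i] <- ts$trials[[i]]$eeg
  }
  list(au = au, eeg = eeg,
       fluency = vapply(ts$trials, `[[`, "", "fluency"),
       paradigm_class = paradigm_class(vapply(ts$trials, `[[`, "", "paradigm")))
}

# ---- AU tables -------------------------------------------------------------

#' Read a per-session AU intensity table
#'
#' Reads the common AU-detector CSV dialect: a header row with columns
#' `frame`, `timestamp_ms` and one intensity column per AU, named either
#' `AU01_r` (intensity suffix) or plain `AU01`, one row per video frame.
#'
#' @param path CSV file
#' @param au_names ordered AU identifiers to extract;
#'   default [au_default_names()]
#' @return list with `au` (matrix, `length(au_names)` x frames, rows ordered
#'   as `au_names`) and `timestamps_ms` (frame timebase, nominally 58 frames/s)
#' @export
read_au_table <- function(path, au_names = au_default_names()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"timestamp_ms" %in% names(df))
    stop("AU table lacks a 'timestamp_ms' column")
  ts <- df$timestamp_ms
  if (any(diff(ts) <= 0)) stop("non-monotone frame timestamps in ", path)
  cols <- character(length(au_names))
  for (i in seq_along(au_names)) {
    cand <- c(paste0(au_names[i], "_r"), au_names[i])
    hit <- cand[cand %in% names(df)]
    if (length(hit) == 0)
      stop("requested AU column missing: ", au_names[i])
    cols[i] <- hit[1]
  }
  au <- t(as.matrix(df[, cols]))
  rownames(au) <- au_names
  list(au = au, timestamps_ms = ts)
}

# ---- EEG recordings --------------------------------------------------------

#' Read a continuous EEG recording (EDF or HDF5)
#'
#' EDF files are parsed directly (16-bit integer data with per-signal physical
#' scaling); HDF5 containers must hold datasets `data` (channels x samples),
#' `sfreq`, and `ch_names`. Channel labels and the declared sample rate are
#' preserved verbatim.
#'
#' @param path file ending in `.edf` or `.h5`/`.hdf5`
#' @return an `ssml_recording`: list with `data` (channels x samples matrix,
#'   rownames = channel labels), `sfreq` (Hz), `ch_names`
#' @export
read_eeg_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
                edf = read_edf(path),
                h5 = ,
                hdf5 = read_recording_h5(path),
                stop("unsupported recording format: .", ext))
  rec
}

new_recording <- function(data, sfreq, ch_names) {
  stopifnot(nrow(data) == length(ch_names))
  rownames(data) <- ch_names
  structure(list(data = data, sfreq = sfreq, ch_names = ch_names),
            class = "ssml_recording")
}

read_recording_h5 <- function(path) {
  data <- rhdf5::h5read(path, "data")
  sfreq <- as.numeric(rhdf5::h5read(path, "sfreq"))
  ch <- as.character(rhdf5::h5read(path, "ch_names"))
  new_recording(as.matrix(data), sfreq, ch)
}

#' Write a continuous recording to HDF5
#' @param rec an `ssml_recording`
#' @param path output file
#' @export
write_recording_h5 <- function(rec, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(unname(rec$data), path, "data")
  rhdf5::h5write(rec$sfreq, path, "sfreq")
  rhdf5::h5write(rec$ch_names, path, "ch_names")
  rhdf5::h5closeAll()
  invisible(path)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Minimal EDF writer: one data record per second, 16-bit integers with
#' per-signal physical scaling chosen from the data range. Intended for
#' creating test fixtures and for interoperability; amplitude resolution is
#' the EDF-standard 16 bits.
#'
#' @param rec an `ssml_recording` (all channels at one sample rate)
#' @param path output `.edf` file
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  spr <- as.integer(rec$sfreq)            # samples per 1 s record
  n_rec <- ncol(rec$data) %/% spr
  stopifnot(n_rec * spr == ncol(rec$data))
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width, eos = NULL)
  wr("0", 8); wr("synthetic subject", 80); wr("synthetic recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44); wr(n_rec, 8); wr(1, 8); wr(ns, 4)
  for (lab in rec$ch_names) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr("uV", 8)                      # physical dimension
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    for (i in seq_len(ns)) {
      dig <- round((rec$data[i, cols] - pmin_[i]) / scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed sample rates across channels: ",
         paste(unique(spr), collapse = ", "))
  sfreq <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      data[i, (r - 1L) * spr[1] + seq_len(spr[1])] <- (dig - dmin[i]) * scale[i] + pmin_[i]
    }
  }
  new_recording(data, sfreq, labels)
}

# ---- event/label tables ----------------------------------------------------

#' Read an event/label table
#'
#' Tab- or comma-separated with a header row and columns
#' `subject`, `session`, `paradigm`, `fluency`, `s1_ms`.
#'
#' @param path file path
#' @return data.frame of events
#' @export
read_event_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  ev <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject", "session", "paradigm", "fluency", "s1_ms")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event table lacks columns: ", paste(miss, collapse = ", "))
  ev
}

#' Code and filter trials from an event table
#'
#' Applies the trial-coding rules: trials labelled `fluent` or `stuttered`
#' enter the downstream (supervised) set; trials with any other disfluency or
#' that were missed are excluded from it; all rows remain available for the
#' self-supervised pretext stage (labels are not needed there). Optionally
#' balances the downstream set by randomly down-sampling the majority class.
#'
#' @param events data.frame with columns `subject`, `session`, `paradigm`,
#'   `fluency`, `s1_ms`
#' @param balance if TRUE, down-sample so fluent and stuttered counts match
#' @param seed RNG seed for the down-sampling draw (required when `balance`)
#' @return list with `downstream` (filtered, possibly balanced data.frame),
#'   `pretext` (all rows), and `report` (named counts: fluent, stuttered,
#'   excluded)
#' @export
code_and_filter_trials <- function(events, balance = FALSE, seed = NULL) {
  bad <- setdiff(unique(events$fluency), FLUENCY_LEVELS)
  if (length(bad)) stop("unknown fluency code: ", paste(bad, collapse = ", "))
  invisible(paradigm_class(events$paradigm))   # validates codes
  keep <- events$fluency %in% c("fluent", "stuttered")
  down <- events[keep, , drop = FALSE]
  report <- c(fluent = sum(events$fluency == "fluent"),
              stuttered = sum(events$fluency == "stuttered"),
              excluded = sum(!keep))
  if (balance) {
    if (is.null(seed)) stop("balancing requires an explicit seed")
    down <- balance_classes(down, seed)
  }
  list(downstream = down, pretext = events, report = report)
}

balance_classes <- function(df, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx_f <- which(df$fluency == "fluent")
  idx_s <- which(df$fluency == "stuttered")
  k <- min(length(idx_f), length(idx_s))
  keep <- sort(c(sample(idx_f, k), sample(idx_s, k)))
  df[keep, , drop = FALSE]
}

#' Balance a trial set across fluency classes
#'
#' Random down-sampling of the majority class with an explicit seed, so the
#' downstream set has equal fluent and stuttered counts.
#'
#' @param ts an `ssml_trialset` containing only fluent/stuttered trials
#' @param seed RNG seed
#' @return balanced `ssml_trialset`
#' @export
balance_trialset <- function(ts, seed) {
  fl <- vapply(ts$trials, `[[`, "", "fluency")
  stopifnot(all(fl %in% c("fluent", "stuttered")))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx_f <- which(fl == "fluent"); idx_s <- which(fl == "stuttered")
  k <- min(length(idx_f), length(idx_s))
  keep <- sort(c(sample(idx_f, k), sample(idx_s, k)))
  ts[keep]
}

# ---- HDF5 trial store ------------------------------------------------------

#' Persist a trial set to HDF5
#'
#' Layout: `/trials/<idx>/au` and `/trials/<idx>/eeg` as float64 (bit-exact
#' round trip), plus label vectors under `/meta`.
#'
#' @param ts an `ssml_trialset`
#' @param path output `.h5` file
#' @export
write_trialset <- function(ts, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "trials")
  rhdf5::h5createGroup(path, "meta")
  n <- length(ts)
  for (i in seq_len(n)) {
    g <- sprintf("trials/t%05d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(unname(ts$trials[[i]]$au), path, paste0(g, "/au"))
    rhdf5::h5write(unname(ts$trials[[i]]$eeg), path, paste0(g, "/eeg"))
  }
  lab <- trialset_labels(ts)
  for (nm in names(lab)) rhdf5::h5write(lab[[nm]], path, paste0("meta/", nm))
  prov <- ts$provenance
  if (length(prov))
    rhdf5::h5write(vapply(prov, function(p) paste(deparse(p), collapse = ""), ""),
                   path, "meta/provenance")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a trial set written by [write_trialset()]
#' @param path `.h5` file
#' @return an `ssml_trialset`
#' @export
read_trialset <- function(path) {
  meta <- list(subject = as.character(rhdf5::h5read(path, "meta/subject")),
               session = as.character(rhdf5::h5read(path, "meta/session")),
               paradigm = as.character(rhdf5::h5read(path, "meta/paradigm")),
               fluency = as.character(rhdf5::h5read(path, "meta/fluency")),
               s1_ms = as.numeric(rhdf5::h5read(path, "meta/s1_ms")))
  n <- length(meta$subject)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    g <- sprintf("trials/t%05d", i)
    au <- as.matrix(rhdf5::h5read(path, paste0(g, "/au")))
    eeg <- as.matrix(rhdf5::h5read(path, paste0(g, "/eeg")))
    rownames(au) <- au_default_names()
    rownames(eeg) <- channel_whitelist_62()
    trials[[i]] <- new_trial(meta$subject[i], meta$session[i], meta$paradigm[i],
                             meta$fluency[i], au, eeg, meta$s1_ms[i])
  }
  rhdf5::h5closeAll()
  new_trialset(trials, provenance = list(path = path))
}
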