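# Shared fixtures: small synthetic trial sets and toy session files, all
# generated in code at test time.

small_trialset <- function(n_per_session = 60, n_subjects = 2, effect = 1,
                           seed = 1, ...) {
  cfg <- synthetic_config(n_subjects = n_subjects, sessions_per_subject = 1,
                          trials_per_session = n_per_session,
                          effect_size = effect, seed = seed, ...)
  generate_dataset(cfg)
}

# toy AU csv: 17 (or more) AU columns at 58 frames/s
write_toy_au_csv <- function(path, n_frames = 3, values = NULL,
                             extra_cols = character(0),
                             au_names = au_default_names()) {
  ts <- round((seq_len(n_frames) - 1) * 1000 / 58, 3)
  df <- data.frame(frame = seq_len(n_frames) - 1, timestamp_ms = ts)
  if (is.null(values))
    values <- matrix(seq_len(length(au_names) * n_frames), length(au_names))
  for (i in seq_along(au_names)) df[[paste0(au_names[i], "_r")]] <- values[i, ]
  for (ex in extra_cols) df[[ex]] <- 0.5
  utils::write.csv(df, path, row.names = FALSE)
  invisible(values)
}

toy_events <- function() {
  data.frame(
    subject = "S01", session = "S01_sess1",
    paradigm = rep(c("WG", "WAG", "CW", "CAW"), length.out = 10),
    fluency = c("fluent", "fluent", "fluent", "fluent",
                "stuttered", "stuttered", "stuttered",
                "other_disfluency", "other_disfluency", "missed"),
    s1_ms = seq(0, by = 4000, length.out = 10),
    stringsAsFactors = FALSE)
}

# fast training settings for tests
fast_train <- function(seed = 1, epochs = 8, batch = 32, lr = 0.02) {
  train_config(lr0 = lr, batch_size = batch, max_epochs = epochs,
               early_stop_patience = epochs, seed = seed)
}
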