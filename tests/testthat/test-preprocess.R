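# Epoch extraction, resampling, session normalization, trial assembly.

test_that("EEG epochs cover the half-open 1,500 ms window at source rate", {
  set.seed(2)
  ch <- montage_64()
  rec <- ssmlr:::new_recording(matrix(rnorm(64 * 5000), 64,
                                      dimnames = list(ch, NULL)), 1000, ch)
  eps <- extract_epochs(rec, s1_times = 2000)
  expect_length(eps, 1)
  expect_identical(dim(eps[[1]]), c(64L, 1500L))
  expect_equal(eps[[1]], rec$data[, 2001:3500])
  expect_error(extract_epochs(rec, s1_times = 4000), "4000")
})

test_that("AU epochs have exactly 87 frames despite frame-timing jitter", {
  set.seed(3)
  mk_stream <- function(ts) list(au = matrix(rnorm(17 * length(ts)), 17,
                                             dimnames = list(au_default_names(), NULL)),
                                 timestamps_ms = ts)
  # nominal timing: 87 frames in [0, 1500)
  ts_nom <- (0:199) * 1000 / 58
  expect_identical(ncol(extract_epochs(mk_stream(ts_nom), 0)[[1]]), 87L)
  # jitter producing 86 in-window frames -> padded by repeating the last frame
  ts86 <- sort(ts_nom[-5] + stats::runif(199, -0.5, 0.5))
  ep86 <- extract_epochs(mk_stream(ts86), 0)[[1]]
  expect_identical(ncol(ep86), 87L)
  expect_identical(ep86[, 87], ep86[, 86])
  # jitter producing 88 in-window frames -> truncated at the end
  ts88 <- sort(c(ts_nom, 730.1))
  expect_identical(ncol(extract_epochs(mk_stream(ts88), 0)[[1]]), 87L)
})

test_that("resampling 1,500 ms from 1,000 Hz to 128 Hz gives exactly 192 samples", {
  x <- matrix(rnorm(3 * 1500), 3)
  y <- resample_epoch_eeg(x, 128, 1000)
  expect_identical(dim(y), c(3L, 192L))
  # the 192-column property holds for any source rate >= 256 Hz
  for (sr in c(256, 500, 512, 1000)) {
    n <- round(1.5 * sr)
    expect_identical(ncol(resample_epoch_eeg(matrix(rnorm(n), 1), 128, sr)), 192L)
  }
})

test_that("resampling preserves DC and band-limited content", {
  t <- (0:1499) / 1000
  # constant epoch -> constant output
  z <- resample_epoch_eeg(rep(3.7, 1500), 128, 1000)
  expect_lt(max(abs(z - 3.7)), 1e-3)
  # 5 Hz sine matches the analytic sine at the new time points
  y <- resample_epoch_eeg(sin(2 * pi * 5 * t), 128, 1000)
  t2 <- (seq_along(y) - 1) / 128
  trim <- 10:(length(y) - 9)
  expect_lt(max(abs(y[trim] - sin(2 * pi * 5 * t2)[trim])), 1e-2)
  # energy of passband tones preserved within 1% (Parseval over the same
  # trimmed window, against the analytic tone at the new rate)
  for (f0 in c(5, 15, 25, 35, 45)) {
    y <- resample_epoch_eeg(sin(2 * pi * f0 * t), 128, 1000)
    ref <- sin(2 * pi * f0 * t2)
    expect_lt(abs(mean(y[trim]^2) / mean(ref[trim]^2) - 1), 0.01)
  }
  expect_error(resample_epoch_eeg(c(1, NA, 3), 128, 1000), "finite")
  expect_error(resample_epoch_eeg(rnorm(100), 256, 128), "above source")
})

test_that("session normalization divides by one robust constant", {
  set.seed(6)
  eps <- lapply(1:5, function(i) matrix(rnorm(62 * 192, sd = 2), 62))
  res <- normalize_session(eps)
  expect_equal(res$constant, stats::mad(unlist(eps)))
  expect_equal(res$epochs[[2]], eps[[2]] / res$constant)
  # method none is the identity, twice over
  res0 <- normalize_session(normalize_session(eps, "none")$epochs, "none")
  expect_identical(res0$epochs, eps)
  expect_identical(res0$constant, 1)
  # two sessions with different scales agree after normalization
  eps2 <- lapply(eps, function(e) e * 7.3)
  r1 <- normalize_session(eps); r2 <- normalize_session(eps2)
  expect_lt(abs(stats::mad(unlist(r1$epochs)) - stats::mad(unlist(r2$epochs))), 1e-9)
  expect_error(normalize_session(list(matrix(0, 62, 192))), "degenerate")
})

test_that("assemble_trial enforces shapes and follows whitelist row order", {
  set.seed(7)
  cfg <- preprocess_config()
  au <- matrix(abs(rnorm(17 * 87)), 17, dimnames = list(au_default_names(), NULL))
  eeg64 <- matrix(rnorm(64 * 192), 64, dimnames = list(montage_64(), NULL))
  tr <- assemble_trial(au, eeg64, list(subject = "S01", session = "s1",
                                       paradigm = "WG", fluency = "fluent"), cfg)
  expect_s3_class(tr, "ssml_trial")
  expect_identical(rownames(tr$eeg), channel_whitelist_62())

  # a permuted whitelist permutes EEG rows accordingly
  perm <- rev(channel_whitelist_62())
  cfg_p <- preprocess_config(channel_whitelist = perm)
  tr_p <- assemble_trial(au, eeg64, list(subject = "S01", session = "s1",
                                         paradigm = "WG", fluency = "fluent"), cfg_p)
  expect_identical(tr_p$eeg, tr$eeg[perm, ])

  expect_error(preprocess_config(channel_whitelist = perm[1:61]) |>
                 (\(c) assemble_trial(au, eeg64, list(subject = "s", session = "s",
                                                      paradigm = "WG",
                                                      fluency = "fluent"), c))(),
               "62")
  expect_error(assemble_trial(au[, 1:80], eeg64,
                              list(subject = "s", session = "s",
                                   paradigm = "WG", fluency = "fluent"), cfg),
               "frames")
})

test_that("epoching and assembly are deterministic end to end", {
  set.seed(11)
  ch <- montage_64()
  rec <- ssmlr:::new_recording(matrix(rnorm(64 * 4000), 64,
                                      dimnames = list(ch, NULL)), 1000, ch)
  run <- function() {
    ep <- extract_epochs(rec, 500)[[1]]
    ep <- resample_epoch_eeg(ep, 128, 1000)
    ep <- normalize_session(list(ep))$epochs[[1]]
    au <- matrix(1, 17, 87, dimnames = list(au_default_names(), NULL))
    assemble_trial(au, ep, list(subject = "a", session = "b",
                                paradigm = "CW", fluency = "stuttered"))
  }
  expect_identical(run(), run())
})
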