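# The synthetic generator: determinism, class priors, planted structure,
# and the Bayes-optimal reference oracle.

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_subjects = 2, sessions_per_subject = 1,
                          trials_per_session = 50, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_length(d1$trialset, 100)
  for (tr in d1$trialset$trials[1:3]) expect_s3_class(validate_trial(tr), "ssml_trial")
})

test_that("class priors match stutter_rate within binomial error", {
  cfg <- synthetic_config(n_subjects = 1, sessions_per_subject = 1,
                          trials_per_session = 600, stutter_rate = 0.3, seed = 21)
  gen <- generate_dataset(cfg)
  p_hat <- mean(gen$ground_truth$labels$fluency == "stuttered")
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 600))
})

test_that("only the planted (AU row, zone) cells separate the classes", {
  gen <- small_trialset(500, n_subjects = 1, effect = 1, seed = 31)
  tens <- ssmlr:::trialset_tensors(gen$trialset)
  stut <- tens$fluency == "stuttered"
  zone_mean <- function(au_row, cols) apply(tens$au[1, au_row, cols, ], 2, mean)
  p_of <- function(au_name, zone_cols) {
    i <- match(au_name, au_default_names())
    a <- zone_mean(i, zone_cols)
    stats::t.test(a[stut], a[!stut])$p.value
  }
  early <- 1:29; mid <- 30:58; late <- 59:87
  # planted: upper AUs early & late (opposite classes), AU14 late & early
  expect_lt(p_of("AU01", early), 0.01)
  expect_lt(p_of("AU06", late), 0.01)
  expect_lt(p_of("AU14", early), 0.01)
  expect_lt(p_of("AU20", late), 0.01)
  # non-planted rows and the middle zone carry no class signal
  p_null <- c(p_of("AU05", early), p_of("AU25", late), p_of("AU01", mid),
              p_of("AU12", mid), p_of("AU45", late))
  expect_gt(min(p_null), 1e-4)
  expect_gt(mean(p_null > 0.05), 0.5)
})

test_that("EEG carries the paradigm signatures used as pretext pseudo-labels", {
  gen <- small_trialset(400, n_subjects = 1, effect = 0, seed = 41)
  tens <- ssmlr:::trialset_tensors(gen$trialset)
  para <- tens$paradigm_class
  cz <- match("CZ", channel_whitelist_62())
  tone_win <- 85:95        # around 700 ms at 128 Hz
  tone_amp <- apply(tens$eeg[1, cz, tone_win, ], 2, mean)
  # tone paradigms (WAG=1, CAW=3) show the tone-locked burst
  expect_lt(stats::t.test(tone_amp[para %in% c(1, 3)],
                          tone_amp[para %in% c(0, 2)])$p.value, 1e-6)
  # cue-at-S1 paradigms show the S2-locked anticipation ramp late
  late_amp <- apply(tens$eeg[1, cz, 170:192, ], 2, mean)
  expect_lt(stats::t.test(late_amp[para %in% c(2, 3)],
                          late_amp[para %in% c(0, 1)])$p.value, 1e-6)
})

test_that("the Bayes oracle matches its closed form and is monotone in effect size", {
  # occurrence_prob = 1: the closed form Phi(d'/2) applies exactly
  base <- function(E, seed = 3) synthetic_config(
    n_subjects = 1, sessions_per_subject = 1, trials_per_session = 10,
    effect_size = E, occurrence_prob = 1, seed = seed)
  # no signal -> chance
  b0 <- bayes_reference_accuracy(base(0), n_mc = 800)
  expect_lt(abs(b0$accuracy - 0.5), 3 * sqrt(0.25 / 800))
  expect_equal(b0$d_prime, 0)
  # Monte-Carlo agrees with the Gaussian closed form Phi(d'/2)
  b1 <- bayes_reference_accuracy(base(0.4), n_mc = 1500)
  expect_lt(abs(b1$accuracy - b1$accuracy_closed_form), 4 * b1$se + 0.01)
  # a config scaled to d' = 2 attains the two-Gaussian accuracy 0.841
  E2 <- 2 / bayes_reference_accuracy(base(1), n_mc = 2)$d_prime
  b2 <- bayes_reference_accuracy(base(E2), n_mc = 1500)
  expect_equal(b2$d_prime, 2, tolerance = 1e-8)
  expect_lt(abs(b2$accuracy - stats::pnorm(1)), 4 * b2$se + 0.01)
  # accuracy is monotone nondecreasing in effect_size (MC slack allowed),
  # also under the default stochastic burst occurrence
  accs <- vapply(c(0, 0.3, 0.6, 1.2), function(E)
    bayes_reference_accuracy(base(E), n_mc = 800)$accuracy, numeric(1))
  expect_true(all(diff(accs) > -0.03))
  cfg_occ <- function(E) synthetic_config(n_subjects = 1,
                                          sessions_per_subject = 1,
                                          trials_per_session = 10,
                                          effect_size = E, seed = 3)
  accs2 <- vapply(c(0, 0.6, 1.2), function(E)
    bayes_reference_accuracy(cfg_occ(E), n_mc = 800)$accuracy, numeric(1))
  expect_true(all(diff(accs2) > -0.03))
  expect_true(is.na(bayes_reference_accuracy(cfg_occ(1), n_mc = 2)$accuracy_closed_form))
})

test_that("disabling a modality removes its share of the discriminability", {
  cfg_both <- synthetic_config(n_subjects = 1, sessions_per_subject = 1,
                               trials_per_session = 10, effect_size = 1, seed = 5)
  cfg_au <- synthetic_config(n_subjects = 1, sessions_per_subject = 1,
                             trials_per_session = 10, effect_size = 1,
                             plant_eeg = FALSE, seed = 5)
  cfg_eeg <- synthetic_config(n_subjects = 1, sessions_per_subject = 1,
                              trials_per_session = 10, effect_size = 1,
                              plant_au = FALSE, seed = 5)
  d_both <- bayes_reference_accuracy(cfg_both, n_mc = 2)$d_prime
  d_au <- bayes_reference_accuracy(cfg_au, n_mc = 2)$d_prime
  d_eeg <- bayes_reference_accuracy(cfg_eeg, n_mc = 2)$d_prime
  expect_gt(d_au, 0); expect_gt(d_eeg, 0)
  expect_equal(d_both^2, d_au^2 + d_eeg^2, tolerance = 1e-8)
})
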