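# Pretext machinery: transformation sampling, application, dataset
# construction, and the loss closed forms.

test_that("sampled transformations are uniform over the 11 joint classes", {
  set.seed(13)
  n <- 11000
  specs <- replicate(n, sample_transformation(), simplify = FALSE)
  st <- vapply(specs, `[[`, 0L, "st_class")
  counts <- table(factor(st, levels = 0:10))
  expect_true(all(abs(counts - n / 11) < 3 * sqrt(n * (1 / 11) * (10 / 11))))
  # kind = none always carries the no-window label
  none <- Filter(function(s) s$kind == "none", specs)
  expect_true(all(vapply(none, function(s)
    identical(s$window_index, "no-window") && s$window_class == 14L, logical(1))))
  # windows uniform over 0..13 for windowed kinds
  win <- vapply(Filter(function(s) s$kind != "none", specs), `[[`, 0L, "window_class")
  expect_true(all(win %in% 0:13))
  expect_gt(stats::chisq.test(table(factor(win, levels = 0:13)))$p.value, 1e-4)
  # fixed seed reproduces the spec sequence
  set.seed(99); a <- replicate(5, sample_transformation(), simplify = FALSE)
  set.seed(99); b <- replicate(5, sample_transformation(), simplify = FALSE)
  expect_identical(a, b)
})

test_that("transformation specs enforce the legal parameter sets", {
  expect_error(transformation_spec("scale", 0.3), "illegal theta")
  expect_error(transformation_spec("gaussian_noise", 1.5), "illegal theta")
  expect_error(transformation_spec("none", window_index = 3), "no-window")
  expect_error(transformation_spec("warp"), "unknown transformation")
  s <- transformation_spec("scale", 0.25, 3, "upper")
  expect_identical(s$st_class, 0L)
  expect_identical(transformation_spec("zero_fill", window_index = 0)$st_class, 9L)
  expect_identical(transformation_spec("none")$st_class, 10L)
})

test_that("transformations touch only the (region x window) block", {
  set.seed(17)
  au <- matrix(abs(rnorm(17 * 87)), 17, dimnames = list(au_default_names(), NULL))
  # identity for kind = none
  expect_identical(apply_transformation(au, transformation_spec("none")), au)
  # all-ones input, scale 0.25, upper region, window 3
  ones <- matrix(1, 17, 87, dimnames = list(au_default_names(), NULL))
  sc <- apply_transformation(ones, transformation_spec("scale", 0.25, 3, "upper"))
  rows <- which(au_region_map() == "upper")
  cols <- 3 * 6 + 1:6
  expect_true(all(sc[rows, cols] == 0.25))
  expect_true(all(sc[-rows, ] == 1))
  expect_true(all(sc[, -cols] == 1))
  # out-of-block entries are bit-identical for every kind
  for (spec in list(transformation_spec("scale", 1.75, 7, "lower"),
                    transformation_spec("zero_fill", window_index = 0, region = "upper"),
                    transformation_spec("gaussian_noise", 0.5, 13, "lower"))) {
    out <- apply_transformation(au, spec)
    rr <- ssmlr:::region_rows(spec$region)
    cc <- ssmlr:::window_cols(spec$window_index)
    expect_identical(out[-rr, ], au[-rr, ])
    expect_identical(out[rr, -cc], au[rr, -cc])
  }
})

test_that("gaussian-noise transformations add N(0, theta^2) draws", {
  set.seed(19)
  au <- matrix(0, 17, 87, dimnames = list(au_default_names(), NULL))
  spec <- transformation_spec("gaussian_noise", 0.5, 5, "lower")
  rows <- ssmlr:::region_rows("lower"); cols <- ssmlr:::window_cols(5)
  draws <- unlist(replicate(200, {
    out <- apply_transformation(au, spec)
    out[rows, cols]
  }, simplify = FALSE))
  n <- length(draws)
  expect_gt(n, 10000)
  expect_lt(abs(mean(draws)), 3 * 0.5 / sqrt(n))
  expect_lt(abs(stats::sd(draws) - 0.5), 3 * 0.5 / sqrt(2 * n))
})

test_that("pretext datasets resample trials and keep EEG untransformed", {
  gen <- small_trialset(50, n_subjects = 1, seed = 23)
  ds <- build_pretext_dataset(gen$trialset, 400, seed = 5)
  expect_identical(dim(ds$au), c(1L, 17L, 87L, 400L))
  expect_identical(length(ds$y_para), 400L)
  # paradigm classes match the trial mix within binomial error
  mix <- table(factor(ssmlr:::trialset_tensors(gen$trialset)$paradigm_class,
                      levels = 0:3)) / 50
  counts <- table(factor(ds$y_para, levels = 0:3))
  for (k in 1:4)
    expect_lt(abs(counts[k] - 400 * mix[k]), 4 * sqrt(400 * mix[k] * (1 - mix[k])) + 4)
  # EEG is carried over untouched
  i <- ds$trial_index[7]
  expect_identical(ds$eeg[1, , , 7], unname(gen$trialset$trials[[i]]$eeg))
  # determinism and contract errors
  expect_identical(build_pretext_dataset(gen$trialset, 50, seed = 9),
                   build_pretext_dataset(gen$trialset, 50, seed = 9))
  expect_error(build_pretext_dataset(gen$trialset, 0), "positive")
  expect_error(build_pretext_dataset(new_trialset(list()), 10), "empty")
})

test_that("pretext losses reproduce their closed forms", {
  # uniform predictions: ln 4, ln 11, ln 15
  expect_equal(paradigm_loss(rep(1 / 4, 4), 2), log(4), tolerance = 1e-12)
  tl <- transformation_losses(rep(1 / 11, 11), 3, rep(1 / 15, 15), 14)
  expect_equal(tl$L_st, log(11), tolerance = 1e-12)
  expect_equal(tl$L_win, log(15), tolerance = 1e-12)
  # one-hot correct predictions give zero loss
  expect_equal(paradigm_loss(c(1, 0, 0, 0), 0), 0)
  tl0 <- transformation_losses(c(rep(0, 5), 1, rep(0, 5)), 5,
                               c(1, rep(0, 14)), 0)
  expect_equal(tl0$L_st, 0); expect_equal(tl0$L_win, 0)
  # -ln 0.7 for a 70% confident correct prediction
  expect_equal(paradigm_loss(c(0.7, 0.1, 0.1, 0.1), 0), -log(0.7),
               tolerance = 1e-12)
  # zero probability at the true class is clamped, not an error
  expect_true(is.finite(paradigm_loss(c(0, 1, 0, 0), 0)))
  # batched form averages
  p <- cbind(c(1, 0, 0, 0), rep(1 / 4, 4))
  expect_equal(paradigm_loss(p, c(0, 1)), log(4) / 2, tolerance = 1e-12)
})

test_that("the alignment loss is a KL divergence toward the EEG side", {
  # identical embeddings give exactly zero
  z <- rnorm(64)
  expect_equal(alignment_loss(z, z), 0)
  # 2-dim toy: p = (0.5, 0.5), q = (0.9, 0.1) -> KL approx 0.5108
  z_eeg <- c(0, 0)
  z_au <- log(c(0.9, 0.1))
  expect_equal(alignment_loss(z_au, z_eeg),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1), tolerance = 1e-12)
  # nonnegative on random probes (Gibbs inequality)
  set.seed(29)
  for (i in 1:20)
    expect_gte(alignment_loss(rnorm(64), rnorm(64)), 0)
  # temperature rescales the softmax
  cfgT <- pretext_loss_config(temperature = 10)
  expect_lt(alignment_loss(z_au, z_eeg, cfgT), alignment_loss(z_au, z_eeg))
})

test_that("the total loss is the weighted four-term sum", {
  cfg <- pretext_loss_config(alpha = 1, beta = 1)
  expect_equal(total_pretext_loss(0.3, 0.2, 0.1, 0.05, cfg), 0.65)
  cfg0 <- pretext_loss_config(alpha = 0, beta = 0)
  expect_equal(total_pretext_loss(0.3, 5, 7, 0.05, cfg0), 0.35)
  expect_equal(total_pretext_loss(0, 0, 0, 0, cfg), 0)
  expect_error(pretext_loss_config(alpha = -1), "nonnegative")
  # monotone nondecreasing in each component
  base <- total_pretext_loss(0.3, 0.2, 0.1, 0.05, cfg)
  expect_gt(total_pretext_loss(0.4, 0.2, 0.1, 0.05, cfg), base)
  expect_gt(total_pretext_loss(0.3, 0.3, 0.1, 0.05, cfg), base)
  expect_gt(total_pretext_loss(0.3, 0.2, 0.2, 0.05, cfg), base)
  expect_gt(total_pretext_loss(0.3, 0.2, 0.1, 0.15, cfg), base)
})
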