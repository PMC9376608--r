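# Explanations: the exact-Shapley oracle, DeepLIFT multiplier agreement,
# reference selection, completeness.

test_that("exact Shapley values obey the closed form for linear models", {
  f_lin <- function(X) X %*% c(1, 2) + 3
  phi <- exact_shapley_oracle(function(X) as.vector(f_lin(X)),
                              x = c(3, 1), reference = c(1, 1))
  expect_equal(phi, c(2, 0), tolerance = 1e-12)
  expect_equal(sum(phi), 2, tolerance = 1e-12)   # f(x) - f(ref)
  # general linear case: phi_i = w_i (x_i - ref_i)
  set.seed(71)
  w <- rnorm(8); x <- rnorm(8); r <- rnorm(8)
  phi8 <- exact_shapley_oracle(function(X) as.vector(X %*% w), x, r)
  expect_equal(phi8, w * (x - r), tolerance = 1e-10)
})

test_that("the Shapley oracle satisfies symmetry and null-player axioms", {
  # symmetric features with identical values get identical attributions
  f_sym <- function(X) X[, 1] * X[, 2] + X[, 1] + X[, 2]
  phi <- exact_shapley_oracle(f_sym, c(2, 2), c(0, 0))
  expect_equal(phi[1], phi[2], tolerance = 1e-12)
  # x = reference -> all-zero attributions
  expect_equal(exact_shapley_oracle(f_sym, c(1, 3), c(1, 3)), c(0, 0))
  expect_error(exact_shapley_oracle(function(X) rowSums(X),
                                    rnorm(25), rnorm(25)), "too many")
})

# single-reference DeepLIFT attributions through a dense network
deeplift_dense <- function(net, x, r) {
  fx <- ssmlr:::nn_forward(net, matrix(x), training = FALSE)
  fr <- ssmlr:::nn_forward(net, matrix(r), training = FALSE)
  m <- ssmlr:::nn_multipliers(net, fx$caches, fr$caches, matrix(1, 1, 1))
  list(phi = as.vector(m) * (x - r),
       delta = as.vector(fx$out) - as.vector(fr$out))
}

test_that("DeepLIFT attributions equal exact Shapley values for linear maps", {
  set.seed(73)
  net <- ssmlr:::nn_network(6L, list(ssmlr:::nn_dense(1)))
  w <- as.vector(net$layers[[1]]$par$W)
  x <- rnorm(6); r <- rnorm(6)
  dl <- deeplift_dense(net, x, r)
  oracle <- exact_shapley_oracle(
    function(X) as.vector(X %*% w) + net$layers[[1]]$par$b, x, r)
  expect_equal(dl$phi, oracle, tolerance = 1e-10)
  expect_equal(sum(dl$phi), dl$delta, tolerance = 1e-10)
})

test_that("DeepLIFT tracks exact Shapley for one-hidden-layer nets", {
  # the rescale rule is a linear-time approximation: it is exact for linear
  # maps and keeps completeness exactly, but individual attributions deviate
  # from exact Shapley values through ReLU kinks; on random probes the
  # typical relative deviation is on the order of 10-20%
  set.seed(79)
  errs <- numeric(10)
  for (probe in 1:10) {
    net <- ssmlr:::nn_network(8L, list(ssmlr:::nn_dense(6), ssmlr:::nn_relu(),
                                       ssmlr:::nn_dense(1)))
    x <- rnorm(8); r <- rnorm(8)
    dl <- deeplift_dense(net, x, r)
    f <- function(X) apply(X, 1, function(row)
      as.vector(ssmlr:::nn_forward(net, matrix(row), training = FALSE)$out))
    oracle <- exact_shapley_oracle(f, x, r)
    expect_equal(sum(dl$phi), dl$delta, tolerance = 1e-8)  # completeness
    errs[probe] <- max(abs(dl$phi - oracle)) / max(abs(oracle))
  }
  expect_lt(stats::median(errs), 0.2)
  expect_lt(max(errs), 0.5)
})

test_that("reference selection enforces the population-matching policy", {
  gen <- small_trialset(60, n_subjects = 2, seed = 81,
                        paradigm_mix = c(WG = 1, WAG = 0, CW = 0, CAW = 0))
  ts <- gen$trialset
  refs <- select_references(ts, 5, k = 20, seed = 3)
  expect_length(refs$indices, 20)
  expect_false(5 %in% refs$indices)
  tr <- ts$trials[[5]]
  for (rt in refs$trials) {
    expect_identical(rt$subject_id, tr$subject_id)
    expect_identical(rt$session_id, tr$session_id)
    expect_identical(rt$paradigm, tr$paradigm)
  }
  expect_identical(select_references(ts, 5, k = 20, seed = 3)$indices,
                   refs$indices)
  # too few matched trials: error reports the eligible count
  gen2 <- small_trialset(6, n_subjects = 1, seed = 82,
                         paradigm_mix = c(WG = 1, WAG = 0, CW = 0, CAW = 0))
  expect_error(select_references(gen2$trialset, 1, k = 20), "5 eligible")
})

make_untrained_model <- function(ts, delta = 1, gamma = 1, variant = "A",
                                 seed = 5) {
  set.seed(seed)
  list(mode = "ssml_ensemble", variant = variant,
       encoder_eeg = build_encoder(encoder_config(variant, "EEG")),
       head_eeg = build_heads("downstream"),
       encoder_au = build_encoder(encoder_config(variant, "AU")),
       head_au = build_heads("downstream"),
       weights = list(delta = delta, gamma = gamma)) |>
    structure(class = "ssml_model")
}

test_that("explanations have the trial-map shapes and satisfy completeness", {
  gen <- small_trialset(40, n_subjects = 1, seed = 83,
                        paradigm_mix = c(WG = 1, WAG = 0, CW = 0, CAW = 0))
  ts <- gen$trialset
  model <- make_untrained_model(ts)
  refs <- select_references(ts, 1, k = 10, seed = 4)
  ex <- explain_trial(model, ts$trials[[1]], refs)
  expect_identical(dim(ex$e_au), c(17L, 87L))
  expect_identical(dim(ex$e_eeg), c(62L, 192L))
  expect_true(all(is.finite(ex$e_au)) && all(is.finite(ex$e_eeg)))
  resid <- abs(sum(ex$e_au) + sum(ex$e_eeg) - (ex$f_x - ex$base_value))
  expect_lt(resid / max(abs(ex$f_x - ex$base_value), 1e-8), 1e-3)
  # averaging is invariant to reference ordering
  refs_rev <- refs; refs_rev$trials <- rev(refs$trials)
  ex2 <- explain_trial(model, ts$trials[[1]], refs_rev)
  expect_equal(ex2$e_au, ex$e_au, tolerance = 1e-12)
  # a dead AU branch (gamma = 0) yields an all-but-zero AU map
  m0 <- make_untrained_model(ts, delta = 1, gamma = 0)
  ex0 <- explain_trial(m0, ts$trials[[1]], refs)
  expect_lt(max(abs(ex0$e_au)), 1e-6)
  # degenerate reference = the trial itself -> both maps all zero
  exd <- explain_trial(model, ts$trials[[1]], list(ts$trials[[1]]))
  expect_lt(max(abs(exd$e_au)), 1e-12)
  expect_lt(max(abs(exd$e_eeg)), 1e-12)
})

test_that("additivity residuals are near-exact for the average-pooling variant", {
  gen <- small_trialset(30, n_subjects = 1, seed = 87,
                        paradigm_mix = c(WG = 1, WAG = 0, CW = 0, CAW = 0))
  model <- make_untrained_model(gen$trialset)
  rep_a <- additivity_report(model, gen$trialset, indices = 1:6, k = 5, seed = 2)
  expect_identical(nrow(rep_a$per_trial), 6L)
  expect_lt(max(rep_a$per_trial$abs_residual), 1e-9)
})
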