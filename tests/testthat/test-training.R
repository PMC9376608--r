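# Training: ensemble combination, metrics, cross-validation plumbing, and
# pretraining behaviour at small scale.

test_that("ensemble_predict follows the weighted-sigmoid closed forms", {
  expect_equal(ensemble_predict(5, -3, list(delta = 0, gamma = 0)), 0.5)
  expect_equal(ensemble_predict(2, 0, list(delta = 1, gamma = 0)),
               1 / (1 + exp(-2)), tolerance = 1e-12)
  # delta=1, gamma=0 reduces to the EEG branch probability for every trial
  z <- rnorm(50)
  expect_equal(ensemble_predict(z, rnorm(50), list(delta = 1, gamma = 0)),
               1 / (1 + exp(-z)))
  expect_error(ensemble_predict(1, 1, list(delta = -1, gamma = 0)))
})

test_that("grid search sends the weight of a pure-noise branch to the grid minimum", {
  set.seed(41)
  y <- rep(0:1, each = 100)
  z_eeg <- 2 * (y - 0.5) + rnorm(200, sd = 0.3)   # informative branch
  z_au <- rnorm(200, sd = 2)                      # pure noise branch
  w <- ssmlr:::search_ensemble_weights(z_eeg, z_au, y)
  expect_identical(w$gamma, 0)
  expect_gt(w$delta, 0)
})

test_that("evaluate_metrics reproduces rank-AUC and F1 closed forms", {
  # perfectly ranked scores
  m <- evaluate_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy_percent, 100)
  # TP=8, FP=2, FN=2 -> precision 0.8, recall 0.8, F1 0.8
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  expect_equal(evaluate_metrics(scores, labels)$f1, 0.8, tolerance = 1e-12)
  # labels independent of scores -> AUC near 1/2 with rank-statistic error
  set.seed(43)
  n <- 10000
  m0 <- evaluate_metrics(runif(n), rbinom(n, 1, 0.5))
  se <- sqrt((n / 2 + 1) / (3 * (n / 2) * (n / 2)))  # null Wilcoxon sd of AUC
  expect_lt(abs(m0$auc - 0.5), 4 * se)
  expect_error(evaluate_metrics(runif(5), rep(1, 5)), "one class")
})

test_that("rank AUC agrees with the independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(60) + y
    expect_equal(evaluate_metrics(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-10)
  }
})

test_that("cross-validation splits have the planned arithmetic and are disjoint", {
  gen <- small_trialset(130, n_subjects = 1, effect = 2, seed = 51)
  bal <- balance_trialset(gen$trialset, seed = 1)
  y_all <- vapply(bal$trials, `[[`, "", "fluency")
  keep <- c(which(y_all == "fluent")[1:50], which(y_all == "stuttered")[1:50])
  bal <- bal[keep]  # exactly 50 + 50
  y <- vapply(bal$trials, `[[`, "", "fluency")
  plan <- cv_plan(n_folds = 10, seed = 7)
  set.seed(plan$seed)
  hold <- ssmlr:::stratified_sample(as.integer(y == "stuttered"),
                                    max(2L, round(0.1 * 100)))
  expect_length(hold, 10)   # holdout 10 of 100
  pool <- setdiff(1:100, hold)
  folds <- ssmlr:::make_folds(as.integer(y[pool] == "stuttered"), 10)
  expect_identical(sort(unique(folds)), 1:10)
  expect_identical(length(folds), 90L)  # pool 90
  expect_true(all(table(folds) == 9))   # each fold validates on 9
  # same seed, same folds
  set.seed(plan$seed)
  hold2 <- ssmlr:::stratified_sample(as.integer(y == "stuttered"), 10)
  expect_identical(hold, hold2)
  # too few trials errors with the required minimum
  expect_error(cross_validate(bal[1:8], cv_plan(n_folds = 10)), "at least")
})

test_that("downstream training rejects unbalanced sets in strict mode", {
  gen <- small_trialset(40, n_subjects = 1, seed = 53)
  fl <- vapply(gen$trialset$trials, `[[`, "", "fluency")
  if (sum(fl == "fluent") == sum(fl == "stuttered"))
    gen$trialset <- gen$trialset[-1]
  expect_error(train_downstream(NULL, gen$trialset, fast_train(epochs = 1),
                                mode = "fsml"),
               "unbalanced")
})

test_that("pretraining is deterministic and beats the uniform-loss references", {
  gen <- small_trialset(40, n_subjects = 1, effect = 1, seed = 57)
  cfg <- fast_train(seed = 5, epochs = 8, batch = 48, lr = 0.02)
  ck1 <- pretrain(gen$trialset, n_samples = 480, config = cfg)
  ck2 <- pretrain(gen$trialset, n_samples = 480, config = cfg)
  expect_identical(tail(ck1$history$train_loss, 1),
                   tail(ck2$history$train_loss, 1))
  # all three pretext tasks end below their uniform-prediction losses
  h <- tail(ck1$history, 1)
  expect_lt(h$val_L_para, log(4))
  expect_lt(h$val_L_st, log(11))
  expect_lt(h$val_L_win, log(15))
})

test_that("flipping holdout labels post hoc never changes the trained weights", {
  gen <- small_trialset(44, n_subjects = 1, effect = 2, seed = 61)
  bal <- balance_trialset(gen$trialset, seed = 2)
  plan <- cv_plan(n_folds = 2, seed = 13)
  cfg <- fast_train(seed = 9, epochs = 2, batch = 16)
  cv1 <- cross_validate(bal, plan, cfg, mode = "fsml")
  # corrupt the held-out trial content (labels, and hence the stratified
  # split, unchanged): fold training and model selection must not notice
  bal2 <- bal
  for (i in cv1$holdout_idx) {
    bal2$trials[[i]]$au[] <- 1
    bal2$trials[[i]]$eeg[] <- 0
  }
  cv2 <- cross_validate(bal2, plan, cfg, mode = "fsml")
  expect_identical(cv1$holdout_idx, cv2$holdout_idx)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$best_model$encoder_au$layers[[1]]$par$W,
                   cv2$best_model$encoder_au$layers[[1]]$par$W)
})
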