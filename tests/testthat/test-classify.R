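bench <- function(n = 300, sep = 4, seed = 7) {
  fm <- make_separable_features(n_per_class = n, dim = 8, separation_sd = sep,
                                seed = seed)
  split_trials(fm, 0.7, seed = 1)
}

test_that("classifier specs validate their hyperparameter schemas", {
  expect_s3_class(classifier_spec("knn", k = 3), "classifier_spec")
  expect_error(classifier_spec("knn", cost = 2), "unknown hyperparameter")
  expect_error(classifier_spec("gcql", hidden = 8), "unknown hyperparameter")
  expect_error(gcql_config(gamma = 2), "gamma")
  expect_error(gcql_config(eps_start = 0.1, eps_end = 0.5), "eps")
})

test_that("trial-granular splitting preserves structure", {
  # 48 trials at 24/class, 0.7 -> 34 train / 14 test
  fm <- make_separable_features(n_per_class = 240, dim = 2, separation_sd = 1,
                                seed = 2)
  sp <- split_trials(fm, 0.7, seed = 3)
  expect_equal(length(unique(sp$train$trial_id)), 34)
  expect_equal(length(unique(sp$test$trial_id)), 14)
  expect_length(intersect(unique(sp$train$trial_id),
                          unique(sp$test$trial_id)), 0)
  # class balance within a trial of parity
  tr_counts <- table(sp$train[!duplicated(sp$train$trial_id), ]$label)
  expect_lte(abs(diff(as.vector(tr_counts))), 1)
  # determinism and fraction validation
  sp2 <- split_trials(fm, 0.7, seed = 3)
  expect_identical(sp$train$window_id, sp2$train$window_id)
  expect_error(split_trials(fm, 1.0), "strictly between")
  one_trial <- fm[fm$trial_id %in% c(1, 25), ]
  expect_error(split_trials(one_trial, 0.7), "2 trials per class")
})

test_that("KNN with one neighbour memorises its training set", {
  sp <- bench(100, sep = 1)
  m <- fit_aad(sp$train, classifier_spec("knn"))
  expect_equal(mean(predict(m, sp$train) == sp$train$label), 1)
})

test_that("SVM separates well-separated blobs", {
  sp <- bench(100, sep = 4)
  m <- fit_aad(sp$train, classifier_spec("svm", seed = 4))
  expect_gte(evaluate_aad(m, sp$test)$acc, 0.99)
})

test_that("recurrent classifiers train reproducibly and separate the benchmark", {
  sp <- bench(150, sep = 4)
  for (kind in c("lstm", "bilstm")) {
    spec <- classifier_spec(kind, epochs = 20, seed = 8)
    m1 <- fit_aad(sp$train, spec)
    m2 <- fit_aad(sp$train, spec)
    expect_identical(predict(m1, sp$test), predict(m2, sp$test))
    expect_gte(evaluate_aad(m1, sp$test)$acc, 0.95)
  }
})

test_that("GCQL learns separable features and behaves at chance on null data", {
  sp <- bench(200, sep = 4)
  m <- train_gcql(sp$train, gcql_config(epochs = 25), seed = 9)
  expect_gte(evaluate_aad(m, sp$test)$acc, 0.95)
  m2 <- train_gcql(sp$train, gcql_config(epochs = 25), seed = 9)
  expect_identical(predict(m, sp$test), predict(m2, sp$test))
  # label shuffling destroys the signal: chance-level held-out accuracy
  sp0 <- bench(200, sep = 0, seed = 11)
  m0 <- train_gcql(sp0$train, gcql_config(epochs = 15), seed = 9)
  acc0 <- evaluate_aad(m0, sp0$test)$acc
  expect_gte(acc0, 0.40)
  expect_lte(acc0, 0.60)
})

test_that("a gamma-zero TD target reduces to reward regression", {
  sp <- bench(150, sep = 4)
  m <- train_gcql(sp$train, gcql_config(epochs = 20, gamma = 0), seed = 12)
  # direct reward regression baseline: +1 for the true action, -1 otherwise,
  # fitted by least squares on the same standardized features
  cols <- setdiff(names(sp$train), c("window_id", "trial_id", "label"))
  Xtr <- scale(as.matrix(sp$train[, cols]))
  Xte <- scale(as.matrix(sp$test[, cols]),
               center = attr(Xtr, "scaled:center"),
               scale = attr(Xtr, "scaled:scale"))
  r1 <- ifelse(sp$train$label == "SPK1", 1, -1)
  fit1 <- stats::lm.fit(cbind(1, Xtr), r1)
  q1 <- cbind(1, Xte) %*% fit1$coefficients
  baseline <- ifelse(q1 > 0, "SPK1", "SPK2")
  agree <- mean(as.character(predict(m, sp$test)) == baseline)
  expect_gte(agree, 0.95)
})

test_that("evaluation arithmetic follows the confusion-matrix definitions", {
  rep <- confusion_report(tp = 45, tn = 40, fp = 10, fn = 5)
  expect_equal(rep$acc, 0.85)
  expect_equal(rep$tpr, 0.90)
  expect_equal(rep$tnr, 0.80)
  # perfect predictor and the all-positive degenerate predictor
  sp <- bench(100, sep = 4)
  m <- fit_aad(sp$train, classifier_spec("knn"))
  r <- evaluate_aad(m, sp$test)
  expect_equal(r$tp + r$tn + r$fp + r$fn, nrow(sp$test))
  expect_true(all(c(r$acc, r$tpr, r$tnr) >= 0 & c(r$acc, r$tpr, r$tnr) <= 1))
  # permutation invariance over test rows
  perm <- sp$test[sample(nrow(sp$test)), ]
  attr(perm, "window_length_s") <- attr(sp$test, "window_length_s")
  r2 <- evaluate_aad(m, perm)
  expect_equal(r2[, c("tp", "tn", "fp", "fn")], r[, c("tp", "tn", "fp", "fn")])
  # absent class leaves its rate NaN with a warning
  pos_only <- sp$test[sp$test$label == "SPK1", ]
  expect_warning(r3 <- evaluate_aad(m, pos_only), "absent")
  expect_true(is.nan(r3$tnr))
})

test_that("window sweeps run the whole pipeline per length", {
  sim <- small_sim(seed = 44, n_trials = 3, trial_s = 5)
  rec <- sim$recording
  sw <- suppressWarnings(window_sweep(
    rec, lengths_s = c(1, 2, 10),
    spec = classifier_spec("knn"), seed = 2))
  # the 10 s length exceeds the 5 s trials and is skipped
  expect_equal(nrow(sw), 2)
  expect_equal(sw$window_length_s, c(1, 2))
  expect_true(all(sw$tp + sw$tn + sw$fp + sw$fn > 0))
})
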