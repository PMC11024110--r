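#' Classifier specification
#'
#' Declares one of the five attention decoders with its hyperparameters.
#' Defaults follow the pipeline's implementation setup: KNN with one
#' neighbour and Euclidean distance; SVM with a Gaussian kernel and box
#' constraint 1; LSTM with 5 recurrent layers and Bi-LSTM with 3, both with
#' dropout 0.2, batch size 512, Adam, 100 epochs; features are z-scored with
#' training-split statistics before every model.
#'
#' @param method `"knn"`, `"svm"`, `"lstm"`, `"bilstm"` or `"gcql"`.
#' @param ... hyperparameter overrides, validated against the method's schema:
#'   KNN `k`; SVM `cost`, `gamma`; LSTM/Bi-LSTM `hidden`, `n_layers`,
#'   `dropout`, `batch_size`, `epochs`, `lr`, `seq_len`; GCQL accepts a
#'   [gcql_config()] as `config` plus `seq_len`.
#' @param seed RNG seed for any stochastic training.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(method = c("knn", "svm", "lstm", "bilstm", "gcql"),
                            ..., seed = 1) {
  kind <- match.arg(method)
  defaults <- switch(kind,
    knn = list(k = 1),
    svm = list(cost = 1, gamma = NULL),
    lstm = list(hidden = 32, n_layers = 5, dropout = 0.2, batch_size = 512,
                epochs = 100, lr = 1e-3, seq_len = 1),
    bilstm = list(hidden = 32, n_layers = 3, dropout = 0.2, batch_size = 512,
                  epochs = 100, lr = 1e-3, seq_len = 1),
    gcql = list(config = gcql_config(), seq_len = 1)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  assert_that(length(unknown) == 0,
              sprintf("unknown hyperparameter(s) for %s: %s", kind,
                      paste(unknown, collapse = ", ")))
  hp <- utils::modifyList(defaults, over)
  structure(list(kind = kind, hyper = hp, seed = seed),
            class = "classifier_spec")
}

#' GRU-CNN Q-learning configuration
#'
#' The Q-network is a GRU stage over the (short) feature sequence, a 1-D
#' convolution stage over the GRU outputs, and a dense head emitting two
#' action values (predict SPK1 / predict SPK2). Each analysis window is a
#' single-step episode: reward `reward_correct` when the greedy/exploratory
#' action matches the label, else `reward_wrong`. Episodes are terminal, so
#' with the default `gamma = 0` the temporal-difference target reduces to the
#' immediate reward. Behaviour policy is epsilon-greedy with a linear decay;
#' transitions go through an experience-replay buffer.
#'
#' @param gru_units,conv_filters,kernel_size,dense_units architecture sizes.
#' @param gamma discount factor in `[0, 1]`.
#' @param eps_start,eps_end exploration schedule endpoints
#'   (`eps_end <= eps_start <= 1`), decayed linearly over training steps.
#' @param replay_size experience-replay capacity.
#' @param batch_size replay minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs passes over the training episodes.
#' @param reward_correct,reward_wrong rewards for matching / missing the label.
#' @return A `gcql_config` object.
#' @export
gcql_config <- function(gru_units = 64, conv_filters = 32, kernel_size = 3,
                        dense_units = 32, gamma = 0, eps_start = 1,
                        eps_end = 0.05, replay_size = 10000, batch_size = 512,
                        learning_rate = 1e-3, epochs = 100,
                        reward_correct = 1, reward_wrong = -1) {
  assert_that(gamma >= 0 && gamma <= 1, "gamma must be in [0, 1]")
  assert_that(eps_end <= eps_start && eps_start <= 1 && eps_end >= 0,
              "need 0 <= eps_end <= eps_start <= 1")
  structure(list(gru_units = gru_units, conv_filters = conv_filters,
                 kernel_size = kernel_size, dense_units = dense_units,
                 gamma = gamma, eps_start = eps_start, eps_end = eps_end,
                 replay_size = replay_size, batch_size = batch_size,
                 learning_rate = learning_rate, epochs = epochs,
                 reward_correct = reward_correct, reward_wrong = reward_wrong),
            class = "gcql_config")
}

#' Split a feature table into train and test at trial granularity
#'
#' Windows of one trial never straddle the split; the split is stratified by
#' class so balance is preserved to within one trial. 70/30 is the pipeline
#' default (34 of 48 trials in training).
#'
#' @param fm a [build_features()] tibble.
#' @param train_fraction fraction of trials (per class) in the training set.
#' @param seed RNG seed.
#' @return `list(train =, test =)` of feature tibbles.
#' @export
split_trials <- function(fm, train_fraction = 0.7, seed = 1) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be strictly between 0 and 1")
  tr_class <- fm |> group_by(.data$trial_id) |>
    summarise(class = .data$label[1], .groups = "drop")
  counts <- table(tr_class$class)
  assert_that(all(counts >= 2),
              "need at least 2 trials per class to split")
  train_ids <- withr::with_seed(derive_seed(seed, "split"), {
    unlist(lapply(split(tr_class$trial_id, tr_class$class), function(ids) {
      n_tr <- round(train_fraction * length(ids))
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
      sample(ids, n_tr)
    }))
  })
  list(train = fm[fm$trial_id %in% train_ids, ],
       test = fm[!fm$trial_id %in% train_ids, ])
}

# deterministic k-nearest-neighbour vote: neighbours ordered by (distance,
# training index), vote ties resolved toward the lowest class index — so
# repeated calls always agree, even on heavily quantised features
knn_predict <- function(Xtr, ytr, Xte, k) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  apply(d2, 1, function(dr) {
    nn <- order(dr, seq_along(dr))[seq_len(k)]
    votes <- tabulate(ytr[nn], nbins = 2)
    which.max(votes)
  })
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")
}

# group rows into [B, seq_len, D] sequences of consecutive windows within a
# trial (history padded by repeating the earliest available window)
make_sequences <- function(X, trial_id, seq_len) {
  B <- nrow(X)
  arr <- array(0, c(B, seq_len, ncol(X)))
  for (i in seq_len(B)) {
    for (s in seq_len(seq_len)) {
      j <- i - seq_len + s
      while (j < 1 || trial_id[j] != trial_id[i]) j <- j + 1
      arr[i, s, ] <- X[j, ]
    }
  }
  arr
}

#' Train an attention classifier
#'
#' Fits the classifier declared by `spec` on a feature table. Features are
#' z-scored with training statistics (stored in the model and re-applied at
#' prediction). Training is fully seeded: the same spec and data give
#' identical models.
#'
#' @param train a [build_features()] tibble with both classes present.
#' @param spec a [classifier_spec()].
#' @return An `aad_model`.
#' @export
fit_aad <- function(train, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  assert_that(nrow(train) > 0, "empty training set")
  assert_that(all(c("SPK1", "SPK2") %in% train$label),
              "both classes must be present for training")
  cols <- feature_columns(train)
  X <- as.matrix(train[, cols])
  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  y <- ifelse(train$label == "SPK1", 1L, 2L)
  hp <- spec$hyper
  fit <- switch(spec$kind,
    knn = list(X = Xs, y = y, k = hp$k),
    svm = withr::with_seed(derive_seed(spec$seed, "svm"), {
      e1071::svm(Xs, factor(y, levels = 1:2), kernel = "radial",
                 cost = hp$cost, gamma = hp$gamma %||% (1 / ncol(Xs)),
                 scale = FALSE)
    }),
    lstm = train_rnn_classifier(
      make_sequences(Xs, train$trial_id, hp$seq_len), y,
      bidirectional = FALSE, hidden = hp$hidden, n_layers = hp$n_layers,
      dropout = hp$dropout, batch_size = hp$batch_size, epochs = hp$epochs,
      lr = hp$lr, seed = spec$seed),
    bilstm = train_rnn_classifier(
      make_sequences(Xs, train$trial_id, hp$seq_len), y,
      bidirectional = TRUE, hidden = hp$hidden, n_layers = hp$n_layers,
      dropout = hp$dropout, batch_size = hp$batch_size, epochs = hp$epochs,
      lr = hp$lr, seed = spec$seed),
    gcql = train_gcql_core(make_sequences(Xs, train$trial_id, hp$seq_len), y,
                           hp$config, seed = spec$seed)
  )
  structure(list(kind = spec$kind, spec = spec, fit = fit, standardize = st,
                 features = cols, seq_len = hp$seq_len %||% 1),
            class = "aad_model")
}

#' @export
print.aad_model <- function(x, ...) {
  cat(sprintf("<aad_model> %s over %d features\n", x$kind, length(x$features)))
  invisible(x)
}

#' Train the GRU-CNN Q-learning classifier
#'
#' Convenience front-end equivalent to
#' `fit_aad(train, classifier_spec("gcql", config = config))`.
#'
#' @param train a [build_features()] tibble.
#' @param config a [gcql_config()].
#' @param seq_len consecutive-window sequence length fed to the GRU stage.
#' @param seed RNG seed.
#' @return An `aad_model`.
#' @export
train_gcql <- function(train, config = gcql_config(), seq_len = 1, seed = 1) {
  fit_aad(train, classifier_spec("gcql", config = config, seq_len = seq_len,
                                 seed = seed))
}

train_gcql_core <- function(X, y, cfg, seed = 1) {
  B <- dim(X)[1]; D <- dim(X)[3]
  n_batches <- ceiling(B / min(cfg$batch_size, B))
  total_steps <- cfg$epochs * n_batches
  withr::with_seed(derive_seed(seed, "gcql"), {
    params <- gcql_net_init(D, cfg$gru_units, cfg$conv_filters,
                            cfg$kernel_size, cfg$dense_units)
    state <- adam_init(params)
    cap <- cfg$replay_size
    rep_X <- array(0, c(cap, dim(X)[2], D))
    rep_a <- integer(cap); rep_r <- numeric(cap)
    n_stored <- 0L; write_pos <- 0L
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(B)
      for (start in seq(1, B, by = cfg$batch_size)) {
        step <- step + 1L
        idx <- ord[start:min(start + cfg$batch_size - 1, B)]
        epsilon <- cfg$eps_start +
          (cfg$eps_end - cfg$eps_start) * (step - 1) / max(total_steps - 1, 1)
        Xb <- X[idx, , , drop = FALSE]
        fw <- gcql_net_forward(seq_to_list(Xb), params, cfg$gru_units)
        greedy <- max.col(fw$q, ties.method = "first")
        explore <- stats::runif(length(idx)) < epsilon
        rand_a <- sample(1:2, length(idx), replace = TRUE)
        act <- ifelse(explore, rand_a, greedy)
        rew <- ifelse(act == y[idx], cfg$reward_correct, cfg$reward_wrong)
        # single-step terminal episodes: no bootstrap term survives gamma
        for (j in seq_along(idx)) {
          write_pos <- (write_pos %% cap) + 1L
          rep_X[write_pos, , ] <- X[idx[j], , ]
          rep_a[write_pos] <- act[j]; rep_r[write_pos] <- rew[j]
          n_stored <- min(n_stored + 1L, cap)
        }
        take <- sample.int(n_stored, min(cfg$batch_size, n_stored))
        Xr <- rep_X[take, , , drop = FALSE]
        fr <- gcql_net_forward(seq_to_list(Xr), params, cfg$gru_units)
        qa <- fr$q[cbind(seq_along(take), rep_a[take])]
        td <- qa - rep_r[take]
        if (!all(is.finite(td))) {
          abort(sprintf("GCQL training diverged at step %d (non-finite TD error)",
                        step))
        }
        dq <- fr$q * 0
        dq[cbind(seq_along(take), rep_a[take])] <- 2 * td / length(take)
        grads <- gcql_net_backward(dq, fr, params, cfg$gru_units)
        st <- adam_step(params, grads, state, lr = cfg$learning_rate)
        params <- st$params; state <- st$state
      }
    }
  })
  list(params = params, config = cfg)
}

#' Predict attended speaker for new windows
#'
#' @param object an `aad_model` from [fit_aad()].
#' @param newdata a feature tibble with the model's feature columns.
#' @param ... unused.
#' @return Factor of `"SPK1"`/`"SPK2"` predictions, one per row.
#' @export
predict.aad_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features])
  Xs <- standardize_apply(X, object$standardize)
  pred_idx <- switch(object$kind,
    knn = knn_predict(object$fit$X, object$fit$y, Xs, object$fit$k),
    svm = as.integer(as.character(stats::predict(object$fit, Xs))),
    lstm = ,
    bilstm = max.col(predict_rnn_classifier(
      object$fit, make_sequences(Xs, newdata$trial_id, object$seq_len)),
      ties.method = "first"),
    gcql = {
      fw <- gcql_net_forward(
        seq_to_list(make_sequences(Xs, newdata$trial_id, object$seq_len)),
        object$fit$params, object$fit$config$gru_units)
      max.col(fw$q, ties.method = "first")
    }
  )
  factor(c("SPK1", "SPK2")[pred_idx], levels = c("SPK1", "SPK2"))
}

#' Evaluate a fitted model on held-out windows
#'
#' Confusion counts with SPK1 as the positive class and the three headline
#' metrics: `acc = (TP+TN)/(TP+TN+FP+FN)`, `tpr = TP/(TP+FN)` (sensitivity),
#' `tnr = TN/(TN+FP)` (specificity). A class absent from the test set leaves
#' its rate `NaN` with a warning.
#'
#' @param model an `aad_model`.
#' @param test a feature tibble.
#' @param positive_class the positive label, default `"SPK1"`.
#' @return A one-row `eval_report` tibble: `tp`, `tn`, `fp`, `fn`, `acc`,
#'   `tpr`, `tnr`, `window_length_s`.
#' @export
evaluate_aad <- function(model, test, positive_class = "SPK1") {
  assert_that(nrow(test) > 0, "empty test set")
  pred <- predict(model, test)
  truth <- test$label
  pos <- positive_class
  neg <- setdiff(c("SPK1", "SPK2"), pos)
  confusion_report(
    tp = sum(pred == pos & truth == pos),
    tn = sum(pred == neg & truth == neg),
    fp = sum(pred == pos & truth == neg),
    fn = sum(pred == neg & truth == pos),
    window_length_s = attr(test, "window_length_s") %||% NA_real_
  )
}

#' Build an evaluation report from raw confusion counts
#'
#' @param tp,tn,fp,fn confusion counts (SPK1 positive).
#' @param window_length_s window length the counts refer to (s), optional.
#' @return A one-row `eval_report` tibble.
#' @export
confusion_report <- function(tp, tn, fp, fn, window_length_s = NA_real_) {
  if (tp + fn == 0 || tn + fp == 0) {
    warn("a class is absent from the test set; its rate is NaN")
  }
  out <- tibble(tp = tp, tn = tn, fp = fp, fn = fn,
                acc = (tp + tn) / (tp + tn + fp + fn),
                tpr = tp / (tp + fn), tnr = tn / (tn + fp),
                window_length_s = window_length_s)
  class(out) <- c("eval_report", class(out))
  out
}

#' Sweep the analysis window length
#'
#' Runs the full decoding pipeline — window, featurise, trial-granular split,
#' train, evaluate — once per requested window length with a shared seed.
#' The default feature is the recurrence rate of the window's GFP series
#' (`rr(gfp)`), the combination this pipeline found optimal, which remains
#' defined down to windows of a few samples. Lengths longer than the shortest
#' trial are skipped with a warning.
#'
#' @param rec a preprocessed [eeg_recording()] with labelled trials.
#' @param lengths_s window lengths (s) to evaluate.
#' @param spec a [classifier_spec()].
#' @param prototypes optional [fit_prototypes()] result (required by feature
#'   modes that need microstates).
#' @param mode,selection,rqa_cfg,subwindow_s forwarded to [build_features()].
#' @param train_fraction forwarded to [split_trials()].
#' @param seed shared RNG seed.
#' @return An `aad_sweep` tibble of one [evaluate_aad()] row per length.
#' @export
window_sweep <- function(rec, lengths_s = c(0.02, 0.1, 0.5, 1, 2, 5, 10, 20, 50),
                         spec = classifier_spec("gcql"), prototypes = NULL,
                         mode = "rqa_only", selection = "rr(gfp)",
                         rqa_cfg = embedding_config(), subwindow_s = 0.25,
                         train_fraction = 0.7, seed = 1) {
  shortest <- min(rec$trials$end - rec$trials$start) / rec$sfreq
  reports <- list()
  for (len in lengths_s) {
    if (len > shortest) {
      warn(sprintf("window %g s exceeds the shortest trial (%.2f s); skipped",
                   len, shortest))
      next
    }
    windows <- segment_windows(rec, len)
    fm <- build_features(windows, prototypes, mode = mode, rqa_cfg = rqa_cfg,
                         subwindow_s = subwindow_s, selection = selection)
    sp <- split_trials(fm, train_fraction, seed = seed)
    model <- fit_aad(sp$train, spec)
    rep <- evaluate_aad(model, sp$test)
    rep$window_length_s <- len
    reports[[length(reports) + 1L]] <- rep
  }
  out <- bind_rows(reports)
  class(out) <- c("aad_sweep", "eval_report", class(tibble()))
  out
}
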