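fixture_pipeline <- function(seed = 31, snr = 10, n_trials = 2, trial_s = 4) {
  sim <- small_sim(seed = seed, snr = snr, n_trials = n_trials,
                   trial_s = trial_s)
  rec <- sim$recording
  gfp <- compute_gfp(rec$data, rec$sfreq)
  pk <- find_gfp_peaks(gfp, 10, rec$sfreq)
  proto <- fit_prototypes(t(rec$data[, pk]), 4, n_init = 3, seed = seed)
  list(sim = sim, rec = rec, proto = proto)
}

test_that("microstate parameter series have the documented shapes", {
  fx <- fixture_pipeline()
  w <- segment_windows(fx$rec, 1)
  x <- w$data[[1]]
  s <- ms_parameter_series(x, fx$proto, "mean_gfp", sfreq = 256)
  expect_named(s, "gfp")
  expect_length(s$gfp, 256)
  expect_equal(s$gfp, compute_gfp(x, 256)$values)
  cov <- ms_parameter_series(x, fx$proto, "coverage", subwindow_s = 0.25,
                             sfreq = 256)
  expect_length(cov, 4)
  expect_true(all(lengths(cov) == 4))
  expect_true(all(unlist(cov) >= 0 & unlist(cov) <= 1))
  # coverage points per sub-window sum to one across states
  expect_equal(Reduce(`+`, cov), rep(1, 4), tolerance = 1e-9)
  expect_error(ms_parameter_series(x[, 1:128], fx$proto, "coverage",
                                   subwindow_s = 0.25, sfreq = 256),
               "fewer than 4")
})

test_that("feature tables have the advertised column structure", {
  fx <- fixture_pipeline()
  w <- segment_windows(fx$rec, 1)
  ms <- build_features(w, fx$proto, mode = "ms_only")
  expect_equal(length(setdiff(names(ms), c("window_id", "trial_id", "label"))),
               16)   # 4 parameters x 4 states
  rq <- build_features(w, fx$proto, mode = "rqa_only")
  expect_equal(length(setdiff(names(rq), c("window_id", "trial_id", "label"))),
               8)
  mv <- build_features(w[1:4, ], fx$proto, mode = "multivariate")
  cols <- setdiff(names(mv), c("window_id", "trial_id", "label"))
  expect_length(cols, 104)  # 8 metrics x (1 gfp + 3 params x 4 states)
  expect_true("rr(gfp)" %in% cols)
  expect_true("rpde(coverage[2])" %in% cols)
  expect_false(anyNA(mv))
  # named selection, and unknown names rejected
  sel <- build_features(w, fx$proto, mode = "rqa_only",
                        selection = c("rr(gfp)", "det(gfp)"))
  expect_equal(setdiff(names(sel), c("window_id", "trial_id", "label")),
               c("rr(gfp)", "det(gfp)"))
  expect_error(build_features(w, fx$proto, mode = "rqa_only",
                              selection = "nope"), "unknown feature")
})

test_that("the pipeline's rr(gfp) equals a manual composition", {
  fx <- fixture_pipeline(seed = 32)
  w <- segment_windows(fx$rec, 1)
  fm <- build_features(w, fx$proto, mode = "rqa_only")
  cfg <- embedding_config()
  for (i in c(1, 5)) {
    manual <- rqa_features(recurrence_matrix(
      compute_gfp(w$data[[i]], 256)$values, cfg))
    expect_equal(fm[["rr(gfp)"]][i], manual$rr)
    expect_equal(fm[["rpde(gfp)"]][i], manual$rpde)
  }
})

test_that("feature assembly is deterministic", {
  fx <- fixture_pipeline(seed = 33)
  w <- segment_windows(fx$rec, 1)
  a <- build_features(w, fx$proto, mode = "rqa_only")
  b <- build_features(w, fx$proto, mode = "rqa_only")
  expect_identical(a, b)
})

test_that("screening separates shifted groups and respects invariances", {
  mk_fm <- function(x1, x2) {
    tibble::tibble(window_id = seq_along(c(x1, x2)),
                   trial_id = rep(1:2, c(length(x1), length(x2))),
                   label = rep(c("SPK1", "SPK2"), c(length(x1), length(x2))),
                   f = c(x1, x2))
  }
  set.seed(34)
  base <- rnorm(100)
  # identical distributions (same draw) -> not significant
  same <- screen_features(mk_fm(base, base))
  expect_false(same$significant[1])
  # 3 sigma shift at n = 100/group -> detected
  shift <- screen_features(mk_fm(base, rnorm(100) + 3))
  expect_true(shift$significant[1])
  expect_lt(shift$group_p[1], 1e-10)
  # constant feature flagged degenerate with p 1
  const <- screen_features(mk_fm(rep(1, 10), rep(1, 10)))
  expect_true(const$degenerate[1])
  expect_equal(const$group_p[1], 1)
  expect_false(const$significant[1])
  # row order invariance
  fm <- mk_fm(base, rnorm(100, 0.5))
  perm <- fm[sample(nrow(fm)), ]
  expect_equal(screen_features(fm)$group_p, screen_features(perm)$group_p)
  # p-values live in [0, 1]
  expect_true(all(shift$group_p >= 0 & shift$group_p <= 1))
  expect_error(screen_features(mk_fm(rnorm(2), rnorm(100))), "at least 3")
})

test_that("null screening holds its false-positive rate", {
  # 400 null simulations at n = 20/group; the empirical alpha must sit in
  # the binomial band around 0.05
  set.seed(35)
  hits <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    fm <- tibble::tibble(window_id = 1:40, trial_id = rep(1:4, each = 10),
                         label = rep(c("SPK1", "SPK2"), each = 20),
                         f = rnorm(40))
    hits <- hits + screen_features(fm)$significant[1]
  }
  expect_gt(hits / n_sim, 0.02)
  expect_lt(hits / n_sim, 0.08)
})
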