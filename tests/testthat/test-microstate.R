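test_that("GFP matches its definition and the naive loop", {
  expect_equal(compute_gfp(matrix(c(2, 2, 2), 3, 1))$values, 0)
  expect_equal(compute_gfp(matrix(c(1, -1), 2, 1))$values, 1)
  expect_equal(compute_gfp(matrix(c(2, 0, -2, 0), 4, 1))$values, sqrt(2))
  expect_error(compute_gfp(matrix(1, 1, 5)), "2 channels")
  set.seed(3)
  x <- matrix(rnorm(16 * 200), 16)
  expect_equal(compute_gfp(x)$values, naive_gfp(x), tolerance = 1e-12)
})

test_that("GFP peak finding agrees with exhaustive scan and spaces peaks", {
  expect_equal(find_gfp_peaks(c(0, 1, 0, 2, 0), min_distance_ms = 0,
                              sfreq = 1000), c(2L, 4L))
  expect_length(find_gfp_peaks(1:10, sfreq = 1000), 0)
  set.seed(4)
  v <- abs(sin(seq(0, 20, length.out = 500))) + rnorm(500, sd = 0.05)
  expect_equal(find_gfp_peaks(v, min_distance_ms = 0, sfreq = 100),
               naive_peaks(v))
  spaced <- find_gfp_peaks(v, min_distance_ms = 100, sfreq = 100)
  expect_true(all(diff(spaced) >= 10))
  expect_true(all(spaced %in% naive_peaks(v)))
})

test_that("noiseless planted templates are recovered with GEV 1", {
  K <- 4; C <- 8
  tpl <- make_templates(K, C, seed = 6)
  set.seed(7)
  pol <- sample(c(-1, 1), 200, replace = TRUE)
  amp <- runif(200, 0.5, 2)
  maps <- tpl[sample(K, 200, replace = TRUE), ] * pol * amp
  for (method in c("kmeans", "aahc")) {
    fit <- fit_prototypes(maps, K, method = method, n_init = 5, seed = 1)
    expect_equal(fit$gev_total, 1, tolerance = 1e-9)
    # recovered maps match templates up to sign and permutation (spatial
    # correlation: both sides channel-centered and unit-normalised)
    tc <- tpl - rowMeans(tpl)
    tc <- tc / sqrt(rowSums(tc^2))
    cors <- abs(fit$maps %*% t(tc))
    expect_true(all(apply(cors, 2, max) > 0.999))
    expect_equal(sort(apply(cors, 1, which.max)), 1:4)
  }
  expect_equal(sum(fit_prototypes(maps, K, "kmeans", seed = 1)$gev_per_state),
               1, tolerance = 1e-9)
})

test_that("all four fitting methods return unit-norm maps and valid GEV", {
  sim <- small_sim(seed = 13, n_trials = 1, trial_s = 4)
  gfp <- compute_gfp(sim$recording$data, 256)
  pk <- find_gfp_peaks(gfp, 10, 256)
  maps <- t(sim$recording$data[, pk])
  for (method in c("kmeans", "aahc", "pca", "ica")) {
    fit <- fit_prototypes(maps, 4, method = method, n_init = 3, seed = 2)
    expect_equal(sqrt(rowSums(fit$maps^2)), rep(1, 4), tolerance = 1e-9)
    expect_gte(fit$gev_total, 0)
    expect_lte(fit$gev_total, 1)
  }
})

test_that("K = 1 k-means returns the dominant eigenvector direction", {
  set.seed(8)
  maps <- matrix(rnorm(60 * 6), 60)
  fit <- fit_prototypes(maps, 1, "kmeans", n_init = 2, seed = 3)
  cm <- maps - rowMeans(maps)
  U <- cm / sqrt(rowSums(cm^2))
  w <- rowSums(cm^2) / ncol(maps)      # gfp^2 weights used in the update
  ev <- eigen(crossprod(U * sqrt(w)), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(fit$maps[1, ] * ev / sqrt(sum(ev^2)))), 1,
               tolerance = 1e-8)
})

test_that("prototype fitting is deterministic under a fixed seed", {
  sim <- small_sim(seed = 21, n_trials = 1, trial_s = 3)
  maps <- t(sim$recording$data[, find_gfp_peaks(compute_gfp(sim$recording$data,
                                                            256), 10, 256)])
  f1 <- fit_prototypes(maps, 4, "kmeans", n_init = 4, seed = 9)
  f2 <- fit_prototypes(maps, 4, "kmeans", n_init = 4, seed = 9)
  expect_identical(f1$maps, f2$maps)
})

test_that("backfit labels by absolute correlation with polarity and ties", {
  tpl <- make_templates(3, 8, seed = 10)
  proto <- fit_prototypes(tpl * 5, 3, "kmeans", n_init = 2, seed = 1)
  # align prototype indices to templates
  ord <- apply(abs(proto$maps %*% t(tpl)), 2, which.max)
  x <- t(rbind(tpl[2, ], -tpl[2, ]))
  seg <- backfit(x, proto)
  expect_equal(seg$labels, rep(ord[2], 2))
  expect_equal(seg$polarity[1], -seg$polarity[2])
  # global sign flip: labels unchanged, polarities negated
  sim <- small_sim(seed = 30, n_trials = 1, trial_s = 2)
  pk <- find_gfp_peaks(compute_gfp(sim$recording$data, 256), 10, 256)
  pr <- fit_prototypes(t(sim$recording$data[, pk]), 4, seed = 2)
  s1 <- backfit(sim$recording$data, pr)
  s2 <- backfit(-sim$recording$data, pr)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$polarity, -s2$polarity)
  # zero-variance sample inherits the previous label
  y <- t(rbind(tpl[1, ], c(1, rep(0, 7)) * 0))
  expect_warning(s3 <- backfit(y, proto), "zero-variance")
  expect_equal(s3$labels[2], s3$labels[1])
})

test_that("GEV matches a direct summation oracle and its bounds", {
  sim <- small_sim(seed = 14, n_trials = 1, trial_s = 2, n_channels = 8)
  x <- sim$recording$data[, 1:50]
  pk <- find_gfp_peaks(compute_gfp(sim$recording$data, 256), 10, 256)
  proto <- fit_prototypes(t(sim$recording$data[, pk]), 4, seed = 5)
  seg <- backfit(x, proto)
  expect_equal(compute_gev(x, proto, seg),
               naive_gev(x, proto$maps, seg$labels), tolerance = 1e-12)
  # exact scaled copies of prototypes -> GEV 1
  idx <- c(1, 3, 2, 4, 1)
  xc <- t(proto$maps[idx, ] * c(2, 1, 0.5, 3, 1))
  segc <- backfit(xc, proto)
  expect_equal(compute_gev(xc, proto, segc), 1, tolerance = 1e-9)
  # orthogonal assignment -> GEV 0 (templates zero-mean so centering is a
  # no-op and orthogonality is exact in correlation space)
  h <- stats::contr.helmert(8)
  tpl <- t(h[, 1:4]) / sqrt(colSums(h[, 1:4]^2))
  protoT <- fit_prototypes(tpl, 4, seed = 1)
  ord <- apply(abs(protoT$maps %*% t(tpl)), 2, which.max)
  xo <- t(tpl[c(1, 2), ])
  sego <- structure(list(labels = ord[c(2, 1)], polarity = c(1L, 1L),
                         K = 4, sfreq = 256),
                    class = "microstate_segmentation")
  gev_orth <- compute_gev(xo, protoT, sego)
  expect_lt(gev_orth, 1e-9)
  seg0 <- structure(list(labels = rep(1L, 4), polarity = rep(1L, 4),
                         K = 4, sfreq = 256),
                    class = "microstate_segmentation")
  expect_error(compute_gev(matrix(0, 8, 4), protoT, seg0), "all-zero")
})

test_that("microstate parameters follow run-length arithmetic", {
  mk_seg <- function(labels, K, sfreq) {
    structure(list(labels = labels, polarity = rep(1L, length(labels)),
                   K = K, sfreq = sfreq), class = "microstate_segmentation")
  }
  gfp10 <- structure(list(values = rep(2, 10), sfreq = 10), class = "gfp_series")
  mf <- microstate_features(mk_seg(rep(c(1L, 2L), each = 5), 2, 10), gfp10)
  expect_equal(mf$coverage, c(0.5, 0.5))
  expect_equal(mf$occurrence, c(1, 1))
  expect_equal(mf$duration_ms, c(500, 500))
  expect_equal(mf$mean_gfp, c(2, 2))
  mf2 <- microstate_features(mk_seg(rep(c(1L, 2L), 5), 2, 10), gfp10)
  expect_equal(mf2$occurrence[1], 5)
  expect_equal(mf2$duration_ms[1], 100)
  expect_equal(mf2$coverage[1], 0.5)
  # absent state rows are zero and coverages always sum to 1
  mf3 <- microstate_features(mk_seg(rep(1L, 10), 3, 10), gfp10)
  expect_equal(mf3$coverage, c(1, 0, 0))
  expect_equal(mf3$occurrence[2:3], c(0, 0))
  # property: coverage == occurrence * duration / 1000 for interior states
  set.seed(15)
  for (rep_i in 1:5) {
    labels <- rep(sample(1:3, 20, replace = TRUE), times = sample(1:6, 20, TRUE))
    gfp <- structure(list(values = runif(length(labels)), sfreq = 50),
                     class = "gfp_series")
    mf4 <- microstate_features(mk_seg(labels, 3, 50), gfp)
    expect_equal(sum(mf4$coverage), 1, tolerance = 1e-9)
    expect_equal(mf4$coverage,
                 mf4$occurrence * mf4$duration_ms / 1000, tolerance = 1e-9)
  }
})

test_that("the state-count scan peaks at the planted K and is monotone", {
  sim <- small_sim(seed = 17, snr = 20, n_trials = 2, trial_s = 4)
  tab <- scan_n_states(sim$recording$data, K_range = 2:6,
                       methods = "kmeans", n_rerun = 3, sfreq = 256, seed = 1)
  expect_equal(nrow(tab), 5)
  g <- tab$gev
  expect_true(all(diff(g) >= -1e-9))           # non-decreasing in K
  # elbow: the incremental gain collapses right after the planted K = 4
  gains <- diff(g)                             # gain arriving at K = 3..6
  drops <- gains[-length(gains)] - gains[-1]   # collapse after K = 3..5
  expect_equal(tab$K[which.max(drops) + 1], 4)
  expect_gte(g[tab$K == 4], 0.95)
  # single-cell scan
  tab1 <- scan_n_states(sim$recording$data[, 1:512], K_range = 2,
                        methods = "pca", n_rerun = 1, sfreq = 256, seed = 1)
  expect_equal(dim(tab1), c(1L, 3L))
})
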