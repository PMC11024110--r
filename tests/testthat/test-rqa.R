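test_that("time-delay embedding follows the length formula", {
  expect_equal(as.vector(embed_series(c(3, 1, 4, 1, 5), 1, 1)), c(3, 1, 4, 1, 5))
  expect_equal(embed_series(1:4, 2, 1),
               matrix(c(1, 2, 3, 2, 3, 4), 3))
  expect_equal(nrow(embed_series(1:10, 3, 2)), 6)
  expect_error(embed_series(1:3, 4, 1), "too short")
})

test_that("recurrence matrices match the definition on fixtures", {
  cfg <- embedding_config(epsilon = 0.1)
  rp <- recurrence_matrix(rep(5, 4), cfg)
  expect_equal(rp$matrix, matrix(1L, 4, 4))
  rp2 <- recurrence_matrix(c(0, 10, 0, 10), embedding_config(epsilon = 1))
  par <- outer(1:4, 1:4, function(i, j) as.integer((i - j) %% 2 == 0))
  expect_equal(rp2$matrix, par)
  expect_equal(mean(rp2$matrix), 0.5)
  expect_true(isSymmetric(rp2$matrix))
  expect_true(all(diag(rp2$matrix) == 1))
  # seeded random series against the double-loop oracle
  set.seed(20)
  for (m in c(1, 2, 3)) {
    s <- rnorm(30)
    eps <- 0.5
    rp3 <- recurrence_matrix(s, embedding_config(m = m, tau = 2, epsilon = eps))
    expect_identical(rp3$matrix, naive_rp(s, m, 2, eps))
  }
  expect_error(embedding_config(epsilon = -1), "positive")
})

test_that("line histograms agree with explicit walks", {
  # all-ones 10x10, LOI-only exclusion: two diagonals of each length 1..9
  rp <- recurrence_matrix(rep(1, 10), embedding_config(epsilon = 0.5, theiler = 0))
  h <- diagonal_histogram(rp)
  expect_equal(h, stats::setNames(rep(2L, 9), as.character(1:9)))
  # parity series: two maximal off-LOI diagonals of length 2 (theiler 1)
  rp2 <- recurrence_matrix(c(0, 10, 0, 10), embedding_config(epsilon = 1))
  h2 <- diagonal_histogram(rp2)
  expect_equal(h2, stats::setNames(2L, "2"))
  # verticals: all-ones 4x4 -> four lines of 4; identity -> four lines of 1
  rp3 <- recurrence_matrix(rep(2, 4), embedding_config(epsilon = 0.5))
  expect_equal(vertical_histogram(rp3), stats::setNames(4L, "4"))
  rp_id <- rp3; rp_id$matrix <- diag(4L); rp_id$n_points <- 4L
  expect_equal(vertical_histogram(rp_id), stats::setNames(4L, "1"))
  # recurrence times: period-2 series -> all gaps 2; constant -> none
  rp4 <- recurrence_matrix(rep(c(0, 10), 3), embedding_config(epsilon = 1))
  t4 <- recurrence_times(rp4)
  expect_equal(names(t4), "2")
  expect_length(recurrence_times(rp3), 0)
  # seeded random plots against the walking oracles
  set.seed(21)
  for (i in 1:5) {
    s <- rnorm(25)
    rp5 <- recurrence_matrix(s, embedding_config(epsilon = 0.8, theiler = 1))
    expect_equal(sort(rep(as.integer(names(diagonal_histogram(rp5))),
                          diagonal_histogram(rp5))),
                 sort(naive_diag_hist(rp5$matrix, 1)))
    expect_equal(sort(rep(as.integer(names(vertical_histogram(rp5))),
                          vertical_histogram(rp5))),
                 sort(naive_vert_hist(rp5$matrix)))
    expect_equal(sort(rep(as.integer(names(recurrence_times(rp5))),
                          recurrence_times(rp5))),
                 sort(naive_rec_times(rp5$matrix)))
  }
})

test_that("the eight features match the brute-force oracle exactly", {
  # hand-derived fixtures first
  f <- rqa_of_series(c(0, 10, 0, 10), embedding_config(epsilon = 1))
  expect_equal(f$rr, 0.5)
  expect_equal(f$det, 1)
  expect_equal(f$l_max, 2)
  expect_equal(f$entr, 0)
  fc <- rqa_of_series(rep(7, 10), embedding_config(epsilon = 0.1, theiler = 0))
  expect_equal(fc$rr, 1)
  expect_equal(fc$v_max, 10)
  expect_equal(fc$tt, 10)
  expect_equal(fc$l_max, 9)
  expect_equal(fc$rpde, 0)
  # long period-2 series: a single recurrence time, zero entropy
  fp <- rqa_of_series(rep(c(0, 10), 20), embedding_config(epsilon = 1))
  expect_equal(fp$rpde, 0)
  # 100 seeded random series, exact agreement on every feature
  set.seed(22)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    s <- rnorm(n)
    m <- sample(1:2, 1)
    eps <- runif(1, 0.3, 1.5)
    th <- sample(0:1, 1)
    cfg <- embedding_config(m = m, tau = 1, epsilon = eps, theiler = th)
    got <- as.numeric(rqa_of_series(s, cfg))
    want <- unname(naive_rqa(s, m, 1, eps, th, 2, 2))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("histogram sums account for every recurrence point", {
  set.seed(23)
  for (i in 1:10) {
    s <- rnorm(30)
    cfg <- embedding_config(epsilon = 0.7, theiler = 1)
    rp <- recurrence_matrix(s, cfg)
    dh <- diagonal_histogram(rp)
    vh <- vertical_histogram(rp)
    n <- rp$n_points
    off_band <- sum(rp$matrix[abs(row(rp$matrix) - col(rp$matrix)) > 1])
    expect_equal(sum(as.integer(names(dh)) * dh), off_band)
    expect_equal(sum(as.integer(names(vh)) * vh), sum(rp$matrix))
  }
})

test_that("recurrence rate is monotone in epsilon and scale-invariant", {
  set.seed(24)
  s <- rnorm(40)
  rr <- sapply(c(0.2, 0.5, 1, 2, 4), function(e)
    mean(recurrence_matrix(s, embedding_config(epsilon = e))$matrix))
  expect_true(all(diff(rr) >= 0))
  expect_true(all(rr >= 0 & rr <= 1))
  # scaling series and epsilon together leaves the plot unchanged
  r1 <- recurrence_matrix(s, embedding_config(epsilon = 0.8))
  r2 <- recurrence_matrix(5 * s, embedding_config(epsilon = 4))
  expect_identical(r1$matrix, r2$matrix)
})

test_that("automatic thresholds hit their targets", {
  set.seed(25)
  s <- rnorm(50)
  traj <- embed_series(s, 1, 1)
  # target_rr 1 -> the maximal pairwise distance
  expect_equal(auto_epsilon(traj, "target_rr", 1),
               max(abs(outer(s, s, "-"))))
  # std fraction
  s2 <- s * 2 / sd(s)
  expect_equal(auto_epsilon(embed_series(s2, 1, 1), "std_fraction", 0.2), 0.4)
  expect_error(auto_epsilon(embed_series(rep(1, 10), 1, 1), "std_fraction", 0.2),
               "zero-variance")
  # achieved RR within one matrix cell of the request
  eps <- auto_epsilon(traj, "target_rr", 0.1)
  rr <- mean(recurrence_matrix(s, embedding_config(epsilon = eps))$matrix)
  expect_lte(abs(rr - 0.1), 2 / 50^2 + 1e-12)  # symmetric twin can tie
  expect_gte(rr, 0.1)
  # smallest such epsilon: nudging it down misses the target
  rr_down <- mean(recurrence_matrix(s, embedding_config(epsilon = eps * (1 - 1e-9)))$matrix)
  expect_lt(rr_down, 0.1)
})

test_that("very long series are decimated to the configured cap", {
  s <- sin(seq(0, 100, length.out = 5000))
  rp <- recurrence_matrix(s, embedding_config(epsilon = 0.3, max_points = 500))
  expect_lte(rp$n_points, 500)
})
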