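#' Recurrence-analysis configuration
#'
#' Bundles the time-delay embedding and recurrence-thresholding parameters.
#' The distance is the Chebyshev (maximum) norm throughout. The threshold can
#' be fixed (`epsilon`) or derived per series: `"std_fraction"` (the default)
#' sets `epsilon = eps_value * sd(series)`, which normalises amplitude across
#' windows while leaving the recurrence rate free to vary — essential, since
#' RR itself is the pipeline's headline feature; `"target_rr"` picks the
#' smallest epsilon whose recurrence rate reaches `eps_value`, useful when
#' the *other* line-structure features should be compared at matched density
#' (note it pins RR to `eps_value` by construction).
#'
#' Line statistics use `l_min`/`v_min` = 2 and a Theiler exclusion of
#' `theiler` diagonals around the line of identity (LOI) for *diagonal*
#' statistics only; the recurrence rate and vertical statistics use the full
#' matrix including the LOI.
#'
#' @param m embedding dimension (>= 1).
#' @param tau embedding delay in samples (>= 1).
#' @param epsilon fixed recurrence threshold (series units), or `NULL` to use
#'   the strategy below.
#' @param eps_strategy `"target_rr"` or `"std_fraction"`.
#' @param eps_value fraction in (0, 1) interpreted per strategy.
#' @param theiler half-width of the diagonal band excluded from diagonal-line
#'   statistics (0 excludes the LOI only).
#' @param l_min,v_min minimal diagonal / vertical line lengths.
#' @param max_points series longer than this are decimated before the N x N
#'   matrix is built (bounds memory on very long windows).
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(m = 1, tau = 1, epsilon = NULL,
                             eps_strategy = c("std_fraction", "target_rr"),
                             eps_value = 0.2, theiler = 1,
                             l_min = 2, v_min = 2, max_points = 2048) {
  eps_strategy <- match.arg(eps_strategy)
  assert_that(m >= 1 && tau >= 1, "need m >= 1 and tau >= 1")
  assert_that(l_min >= 2 && v_min >= 2, "l_min and v_min must be >= 2")
  assert_that(theiler >= 0, "theiler must be >= 0")
  if (!is.null(epsilon)) assert_that(epsilon > 0, "epsilon must be positive")
  assert_that(eps_value > 0 && eps_value < 1, "eps_value must be in (0, 1)")
  structure(list(m = as.integer(m), tau = as.integer(tau), epsilon = epsilon,
                 eps_strategy = eps_strategy, eps_value = eps_value,
                 norm = "chebyshev", theiler = as.integer(theiler),
                 l_min = as.integer(l_min), v_min = as.integer(v_min),
                 max_points = as.integer(max_points)),
            class = "embedding_config")
}

#' Time-delay embedding
#'
#' Builds the `N = length(series) - (m-1) tau` phase-space points
#' `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`.
#'
#' @param series numeric vector.
#' @param m embedding dimension.
#' @param tau delay in samples.
#' @return An `N x m` matrix (for `m = 1`, a one-column matrix equal to the
#'   series).
#' @export
embed_series <- function(series, m = 1, tau = 1) {
  series <- as.numeric(series)
  n <- length(series) - (m - 1) * tau
  assert_that(n >= 1, "series too short for this embedding")
  sapply(seq_len(m), function(j) series[seq_len(n) + (j - 1) * tau]) |>
    matrix(nrow = n)
}

chebyshev_distances <- function(traj) {
  n <- nrow(traj)
  D <- matrix(0, n, n)
  for (j in seq_len(ncol(traj))) {
    D <- pmax(D, abs(outer(traj[, j], traj[, j], "-")))
  }
  D
}

#' Choose a recurrence threshold
#'
#' `"target_rr"`: the smallest epsilon whose recurrence rate (full matrix,
#' LOI included, boundary `distance == epsilon` recurrent) is at least
#' `value` — computed exactly as an order statistic of the pairwise
#' distances. `"std_fraction"`: `value * sd(series)` (sample sd); errors on
#' zero-variance input.
#'
#' @param traj an [embed_series()] trajectory (or numeric vector, embedded
#'   as-is with m = 1).
#' @param strategy `"target_rr"` or `"std_fraction"`.
#' @param value fraction in (0, 1); `value = 1` is allowed for `"target_rr"`
#'   and returns the maximal pairwise distance.
#' @return The threshold epsilon.
#' @export
auto_epsilon <- function(traj, strategy = c("target_rr", "std_fraction"),
                         value = 0.1) {
  strategy <- match.arg(strategy)
  if (!is.matrix(traj)) traj <- matrix(as.numeric(traj), ncol = 1)
  assert_that(value > 0 && value <= 1, "value must be in (0, 1]")
  if (strategy == "std_fraction") {
    s <- stats::sd(traj[, 1])
    assert_that(s > 0, "zero-variance series: std_fraction threshold undefined")
    return(value * s)
  }
  d <- sort(as.vector(chebyshev_distances(traj)))
  eps <- d[min(length(d), ceiling(value * length(d)))]
  # a zero-distance quantile (ties / constant series) still thresholds validly
  if (eps <= 0) eps <- .Machine$double.eps
  eps
}

#' Recurrence plot of a trajectory
#'
#' `R_ij = 1` iff the Chebyshev distance between phase-space points i and j is
#' at most epsilon (Heaviside convention: distance exactly epsilon counts).
#' The matrix is symmetric with an all-ones main diagonal.
#'
#' @param x numeric series or an already-embedded trajectory matrix.
#' @param config an [embedding_config()].
#' @return A `recurrence_plot`: `matrix` (N x N, 0/1), `config` (with the
#'   resolved `epsilon`), `n_points`.
#' @export
recurrence_matrix <- function(x, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  if (!is.matrix(x)) {
    x <- as.numeric(x)
    if (length(x) > config$max_points) {
      step <- ceiling(length(x) / config$max_points)
      x <- x[seq(1, length(x), by = step)]
    }
    traj <- embed_series(x, config$m, config$tau)
  } else traj <- x
  assert_that(nrow(traj) >= 2, "need at least 2 phase-space points")
  eps <- config$epsilon %||%
    auto_epsilon(traj, config$eps_strategy, config$eps_value)
  assert_that(eps > 0, "epsilon must be positive")
  D <- chebyshev_distances(traj)
  R <- (D <= eps) * 1L
  config$epsilon <- eps
  structure(list(matrix = R, config = config, n_points = nrow(R)),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence_plot> %d x %d, RR = %.3f, eps = %.4g\n",
              x$n_points, x$n_points, mean(x$matrix), x$config$epsilon))
  invisible(x)
}

#' Histogram of maximal diagonal line lengths
#'
#' Counts maximal runs of recurrences along every diagonal with
#' `|i - j| > theiler` (LOI and Theiler band excluded); upper and lower
#' triangles both counted.
#'
#' @param rp a [recurrence_matrix()] result.
#' @return Named integer vector: `P[l]` = number of maximal diagonal lines of
#'   length l (empty when there are none).
#' @export
diagonal_histogram <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  n <- rp$n_points
  lens <- integer()
  for (d in seq_len(n - 1)) {
    if (d <= rp$config$theiler) next
    diag_vals <- rp$matrix[cbind(seq_len(n - d), seq_len(n - d) + d)]
    r <- rle(diag_vals)
    lens <- c(lens, rep(r$lengths[r$values == 1], 2L))  # symmetric: both triangles
  }
  if (!length(lens)) return(integer())
  tab <- table(lens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Histogram of maximal vertical line lengths
#'
#' Maximal vertical runs of recurrences per column over the full matrix (LOI
#' included — the standard laminarity convention).
#'
#' @param rp a [recurrence_matrix()] result.
#' @return Named integer vector `P[v]`.
#' @export
vertical_histogram <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  lens <- integer()
  for (j in seq_len(rp$n_points)) {
    r <- rle(rp$matrix[, j])
    lens <- c(lens, r$lengths[r$values == 1])
  }
  if (!length(lens)) return(integer())
  tab <- table(lens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Histogram of recurrence times
#'
#' Per column, consecutive recurrences are collapsed to the first sample of
#' each run (type-II recurrence times); the recurrence times are the gaps
#' between successive run starts, pooled over all columns.
#'
#' @param rp a [recurrence_matrix()] result.
#' @return Named integer vector `P[t]` (empty for e.g. a constant series,
#'   whose single run per column leaves no gaps).
#' @export
recurrence_times <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  gaps <- integer()
  for (j in seq_len(rp$n_points)) {
    rows <- which(rp$matrix[, j] == 1)
    if (length(rows) < 2) next
    starts <- rows[c(TRUE, diff(rows) > 1)]
    if (length(starts) >= 2) gaps <- c(gaps, diff(starts))
  }
  if (!length(gaps)) return(integer())
  tab <- table(gaps)
  stats::setNames(as.integer(tab), names(tab))
}

hist_levels <- function(h) as.integer(names(h))

#' The eight recurrence quantification features
#'
#' From a recurrence plot: `rr` — recurrence rate, the fraction of recurrent
#' cells over the full N^2 matrix (LOI included); `det` — determinism, the
#' fraction of off-LOI recurrence points on diagonal lines of length >=
#' `l_min`; `l_mean`, `l_max` — mean (over lines >= `l_min`) and maximal
#' diagonal line length; `entr` — Shannon entropy (nats) of the diagonal
#' line-length distribution restricted to lengths >= `l_min`; `tt` — trapping
#' time, the mean vertical line length over lines >= `v_min`; `v_max` —
#' maximal vertical line length; `rpde` — recurrence-time entropy normalised
#' by `ln(T_max)`, in [0, 1].
#'
#' Degenerate cases return 0: no diagonal lines >= `l_min` gives `det`,
#' `l_mean`, `entr` = 0; no verticals >= `v_min` gives `tt` = 0; an empty
#' recurrence-time histogram or `T_max <= 1` gives `rpde` = 0.
#'
#' @param rp a [recurrence_matrix()] result.
#' @return A one-row tibble with columns `rr`, `det`, `l_mean`, `l_max`,
#'   `entr`, `tt`, `v_max`, `rpde`.
#' @export
rqa_features <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  cfg <- rp$config
  n <- rp$n_points
  rr <- sum(rp$matrix) / n^2

  Pl <- diagonal_histogram(rp)
  l <- hist_levels(Pl)
  tot_pts <- sum(l * Pl)
  sel <- l >= cfg$l_min
  det <- if (tot_pts > 0 && any(sel)) sum(l[sel] * Pl[sel]) / tot_pts else 0
  l_max <- if (length(l)) max(l) else 0
  l_mean <- if (any(sel)) sum(l[sel] * Pl[sel]) / sum(Pl[sel]) else 0
  entr <- if (any(sel)) {
    p <- Pl[sel] / sum(Pl[sel])
    -sum(p * log(p))
  } else 0

  Pv <- vertical_histogram(rp)
  v <- hist_levels(Pv)
  selv <- v >= cfg$v_min
  tt <- if (any(selv)) sum(v[selv] * Pv[selv]) / sum(Pv[selv]) else 0
  v_max <- if (length(v)) max(v) else 0

  Pt <- recurrence_times(rp)
  tvals <- hist_levels(Pt)
  t_max <- if (length(tvals)) max(tvals) else 0
  rpde <- if (t_max > 1) {
    p <- Pt / sum(Pt)
    h <- -sum(p * log(p))
    h / log(t_max)
  } else 0

  tibble(rr = rr, det = det, l_mean = l_mean, l_max = as.numeric(l_max),
         entr = entr, tt = tt, v_max = as.numeric(v_max), rpde = rpde)
}

#' RQA features straight from a scalar series
#'
#' Convenience wrapper: embed, threshold, and quantify in one call.
#'
#' @param series numeric vector.
#' @param config an [embedding_config()].
#' @return A one-row tibble as [rqa_features()].
#' @export
rqa_of_series <- function(series, config = embedding_config()) {
  rqa_features(recurrence_matrix(series, config))
}
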