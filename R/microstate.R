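#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp potential across the
#' N electrodes at each sample: `sqrt(sum_i (x_i(t) - xbar(t))^2 / N)`
#' (population form, divide by N). Peaks of GFP mark moments of strong, stable
#' topography and anchor the microstate analysis.
#'
#' @param x numeric matrix, channels x samples (at least 2 channels).
#' @param sfreq sampling rate (Hz); taken from `attr(x, "sfreq")` if absent.
#' @return A `gfp_series`: list with `values` (nonnegative, per sample) and
#'   `sfreq`.
#' @export
compute_gfp <- function(x, sfreq = NULL) {
  assert_that(is.matrix(x) && nrow(x) >= 2,
              "GFP needs a channels x samples matrix with >= 2 channels")
  sfreq <- sfreq %||% attr(x, "sfreq")
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  v[v < 0] <- 0   # guard fp round-off
  structure(list(values = sqrt(v), sfreq = sfreq), class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples%s, mean %.3g uV\n", length(x$values),
              if (!is.null(x$sfreq)) sprintf(" @ %g Hz", x$sfreq) else "",
              mean(x$values)))
  invisible(x)
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP series, thinned so that surviving peaks are
#' at least `min_distance_ms` apart (higher peaks win). Endpoints are never
#' peaks.
#'
#' @param gfp a [compute_gfp()] result, or a numeric vector.
#' @param min_distance_ms minimum spacing between returned peaks (ms).
#' @param sfreq required if `gfp` is a bare vector without a rate.
#' @return Integer sample indices (1-based), sorted; possibly empty.
#' @export
find_gfp_peaks <- function(gfp, min_distance_ms = 10, sfreq = NULL) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  sfreq <- sfreq %||% (if (inherits(gfp, "gfp_series")) gfp$sfreq else NULL)
  assert_that(length(v) >= 3, "series must have at least 3 samples")
  n <- length(v)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (!length(cand)) return(integer())
  min_dist <- if (is.null(sfreq)) 1L else max(1L, floor(min_distance_ms * sfreq / 1000))
  if (min_dist > 1L) {
    keep <- logical(length(cand))
    taken <- integer()
    for (i in order(v[cand], decreasing = TRUE)) {
      if (!length(taken) || all(abs(cand[i] - taken) >= min_dist)) {
        keep[i] <- TRUE
        taken <- c(taken, cand[i])
      }
    }
    cand <- sort(cand[keep])
  }
  cand
}

# center rows across channels; returns list(maps, gfp, norms)
center_maps <- function(M) {
  Mc <- M - rowMeans(M)
  nrm <- sqrt(rowSums(Mc^2))
  list(maps = Mc, norms = nrm, gfp = nrm / sqrt(ncol(M)))
}

unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

# deterministic sign: largest-|.| element made positive
fix_sign <- function(M) {
  s <- apply(M, 1, function(r) sign(r[which.max(abs(r))]))
  s[s == 0] <- 1
  M * s
}

dominant_eigvec <- function(X, w = NULL) {
  # first eigenvector of sum_i w_i x_i x_i^T
  if (!is.null(w)) X <- X * sqrt(w)
  C <- crossprod(X)
  eigen(C, symmetric = TRUE)$vectors[, 1]
}

# GEV of an assignment over unit-norm centered maps U with gfp weights
peak_gev <- function(U, gfp, protos, assign) {
  corr <- rowSums(U * protos[assign, , drop = FALSE])
  per <- gfp^2 * corr^2
  tot <- sum(gfp^2)
  list(total = sum(per) / tot,
       per_state = vapply(seq_len(nrow(protos)),
                          function(k) sum(per[assign == k]) / tot, 0.0))
}

modified_kmeans_once <- function(U, gfp, K, max_iter, init = NULL) {
  n <- nrow(U)
  protos <- if (is.null(init)) U[sample.int(n, K), , drop = FALSE] else init
  protos <- unit_rows(protos)
  assign_prev <- rep(0L, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    S <- U %*% t(protos)
    a <- max.col(S^2, ties.method = "first")
    if (identical(a, assign_prev)) { converged <- TRUE; break }
    assign_prev <- a
    for (k in seq_len(K)) {
      idx <- which(a == k)
      if (!length(idx)) {      # dead cluster: grab the worst-explained map
        worst <- which.min(apply(S^2, 1, max))
        protos[k, ] <- U[worst, ]
      } else {
        protos[k, ] <- dominant_eigvec(U[idx, , drop = FALSE], gfp[idx]^2)
      }
    }
    protos <- unit_rows(protos)
  }
  S <- U %*% t(protos)
  a <- max.col(S^2, ties.method = "first")
  list(protos = protos, assign = a, converged = converged,
       gev = peak_gev(U, gfp, protos, a))
}

aahc_fit <- function(U, gfp, K) {
  n <- nrow(U)
  members <- as.list(seq_len(n))
  protos <- U
  w <- gfp^2
  repeat {
    if (length(members) <= K) break
    # per-cluster GEV contribution
    contrib <- vapply(seq_along(members), function(k) {
      idx <- members[[k]]
      cc <- U[idx, , drop = FALSE] %*% protos[k, ]
      sum(w[idx] * cc^2)
    }, 0.0)
    worst <- which.min(contrib)
    orphans <- members[[worst]]
    members[[worst]] <- NULL
    protos <- protos[-worst, , drop = FALSE]
    S <- U[orphans, , drop = FALSE] %*% t(protos)
    dest <- max.col(S^2, ties.method = "first")
    for (k in unique(dest)) {
      members[[k]] <- c(members[[k]], orphans[dest == k])
      protos[k, ] <- dominant_eigvec(U[members[[k]], , drop = FALSE],
                                     w[members[[k]]])
    }
    protos <- unit_rows(protos)
  }
  S <- U %*% t(protos)
  a <- max.col(S^2, ties.method = "first")
  list(protos = protos, assign = a)
}

sym_orth <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                   length(e$values)) %*% t(e$vectors)
  solve_sqrt %*% W
}

ica_prototypes <- function(X, K, max_iter = 200, tol = 1e-6) {
  # symmetric FastICA (tanh contrast) on the peak-map ensemble;
  # prototypes are the unit-normalised mixing columns
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  d <- pmax(ev$values[seq_len(K)], 1e-12)
  E <- ev$vectors[, seq_len(K), drop = FALSE]
  Z <- Xc %*% E %*% diag(1 / sqrt(d), K)          # n x K whitened
  W <- sym_orth(matrix(stats::rnorm(K * K), K))
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)
    G <- tanh(WX)
    W1 <- t(G) %*% Z / nrow(Z) - diag(colMeans(1 - G^2), K) %*% W
    W1 <- sym_orth(W1)
    if (max(abs(abs(rowSums(W1 * W)) - 1)) < tol) { W <- W1; break }
    W <- W1
  }
  A <- E %*% diag(sqrt(d), K) %*% t(W)            # C x K mixing
  unit_rows(t(A))
}

#' Fit microstate prototype topographies
#'
#' Clusters GFP-peak topographies into K unit-norm prototype maps. Maps are
#' mean-centered across channels and unit-normalised before clustering; all
#' methods are polarity-invariant (a map and its negation are the same state).
#'
#' Methods: `"kmeans"` — the modified (polarity-invariant) k-means maximising
#' the GFP^2-weighted squared spatial correlation, best of `n_init` restarts
#' by GEV; `"aahc"` — atomize-and-agglomerate hierarchical clustering down to
#' K; `"pca"` — the first K principal-component loadings of the peak maps;
#' `"ica"` — K FastICA mixing columns, unit-normalised.
#'
#' @param peak_maps numeric matrix, peaks x channels (raw topographies at GFP
#'   peaks).
#' @param K number of states (2..n_peaks; `K = 1` is allowed and returns the
#'   dominant eigenvector direction).
#' @param method `"kmeans"`, `"aahc"`, `"pca"` or `"ica"`.
#' @param n_init random restarts (kmeans).
#' @param max_iter iteration cap per restart.
#' @param seed RNG seed.
#' @param init_maps optional extra warm-start initialisation (rows = maps,
#'   fewer than K rows are topped up with the worst-explained peaks).
#' @return A `microstate_prototypes` object: `maps` (K x channels, unit norm),
#'   `method`, `gev_total`, `gev_per_state`, fitting metadata.
#' @export
fit_prototypes <- function(peak_maps, K, method = c("kmeans", "aahc", "pca", "ica"),
                           n_init = 10, max_iter = 100, seed = 1,
                           init_maps = NULL) {
  method <- match.arg(method)
  assert_that(is.matrix(peak_maps) && nrow(peak_maps) >= max(K, 1),
              "need at least K peak maps")
  assert_that(K >= 1, "K must be >= 1")
  cm <- center_maps(peak_maps)
  ok <- cm$norms > 0
  assert_that(any(ok), "all peak maps are flat")
  U <- unit_rows(cm$maps[ok, , drop = FALSE])
  gfp <- cm$gfp[ok]
  fit <- withr::with_seed(derive_seed(seed, paste0("proto-", method, K)), {
    switch(method,
      kmeans = {
        best <- NULL
        inits <- c(vector("list", n_init), if (!is.null(init_maps)) list(prep_init(init_maps, U, K)))
        for (i in seq_along(inits)) {
          f <- modified_kmeans_once(U, gfp, K, max_iter, init = inits[[i]])
          if (is.null(best) || f$gev$total > best$gev$total) best <- f
        }
        if (!best$converged) warn("modified k-means did not converge; best restart returned")
        best
      },
      aahc = aahc_fit(U, gfp, K),
      pca = {
        protos <- t(svd(U * gfp, nu = 0, nv = K)$v)   # GFP-weighted loadings
        list(protos = unit_rows(protos))
      },
      ica = list(protos = ica_prototypes(U * gfp, K))
    )
  })
  protos <- fix_sign(unit_rows(fit$protos))
  S <- U %*% t(protos)
  a <- max.col(S^2, ties.method = "first")
  g <- peak_gev(U, gfp, protos, a)
  structure(list(maps = protos, method = method, K = K,
                 gev_total = g$total, gev_per_state = g$per_state,
                 n_init = n_init, max_iter = max_iter, seed = seed),
            class = "microstate_prototypes")
}

prep_init <- function(init_maps, U, K) {
  init <- unit_rows(init_maps - rowMeans(init_maps))
  while (nrow(init) < K) {
    S <- U %*% t(init)
    worst <- which.min(apply(S^2, 1, max))
    init <- rbind(init, U[worst, ])
  }
  init[seq_len(K), , drop = FALSE]
}

#' @export
print.microstate_prototypes <- function(x, ...) {
  cat(sprintf("<microstate_prototypes> K = %d (%s), GEV = %.3f\n",
              x$K, x$method, x$gev_total))
  invisible(x)
}

# spatial Pearson correlations of every sample against every prototype
sample_map_corr <- function(x, maps) {
  Xc <- sweep(x, 2, colMeans(x))
  xn <- sqrt(colSums(Xc^2))
  Mc <- maps - rowMeans(maps)
  Mn <- Mc / sqrt(rowSums(Mc^2))
  corr <- (Mn %*% Xc) / rep(pmax(xn, .Machine$double.eps), each = nrow(maps))
  list(corr = corr, degenerate = xn == 0)
}

#' Backfit prototypes onto EEG samples
#'
#' Labels every sample with the prototype whose absolute spatial correlation
#' with the instantaneous topography is largest (polarity-invariant); the
#' polarity is the sign of the winning correlation. Ties go to the lowest
#' state index. Zero-variance samples inherit the previous sample's label
#' (state 1 at the start) with a warning.
#'
#' @param x channels x samples matrix.
#' @param prototypes a [fit_prototypes()] result.
#' @param sfreq sampling rate (Hz), optional metadata.
#' @param min_duration_ms optional temporal smoothing: maximal runs shorter
#'   than this are reassigned to the neighbouring state with the higher
#'   correlation. Off (`0`) by default.
#' @return A `microstate_segmentation`: `labels` (1..K per sample),
#'   `polarity` (-1/+1), `K`, `sfreq`.
#' @export
backfit <- function(x, prototypes, sfreq = NULL, min_duration_ms = 0) {
  stopifnot(inherits(prototypes, "microstate_prototypes"))
  assert_that(ncol(prototypes$maps) == nrow(x),
              "prototypes and data disagree on channel count")
  sm <- sample_map_corr(x, prototypes$maps)
  labels <- max.col(t(sm$corr^2), ties.method = "first")
  pol <- ifelse(sm$corr[cbind(labels, seq_along(labels))] >= 0, 1L, -1L)
  if (any(sm$degenerate)) {
    warn(sprintf("%d zero-variance sample(s) inherit neighbouring label",
                 sum(sm$degenerate)))
    for (t in which(sm$degenerate)) {
      labels[t] <- if (t == 1L) 1L else labels[t - 1L]
      pol[t] <- 1L
    }
  }
  if (min_duration_ms > 0 && !is.null(sfreq)) {
    min_len <- max(1L, floor(min_duration_ms * sfreq / 1000))
    labels <- smooth_short_runs(labels, sm$corr, min_len)
  }
  structure(list(labels = labels, polarity = pol, K = prototypes$K,
                 sfreq = sfreq), class = "microstate_segmentation")
}

smooth_short_runs <- function(labels, corr, min_len) {
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < min_len)
    if (!length(short)) break
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    i <- short[which.min(r$lengths[short])]
    idx <- starts[i]:ends[i]
    cand <- unique(c(if (i > 1) r$values[i - 1], if (i < length(r$values)) r$values[i + 1]))
    if (!length(cand)) break
    sc <- vapply(cand, function(k) mean(corr[k, idx]^2), 0.0)
    labels[idx] <- cand[which.max(sc)]
  }
  labels
}

#' @export
print.microstate_segmentation <- function(x, ...) {
  cat(sprintf("<microstate_segmentation> %d samples, K = %d\n",
              length(x$labels), x$K))
  invisible(x)
}

#' Global explained variance of a segmentation
#'
#' `GEV = sum_t GFP(t)^2 corr^2(x(t), map_label(t)) / sum_t GFP(t)^2` with
#' `corr` the spatial Pearson correlation — the fraction of GFP-weighted
#' topographic variance the assigned prototypes explain, in `[0, 1]`.
#'
#' @param x channels x samples matrix.
#' @param prototypes a [fit_prototypes()] result.
#' @param seg a [backfit()] segmentation covering all samples.
#' @return GEV fraction.
#' @export
compute_gev <- function(x, prototypes, seg) {
  stopifnot(inherits(seg, "microstate_segmentation"))
  assert_that(length(seg$labels) == ncol(x),
              "segmentation does not cover all samples")
  gfp <- compute_gfp(x)$values
  denom <- sum(gfp^2)
  assert_that(denom > 0, "all-zero window: GEV undefined")
  sm <- sample_map_corr(x, prototypes$maps)
  cc <- sm$corr[cbind(seg$labels, seq_along(seg$labels))]
  cc[sm$degenerate] <- 0
  sum(gfp^2 * cc^2) / denom
}

#' Microstate parameters of a segmentation
#'
#' Per state: `mean_gfp` — mean GFP over the state's samples (microvolts);
#' `occurrence` — maximal runs of the state per second (1/s); `duration_ms` —
#' mean run length (ms); `coverage` — fraction of samples in the state.
#' States absent from the window get 0 throughout. Coverages sum to 1.
#'
#' @param seg a [backfit()] segmentation.
#' @param gfp the matching [compute_gfp()] series.
#' @return A tibble with columns `state`, `mean_gfp`, `occurrence`,
#'   `duration_ms`, `coverage`.
#' @export
microstate_features <- function(seg, gfp) {
  stopifnot(inherits(seg, "microstate_segmentation"))
  v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  assert_that(length(v) == length(seg$labels), "seg and gfp are not aligned")
  sfreq <- seg$sfreq %||% (if (inherits(gfp, "gfp_series")) gfp$sfreq else NULL)
  assert_that(!is.null(sfreq), "a sampling rate is required (seg$sfreq or gfp$sfreq)")
  n <- length(seg$labels)
  secs <- n / sfreq
  r <- rle(seg$labels)
  out <- map(seq_len(seg$K), function(k) {
    runs <- r$lengths[r$values == k]
    if (!length(runs)) {
      tibble(state = k, mean_gfp = 0, occurrence = 0, duration_ms = 0, coverage = 0)
    } else {
      tibble(state = k,
             mean_gfp = mean(v[seg$labels == k]),
             occurrence = length(runs) / secs,
             duration_ms = mean(runs) * 1000 / sfreq,
             coverage = sum(runs) / n)
    }
  })
  bind_rows(out)
}

#' Scan the number of microstates
#'
#' Fits prototypes for every `(method, K)` cell, keeping the best of
#' `n_rerun` re-runs by GEV, and reports the GEV surface plus the best K per
#' method. GEV is evaluated on the GFP-peak topographies (`on = "peaks"`,
#' the model-selection convention; the k-means route then uses the previous
#' K's maps as a warm start, making GEV non-decreasing in K) or on the full
#' data via backfitting (`on = "data"`).
#'
#' @param x channels x samples matrix.
#' @param K_range candidate state counts (2..10 by default).
#' @param methods subset of `c("kmeans", "aahc", "pca", "ica")`.
#' @param n_rerun re-runs per cell; the maximum GEV is kept.
#' @param on `"peaks"` or `"data"`.
#' @param sfreq sampling rate for peak picking (optional).
#' @param seed RNG seed.
#' @return A tibble `method`, `K`, `gev`, with `attr(, "best_k")` naming the
#'   argmax-K per method.
#' @export
scan_n_states <- function(x, K_range = 2:10, methods = "kmeans", n_rerun = 10,
                          on = c("peaks", "data"), sfreq = NULL, seed = 1) {
  on <- match.arg(on)
  gfp <- compute_gfp(x, sfreq)
  peaks <- find_gfp_peaks(gfp, min_distance_ms = 0, sfreq = sfreq)
  assert_that(length(peaks) >= max(K_range),
              "fewer GFP peaks than the largest K requested")
  pk <- t(x[, peaks, drop = FALSE])
  rows <- list()
  for (m in methods) {
    prev <- NULL
    for (K in sort(K_range)) {
      best <- NULL
      for (r in seq_len(n_rerun)) {
        f <- fit_prototypes(pk, K, method = m, n_init = 1,
                            seed = derive_seed(seed, paste(m, K, r)),
                            init_maps = if (m == "kmeans") prev else NULL)
        g <- if (on == "peaks") f$gev_total else
          compute_gev(x, f, backfit(x, f, sfreq = sfreq))
        if (is.null(best) || g > best$g) best <- list(g = g, f = f)
      }
      prev <- best$f$maps
      rows[[length(rows) + 1L]] <- tibble(method = m, K = K, gev = best$g)
    }
  }
  out <- bind_rows(rows)
  best_k <- out |> group_by(.data$method) |>
    summarise(best_K = .data$K[which.max(.data$gev)], .groups = "drop")
  attr(out, "best_k") <- best_k
  out
}

#' @importFrom rlang .data
NULL
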