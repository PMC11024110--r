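#' Scalar series of a microstate parameter within a window
#'
#' Produces the scalar time series that recurrence analysis is applied to.
#' `"mean_gfp"` returns a single series: the raw GFP(t) sequence of the
#' window. `"occurrence"`, `"duration"` and `"coverage"` return one series
#' per state, the parameter recomputed on consecutive non-overlapping
#' sub-windows of `subwindow_s` seconds.
#'
#' @param window channels x samples matrix.
#' @param prototypes a [fit_prototypes()] result.
#' @param param `"mean_gfp"`, `"occurrence"`, `"duration"` or `"coverage"`.
#' @param subwindow_s sub-window length (s) for the per-state parameters.
#' @param sfreq sampling rate (Hz).
#' @return A named list of numeric series: `gfp` for `"mean_gfp"`, otherwise
#'   `"<param>[k]"` per state k.
#' @export
ms_parameter_series <- function(window, prototypes, param = c("mean_gfp",
                                "occurrence", "duration", "coverage"),
                                subwindow_s = 0.25, sfreq) {
  param <- match.arg(param)
  gfp <- compute_gfp(window, sfreq)
  if (param == "mean_gfp") return(list(gfp = gfp$values))
  sub <- as.integer(round(subwindow_s * sfreq))
  assert_that(sub >= 2, "sub-window must span at least 2 samples")
  n_sub <- ncol(window) %/% sub
  assert_that(n_sub >= 4,
              "fewer than 4 sub-windows: series too short for recurrence analysis")
  seg <- backfit(window, prototypes, sfreq = sfreq)
  col <- switch(param, occurrence = "occurrence", duration = "duration_ms",
                coverage = "coverage")
  series <- matrix(0, n_sub, prototypes$K)
  for (i in seq_len(n_sub)) {
    idx <- seq.int((i - 1L) * sub + 1L, i * sub)
    sub_seg <- structure(list(labels = seg$labels[idx],
                              polarity = seg$polarity[idx],
                              K = seg$K, sfreq = sfreq),
                         class = "microstate_segmentation")
    mf <- microstate_features(sub_seg, gfp$values[idx])
    series[i, ] <- mf[[col]]
  }
  stats::setNames(lapply(seq_len(prototypes$K), function(k) series[, k]),
                  sprintf("%s[%d]", param, seq_len(prototypes$K)))
}

window_sfreq <- function(windows) {
  sf <- attr(windows, "sfreq")
  assert_that(!is.null(sf), "windows tibble lacks its sfreq attribute")
  sf
}

#' Assemble the per-window feature table
#'
#' Three modes. `"ms_only"`: the four microstate parameters for each of the K
#' states (4K columns, e.g. `occurrence[2]`). `"rqa_only"`: the eight
#' recurrence features of the window's GFP series (`rr(gfp)` ...).
#' `"multivariate"`: the eight recurrence features applied to every
#' microstate parameter series — the GFP series plus occurrence, duration and
#' coverage per state — giving `8 x (1 + 3K)` columns such as
#' `rr(gfp)` (the pipeline's optimal feature) and `rpde(coverage[2])`.
#'
#' Windows on which a feature is undefined are dropped with a warning, so the
#' returned table has no NA rows.
#'
#' @param windows a [segment_windows()] tibble.
#' @param prototypes a [fit_prototypes()] result.
#' @param mode `"ms_only"`, `"rqa_only"` or `"multivariate"`.
#' @param rqa_cfg an [embedding_config()] for the recurrence features.
#' @param subwindow_s sub-window (s) for per-state parameter series.
#' @param selection `"all"` or a character vector of feature columns to keep.
#' @return A feature tibble: `window_id`, `trial_id`, `label`, then feature
#'   columns; `attr(, "window_length_s")` records the window length.
#' @export
build_features <- function(windows, prototypes = NULL,
                           mode = c("multivariate", "ms_only", "rqa_only"),
                           rqa_cfg = embedding_config(),
                           subwindow_s = 0.25, selection = "all") {
  mode <- match.arg(mode)
  assert_that(nrow(windows) > 0, "no windows to featurise")
  sfreq <- window_sfreq(windows)
  if (mode != "rqa_only") {
    assert_that(inherits(prototypes, "microstate_prototypes"),
                "this mode needs fitted prototypes")
  }
  feat_row <- function(w) {
    x <- w$data[[1]]
    if (mode == "ms_only") {
      gfp <- compute_gfp(x, sfreq)
      seg <- backfit(x, prototypes, sfreq = sfreq)
      mf <- microstate_features(seg, gfp)
      vals <- c(mean_gfp = mf$mean_gfp, occurrence = mf$occurrence,
                duration = mf$duration_ms, coverage = mf$coverage)
      names(vals) <- sprintf("%s[%d]",
                             rep(c("mean_gfp", "occurrence", "duration", "coverage"),
                                 each = prototypes$K),
                             rep(seq_len(prototypes$K), 4))
      vals
    } else if (mode == "rqa_only") {
      f <- rqa_of_series(compute_gfp(x, sfreq)$values, rqa_cfg)
      stats::setNames(as.numeric(f[1, ]), sprintf("%s(gfp)", names(f)))
    } else {
      series <- c(
        ms_parameter_series(x, prototypes, "mean_gfp", subwindow_s, sfreq),
        ms_parameter_series(x, prototypes, "occurrence", subwindow_s, sfreq),
        ms_parameter_series(x, prototypes, "duration", subwindow_s, sfreq),
        ms_parameter_series(x, prototypes, "coverage", subwindow_s, sfreq)
      )
      unlist(unname(imap(series, function(s, nm) {
        f <- if (stats::sd(s) == 0 && rqa_cfg$eps_strategy == "std_fraction" &&
                 is.null(rqa_cfg$epsilon)) {
          rqa_features(recurrence_matrix(s, modifyList_cfg(rqa_cfg, epsilon = 1e-12)))
        } else {
          rqa_of_series(s, rqa_cfg)
        }
        stats::setNames(as.numeric(f[1, ]), sprintf("%s(%s)", names(f), nm))
      })))
    }
  }
  rows <- vector("list", nrow(windows))
  ok <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    vals <- tryCatch(feat_row(windows[i, ]), error = function(e) NULL)
    if (!is.null(vals) && all(is.finite(vals))) {
      rows[[i]] <- vals; ok[i] <- TRUE
    }
  }
  if (!all(ok)) {
    warn(sprintf("%d window(s) with undefined features dropped", sum(!ok)))
  }
  assert_that(any(ok), "every window produced undefined features")
  fmat <- do.call(rbind, rows[ok])
  out <- dplyr::bind_cols(
    windows[ok, c("window_id", "trial_id", "label")],
    as_tibble(fmat)
  )
  if (!identical(selection, "all")) {
    missing <- setdiff(selection, colnames(fmat))
    assert_that(length(missing) == 0,
                sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
    out <- out[, c("window_id", "trial_id", "label", selection)]
  }
  attr(out, "window_length_s") <- windows$length_s[1]
  out
}

modifyList_cfg <- function(cfg, ...) {
  out <- utils::modifyList(unclass(cfg), list(...))
  class(out) <- "embedding_config"
  out
}

feature_columns <- function(fm) {
  setdiff(names(fm), c("window_id", "trial_id", "label"))
}

#' Screen features between the two attention classes
#'
#' Per feature: a Lilliefors (Kolmogorov–Smirnov with estimated parameters)
#' normality p-value, and a two-sided Mann–Whitney U (Wilcoxon rank-sum)
#' p-value comparing the SPK1 and SPK2 rows. A feature is flagged significant
#' when the group p-value is below `alpha`. Constant (degenerate) features
#' get p = 1. Raw p-values are reported; `adjust = "BH"` applies
#' Benjamini–Hochberg to the group tests.
#'
#' @param fm a [build_features()] tibble with both classes present (>= 3 rows
#'   each).
#' @param alpha significance level.
#' @param adjust `"none"` (default, matching the screening tables this
#'   pipeline mirrors) or `"BH"`.
#' @return A tibble: `feature`, `normality_p`, `group_p`, `significant`,
#'   `degenerate`.
#' @export
screen_features <- function(fm, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  g1 <- fm$label == "SPK1"; g2 <- fm$label == "SPK2"
  assert_that(sum(g1) >= 3 && sum(g2) >= 3,
              "need both classes with at least 3 rows each")
  cols <- feature_columns(fm)
  res <- map(cols, function(cn) {
    x <- fm[[cn]]
    if (stats::sd(x) == 0) {
      return(tibble(feature = cn, normality_p = 1, group_p = 1,
                    degenerate = TRUE))
    }
    np <- tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA_real_)
    gp <- tryCatch(
      suppressWarnings(stats::wilcox.test(x[g1], x[g2], exact = FALSE)$p.value),
      error = function(e) 1)
    if (is.na(gp)) gp <- 1    # e.g. all ties across groups
    tibble(feature = cn, normality_p = np, group_p = gp, degenerate = FALSE)
  }) |> bind_rows()
  if (adjust == "BH") res$group_p <- stats::p.adjust(res$group_p, "BH")
  res$significant <- res$group_p < alpha & !res$degenerate
  res[, c("feature", "normality_p", "group_p", "significant", "degenerate")]
}
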