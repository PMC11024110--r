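#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   geom_col labs scale_fill_manual theme_minimal facet_wrap scale_x_log10
#' @export
ggplot2::autoplot

#' @describeIn fit_prototypes per-state tidy summary: `state`, `gev`, and the
#'   map loadings nested in `map`.
#' @param x,object a `microstate_prototypes`.
#' @param ... unused.
#' @method tidy microstate_prototypes
#' @export
tidy.microstate_prototypes <- function(x, ...) {
  tibble(state = seq_len(x$K),
         gev = x$gev_per_state,
         map = lapply(seq_len(x$K), function(k) x$maps[k, ]))
}

#' @describeIn fit_prototypes one-row model summary.
#' @method glance microstate_prototypes
#' @export
glance.microstate_prototypes <- function(x, ...) {
  tibble(method = x$method, K = x$K, gev_total = x$gev_total,
         n_init = x$n_init, seed = x$seed)
}

#' @describeIn microstate_features tidy run-length view of a segmentation:
#'   one row per maximal state run.
#' @param x a `microstate_segmentation`.
#' @param ... unused.
#' @method tidy microstate_segmentation
#' @export
tidy.microstate_segmentation <- function(x, ...) {
  r <- rle(x$labels)
  ends <- cumsum(r$lengths)
  tibble(state = r$values,
         start = ends - r$lengths + 1L,
         end = ends,
         duration_ms = if (!is.null(x$sfreq)) r$lengths * 1000 / x$sfreq
                       else NA_real_)
}

#' @describeIn fit_aad one-row training summary of a fitted decoder.
#' @method glance aad_model
#' @export
glance.aad_model <- function(x, ...) {
  tibble(kind = x$kind, n_features = length(x$features),
         seq_len = x$seq_len, seed = x$spec$seed)
}

#' Plot a recurrence plot
#'
#' @param object a [recurrence_matrix()] result.
#' @param ... unused.
#' @return A ggplot raster of the binary recurrence matrix.
#' @method autoplot recurrence_plot
#' @export
autoplot.recurrence_plot <- function(object, ...) {
  df <- expand.grid(i = seq_len(object$n_points), j = seq_len(object$n_points))
  df$recurrent <- as.vector(object$matrix) == 1
  ggplot(df[df$recurrent, ], aes(x = .data$i, y = .data$j)) +
    geom_tile(fill = "grey20") +
    labs(x = "time i", y = "time j",
         title = sprintf("Recurrence plot (RR = %.3f, eps = %.3g)",
                         mean(object$matrix), object$config$epsilon)) +
    theme_minimal()
}

#' Plot a GFP series
#'
#' @param object a [compute_gfp()] result.
#' @param peaks optional peak indices from [find_gfp_peaks()] to mark.
#' @param ... unused.
#' @return A ggplot line plot of GFP over time.
#' @method autoplot gfp_series
#' @export
autoplot.gfp_series <- function(object, peaks = NULL, ...) {
  t <- if (!is.null(object$sfreq)) (seq_along(object$values) - 1) / object$sfreq
       else seq_along(object$values)
  p <- ggplot(tibble(t = t, gfp = object$values), aes(.data$t, .data$gfp)) +
    geom_line(colour = "firebrick") +
    labs(x = if (!is.null(object$sfreq)) "time (s)" else "sample",
         y = "GFP (uV)") +
    theme_minimal()
  if (!is.null(peaks)) {
    p <- p + geom_point(data = tibble(t = t[peaks], gfp = object$values[peaks]),
                        size = 0.8)
  }
  p
}

#' Plot a microstate segmentation
#'
#' GFP trace coloured by the active microstate, the conventional microstate
#' syntax plot.
#'
#' @param object a [backfit()] segmentation.
#' @param gfp the matching [compute_gfp()] series.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot microstate_segmentation
#' @export
autoplot.microstate_segmentation <- function(object, gfp, ...) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  sf <- object$sfreq %||% 1
  df <- tibble(t = (seq_along(v) - 1) / sf, gfp = v,
               state = factor(object$labels, levels = seq_len(object$K)))
  ggplot(df, aes(.data$t, .data$gfp, fill = .data$state)) +
    geom_col(width = 1 / sf) +
    labs(x = if (!is.null(object$sfreq)) "time (s)" else "sample",
         y = "GFP (uV)", fill = "state") +
    theme_minimal()
}

#' Plot decoding performance across window lengths
#'
#' @param object an [window_sweep()] result.
#' @param ... unused.
#' @return A ggplot of ACC/TPR/TNR against window length (log scale).
#' @method autoplot aad_sweep
#' @export
autoplot.aad_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("window_length_s", "acc",
                                                  "tpr", "tnr")],
                            cols = c("acc", "tpr", "tnr"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(.data$window_length_s, .data$value,
                 colour = toupper(.data$metric))) +
    geom_line() + geom_point() +
    scale_x_log10() +
    labs(x = "window length (s)", y = "rate", colour = NULL) +
    theme_minimal()
}

#' Plot a feature screening result
#'
#' @param object a [screen_features()] tibble.
#' @param ... unused.
#' @return A ggplot bar chart of -log10 group p-values.
#' @export
plot_screening <- function(object, ...) {
  df <- mutate(object, neglogp = -log10(pmax(.data$group_p, 1e-16)))
  ggplot(df, aes(x = stats::reorder(.data$feature, .data$neglogp),
                 y = .data$neglogp, fill = .data$significant)) +
    geom_col() +
    ggplot2::coord_flip() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    labs(x = NULL, y = "-log10 p (Mann-Whitney)", fill = "p < 0.05") +
    theme_minimal()
}
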