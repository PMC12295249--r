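#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   facet_wrap labs theme_minimal geom_boxplot geom_jitter geom_errorbar
#' @export
ggplot2::autoplot

#' Plot a multi-channel recording
#'
#' @param object A [pw_recording()].
#' @param ... Unused.
#' @return A ggplot with one facet per channel.
#' @export
autoplot.pw_recording <- function(object, ...) {
  df <- purrr::map_dfr(object$traces, as_tibble)
  df$kind <- factor(df$kind, levels = intersect(ALL_KINDS, unique(df$kind)))
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~kind, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL,
         title = sprintf("Recording %s", object$patient_id)) +
    theme_minimal()
}

#' Plot a beat with its fiducial points
#'
#' @param seg A `pw_segment`.
#' @param fiducials Tibble from a fiducial detector (period-local times).
#' @return A ggplot.
#' @export
plot_fiducials <- function(seg, fiducials) {
  t <- (seq_along(seg$samples) - 1) / seg$fs
  df <- tibble(time_s = t, value = seg$samples)
  pts <- filter(fiducials, .data$detected)
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line() +
    geom_point(data = pts, aes(x = .data$time_s, y = .data$amplitude),
               color = "red", size = 2) +
    ggplot2::geom_text(data = pts,
                       aes(x = .data$time_s, y = .data$amplitude,
                           label = .data$point),
                       vjust = -0.8, color = "red") +
    labs(x = "time from onset (s)", y = seg$kind) +
    theme_minimal()
}

#' Plot a synchronized ensemble: beats overlaid per channel
#'
#' @param object A `pw_sync`.
#' @param ... Unused.
#' @return A ggplot faceted by channel.
#' @export
autoplot.pw_sync <- function(object, ...) {
  df <- purrr::map_dfr(names(object$channels), function(ch) {
    purrr::map_dfr(object$channels[[ch]], function(sg) {
      tibble(channel = ch, beat = sg$beat,
             time_s = (seq_along(sg$samples) - 1) / sg$fs,
             value = sg$samples)
    })
  })
  ggplot(df, aes(x = .data$time_s, y = .data$value,
                 group = .data$beat)) +
    geom_line(alpha = 0.4, linewidth = 0.3) +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time from onset (s)", y = NULL) +
    theme_minimal()
}

#' Scatter plot of a correlation result
#'
#' @param object A `pw_correlation`.
#' @param ... Unused.
#' @export
autoplot.pw_correlation <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    labs(title = sprintf("Spearman rho = %.3f (%d%% CI %.3f-%.3f)",
                         object$rho, round(100 * object$conf_level),
                         object$ci_low, object$ci_high)) +
    theme_minimal()
}

#' Box plot of a group comparison
#'
#' @param object A `pw_group_comparison`.
#' @param ... Unused.
#' @export
autoplot.pw_group_comparison <- function(object, ...) {
  ggplot(object$data, aes(x = .data$group, y = .data$value)) +
    geom_boxplot(outlier.color = "red") +
    labs(x = "group", y = "value",
         title = paste("Rank-sum:",
                       paste(sprintf("%s p=%.3g", object$tests$comparison,
                                     object$tests$p_value),
                             collapse = "; "))) +
    theme_minimal()
}
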