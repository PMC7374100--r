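#' Plot a cumulative reliability curve
#'
#' Line plot of the concordance correlation coefficient per trial with its
#' confidence band and a dashed reference line at the efficiency
#' threshold.
#'
#' @param object A `trr_curve` from [cumulative_trr()].
#' @param threshold Reference reliability level to mark. Default 0.9.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trr_curve <- function(object, threshold = 0.9, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial, y = .data$ccc)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Trial", y = "Test–retest reliability (CCC)",
      title = "Cumulative test–retest reliability"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the engine's joint posterior over (log k, beta)
#'
#' @param engine An [ado_engine()].
#' @return A ggplot tile map of the grid posterior.
#' @export
plot_posterior <- function(engine) {
  ggplot2::ggplot(tidy(engine),
                  ggplot2::aes(x = .data$log_k, y = .data$beta,
                               fill = .data$mass)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "log k", y = expression(beta),
                  fill = "posterior mass") +
    ggplot2::theme_minimal()
}

#' Plot the trial-by-trial trajectory of a session
#'
#' Shows the presented sooner rewards and the running posterior mean of
#' `log k` (with a one-SD band) over trials.
#'
#' @param session A session tibble from [run_ado_session()] or
#'   [run_sc_session()].
#' @return A ggplot object.
#' @export
plot_session <- function(session) {
  est <- session[!is.na(session$post_mean_logk), ]
  ggplot2::ggplot(est, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$post_mean_logk - .data$post_sd_logk,
                   ymax = .data$post_mean_logk + .data$post_sd_logk),
      fill = "grey70", alpha = 0.5
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$post_mean_logk)) +
    ggplot2::labs(x = "Trial", y = "posterior log k (mean ± SD)") +
    ggplot2::theme_minimal()
}
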