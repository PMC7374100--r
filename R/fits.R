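#' Final parameter fits for every session in a log
#'
#' Batch-refits the grid posterior to each (agent, method, session) block
#' of a long session log and returns one row per session: posterior means
#' and SDs of `log k` and `beta`, plus the equal-tailed credible interval
#' for `log k`. By default the refit uses the fine [inference_grid()], so
#' these are the estimates to use for precision, outlier screening,
#' parameter-correlation diagnostics and coverage checks.
#'
#' @param logs A long log from [run_cohort_sessions()] or [run_visit()].
#' @param grid Fitting grid; default [inference_grid()].
#' @param level Credible-interval level. Default 0.95.
#' @return A tibble with columns `agent_id`, `method`, `session`,
#'   `mean_log_k`, `sd_log_k`, `mean_beta`, `sd_beta`, `ci_lo`, `ci_hi`.
#' @export
fit_cohort_sessions <- function(logs, grid = inference_grid(), level = 0.95) {
  logs |>
    dplyr::group_by(.data$agent_id, .data$method, .data$session) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_dd_session(d, grid)
      est <- point_estimates(fit)
      ci <- credible_interval_logk(fit, level = level)
      tibble::tibble(
        mean_log_k = est$mean[1], sd_log_k = est$sd[1],
        mean_beta = est$mean[2], sd_beta = est$sd[2],
        ci_lo = ci$lo, ci_hi = ci$hi
      )
    }) |>
    dplyr::ungroup()
}
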