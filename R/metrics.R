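#' Lin's concordance correlation coefficient
#'
#' Agreement between two sets of measurements,
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}
#'   {\sigma_x^2 + \sigma_y^2 + (\mu_x - \mu_y)^2},}
#' which penalizes location and scale shifts as well as imprecision
#' (unlike the Pearson correlation, which measures association only).
#' Moments use the population (1/n) convention of Lin's original
#' definition. The 95% confidence interval is obtained on the Fisher
#' z-scale with Lin's asymptotic standard error and back-transformed.
#'
#' @param x,y Numeric vectors of equal length >= 3; at least one must be
#'   non-constant.
#' @param conf_level Confidence level, default 0.95.
#'
#' @return A one-row tibble: `est`, `lo`, `hi`, `n`.
#' @examples
#' ccc(1:10, 1:10)$est # exactly 1
#' @export
ccc <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) rlang::abort("ccc requires at least 3 observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    rlang::abort("ccc requires finite inputs.")
  }
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) rlang::abort("ccc undefined: both vectors constant and equal.")
  if (sx2 == 0 || sy2 == 0) {
    # one vector constant: no covariation, agreement coefficient is 0
    return(tibble::tibble(est = 0, lo = NA_real_, hi = NA_real_, n = n))
  }
  rc <- 2 * sxy / denom
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (abs(rc) >= 1 - 1e-14 || abs(r) < 1e-14) {
    # degenerate se (perfect agreement or zero association)
    return(tibble::tibble(est = rc, lo = rc, hi = rc, n = n))
  }
  se_z <- sqrt((
    (1 - r^2) * rc^2 / ((1 - rc^2) * r^2) +
      2 * rc^3 * (1 - rc) * u^2 / (r * (1 - rc^2)^2) -
      rc^4 * u^4 / (2 * r^2 * (1 - rc^2)^2)
  ) / (n - 2))
  zc <- atanh(rc)
  tibble::tibble(
    est = rc,
    lo = tanh(zc - z * se_z),
    hi = tanh(zc + z * se_z),
    n = n
  )
}

#' Extract per-trial estimate trajectories from session logs
#'
#' Pulls one session's trial-wise posterior-mean trajectory per agent from
#' a long log produced by [run_cohort_sessions()] (or [run_visit()]),
#' dropping trials without an estimate (staircase logs evaluated every
#' third trial carry `NA` elsewhere).
#'
#' @param logs A long session log tibble.
#' @param session Session number to extract.
#' @param method Optional method filter (`"ado"` or `"sc"`).
#' @param parameter `"logk"` (default) or `"beta"`.
#' @return A tibble `agent_id`, `trial`, `estimate`.
#' @export
estimate_trajectories <- function(logs, session = 1L, method = NULL,
                                  parameter = c("logk", "beta")) {
  parameter <- match.arg(parameter)
  col <- paste0("post_mean_", parameter)
  out <- logs
  if (!is.null(method)) out <- dplyr::filter(out, .data$method == !!method)
  out <- dplyr::filter(out, .data$session == !!session, !is.na(.data[[col]]))
  dplyr::select(out, "agent_id", "trial", estimate = dplyr::all_of(col))
}

#' Cumulative test-retest reliability curve
#'
#' For each trial `t`, computes the concordance correlation coefficient
#' across participants between the session-A and session-B parameter
#' estimates based on the first `t` choices. The participant count is
#' fixed across trials; what grows with `t` is the number of choices
#' informing each estimate.
#'
#' @param est_a,est_b Trajectory tibbles (`agent_id`, `trial`, `estimate`)
#'   from two sessions of the same participants, e.g. from
#'   [estimate_trajectories()]. Only trials present for every participant
#'   in both sessions are evaluated.
#' @param conf_level Confidence level for the CCC interval.
#'
#' @return A `trr_curve` tibble: `trial`, `n`, `ccc`, `lo`, `hi`.
#' @export
cumulative_trr <- function(est_a, est_b, conf_level = 0.95) {
  ids <- sort(unique(est_a$agent_id))
  if (!setequal(ids, unique(est_b$agent_id))) {
    rlang::abort("the two sessions cover different participant sets.")
  }
  if (length(ids) < 3) rlang::abort("cumulative TRR requires >= 3 participants.")
  joined <- dplyr::inner_join(
    est_a, est_b,
    by = c("agent_id", "trial"), suffix = c("_a", "_b")
  )
  complete <- joined |>
    dplyr::count(.data$trial) |>
    dplyr::filter(.data$n == length(ids)) |>
    dplyr::pull(.data$trial)
  if (length(complete) == 0) {
    rlang::abort("no trial has estimates for every participant in both sessions.")
  }
  out <- joined |>
    dplyr::filter(.data$trial %in% complete) |>
    dplyr::group_by(.data$trial) |>
    dplyr::group_modify(function(d, key) {
      cc <- ccc(d$estimate_a, d$estimate_b, conf_level = conf_level)
      tibble::tibble(n = cc$n, ccc = cc$est, lo = cc$lo, hi = cc$hi)
    }) |>
    dplyr::ungroup()
  class(out) <- c("trr_curve", class(out))
  out
}

#' Trials required to reach a reliability threshold
#'
#' The efficiency metric: the smallest evaluated trial at which the
#' cumulative reliability curve reaches the threshold.
#'
#' @param curve A `trr_curve` tibble from [cumulative_trr()].
#' @param threshold Reliability threshold in (0, 1). Default 0.9.
#' @return The trial number, or `NA_integer_` if the curve never reaches
#'   the threshold ("not reached").
#' @export
trials_to_threshold <- function(curve, threshold = 0.9) {
  if (threshold <= 0 || threshold >= 1) {
    rlang::abort("`threshold` must be in (0, 1).")
  }
  hit <- curve$trial[curve$ccc >= threshold]
  if (length(hit) == 0) NA_integer_ else as.integer(min(hit))
}

#' Per-session precision of the discounting-rate estimate
#'
#' Precision is the SD of the individual posterior distribution of
#' `log k` at the end of a session (smaller is more precise);
#' `precision_summary()` gives the cohort presentation, mean (SD) across
#' participants per method and session.
#'
#' @param session A session tibble with a `post_sd_logk` column.
#' @return `session_precision()`: a single number.
#' @export
session_precision <- function(session) {
  sd_col <- session$post_sd_logk[!is.na(session$post_sd_logk)]
  if (length(sd_col) == 0) rlang::abort("session carries no posterior estimates.")
  sd_col[length(sd_col)]
}

#' @rdname session_precision
#' @param logs A long session log tibble with `agent_id`, `method`,
#'   `session` columns.
#' @return `precision_summary()`: a tibble with one row per
#'   (method, session): `mean_precision`, `sd_precision`, `n`.
#' @export
precision_summary <- function(logs) {
  logs |>
    dplyr::filter(!is.na(.data$post_sd_logk)) |>
    dplyr::group_by(.data$agent_id, .data$method, .data$session) |>
    dplyr::slice_max(.data$trial, n = 1) |>
    dplyr::group_by(.data$method, .data$session) |>
    dplyr::summarise(
      mean_precision = mean(.data$post_sd_logk),
      sd_precision = stats::sd(.data$post_sd_logk),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Exclude inconsistent participants
#'
#' Removes participants whose parameter-posterior SD exceeds the cohort
#' mean by more than two cohort SDs — i.e. participants whose choices were
#' too inconsistent to constrain the model. The rule is applied in a
#' single pass (thresholds are not recomputed after removal).
#'
#' @param results A tibble with one row per participant.
#' @param sd_col Column holding each participant's posterior SD; default
#'   `post_sd_logk`.
#' @return `results` restricted to retained participants.
#' @export
exclude_outliers <- function(results, sd_col = "post_sd_logk") {
  if (nrow(results) < 3) rlang::abort("need >= 3 participants.")
  v <- results[[sd_col]]
  cutoff <- mean(v) + 2 * stats::sd(v)
  results[v <= cutoff, ]
}

#' Correlation between discounting rate and choice consistency
#'
#' Pearson correlation (with two-sided p-value) between recovered `log k`
#' and `1/beta` across a cohort. A strong correlation signals that
#' estimated discounting rates are contaminated by response inconsistency.
#'
#' @param results A tibble with one row per participant.
#' @param logk_col,beta_col Column names. Defaults `mean_log_k`,
#'   `mean_beta`.
#' @return A one-row tibble: `estimate` (r), `p.value`, `n`.
#' @export
param_correlation <- function(results, logk_col = "mean_log_k",
                              beta_col = "mean_beta") {
  x <- results[[logk_col]]
  y <- 1 / results[[beta_col]]
  if (length(x) < 3) rlang::abort("need >= 3 participants.")
  if (any(!is.finite(y))) rlang::abort("1/beta must be finite (beta > 0).")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("zero variance in log k or 1/beta.")
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 n = length(x))
}
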