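# deterministic sub-seed derivation; kept within 32-bit integer range
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 69069 + i * 12345 + 1) %% 2147483647
  as.integer(s)
}

session_cols <- c("trial", "r_ss", "t_ss", "r_ll", "t_ll", "choice",
                  "post_mean_logk", "post_sd_logk",
                  "post_mean_beta", "post_sd_beta")

#' Run one adaptive (ADO) session for a simulated agent
#'
#' The full closed loop: each trial the engine selects the
#' mutual-information-optimal design under its current posterior (subject to
#' any easy-trial policy), the agent responds stochastically from its true
#' parameters, and the posterior is updated. Posterior means and SDs of
#' both parameters are logged on every trial.
#'
#' @param agent A one-row cohort tibble (see [make_cohort()]).
#' @param engine An [ado_engine()] template; it is reset to its prior
#'   before the session.
#' @param n_trials Number of trials. Default 42.
#' @param seed Integer seed for the agent's response stream.
#' @param fit_engine Optional [inference_grid()]. If supplied, the logged
#'   per-trial estimate columns are recomputed on it (exact inference; see
#'   [inference_grid()]), and the resulting final fit is attached as
#'   attribute `"fit"`. If `NULL` (default) the log carries the selection
#'   engine's own running estimates, whose resolution is limited by its
#'   grid spacing.
#' @param keep_fit If `FALSE`, skip attaching fitted-engine attributes
#'   (saves a batch refit when only the log itself is wanted, as in cohort
#'   simulations, where final fits come from [fit_cohort_sessions()]).
#'
#' @return A tibble with one row per trial (design, choice and running
#'   posterior estimates), with the final fitted engine attached as
#'   attribute `"engine"`.
#' @export
run_ado_session <- function(agent, engine = ado_engine(), n_trials = 42L,
                            seed = 1L, fit_engine = NULL, keep_fit = TRUE) {
  engine <- ado_reset(engine)
  n_trials <- as.integer(n_trials)
  rows <- matrix(NA_real_, n_trials, 9)
  # the trial loop works directly on the precomputed per-candidate
  # likelihood matrices; it is algebraically identical to chaining
  # next_trial() / update_posterior() / point_estimates() (asserted in the
  # test suite) but avoids per-trial data-frame overhead
  space <- engine$design_space
  lik <- engine$lik
  if (is.null(lik)) {
    rlang::abort("`engine` has no design cache; build it with cache_designs = TRUE.")
  }
  scan <- engine$scan
  nd <- nrow(space)
  th_k <- engine$th_logk
  th_b <- engine$th_beta
  p_agent <- agent_choice_prob(space, agent$true_log_k, agent$true_beta,
                               agent$lapse)
  m <- engine$mass
  top_design <- NA_integer_
  top_streak <- 0L
  history <- vector("list", n_trials)
  # active set: theta cells whose relative mass has not fallen below the
  # floor; dropped cells cannot regain mass under a product of Bernoulli
  # likelihoods, so the utility scan shrinks as the posterior concentrates
  act <- seq_along(m)
  scan_act <- scan
  withr::with_seed(seed, {
    for (t in seq_len(n_trials)) {
      keep <- m[act] > 1e-15
      if (sum(keep) < 0.6 * length(act)) {
        act <- act[keep]
        scan_act <- scan[act, , drop = FALSE]
      }
      both <- as.numeric(crossprod(scan_act, m[act]))
      pred <- both[seq_len(nd)]
      u <- pmax(-(xlogx(pred) + xlogx(1 - pred)) + both[nd + seq_len(nd)], 0)
      best <- if (max(u) > .u_floor) which.max(u) else which.min(abs(pred - 0.5))
      j <- best
      if (!is.null(engine$policy)) {
        top_streak <- if (identical(best, top_design)) top_streak + 1L else 1L
        top_design <- best
        if (top_streak >= engine$policy$streak) {
          j <- which.max(abs(pred - 0.5))
          top_streak <- 0L
        }
      }
      ch <- stats::rbinom(1, 1, p_agent[j])
      m <- m * if (ch == 1) lik[, j] else 1 - lik[, j]
      m <- m / sum(m)
      mu_k <- sum(m * th_k); mu_b <- sum(m * th_b)
      rows[t, ] <- c(
        space$r_ss[j], space$t_ss[j], space$r_ll[j], space$t_ll[j], ch,
        mu_k, sqrt(max(sum(m * (th_k - mu_k)^2), 0)),
        mu_b, sqrt(max(sum(m * (th_b - mu_b)^2), 0))
      )
      history[[t]] <- c(r_ss = space$r_ss[j], t_ss = space$t_ss[j],
                        r_ll = space$r_ll[j], t_ll = space$t_ll[j],
                        choice = ch)
    }
  })
  engine$mass <- m
  engine$history <- history
  engine$trial_index <- n_trials
  engine$top_design <- top_design
  engine$top_streak <- top_streak
  out <- tibble::tibble(
    trial = seq_len(n_trials),
    r_ss = rows[, 1], t_ss = rows[, 2], r_ll = rows[, 3], t_ll = rows[, 4],
    choice = rows[, 5],
    post_mean_logk = rows[, 6], post_sd_logk = rows[, 7],
    post_mean_beta = rows[, 8], post_sd_beta = rows[, 9]
  )
  if (!is.null(fit_engine)) {
    est <- cumulative_estimates(out, fit_engine)
    out[names(est)[-1]] <- est[-1]
    if (keep_fit) attr(out, "fit") <- fit_dd_session(out, fit_engine)
  }
  attr(out, "engine") <- engine
  out
}

#' Run one staircase (SC) session for a simulated agent
#'
#' Runs the adjusting-amount staircase (42 fixed-schedule choices over the
#' seven protocol delays, delay order seeded-random), then fits the same
#' grid posterior the adaptive engine uses to the raw choices. Cumulative
#' per-trial estimates are computed at the trials given by `estimate_at`
#' (conventionally every third trial for staircase data).
#'
#' @inheritParams run_ado_session
#' @param estimate_at Trials at which cumulative estimates are evaluated;
#'   default every trial. Rows at other trials carry `NA` estimates.
#' @return A 42-row session tibble in the same schema as
#'   [run_ado_session()], with attributes `"engine"` (final batch fit) and
#'   `"indifference_points"` (7-row tibble).
#' @export
run_sc_session <- function(agent, engine = ado_engine(), seed = 1L,
                           estimate_at = 1:42, fit_engine = NULL,
                           keep_fit = TRUE) {
  grid <- if (is.null(fit_engine)) engine else fit_engine
  sc <- simulate_staircase(agent, seed = seed)
  est <- cumulative_estimates(sc$session, grid, at = estimate_at)
  out <- dplyr::left_join(sc$session, est, by = "trial")
  if (keep_fit) {
    fit <- fit_dd_session(sc$session, grid)
    attr(out, "engine") <- fit
    if (!is.null(fit_engine)) attr(out, "fit") <- fit
  }
  attr(out, "indifference_points") <- sc$indifference_points
  out
}

#' Simulate a cohort of sessions
#'
#' Runs `n_sessions` independent sessions of one method for every agent in
#' a cohort. Sessions are independent measurements: each starts from the
#' engine prior, and every (agent, session) pair gets its own derived
#' response seed.
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param method `"ado"` or `"sc"`.
#' @param engine Engine template shared across sessions.
#' @param n_sessions Sessions per agent. Default 2 (a test-retest pair).
#' @param n_trials Trials per ADO session (the staircase is always 42).
#' @param seed Base seed; per-session seeds are derived deterministically.
#' @param estimate_at Passed to [run_sc_session()] for `method = "sc"`.
#' @param fit_engine Optional [inference_grid()] used for the logged
#'   estimates, as in [run_ado_session()].
#'
#' @return A long tibble of all trials with leading columns `agent_id`,
#'   `method` and `session`.
#' @export
run_cohort_sessions <- function(cohort, method = c("ado", "sc"),
                                engine = ado_engine(), n_sessions = 2L,
                                n_trials = 42L, seed = 1L,
                                estimate_at = 1:42, fit_engine = NULL) {
  method <- match.arg(method)
  runs <- tidyr::expand_grid(agent_id = cohort$agent_id,
                             session = seq_len(n_sessions))
  parts <- purrr::pmap(runs, function(agent_id, session) {
    agent <- cohort[cohort$agent_id == agent_id, ]
    s <- derive_seed(seed, agent_id, session, if (method == "ado") 1L else 2L)
    log <- if (method == "ado") {
      run_ado_session(agent, engine, n_trials = n_trials, seed = s,
                      fit_engine = fit_engine, keep_fit = FALSE)
    } else {
      run_sc_session(agent, engine, seed = s, estimate_at = estimate_at,
                     fit_engine = fit_engine, keep_fit = FALSE)
    }
    dplyr::bind_cols(
      tibble::tibble(agent_id = agent_id, method = method, session = session),
      log
    )
  })
  dplyr::bind_rows(parts)
}

#' Write or read a session log
#'
#' Session logs are plain CSV with one row per trial and the columns
#' `trial, r_ss, t_ss, r_ll, t_ll, choice, post_mean_logk, post_sd_logk,
#' post_mean_beta, post_sd_beta`.
#'
#' @param session A session tibble.
#' @param path File path.
#' @return `write_session()` returns `session` invisibly; `read_session()`
#'   returns the session tibble.
#' @export
write_session <- function(session, path) {
  missing <- setdiff(session_cols, names(session))
  for (m in missing) session[[m]] <- NA_real_
  readr::write_csv(session[session_cols], path)
  invisible(session)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("trial", "r_ss", "t_ss", "r_ll", "t_ll", "choice"),
                     names(out))
  if (length(missing)) {
    rlang::abort(paste0("session file lacks columns: ",
                        paste(missing, collapse = ", ")))
  }
  out
}
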