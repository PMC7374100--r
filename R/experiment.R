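#' Visit protocol
#'
#' The session structure of one lab visit. The default matches the
#' two-method comparison design: two adaptive and two staircase sessions
#' of 42 trials each, with task order counterbalanced across participants.
#' The short-form protocol (two 20-trial adaptive sessions, no staircase)
#' is `visit_protocol(ado_trials = 20, n_sc_sessions = 0)`.
#'
#' @param ado_trials Trials per adaptive session. Default 42.
#' @param n_ado_sessions,n_sc_sessions Sessions per method. Defaults 2 and 2.
#' @param sc_estimate_every Staircase cumulative estimates are evaluated
#'   every this many trials. Default 3.
#' @return A `visit_protocol` list.
#' @export
visit_protocol <- function(ado_trials = 42L, n_ado_sessions = 2L,
                           n_sc_sessions = 2L, sc_estimate_every = 3L) {
  if (ado_trials < 1 || n_ado_sessions < 0 || n_sc_sessions < 0) {
    rlang::abort("invalid protocol.")
  }
  structure(
    list(
      ado_trials = as.integer(ado_trials),
      n_ado_sessions = as.integer(n_ado_sessions),
      n_sc_sessions = as.integer(n_sc_sessions),
      sc_estimate_every = as.integer(sc_estimate_every)
    ),
    class = "visit_protocol"
  )
}

#' Run one visit of a simulated study
#'
#' Executes the protocol's sessions for every agent in the cohort. Each
#' session starts from the engine prior (sessions are independent
#' measurements), and task order — adaptive-first versus staircase-first —
#' alternates across participants so that exactly half (rounded up)
#' complete the adaptive tasks first. Order is recorded in the log; since
#' sessions share no state it does not affect the simulated data.
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param protocol A [visit_protocol()].
#' @param engine An [ado_engine()] template.
#' @param seed Base seed; all per-session seeds derive from it.
#'
#' @return A long tibble of every trial of every session:
#'   `agent_id`, `ado_first`, `method`, `session`, `trial`, design columns,
#'   `choice`, posterior-estimate columns.
#' @export
run_visit <- function(cohort, protocol = visit_protocol(),
                      engine = ado_engine(), seed = 1L) {
  order_tbl <- tibble::tibble(
    agent_id = cohort$agent_id,
    ado_first = seq_along(cohort$agent_id) %% 2L == 1L
  )
  parts <- list()
  if (protocol$n_ado_sessions > 0) {
    parts$ado <- run_cohort_sessions(
      cohort, "ado", engine,
      n_sessions = protocol$n_ado_sessions,
      n_trials = protocol$ado_trials,
      seed = derive_seed(seed, 11L)
    )
  }
  if (protocol$n_sc_sessions > 0) {
    parts$sc <- run_cohort_sessions(
      cohort, "sc", engine,
      n_sessions = protocol$n_sc_sessions,
      seed = derive_seed(seed, 22L),
      estimate_at = seq(protocol$sc_estimate_every, 42L,
                        by = protocol$sc_estimate_every)
    )
  }
  dplyr::bind_rows(parts) |>
    dplyr::left_join(order_tbl, by = "agent_id") |>
    dplyr::relocate("agent_id", "ado_first", "method", "session")
}

#' Evaluate reliability, precision and efficiency from visit logs
#'
#' Computes, per method, the cumulative within-visit test-retest
#' reliability curve between two sessions, its maximum, the trials needed
#' to reach the reliability threshold, and the cohort precision summary.
#'
#' @param logs A visit log from [run_visit()] (or any log with the same
#'   columns) containing at least two sessions per method.
#' @param sessions Length-2 session numbers compared for reliability.
#' @param threshold Reliability threshold for the efficiency metric.
#' @param fit_grid Grid for the precision refits (see
#'   [fit_cohort_sessions()]); default [inference_grid()].
#' @return A list: `trr` (named list of `trr_curve`s per method),
#'   `fits` (per-session final fits), `summary` (tibble per method:
#'   `max_trr`, `trials_to_threshold`, `mean_precision`, `sd_precision`,
#'   `n`).
#' @export
evaluate_visit <- function(logs, sessions = c(1L, 2L), threshold = 0.9,
                           fit_grid = inference_grid()) {
  methods <- unique(logs$method)
  curves <- list()
  rows <- list()
  fits <- fit_cohort_sessions(
    dplyr::filter(logs, .data$session %in% sessions), grid = fit_grid
  )
  prec <- fits |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_precision = mean(.data$sd_log_k),
      sd_precision = stats::sd(.data$sd_log_k),
      n = dplyr::n_distinct(.data$agent_id), .groups = "drop"
    )
  for (m in methods) {
    have <- unique(logs$session[logs$method == m])
    if (!all(sessions %in% have)) next # reliability needs a session pair
    curve <- cumulative_trr(
      estimate_trajectories(logs, session = sessions[1], method = m),
      estimate_trajectories(logs, session = sessions[2], method = m)
    )
    curves[[m]] <- curve
    rows[[m]] <- tibble::tibble(
      method = m,
      max_trr = max(curve$ccc),
      trials_to_threshold = trials_to_threshold(curve, threshold)
    )
  }
  summary <- dplyr::bind_rows(rows) |>
    dplyr::left_join(prec, by = "method")
  list(trr = curves, fits = fits, summary = summary)
}

#' Run a two-visit test-retest study
#'
#' Runs the visit protocol twice on the same cohort, with the agents'
#' true `log k` perturbed between visits by their configured drift SD
#' (emulating true between-visit change in impulsivity). Returns the logs
#' of both visits plus within-visit and between-visit reliability
#' evaluations.
#'
#' @inheritParams run_visit
#' @return A list: `visit1`, `visit2` (visit logs), `cohort`,
#'   `cohort_visit2` (drifted parameters), `within` (list of
#'   [evaluate_visit()] results per visit), `between` (named list of
#'   between-visit `trr_curve`s per method, first session of each visit).
#' @export
run_two_visit_study <- function(cohort, protocol = visit_protocol(),
                                engine = ado_engine(), seed = 1L) {
  v1 <- run_visit(cohort, protocol, engine, seed = derive_seed(seed, 1L))
  cohort2 <- drift_cohort(cohort, seed = derive_seed(seed, 99L))
  v2 <- run_visit(cohort2, protocol, engine, seed = derive_seed(seed, 2L))
  between <- list()
  for (m in unique(v1$method)) {
    between[[m]] <- cumulative_trr(
      estimate_trajectories(v1, session = 1L, method = m),
      estimate_trajectories(v2, session = 1L, method = m)
    )
  }
  list(
    visit1 = v1, visit2 = v2,
    cohort = cohort, cohort_visit2 = cohort2,
    within = list(visit1 = evaluate_visit(v1), visit2 = evaluate_visit(v2)),
    between = between
  )
}
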