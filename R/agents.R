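#' Simulate a cohort of synthetic participants
#'
#' Each agent is a stochastic hyperbolic/softmax responder with true
#' parameters `(log k, beta)`, an optional lapse rate (probability of a
#' uniformly random response) and an optional between-visit drift SD on
#' `log k`. Defaults draw `log k` uniformly over `[log 1e-4, log 0.5]` —
#' inside the engine's operative `k` range — and `beta` log-normally with
#' median 1.
#'
#' @param n Number of agents, >= 1.
#' @param logk_dist Function `(n) -> n` draws of true `log k`; default
#'   `runif(n, log(1e-4), log(0.5))`.
#' @param beta_dist Function `(n) -> n` draws of true `beta` (> 0); default
#'   `rlnorm(n, 0, 0.5)`.
#' @param lapse Lapse rate in `[0, 0.5]`, recycled across agents. Default 0.
#' @param drift_sd SD of the Gaussian perturbation added to `log k` between
#'   visits, >= 0. Default 0.1.
#' @param seed Integer seed; the same seed regenerates the same cohort.
#'
#' @return A tibble with one row per agent: `agent_id`, `true_log_k`,
#'   `true_beta`, `lapse`, `drift_sd`.
#' @examples
#' make_cohort(5, seed = 42)
#' @export
make_cohort <- function(n,
                        logk_dist = function(n) stats::runif(n, log(1e-4), log(0.5)),
                        beta_dist = function(n) stats::rlnorm(n, 0, 0.5),
                        lapse = 0,
                        drift_sd = 0.1,
                        seed = 1L) {
  if (n < 1) rlang::abort("`n` must be >= 1.")
  if (any(lapse < 0 | lapse > 0.5)) rlang::abort("`lapse` must be in [0, 0.5].")
  if (any(drift_sd < 0)) rlang::abort("`drift_sd` must be >= 0.")
  withr::with_seed(seed, {
    tibble::tibble(
      agent_id = seq_len(n),
      true_log_k = logk_dist(n),
      true_beta = beta_dist(n),
      lapse = rep_len(lapse, n),
      drift_sd = rep_len(drift_sd, n)
    )
  })
}

#' Apply between-visit parameter drift to a cohort
#'
#' Returns the visit-2 cohort: each agent's `true_log_k` is perturbed by an
#' independent `Normal(0, drift_sd)` draw; other fields are unchanged.
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param seed Integer seed for the drift draws.
#' @return The drifted cohort tibble.
#' @export
drift_cohort <- function(cohort, seed = 1L) {
  withr::with_seed(seed, {
    dplyr::mutate(
      cohort,
      true_log_k = .data$true_log_k +
        stats::rnorm(dplyr::n(), 0, .data$drift_sd)
    )
  })
}

#' Probability that an agent chooses the larger-later option
#'
#' The generative response probability: a softmax choice with the agent's
#' true parameters, mixed with a uniform response at the lapse rate,
#' `p = (1 - lapse) * P(LL | theta_true) + lapse / 2`.
#'
#' @param design A design tibble.
#' @param true_log_k,true_beta Agent parameters.
#' @param lapse Lapse rate in `[0, 0.5]`.
#' @return Numeric vector of probabilities.
#' @export
agent_choice_prob <- function(design, true_log_k, true_beta, lapse = 0) {
  p <- p_choose_ll(design, true_log_k, true_beta)
  (1 - lapse) * p + lapse * 0.5
}

#' Draw an agent's choice for a design
#'
#' Bernoulli draw from [agent_choice_prob()] using the current RNG stream,
#' so seeding the stream makes response sequences reproducible.
#'
#' @inheritParams agent_choice_prob
#' @return 0/1 choices, one per design row.
#' @export
respond <- function(design, true_log_k, true_beta, lapse = 0) {
  p <- agent_choice_prob(design, true_log_k, true_beta, lapse)
  stats::rbinom(length(p), 1, p)
}

#' Choice-source closure for one agent
#'
#' Wraps one cohort row as a function `(design) -> choice` for interfaces
#' that pull choices, such as [run_staircase()].
#'
#' @param agent A one-row cohort tibble (or any list with `true_log_k`,
#'   `true_beta`, `lapse`).
#' @return A function of a one-row design returning 0 or 1.
#' @export
agent_responder <- function(agent) {
  force(agent)
  function(design) {
    respond(design, agent$true_log_k, agent$true_beta, agent$lapse)
  }
}
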