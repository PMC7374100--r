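#' Candidate design space for the adaptive task
#'
#' The stimulus set the engine optimizes over. The sooner delay and the
#' later-larger reward are fixed anchors (0 days and $800); the free
#' coordinates are the sooner reward and the later delay. Defaults use the
#' staircase protocol's finest dollar increment ($12.5) as the amount step
#' and the seven protocol delays plus intermediate values.
#'
#' Candidates are returned in the canonical ordering (ascending `t_ll`, then
#' ascending `r_ss`), which is also the deterministic tie-break order for
#' design selection.
#'
#' @param r_ss Vector of candidate sooner rewards (USD), all in `(0, r_ll)`.
#' @param t_ll Vector of candidate later delays (days), all `> t_ss`.
#' @param t_ss Fixed sooner delay (days). Default 0.
#' @param r_ll Fixed later reward (USD). Default 800.
#'
#' @return A design tibble (see [dd_design()]) with one row per candidate.
#' @examples
#' nrow(ado_design_space()) # 63 amounts x 10 delays
#' @export
ado_design_space <- function(r_ss = seq(12.5, 787.5, by = 12.5),
                             t_ll = c(1, 3, 7, 14, 30, 90, 180, 365, 1095, 3650),
                             t_ss = 0,
                             r_ll = 800) {
  space <- tidyr::expand_grid(t_ll = sort(unique(t_ll)), r_ss = sort(unique(r_ss)))
  space <- tibble::tibble(
    r_ss = space$r_ss, t_ss = t_ss, r_ll = r_ll, t_ll = space$t_ll
  )
  validate_design(space)
  space
}

#' Initialize an ADO engine
#'
#' Builds the engine state: a discretized joint prior over
#' `(log k, beta)` together with a fixed candidate design space. The grid is
#' equally spaced in `log k` between `log(k_bounds[1])` and
#' `log(k_bounds[2])` and equally spaced in `beta` over `beta_bounds`. The
#' default prior is uniform over the grid.
#'
#' Choice probabilities for every (grid point, candidate design) pair are
#' precomputed at initialization, so per-trial design selection is a pair of
#' matrix-vector products.
#'
#' @param k_bounds Length-2 numeric, bounds on the discounting rate `k`
#'   (per day). Default `c(1e-5, 1)`.
#' @param beta_bounds Length-2 numeric, bounds on the inverse temperature.
#'   Default `c(0.2, 5)`; the lower bound is kept above zero so that every
#'   grid point yields an identifiable likelihood.
#' @param n_k,n_beta Grid resolutions (>= 2). Defaults 150 and 25. The
#'   `log k` resolution must stay comparable to the width of the posterior
#'   a full session can reach: once the posterior is resolved at cell
#'   level, expected information gain is ~0 for every candidate and
#'   selection loses its signal (see [next_trial()] for the fallback).
#' @param design_space Candidate designs, a design tibble; default
#'   [ado_design_space()].
#' @param prior `"uniform"` (default) or a numeric matrix/vector of
#'   non-negative prior mass with `n_k * n_beta` elements (`log k` varying
#'   fastest); it is normalized internally.
#' @param policy Easy-trial insertion policy from [easy_trial_policy()], or
#'   `NULL` (default) for pure information-maximizing selection.
#' @param cache_designs If `TRUE` (default), precompute the per-candidate
#'   choice probabilities at initialization. Set `FALSE` for engines used
#'   only to fit completed sessions (see [inference_grid()]), where the
#'   cache would be wasted work.
#'
#' @return An object of class `ado_engine`.
#' @examples
#' eng <- ado_engine(n_k = 10, n_beta = 5)
#' glance(eng)
#' @export
ado_engine <- function(k_bounds = c(1e-5, 1),
                       beta_bounds = c(0.2, 5),
                       n_k = 150,
                       n_beta = 25,
                       design_space = ado_design_space(),
                       prior = "uniform",
                       policy = NULL,
                       cache_designs = TRUE) {
  if (length(k_bounds) != 2 || any(k_bounds <= 0) || k_bounds[1] >= k_bounds[2]) {
    rlang::abort("`k_bounds` must be positive with k_bounds[1] < k_bounds[2].")
  }
  if (length(beta_bounds) != 2 || beta_bounds[1] < 0 ||
      beta_bounds[1] >= beta_bounds[2]) {
    rlang::abort("`beta_bounds` must satisfy 0 <= lo < hi.")
  }
  if (n_k < 2 || n_beta < 2) rlang::abort("grid resolutions must be >= 2.")
  validate_design(design_space)
  design_space <- dplyr::arrange(design_space, .data$t_ll, .data$r_ss)

  log_k <- seq(log(k_bounds[1]), log(k_bounds[2]), length.out = n_k)
  beta <- seq(beta_bounds[1], beta_bounds[2], length.out = n_beta)
  th_logk <- rep(log_k, times = n_beta)
  th_beta <- rep(beta, each = n_k)

  if (identical(prior, "uniform")) {
    mass <- rep(1 / (n_k * n_beta), n_k * n_beta)
  } else {
    mass <- as.numeric(prior)
    if (length(mass) != n_k * n_beta || any(mass < 0) || sum(mass) <= 0) {
      rlang::abort("`prior` must be non-negative with n_k * n_beta elements.")
    }
    mass <- mass / sum(mass)
  }

  # p(y = 1 | theta, d) for all grid points x candidates, and the per-cell
  # negative conditional entropy p log p + (1-p) log(1-p); both reused every
  # trial by design_utility() and the session loop.
  if (cache_designs) {
    lik <- choice_prob_matrix(design_space, th_logk, th_beta)
  } else {
    lik <- list(p = NULL, plogp = NULL)
  }

  structure(
    list(
      log_k = log_k, beta = beta,
      th_logk = th_logk, th_beta = th_beta,
      mass = mass, prior_mass = mass,
      design_space = design_space,
      lik = lik$p, neg_cond_ent = lik$plogp,
      scan = if (cache_designs) cbind(lik$p, lik$plogp) else NULL,
      history = list(),
      trial_index = 0L,
      policy = policy,
      top_design = NA_integer_, top_streak = 0L,
      k_bounds = k_bounds, beta_bounds = beta_bounds
    ),
    class = "ado_engine"
  )
}

# choice probabilities p(y=1 | theta, d) as an (n_theta x n_design) matrix,
# built per beta block from the shared (k x design) value-difference matrix
choice_prob_matrix <- function(design_space, th_logk, th_beta,
                               entropy = TRUE) {
  log_k <- unique(th_logk)
  beta <- unique(th_beta)
  k <- exp(log_k)
  nk <- length(k)
  nd <- nrow(design_space)
  # arithmetic mirrors p_choose_ll() exactly so cached and direct
  # likelihoods agree bit-for-bit
  v_ss <- matrix(design_space$r_ss, nk, nd, byrow = TRUE) /
    (1 + outer(k, design_space$t_ss))
  v_ll <- matrix(design_space$r_ll, nk, nd, byrow = TRUE) /
    (1 + outer(k, design_space$t_ll))
  dv <- v_ll - v_ss
  p <- matrix(0, length(th_logk), nrow(design_space))
  for (j in seq_along(beta)) {
    rows <- (j - 1L) * length(log_k) + seq_along(log_k)
    p[rows, ] <- stats::plogis(beta[j] * dv)
  }
  p <- pmin(pmax(p, .p_eps), 1 - .p_eps)
  list(p = p,
       plogp = if (entropy) p * log(p) + (1 - p) * log1p(-p) else NULL)
}

#' @export
print.ado_engine <- function(x, ...) {
  cat(
    "<ado_engine> ", length(x$log_k), " x ", length(x$beta),
    " grid over (log k, beta), ", nrow(x$design_space),
    " candidate designs, ", x$trial_index, " trial(s) observed\n",
    sep = ""
  )
  est <- point_estimates(x)
  cat(sprintf(
    "  log k: %.3f (sd %.3f)   beta: %.3f (sd %.3f)\n",
    est$mean[1], est$sd[1], est$mean[2], est$sd[2]
  ))
  invisible(x)
}

#' Fine parameter grid for fitting completed sessions
#'
#' An engine configured for inference rather than design selection: a much
#' finer `log k` grid and no per-candidate likelihood cache. Design
#' selection only needs the grid to rank candidate utilities, but reported
#' estimates — posterior means, SDs (the precision metric) and credible
#' intervals — need cells narrower than the posterior itself, which after a
#' full adaptive session is only a few hundredths of a log-unit wide.
#' Sequential (adaptive) stimulus selection does not bias likelihood-based
#' inference, so refitting the recorded choices on this grid is exact.
#'
#' For credible-interval calibration the cell width should stay below
#' about half the posterior SD; with very consistent responders (posterior
#' SD near 0.01 log-units after 42 adaptive trials) that calls for
#' `n_k = 1600`, while the default 800 is ample for point estimates,
#' precision summaries and trajectories.
#'
#' @inheritParams ado_engine
#' @param n_k Fine resolution for `log k`; default 800.
#' @return An `ado_engine` suitable for [fit_dd_session()],
#'   [cumulative_estimates()] and [fit_cohort_sessions()].
#' @export
inference_grid <- function(k_bounds = c(1e-5, 1), beta_bounds = c(0.2, 5),
                           n_k = 800, n_beta = 25) {
  ado_engine(
    k_bounds = k_bounds, beta_bounds = beta_bounds,
    n_k = n_k, n_beta = n_beta, cache_designs = FALSE
  )
}

#' Reset an engine to its prior
#'
#' Returns the engine with prior mass restored and history cleared, keeping
#' the (already precomputed) grid and design space. Used to reuse one engine
#' template across many simulated sessions.
#'
#' @param engine An [ado_engine()].
#' @return The reset engine.
#' @export
ado_reset <- function(engine) {
  engine$mass <- engine$prior_mass
  engine$history <- list()
  engine$trial_index <- 0L
  engine$top_design <- NA_integer_
  engine$top_streak <- 0L
  engine
}

#' Bayes-update the engine posterior with one observed choice
#'
#' Multiplies the current grid mass by the Bernoulli likelihood of the
#' observed choice at the presented design and renormalizes. The design and
#' choice are appended to the engine history, so the posterior always equals
#' the prior updated by exactly the recorded trials.
#'
#' @param engine An [ado_engine()].
#' @param design A one-row design tibble (need not belong to the candidate
#'   space).
#' @param choice 0 (smaller-sooner) or 1 (larger-later).
#'
#' @return The updated engine.
#' @export
update_posterior <- function(engine, design, choice) {
  validate_design(design)
  if (nrow(design) != 1) rlang::abort("`design` must be a single row.")
  if (!choice %in% c(0, 1)) rlang::abort("`choice` must be 0 or 1.")
  p1 <- p_choose_ll(design, engine$th_logk, engine$th_beta)
  lik <- if (choice == 1) p1 else 1 - p1
  m <- engine$mass * lik
  tot <- sum(m)
  if (!is.finite(tot) || tot <= 0) {
    rlang::abort("posterior update produced no mass; likelihoods degenerate.")
  }
  engine$mass <- m / tot
  engine$trial_index <- engine$trial_index + 1L
  engine$history[[engine$trial_index]] <- c(
    r_ss = design$r_ss, t_ss = design$t_ss,
    r_ll = design$r_ll, t_ll = design$t_ll, choice = choice
  )
  engine
}

#' Posterior predictive probability of a larger-later choice
#'
#' Marginalizes the softmax choice probability over the current grid
#' posterior: `p(y = 1 | d) = sum_theta mass(theta) p(y = 1 | theta, d)`.
#'
#' @inheritParams update_posterior
#' @param design A design tibble; one or more rows.
#' @return Numeric vector of probabilities in (0, 1), one per design row.
#' @export
predictive_prob <- function(engine, design) {
  validate_design(design)
  vapply(
    seq_len(nrow(design)),
    function(i) {
      sum(engine$mass *
            p_choose_ll(design[i, ], engine$th_logk, engine$th_beta))
    },
    numeric(1)
  )
}

#' Expected information gain of candidate designs
#'
#' The mutual information between the model parameters and the choice
#' outcome at each design,
#' \deqn{U(d) = \sum_\theta \sum_{y \in \{0,1\}} m(\theta)\, p(y|\theta,d)
#'   \log \frac{p(y|\theta,d)}{p(y|d)}}
#' in nats, computed as the entropy of the posterior predictive minus the
#' expected conditional entropy. It is non-negative, and zero exactly when
#' every plausible parameter value predicts the same choice probability.
#'
#' @param engine An [ado_engine()].
#' @param design Optional design tibble to score; defaults to the engine's
#'   whole candidate space.
#'
#' @return A tibble of the scored designs with columns `utility` (nats) and
#'   `pred_p` (posterior predictive probability of the larger-later choice).
#' @export
design_utility <- function(engine, design = NULL) {
  if (is.null(design) && !is.null(engine$lik)) {
    space <- engine$design_space
    p <- engine$lik
    plogp <- engine$neg_cond_ent
  } else {
    if (is.null(design)) design <- engine$design_space
    validate_design(design)
    space <- design
    mat <- choice_prob_matrix(space, engine$th_logk, engine$th_beta)
    p <- mat$p
    plogp <- mat$plogp
  }
  pred <- as.numeric(crossprod(p, engine$mass))
  exp_neg_cond_ent <- as.numeric(crossprod(plogp, engine$mass))
  pred_ent <- -(xlogx(pred) + xlogx(1 - pred))
  u <- pmax(pred_ent + exp_neg_cond_ent, 0)
  dplyr::mutate(space, utility = u, pred_p = pred)
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# below this expected information gain (nats) the grid posterior is treated
# as fully resolved and selection falls back to predicted indifference
.u_floor <- 1e-9

#' Select the most informative design
#'
#' Returns the candidate maximizing [design_utility()] under the current
#' posterior. Ties are broken deterministically by the canonical candidate
#' ordering (ascending later delay, then ascending sooner reward).
#'
#' @inheritParams design_utility
#' @param space Optional candidate set overriding the engine's.
#' @return A one-row design tibble with its `utility` and `pred_p`.
#' @export
select_design <- function(engine, space = NULL) {
  u <- design_utility(engine, design = space)
  if (nrow(u) == 0) rlang::abort("empty design space.")
  # utilities within numerical noise of the maximum count as tied; the
  # first such candidate (canonical ordering) wins
  u[which(u$utility >= max(u$utility) - 1e-12)[1], ]
}

#' Easy-trial insertion policy
#'
#' Once the optimizer's preferred design has stabilized, occasionally
#' presenting an "easy" trial (one whose predicted choice is most
#' one-sided) counters fatigue from a long run of near-indifference
#' choices, without changing the total trial count.
#'
#' @param streak Number of consecutive trials with an unchanged top-utility
#'   design after which one easy trial is inserted. Default 3.
#' @return A policy object for [ado_engine()] / [next_trial()].
#' @export
easy_trial_policy <- function(streak = 3L) {
  if (streak < 1) rlang::abort("`streak` must be >= 1.")
  structure(list(streak = as.integer(streak)), class = "easy_trial_policy")
}

#' Choose the next trial, applying the engine's trial-mix policy
#'
#' Without a policy this is [select_design()], with one refinement: when
#' the maximum expected information gain over all candidates is numerically
#' zero (below 1e-9 nats — the grid posterior is fully resolved at its
#' resolution), the candidate whose posterior predictive probability is
#' closest to 0.5 is presented instead, since near-indifference trials
#' remain the most informative about the remaining within-cell uncertainty.
#'
#' With an [easy_trial_policy()], when the top-utility design has been
#' unchanged for the configured number of consecutive selections, the next
#' trial is instead an easy one — the candidate whose predictive
#' probability is farthest from 0.5 — and the streak counter resets.
#'
#' @inheritParams select_design
#' @return A one-row design tibble.
#' @export
next_trial <- function(engine, space = NULL) {
  u <- design_utility(engine, design = space)
  if (nrow(u) == 0) rlang::abort("empty design space.")
  best <- if (max(u$utility) > .u_floor) which.max(u$utility) else
    which.min(abs(u$pred_p - 0.5))
  pick <- best
  if (!is.null(engine$policy)) {
    streak <- if (identical(best, engine$top_design)) engine$top_streak + 1L else 1L
    if (streak >= engine$policy$streak) {
      pick <- which.max(abs(u$pred_p - 0.5))
      streak <- 0L
    }
    # streak bookkeeping rides along on the returned design's attributes so
    # the session loop can thread it back through update_posterior
    attr(u, "streak") <- streak
  }
  out <- u[pick, ]
  attr(out, "top_design") <- best
  attr(out, "top_streak") <- if (is.null(engine$policy)) 0L else attr(u, "streak")
  out
}

#' Marginal posterior point estimates
#'
#' Means and standard deviations of the marginal grid posteriors of
#' `log k` and `beta`.
#'
#' @param engine An [ado_engine()].
#' @return A tibble with columns `parameter` (`"log_k"`, `"beta"`), `mean`
#'   and `sd`.
#' @export
point_estimates <- function(engine) {
  m <- engine$mass
  stats_for <- function(x) {
    mu <- sum(m * x)
    c(mu, sqrt(max(sum(m * (x - mu)^2), 0)))
  }
  lk <- stats_for(engine$th_logk)
  be <- stats_for(engine$th_beta)
  tibble::tibble(
    parameter = c("log_k", "beta"),
    mean = c(lk[1], be[1]),
    sd = c(lk[2], be[2])
  )
}

#' Marginal credible interval for log k
#'
#' Equal-tailed interval of the marginal posterior of `log k`. The grid
#' posterior is interpreted as a piecewise-constant density over the grid
#' cells (each grid point representing the cell centred on it), and the
#' interval endpoints are the corresponding continuous quantiles, linearly
#' interpolated within cells. This keeps intervals meaningful even when
#' the mass concentrates on very few cells.
#'
#' @param engine An [ado_engine()].
#' @param level Coverage level, default 0.95.
#' @return A tibble with columns `lo` and `hi`.
#' @export
credible_interval_logk <- function(engine, level = 0.95) {
  marg <- rowSums(matrix(engine$mass, length(engine$log_k), length(engine$beta)))
  h <- engine$log_k[2] - engine$log_k[1]
  edges <- c(engine$log_k - h / 2, engine$log_k[length(engine$log_k)] + h / 2)
  cdf <- c(0, cumsum(marg))
  qtl <- function(a) {
    j <- which(cdf >= a)[1] # right edge index of the crossing cell
    if (j == 1) return(edges[1])
    edges[j - 1] + (a - cdf[j - 1]) / marg[j - 1] * h
  }
  a <- (1 - level) / 2
  tibble::tibble(lo = qtl(a), hi = qtl(1 - a))
}

#' Session log of an engine
#'
#' @param engine An [ado_engine()].
#' @return A tibble with one row per observed trial: `trial`, the design
#'   columns and `choice`.
#' @export
session_log <- function(engine) {
  if (length(engine$history) == 0) {
    return(tibble::tibble(
      trial = integer(), r_ss = numeric(), t_ss = numeric(),
      r_ll = numeric(), t_ll = numeric(), choice = numeric()
    ))
  }
  h <- do.call(rbind, engine$history)
  tibble::tibble(
    trial = seq_len(nrow(h)),
    r_ss = h[, "r_ss"], t_ss = h[, "t_ss"],
    r_ll = h[, "r_ll"], t_ll = h[, "t_ll"], choice = h[, "choice"]
  )
}

#' Rebuild an engine posterior from its recorded history
#'
#' Replays the stored trials on a freshly reset copy of the engine. The
#' result must match the live posterior exactly (replay consistency).
#'
#' @param engine An [ado_engine()].
#' @return An engine with the same posterior, rebuilt from history.
#' @export
replay_engine <- function(engine) {
  fresh <- ado_reset(engine)
  log <- session_log(engine)
  for (i in seq_len(nrow(log))) {
    fresh <- update_posterior(fresh, log[i, c("r_ss", "t_ss", "r_ll", "t_ll")],
                              log$choice[i])
  }
  fresh
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the engine's joint posterior
#'
#' @param x An [ado_engine()].
#' @param ... Unused.
#' @return A tibble with one row per grid cell: `log_k`, `beta`, `mass`.
#' @export
tidy.ado_engine <- function(x, ...) {
  tibble::tibble(log_k = x$th_logk, beta = x$th_beta, mass = x$mass)
}

#' One-row summary of an engine fit
#'
#' @param x An [ado_engine()].
#' @param ... Unused.
#' @return A tibble with posterior means/SDs of both parameters and the
#'   number of observed trials.
#' @export
glance.ado_engine <- function(x, ...) {
  est <- point_estimates(x)
  tibble::tibble(
    mean_log_k = est$mean[1], sd_log_k = est$sd[1],
    mean_beta = est$mean[2], sd_beta = est$sd[2],
    n_trials = x$trial_index
  )
}
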