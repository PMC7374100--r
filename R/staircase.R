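#' Protocol delays of the adjusting-amount staircase
#'
#' The seven delays of the conventional task — 1 week, 2 weeks, 1 month,
#' 6 months, 1 year, 3 years, 10 years — mapped to calendar-approximate day
#' counts.
#'
#' @return Integer vector of delays in days.
#' @export
sc_delays <- function() c(7, 14, 30, 180, 365, 1095, 3650)

# fixed adjustment schedule: each increment is half the preceding one
.sc_increments <- c(200, 100, 50, 25, 12.5)

#' Start a staircase for one delay
#'
#' The first choice is $400 now versus $800 at the given delay; after each
#' choice the immediate amount moves by the current increment in the
#' direction that makes the unchosen option more attractive, and the
#' increment halves (200, 100, 50, 25, 12.5).
#'
#' @param delay Later-reward delay in days.
#' @return A `staircase` state object.
#' @export
sc_start <- function(delay) {
  if (delay <= 0) rlang::abort("`delay` must be > 0 days.")
  structure(
    list(delay = delay, immediate_amount = 400, step_index = 0L,
         indifference_point = NULL),
    class = "staircase"
  )
}

#' Advance a staircase by one choice
#'
#' For the first five choices the immediate amount is decreased by the
#' current increment if the immediate option was chosen and increased if
#' the delayed option was chosen, and the increment halves. The sixth
#' choice, made at the amount produced by the final $12.5 adjustment,
#' terminates the staircase; that amount is the recorded indifference
#' point.
#'
#' @param state A `staircase` state from [sc_start()].
#' @param choice 0 (immediate/smaller-sooner) or 1 (delayed/larger-later).
#' @return The updated state. After the terminal choice,
#'   `sc_is_done(state)` is `TRUE` and `state$indifference_point` holds the
#'   indifference point in USD.
#' @export
sc_next <- function(state, choice) {
  if (!inherits(state, "staircase")) rlang::abort("`state` must be a staircase.")
  if (sc_is_done(state)) rlang::abort("staircase already terminated.")
  if (!choice %in% c(0, 1)) rlang::abort("`choice` must be 0 or 1.")
  i <- state$step_index + 1L
  if (i <= length(.sc_increments)) {
    step <- .sc_increments[i]
    state$immediate_amount <- state$immediate_amount +
      if (choice == 1) step else -step
  } else {
    state$indifference_point <- state$immediate_amount
  }
  state$step_index <- i
  state
}

#' @rdname sc_next
#' @export
sc_is_done <- function(state) state$step_index >= 6L

#' Current design presented by a staircase
#'
#' @param state A `staircase` state.
#' @return A one-row design tibble: the immediate amount now versus $800 at
#'   the staircase's delay.
#' @export
sc_design <- function(state) {
  dd_design(r_ss = state$immediate_amount, t_ss = 0, r_ll = 800,
            t_ll = state$delay)
}

#' Run a full staircase session
#'
#' Runs the six-choice adjusting-amount staircase at each of the seven
#' protocol delays, presenting delays in a seeded random order, for 42
#' choices in total.
#'
#' @param choose A function `(design) -> {0, 1}` supplying each choice;
#'   typically an agent's response rule (see [agent_responder()]).
#' @param seed Integer seed controlling the delay order (and the choice
#'   source, if stochastic, when it draws from the session RNG stream).
#'
#' @return A list with `session` — a 42-row tibble of `trial`, design
#'   columns and `choice` — and `indifference_points`, a 7-row tibble of
#'   `delay_days` and `indifference_point`.
#' @export
run_staircase <- function(choose, seed = 1L) {
  withr::with_seed(seed, {
    delays <- sample(sc_delays())
    rows <- vector("list", 42L)
    ips <- numeric(length(delays))
    t <- 0L
    for (j in seq_along(delays)) {
      st <- sc_start(delays[j])
      while (!sc_is_done(st)) {
        d <- sc_design(st)
        ch <- choose(d)
        t <- t + 1L
        rows[[t]] <- c(r_ss = d$r_ss, t_ss = d$t_ss, r_ll = d$r_ll,
                       t_ll = d$t_ll, choice = ch)
        st <- sc_next(st, ch)
      }
      ips[j] <- st$indifference_point
    }
    h <- do.call(rbind, rows)
    list(
      session = tibble::tibble(
        trial = seq_len(nrow(h)),
        r_ss = h[, "r_ss"], t_ss = h[, "t_ss"],
        r_ll = h[, "r_ll"], t_ll = h[, "t_ll"], choice = h[, "choice"]
      ),
      indifference_points = tibble::tibble(
        delay_days = delays, indifference_point = ips
      )
    )
  })
}

# scalar-arithmetic staircase simulation for a softmax-hyperbolic agent;
# reproduces run_staircase(agent_responder(agent), seed) exactly (same RNG
# draws, same clamped choice probabilities) without per-trial data frames
simulate_staircase <- function(agent, seed) {
  k <- exp(agent$true_log_k)
  b <- agent$true_beta
  lap <- agent$lapse
  withr::with_seed(seed, {
    delays <- sample(sc_delays())
    n <- 6L * length(delays)
    r_ss <- numeric(n); t_ll <- numeric(n); choice <- numeric(n)
    ips <- numeric(length(delays))
    t <- 0L
    for (j in seq_along(delays)) {
      dly <- delays[j]
      v_ll <- 800 / (1 + k * dly)
      amt <- 400
      for (step in 1:6) {
        p <- stats::plogis(b * (v_ll - amt / (1 + k * 0)))
        p <- pmin(pmax(p, .p_eps), 1 - .p_eps)
        p <- (1 - lap) * p + lap * 0.5
        ch <- stats::rbinom(1L, 1L, p)
        t <- t + 1L
        r_ss[t] <- amt; t_ll[t] <- dly; choice[t] <- ch
        if (step <= 5L) {
          amt <- amt + if (ch == 1) .sc_increments[step] else -.sc_increments[step]
        }
      }
      ips[j] <- amt
    }
    list(
      session = tibble::tibble(
        trial = seq_len(n), r_ss = r_ss, t_ss = 0, r_ll = 800,
        t_ll = t_ll, choice = choice
      ),
      indifference_points = tibble::tibble(
        delay_days = delays, indifference_point = ips
      )
    )
  })
}

#' Fit the hyperbolic model to a completed session
#'
#' Batch grid-posterior fit: the same parameter grid the adaptive engine
#' uses, updated in one pass with every choice of the session. Used for the
#' staircase comparator, where stimuli follow the fixed schedule rather
#' than optimization, and equal by likelihood factorization to sequential
#' trial-by-trial updating.
#'
#' @param session A session tibble with design columns and `choice`.
#' @param engine An [ado_engine()] supplying grid and prior; its posterior
#'   state is ignored (the fit starts from the prior).
#' @return The engine with posterior conditioned on the whole session.
#' @export
fit_dd_session <- function(session, engine = ado_engine()) {
  engine <- ado_reset(engine)
  if (nrow(session) == 0) return(engine)
  if (!all(session$choice %in% c(0, 1))) {
    rlang::abort("`choice` must be coded 0/1.")
  }
  # one batch pass: per-trial log-likelihood matrix, summed over trials
  p1 <- choice_prob_matrix(session, engine$th_logk, engine$th_beta,
                           entropy = FALSE)$p
  ll <- log(p1)
  sel0 <- session$choice == 0
  ll[, sel0] <- log1p(-p1[, sel0, drop = FALSE])
  logm <- log(engine$mass) + rowSums(ll)
  logm <- logm - max(logm)
  m <- exp(logm)
  engine$mass <- m / sum(m)
  engine$trial_index <- nrow(session)
  engine$history <- lapply(seq_len(nrow(session)), function(i) {
    c(r_ss = session$r_ss[i], t_ss = session$t_ss[i],
      r_ll = session$r_ll[i], t_ll = session$t_ll[i],
      choice = session$choice[i])
  })
  engine
}

#' Per-trial cumulative parameter estimates for a session
#'
#' Refits the grid posterior on the first `t` choices for each requested
#' `t`, giving the estimate trajectory that cumulative reliability curves
#' are computed from. For adaptively generated sessions these estimates are
#' already logged trial-by-trial; this function serves fixed-schedule
#' (staircase) sessions, conventionally evaluated every third trial.
#'
#' @param session A session tibble with design columns and `choice`.
#' @param engine Grid/prior template, as in [fit_dd_session()].
#' @param at Integer vector of trial indices to evaluate; default every
#'   trial.
#' @return A tibble with columns `trial`, `post_mean_logk`, `post_sd_logk`,
#'   `post_mean_beta`, `post_sd_beta`.
#' @export
cumulative_estimates <- function(session, engine = ado_engine(),
                                 at = seq_len(nrow(session))) {
  at <- sort(unique(as.integer(at)))
  if (length(at) && max(at) > nrow(session)) {
    rlang::abort("`at` exceeds the session length.")
  }
  engine <- ado_reset(engine)
  # per-trial likelihood matrix (theta x trial); sequential linear-space
  # updates with renormalization after each trial keep everything finite
  p1 <- choice_prob_matrix(session, engine$th_logk, engine$th_beta,
                           entropy = FALSE)$p
  out <- matrix(NA_real_, length(at), 4)
  m <- engine$mass
  next_i <- 1L
  for (i in seq_len(if (length(at)) max(at) else 0L)) {
    m <- m * if (session$choice[i] == 1) p1[, i] else 1 - p1[, i]
    m <- m / sum(m)
    if (next_i <= length(at) && at[next_i] == i) {
      mu_k <- sum(m * engine$th_logk)
      mu_b <- sum(m * engine$th_beta)
      out[next_i, ] <- c(
        mu_k, sqrt(max(sum(m * (engine$th_logk - mu_k)^2), 0)),
        mu_b, sqrt(max(sum(m * (engine$th_beta - mu_b)^2), 0))
      )
      next_i <- next_i + 1L
    }
  }
  tibble::tibble(
    trial = at,
    post_mean_logk = out[, 1], post_sd_logk = out[, 2],
    post_mean_beta = out[, 3], post_sd_beta = out[, 4]
  )
}
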