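#' Hyperbolic subjective value
#'
#' Discounts a delayed reward with the hyperbolic model
#' \deqn{V = A / (1 + kD)}
#' where `A` is the objective amount, `D` the delay in days and `k > 0` the
#' discounting rate. At zero delay the subjective value equals the amount;
#' the value decreases strictly in both delay and discounting rate.
#'
#' @param amount Reward amount in USD; strictly positive. Vectorised.
#' @param delay Delay to receipt in days; non-negative. Vectorised.
#' @param k Hyperbolic discounting rate (1/days); strictly positive.
#'   Vectorised.
#'
#' @return Numeric vector of subjective values (USD-equivalent).
#' @examples
#' subjective_value(800, 365, 0.01)
#' subjective_value(800, 0, 0.05) # == 800, no discounting at zero delay
#' @export
subjective_value <- function(amount, delay, k) {
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    rlang::abort("`amount` must be finite and > 0.")
  }
  if (any(!is.finite(delay)) || any(delay < 0)) {
    rlang::abort("`delay` must be finite and >= 0.")
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    rlang::abort("`k` must be finite and > 0.")
  }
  amount / (1 + k * delay)
}

#' Construct a choice design
#'
#' A design is one trial's stimulus: a smaller-sooner (SS) option
#' `r_ss` at delay `t_ss` against a larger-later (LL) option `r_ll` at delay
#' `t_ll`. Amounts are USD, delays days. All arguments are vectorised and
#' recycled to a common length.
#'
#' @param r_ss,t_ss Sooner reward (USD, > 0) and its delay (days, >= 0).
#' @param r_ll,t_ll Later reward (USD, > `r_ss`) and its delay
#'   (days, > `t_ss`).
#'
#' @return A tibble with columns `r_ss`, `t_ss`, `r_ll`, `t_ll`, one row per
#'   design.
#' @examples
#' dd_design(r_ss = 400, t_ss = 0, r_ll = 800, t_ll = 365)
#' @export
dd_design <- function(r_ss, t_ss = 0, r_ll = 800, t_ll) {
  d <- tibble::tibble(r_ss = r_ss, t_ss = t_ss, r_ll = r_ll, t_ll = t_ll)
  validate_design(d)
  d
}

validate_design <- function(d) {
  need <- c("r_ss", "t_ss", "r_ll", "t_ll")
  if (!all(need %in% names(d))) {
    rlang::abort(paste0(
      "design must have columns ",
      paste(need, collapse = ", "), "."
    ))
  }
  if (any(d$r_ss <= 0) || any(d$t_ss < 0)) {
    rlang::abort("designs require r_ss > 0 and t_ss >= 0.")
  }
  if (any(d$r_ss >= d$r_ll)) {
    rlang::abort("designs require r_ss < r_ll (sooner reward strictly smaller).")
  }
  if (any(d$t_ss >= d$t_ll)) {
    rlang::abort("designs require t_ss < t_ll (sooner option strictly sooner).")
  }
  invisible(d)
}

# probability floor keeping log-likelihoods finite under extreme beta * dV
.p_eps <- 1e-12

#' Softmax probability of choosing the later-larger option
#'
#' Luce's choice rule applied to the difference in hyperbolic subjective
#' values:
#' \deqn{P(LL) = \frac{1}{1 + e^{\beta (V_{SS} - V_{LL})}}}
#' with inverse temperature `beta` acting directly on the dollar-scale value
#' difference. `beta = 0` yields 0.5 for every design; larger `beta` makes
#' choices more deterministic. Computed via the numerically stable logistic
#' and clamped to `[1e-12, 1 - 1e-12]` so downstream log-likelihoods stay
#' finite.
#'
#' @param design A design tibble (see [dd_design()]); one or more rows.
#' @param log_k Natural-log discounting rate. Scalar or vector recycled
#'   against the design rows.
#' @param beta Inverse temperature, >= 0. Recycled likewise.
#'
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' d <- dd_design(r_ss = 400, t_ss = 0, r_ll = 800, t_ll = 365)
#' p_choose_ll(d, log_k = log(1 / 365), beta = 1) # 0.5: equal values
#' @export
p_choose_ll <- function(design, log_k, beta) {
  validate_design(design)
  if (any(beta < 0)) rlang::abort("`beta` must be >= 0.")
  k <- exp(log_k)
  v_ss <- design$r_ss / (1 + k * design$t_ss)
  v_ll <- design$r_ll / (1 + k * design$t_ll)
  p <- stats::plogis(beta * (v_ll - v_ss))
  pmin(pmax(p, .p_eps), 1 - .p_eps)
}

#' Bernoulli log-likelihood of a choice session
#'
#' Sums `log P(choice)` over the trials of a session under the
#' hyperbolic/softmax model, with choices coded 0 = smaller-sooner and
#' 1 = larger-later. The result is additive over concatenated sessions and
#' invariant to trial order.
#'
#' @param session A tibble with design columns (`r_ss`, `t_ss`, `r_ll`,
#'   `t_ll`) and a `choice` column in `{0, 1}`. May be empty.
#' @param log_k,beta Model parameters as in [p_choose_ll()].
#'
#' @return A single log-probability, `<= 0`; `0` for an empty session.
#' @export
log_likelihood <- function(session, log_k, beta) {
  if (nrow(session) == 0) return(0)
  if (!"choice" %in% names(session)) {
    rlang::abort("`session` must have a `choice` column.")
  }
  if (!all(session$choice %in% c(0, 1))) {
    rlang::abort("`choice` must be coded 0 (smaller-sooner) or 1 (larger-later).")
  }
  p <- p_choose_ll(session, log_k, beta)
  sum(ifelse(session$choice == 1, log(p), log1p(-p)))
}
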