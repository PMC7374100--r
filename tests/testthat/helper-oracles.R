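# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

# Lin's concordance coefficient, population moments, written directly from
# the defining formula
ccc_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# mutual information I(theta; y | d) as an explicit double sum over grid
# cells and outcomes
utility_oracle <- function(engine, design) {
  p1 <- p_choose_ll(design, engine$th_logk, engine$th_beta)
  m <- engine$mass
  marg1 <- sum(m * p1)
  marg0 <- sum(m * (1 - p1))
  total <- 0
  for (i in seq_along(m)) {
    for (y in 0:1) {
      py <- if (y == 1) p1[i] else 1 - p1[i]
      marg <- if (y == 1) marg1 else marg0
      if (m[i] > 0 && py > 0) total <- total + m[i] * py * log(py / marg)
    }
  }
  total
}

# posterior after a batch of records: direct normalization of
# prior x product of Bernoulli likelihoods, one explicit loop per trial
posterior_oracle <- function(engine, session) {
  m <- engine$prior_mass
  for (i in seq_len(nrow(session))) {
    p1 <- p_choose_ll(session[i, ], engine$th_logk, engine$th_beta)
    m <- m * if (session$choice[i] == 1) p1 else 1 - p1
  }
  m / sum(m)
}

# a small engine used across tests (cheap to build repeatedly)
toy_engine <- function(...) {
  ado_engine(
    n_k = 12, n_beta = 6,
    design_space = ado_design_space(r_ss = seq(100, 700, by = 100),
                                    t_ll = c(30, 365, 3650)),
    ...
  )
}

# deterministic value-thresholding responder (the beta -> Inf limit)
threshold_chooser <- function(k) {
  function(design) {
    v_ll <- design$r_ll / (1 + k * design$t_ll)
    v_ss <- design$r_ss / (1 + k * design$t_ss)
    as.numeric(v_ll > v_ss)
  }
}
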