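# dense random MDP (every transition probability positive)
random_dense_mdp <- function(seed, ns = 10L, na = 2L, gamma = 0.95) {
  set.seed(seed)
  tr <- array(stats::runif(ns * na * ns), c(ns, na, ns))
  for (s in seq_len(ns)) for (a in seq_len(na))
    tr[s, a, ] <- tr[s, a, ] / sum(tr[s, a, ])
  rw <- matrix(stats::runif(ns * na), ns, na)
  tabular_mdp(rw, tr, gamma)
}

random_prob_vec <- function(n) {
  x <- stats::rgamma(n, 1)
  x / sum(x)
}

# independent oracle: the lambda-return from its definition as the
# exponentially weighted average of k-step returns
lambda_return_definitional <- function(rewards, values, gamma, lam, horizon) {
  disc <- cumsum(gamma^(seq_len(horizon) - 1) * rewards[seq_len(horizon)])
  g <- disc + gamma^seq_len(horizon) * values[seq_len(horizon)]
  sum((1 - lam) * lam^(seq_len(horizon) - 1) * g)
}

# dataset whose empirical frequencies equal the MDP's transition rows exactly
# (requires rows with denominator-`denom` rational probabilities)
exact_frequency_dataset <- function(mdp, denom = 10L) {
  rows <- list()
  for (s in seq_len(mdp$n_states)) for (a in seq_len(mdp$n_actions)) {
    cnt <- round(mdp$transitions[s, a, ] * denom)
    stopifnot(sum(cnt) == denom)
    for (k in which(cnt > 0))
      rows[[length(rows) + 1L]] <-
        data.frame(state = rep(s, cnt[k]), action = a, next_state = k,
                   reward = mdp$rewards[s, a])
  }
  ds <- do.call(rbind, rows)
  class(ds) <- c("transition_dataset", "data.frame")
  ds
}
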