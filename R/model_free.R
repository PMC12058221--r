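#' Configuration for regularized fitted Q-iteration
#'
#' @param gamma true discount used in the weighted-average Bellman targets.
#' @param n_iterations number of target/fit cycles (>= 1).
#' @param epsilon_mode `"global"` (fixed scalar `epsilon_global`),
#'   `"per_sa_sse"` (re-estimated each iteration from the sum of squared
#'   target errors), `"per_sa_multinomial"` (re-estimated each iteration from
#'   the multinomial bias-variance form), or `"oracle_Q"` (computed once from
#'   a supplied true Q, the no-estimation-error diagnostic).
#' @param epsilon_global scalar in `[0, 1]` for `"global"`.
#' @param rng_seed seed for the random initialization of the per-pair
#'   epsilon values in the adaptive modes.
#' @param q_true true Q table (required for `"oracle_Q"`).
#' @param store_history keep per-iteration Q/policy/epsilon snapshots.
#' @return list of class `fqi_config`.
#' @export
fqi_config <- function(gamma, n_iterations = 50L,
                       epsilon_mode = c("global", "per_sa_sse",
                                        "per_sa_multinomial", "oracle_Q"),
                       epsilon_global = 0, rng_seed = 1L, q_true = NULL,
                       store_history = FALSE) {
  epsilon_mode <- match.arg(epsilon_mode)
  if (n_iterations < 1L) stop("`n_iterations` must be >= 1")
  if (epsilon_global < 0 || epsilon_global > 1)
    stop("`epsilon_global` must lie in [0, 1]")
  if (epsilon_mode == "oracle_Q" && is.null(q_true))
    stop("oracle_Q mode requires `q_true`")
  structure(list(gamma = gamma, n_iterations = as.integer(n_iterations),
                 epsilon_mode = epsilon_mode,
                 epsilon_global = epsilon_global,
                 rng_seed = as.integer(rng_seed), q_true = q_true,
                 store_history = store_history),
            class = "fqi_config")
}

#' Fitted Q-iteration with a weighted-average Bellman update
#'
#' Tabular FQI on a batch of (s, a, s') tuples with known rewards. Each
#' iteration computes per-tuple targets
#' `q = R(s, a) + gamma (1 - eps(s, a)) max_a' Qhat(s', a')
#'             + gamma eps(s, a) * mean_s'' max_a' Qhat(s'', a')`
#' (the uniform-regularization-row instantiation of the weighted-average
#' update), fits `Qhat(s, a)` as the per-(s, a) mean of its targets — the
#' exact least-squares solution of a one-hot linear regression — and then
#' refreshes `eps` according to the configured mode. State-action pairs
#' absent from the data keep their initialization (zero) and are reported.
#'
#' @param ds a `transition_dataset` (or data.frame with `state`, `action`,
#'   `next_state`).
#' @param rewards known reward matrix `n_states x n_actions`.
#' @param cfg an [fqi_config()].
#' @param n_states,n_actions MDP dimensions.
#' @return list with `q`, `policy`, `epsilon` (final matrix), `unobserved`
#'   ((state, action) pairs never seen), and — when
#'   `cfg$store_history` — `epsilon_history`, `policy_history`, `q_history`.
#' @export
fqi_regularized <- function(ds, rewards, cfg, n_states, n_actions) {
  stopifnot(inherits(cfg, "fqi_config"))
  if (nrow(ds) == 0L) stop("dataset is empty")
  ns <- n_states; na <- n_actions
  counts <- count_transitions(ds, ns, na)
  nmat <- apply(counts, c(1, 2), sum)
  sa <- ds$state + (ds$action - 1L) * ns
  tab <- tabulate(sa, nbins = ns * na)
  observed <- tab > 0
  set.seed(cfg$rng_seed)
  eps <- switch(cfg$epsilon_mode,
    global = matrix(cfg$epsilon_global, ns, na),
    oracle_Q = epsilon_star_sse(counts, cfg$q_true,
                                greedy_policy(cfg$q_true), rewards,
                                cfg$gamma),
    matrix(stats::runif(ns * na), ns, na))
  t_mle <- if (cfg$epsilon_mode == "per_sa_multinomial")
    mle_transition(counts) else NULL
  q <- matrix(0, ns, na)
  eps_hist <- pol_hist <- q_hist <- if (cfg$store_history) vector("list", cfg$n_iterations)
  for (it in seq_len(cfg$n_iterations)) {
    v <- rowmax(q)
    qreg <- mean(v)
    evec <- eps[cbind(ds$state, ds$action)]
    targets <- rewards[cbind(ds$state, ds$action)] +
      cfg$gamma * (1 - evec) * v[ds$next_state] +
      cfg$gamma * evec * qreg
    sums <- numeric(ns * na)
    agg <- rowsum(targets, group = sa)
    sums[as.integer(rownames(agg))] <- agg
    qvec <- as.vector(q)
    qvec[observed] <- sums[observed] / tab[observed]
    q <- matrix(qvec, ns, na)
    pol <- greedy_policy(q)
    if (cfg$epsilon_mode == "per_sa_sse") {
      eps <- epsilon_star_sse(counts, q, pol, rewards, cfg$gamma)
    } else if (cfg$epsilon_mode == "per_sa_multinomial") {
      eps <- epsilon_star_multinomial(t_mle, nmat, q, pol, rewards, cfg$gamma)
    }
    if (cfg$store_history) {
      eps_hist[[it]] <- eps
      pol_hist[[it]] <- pol
      q_hist[[it]] <- q
    }
  }
  unobs <- which(matrix(!observed, ns, na), arr.ind = TRUE)
  colnames(unobs) <- c("state", "action")
  out <- list(q = q, policy = greedy_policy(q), epsilon = eps,
              unobserved = unobs)
  if (cfg$store_history) {
    out$epsilon_history <- eps_hist
    out$policy_history <- pol_hist
    out$q_history <- q_hist
  }
  out
}

#' Per-pair shrinkage minimizing the sum of squared target errors
#'
#' For a fixed policy `pi` with values `V_k = Q^pi(s_k, pi(s_k))` and
#' `v_avg = mean_k V_k`, the contribution of pair (i, j) to the
#' sum of squared errors is
#' `sum_k c_{i,j,k} (R(i,j) + gamma (1 - eps) V_k + gamma eps v_avg
#'                   - Q^pi(i, j))^2`,
#' a quadratic in `eps` minimized in closed form and clamped to `[0, 1]`.
#' Pairs with no data get 1 (full shrinkage); a vanishing quadratic
#' coefficient (every observed next-state value equal to `v_avg`) leaves the
#' error flat in `eps` and returns 0 by convention. The unclamped stationary
#' points are attached as attribute `"unclamped"`.
#'
#' @param counts count tensor.
#' @param q_pi Q table of the current policy iterate.
#' @param policy policy consistent with `q_pi`.
#' @param rewards reward matrix.
#' @param gamma discount.
#' @return `n_states x n_actions` matrix of shrinkage weights.
#' @export
epsilon_star_sse <- function(counts, q_pi, policy, rewards, gamma) {
  d <- dim(counts)
  ns <- d[1]; na <- d[2]
  vvec <- q_pi[cbind(seq_len(ns), policy)]
  v_avg <- mean(vvec)
  eps <- matrix(1, ns, na)
  unclamped <- matrix(NA_real_, ns, na)
  bvec <- gamma * (v_avg - vvec)           # d(target)/d(eps) per next state
  for (a in seq_len(na)) {
    cmat <- matrix(counts[, a, ], ns, ns)
    nn <- rowSums(cmat)
    avec_base <- rewards[, a] - q_pi[, a]  # per-(i, a) constant offset
    # per row i: sum_k c_ik (A_ik + eps B_k)^2, A_ik = avec_base[i] + gamma V_k
    cb2 <- as.numeric(cmat %*% bvec^2)
    cgb <- as.numeric(cmat %*% (bvec * gamma * vvec))
    cb <- as.numeric(cmat %*% bvec)
    num <- -(avec_base * cb + cgb)
    for (i in seq_len(ns)) {
      if (nn[i] == 0) next
      if (cb2[i] <= 0) { eps[i, a] <- 0; next }
      u <- num[i] / cb2[i]
      unclamped[i, a] <- u
      eps[i, a] <- min(max(u, 0), 1)
    }
  }
  attr(eps, "unclamped") <- unclamped
  eps
}

#' Matrix-form assembly of the SSE shrinkage weights
#'
#' Assembles the same unclamped stationary points as [epsilon_star_sse()]
#' from the stacked count matrix `C` (one row per (state, action), one
#' column per next state) and the policy selector `Pi` mapping the
#' vectorized Q to next-state values — the diagonal of the matrix expression
#' for the simultaneous solution. Used as a cross-check of the scalar route.
#'
#' @inheritParams epsilon_star_sse
#' @return `n_states x n_actions` matrix of unclamped stationary points
#'   (`NA` where the quadratic degenerates or the pair has no data).
#' @export
epsilon_star_sse_matrix <- function(counts, q_pi, policy, rewards, gamma) {
  d <- dim(counts)
  ns <- d[1]; na <- d[2]
  cmat <- matrix(counts, ns * na, ns)  # row order: state fastest, then action
  pim <- matrix(0, ns, ns * na)                            # V = Pi %*% vec(Q)
  pim[cbind(seq_len(ns), seq_len(ns) + (policy - 1L) * ns)] <- 1
  vvec <- as.numeric(pim %*% as.vector(q_pi))
  v_avg <- mean(vvec)
  b <- gamma * (v_avg - vvec)
  avec <- as.vector(rewards) - as.vector(q_pi)
  cb2 <- as.numeric(cmat %*% b^2)
  num <- -(avec * as.numeric(cmat %*% b) +
             as.numeric(cmat %*% (b * gamma * vvec)))
  out <- num / cb2
  out[cb2 <= 0 | rowSums(cmat) == 0] <- NA_real_
  matrix(out, ns, na)
}

#' Per-pair shrinkage from the multinomial bias-variance form
#'
#' Treats the empirical next-state frequencies at each pair as a multinomial
#' draw. With `m = sum_k T_k V_k` and
#' `s2 = sum_k T_k V_k^2 - m^2` (the sampling variance of one draw of the
#' next-state value), the regularized target has
#' `bias = gamma * eps * (v_avg - m)` and
#' `variance = gamma^2 (1 - eps)^2 s2 / n`, giving the closed-form minimizer
#' `eps* = (s2 / n) / ((v_avg - m)^2 + s2 / n)`, clamped to `[0, 1]`.
#' `n = 0` gives 1; a degenerate objective (zero variance and zero bias gap)
#' gives 0 by convention.
#'
#' @param t_rows transition array of plug-in rows (e.g. the MLE).
#' @param n matrix of per-pair observation counts.
#' @param q_pi Q table of the current policy iterate.
#' @param policy policy consistent with `q_pi`.
#' @param rewards reward matrix (unused by the minimizer itself; kept for a
#'   uniform signature across the two methods).
#' @param gamma discount.
#' @return `n_states x n_actions` matrix of shrinkage weights.
#' @export
epsilon_star_multinomial <- function(t_rows, n, q_pi, policy, rewards,
                                     gamma) {
  d <- dim(t_rows)
  ns <- d[1]; na <- d[2]
  vvec <- q_pi[cbind(seq_len(ns), policy)]
  v_avg <- mean(vvec)
  eps <- matrix(1, ns, na)
  for (a in seq_len(na)) {
    rows <- matrix(t_rows[, a, ], ns, ns)
    m <- as.numeric(rows %*% vvec)
    s2 <- pmax(as.numeric(rows %*% vvec^2) - m^2, 0)
    for (i in seq_len(ns)) {
      if (n[i, a] == 0) next
      varpart <- s2[i] / n[i, a]
      gap2 <- (v_avg - m[i])^2
      eps[i, a] <- if (varpart + gap2 <= 0) 0 else varpart / (gap2 + varpart)
    }
  }
  eps
}

#' Machine-check the model-free discount equivalence
#'
#' Runs FQI twice on the same dataset: once with planning discount
#' `gamma * (1 - epsilon)` and no shrinkage, once with discount `gamma` and
#' the weighted-average update at shared `epsilon`. The two runs must produce
#' identical greedy policies at every iteration up to numerical ties
#' (Q-gap < `tol`). Requires every (state, action) pair to appear in the
#' data (otherwise the constant-offset argument behind the equivalence
#' breaks at the untouched initialization entries).
#'
#' @param ds a `transition_dataset`.
#' @param rewards reward matrix.
#' @param gamma true discount.
#' @param epsilon shared shrinkage weight in `(0, 1]`.
#' @param n_iterations FQI iterations.
#' @param n_states,n_actions MDP dimensions.
#' @param tol tie tolerance on Q-gaps.
#' @return list with `equivalent`, `n_disagreements`, `first_disagreement`
#'   (iteration index or `NA`), and the two final fits `fit_discount`,
#'   `fit_weighted`.
#' @export
verify_theorem2 <- function(ds, rewards, gamma, epsilon, n_iterations = 30L,
                            n_states, n_actions, tol = 1e-8) {
  if (epsilon <= 0 || epsilon > 1) stop("`epsilon` must be in (0, 1]")
  cfg1 <- fqi_config(gamma = gamma * (1 - epsilon),
                     n_iterations = n_iterations, epsilon_mode = "global",
                     epsilon_global = 0, store_history = TRUE)
  cfg2 <- fqi_config(gamma = gamma, n_iterations = n_iterations,
                     epsilon_mode = "global", epsilon_global = epsilon,
                     store_history = TRUE)
  f1 <- fqi_regularized(ds, rewards, cfg1, n_states, n_actions)
  f2 <- fqi_regularized(ds, rewards, cfg2, n_states, n_actions)
  ndis <- 0L
  first <- NA_integer_
  for (it in seq_len(n_iterations)) {
    cmp <- compare_policies(list(q = f1$q_history[[it]],
                                 policy = f1$policy_history[[it]]),
                            list(q = f2$q_history[[it]],
                                 policy = f2$policy_history[[it]]), tol)
    if (!cmp$equivalent) {
      ndis <- ndis + nrow(cmp$report)
      if (is.na(first)) first <- it
    }
  }
  list(equivalent = ndis == 0L, n_disagreements = ndis,
       first_disagreement = first, fit_discount = f1, fit_weighted = f2)
}
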