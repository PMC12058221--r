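#' Construct a tabular Markov decision process
#'
#' A finite MDP is defined by a reward table `R(s, a)`, a transition tensor
#' `T(s, a, s')` whose rows are probability distributions over successor
#' states, and a discount factor `gamma` in `[0, 1)`. States and actions are
#' 1-based integer indices inside R; serialized files use 0-based indices
#' (see [write_mdp_json()]).
#'
#' @param rewards numeric matrix, `n_states x n_actions`.
#' @param transitions numeric array, `n_states x n_actions x n_states`;
#'   `transitions[s, a, ]` must sum to 1.
#' @param gamma discount factor in `[0, 1)` under which policies are
#'   ultimately evaluated.
#' @param name optional environment name carried along for reporting.
#' @return An object of class `tabular_mdp` with elements `n_states`,
#'   `n_actions`, `rewards`, `transitions`, `gamma`.
#' @examples
#' mdp <- tabular_mdp(matrix(c(1, 0), 1, 2), array(1, c(1, 2, 1)), gamma = 0.9)
#' solve_optimal(mdp)$policy
#' @export
tabular_mdp <- function(rewards, transitions, gamma, name = NULL) {
  rewards <- as.matrix(rewards)
  ns <- nrow(rewards)
  na <- ncol(rewards)
  if (!is.array(transitions) || length(dim(transitions)) != 3L)
    stop("`transitions` must be a 3-d array (state, action, next_state)")
  if (!all(dim(transitions) == c(ns, na, ns)))
    stop("`transitions` must have dimensions n_states x n_actions x n_states")
  if (!all(is.finite(rewards))) stop("rewards must be finite")
  if (!all(is.finite(transitions)) || any(transitions < -1e-12) ||
      any(transitions > 1 + 1e-12))
    stop("transition entries must lie in [0, 1]")
  rowsums <- apply(transitions, c(1, 2), sum)
  if (any(abs(rowsums - 1) > 1e-9))
    stop("every transition row T(s, a, .) must sum to 1 (tolerance 1e-9)")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma >= 1)
    stop("`gamma` must be a single number in [0, 1)")
  structure(
    list(n_states = ns, n_actions = na, rewards = rewards,
         transitions = transitions, gamma = gamma, name = name),
    class = "tabular_mdp")
}

#' @export
print.tabular_mdp <- function(x, ...) {
  cat(sprintf("tabular_mdp%s: %d states, %d actions, gamma = %g\n",
              if (is.null(x$name)) "" else paste0(" (", x$name, ")"),
              x$n_states, x$n_actions, x$gamma))
  invisible(x)
}

check_policy <- function(mdp, policy) {
  policy <- as.integer(policy)
  if (length(policy) != mdp$n_states ||
      any(policy < 1L) || any(policy > mdp$n_actions) || anyNA(policy))
    stop("`policy` must map every state to an action index in 1..n_actions")
  policy
}

rowmax <- function(q) {
  v <- q[, 1L]
  if (ncol(q) > 1L)
    for (a in 2:ncol(q)) v <- pmax(v, q[, a])
  v
}

#' Greedy policy of a Q table
#'
#' Ties are broken toward the lowest action index so that provably equivalent
#' solvers return identical policies.
#'
#' @param q numeric matrix of state-action values.
#' @return integer vector of actions, one per state.
#' @export
greedy_policy <- function(q) {
  max.col(q, ties.method = "first")
}

#' Solve an MDP by value iteration
#'
#' Iterates the Bellman optimality operator
#' `Q(s, a) <- R(s, a) + gamma_p * sum_s' T(s, a, s') max_a' Q(s', a')`
#' to a sup-norm fixed point. The planning discount `planning_gamma` may be
#' lower than the MDP's evaluation discount; running with
#' `planning_gamma < gamma` is discount regularization.
#'
#' @param mdp a [tabular_mdp()].
#' @param planning_gamma discount used for planning, in `[0, 1)`; defaults to
#'   the MDP's own `gamma`.
#' @param tol sup-norm stopping tolerance on successive Q iterates.
#' @param max_iter iteration cap; exceeding it is an error that names the
#'   residual.
#' @return list with `q` (matrix), `policy` (greedy, lowest-index ties),
#'   `iterations`, `residual`.
#' @export
solve_optimal <- function(mdp, planning_gamma = mdp$gamma, tol = 1e-10,
                          max_iter = 100000L) {
  stopifnot(inherits(mdp, "tabular_mdp"))
  if (planning_gamma < 0 || planning_gamma >= 1)
    stop("`planning_gamma` must be in [0, 1)")
  if (tol <= 0) stop("`tol` must be positive")
  ns <- mdp$n_states
  na <- mdp$n_actions
  tlist <- lapply(seq_len(na), function(a)
    matrix(mdp$transitions[, a, ], nrow = ns))
  q <- matrix(0, ns, na)
  residual <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    v <- rowmax(q)
    qn <- mdp$rewards
    for (a in seq_len(na))
      qn[, a] <- qn[, a] + planning_gamma * (tlist[[a]] %*% v)
    residual <- max(abs(qn - q))
    q <- qn
    if (residual < tol) {
      return(list(q = q, policy = greedy_policy(q), iterations = it,
                  residual = residual))
    }
  }
  stop(sprintf(
    "value iteration did not converge in %d iterations (residual %.3e > tol %.3e)",
    max_iter, residual, tol))
}

#' Evaluate a deterministic policy exactly
#'
#' Solves the linear Bellman system `V = R_pi + gamma * T_pi V` directly;
#' the system is nonsingular for any `eval_gamma < 1`.
#'
#' @param mdp a [tabular_mdp()].
#' @param policy integer action per state.
#' @param eval_gamma discount for evaluation, in `[0, 1)`; defaults to the
#'   MDP's `gamma`.
#' @return numeric vector of state values.
#' @export
evaluate_policy <- function(mdp, policy, eval_gamma = mdp$gamma) {
  stopifnot(inherits(mdp, "tabular_mdp"))
  if (eval_gamma < 0 || eval_gamma >= 1)
    stop("`eval_gamma` must be in [0, 1)")
  policy <- check_policy(mdp, policy)
  ns <- mdp$n_states
  idx <- cbind(seq_len(ns), policy)
  tpi <- t(vapply(seq_len(ns),
                  function(s) mdp$transitions[s, policy[s], ], numeric(ns)))
  rpi <- mdp$rewards[idx]
  as.numeric(solve(diag(ns) - eval_gamma * tpi, rpi))
}

#' Loss of a candidate policy relative to the optimal policy
#'
#' Mean over states of `V^{pi*}(s) - V^{pi}(s)`, both evaluated in the true
#' MDP under its true discount. Nonnegative (up to solver tolerance) because
#' no policy beats the optimal one.
#'
#' @param true_mdp the environment MDP.
#' @param candidate integer action per state.
#' @param v_star optional precomputed optimal value vector (reused across
#'   many candidates in sweeps).
#' @return single nonnegative number.
#' @export
policy_loss <- function(true_mdp, candidate, v_star = NULL) {
  if (is.null(v_star)) {
    pi_star <- solve_optimal(true_mdp)$policy
    v_star <- evaluate_policy(true_mdp, pi_star)
  }
  v_pi <- evaluate_policy(true_mdp, candidate)
  mean(v_star - v_pi)
}

#' Optimal state values of an MDP
#'
#' Convenience wrapper: greedy policy of the converged Q, evaluated exactly by
#' a linear solve.
#'
#' @inheritParams solve_optimal
#' @return numeric vector of optimal state values.
#' @export
optimal_values <- function(mdp, tol = 1e-10, max_iter = 100000L) {
  sol <- solve_optimal(mdp, mdp$gamma, tol = tol, max_iter = max_iter)
  evaluate_policy(mdp, sol$policy)
}

#' Truncated lambda-return decomposition
#'
#' For reward sequence `R_{t+1}, R_{t+2}, ...` and bootstrap values
#' `V(S_{t+1}), V(S_{t+2}), ...`, the lambda-return decomposes as
#' `R^lambda = sum_k (gamma*lambda)^k R_{t+k+1}
#'            + (1-lambda) gamma sum_k (lambda*gamma)^k V(S_{t+k+1})`.
#' Dropping the second (bootstrap) term — i.e. setting all values to zero —
#' leaves exactly the return that discount regularization computes with
#' planning discount `gamma_p = gamma * lambda`; the second term is the bias
#' of that truncation.
#'
#' @param rewards numeric vector `R_{t+1}, R_{t+2}, ...`.
#' @param values numeric vector `V(S_{t+1}), V(S_{t+2}), ...`, same length.
#' @param gamma discount in `[0, 1]`.
#' @param lam trace parameter lambda in `[0, 1]`.
#' @param horizon number of terms kept in the (finite) sums; must not exceed
#'   the sequence length.
#' @return list with `truncated` (discount-regularized part), `bias`
#'   (bootstrap part) and `full` (their sum, the lambda-return up to the
#'   geometric tail).
#' @export
lambda_return <- function(rewards, values, gamma, lam,
                          horizon = length(rewards)) {
  if (gamma < 0 || gamma > 1 || lam < 0 || lam > 1)
    stop("`gamma` and `lam` must lie in [0, 1]")
  if (length(rewards) != length(values))
    stop("`rewards` and `values` must have equal length")
  if (horizon < 1 || horizon > length(rewards))
    stop("`horizon` must be between 1 and the sequence length")
  k <- seq_len(horizon) - 1
  w <- (gamma * lam)^k
  truncated <- sum(w * rewards[seq_len(horizon)])
  bias <- (1 - lam) * gamma * sum(w * values[seq_len(horizon)])
  list(full = truncated + bias, truncated = truncated, bias = bias)
}

#' Discount-regularized return
#'
#' Plain truncated discounted sum `sum_k gamma_p^k R_{t+k+1}`; equals the
#' `truncated` component of [lambda_return()] when `gamma_p = gamma * lam`.
#'
#' @param rewards numeric reward sequence.
#' @param gamma_p planning discount in `[0, 1)`.
#' @return single number.
#' @export
discount_regularized_return <- function(rewards, gamma_p) {
  if (gamma_p < 0 || gamma_p >= 1) stop("`gamma_p` must be in [0, 1)")
  sum(gamma_p^(seq_along(rewards) - 1) * rewards)
}

#' Write / read a tabular MDP as JSON
#'
#' Row-major serialization with 0-based conventions:
#' `{"n_states", "n_actions", "gamma", "rewards", "transitions"}` where
#' `rewards` iterates actions fastest and `transitions` iterates next-state
#' fastest, then action, then state.
#'
#' @param mdp a [tabular_mdp()].
#' @param path file path.
#' @return `write_mdp_json` returns `path` invisibly; `read_mdp_json` returns
#'   a [tabular_mdp()].
#' @export
write_mdp_json <- function(mdp, path) {
  stopifnot(inherits(mdp, "tabular_mdp"))
  obj <- list(
    n_states = mdp$n_states,
    n_actions = mdp$n_actions,
    gamma = mdp$gamma,
    rewards = as.vector(t(mdp$rewards)),
    transitions = as.vector(aperm(mdp$transitions, c(3, 2, 1))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mdp_json
#' @export
read_mdp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ns <- obj$n_states
  na <- obj$n_actions
  rewards <- matrix(obj$rewards, ns, na, byrow = TRUE)
  # stored next-state fastest, then action, then state
  transitions <- aperm(array(obj$transitions, c(ns, na, ns)), c(3, 2, 1))
  tabular_mdp(rewards, transitions, obj$gamma)
}
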