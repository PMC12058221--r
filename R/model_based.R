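#' Convert between a planning discount and a mixing weight
#'
#' Planning with discount `gamma_p <= gamma` is equivalent to planning at the
#' true discount with the transition matrix shrunk by
#' `eps = (gamma - gamma_p) / gamma` toward a shared regularization row.
#' `gamma_p_from_epsilon()` is the inverse map `gamma_p = gamma * (1 - eps)`.
#'
#' @param gamma true discount, strictly positive.
#' @param gamma_p planning discount in `[0, gamma]`.
#' @param epsilon mixing weight in `[0, 1]`.
#' @return a single number.
#' @export
epsilon_from_gammas <- function(gamma, gamma_p) {
  if (gamma <= 0) stop("`gamma` must be positive (eps undefined at gamma = 0)")
  if (gamma_p < 0 || gamma_p > gamma)
    stop("`gamma_p` must lie in [0, gamma]")
  (gamma - gamma_p) / gamma
}

#' @rdname epsilon_from_gammas
#' @export
gamma_p_from_epsilon <- function(gamma, epsilon) {
  if (epsilon < 0 || epsilon > 1) stop("`epsilon` must lie in [0, 1]")
  gamma * (1 - epsilon)
}

#' Dirichlet prior magnitude implied by discount regularization
#'
#' Planning with `gamma_p` acts like a uniform Dirichlet prior whose total
#' magnitude at each (state, action) is proportional to the amount of data
#' there: `sum_k alpha_{i,j,k} = ((gamma - gamma_p) / gamma_p) * n(i, j)`,
#' split evenly over next states. The dependence on `n(i, j)` is the
#' undesirable property that motivates state-action-specific regularization:
#' better-observed pairs are regularized harder. `gamma_p = 0` has no finite
#' prior (the fully myopic, bandit-like case) and is an error.
#'
#' @param gamma true discount.
#' @param gamma_p planning discount in `(0, gamma]`.
#' @param counts count tensor from [count_transitions()].
#' @return array of Dirichlet parameters shaped like `counts`.
#' @export
prior_magnitude_from_counts <- function(gamma, gamma_p, counts) {
  if (gamma_p <= 0)
    stop(paste("`gamma_p` must be positive: gamma_p = 0 (the bandit case)",
               "implies a prior of infinite magnitude"))
  if (gamma_p > gamma) stop("`gamma_p` must not exceed `gamma`")
  d <- dim(counts)
  ns <- d[1]
  n <- apply(counts, c(1, 2), sum)
  total <- (gamma - gamma_p) / gamma_p * n
  alpha <- array(0, d)
  for (k in seq_len(ns)) alpha[, , k] <- total / ns
  alpha
}

#' Specify a transition-matrix regularizer
#'
#' @param method `"discount"` (plan at `gamma_p` on the MLE model),
#'   `"weighted_average"` (shrink each MLE row toward a shared row with
#'   weight `epsilon`), `"dirichlet_prior"` (posterior mean under `prior`),
#'   or `"sa_specific"` (weighted average with a per-(state, action)
#'   `epsilon` matrix).
#' @param gamma_p planning discount (discount method).
#' @param epsilon scalar in `[0, 1]`, or a matrix for `sa_specific`.
#' @param t_reg_row shared regularization distribution over next states;
#'   `NULL` means uniform.
#' @param prior scalar or array Dirichlet parameter (dirichlet_prior method).
#' @return object of class `regularization_spec`.
#' @export
regularization_spec <- function(method = c("discount", "weighted_average",
                                           "dirichlet_prior", "sa_specific"),
                                gamma_p = NULL, epsilon = NULL,
                                t_reg_row = NULL, prior = NULL) {
  method <- match.arg(method)
  if (method == "discount" && is.null(gamma_p))
    stop("discount method needs `gamma_p`")
  if (method %in% c("weighted_average", "sa_specific") && is.null(epsilon))
    stop(sprintf("%s method needs `epsilon`", method))
  if (method == "dirichlet_prior" && is.null(prior))
    stop("dirichlet_prior method needs `prior`")
  if (!is.null(epsilon) && (any(epsilon < 0) || any(epsilon > 1)))
    stop("`epsilon` entries must lie in [0, 1]")
  if (!is.null(t_reg_row)) {
    if (any(t_reg_row < 0) || abs(sum(t_reg_row) - 1) > 1e-9)
      stop("`t_reg_row` must be a probability vector")
  }
  structure(list(method = method, gamma_p = gamma_p, epsilon = epsilon,
                 t_reg_row = t_reg_row, prior = prior),
            class = "regularization_spec")
}

#' Shrink transition rows toward a shared regularization row
#'
#' Row-wise weighted average
#' `(1 - eps_{i,j}) * t_hat[i, j, ] + eps_{i,j} * t_reg_row`. With a scalar
#' `epsilon` this is the transition-matrix form of discount regularization;
#' a matrix `epsilon` gives state-action-specific shrinkage.
#'
#' @param t_hat transition array (e.g. from [mle_transition()]).
#' @param epsilon scalar or `n_states x n_actions` matrix in `[0, 1]`.
#' @param t_reg_row probability vector over next states; `NULL` = uniform.
#' @return transition array with stochastic rows.
#' @export
weighted_average_transition <- function(t_hat, epsilon, t_reg_row = NULL) {
  d <- dim(t_hat)
  ns <- d[1]; na <- d[2]
  if (is.null(t_reg_row)) t_reg_row <- rep(1 / ns, ns)
  if (length(t_reg_row) != ns || any(t_reg_row < 0) ||
      abs(sum(t_reg_row) - 1) > 1e-9)
    stop("`t_reg_row` must be a probability vector of length n_states")
  if (length(epsilon) == 1L) epsilon <- matrix(epsilon, ns, na)
  epsilon <- as.matrix(epsilon)
  if (!all(dim(epsilon) == c(ns, na)) || any(epsilon < 0) || any(epsilon > 1))
    stop("`epsilon` must be a scalar or n_states x n_actions matrix in [0, 1]")
  out <- array(0, d)
  for (k in seq_len(ns))
    out[, , k] <- (1 - epsilon) * t_hat[, , k] + epsilon * t_reg_row[k]
  out
}

#' Mean squared error of a shrunk empirical transition row
#'
#' For a true row `T`, `n` multinomial observations, and shrinkage weight
#' `eps` toward `t_reg_row` (uniform by default, the case for which the
#' closed form is derived), the row MSE decomposes into
#' `variance = (1 - eps)^2 (1/n) sum_k T_k (1 - T_k)` and
#' `bias2 = eps^2 sum_k (treg_k - T_k)^2`. Non-uniform `t_reg_row` uses the
#' same variance term with the generalized bias gap.
#'
#' @param t_row true transition probability row.
#' @param n number of observations (>= 1 for the variance term).
#' @param epsilon shrinkage weight in `[0, 1]`.
#' @param t_reg_row regularization row; `NULL` = uniform.
#' @return list with `mse`, `variance_part`, `bias_part`.
#' @export
row_mse <- function(t_row, n, epsilon, t_reg_row = NULL) {
  ns <- length(t_row)
  if (is.null(t_reg_row)) t_reg_row <- rep(1 / ns, ns)
  variance_part <- (1 - epsilon)^2 * sum(t_row * (1 - t_row)) / n
  bias_part <- epsilon^2 * sum((t_reg_row - t_row)^2)
  list(mse = variance_part + bias_part,
       variance_part = variance_part, bias_part = bias_part)
}

#' Closed-form MSE-minimizing shrinkage weight for one row
#'
#' The minimizer of [row_mse()] over `eps` is
#' `eps* = K / (K + n)` with
#' `K = sum_k T_k (1 - T_k) / sum_k (treg_k - T_k)^2`
#' (uniform `treg` by default). Conventions: a deterministic row has `K = 0`
#' hence `eps* = 0` (no variance to trade away); a row equal to the
#' regularization row has a vanishing bias denominator and shrinkage is free,
#' so `eps* = 1`; `n = 0` (no data) also gives `eps* = 1`.
#'
#' @param t_row transition probability row (must sum to 1).
#' @param n observation count (>= 0).
#' @param t_reg_row regularization row; `NULL` = uniform.
#' @return `eps*` in `[0, 1]`; the `K` value is attached as attribute `"k"`.
#' @export
epsilon_star_row <- function(t_row, n, t_reg_row = NULL) {
  ns <- length(t_row)
  if (any(t_row < 0) || abs(sum(t_row) - 1) > 1e-8)
    stop("`t_row` must be a probability vector")
  if (is.null(t_reg_row)) t_reg_row <- rep(1 / ns, ns)
  vterm <- sum(t_row * (1 - t_row))
  bterm <- sum((t_reg_row - t_row)^2)
  if (n == 0) return(structure(1, k = if (bterm > 0) vterm / bterm else Inf))
  if (bterm == 0) return(structure(1, k = Inf))
  k <- vterm / bterm
  structure(k / (k + n), k = k)
}

#' State-action-specific shrinkage weights from batch data
#'
#' Applies [epsilon_star_row()] across all (state, action) pairs, with the
#' true row taken from (a) the true transition matrix (`"oracle_T"`, a
#' diagnostic upper bound), (b) the MLE plug-in (`"mle_plugin"`), or (c)
#' averaged over draws from the per-row Dirichlet posterior under a
#' symmetric Jeffreys prior (`Dirichlet(prior_mass + c)` with
#' `prior_mass = 1/2`; `"posterior_sample"`, the default used by the sweep
#' harness): the MSE curve averaged over sampled rows is minimized over a
#' grid of `grid_size` points followed by local refinement. At the sparse
#' sample sizes this estimator targets, a symmetric unit prior would carry
#' as much mass as the data itself and smear the sampled rows toward
#' uniform, inflating the weights; the Jeffreys mass is the canonical weak
#' choice. Pairs with no data get `eps* = 1`.
#'
#' @param counts count tensor.
#' @param mode `"oracle_T"`, `"mle_plugin"` or `"posterior_sample"`.
#' @param true_t true transition array (required for `"oracle_T"`).
#' @param n_samples posterior draws per row (posterior_sample mode).
#' @param seed RNG seed for the posterior draws.
#' @param prior_mass per-cell symmetric Dirichlet prior parameter for the
#'   posterior draws (default Jeffreys, 1/2).
#' @param grid_size grid resolution before refinement.
#' @param t_reg_row regularization row; `NULL` = uniform.
#' @return list of class `epsilon_star_report` with `epsilon_star`
#'   (matrix), `k_values`, `n_values`, `mode`.
#' @export
epsilon_star_from_data <- function(counts,
                                   mode = c("posterior_sample", "mle_plugin",
                                            "oracle_T"),
                                   true_t = NULL, n_samples = 50L, seed = 1L,
                                   prior_mass = 0.5, grid_size = 1000L,
                                   t_reg_row = NULL) {
  mode <- match.arg(mode)
  d <- dim(counts)
  ns <- d[1]; na <- d[2]
  if (mode == "oracle_T" && is.null(true_t))
    stop("oracle_T mode requires `true_t`")
  if (is.null(t_reg_row)) t_reg_row <- rep(1 / ns, ns)
  n <- apply(counts, c(1, 2), sum)
  eps <- matrix(1, ns, na)
  kv <- matrix(Inf, ns, na)
  if (mode == "posterior_sample") set.seed(seed)
  t_hat <- if (mode == "mle_plugin") mle_transition(counts) else NULL
  grid <- seq(0, 1, length.out = grid_size + 1L)
  for (a in seq_len(na)) for (s in seq_len(ns)) {
    nn <- n[s, a]
    if (nn == 0) next  # eps* = 1, no data
    if (mode == "posterior_sample") {
      g <- matrix(stats::rgamma(n_samples * ns,
                                shape = rep(prior_mass + counts[s, a, ],
                                            each = n_samples)),
                  n_samples, ns)
      rows <- g / rowSums(g)
      # averaged MSE over sampled rows is quadratic in eps:
      # (1-eps)^2 * A + eps^2 * B
      avar <- mean(rowSums(rows * (1 - rows))) / nn
      abias <- mean(rowSums((matrix(t_reg_row, n_samples, ns,
                                    byrow = TRUE) - rows)^2))
      f <- function(e) (1 - e)^2 * avar + e^2 * abias
      vals <- f(grid)
      best <- which.min(vals)
      lo <- grid[max(1L, best - 1L)]
      hi <- grid[min(length(grid), best + 1L)]
      e <- if (lo < hi) stats::optimize(f, c(lo, hi))$minimum else grid[best]
      eps[s, a] <- min(max(e, 0), 1)
      kv[s, a] <- if (abias > 0) (avar * nn) / abias else Inf
    } else {
      row <- if (mode == "oracle_T") true_t[s, a, ] else t_hat[s, a, ]
      e <- epsilon_star_row(row, nn, t_reg_row)
      eps[s, a] <- as.numeric(e)
      kv[s, a] <- attr(e, "k")
    }
  }
  structure(list(epsilon_star = eps, k_values = kv, n_values = n, mode = mode),
            class = "epsilon_star_report")
}

#' Certainty-equivalence policy under a chosen regularizer
#'
#' Estimates the transition model from counts, applies the regularizer in
#' `spec`, and plans: the `discount` method solves the MLE model at
#' `gamma_p`; all other methods solve the regularized model at the true
#' `gamma`.
#'
#' @param counts count tensor.
#' @param rewards known reward matrix.
#' @param gamma true discount.
#' @param spec a [regularization_spec()].
#' @param tol,max_iter forwarded to [solve_optimal()].
#' @return list with `policy`, `q`, `planning_gamma`, `transitions` (the
#'   model actually planned on).
#' @export
regularized_policy <- function(counts, rewards, gamma, spec,
                               tol = 1e-10, max_iter = 100000L) {
  stopifnot(inherits(spec, "regularization_spec"))
  t_mle <- mle_transition(counts)
  if (spec$method == "discount") {
    t_plan <- t_mle
    g_plan <- spec$gamma_p
  } else if (spec$method == "dirichlet_prior") {
    t_plan <- dirichlet_posterior_mean(counts, spec$prior)
    g_plan <- gamma
  } else {
    t_plan <- weighted_average_transition(t_mle, spec$epsilon, spec$t_reg_row)
    g_plan <- gamma
  }
  mdp_plan <- tabular_mdp(rewards, t_plan, gamma)
  sol <- solve_optimal(mdp_plan, g_plan, tol = tol, max_iter = max_iter)
  list(policy = sol$policy, q = sol$q, planning_gamma = g_plan,
       transitions = t_plan)
}

#' Machine-check the discount / weighted-average policy equivalence
#'
#' Solves the same MDP two ways: (a) original transitions with planning
#' discount `gamma * (1 - epsilon)`; (b) transitions shrunk by `epsilon`
#' toward the shared row `t_reg_row`, with planning discount `gamma`. The two
#' optimal policies must agree at every state up to numerical ties: a
#' disagreement only counts if in both solutions the Q-gap between the two
#' actions exceeds `tol`.
#'
#' @param mdp a [tabular_mdp()].
#' @param epsilon shared mixing weight in `(0, 1]`.
#' @param t_reg_row shared regularization row; `NULL` = uniform.
#' @param tol Q-gap below which an action difference is treated as a tie.
#' @return list with `equivalent` (logical) and `report`, a data.frame of
#'   disagreeing states with their Q-gaps (zero rows when equivalent).
#' @export
verify_theorem1 <- function(mdp, epsilon, t_reg_row = NULL, tol = 1e-8) {
  if (epsilon <= 0 || epsilon > 1) stop("`epsilon` must be in (0, 1]")
  s1 <- solve_optimal(mdp, mdp$gamma * (1 - epsilon))
  t2 <- weighted_average_transition(mdp$transitions, epsilon, t_reg_row)
  m2 <- tabular_mdp(mdp$rewards, t2, mdp$gamma)
  s2 <- solve_optimal(m2, mdp$gamma)
  compare_policies(s1, s2, tol)
}

# shared tie-aware policy comparison for the two equivalence theorems
compare_policies <- function(s1, s2, tol) {
  p1 <- s1$policy
  p2 <- s2$policy
  diff <- which(p1 != p2)
  if (length(diff) == 0L) {
    return(list(equivalent = TRUE,
                report = data.frame(state = integer(), action_1 = integer(),
                                    action_2 = integer(), q_gap = numeric())))
  }
  gap1 <- s1$q[cbind(diff, p1[diff])] - s1$q[cbind(diff, p2[diff])]
  gap2 <- s2$q[cbind(diff, p2[diff])] - s2$q[cbind(diff, p1[diff])]
  gap <- pmin(gap1, gap2)
  bad <- gap >= tol
  list(equivalent = !any(bad),
       report = data.frame(state = diff[bad], action_1 = p1[diff][bad],
                           action_2 = p2[diff][bad], q_gap = gap[bad]))
}
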