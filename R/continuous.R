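#' Fit a per-action kernel-regression transition model
#'
#' Models the expected next state given the current state, separately for
#' each discrete action, with a Nadaraya-Watson (Gaussian-kernel) estimator.
#' The residual scale is estimated by the ordered-difference estimator
#' `sigma^2 = (1 / (2 (n - 1))) * sum_d (s'_{(d+1)} - s'_{(d)})^2`, where the
#' next states are ordered by their originating states — an estimate of the
#' regression noise that requires no pilot fit. The default bandwidth is
#' Silverman's rule of thumb on the per-action state sample
#' ([stats::bw.nrd0()]), overridable.
#'
#' @param ds data.frame with columns `state` (in `[0, 1]`), `action`
#'   (integer), `next_state`.
#' @param bandwidth positive scalar or per-action vector; `NULL` = Silverman
#'   rule per action.
#' @param t_reg_mean mean of the regularization transition distribution
#'   (0.5 for the uniform distribution on the unit interval).
#' @param se_form `"sum_k2"` for the effective-kernel-norm standard error
#'   `sigma * sqrt(sum K_i^2) / sum K_j` (default) or `"sum_k"` for the
#'   variant `sigma * sqrt(sum K_i) / sum K_j`.
#' @return object of class `kernel_transition_model`.
#' @export
fit_kernel_model <- function(ds, bandwidth = NULL, t_reg_mean = 0.5,
                             se_form = c("sum_k2", "sum_k")) {
  se_form <- match.arg(se_form)
  actions <- sort(unique(ds$action))
  per_action <- lapply(actions, function(a) {
    sub <- ds[ds$action == a, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L)
      stop(sprintf("action %d has %d tuple(s); need at least 2 to fit", a, n))
    ord <- order(sub$state)
    s <- sub$state[ord]
    s2 <- sub$next_state[ord]
    sigma2 <- sum(diff(s2)^2) / (2 * (n - 1))
    h <- if (is.null(bandwidth)) {
      hh <- stats::bw.nrd0(s)
      if (hh <= 0) hh <- 0.05  # degenerate sample (all states equal)
      hh
    } else if (length(bandwidth) == 1L) bandwidth else bandwidth[a]
    if (h <= 0) stop("`bandwidth` must be positive")
    list(s = s, s_next = s2, h = h, sigma = sqrt(sigma2), n = n)
  })
  names(per_action) <- as.character(actions)
  structure(list(actions = actions, fits = per_action,
                 t_reg_mean = t_reg_mean, se_form = se_form),
            class = "kernel_transition_model")
}

#' Nadaraya-Watson prediction with a standard error
#'
#' Kernel-weighted mean of observed next states,
#' `sum_d K_h(s - s_d) s'_d / sum_d K_h(s - s_d)`, with a pointwise standard
#' error built from the model's residual scale and the kernel weight profile
#' (see [fit_kernel_model()] for the two forms). Vectorized over `s`.
#'
#' @param model a [fit_kernel_model()] result.
#' @param s numeric vector of query states.
#' @param a single action index present in the model.
#' @return list with numeric vectors `mean` and `se`.
#' @export
nw_predict_with_se <- function(model, s, a) {
  stopifnot(inherits(model, "kernel_transition_model"))
  fit <- model$fits[[as.character(a)]]
  if (is.null(fit)) stop(sprintf("no kernel fit for action %s", a))
  u <- outer(s, fit$s, "-") / fit$h
  w <- exp(-0.5 * u^2)  # Gaussian kernel; the 1/(h sqrt(2 pi)) factor cancels
  sw <- rowSums(w)
  if (any(sw <= 0 | !is.finite(sw)))
    stop("all kernel weights underflowed to zero; increase the bandwidth")
  mean_pred <- as.numeric(w %*% fit$s_next) / sw
  se <- if (model$se_form == "sum_k2") {
    fit$sigma * sqrt(rowSums(w^2)) / sw
  } else {
    fit$sigma * sqrt(sw) / sw
  }
  list(mean = mean_pred, se = se)
}

#' Continuous-state shrinkage weight
#'
#' Balances the squared standard error of the kernel prediction against the
#' squared gap to the regularization mean:
#' `eps* = se^2 / ((t_reg_mean - T_NW)^2 + se^2)`, in `[0, 1]`. When both the
#' standard error and the gap vanish the estimate and the regularizer agree
#' exactly and the weight defaults to 1. Vectorized over `s`.
#'
#' @param model a [fit_kernel_model()] result.
#' @param s numeric vector of query states.
#' @param a single action index.
#' @return numeric vector of weights in `[0, 1]`.
#' @export
epsilon_star_continuous <- function(model, s, a) {
  p <- nw_predict_with_se(model, s, a)
  gap2 <- (model$t_reg_mean - p$mean)^2
  se2 <- p$se^2
  out <- ifelse(gap2 + se2 <= 0, 1, se2 / (gap2 + se2))
  pmin(pmax(out, 0), 1)
}

#' Value-function models for fitted value iteration
#'
#' Both constructors return a mutable model obeying the contract
#' `vm$fit(states, targets)` then `vm$predict(states)`; before the first fit,
#' `predict` returns zeros. `value_model_extratrees()` is a
#' randomized-tree ensemble (ranger with the extratrees split rule,
#' full-sample unreplicated draws), deterministic given its seed.
#' `value_model_interp()` interpolates the fitted points piecewise-linearly
#' (constant extrapolation) — an exact-fit model useful for diagnostics and
#' for comparing against dynamic programming on a grid.
#'
#' @param num_trees number of trees.
#' @param seed integer seed passed to ranger.
#' @param min_node_size minimal terminal node size.
#' @return object of class `value_model`.
#' @export
value_model_extratrees <- function(num_trees = 50L, seed = 1L,
                                   min_node_size = 5L) {
  e <- new.env(parent = emptyenv())
  e$rf <- NULL
  e$fit <- function(states, targets) {
    e$rf <- ranger::ranger(
      y = targets, x = data.frame(s = states),
      num.trees = num_trees, mtry = 1,
      splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1,
      min.node.size = min_node_size, seed = seed, num.threads = 1L)
    invisible(e)
  }
  e$predict <- function(states) {
    if (is.null(e$rf)) return(rep(0, length(states)))
    stats::predict(e$rf, data.frame(s = states),
                   num.threads = 1L)$predictions
  }
  class(e) <- "value_model"
  e
}

#' @rdname value_model_extratrees
#' @export
value_model_interp <- function() {
  e <- new.env(parent = emptyenv())
  e$f <- NULL
  e$fit <- function(states, targets) {
    e$f <- stats::approxfun(states, targets, rule = 2)
    invisible(e)
  }
  e$predict <- function(states) {
    if (is.null(e$f)) return(rep(0, length(states)))
    e$f(states)
  }
  class(e) <- "value_model"
  e
}

#' Regularized fitted value iteration on a 1-d continuous state space
#'
#' Samples `n_sample_states` states (a deterministic uniform grid by default,
#' or seeded uniform draws), fits the kernel transition model, precomputes
#' the predicted next state and the shrinkage weight for every (sample
#' state, action) pair — the weights are fixed before iteration begins and
#' never drift — then iterates the weighted-average backup
#' `Q(s_n, a_k) = R(s_n, a_k) + gamma (1 - eps) V(s'_{n,k})
#'               + gamma eps mean_n' V(s_{n'})`
#' and refits the value model on `(s_n, max_k Q(s_n, a_k))`. Global mode with
#' a shared `epsilon_global` reproduces discount regularization.
#'
#' @param ds data.frame of `(state, action, next_state)` tuples.
#' @param reward_fn function `(s, a) -> reward`, vectorized over `s`.
#' @param gamma discount.
#' @param n_sample_states number of backup states.
#' @param n_iterations backup/refit cycles.
#' @param value_model a `value_model` (see [value_model_extratrees()]).
#' @param mode `"sa_specific"` (per-pair weights from
#'   [epsilon_star_continuous()]) or `"global"`.
#' @param epsilon_global shared weight for `"global"` mode.
#' @param rng_seed seed covering state sampling (random scheme) and any
#'   stochasticity in the value model refits.
#' @param sample_scheme `"grid"` (deterministic) or `"random"`.
#' @param kernel_model optional prefitted [fit_kernel_model()]; `NULL` fits
#'   one from `ds`.
#' @param t_reg_mean,bandwidth,se_form forwarded to [fit_kernel_model()]
#'   when it is fitted here.
#' @return list of class `fvi_fit` with the fitted `value_model`,
#'   `policy_fn(s)` (greedy action function), `q_fn(s)` (matrix of Q values),
#'   `epsilon` (matrix, sample states x actions), `sample_states`,
#'   `kernel_model`.
#' @export
fvi_regularized <- function(ds, reward_fn, gamma = 0.99,
                            n_sample_states = 200L, n_iterations = 50L,
                            value_model = value_model_extratrees(),
                            mode = c("sa_specific", "global"),
                            epsilon_global = 0, rng_seed = 1L,
                            sample_scheme = c("grid", "random"),
                            kernel_model = NULL, t_reg_mean = 0.5,
                            bandwidth = NULL, se_form = "sum_k2") {
  mode <- match.arg(mode)
  sample_scheme <- match.arg(sample_scheme)
  set.seed(rng_seed)
  states <- if (sample_scheme == "grid")
    seq(0, 1, length.out = n_sample_states)
  else stats::runif(n_sample_states)
  if (is.null(kernel_model))
    kernel_model <- fit_kernel_model(ds, bandwidth = bandwidth,
                                     t_reg_mean = t_reg_mean,
                                     se_form = se_form)
  actions <- kernel_model$actions
  na <- length(actions)
  nexts <- matrix(0, n_sample_states, na)
  eps <- matrix(epsilon_global, n_sample_states, na)
  rmat <- matrix(0, n_sample_states, na)
  for (k in seq_len(na)) {
    a <- actions[k]
    nexts[, k] <- nw_predict_with_se(kernel_model, states, a)$mean
    if (mode == "sa_specific")
      eps[, k] <- epsilon_star_continuous(kernel_model, states, a)
    rmat[, k] <- reward_fn(states, a)
  }
  for (it in seq_len(n_iterations)) {
    vnext <- matrix(value_model$predict(as.vector(nexts)),
                    n_sample_states, na)
    vbar <- mean(value_model$predict(states))
    qmat <- rmat + gamma * (1 - eps) * vnext + gamma * eps * vbar
    if (!all(is.finite(qmat)))
      stop(sprintf("non-finite Q values at FVI iteration %d", it))
    value_model$fit(states, rowmax(qmat))
  }
  vbar_final <- mean(value_model$predict(states))
  q_fn <- function(s) {
    q <- matrix(0, length(s), na)
    for (k in seq_len(na)) {
      a <- actions[k]
      pn <- nw_predict_with_se(kernel_model, s, a)$mean
      e <- if (mode == "sa_specific")
        epsilon_star_continuous(kernel_model, s, a)
      else rep(epsilon_global, length(s))
      q[, k] <- reward_fn(s, a) + gamma * (1 - e) * value_model$predict(pn) +
        gamma * e * vbar_final
    }
    q
  }
  policy_fn <- function(s) actions[max.col(q_fn(s), ties.method = "first")]
  structure(list(value_model = value_model, policy_fn = policy_fn,
                 q_fn = q_fn, epsilon = eps, sample_states = states,
                 kernel_model = kernel_model, mode = mode, gamma = gamma),
            class = "fvi_fit")
}

#' Exact grid discretization of a continuous environment
#'
#' Converts a [make_continuous_river_swim()]-style environment (drift plus
#' uniform noise, clipped to the unit interval) into a tabular MDP over
#' `n_cells` equal cells. Transition probabilities are exact uniform-CDF
#' masses of the noise interval falling into each cell, with clipped mass
#' assigned to the boundary cells — so policy values computed on the grid
#' converge to the continuous values as the grid refines. Used as the
#' evaluation oracle for continuous policies.
#'
#' @param env a continuous environment (class `continuous_env`).
#' @param n_cells number of grid cells.
#' @return a [tabular_mdp()] over cell midpoints, with the midpoints
#'   attached as attribute `"midpoints"`.
#' @export
discretize_continuous <- function(env, n_cells = 201L) {
  stopifnot(inherits(env, "continuous_env"))
  m <- (seq_len(n_cells) - 0.5) / n_cells
  b <- seq_len(n_cells - 1L) / n_cells
  na <- env$n_actions
  trans <- array(0, c(n_cells, na, n_cells))
  rewards <- matrix(0, n_cells, na)
  for (a in seq_len(na)) {
    drift <- env$drift[a]
    hw <- env$halfwidth[a]
    lo <- m + drift - hw
    cdf <- function(x) pmin(1, pmax(0, (x - lo) / (2 * hw)))
    cm <- vapply(b, cdf, numeric(n_cells))       # n_cells x (n_cells - 1)
    trans[, a, ] <- cbind(cm, 1) - cbind(0, cm)
    rewards[, a] <- env$reward_fn(m, a)
  }
  mdp <- tabular_mdp(rewards, trans, env$gamma)
  attr(mdp, "midpoints") <- m
  mdp
}

#' Loss of a continuous-state policy against the optimal policy
#'
#' Evaluates both the optimal policy of the discretized environment and the
#' supplied policy function (queried at cell midpoints) by exact linear
#' solves on the grid, and returns the mean value gap across grid states.
#'
#' @param env a `continuous_env`.
#' @param policy_fn function mapping a vector of states to action indices.
#' @param n_cells grid resolution.
#' @param disc optional precomputed [discretize_continuous()] result (reused
#'   across many policies in sweeps).
#' @param v_star optional precomputed optimal value vector on the grid.
#' @return single nonnegative number.
#' @export
continuous_policy_loss <- function(env, policy_fn, n_cells = 201L,
                                   disc = NULL, v_star = NULL) {
  if (is.null(disc)) disc <- discretize_continuous(env, n_cells)
  m <- attr(disc, "midpoints")
  if (is.null(v_star)) v_star <- optimal_values(disc)
  acts <- policy_fn(m)
  v_pi <- evaluate_policy(disc, acts)
  mean(v_star - v_pi)
}
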