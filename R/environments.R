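#' 10-state random chain environment
#'
#' A distribution over 10-state, 2-action MDPs: for every (state, action)
#' pair, 5 successor states are chosen at random to carry nonzero
#' probability; those probabilities are drawn independently from
#' Uniform(0, 1) and normalized to sum to one. Rewards are independent
#' Uniform(0, 1) draws per (state, action). A fresh MDP is typically drawn
#' per replicate in sweeps.
#'
#' @param seed integer seed; construction is bit-reproducible given it.
#' @param gamma discount (default 0.99).
#' @param n_states,n_actions,n_successors sizes (defaults 10, 2, 5).
#' @return a [tabular_mdp()].
#' @export
make_random_chain <- function(seed, gamma = 0.99, n_states = 10L,
                              n_actions = 2L, n_successors = 5L) {
  set.seed(seed)
  trans <- array(0, c(n_states, n_actions, n_states))
  for (s in seq_len(n_states)) for (a in seq_len(n_actions)) {
    succ <- sample.int(n_states, n_successors)
    p <- stats::runif(n_successors)
    trans[s, a, succ] <- p / sum(p)
  }
  rewards <- matrix(stats::runif(n_states * n_actions), n_states, n_actions)
  tabular_mdp(rewards, trans, gamma, name = "random_chain")
}

#' River Swim environment
#'
#' Six states in a row, two actions. Action 1 (swim left, with the current)
#' moves one state left deterministically; the left-most state pays a small
#' reward for it. Action 2 (swim right, against the current) succeeds with
#' probability `p_right`, stays with `p_stay`, slips left with `p_left`; the
#' right-most state pays the large reward. At the endpoints the blocked
#' movement mass is folded into staying. The numeric defaults follow the
#' standard construction of this benchmark; all are overridable.
#'
#' @param gamma discount.
#' @param r_left reward for swimming left in the left-most state.
#' @param r_right reward for swimming right in the right-most state.
#' @param p_right,p_stay,p_left right-action probabilities at interior
#'   states (must sum to 1).
#' @param n_states chain length.
#' @return a [tabular_mdp()].
#' @export
make_river_swim <- function(gamma = 0.99, r_left = 0.005, r_right = 1,
                            p_right = 0.3, p_stay = 0.6, p_left = 0.1,
                            n_states = 6L) {
  p <- c(p_right, p_stay, p_left)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("right-action probabilities must be nonnegative and sum to 1")
  ns <- n_states
  trans <- array(0, c(ns, 2L, ns))
  rewards <- matrix(0, ns, 2L)
  for (s in seq_len(ns)) {
    trans[s, 1L, max(s - 1L, 1L)] <- 1            # left: deterministic
    right_to <- min(s + 1L, ns)
    left_to <- max(s - 1L, 1L)
    trans[s, 2L, right_to] <- trans[s, 2L, right_to] + p_right
    trans[s, 2L, s] <- trans[s, 2L, s] + p_stay
    trans[s, 2L, left_to] <- trans[s, 2L, left_to] + p_left
  }
  rewards[1L, 1L] <- r_left
  rewards[ns, 2L] <- r_right
  tabular_mdp(rewards, trans, gamma, name = "river_swim")
}

#' 4x4 GridWorld environment
#'
#' A distribution over 16-state, 4-action MDPs on a 4x4 grid (actions:
#' left, right, up, down). For each state a success probability `p_s` is
#' drawn from Uniform(0, 1): with probability `p_s` the agent moves in the
#' intended direction if possible (staying put at a wall), and with
#' probability `1 - p_s` it jumps to a successor state fixed at random when
#' the MDP is constructed. One random state has reward 1; all other state
#' rewards are Uniform(-0.5, 0.5) (rewards depend on the state only).
#'
#' @param seed integer seed.
#' @param gamma discount.
#' @param side grid side length (default 4).
#' @return a [tabular_mdp()].
#' @export
make_gridworld <- function(seed, gamma = 0.99, side = 4L) {
  set.seed(seed)
  ns <- side * side
  na <- 4L
  p_s <- stats::runif(ns)
  jump_to <- sample.int(ns, ns, replace = TRUE)
  # state s at (row, col): row-major, row = (s-1) %/% side, col = (s-1) %% side
  trans <- array(0, c(ns, na, ns))
  moves <- list(c(0L, -1L), c(0L, 1L), c(-1L, 0L), c(1L, 0L))  # L R U D
  for (s in seq_len(ns)) {
    row <- (s - 1L) %/% side
    col <- (s - 1L) %% side
    for (a in seq_len(na)) {
      nr <- row + moves[[a]][1L]
      nc <- col + moves[[a]][2L]
      target <- if (nr < 0L || nr >= side || nc < 0L || nc >= side) s
      else nr * side + nc + 1L
      trans[s, a, target] <- trans[s, a, target] + p_s[s]
      trans[s, a, jump_to[s]] <- trans[s, a, jump_to[s]] + 1 - p_s[s]
    }
  }
  r_state <- stats::runif(ns, -0.5, 0.5)
  r_state[sample.int(ns, 1L)] <- 1
  rewards <- matrix(r_state, ns, na)
  tabular_mdp(rewards, trans, gamma, name = "gridworld")
}

#' Continuous River Swim environment
#'
#' One-dimensional state space `[0, 1]` with two discrete actions. Action 1
#' swims against the current: it drifts the state upward (toward the large
#' reward at the top) with wide uniform noise. Action 2 swims with the
#' current: it drifts downward (toward the small reward at the bottom) with
#' narrow noise. Next states are clipped to `[0, 1]`. The reward is a pair
#' of linear bumps at the ends of the interval,
#' `r(s) = r_low * max(0, 1 - s / w_low) + r_high * max(0, (s - (1 - w_high)) / w_high)`.
#' Noise widths are full interval widths (noise ~ Uniform(-w/2, w/2)).
#'
#' @param gamma discount.
#' @param drift absolute drift magnitude per step.
#' @param widths noise interval widths per action (against, with).
#' @param r_low,r_high reward heights at the bottom and top bumps.
#' @param bump_width width of each reward bump.
#' @return object of class `continuous_env`: a list with `reward_fn(s, a)`,
#'   `step_fn(s, a)` (vectorized; uses the current RNG stream), `bounds`,
#'   `n_actions`, `gamma`, `drift`, `halfwidth`.
#' @export
make_continuous_river_swim <- function(gamma = 0.99, drift = 0.1,
                                       widths = c(0.3, 0.05),
                                       r_low = 0.1, r_high = 1,
                                       bump_width = 0.2) {
  drift_vec <- c(drift, -drift)   # action 1 up (against), action 2 down
  halfwidth <- widths / 2
  reward_fn <- function(s, a = NULL) {
    r_low * pmax(0, 1 - s / bump_width) +
      r_high * pmax(0, (s - (1 - bump_width)) / bump_width)
  }
  step_fn <- function(s, a) {
    a <- rep_len(a, length(s))
    noise <- stats::runif(length(s), -halfwidth[a], halfwidth[a])
    pmin(pmax(s + drift_vec[a] + noise, 0), 1)
  }
  structure(list(reward_fn = reward_fn, step_fn = step_fn,
                 bounds = c(0, 1), n_actions = 2L, gamma = gamma,
                 drift = drift_vec, halfwidth = halfwidth),
            class = "continuous_env")
}

#' Sample a batch dataset from a continuous environment
#'
#' States are drawn uniformly over the state space and actions uniformly
#' over the action set; next states come from the environment's step
#' function.
#'
#' @param env a `continuous_env`.
#' @param n number of tuples.
#' @param seed integer seed.
#' @return data.frame with columns `state`, `action`, `next_state`, of class
#'   `continuous_dataset`.
#' @export
sample_continuous_dataset <- function(env, n, seed) {
  stopifnot(inherits(env, "continuous_env"))
  if (n < 1L) stop("`n` must be positive")
  set.seed(seed)
  s <- stats::runif(n, env$bounds[1], env$bounds[2])
  a <- sample.int(env$n_actions, n, replace = TRUE)
  ds <- data.frame(state = s, action = a, next_state = env$step_fn(s, a))
  attr(ds, "seed") <- seed
  class(ds) <- c("continuous_dataset", "data.frame")
  ds
}

#' Construct a benchmark environment by name
#'
#' Single entry point used by the sweep harness and the command-line
#' interface.
#'
#' @param name one of `"random_chain"`, `"river_swim"`, `"gridworld"`,
#'   `"continuous_river_swim"`.
#' @param seed integer seed (used by the randomized constructors).
#' @param overrides named list of constructor arguments to override.
#' @return a [tabular_mdp()] or a `continuous_env`.
#' @export
make_environment <- function(name, seed = 1L, overrides = list()) {
  switch(name,
    random_chain = do.call(make_random_chain, c(list(seed = seed), overrides)),
    river_swim = do.call(make_river_swim, overrides),
    gridworld = do.call(make_gridworld, c(list(seed = seed), overrides)),
    continuous_river_swim = do.call(make_continuous_river_swim, overrides),
    stop(sprintf("unknown environment '%s'", name)))
}
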