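test_that("unregularized FQI on exact-frequency data equals planning on the MLE model", {
  mdp <- make_river_swim(gamma = 0.9)
  ds <- exact_frequency_dataset(mdp, denom = 10L)
  cfg <- fqi_config(gamma = 0.9, n_iterations = 300L, epsilon_mode = "global",
                    epsilon_global = 0)
  fit <- fqi_regularized(ds, mdp$rewards, cfg, 6, 2)
  counts <- count_transitions(ds, 6, 2)
  oracle <- solve_optimal(tabular_mdp(mdp$rewards, mle_transition(counts),
                                      0.9))
  expect_equal(fit$q, oracle$q, tolerance = 1e-6)
  expect_identical(fit$policy, oracle$policy)
  expect_equal(nrow(fit$unobserved), 0)
})

test_that("full shrinkage collapses targets to reward plus a constant", {
  mdp <- make_river_swim(gamma = 0.9)
  ds <- sample_dataset(mdp, "equal_counts", 4L, seed = 31)
  cfg <- fqi_config(gamma = 0.9, n_iterations = 200L, epsilon_mode = "global",
                    epsilon_global = 1)
  fit <- fqi_regularized(ds, mdp$rewards, cfg, 6, 2)
  offsets <- fit$q - mdp$rewards
  expect_lt(diff(range(offsets)), 1e-6)
})

test_that("one iteration from zero returns the observed mean reward", {
  mdp <- make_random_chain(32)
  ds <- sample_dataset(mdp, "uniform_sa", 80L, seed = 32)
  cfg <- fqi_config(gamma = 0.99, n_iterations = 1L, epsilon_mode = "global",
                    epsilon_global = 0.3)
  fit <- fqi_regularized(ds, mdp$rewards, cfg, 10, 2)
  counts <- apply(count_transitions(ds, 10, 2), c(1, 2), sum)
  expect_equal(fit$q[counts > 0], mdp$rewards[counts > 0])
  expect_true(all(fit$q[counts == 0] == 0))
})

test_that("SSE weight matches hand algebra on a single observed tuple", {
  # one tuple (s1, a1) -> s2; quadratic in eps minimized at -A/B
  counts <- array(0L, c(2, 1, 2)); counts[1, 1, 2] <- 1L
  q <- matrix(c(0.4, 1.2), 2, 1)
  policy <- c(1L, 1L)
  rewards <- matrix(c(0.3, 0), 2, 1)
  gamma <- 0.9
  v <- c(0.4, 1.2); v_avg <- 0.8
  a_term <- rewards[1, 1] + gamma * v[2] - q[1, 1]
  b_term <- gamma * (v_avg - v[2])
  eps <- epsilon_star_sse(counts, q, policy, rewards, gamma)
  expect_equal(eps[1, 1], min(max(-a_term / b_term, 0), 1))
  expect_equal(eps[2, 1], 1)  # no data -> full shrinkage
})

test_that("degenerate SSE quadratics fall back to zero shrinkage", {
  counts <- array(1L, c(3, 1, 3))
  q <- matrix(0.7, 3, 1)  # all next-state values equal the average
  eps <- epsilon_star_sse(counts, q, rep(1L, 3), matrix(0.1, 3, 1), 0.9)
  expect_true(all(eps == 0))
})

test_that("SSE weights agree with direct grid minimization of the error sum", {
  set.seed(33)
  grid <- seq(0, 1, length.out = 10001)
  for (i in 1:10) {
    ns <- 5L; na <- 2L
    counts <- array(rpois(ns * na * ns, 2), c(ns, na, ns))
    q <- matrix(rnorm(ns * na), ns, na)
    rewards <- matrix(runif(ns * na), ns, na)
    policy <- greedy_policy(q)
    gamma <- 0.9
    eps <- epsilon_star_sse(counts, q, policy, rewards, gamma)
    v <- q[cbind(1:ns, policy)]
    v_avg <- mean(v)
    for (s in 1:ns) for (a in 1:na) {
      cc <- counts[s, a, ]
      if (sum(cc) == 0) next
      sse <- vapply(grid, function(e) {
        tgt <- rewards[s, a] + gamma * (1 - e) * v + gamma * e * v_avg
        sum(cc * (tgt - q[s, a])^2)
      }, numeric(1))
      expect_lt(abs(eps[s, a] - grid[which.min(sse)]), 1e-4)
    }
  }
})

test_that("matrix assembly reproduces the scalar SSE stationary points", {
  set.seed(34)
  for (i in 1:5) {
    ns <- 6L; na <- 2L
    counts <- array(rpois(ns * na * ns, 3), c(ns, na, ns))
    q <- matrix(rnorm(ns * na), ns, na)
    rewards <- matrix(runif(ns * na), ns, na)
    policy <- greedy_policy(q)
    scalar <- attr(epsilon_star_sse(counts, q, policy, rewards, 0.95),
                   "unclamped")
    mat <- epsilon_star_sse_matrix(counts, q, policy, rewards, 0.95)
    both <- !is.na(scalar) & !is.na(mat)
    expect_gt(sum(both), 0)
    expect_equal(scalar[both], mat[both], tolerance = 1e-8)
  }
})

test_that("multinomial weights follow the bias-variance closed form", {
  ns <- 4L
  t_rows <- array(0, c(ns, 1, ns))
  for (s in 1:ns) t_rows[s, 1, ] <- random_prob_vec(ns)
  # constant value function: flat objective -> convention 0
  qconst <- matrix(1, ns, 1)
  n <- matrix(5L, ns, 1)
  eps <- epsilon_star_multinomial(t_rows, n, qconst, rep(1L, ns),
                                  matrix(0, ns, 1), 0.9)
  expect_true(all(eps == 0))
  # deterministic row whose successor value equals the average
  t_det <- array(0, c(2, 1, 2)); t_det[1, 1, 2] <- 1; t_det[2, 1, 1] <- 1
  q2 <- matrix(c(0.5, 0.5), 2, 1)
  e2 <- epsilon_star_multinomial(t_det, matrix(3L, 2, 1), q2, c(1L, 1L),
                                 matrix(0, 2, 1), 0.9)
  expect_true(all(e2 == 0))
  # no data -> full shrinkage
  e0 <- epsilon_star_multinomial(t_rows, matrix(0L, ns, 1), qconst,
                                 rep(1L, ns), matrix(0, ns, 1), 0.9)
  expect_true(all(e0 == 1))
})

test_that("multinomial weight minimizes the simulated target MSE", {
  set.seed(35)
  gamma <- 0.9
  ns <- 4L
  t_row <- c(0.4, 0.3, 0.2, 0.1)
  v <- c(1.5, 0.2, 0.9, 2.4)
  v_avg <- mean(v)
  n <- 8L
  m <- sum(t_row * v)
  t_rows <- array(0, c(ns, 1, ns))
  for (s in 1:ns) t_rows[s, 1, ] <- random_prob_vec(ns)
  t_rows[1, 1, ] <- t_row
  eps_pkg <- epsilon_star_multinomial(
    t_rows, matrix(n, ns, 1),
    q_pi = matrix(v, ns, 1), policy = rep(1L, ns),
    rewards = matrix(0, ns, 1), gamma = gamma)
  # Monte-Carlo oracle: empirical MSE of the shrunk target over count draws
  draws <- stats::rmultinom(20000, n, t_row) / n
  vhat <- as.numeric(crossprod(draws, v))
  emp_mse <- function(e) {
    est <- gamma * (1 - e) * vhat + gamma * e * v_avg
    mean((est - gamma * m)^2)
  }
  grid <- seq(0, 1, length.out = 401)
  emp <- vapply(grid, emp_mse, numeric(1))
  expect_lt(abs(eps_pkg[1, 1] - grid[which.min(emp)]), 0.05)
  # analytic MSE curve tracks the empirical one
  ana <- vapply(grid, function(e)
    gamma^2 * e^2 * (v_avg - m)^2 +
      gamma^2 * (1 - e)^2 * (sum(t_row * v^2) - m^2) / n, numeric(1))
  expect_lt(max(abs(ana - emp)) / max(emp), 0.05)
})

test_that("per-pair weights are wired through the estimation modes in FQI", {
  mdp <- make_river_swim(gamma = 0.9)
  ds <- sample_dataset(mdp, "equal_counts", 6L, seed = 36)
  for (mode in c("per_sa_sse", "per_sa_multinomial")) {
    cfg <- fqi_config(gamma = 0.9, n_iterations = 15L, epsilon_mode = mode,
                      rng_seed = 4, store_history = TRUE)
    fit <- fqi_regularized(ds, mdp$rewards, cfg, 6, 2)
    expect_true(all(fit$epsilon >= 0 & fit$epsilon <= 1))
    # the weights are refreshed from the fitted Q each iteration
    expect_false(identical(fit$epsilon_history[[1]],
                           fit$epsilon_history[[15]]))
  }
  # oracle mode keeps the weights fixed at the true-Q solution
  q_true <- solve_optimal(mdp)$q
  cfg <- fqi_config(gamma = 0.9, n_iterations = 5L, epsilon_mode = "oracle_Q",
                    q_true = q_true, store_history = TRUE)
  fit <- fqi_regularized(ds, mdp$rewards, cfg, 6, 2)
  expect_identical(fit$epsilon_history[[1]], fit$epsilon_history[[5]])
})

test_that("FQI under a reduced discount equals FQI with the averaged update", {
  mdp <- make_river_swim()
  for (i in 1:10) {
    ds <- sample_dataset(mdp, "equal_counts", 5L, seed = 600 + i)
    for (eps in c(0.2, 0.6)) {
      v <- verify_theorem2(ds, mdp$rewards, mdp$gamma, eps,
                           n_iterations = 25L, n_states = 6, n_actions = 2)
      expect_true(v$equivalent)
    }
  }
  expect_error(verify_theorem2(sample_dataset(mdp, "equal_counts", 5L, 1),
                               mdp$rewards, mdp$gamma, 0,
                               n_states = 6, n_actions = 2),
               "epsilon")
})
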