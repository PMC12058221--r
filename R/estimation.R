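#' Derive a reproducible child seed
#'
#' Mixes a master seed with a replicate index through a Lehmer-style step so
#' that every replicate of a sweep gets its own deterministic substream. The
#' result stays below 2^31.
#'
#' @param master integer master seed.
#' @param index nonnegative integer (replicate number, grid position, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(index) * 9973 + 1) %% 2147483647)
}

# vectorized categorical draw: one next state per row of `prob_rows`
# given uniform variates u; last column forced to 1 to absorb rounding
draw_categorical <- function(prob_rows, u) {
  cum <- t(apply(prob_rows, 1, cumsum))
  cum[, ncol(cum)] <- 1
  max.col(u <= cum, ties.method = "first")
}

#' Sample a batch transition dataset from a tabular MDP
#'
#' Three sampling schemes cover the designs used for batch experiments:
#' `equal_counts` draws exactly `size` next states for every (state, action)
#' pair; `uniform_sa` draws `size` tuples with state and action chosen
#' uniformly at random; `trajectories` rolls out `size$n_trajectories`
#' trajectories of `size$length` steps under a behavior policy (default:
#' uniform-random actions) from a uniform start distribution.
#'
#' @param mdp a [tabular_mdp()].
#' @param scheme one of `"equal_counts"`, `"uniform_sa"`, `"trajectories"`.
#' @param size per-pair count (`equal_counts`), total tuple count
#'   (`uniform_sa`), or `list(n_trajectories =, length =)` (`trajectories`).
#' @param seed integer seed; sampling is bit-reproducible given it.
#' @param behavior_policy optional integer action per state for the
#'   trajectory scheme; `NULL` means uniform-random actions.
#' @return data.frame with columns `state`, `action`, `next_state`, `reward`
#'   (1-based indices), of class `transition_dataset`, carrying `seed` and
#'   `scheme` attributes. Rewards are the known `R(s, a)`.
#' @export
sample_dataset <- function(mdp, scheme = c("equal_counts", "uniform_sa",
                                           "trajectories"),
                           size, seed, behavior_policy = NULL) {
  stopifnot(inherits(mdp, "tabular_mdp"))
  scheme <- match.arg(scheme)
  ns <- mdp$n_states
  na <- mdp$n_actions
  set.seed(seed)
  if (scheme == "equal_counts") {
    m <- as.integer(size)
    if (length(m) != 1L || m < 1L) stop("`size` must be a positive per-pair count")
    s <- rep(rep(seq_len(ns), each = m), na)
    a <- rep(seq_len(na), each = ns * m)
    nxt <- integer(length(s))
    pos <- 1L
    for (aa in seq_len(na)) for (ss in seq_len(ns)) {
      nxt[pos:(pos + m - 1L)] <-
        sample.int(ns, m, replace = TRUE, prob = mdp$transitions[ss, aa, ])
      pos <- pos + m
    }
  } else if (scheme == "uniform_sa") {
    n <- as.integer(size)
    if (length(n) != 1L || n < 1L) stop("`size` must be a positive tuple count")
    s <- sample.int(ns, n, replace = TRUE)
    a <- sample.int(na, n, replace = TRUE)
    rows <- matrix(mdp$transitions, ns * na, ns)[(a - 1L) * ns + s, ,
                                                 drop = FALSE]
    nxt <- draw_categorical(rows, stats::runif(n))
  } else {
    if (!is.list(size) || is.null(size$n_trajectories) || is.null(size$length))
      stop("`size` must be list(n_trajectories =, length =) for trajectories")
    ntr <- as.integer(size$n_trajectories)
    len <- as.integer(size$length)
    if (ntr < 1L || len < 1L) stop("trajectory counts must be positive")
    if (!is.null(behavior_policy))
      behavior_policy <- check_policy(mdp, behavior_policy)
    tmat <- matrix(mdp$transitions, ns * na, ns)
    cur <- sample.int(ns, ntr, replace = TRUE)
    s <- a <- nxt <- integer(ntr * len)
    for (step in seq_len(len)) {
      act <- if (is.null(behavior_policy))
        sample.int(na, ntr, replace = TRUE) else behavior_policy[cur]
      rows <- tmat[(act - 1L) * ns + cur, , drop = FALSE]
      nn <- draw_categorical(rows, stats::runif(ntr))
      idx <- (step - 1L) * ntr + seq_len(ntr)
      s[idx] <- cur
      a[idx] <- act
      nxt[idx] <- nn
      cur <- nn
    }
  }
  ds <- data.frame(state = s, action = a, next_state = nxt,
                   reward = mdp$rewards[cbind(s, a)])
  attr(ds, "seed") <- seed
  attr(ds, "scheme") <- scheme
  class(ds) <- c("transition_dataset", "data.frame")
  ds
}

#' Tally a dataset into a count tensor
#'
#' @param ds a [sample_dataset()] result or any data.frame with `state`,
#'   `action`, `next_state` columns (1-based).
#' @param n_states,n_actions dimensions of the source MDP.
#' @return integer array `c[i, j, k]`, the number of observed transitions
#'   from state i under action j to state k.
#' @export
count_transitions <- function(ds, n_states, n_actions) {
  if (nrow(ds) == 0L)
    return(array(0L, c(n_states, n_actions, n_states)))
  if (any(ds$state < 1L | ds$state > n_states) ||
      any(ds$action < 1L | ds$action > n_actions) ||
      any(ds$next_state < 1L | ds$next_state > n_states))
    stop("dataset contains out-of-range state or action indices")
  idx <- ds$state + (ds$action - 1L) * n_states +
    (ds$next_state - 1L) * n_states * n_actions
  array(tabulate(idx, nbins = n_states * n_actions * n_states),
        c(n_states, n_actions, n_states))
}

#' Maximum-likelihood transition estimate
#'
#' Rows with at least one observation become empirical frequencies
#' `c / n(i, j)`. Unobserved rows are either replaced by the uniform
#' distribution (`"uniform"`, the planning default) or left uniform and
#' reported to the caller (`"flag"`) via the `"unobserved"` attribute, a
#' two-column matrix of (state, action) pairs.
#'
#' @param counts count tensor from [count_transitions()].
#' @param zero_row_mode `"uniform"` or `"flag"`.
#' @return transition array with stochastic rows.
#' @export
mle_transition <- function(counts, zero_row_mode = c("uniform", "flag")) {
  zero_row_mode <- match.arg(zero_row_mode)
  d <- dim(counts)
  ns <- d[1]; na <- d[2]; nk <- d[3]
  n <- apply(counts, c(1, 2), sum)
  t_hat <- array(0, d)
  for (a in seq_len(na)) {
    rows <- matrix(counts[, a, ], ns, nk)
    nn <- n[, a]
    obs <- nn > 0
    rows[obs, ] <- rows[obs, , drop = FALSE] / nn[obs]
    rows[!obs, ] <- 1 / nk
    t_hat[, a, ] <- rows
  }
  if (zero_row_mode == "flag") {
    unobs <- which(n == 0, arr.ind = TRUE)
    colnames(unobs) <- c("state", "action")
    attr(t_hat, "unobserved") <- unobs
  }
  t_hat
}

#' Posterior-mean transition estimate under a Dirichlet prior
#'
#' With prior `T(s_i, a_j, .) ~ Dirichlet(alpha_{i,j,1..Ns})` and counts `c`,
#' each posterior-mean row is `(c + alpha) / (n + sum(alpha))` — algebraically
#' the weighted average `(1 - eps) * MLE + eps * prior mean` with
#' `eps = sum(alpha) / (n + sum(alpha))`. Rows with zero counts and zero
#' prior mass (a degenerate zero-magnitude prior) fall back to the uniform
#' distribution, matching the MLE zero-row convention.
#'
#' @param counts count tensor.
#' @param alpha positive scalar (uniform prior shorthand, recycled to every
#'   cell) or array the same shape as `counts`.
#' @return transition array of posterior-mean rows.
#' @export
dirichlet_posterior_mean <- function(counts, alpha) {
  d <- dim(counts)
  if (length(alpha) == 1L) {
    if (alpha <= 0) stop("scalar `alpha` must be positive")
    alpha <- array(alpha, d)
  }
  if (!all(dim(alpha) == d)) stop("`alpha` must match the count tensor shape")
  if (any(alpha < 0)) stop("`alpha` entries must be nonnegative")
  nk <- d[3]
  num <- counts + alpha
  denom <- apply(num, c(1, 2), sum)
  post <- array(0, d)
  for (k in seq_len(nk)) post[, , k] <- num[, , k] / denom
  zero <- denom == 0
  if (any(zero))
    for (k in seq_len(nk)) {
      slab <- post[, , k]
      slab[zero] <- 1 / nk
      post[, , k] <- slab
    }
  post
}

#' Write / read transition datasets as CSV
#'
#' File contract: columns `replicate,step,state,action,reward,next_state`
#' with a header and 0-based state/action indices. `read_dataset()` converts
#' back to the package's 1-based in-memory form.
#'
#' @param ds a `transition_dataset` (or plain data.frame with the same
#'   columns).
#' @param path file path.
#' @param replicate replicate label written to the file.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   `transition_dataset`.
#' @export
write_dataset <- function(ds, path, replicate = 0L) {
  out <- data.frame(replicate = replicate,
                    step = seq_len(nrow(ds)) - 1L,
                    state = ds$state - 1L,
                    action = ds$action - 1L,
                    reward = ds$reward,
                    next_state = ds$next_state - 1L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path)
  needed <- c("state", "action", "reward", "next_state")
  if (!all(needed %in% names(raw)))
    stop("dataset CSV must have columns replicate,step,state,action,reward,next_state")
  ds <- data.frame(state = raw$state + 1L, action = raw$action + 1L,
                   next_state = raw$next_state + 1L, reward = raw$reward)
  class(ds) <- c("transition_dataset", "data.frame")
  ds
}
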