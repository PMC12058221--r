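#' Configure a regularization sweep
#'
#' Describes a replicated batch experiment: an environment, a dataset
#' scheme, a set of regularization methods, and a grid of regularization
#' strengths. Within each replicate all methods share the same dataset, so
#' loss curves are paired.
#'
#' @param environment list with `name` and optional `overrides` (see
#'   [make_environment()]).
#' @param n_replicates number of replicate datasets.
#' @param data list with `scheme` and `size` (see [sample_dataset()]).
#' @param methods character vector drawn from `"discount"`,
#'   `"uniform_prior"`, `"sa_specific"`, `"sa_oracle"`, `"fqi_discount"`,
#'   `"fqi_weighted"`. Grid methods are evaluated at every `epsilon_grid`
#'   point (discount methods at the matched `gamma_p = gamma (1 - eps)`);
#'   state-action-specific methods contribute one parameter-free loss per
#'   replicate.
#' @param epsilon_grid regularization strengths in `[0, 1]`.
#' @param master_seed integer master seed; replicate seeds are derived from
#'   it with [derive_seed()].
#' @param resample_env draw a fresh environment per replicate (the sampled
#'   environments, random chain and gridworld, are distributions over MDPs).
#' @param sa_mode mode for the state-action-specific model-based method
#'   (see [epsilon_star_from_data()]).
#' @param fqi_iterations iterations for the FQI methods.
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(environment, n_replicates = 200L,
                         data = list(scheme = "uniform_sa", size = 100L),
                         methods = c("discount", "uniform_prior",
                                     "sa_specific"),
                         epsilon_grid = seq(0.1, 0.9, by = 0.1),
                         master_seed = 1L, resample_env = TRUE,
                         sa_mode = "posterior_sample",
                         fqi_iterations = 30L) {
  if (any(epsilon_grid < 0) || any(epsilon_grid > 1))
    stop("`epsilon_grid` must lie in [0, 1]")
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1")
  known <- c("discount", "uniform_prior", "sa_specific", "sa_oracle",
             "fqi_discount", "fqi_weighted")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  structure(list(environment = environment,
                 n_replicates = as.integer(n_replicates), data = data,
                 methods = methods, epsilon_grid = epsilon_grid,
                 master_seed = as.integer(master_seed),
                 resample_env = isTRUE(resample_env), sa_mode = sa_mode,
                 fqi_iterations = as.integer(fqi_iterations)),
            class = "sweep_config")
}

#' Read a sweep configuration from YAML
#'
#' Top-level keys mirror the [sweep_config()] arguments; the regularizer
#' list lives under `methods` and the grid under `epsilon_grid`.
#'
#' @param path YAML file path.
#' @return a `sweep_config`.
#' @export
read_sweep_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(sweep_config)))]
  if (!is.null(args$epsilon_grid)) args$epsilon_grid <- unlist(args$epsilon_grid)
  if (!is.null(args$methods)) args$methods <- unlist(args$methods)
  do.call(sweep_config, args)
}

#' Run a regularization sweep
#'
#' For each replicate: draw (or reuse) the environment, sample a dataset,
#' fit and regularize per method and grid point, and score each learned
#' policy by [policy_loss()] against the true environment under its true
#' discount. Fully reproducible from the master seed.
#'
#' @param cfg a [sweep_config()].
#' @param progress emit per-replicate progress to stderr.
#' @return data.frame of class `sweep_result` with columns `method`,
#'   `param` (epsilon; `NA` for parameter-free methods), `replicate`,
#'   `loss`.
#' @export
run_sweep <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  env0 <- if (!cfg$resample_env)
    make_environment(cfg$environment$name, seed = cfg$master_seed,
                     overrides = cfg$environment$overrides %||% list())
  rows <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    env_seed <- derive_seed(cfg$master_seed, 2L * r)
    data_seed <- derive_seed(cfg$master_seed, 2L * r + 1L)
    mdp <- if (cfg$resample_env)
      make_environment(cfg$environment$name, seed = env_seed,
                       overrides = cfg$environment$overrides %||% list())
    else env0
    ds <- sample_dataset(mdp, scheme = cfg$data$scheme, size = cfg$data$size,
                         seed = data_seed)
    counts <- count_transitions(ds, mdp$n_states, mdp$n_actions)
    v_star <- optimal_values(mdp)
    rows[[r]] <- run_methods_one_replicate(cfg, mdp, ds, counts, v_star, r,
                                           data_seed)
    if (progress)
      message(sprintf("replicate %d/%d done", r, cfg$n_replicates))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_methods_one_replicate <- function(cfg, mdp, ds, counts, v_star, r,
                                      data_seed) {
  gamma <- mdp$gamma
  res <- list()
  add <- function(method, param, loss) {
    res[[length(res) + 1L]] <<- data.frame(method = method, param = param,
                                           replicate = r, loss = loss)
  }
  score <- function(policy) policy_loss(mdp, policy, v_star = v_star)
  for (method in cfg$methods) {
    if (method == "discount") {
      for (e in cfg$epsilon_grid) {
        spec <- regularization_spec("discount",
                                    gamma_p = gamma_p_from_epsilon(gamma, e))
        add(method, e, score(regularized_policy(counts, mdp$rewards, gamma,
                                                spec)$policy))
      }
    } else if (method == "uniform_prior") {
      # uniform Dirichlet prior with the SAME total magnitude at every
      # (s, a); the grid point e is the shrinkage weight it implies at the
      # average per-pair count, M = e / (1 - e) * n_bar. Unlike discount
      # regularization (shared eps), the implied eps then varies with
      # n(i, j): sparsely observed pairs are shrunk harder.
      n_bar <- nrow(ds) / (mdp$n_states * mdp$n_actions)
      for (e in cfg$epsilon_grid) {
        if (e >= 1) stop("epsilon_grid must stay below 1 for uniform_prior")
        m_tot <- e / (1 - e) * n_bar
        spec <- regularization_spec("dirichlet_prior",
                                    prior = m_tot / mdp$n_states)
        add(method, e, score(regularized_policy(counts, mdp$rewards, gamma,
                                                spec)$policy))
      }
    } else if (method %in% c("sa_specific", "sa_oracle")) {
      rep_mode <- if (method == "sa_oracle") "oracle_T" else cfg$sa_mode
      report <- epsilon_star_from_data(counts, mode = rep_mode,
                                       true_t = mdp$transitions,
                                       seed = derive_seed(data_seed, 7L))
      spec <- regularization_spec("sa_specific",
                                  epsilon = report$epsilon_star)
      add(method, NA_real_, score(regularized_policy(counts, mdp$rewards,
                                                     gamma, spec)$policy))
    } else if (method %in% c("fqi_discount", "fqi_weighted")) {
      for (e in cfg$epsilon_grid) {
        cfg_fqi <- if (method == "fqi_discount")
          fqi_config(gamma = gamma * (1 - e),
                     n_iterations = cfg$fqi_iterations,
                     epsilon_mode = "global", epsilon_global = 0)
        else fqi_config(gamma = gamma, n_iterations = cfg$fqi_iterations,
                        epsilon_mode = "global", epsilon_global = e)
        fit <- fqi_regularized(ds, mdp$rewards, cfg_fqi, mdp$n_states,
                               mdp$n_actions)
        add(method, e, score(fit$policy))
      }
    }
  }
  do.call(rbind, res)
}

#' Replicated continuous-state regularization comparison
#'
#' Repeats, for `n_replicates` seeded datasets from the continuous River
#' Swim environment: fit regularized fitted value iteration with the
#' state-action-specific weights and with each global epsilon in
#' `epsilon_grid` (epsilon 0 is the unregularized baseline), then score
#' every learned policy on a fixed exact discretization of the true
#' dynamics. Datasets and value-model seeds are shared across methods
#' within a replicate, so losses are paired.
#'
#' @param env a `continuous_env` (default [make_continuous_river_swim()]).
#' @param n_replicates replicate datasets.
#' @param dataset_size tuples per dataset.
#' @param epsilon_grid global epsilons to compare against; always includes
#'   the values given (use `0` for the unregularized baseline).
#' @param master_seed integer master seed.
#' @param n_sample_states,n_iterations,num_trees FVI settings.
#' @param n_cells evaluation grid resolution.
#' @param progress emit per-replicate progress to stderr.
#' @return `sweep_result` data.frame (`method` is `"fvi_sa_specific"` or
#'   `"fvi_global"`, `param` the epsilon or `NA`).
#' @export
run_continuous_sweep <- function(env = make_continuous_river_swim(),
                                 n_replicates = 100L, dataset_size = 30L,
                                 epsilon_grid = 0, master_seed = 1L,
                                 n_sample_states = 200L, n_iterations = 50L,
                                 num_trees = 50L, n_cells = 201L,
                                 progress = FALSE) {
  disc <- discretize_continuous(env, n_cells)
  v_star <- optimal_values(disc)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    data_seed <- derive_seed(master_seed, 3L * r)
    fit_seed <- derive_seed(master_seed, 3L * r + 1L)
    ds <- sample_continuous_dataset(env, dataset_size, seed = data_seed)
    km <- fit_kernel_model(ds, t_reg_mean = 0.5)
    res <- list()
    fit_sa <- fvi_regularized(
      ds, env$reward_fn, gamma = env$gamma,
      n_sample_states = n_sample_states, n_iterations = n_iterations,
      value_model = value_model_extratrees(num_trees, seed = fit_seed),
      mode = "sa_specific", rng_seed = fit_seed, kernel_model = km)
    res[[1L]] <- data.frame(
      method = "fvi_sa_specific", param = NA_real_, replicate = r,
      loss = continuous_policy_loss(env, fit_sa$policy_fn, disc = disc,
                                    v_star = v_star))
    for (e in epsilon_grid) {
      fit_g <- fvi_regularized(
        ds, env$reward_fn, gamma = env$gamma,
        n_sample_states = n_sample_states, n_iterations = n_iterations,
        value_model = value_model_extratrees(num_trees, seed = fit_seed),
        mode = "global", epsilon_global = e, rng_seed = fit_seed,
        kernel_model = km)
      res[[length(res) + 1L]] <- data.frame(
        method = "fvi_global", param = e, replicate = r,
        loss = continuous_policy_loss(env, fit_g$policy_fn, disc = disc,
                                      v_star = v_star))
    }
    rows[[r]] <- do.call(rbind, res)
    if (progress)
      message(sprintf("replicate %d/%d done", r, n_replicates))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Aggregate a sweep result
#'
#' Mean loss and standard error per (method, parameter) cell. Cells with a
#' single replicate report `NA` standard error; constant losses report 0.
#'
#' @param result a [run_sweep()] result.
#' @return data.frame with columns `method`, `param`, `n`, `mean_loss`,
#'   `se_loss`.
#' @export
summarize_sweep <- function(result) {
  if (nrow(result) == 0L) stop("empty sweep result")
  key <- interaction(result$method, result$param, drop = TRUE)
  parts <- split(result, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    n <- nrow(p)
    data.frame(method = p$method[1], param = p$param[1], n = n,
               mean_loss = mean(p$loss),
               se_loss = if (n > 1) stats::sd(p$loss) / sqrt(n) else NA_real_)
  }))
  # parameter-free methods are dropped by interaction() on NA params
  nap <- result[is.na(result$param), , drop = FALSE]
  if (nrow(nap) > 0L) {
    out2 <- do.call(rbind, lapply(split(nap, nap$method), function(p) {
      n <- nrow(p)
      data.frame(method = p$method[1], param = NA_real_, n = n,
                 mean_loss = mean(p$loss),
                 se_loss = if (n > 1) stats::sd(p$loss) / sqrt(n) else NA_real_)
    }))
    out <- rbind(out, out2)
  }
  out <- out[order(out$method, out$param), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot sweep loss curves
#'
#' Mean loss against regularization strength per method, with one-standard-
#' error ribbons; parameter-free methods are drawn as horizontal lines.
#' Requires ggplot2.
#'
#' @param result a [run_sweep()] result.
#' @return a ggplot object.
#' @export
plot_sweep <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep requires the ggplot2 package")
  sm <- summarize_sweep(result)
  curves <- sm[!is.na(sm$param), , drop = FALSE]
  flats <- sm[is.na(sm$param), , drop = FALSE]
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = param, y = mean_loss,
                                    colour = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean_loss - se_loss,
                                          ymax = mean_loss + se_loss)) +
    ggplot2::labs(x = "regularization strength (epsilon)",
                  y = "mean policy loss", colour = NULL)
  if (nrow(flats) > 0L)
    p <- p + ggplot2::geom_hline(
      data = flats,
      ggplot2::aes(yintercept = mean_loss, colour = method),
      linetype = "dashed")
  p
}

utils::globalVariables(c("param", "mean_loss", "se_loss", "method"))
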