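#' Habitual (model-free) Q-table of Beta posteriors
#'
#' The cache controller: one Beta posterior over the value of each
#' (state, action) pair, updated by bootstrapped, cost-adjusted targets.
#' Priors default to the uninformative Beta(1, 1).
#'
#' @param n_states number of (observed) states.
#' @param actions character vector of action names.
#' @param prior a [beta_dist()] used as prior for every entry.
#' @param state_names optional state labels.
#' @return An object of class `cache_q_table` holding `alpha` and `beta`
#'   matrices (states x actions) plus the matching prior matrices.
#' @export
cache_q_table <- function(n_states, actions, prior = beta_dist(1, 1),
                          state_names = NULL) {
  stopifnot(n_states >= 1, length(actions) >= 1, inherits(prior, "beta_dist"))
  dn <- list(state_names %||% as.character(seq_len(n_states)), actions)
  structure(list(
    alpha = matrix(prior$shape1, n_states, length(actions), dimnames = dn),
    beta  = matrix(prior$shape2, n_states, length(actions), dimnames = dn),
    prior_alpha = matrix(prior$shape1, n_states, length(actions), dimnames = dn),
    prior_beta  = matrix(prior$shape2, n_states, length(actions), dimnames = dn),
    actions = actions
  ), class = "cache_q_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior means of a cache table
#' @param table a [cache_q_table()].
#' @return Matrix of posterior means, states x actions.
#' @export
cache_means <- function(table) {
  stopifnot(inherits(table, "cache_q_table"))
  table$alpha / (table$alpha + table$beta)
}

#' Bootstrapped target mean for a cache update
#'
#' The discounted successor value plus the executed action's reward,
#' clamped into the Beta support:
#' mu_hat = clamp(gamma * mu_successor_best + r_a).
#'
#' @param successor_best_mean posterior mean of the successor's greedy action.
#' @param action_reward per-action transition reward (cost if negative).
#' @param gamma discount factor in \[0, 1\].
#' @return Target mean in \[0.001, 0.999\].
#' @export
td_target_mean <- function(successor_best_mean, action_reward, gamma) {
  clamp_unit_interval(gamma * successor_best_mean + action_reward)
}

#' Update one cache entry from an executed transition
#'
#' Non-terminal transitions build a reshaped target distribution from the
#' successor's greedy-action posterior (see [reshape_to_mean()]) at the
#' bootstrapped mean [td_target_mean()], then fold it into the entry with
#' [mixture_update()]. Terminal transitions perform a fractional Bernoulli
#' update with the observed reward: alpha += clamp(r_obs + r_a),
#' beta += 1 - clamp(r_obs + r_a), clamped to \[0, 1\].
#'
#' @param table a [cache_q_table()].
#' @param state,action indices (or action name) of the executed pair.
#' @param successor_best the successor's greedy-action [beta_dist()]
#'   (non-terminal case); leave `NULL` for terminal transitions.
#' @param terminal_reward observed terminal reward (terminal case).
#' @param action_reward per-action reward of the executed action.
#' @param gamma discount factor.
#' @return The updated `cache_q_table`.
#' @export
cache_update <- function(table, state, action, successor_best = NULL,
                         terminal_reward = NULL, action_reward = 0,
                         gamma = 1) {
  stopifnot(inherits(table, "cache_q_table"))
  if (is.character(action)) action <- match(action, table$actions)
  if (is.na(action) || action < 1 || action > ncol(table$alpha))
    stop("unknown action")
  if (state < 1 || state > nrow(table$alpha)) stop("unknown state")
  if (is.null(successor_best) == is.null(terminal_reward))
    stop("supply exactly one of successor_best or terminal_reward")
  if (!is.null(terminal_reward)) {
    tr <- min(max(terminal_reward + action_reward, 0), 1)
    table$alpha[state, action] <- table$alpha[state, action] + tr
    table$beta[state, action] <- table$beta[state, action] + (1 - tr)
  } else {
    stopifnot(inherits(successor_best, "beta_dist"))
    mu <- beta_moments(successor_best)[["mean"]]
    target <- reshape_to_mean(successor_best,
                              td_target_mean(mu, action_reward, gamma))
    post <- mixture_update(beta_dist(table$alpha[state, action],
                                     table$beta[state, action]), target)
    table$alpha[state, action] <- post$shape1
    table$beta[state, action] <- post$shape2
  }
  table
}

#' Best and second-best actions by posterior mean
#'
#' Ties are broken by the fixed action ordering of the table so that seeded
#' runs are reproducible.
#'
#' @param table a [cache_q_table()].
#' @param state state index.
#' @return Named integer vector `c(best = , second = )`.
#' @export
best_and_second <- function(table, state) {
  stopifnot(inherits(table, "cache_q_table"))
  m <- cache_means(table)[state, ]
  if (length(m) < 2L) stop("best_and_second needs at least 2 actions")
  b <- unname(which.max(m))       # first index on ties
  rest <- setdiff(seq_along(m), b)
  s <- unname(rest[which.max(m[rest])])
  c(best = b, second = s)
}

#' Apply forgetting decay to every cache entry
#'
#' @param table a [cache_q_table()].
#' @param theta forgetting factor in \[0, 1\].
#' @return The decayed table.
#' @export
cache_decay <- function(table, theta) {
  table$alpha <- decay_toward_prior(table$alpha, table$prior_alpha, theta)
  table$beta <- decay_toward_prior(table$beta, table$prior_beta, theta)
  table
}
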