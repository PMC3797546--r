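#' Goal-directed world model
#'
#' Dirichlet transition rows per (state, action), a Beta reward model per
#' state (only terminal states matter to planning), and the magnitude of the
#' most recent transition-mean shift per (state, action) - the quantity the
#' learning-progress intrinsic reward is proportional to.
#'
#' @param n_states number of (observed) states.
#' @param actions character vector of action names.
#' @param terminal logical vector marking terminal states.
#' @param transition_prior Dirichlet concentration alpha_i for every
#'   successor (default 0.1).
#' @param reward_prior prior [beta_dist()] of the per-state reward model.
#' @param state_names optional state labels.
#' @return An object of class `world_model`.
#' @export
world_model <- function(n_states, actions, terminal = rep(FALSE, n_states),
                        transition_prior = 0.1,
                        reward_prior = beta_dist(1, 1), state_names = NULL) {
  stopifnot(n_states >= 1, length(actions) >= 1,
            length(terminal) == n_states, transition_prior > 0)
  A <- length(actions)
  dn <- list(state_names %||% as.character(seq_len(n_states)), actions)
  structure(list(
    counts = array(transition_prior, dim = c(n_states, A, n_states)),
    transition_prior = transition_prior,
    reward_alpha = rep(reward_prior$shape1, n_states),
    reward_beta = rep(reward_prior$shape2, n_states),
    reward_prior_alpha = rep(reward_prior$shape1, n_states),
    reward_prior_beta = rep(reward_prior$shape2, n_states),
    last_shift = matrix(0, n_states, A, dimnames = dn),
    terminal = terminal,
    actions = actions
  ), class = "world_model")
}

#' Record an observed transition and its learning progress
#'
#' Increments the successor's concentration in the (state, action) Dirichlet
#' row by one and returns the summed absolute shift of the row's mean vector,
#' which is stored as the pair's most recent shift. Shifts caused by
#' forgetting decay are deliberately not counted: decay is homogeneous across
#' the table and would manufacture uniform spurious "progress".
#'
#' @param model a [world_model()].
#' @param state,action,successor indices (action may be a name).
#' @return `list(model = updated model, shift = shift magnitude)`.
#' @export
observe_transition <- function(model, state, action, successor) {
  stopifnot(inherits(model, "world_model"))
  if (is.character(action)) action <- match(action, model$actions)
  n <- dim(model$counts)[1]
  if (is.na(action) || state < 1 || state > n || successor < 1 ||
      successor > n)
    stop("unknown state/action/successor index")
  old <- model$counts[state, action, ]
  new <- old
  new[successor] <- new[successor] + 1
  shift <- sum(abs(new / sum(new) - old / sum(old)))
  model$counts[state, action, ] <- new
  model$last_shift[state, action] <- shift
  list(model = model, shift = shift)
}

#' Learning-progress intrinsic reward
#'
#' I(s, a) = iota * sum_s' |delta mean(s, a, s')| for the most recent
#' observation of the pair; zero for never-observed pairs.
#'
#' @param model a [world_model()].
#' @param state,action indices (action may be a name).
#' @param iota scaling factor bringing intrinsic rewards to the order of
#'   magnitude of extrinsic ones.
#' @return Non-negative reward.
#' @export
intrinsic_reward <- function(model, state, action, iota) {
  stopifnot(inherits(model, "world_model"))
  if (is.character(action)) action <- match(action, model$actions)
  iota * model$last_shift[state, action]
}

#' Bernoulli-style reward-model update on goal entry
#'
#' Same fractional rule as the cache's terminal update so reward means track
#' observed outcome frequencies.
#'
#' @param model a [world_model()].
#' @param state terminal state entered.
#' @param reward observed extrinsic reward (clamped to \[0, 1\]).
#' @return The updated model.
#' @export
observe_reward <- function(model, state, reward) {
  stopifnot(inherits(model, "world_model"))
  r <- min(max(reward, 0), 1)
  model$reward_alpha[state] <- model$reward_alpha[state] + r
  model$reward_beta[state] <- model$reward_beta[state] + (1 - r)
  model
}

#' Posterior mean rewards of the model's states
#' @param model a [world_model()].
#' @return Numeric vector of reward means.
#' @export
reward_means <- function(model) {
  model$reward_alpha / (model$reward_alpha + model$reward_beta)
}

#' Tree search: value iteration on the learned model
#'
#' Iterates Q(s,a) <- r_a \[+ I(s,a) if scope = "global"\] +
#' gamma * sum_s' Pbar(s'|s,a) V(s'), with V equal to the reward-model mean
#' at terminal states and max_a Q elsewhere, until the max absolute change
#' falls below `tol` or the sweep cap is hit. Under global scope the
#' intrinsic reward enters every backup; under local scope it is added only
#' afterwards at the queried root (see [augmented_q()]).
#'
#' @param model a [world_model()].
#' @param gamma discount factor.
#' @param action_rewards numeric vector of per-action rewards.
#' @param scope `"local"` or `"global"` intrinsic-reward scope.
#' @param iota intrinsic scaling (used in the backup only when global).
#' @param tol max-norm convergence tolerance (default 1e-4).
#' @param max_sweeps sweep cap (default 1000); hitting it flags
#'   `converged = FALSE` but is not fatal.
#' @param init optional warm-start Q matrix (same fixed point for gamma < 1).
#' @return An object of class `tree_q`: `values` (states x actions matrix),
#'   `converged`, `sweeps_used`.
#' @export
value_iteration <- function(model, gamma, action_rewards, scope = "local",
                            iota = 0, tol = 1e-4, max_sweeps = 1000,
                            init = NULL) {
  stopifnot(inherits(model, "world_model"))
  scope <- match.arg(scope, c("local", "global"))
  S <- dim(model$counts)[1]
  A <- dim(model$counts)[2]
  stopifnot(length(action_rewards) == A)
  res <- value_iteration_cpp(
    as.numeric(model$counts), S, A, model$terminal, reward_means(model),
    as.numeric(action_rewards), gamma, tol, as.integer(max_sweeps),
    as.numeric(model$last_shift),
    if (scope == "global") iota else 0,
    if (is.null(init)) NULL else as.numeric(init))
  dimnames(res$q) <- dimnames(model$last_shift)
  structure(list(values = res$q, converged = res$converged,
                 sweeps_used = res$sweeps, scope = scope),
            class = "tree_q")
}

#' Intrinsic-augmented tree values at a state
#'
#' Under local scope returns Q_tree(state, .) + I(state, .); under global
#' scope the intrinsic rewards are already inside the backups and the values
#' pass through unchanged.
#'
#' @param tree a `tree_q` from [value_iteration()].
#' @param model the [world_model()] the tree was computed from.
#' @param state state index.
#' @param iota intrinsic scaling factor.
#' @return Named numeric vector of values per action.
#' @export
augmented_q <- function(tree, model, state, iota) {
  stopifnot(inherits(tree, "tree_q"), inherits(model, "world_model"))
  q <- tree$values[state, ]
  if (identical(tree$scope, "global")) return(q)
  q + iota * model$last_shift[state, ]
}

#' Devalue a terminal state's extrinsic reward model
#'
#' Replaces both the reward entry and its prior so forgetting decay cannot
#' restore the old value. The canonical devaluation distribution is
#' Beta(1, 15), concentrating mass near zero.
#'
#' @param model a [world_model()].
#' @param state terminal state to devalue.
#' @param new_reward replacement [beta_dist()].
#' @return The updated model.
#' @export
devalue_state <- function(model, state, new_reward = beta_dist(1, 15)) {
  stopifnot(inherits(model, "world_model"), inherits(new_reward, "beta_dist"))
  S <- length(model$reward_alpha)
  if (state < 1 || state > S) stop("unknown state")
  model$reward_alpha[state] <- new_reward$shape1
  model$reward_beta[state] <- new_reward$shape2
  model$reward_prior_alpha[state] <- new_reward$shape1
  model$reward_prior_beta[state] <- new_reward$shape2
  model
}

#' Apply forgetting decay to all model parameters
#' @param model a [world_model()].
#' @param theta forgetting factor in \[0, 1\].
#' @return The decayed model.
#' @export
model_decay <- function(model, theta) {
  model$counts <- decay_toward_prior(
    model$counts, array(model$transition_prior, dim = dim(model$counts)),
    theta)
  model$reward_alpha <- decay_toward_prior(model$reward_alpha,
                                           model$reward_prior_alpha, theta)
  model$reward_beta <- decay_toward_prior(model$reward_beta,
                                          model$reward_prior_beta, theta)
  model
}
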