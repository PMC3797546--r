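#' Agent configuration
#'
#' Defaults are the Playroom task's published parameter set; use
#' [feeder_config()] for the feeder tasks. All randomness in a run flows from
#' R's RNG seeded with `seed`.
#'
#' @param epsilon exploration probability of the epsilon-greedy policy.
#' @param gamma reward discount factor.
#' @param theta per-step forgetting factor (pseudo-counts decay toward their
#'   priors as theta * p + (1 - theta) * prior).
#' @param iota intrinsic-reward scaling factor.
#' @param tau deliberation cost per tree edge.
#' @param eta average-reward learning rate.
#' @param transition_prior Dirichlet concentration alpha_i of the initial
#'   transition model.
#' @param reward_prior prior [beta_dist()] of the goal-directed reward model
#'   (uninformative Beta(1, 1) by default, like the cache prior). Note the
#'   planner treats a state as terminal only after an episode has actually
#'   ended there, so unexperienced goals are not planning targets regardless
#'   of this prior.
#' @param intrinsic_enabled switch learning-progress rewards on/off.
#' @param scope `"local"` (intrinsic reward added to the root tree values
#'   after the search) or `"global"` (added to every backup target).
#' @param reward_mode `"observed"` average reward or `"fixed"`
#'   (promised-reward manipulation).
#' @param fixed_value R-bar value in fixed mode.
#' @param seed integer seed for the run (`NULL` = leave RNG state alone).
#' @param vi_tol,vi_max_sweeps value-iteration convergence controls.
#' @param vi_warm_start reuse the previous search's Q as initialisation when
#'   gamma < 1 (identical fixed point, large speedup).
#' @return An `agent_config` list.
#' @export
agent_config <- function(epsilon = 0.2, gamma = 0.95, theta = 0.9999,
                         iota = 2.0, tau = 0.1, eta = 0.001,
                         transition_prior = 0.1,
                         reward_prior = beta_dist(1, 1),
                         intrinsic_enabled = TRUE,
                         scope = c("local", "global"),
                         reward_mode = c("observed", "fixed"),
                         fixed_value = 1, seed = NULL,
                         vi_tol = 1e-4, vi_max_sweeps = 1000L,
                         vi_warm_start = TRUE) {
  scope <- match.arg(scope)
  reward_mode <- match.arg(reward_mode)
  stopifnot(epsilon >= 0, epsilon <= 1, gamma >= 0, gamma <= 1,
            theta >= 0, theta <= 1, iota >= 0, tau >= 0,
            eta > 0, eta < 1, transition_prior > 0,
            inherits(reward_prior, "beta_dist"))
  structure(list(epsilon = epsilon, gamma = gamma, theta = theta,
                 iota = iota, tau = tau, eta = eta,
                 transition_prior = transition_prior,
                 reward_prior = reward_prior,
                 intrinsic_enabled = intrinsic_enabled, scope = scope,
                 reward_mode = reward_mode, fixed_value = fixed_value,
                 seed = seed, vi_tol = vi_tol,
                 vi_max_sweeps = as.integer(vi_max_sweeps),
                 vi_warm_start = vi_warm_start),
            class = "agent_config")
}

#' Feeder-task configuration
#'
#' The feeder parameter set: search cost 0.1, exploration 0.2, intrinsic
#' factor 2.0 (the published feeder values), the faster forgetting
#' (theta = 0.98) of the predecessor models the task was inherited from, the
#' unchanged discount gamma = 0.95, and a longer average-reward horizon
#' (eta = 1e-4): feeder trials are two steps, so the per-step reward rate is
#' an order of magnitude above the Playroom's, and a larger eta would let
#' the opportunity cost R-bar * tau overtake the persistent ambiguity VPI
#' (~1e-3) long before the extensive-training mark, destroying the early
#' flexibility / late resistance distinction.
#'
#' @param ... overrides passed to [agent_config()].
#' @return An `agent_config`.
#' @export
feeder_config <- function(...) {
  args <- list(...)
  defaults <- list(gamma = 0.95, theta = 0.98, eta = 1e-4)
  agent_config_args <- utils::modifyList(defaults, args)
  do.call(agent_config, agent_config_args)
}

#' Per-action system selection and mixed Q-values
#'
#' For each action, the VPI of the cache posterior is compared with the
#' opportunity cost R-bar * tau. If any action calls for the goal-directed
#' system, one value iteration serves all tree-selected actions this cycle;
#' the rest answer from the cache. Under local scope the tree values at the
#' queried state receive the intrinsic bonus.
#'
#' @param state observed-state index (non-terminal).
#' @param cache a [cache_q_table()].
#' @param model a [world_model()].
#' @param arb an [arbitration_state()].
#' @param config an [agent_config()].
#' @param action_rewards per-action rewards of the task.
#' @return `list(qstar, systems, searched, tree)` where `qstar` is the mixed
#'   value per action, `systems` is `"tree"`/`"cache"` per action, and `tree`
#'   is the `tree_q` (or `NULL` when no search ran).
#' @export
decide <- function(state, cache, model, arb, config, action_rewards) {
  A <- length(cache$actions)
  v <- vapply(seq_len(A), function(a) vpi(cache, state, a), numeric(1))
  systems <- vapply(v, select_system, character(1), arb = arb)
  searched <- any(systems == "tree")
  tree <- NULL
  qstar <- cache_means(cache)[state, ]
  if (searched) {
    tree <- value_iteration(model, config$gamma, action_rewards,
                            scope = config$scope,
                            iota = if (config$intrinsic_enabled) config$iota else 0,
                            tol = config$vi_tol,
                            max_sweeps = config$vi_max_sweeps)
    aq <- augmented_q(tree, model, state,
                      if (config$intrinsic_enabled) config$iota else 0)
    sel <- systems == "tree"
    qstar[sel] <- aq[sel]
  }
  names(systems) <- cache$actions
  list(qstar = qstar, systems = systems, searched = searched, tree = tree)
}

#' Epsilon-greedy action choice
#'
#' The greedy action is the argmax of the mixed Q-values (exact ties
#' resolved uniformly at random); with probability epsilon a uniformly random
#' action is executed instead. Both actions are reported because behavioural
#' metrics are computed on the theoretical greedy choice.
#'
#' @param qstar named numeric vector of mixed Q-values.
#' @param epsilon exploration probability.
#' @return `list(greedy = index, executed = index)`.
#' @export
act <- function(qstar, epsilon) {
  stopifnot(length(qstar) >= 1)
  mx <- max(qstar)
  ties <- which(qstar == mx)
  greedy <- if (length(ties) > 1L) {
    ties[floor(runif(1) * length(ties)) + 1L]
  } else ties[1L]
  executed <- greedy
  if (epsilon > 0 && runif(1) < epsilon) {
    executed <- min(floor(runif(1) * length(qstar)) + 1L, length(qstar))
  }
  list(greedy = as.integer(greedy), executed = as.integer(executed))
}

#' Run a seeded batch of episodes
#'
#' Executes the full decision loop (decide, act, transition, model
#' observation, cache update, reward-model update on goal entry, average
#' reward, forgetting decay — in that fixed order) for `n_episodes` episodes,
#' applying scheduled devaluations between episodes. The loop runs in
#' compiled code; one row is logged per environment step.
#'
#' @param env an [mdp_spec()].
#' @param config an [agent_config()]; its `seed` (if non-`NULL`) seeds R's
#'   RNG before the run.
#' @param n_episodes number of episodes.
#' @param schedule list of [devaluation_event()] entries.
#' @return A data frame with one row per step: episode/step indices, observed
#'   and true state, greedy (pre-exploration) and executed action, whether a
#'   tree search ran (`searched`), the per-action system-choice bitmask
#'   (`system_mask`, bit a set = action a answered by the tree), cumulative
#'   `tree_searches`, extrinsic/action/intrinsic rewards, the R-bar snapshot,
#'   successor state, episode-`terminal` flag, and the mixed Q-values
#'   `qstar_*`. The final agent state is attached as attribute `"final"`,
#'   the configuration as `"config"`.
#' @export
run_episodes <- function(env, config, n_episodes, schedule = list()) {
  stopifnot(inherits(env, "mdp_spec"), inherits(config, "agent_config"),
            n_episodes >= 0)
  A <- env$n_actions
  cols <- c("episode", "step", "obs_state", "true_state", "greedy_action",
            "executed_action", "searched", "system_mask", "tree_searches",
            "reward_extrinsic", "reward_action", "reward_intrinsic",
            "avg_reward", "next_true", "next_obs", "terminal",
            paste0("qstar_", env$actions))
  if (n_episodes == 0) {
    tr <- as.data.frame(matrix(numeric(0), 0, length(cols),
                               dimnames = list(NULL, cols)))
    attr(tr, "final") <- NULL
    attr(tr, "config") <- config
    return(tr)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- list(epsilon = config$epsilon, gamma = config$gamma,
              theta = config$theta, iota = config$iota, tau = config$tau,
              eta = config$eta, transition_prior = config$transition_prior,
              reward_prior_alpha = config$reward_prior$shape1,
              reward_prior_beta = config$reward_prior$shape2,
              intrinsic_enabled = config$intrinsic_enabled,
              scope_global = identical(config$scope, "global"),
              fixed_mode = identical(config$reward_mode, "fixed"),
              fixed_value = config$fixed_value, vi_tol = config$vi_tol,
              vi_max_sweeps = config$vi_max_sweeps,
              vi_warm_start = config$vi_warm_start)
  res <- run_sim_cpp(unclass(env), cfg, as.integer(n_episodes), schedule)
  m <- res$trace[seq_len(res$rows), , drop = FALSE]
  colnames(m) <- cols
  tr <- as.data.frame(m)
  attr(tr, "final") <- list(
    cache_alpha = res$cache_alpha, cache_beta = res$cache_beta,
    counts = res$counts, reward_alpha = res$reward_alpha,
    reward_beta = res$reward_beta, last_shift = res$last_shift,
    tree_q = res$tree_q, avg_reward = res$avg_reward,
    tree_searches = res$tree_searches)
  attr(tr, "config") <- config
  attr(tr, "env_name") <- env$name
  attr(tr, "actions") <- env$actions
  tr
}

#' Did the greedy action answer from the tree?
#'
#' Decodes the per-action system bitmask of a trace for the recorded greedy
#' action.
#'
#' @param trace a [run_episodes()] trace.
#' @return Logical vector, `TRUE` where the greedy action's value came from
#'   the goal-directed system.
#' @export
greedy_used_tree <- function(trace) {
  bitwAnd(as.integer(trace$system_mask),
          bitwShiftL(1L, as.integer(trace$greedy_action) - 1L)) > 0L
}

#' Write a trace and its metadata to disk
#'
#' One CSV row per step plus a JSON sidecar echoing the configuration and
#' package version, so a run is fully reproducible from its output directory.
#'
#' @param trace a [run_episodes()] trace.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return Invisibly, the CSV path.
#' @export
write_trace <- function(trace, dir, name = "trace") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  write.csv(trace, csv, row.names = FALSE)
  cfg <- unclass(attr(trace, "config"))
  cfg$reward_prior <- c(cfg$reward_prior$shape1, cfg$reward_prior$shape2)
  meta <- list(config = cfg, env = attr(trace, "env_name"),
               package_version = as.character(utils::packageVersion("habitree")))
  jsonlite::write_json(meta, file.path(dir, paste0(name, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(csv)
}
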