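#' Construct a tabular MDP specification
#'
#' The environment container shared by the built-in tasks and by hand-written
#' fixture MDPs. Dynamics always evolve on true states; the agent indexes all
#' of its learning structures by the observed states given by `obs_map`,
#' which is what creates partial observability (and the resulting local
#' minima) in the Playroom.
#'
#' @param states character vector of true-state names.
#' @param actions character vector of action names.
#' @param trans numeric array (states x actions x states) of transition
#'   probabilities; every row must sum to 1 (terminal states self-loop).
#' @param terminal logical vector marking terminal states.
#' @param reward_value extrinsic reward delivered on entering each state
#'   (only terminal entries are ever paid out).
#' @param action_rewards per-action transition reward (cost if negative).
#' @param start index or name of the start state.
#' @param step_cap episode truncation length.
#' @param obs_map integer vector mapping true states to observed-state
#'   indices (default: identity, full observability).
#' @param obs_states optional observed-state names.
#' @param name label for the task.
#' @return An object of class `mdp_spec`.
#' @export
mdp_spec <- function(states, actions, trans, terminal, reward_value,
                     action_rewards, start, step_cap = 100,
                     obs_map = NULL, obs_states = NULL, name = "custom") {
  S <- length(states)
  A <- length(actions)
  stopifnot(identical(dim(trans), c(S, A, S)), length(terminal) == S,
            length(reward_value) == S, length(action_rewards) == A)
  if (is.character(start)) start <- match(start, states)
  stopifnot(!is.na(start), start >= 1, start <= S, !terminal[start])
  if (is.null(obs_map)) {
    obs_map <- seq_len(S)
    obs_states <- states
  }
  stopifnot(length(obs_map) == S, all(obs_map >= 1))
  n_obs <- max(obs_map)
  if (is.null(obs_states)) obs_states <- as.character(seq_len(n_obs))
  terminal_obs <- vapply(seq_len(n_obs),
                         function(o) any(terminal[obs_map == o]), logical(1))
  spec <- structure(list(
    name = name,
    states = states, actions = actions,
    n_true = S, n_obs = n_obs, n_actions = A,
    trans = trans, obs_map = as.integer(obs_map), obs_states = obs_states,
    terminal_true = terminal, terminal_obs = terminal_obs,
    reward_kind = integer(S),              # 0 = constant, 1 = Beta draw
    reward_value = as.numeric(reward_value),
    reward_alpha = rep(1, S), reward_beta = rep(1, S),
    action_rewards = as.numeric(action_rewards),
    start = as.integer(start), step_cap = as.integer(step_cap)
  ), class = "mdp_spec")
  validate_mdp(spec)
  spec
}

#' Validate an MDP specification
#'
#' Checks transition rows sum to 1, terminal states only self-loop, and the
#' observation map is total.
#'
#' @param spec an [mdp_spec()].
#' @return The spec, invisibly; errors on violation.
#' @export
validate_mdp <- function(spec) {
  stopifnot(inherits(spec, "mdp_spec"))
  sums <- apply(spec$trans, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-9)) stop("transition rows must sum to 1")
  for (s in which(spec$terminal_true)) {
    for (a in seq_len(spec$n_actions)) {
      if (spec$trans[s, a, s] != 1)
        stop("terminal states must have no outgoing transitions")
    }
  }
  if (any(is.na(spec$obs_map)) || length(spec$obs_map) != spec$n_true)
    stop("observation map must be total")
  invisible(spec)
}

#' @export
print.mdp_spec <- function(x, ...) {
  cat(sprintf("<mdp_spec '%s'> %d true states (%d observed), %d actions, %d terminal\n",
              x$name, x$n_true, x$n_obs, x$n_actions, sum(x$terminal_true)))
  invisible(x)
}

#' Observe a true state
#'
#' Identity for the feeder; in the Playroom with the light off, hand or eye
#' positions on either coloured box are reported as the generic `some_box`.
#'
#' @param spec an [mdp_spec()].
#' @param state true-state index.
#' @return Observed-state index.
#' @export
observe <- function(spec, state) {
  stopifnot(inherits(spec, "mdp_spec"))
  spec$obs_map[state]
}

# ---------------------------------------------------------------------------
# Feeder task
# ---------------------------------------------------------------------------

#' The feeder (lever press / magazine entry) task
#'
#' A two-decision task modelled on rat conditioning experiments: only a press
#' followed by an entry pays out; any other sequence restarts the apparatus,
#' i.e. returns the agent to the start state within the same trial. The
#' moderate variant adds a chain-pulling action whose chain-then-entry
#' sequence earns an equivalent reward at a distinct terminal, creating
#' persistent ambiguity between press and chain.
#'
#' Action rewards are zero; the cost of a failed sequence is the discounting
#' of the restart path (the restart route is worth gamma^2 times the optimal
#' one), which is what keeps the two actions' value posteriors overlapping
#' and the ambiguity VPI alive. Episodes end only at the rewarded terminals.
#'
#' @param variant `"simple"` (press/entry) or `"moderate"` (adds chain).
#' @return An [mdp_spec()].
#' @export
make_feeder <- function(variant = c("simple", "moderate")) {
  variant <- match.arg(variant)
  if (variant == "simple") {
    states <- c("S0", "S1", "T+")
    actions <- c("press", "entry")
    edges <- list(S0 = c(press = "S1", entry = "S0"),
                  S1 = c(press = "S0", entry = "T+"))
    terminal <- c(FALSE, FALSE, TRUE)
    reward <- c(0, 0, 1)
  } else {
    states <- c("S0", "S1", "S2", "T+", "T+2")
    actions <- c("press", "entry", "chain")
    edges <- list(S0 = c(press = "S1", entry = "S0", chain = "S2"),
                  S1 = c(press = "S0", entry = "T+", chain = "S0"),
                  S2 = c(press = "S0", entry = "T+2", chain = "S0"))
    terminal <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
    reward <- c(0, 0, 0, 1, 1)
  }
  S <- length(states)
  A <- length(actions)
  trans <- array(0, dim = c(S, A, S))
  for (s in seq_len(S)) {
    if (terminal[s]) {
      trans[s, , s] <- 1
      next
    }
    for (a in seq_len(A)) {
      nxt <- match(edges[[states[s]]][[actions[a]]], states)
      trans[s, a, nxt] <- 1
    }
  }
  mdp_spec(states, actions, trans, terminal, reward,
           action_rewards = rep(0, A), start = "S0", step_cap = 50,
           name = paste0("feeder-", variant))
}

# ---------------------------------------------------------------------------
# Playroom task
# ---------------------------------------------------------------------------

playroom_objects <- c("blue_box", "red_box", "switch", "monkey")
playroom_actions <- c("use", "eye_to_random", "hand_to_eye", "null")

#' Goal specification for the Playroom
#'
#' Required music/light values plus optional hand/eye constraints. A state is
#' a goal (terminal) state when all conditions hold on the true state.
#'
#' @param music,light required logical values.
#' @param hand,eye optional character subsets of
#'   `c("blue_box", "red_box", "switch", "monkey")`; `NULL` = unconstrained.
#' @return A `playroom_goal` list.
#' @export
playroom_goal <- function(music = TRUE, light = FALSE,
                          hand = NULL, eye = NULL) {
  for (v in list(hand, eye)) {
    if (!is.null(v) && !all(v %in% playroom_objects))
      stop("goal hand/eye constraints must name Playroom objects")
  }
  stopifnot(is.logical(music), is.logical(light))
  structure(list(music = music, light = light, hand = hand, eye = eye),
            class = "playroom_goal")
}

#' Start configuration for the Playroom
#'
#' Defaults: light and music off, hand and eye resting on the neutral toy
#' monkey.
#'
#' @param light,music initial logicals.
#' @param hand,eye initial object names.
#' @return A `playroom_start` list.
#' @export
playroom_start <- function(light = FALSE, music = FALSE,
                           hand = "monkey", eye = "monkey") {
  stopifnot(hand %in% playroom_objects, eye %in% playroom_objects)
  structure(list(light = light, music = music, hand = hand, eye = eye),
            class = "playroom_start")
}

#' The Playroom object-manipulation task
#'
#' The agent owns a hand and an eye; an object becomes usable only when both
#' rest on it. Using the blue box starts music, the red box stops it, the
#' switch toggles the light, and the toy monkey does nothing (a neutral
#' distractor). With the light off the two coloured boxes are observationally
#' indistinguishable. `eye_to_random` moves the eye to a uniformly random
#' object (the one non-deterministic action), `hand_to_eye` co-locates the
#' hand, and `null` does nothing but earns a small positive action reward
#' (+0.005) while every other action costs -0.02.
#'
#' @param goal a [playroom_goal()].
#' @param start a [playroom_start()].
#' @param extrinsic if `FALSE` the goal states stay terminal but pay 0
#'   (the "no external rewards whatsoever" settings).
#' @param step_cap episode truncation length (default 100 actions).
#' @return An [mdp_spec()]; the true-state table is attached as
#'   `$state_table`.
#' @export
make_playroom <- function(goal = playroom_goal(), start = playroom_start(),
                          extrinsic = TRUE, step_cap = 100) {
  stopifnot(inherits(goal, "playroom_goal"), inherits(start, "playroom_start"))
  tab <- expand.grid(hand = 1:4, eye = 1:4, light = 0:1, music = 0:1)
  S <- nrow(tab)  # 64
  idx <- function(h, e, l, m) h + 4 * (e - 1) + 16 * l + 32 * m
  terminal <- with(tab, music == as.integer(goal$music) &
                        light == as.integer(goal$light) &
                        (if (is.null(goal$hand)) TRUE
                         else playroom_objects[hand] %in% goal$hand) &
                        (if (is.null(goal$eye)) TRUE
                         else playroom_objects[eye] %in% goal$eye))
  A <- length(playroom_actions)
  trans <- array(0, dim = c(S, A, S))
  for (s in seq_len(S)) {
    if (terminal[s]) {
      trans[s, , s] <- 1
      next
    }
    h <- tab$hand[s]; e <- tab$eye[s]; l <- tab$light[s]; m <- tab$music[s]
    # use: affordance fires only when hand and eye are co-located
    h2 <- h; e2 <- e; l2 <- l; m2 <- m
    if (h == e) {
      if (h == 1) m2 <- 1          # blue box starts music
      else if (h == 2) m2 <- 0     # red box stops it
      else if (h == 3) l2 <- 1 - l # switch toggles the light
    }
    trans[s, 1, idx(h2, e2, l2, m2)] <- 1
    # eye_to_random: uniform over all four objects (may stay put)
    for (e2 in 1:4)
      trans[s, 2, idx(h, e2, l, m)] <- trans[s, 2, idx(h, e2, l, m)] + 0.25
    # hand_to_eye
    trans[s, 3, idx(e, e, l, m)] <- 1
    # null
    trans[s, 4, s] <- 1
  }
  # observation: boxes merge when the light is off
  obs_token <- function(h, e, l, m) {
    if (l == 1) sprintf("on:%s:%s:M%d", playroom_objects[h],
                        playroom_objects[e], m)
    else {
      merge <- c("some_box", "some_box", "switch", "monkey")
      sprintf("off:%s:%s:M%d", merge[h], merge[e], m)
    }
  }
  tokens <- mapply(obs_token, tab$hand, tab$eye, tab$light, tab$music)
  obs_states <- unique(tokens)
  obs_map <- match(tokens, obs_states)
  start_idx <- idx(match(start$hand, playroom_objects),
                   match(start$eye, playroom_objects),
                   as.integer(start$light), as.integer(start$music))
  if (terminal[start_idx]) stop("inconsistent goal-spec: start state is a goal state")
  reward <- ifelse(terminal, if (extrinsic) 1 else 0, 0)
  states <- sprintf("%s|%s|L%d|M%d", playroom_objects[tab$hand],
                    playroom_objects[tab$eye], tab$light, tab$music)
  spec <- mdp_spec(states, playroom_actions, trans, terminal, reward,
                   action_rewards = c(-0.02, -0.02, -0.02, 0.005),
                   start = start_idx, step_cap = step_cap,
                   obs_map = obs_map, obs_states = obs_states,
                   name = "playroom")
  spec$state_table <- tab
  spec$goal <- goal
  spec
}

#' Select Playroom true states by attribute
#'
#' @param spec a Playroom [mdp_spec()].
#' @param hand,eye optional object-name subsets.
#' @param light,music optional logicals.
#' @param terminal optional logical filter on terminality.
#' @return Integer vector of true-state indices.
#' @export
playroom_states <- function(spec, hand = NULL, eye = NULL, light = NULL,
                            music = NULL, terminal = NULL) {
  stopifnot(inherits(spec, "mdp_spec"), !is.null(spec$state_table))
  tab <- spec$state_table
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(hand)) keep <- keep & playroom_objects[tab$hand] %in% hand
  if (!is.null(eye)) keep <- keep & playroom_objects[tab$eye] %in% eye
  if (!is.null(light)) keep <- keep & tab$light == as.integer(light)
  if (!is.null(music)) keep <- keep & tab$music == as.integer(music)
  if (!is.null(terminal)) keep <- keep & spec$terminal_true == terminal
  which(keep)
}

#' Build a devaluation event for a run schedule
#'
#' Applied between episodes by [run_episodes()]: the agent's reward model
#' (entry and prior) for the targeted observed states is replaced by
#' `new_reward`, and the environment's payoff at the targeted true states
#' switches to draws from the same distribution, so both controllers
#' experience the devalued outcome.
#'
#' @param spec an [mdp_spec()].
#' @param after_episode the event fires after this many completed episodes.
#' @param states true-state names or indices to devalue (feeder: `"T+"`).
#' @param hand,eye Playroom shorthand: devalue all terminal states whose hand
#'   and eye match these object sets (used instead of `states`).
#' @param new_reward replacement reward distribution, default Beta(1, 15).
#' @return A schedule entry (list) for [run_episodes()].
#' @export
devaluation_event <- function(spec, after_episode, states = NULL,
                              hand = NULL, eye = NULL,
                              new_reward = beta_dist(1, 15)) {
  stopifnot(inherits(spec, "mdp_spec"), inherits(new_reward, "beta_dist"))
  if (is.null(states)) {
    true_states <- playroom_states(spec, hand = hand, eye = eye,
                                   terminal = TRUE)
  } else {
    if (is.character(states)) states <- match(states, spec$states)
    true_states <- as.integer(states)
  }
  if (length(true_states) == 0 || any(is.na(true_states)))
    stop("devaluation_event: no matching states")
  list(after_episode = as.integer(after_episode),
       obs_states = sort(unique(spec$obs_map[true_states])),
       true_states = true_states,
       alpha = new_reward$shape1, beta = new_reward$shape2)
}

# ---------------------------------------------------------------------------
# JSON round-trip so fixture MDPs share the same loader
# ---------------------------------------------------------------------------

#' Write an MDP specification to JSON
#' @param spec an [mdp_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mdp_json <- function(spec, path) {
  stopifnot(inherits(spec, "mdp_spec"))
  out <- list(name = spec$name, states = spec$states, actions = spec$actions,
              trans = as.numeric(spec$trans),
              terminal = spec$terminal_true,
              reward_value = spec$reward_value,
              action_rewards = spec$action_rewards,
              start = spec$start, step_cap = spec$step_cap,
              obs_map = spec$obs_map, obs_states = spec$obs_states)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MDP specification from JSON
#' @param path a file written by [write_mdp_json()] (or by hand).
#' @return An [mdp_spec()].
#' @export
read_mdp_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- length(x$states)
  A <- length(x$actions)
  mdp_spec(x$states, x$actions, array(x$trans, dim = c(S, A, S)),
           as.logical(x$terminal), x$reward_value, x$action_rewards,
           x$start, step_cap = x$step_cap, obs_map = x$obs_map,
           obs_states = x$obs_states, name = x$name %||% "json")
}
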