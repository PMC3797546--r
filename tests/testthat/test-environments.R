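test_that("the simple feeder rewards press-then-entry and restarts otherwise", {
  env <- make_feeder("simple")
  validate_mdp(env)
  s0 <- match("S0", env$states); s1 <- match("S1", env$states)
  tp <- match("T+", env$states)
  press <- match("press", env$actions); entry <- match("entry", env$actions)
  expect_equal(env$trans[s0, press, s1], 1)
  expect_equal(env$trans[s1, entry, tp], 1)
  expect_true(env$terminal_true[tp])
  expect_equal(env$reward_value[tp], 1)
  # any other sequence restarts (returns to the start state, same trial)
  expect_equal(env$trans[s0, entry, s0], 1)
  expect_equal(env$trans[s1, press, s0], 1)
  expect_equal(env$action_rewards, c(0, 0))
})

test_that("the moderate feeder adds an equivalent chain-entry route", {
  env <- make_feeder("moderate")
  validate_mdp(env)
  s0 <- match("S0", env$states); s2 <- match("S2", env$states)
  tp2 <- match("T+2", env$states)
  chain <- match("chain", env$actions); entry <- match("entry", env$actions)
  expect_equal(env$trans[s0, chain, s2], 1)
  expect_equal(env$trans[s2, entry, tp2], 1)
  expect_true(env$terminal_true[tp2])
  expect_equal(env$reward_value[tp2], 1)       # equivalent reward
  expect_equal(env$trans[s2, chain, s0], 1)    # failure restarts
})

test_that("playroom affordances fire only when hand and eye are co-located", {
  env <- make_playroom()
  expect_equal(env$n_true, 64)
  tab <- env$state_table
  st <- function(h, e, l, m) {
    which(tab$hand == h & tab$eye == e & tab$light == l & tab$music == m)
  }
  use <- 1
  # switch toggles the light
  from <- st(3, 3, 1, 1)
  expect_equal(unname(which(env$trans[from, use, ] == 1)), st(3, 3, 0, 1))
  # monkey is a neutral distractor
  from <- st(4, 4, 1, 0)
  expect_equal(unname(which(env$trans[from, use, ] == 1)), from)
  # hand on blue box, eye on switch: nothing happens
  from <- st(1, 3, 1, 0)
  expect_equal(unname(which(env$trans[from, use, ] == 1)), from)
  # blue box starts music, red box stops it
  from <- st(1, 1, 1, 0)
  expect_equal(unname(which(env$trans[from, use, ] == 1)), st(1, 1, 1, 1))
  from <- st(2, 2, 1, 1)
  expect_equal(unname(which(env$trans[from, use, ] == 1)), st(2, 2, 1, 0))
  # eye_to_random is uniform over the four objects
  from <- st(4, 4, 1, 0)
  probs <- env$trans[from, 2, ]
  expect_equal(sum(probs > 0), 4)
  expect_true(all(probs[probs > 0] == 0.25))
  # null changes nothing and earns the only positive action reward
  expect_equal(unname(which(env$trans[from, 4, ] == 1)), from)
  expect_equal(env$action_rewards, c(-0.02, -0.02, -0.02, 0.005))
  validate_mdp(env)
})

test_that("the observation map merges boxes exactly when the light is off", {
  env <- make_playroom()
  tab <- env$state_table
  on_idx <- which(tab$light == 1)
  expect_equal(length(unique(env$obs_map[on_idx])), length(on_idx))
  st <- function(h, e, l, m) {
    which(tab$hand == h & tab$eye == e & tab$light == l & tab$music == m)
  }
  # hand on blue vs red box, light off: identical observations
  expect_equal(observe(env, st(1, 4, 0, 0)), observe(env, st(2, 4, 0, 0)))
  expect_equal(observe(env, st(4, 1, 0, 1)), observe(env, st(4, 2, 0, 1)))
  # switch and monkey stay distinct
  expect_false(observe(env, st(3, 4, 0, 0)) == observe(env, st(4, 4, 0, 0)))
  # merged states offer the same actions (a global action set)
  expect_equal(env$n_obs, 32 + 18)
})

test_that("the proximal goal is 3 actions away and the distal one at least 9", {
  env <- make_playroom()   # goal: music on, light off
  boxes <- c("blue_box", "red_box")
  prox <- playroom_states(env, hand = boxes, eye = boxes, terminal = TRUE)
  dist <- playroom_states(env, hand = "switch", eye = "switch",
                          terminal = TRUE)
  expect_equal(bfs_min_steps(env, env$start, prox), 3)
  expect_gte(bfs_min_steps(env, env$start, dist), 9)
})

test_that("goal and start specifications are validated", {
  expect_error(playroom_goal(hand = "lever"), "objects")
  expect_error(playroom_start(hand = "lever"))
  # a start state that already satisfies the goal is rejected
  expect_error(make_playroom(goal = playroom_goal(music = FALSE, light = FALSE)),
               "inconsistent goal-spec")
})

test_that("devaluation_event resolves states and observation images", {
  env <- make_playroom()
  boxes <- c("blue_box", "red_box")
  ev <- devaluation_event(env, 50, hand = boxes, eye = boxes)
  expect_equal(ev$after_episode, 50L)
  expect_true(all(env$terminal_true[ev$true_states]))
  tab <- env$state_table[ev$true_states, ]
  expect_true(all(tab$hand %in% 1:2 & tab$eye %in% 1:2))
  expect_equal(ev$obs_states, sort(unique(env$obs_map[ev$true_states])))
  expect_equal(ev$alpha, 1)
  expect_equal(ev$beta, 15)
  f <- make_feeder("simple")
  expect_error(devaluation_event(f, 5, states = "no-such-state"),
               "no matching states")
  expect_equal(devaluation_event(f, 20, states = "T+")$true_states,
               match("T+", f$states))
})

test_that("MDP specs survive a JSON round trip through the shared loader", {
  env <- make_feeder("moderate")
  path <- tempfile(fileext = ".json")
  write_mdp_json(env, path)
  back <- read_mdp_json(path)
  expect_equal(back$trans, env$trans)
  expect_equal(back$states, env$states)
  expect_equal(back$obs_map, env$obs_map)
  expect_equal(back$terminal_true, env$terminal_true)
  # a fixture loaded from JSON runs in the engine
  tr <- run_episodes(back, feeder_config(seed = 4), 5)
  expect_gt(nrow(tr), 0)
})

test_that("mdp_spec rejects malformed transition tables", {
  trans <- array(0, dim = c(2, 1, 2))
  trans[1, 1, 1] <- 0.7  # row does not sum to 1
  trans[2, 1, 2] <- 1
  expect_error(mdp_spec(c("a", "b"), "x", trans, c(FALSE, TRUE), c(0, 1), 0, start = 1),
               "sum to 1")
})

test_that("the shipped chain fixture loads and matches the engine's VI example", {
  path <- system.file("extdata", "chain_mdp.json", package = "habitree")
  expect_true(nzchar(path))
  spec <- read_mdp_json(path)
  validate_mdp(spec)
  expect_equal(spec$states, c("S0", "S1", "T"))
  m <- chain_world_model()
  vi <- value_iteration(m, 0.95, spec$action_rewards[c(1, 1)])
  expect_equal(vi$values[2, 1], 0.93, tolerance = 1e-3)
})
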