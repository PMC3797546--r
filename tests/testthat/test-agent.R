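test_that("agent_config validates ranges and feeder_config overrides defaults", {
  cfg <- agent_config()
  expect_equal(cfg$theta, 0.9999)
  expect_equal(cfg$gamma, 0.95)
  expect_equal(cfg$transition_prior, 0.1)
  expect_error(agent_config(epsilon = 1.5))
  expect_error(agent_config(eta = 0))
  fc <- feeder_config(seed = 3)
  expect_equal(fc$theta, 0.98)
  expect_equal(fc$gamma, 0.95)
  expect_equal(fc$eta, 1e-4)
  expect_equal(fc$seed, 3)
})

test_that("a fresh agent with zero opportunity cost consults the tree for every action", {
  cache <- cache_q_table(3, c("a", "b"))
  model <- world_model(3, c("a", "b"), terminal = c(FALSE, FALSE, TRUE))
  arb <- arbitration_state(avg_reward = 0)
  d <- decide(1, cache, model, arb, agent_config(), c(0, 0))
  expect_true(all(d$systems == "tree"))
  expect_true(d$searched)
  expect_s3_class(d$tree, "tree_q")
})

test_that("decide answers from the cache when all VPIs fall below the threshold", {
  cache <- cache_q_table(3, c("a", "b"))
  cache$alpha[1, ] <- c(400, 5)
  cache$beta[1, ] <- c(20, 95)
  model <- world_model(3, c("a", "b"), terminal = c(FALSE, FALSE, TRUE))
  arb <- arbitration_state(avg_reward = 1, tau = 0.1)
  d <- decide(1, cache, model, arb, agent_config(), c(0, 0))
  expect_true(all(d$systems == "cache"))
  expect_false(d$searched)
  expect_null(d$tree)
  expect_equal(unname(d$qstar), unname(cache_means(cache)[1, ]))
})

test_that("act is greedy at epsilon = 0 and uniform at epsilon = 1", {
  q <- c(a = 0.2, b = 0.9, c = 0.4)
  set.seed(2)
  for (k in 1:50) {
    r <- act(q, 0)
    expect_equal(r$greedy, 2L)
    expect_equal(r$executed, 2L)
  }
  n <- 20000
  ex <- integer(n)
  set.seed(3)
  for (k in seq_len(n)) ex[k] <- act(q, 1)$executed
  freq <- tabulate(ex, 3) / n
  sigma <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 3 * sigma + 1e-9))
})

test_that("exact ties for the greedy action are broken uniformly", {
  q <- c(a = 0.7, b = 0.7, c = 0.1)
  set.seed(4)
  g <- replicate(4000, act(q, 0)$greedy)
  expect_true(all(g %in% 1:2))
  expect_equal(mean(g == 1), 0.5, tolerance = 0.04)
})

test_that("runs are bit-identical under a fixed seed", {
  env <- make_feeder("simple")
  sched <- list(devaluation_event(env, 15, states = "T+"))
  t1 <- run_episodes(env, feeder_config(seed = 99), 25, sched)
  t2 <- run_episodes(env, feeder_config(seed = 99), 25, sched)
  expect_identical(t1, t2)
})

test_that("traces satisfy their structural invariants", {
  env <- make_playroom()
  tr <- run_episodes(env, agent_config(seed = 5), 8)
  expect_true(all(tr$step <= env$step_cap))
  expect_equal(sort(unique(tr$episode)), 1:8)
  # tree searches accumulate by at most one per step
  expect_true(all(diff(tr$tree_searches) %in% 0:1))
  expect_true(all(tr$searched == as.integer(tr$system_mask > 0)))
  # the recorded greedy action maximises the recorded mixed Q-values
  q <- as.matrix(tr[, paste0("qstar_", env$actions)])
  qg <- q[cbind(seq_len(nrow(q)), tr$greedy_action)]
  expect_true(all(qg >= apply(q, 1, max) - 1e-12))
  # terminal steps close their episode
  term_rows <- which(tr$terminal == 1)
  for (i in term_rows) {
    if (i < nrow(tr)) expect_equal(tr$episode[i + 1], tr$episode[i] + 1)
  }
  # observed states are consistent with the observation map
  expect_equal(tr$obs_state, env$obs_map[tr$true_state])
  expect_equal(tr$next_obs, env$obs_map[tr$next_true])
})

test_that("n_episodes = 0 yields an empty trace and empty schedules mutate nothing", {
  env <- make_feeder("simple")
  tr0 <- run_episodes(env, feeder_config(seed = 1), 0)
  expect_equal(nrow(tr0), 0)
  tr <- run_episodes(env, feeder_config(seed = 1), 30)
  r_term <- tr$reward_extrinsic[tr$terminal == 1]
  expect_true(all(r_term == 1))  # no devaluation ever
})

test_that("scheduled devaluations apply exactly once, between episodes", {
  env <- make_feeder("simple")
  sched <- list(devaluation_event(env, 10, states = "T+"))
  tr <- run_episodes(env, feeder_config(seed = 8), 20, sched)
  pre <- tr$reward_extrinsic[tr$terminal == 1 & tr$episode <= 10]
  post <- tr$reward_extrinsic[tr$terminal == 1 & tr$episode > 10]
  expect_true(all(pre == 1))
  expect_true(length(post) == 0 || all(post < 1))
  fin <- attr(tr, "final")
  i_tplus <- match("T+", env$states)
  expect_lt(fin$reward_alpha[i_tplus] /
              (fin$reward_alpha[i_tplus] + fin$reward_beta[i_tplus]), 0.3)
})

test_that("greedy_used_tree decodes the per-action system mask", {
  tr <- data.frame(system_mask = c(0, 1, 2, 3), greedy_action = c(1, 1, 2, 2))
  expect_equal(greedy_used_tree(tr), c(FALSE, TRUE, TRUE, TRUE))
})

test_that("write_trace emits a CSV and a JSON config echo", {
  env <- make_feeder("simple")
  tr <- run_episodes(env, feeder_config(seed = 2), 5)
  d <- tempfile("trace")
  csv <- write_trace(tr, d, "run1")
  expect_true(file.exists(csv))
  expect_true(file.exists(file.path(d, "run1_meta.json")))
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(tr))
  meta <- jsonlite::read_json(file.path(d, "run1_meta.json"))
  expect_equal(meta$config$seed, 2)
})
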