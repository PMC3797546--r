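test_that("observe_transition updates counts and measures the mean shift", {
  m <- world_model(2, c("go", "stay"), transition_prior = 0.1)
  r <- observe_transition(m, 1, "go", 1)
  expect_equal(r$shift, 5 / 6, tolerance = 1e-12)  # (0.5,0.5) -> (11/12,1/12)
  expect_equal(r$model$counts[1, 1, ], c(1.1, 0.1))
  expect_equal(r$model$last_shift[1, 1], 5 / 6, tolerance = 1e-12)
  # saturated model barely moves
  m2 <- world_model(2, "a", transition_prior = 1e6)
  expect_lt(observe_transition(m2, 1, 1, 1)$shift, 1e-5)
  # repeated observation of the same successor shrinks the shift
  r2 <- observe_transition(r$model, 1, "go", 1)
  expect_lt(r2$shift, r$shift)
  expect_error(observe_transition(m, 1, 1, 9), "unknown")
})

test_that("intrinsic_reward scales the most recent shift", {
  m <- world_model(2, c("go", "stay"), transition_prior = 0.1)
  m <- observe_transition(m, 1, "go", 1)$model
  expect_equal(intrinsic_reward(m, 1, "go", 2), 5 / 3, tolerance = 1e-12)
  expect_equal(intrinsic_reward(m, 1, "stay", 2), 0)  # never observed
  expect_equal(intrinsic_reward(m, 1, "go", 0), 0)    # disabled
})

test_that("observe_reward tracks outcome frequencies Bernoulli-style", {
  m <- world_model(2, "a", terminal = c(FALSE, TRUE))
  m <- observe_reward(m, 2, 1)
  m <- observe_reward(m, 2, 0.5)
  expect_equal(m$reward_alpha[2], 2.5)
  expect_equal(m$reward_beta[2], 1.5)
})

test_that("value_iteration reproduces hand-computed chain values", {
  m <- chain_world_model()
  vi <- value_iteration(m, 0.95, c(-0.02, -0.02))
  expect_true(vi$converged)
  expect_equal(vi$values[2, 1], 0.93, tolerance = 1e-3)
  expect_equal(vi$values[1, 1], 0.95 * 0.93 - 0.02, tolerance = 1e-3)
})

test_that("value_iteration has a zero fixed point without rewards", {
  m <- random_world_model(5, 2)
  m$reward_alpha[] <- 1e-9
  m$reward_beta[] <- 1e9
  m$last_shift[] <- 0
  vi <- value_iteration(m, 0.9, c(0, 0))
  expect_lt(max(abs(vi$values[!m$terminal, ])), 1e-3)
})

test_that("value_iteration satisfies its own Bellman backup and is idempotent", {
  set.seed(31)
  for (i in 1:10) {
    m <- random_world_model(sample(3:8, 1), sample(2:4, 1))
    ra <- runif(dim(m$counts)[2], -0.05, 0.05)
    vi <- value_iteration(m, 0.92, ra)
    expect_true(vi$converged)
    expect_lte(oracle_bellman_residual(m, vi$values, 0.92, ra), 1e-4)
    vi2 <- value_iteration(m, 0.92, ra)
    expect_identical(vi$values, vi2$values)
  }
})

test_that("value_iteration converges within the contraction bound", {
  set.seed(32)
  m <- random_world_model(6, 3)
  gamma <- 0.9
  vi <- value_iteration(m, gamma, c(0, 0, 0), tol = 1e-4)
  bound <- log(1e-4 * (1 - gamma)) / log(gamma) + 1
  expect_true(vi$converged)
  expect_lte(vi$sweeps_used, ceiling(bound))
})

test_that("augmented_q applies intrinsic bonuses only under local scope", {
  m <- world_model(2, c("go", "stay"), terminal = c(FALSE, TRUE),
                   transition_prior = 0.1)
  m <- observe_transition(m, 1, "go", 2)$model
  vi_loc <- value_iteration(m, 0.95, c(0, 0), scope = "local", iota = 2)
  aq <- augmented_q(vi_loc, m, 1, 2)
  expect_equal(unname(aq["go"] - vi_loc$values[1, "go"]),
               2 * m$last_shift[1, "go"])
  expect_equal(unname(aq["stay"]), unname(vi_loc$values[1, "stay"]))
  vi_glob <- value_iteration(m, 0.95, c(0, 0), scope = "global", iota = 2)
  expect_equal(augmented_q(vi_glob, m, 1, 2), vi_glob$values[1, ])
  expect_equal(augmented_q(vi_loc, m, 1, 0), vi_loc$values[1, ])
  # global scope folds the bonus into the backup target
  expect_gt(vi_glob$values[1, "go"], vi_loc$values[1, "go"])
})

test_that("devalue_state replaces the reward entry and its prior", {
  m <- chain_world_model()
  m <- devalue_state(m, 3, beta_dist(1, 15))
  expect_equal(reward_means(m)[3], 0.0625)
  # forgetting decay cannot restore the old value
  for (k in 1:200) m <- model_decay(m, 0.98)
  expect_equal(reward_means(m)[3], 0.0625, tolerance = 1e-9)
  # one search propagates the drop all the way to the start state
  vi <- value_iteration(m, 0.95, c(-0.02, -0.02))
  expect_lt(vi$values[1, 1], 0.06)
  expect_error(devalue_state(m, 9), "unknown state")
})

test_that("devaluing an unreachable state leaves reachable values unchanged", {
  m <- world_model(4, c("go", "stay"), terminal = c(FALSE, FALSE, TRUE, TRUE),
                   transition_prior = 1e-12)
  m$counts[1, , 2] <- 1e9
  m$counts[2, , 3] <- 1e9   # state 4 unreachable
  m$reward_alpha[3] <- 1e9; m$reward_beta[3] <- 1e-6
  v1 <- value_iteration(m, 0.95, c(0, 0))$values
  v2 <- value_iteration(devalue_state(m, 4, beta_dist(1, 15)),
                        0.95, c(0, 0))$values
  expect_equal(v1[1:2, ], v2[1:2, ], tolerance = 1e-9)
})

test_that("model_decay contracts every table toward its priors", {
  m <- random_world_model(4, 2)
  m0 <- m
  m <- model_decay(m, 0.5)
  expect_equal(m$counts, 0.5 * m0$counts + 0.5 * 0.1)
  expect_equal(m$reward_alpha,
               0.5 * m0$reward_alpha + 0.5 * m0$reward_prior_alpha)
})
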