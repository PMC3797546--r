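# Independent oracles used across the suite. These deliberately avoid the
# package's own integration code paths: closed forms via pbeta/lbeta, dense
# Simpson grids, and plain-R Bellman backups.

# Exact first two moments of the Beta mixture update (target is itself Beta,
# so E[x] and E[x^2] are analytic).
oracle_mixture_moments_exact <- function(pa, pb, ta, tb) {
  e1 <- ta / (ta + tb)
  e2 <- ta * (ta + 1) / ((ta + tb) * (ta + tb + 1))
  s <- pa + pb
  m1 <- (pa + e1) / (s + 1)
  m2 <- (pa^2 + pa + (2 * pa + 1) * e1 + e2) / ((s + 1) * (s + 2))
  c(mean = m1, variance = m2 - m1^2)
}

# Dense-grid (composite Simpson) version of the same moments.
oracle_mixture_moments_grid <- function(pa, pb, ta, tb, n = 1e5) {
  stopifnot(n %% 2 == 0)
  x <- seq(0, 1, length.out = n + 1)
  f <- dbeta(x, ta, tb)
  f[!is.finite(f)] <- 0  # endpoint singularities have measure zero
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1) / (3 * n)
  mass <- sum(w * f)
  e1 <- sum(w * f * x) / mass
  e2 <- sum(w * f * x^2) / mass
  s <- pa + pb
  m1 <- (pa + e1) / (s + 1)
  m2 <- (pa^2 + pa + (2 * pa + 1) * e1 + e2) / ((s + 1) * (s + 2))
  c(mean = m1, variance = m2 - m1^2)
}

# Closed-form VPI via regularised incomplete beta integrals:
#   E[x 1{x < m}] = mean * pbeta(m, a + 1, b)
oracle_vpi_closed <- function(a, b, is_best, best_mean, second_mean) {
  mu <- a / (a + b)
  if (is_best) {
    m <- second_mean
    m * pbeta(m, a, b) - mu * pbeta(m, a + 1, b)
  } else {
    m <- best_mean
    mu * (1 - pbeta(m, a + 1, b)) - m * (1 - pbeta(m, a, b))
  }
}

# Dense midpoint-grid VPI.
oracle_vpi_grid <- function(a, b, is_best, best_mean, second_mean, n = 1e5) {
  x <- (seq_len(n) - 0.5) / n
  g <- if (is_best) pmax(second_mean - x, 0) else pmax(x - best_mean, 0)
  sum(g * dbeta(x, a, b)) / n
}

# Max-norm Bellman residual of a tree_q under its own model (plain R backup).
oracle_bellman_residual <- function(model, q, gamma, action_rewards) {
  S <- dim(model$counts)[1]
  A <- dim(model$counts)[2]
  rmean <- model$reward_alpha / (model$reward_alpha + model$reward_beta)
  V <- ifelse(model$terminal, rmean, apply(q, 1, max))
  resid <- 0
  for (s in which(!model$terminal)) {
    for (a in seq_len(A)) {
      p <- model$counts[s, a, ] / sum(model$counts[s, a, ])
      bq <- action_rewards[a] + gamma * sum(p * V)
      resid <- max(resid, abs(q[s, a] - bq))
    }
  }
  resid
}

# Random learned-looking world model for Bellman-residual property tests.
random_world_model <- function(S, A, n_terminal = 1) {
  term <- rep(FALSE, S)
  term[sample.int(S, n_terminal)] <- TRUE
  if (all(term)) term[1] <- FALSE
  m <- world_model(S, paste0("a", seq_len(A)), terminal = term,
                   transition_prior = 0.1)
  m$counts <- array(runif(S * A * S, 0.1, 5), dim = c(S, A, S))
  m$reward_alpha <- runif(S, 0.5, 10)
  m$reward_beta <- runif(S, 0.5, 10)
  m$last_shift[] <- runif(S * A, 0, 0.5)
  m
}

# Near-deterministic two-step chain S1 -> S2 -> T with terminal reward mean 1
# (pseudo-counts large enough that prior leakage is < 1e-9).
chain_world_model <- function() {
  m <- world_model(3, c("go", "stay"), terminal = c(FALSE, FALSE, TRUE),
                   transition_prior = 1e-12)
  m$counts[1, 1, 2] <- 1e9   # S1 --go--> S2
  m$counts[1, 2, 1] <- 1e9   # S1 --stay--> S1
  m$counts[2, 1, 3] <- 1e9   # S2 --go--> T
  m$counts[2, 2, 2] <- 1e9
  m$reward_alpha[3] <- 1e12
  m$reward_beta[3] <- 1e-6
  m
}

# Shortest possible number of actions from `from` to any of `targets`,
# counting any successor with positive probability as reachable.
bfs_min_steps <- function(spec, from, targets) {
  dist <- rep(NA_integer_, spec$n_true)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    s <- queue[1]
    queue <- queue[-1]
    if (spec$terminal_true[s]) next
    for (a in seq_len(spec$n_actions)) {
      for (s2 in which(spec$trans[s, a, ] > 0)) {
        if (is.na(dist[s2])) {
          dist[s2] <- dist[s] + 1L
          queue <- c(queue, s2)
        }
      }
    }
  }
  suppressWarnings(min(dist[targets], na.rm = TRUE))
}
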