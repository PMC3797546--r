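test_that("beta_dist validates and beta_moments returns closed forms", {
  expect_equal(beta_moments(beta_dist(1, 1))[["mean"]], 0.5)
  expect_equal(beta_moments(beta_dist(1, 15))[["mean"]], 0.0625)
  expect_equal(beta_moments(beta_dist(4, 4))[["variance"]], 1 / 36)
  expect_error(beta_dist(0, 1), "finite and > 0")
  expect_error(beta_dist(1, -2), "finite and > 0")
  expect_error(beta_dist(NA, 1))
})

test_that("reshape_to_mean solves the mean relation on the larger-variance branch", {
  r <- reshape_to_mean(beta_dist(4, 4), 0.75)
  expect_equal(r$shape1, 4)
  expect_equal(r$shape2, 4 / 3)
  # identity and fixed-point cases
  expect_equal(unclass(reshape_to_mean(beta_dist(2, 2), 0.5)),
               list(shape1 = 2, shape2 = 2))
  r2 <- reshape_to_mean(beta_dist(3, 1), 0.75)
  expect_equal(beta_moments(r2)[["mean"]], 0.75)
  expect_equal(beta_moments(r2)[["variance"]],
               beta_moments(beta_dist(3, 1))[["variance"]])
  expect_error(reshape_to_mean(beta_dist(1, 1), 1), "strictly inside")
  expect_error(reshape_to_mean(beta_dist(1, 1), -0.2), "strictly inside")
  expect_error(reshape_to_mean(beta_dist(1, 1), NaN), "strictly inside")
})

test_that("reshape_to_mean properties: exact mean, variance >= rejected candidate", {
  set.seed(11)
  for (i in 1:300) {
    a <- runif(1, 0.2, 40)
    b <- runif(1, 0.2, 40)
    m <- runif(1, 0.02, 0.98)
    r <- reshape_to_mean(beta_dist(a, b), m)
    expect_equal(beta_moments(r)[["mean"]], m, tolerance = 1e-12)
    # two-candidate check done explicitly
    v <- function(p, q) p * q / ((p + q)^2 * (p + q + 1))
    v1 <- v(a, a * (1 - m) / m)
    v2 <- v(b * m / (1 - m), b)
    expect_gte(beta_moments(r)[["variance"]] + 1e-15, max(v1, v2))
    expect_gte(beta_moments(r)[["variance"]] + 1e-15, min(v1, v2))
  }
})

test_that("mixture_update handles degenerate point-mass targets", {
  # near point mass at 1 adds (1, 0); at 0 adds (0, 1)
  up <- mixture_update(beta_dist(2, 3), beta_dist(1e6, 1))
  expect_equal(up$shape1, 3, tolerance = 1e-3)
  expect_equal(up$shape2, 3, tolerance = 1e-3)
  dn <- mixture_update(beta_dist(2, 3), beta_dist(1, 1e6))
  expect_equal(dn$shape1, 2, tolerance = 1e-3)
  expect_equal(dn$shape2, 4, tolerance = 1e-3)
})

test_that("mixture_update moments match the exact mixture moments", {
  # uniform prior and target: frozen value computed from the closed form
  mm <- oracle_mixture_moments_exact(1, 1, 1, 1)
  got <- beta_moments(mixture_update(beta_dist(1, 1), beta_dist(1, 1)))
  expect_equal(got[["mean"]], mm[["mean"]], tolerance = 1e-10)
  expect_equal(got[["variance"]], mm[["variance"]], tolerance = 1e-10)
  set.seed(21)
  for (i in 1:200) {
    pa <- runif(1, 0.7, 60); pb <- runif(1, 0.7, 60)
    ta <- runif(1, 0.7, 60); tb <- runif(1, 0.7, 60)
    want <- oracle_mixture_moments_exact(pa, pb, ta, tb)
    got <- beta_moments(mixture_update(beta_dist(pa, pb), beta_dist(ta, tb)))
    expect_equal(got[["mean"]], want[["mean"]], tolerance = 1e-6)
    expect_equal(got[["variance"]], want[["variance"]], tolerance = 1e-6)
  }
})

test_that("decay_toward_prior is an exact contraction that preserves positivity", {
  expect_equal(decay_toward_prior(c(5, 3), c(1, 1), 1), c(5, 3))
  expect_equal(decay_toward_prior(c(5, 3), c(1, 1), 0), c(1, 1))
  expect_equal(decay_toward_prior(c(5, 3), c(1, 1), 0.5), c(3, 2))
  expect_error(decay_toward_prior(c(1), c(1), 1.2), "theta")
  expect_error(decay_toward_prior(c(1), c(1), -0.1), "theta")
  set.seed(5)
  p <- runif(20, 0.01, 10)
  prior <- runif(20, 0.01, 2)
  th <- 0.83
  for (k in 1:50) {
    p2 <- decay_toward_prior(p, prior, th)
    expect_equal(abs(p2 - prior), th * abs(p - prior), tolerance = 1e-12)
    expect_true(all(p2 > 0))
    p <- p2
  }
  expect_equal(p, prior, tolerance = 1e-3)
})

test_that("dirichlet_mean normalises concentrations", {
  expect_equal(dirichlet_mean(dirichlet_row(c(1, 1))), c(0.5, 0.5))
  expect_equal(dirichlet_mean(dirichlet_row(c(0.1, 0.1))), c(0.5, 0.5))
  expect_equal(dirichlet_mean(dirichlet_row(c(1.1, 0.1))), c(11, 1) / 12)
  expect_error(dirichlet_row(c(1, 0)), "> 0")
})

test_that("clamp_unit_interval clamps to [0.001, 0.999]", {
  expect_equal(clamp_unit_interval(c(-2, 0.5, 3)), c(0.001, 0.5, 0.999))
})
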