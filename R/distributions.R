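#' Beta distribution over a bounded value
#'
#' The basic belief object of both controllers: a Beta posterior over a
#' Q-value or an extrinsic reward, which live in \[0, 1\].
#'
#' @param shape1,shape2 positive pseudo-counts (alpha, beta).
#' @return An object of class `beta_dist`.
#' @examples
#' d <- beta_dist(1, 15)   # the devaluation distribution, mean 1/16
#' beta_moments(d)
#' @export
beta_dist <- function(shape1, shape2) {
  stopifnot(is.numeric(shape1), is.numeric(shape2),
            length(shape1) == 1L, length(shape2) == 1L)
  if (!is.finite(shape1) || !is.finite(shape2) || shape1 <= 0 || shape2 <= 0)
    stop("beta_dist parameters must be finite and > 0")
  structure(list(shape1 = as.numeric(shape1), shape2 = as.numeric(shape2)),
            class = "beta_dist")
}

#' @export
print.beta_dist <- function(x, ...) {
  m <- beta_moments(x)
  cat(sprintf("Beta(%.4g, %.4g)  mean %.4g  var %.4g\n",
              x$shape1, x$shape2, m[["mean"]], m[["variance"]]))
  invisible(x)
}

#' Mean and variance of a Beta posterior
#'
#' @param d a [beta_dist()].
#' @return Named numeric vector with elements `mean` and `variance`.
#' @export
beta_moments <- function(d) {
  stopifnot(inherits(d, "beta_dist"))
  s <- d$shape1 + d$shape2
  c(mean = d$shape1 / s,
    variance = d$shape1 * d$shape2 / (s^2 * (s + 1)))
}

#' Reshape a Beta distribution to a target mean, increasing variance
#'
#' Builds the bootstrapped target distribution for a cache update: one shape
#' parameter of `base` is held fixed and the other is solved from
#' alpha/mu = beta/(1 - mu) so the mean equals `target_mean`. Of the two
#' candidates this admits, the one with the larger variance is returned,
#' reflecting that every step of tree search adds uncertainty.
#'
#' @param base a [beta_dist()] (typically the successor's best action value).
#' @param target_mean required mean, strictly inside (0, 1); callers clamp
#'   with [clamp_unit_interval()] first since discounting and action costs can
#'   push a raw target outside the support.
#' @return A [beta_dist()] with mean `target_mean`.
#' @examples
#' reshape_to_mean(beta_dist(4, 4), 0.75)  # Beta(4, 4/3), the flatter option
#' @export
reshape_to_mean <- function(base, target_mean) {
  stopifnot(inherits(base, "beta_dist"))
  if (!is.numeric(target_mean) || length(target_mean) != 1L ||
      !is.finite(target_mean) || target_mean <= 0 || target_mean >= 1)
    stop("target_mean must be a finite number strictly inside (0, 1)")
  p <- reshape_to_mean_cpp(base$shape1, base$shape2, target_mean)
  beta_dist(p[1], p[2])
}

#' Mixture update of a Beta posterior
#'
#' Moment-matches the mixture
#' \deqn{\int_0^1 Beta(\alpha + x, \beta + (1 - x)) \, q(x) \, dx}
#' where `q` is the density of `target`: a fractional Bernoulli update
#' averaged over the target distribution of the observed value. The first two
#' mixture moments are computed by a fixed 512-node quadrature over the
#' target density and converted back to Beta parameters; parameters are
#' floored at 1e-3 when the mixture variance is too large for its mean.
#'
#' @param prior,target [beta_dist()] objects.
#' @return The moment-matched posterior as a [beta_dist()].
#' @examples
#' mixture_update(beta_dist(1, 1), beta_dist(1, 1))   # Beta(4, 4)
#' @export
mixture_update <- function(prior, target) {
  stopifnot(inherits(prior, "beta_dist"), inherits(target, "beta_dist"))
  p <- mixture_update_cpp(prior$shape1, prior$shape2,
                          target$shape1, target$shape2)
  beta_dist(p[1], p[2])
}

#' Exponential forgetting toward the prior
#'
#' Each tracked pseudo-count decays as p <- theta * p + (1 - theta) * p_prior,
#' once per simulation time step, for every Beta and Dirichlet parameter in
#' both controllers.
#'
#' @param current,prior numeric vectors of equal length with positive entries.
#' @param theta forgetting factor in \[0, 1\] (1 = no forgetting).
#' @return The decayed parameter vector.
#' @export
decay_toward_prior <- function(current, prior, theta) {
  stopifnot(is.numeric(current), is.numeric(prior),
            length(current) == length(prior))
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta > 1)
    stop("theta must be in [0, 1]")
  theta * current + (1 - theta) * prior
}

#' Dirichlet row over successor states
#'
#' One (state, action) entry of the transition model.
#'
#' @param concentration vector of positive pseudo-counts, one per successor.
#' @return An object of class `dirichlet_row`.
#' @export
dirichlet_row <- function(concentration) {
  stopifnot(is.numeric(concentration), length(concentration) >= 1L)
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentration entries must be finite and > 0")
  structure(list(concentration = as.numeric(concentration)),
            class = "dirichlet_row")
}

#' Mean successor distribution of a Dirichlet row
#'
#' @param row a [dirichlet_row()].
#' @return Probability vector (sums to 1).
#' @export
dirichlet_mean <- function(row) {
  stopifnot(inherits(row, "dirichlet_row"))
  row$concentration / sum(row$concentration)
}

#' Clamp a value into the open unit interval
#'
#' Target means handed to [reshape_to_mean()] and cache updates are clamped
#' to \[0.001, 0.999\] because discounting plus action costs can push a raw
#' bootstrap target outside the Beta support.
#'
#' @param x numeric vector.
#' @param eps clamping margin (default 1e-3).
#' @return `x` clamped to `[eps, 1 - eps]`.
#' @export
clamp_unit_interval <- function(x, eps = 1e-3) {
  pmin(pmax(x, eps), 1 - eps)
}
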