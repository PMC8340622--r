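## Linear-influence Gaussian increments between events.
##
## On an interval of length dt with (fixed) influence matrix W, the behavior
## increment dz satisfies (I - alpha W) dz = dt X gamma + eps with
## eps ~ N(0, dt sigma^2 I). Equivalently
##   dz ~ N( dt (I - alpha W)^{-1} X gamma,
##           dt sigma^2 (I - alpha W)^{-1} (I - alpha W)^{-T} ).
## Because the noise variance is linear in dt, increments compose: the sum
## of independent increments over (t0, t1) and (t1, t2) has exactly the
## one-interval distribution over (t0, t2) (for a fixed network).

#' Row-normalized influence matrix
#'
#' Row `i` holds weight `1 / outdegree(i)` on each of actor `i`'s named
#' friends, so `(W z)[i]` is the mean behavior of the people `i` names.
#' Actors with no friends get an all-zero row: with nobody to average over,
#' their behavior follows the covariate trend plus noise only (this also
#' keeps `I - alpha W` invertible for `|alpha| < 1`).
#'
#' @param y adjacency matrix.
#' @return `n x n` matrix; rows of positive-outdegree actors sum to 1.
#' @export
influence_matrix <- function(y) {
  deg <- rowSums(y)
  w <- y / ifelse(deg > 0, deg, 1)
  w[deg == 0, ] <- 0
  w
}

## I - alpha W, with a validity check tied to the |alpha| < 1 bound.
lag_operator <- function(w, alpha) {
  m <- diag(nrow(w)) - alpha * w
  if (abs(det(m)) < 1e-12)
    stop("I - alpha*W is numerically singular (alpha = ", alpha,
         "); |alpha| < 1 with a row-(sub)stochastic W guarantees ",
         "invertibility", call. = FALSE)
  m
}

#' Distribution of a behavior increment over one interval
#'
#' @param w influence matrix from the interval's (fixed) network snapshot.
#' @param X covariate matrix.
#' @param params a [coevol_params()] (`gamma`, `alpha`, `sigma` are used).
#' @param dt positive interval length.
#' @return An object of class `"increment_distribution"`: list with `mean`,
#'   `covariance` (both as above) and `dt`.
#' @export
increment_distribution <- function(w, X, params, dt) {
  stopifnot(dt > 0)
  m <- lag_operator(w, params$alpha)
  minv <- solve(m)
  mu <- dt * as.vector(minv %*% (X %*% params$gamma))
  cov <- dt * params$sigma^2 * tcrossprod(minv)
  structure(list(mean = mu, covariance = (cov + t(cov)) / 2, dt = dt),
            class = "increment_distribution")
}

#' Draw one behavior increment
#'
#' One multivariate-normal draw from an [increment_distribution()], using
#' R's global random number stream (seed with [set.seed()] for
#' reproducibility).
#'
#' @param dist an [increment_distribution()].
#' @return numeric vector of length `n`.
#' @export
sample_increment <- function(dist) {
  n <- length(dist$mean)
  l <- chol(dist$covariance)
  dist$mean + as.vector(crossprod(l, rnorm(n)))
}

## draw an increment directly from (w, params, dt): dz = M^{-1}(dt X gamma
## + sqrt(dt) sigma eps). Avoids forming the covariance.
draw_increment <- function(w, X, params, dt) {
  m <- lag_operator(w, params$alpha)
  n <- nrow(w)
  rhs <- dt * as.vector(X %*% params$gamma) +
    sqrt(dt) * params$sigma * rnorm(n)
  as.vector(solve(m, rhs))
}

#' Log-density of a behavior increment
#'
#' Evaluated in the change-of-variables form: with `M = I - alpha W` and
#' residual `r = M dz - dt X gamma`,
#' `log f(dz) = log|det M| - n/2 log(2 pi dt sigma^2) - ||r||^2 / (2 dt sigma^2)`,
#' which equals the multivariate-normal log-pdf at the mean/covariance of
#' [increment_distribution()]. Full constants are kept so path densities
#' multiply into exact probabilities.
#'
#' @param dz increment vector.
#' @inheritParams increment_distribution
#' @return scalar log-density.
#' @export
increment_log_density <- function(dz, w, X, params, dt) {
  stopifnot(dt > 0)
  if (!all(is.finite(dz))) stop("non-finite increment", call. = FALSE)
  n <- length(dz)
  m <- lag_operator(w, params$alpha)
  r <- as.vector(m %*% dz) - dt * as.vector(X %*% params$gamma)
  s2 <- dt * params$sigma^2
  as.numeric(determinant(m, logarithm = TRUE)$modulus) -
    n / 2 * log(2 * pi * s2) - sum(r^2) / (2 * s2)
}
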