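## Complete-data log-likelihood and the closed-form M-step blocks.
##
## For a complete path (k, times, toggles, increments) started at (y0, z0):
##   l = -lambda T + k log lambda
##       + sum over events of the exact log-probability of the observed
##         toggle (uniform 1/n actor factor included, so exp(l) is the true
##         path density; the factor is constant in all parameters)
##       + sum over the k + 1 intervals of the Gaussian increment
##         log-density (full constants kept).
## Note -lambda T + k log lambda already merges the Poisson event-count
## pmf with the ordered-uniform times density k!/T^k.

## per-interval data: influence matrix, increment, length; plus per-event
## signed change-statistic rows for the network term. This is the one
## pass over a path that every likelihood-type computation shares.
path_interval_data <- function(path, y0, z0, X, spec) {
  rep_ <- replay_path(path, y0, z0)
  k <- path$k
  bounds <- c(0, path$times, path$t_total)
  z <- as.numeric(z0)
  events <- vector("list", k)
  intervals <- vector("list", k + 1L)
  for (u in seq_len(k + 1L)) {
    ypre <- rep_$states[[u]]
    dz <- path$increments[u, ]
    intervals[[u]] <- list(w = influence_matrix(ypre), dz = dz,
                           dt = bounds[u + 1L] - bounds[u])
    z <- z + dz
    if (u <= k) {
      i <- path$toggles[u, 1L]
      j <- path$toggles[u, 2L]
      dm <- delta_matrices(spec, ypre, z, X)
      sgn <- 2 * ypre[i, ] - 1
      s <- vapply(dm, function(d) sgn * d[i, ], numeric(nrow(y0)))
      s <- s[-i, , drop = FALSE]            # (n-1) x q signed delta rows
      sel <- j - (j > i)                    # position of j among alters
      events[[u]] <- list(s = s, sel = sel)
    }
  }
  list(events = events, intervals = intervals, k = k, n = nrow(y0))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## network part of the log-likelihood as a function of theta
network_loglik_term <- function(pd, theta) {
  if (pd$k == 0L) return(0)
  tot <- 0
  for (e in pd$events) {
    lw <- as.vector(e$s %*% theta)
    tot <- tot + lw[e$sel] - logsumexp(lw)
  }
  tot - pd$k * log(pd$n)
}

## behavior part for given (alpha, gamma, sigma2)
behavior_loglik_term <- function(pd, X, alpha, gamma, sigma2) {
  tot <- 0
  trend <- as.vector(X %*% gamma)
  for (iv in pd$intervals) {
    m <- lag_operator(iv$w, alpha)
    r <- as.vector(m %*% iv$dz) - iv$dt * trend
    s2 <- iv$dt * sigma2
    tot <- tot + as.numeric(determinant(m, logarithm = TRUE)$modulus) -
      pd$n / 2 * log(2 * pi * s2) - sum(r^2) / (2 * s2)
  }
  tot
}

#' Complete-data log-likelihood of one path
#'
#' @param path a [coevol_path()].
#' @param y0,z0 initial states the path starts from.
#' @param X covariate matrix.
#' @param params a [coevol_params()].
#' @param spec a [statistic_spec()].
#' @return scalar log-likelihood; `exp()` of it is the exact joint density
#'   of the complete data (event count, times, toggles and increments).
#' @export
complete_log_likelihood <- function(path, y0, z0, X, params, spec) {
  pd <- path_interval_data(path, y0, z0, X, spec)
  -params$lambda * path$t_total + path$k * log(params$lambda) +
    network_loglik_term(pd, params$theta) +
    behavior_loglik_term(pd, X, params$alpha, params$gamma, params$sigma^2)
}

#' Event-rate maximum likelihood estimate
#'
#' `lambda_hat = E(k | observed data) / t_total`, with the conditional
#' expectation approximated by the Monte Carlo average of the imputed event
#' counts.
#'
#' @param expected_k average imputed event count.
#' @param t_total horizon.
#' @return nonnegative scalar; warns when 0 (the rate estimate is then
#'   degenerate).
#' @export
lambda_mle <- function(expected_k, t_total) {
  stopifnot(expected_k >= 0, t_total > 0)
  if (expected_k == 0)
    warning("no events imputed; lambda estimate degenerate at 0")
  expected_k / t_total
}

## shared summary over a collection of paths (one E-step's draws)
summarize_paths <- function(paths, y0, z0, X, spec) {
  pds <- lapply(paths, function(p) path_interval_data(p, y0, z0, X, spec))
  list(pds = pds, R = length(paths),
       kvec = vapply(paths, `[[`, numeric(1), "k"),
       n = nrow(y0),
       n_intervals = sum(vapply(pds, function(p) p$k + 1, numeric(1))))
}

## closed-form gamma at fixed alpha, over all intervals of all paths:
## gamma_hat = (X'X sum dt)^{-1} sum X' (I - alpha W) dz
gamma_closed_form <- function(sm, X, alpha) {
  xtx <- crossprod(X)
  rhs <- numeric(ncol(X))
  dtsum <- 0
  for (pd in sm$pds) for (iv in pd$intervals) {
    a <- as.vector(lag_operator(iv$w, alpha) %*% iv$dz)
    rhs <- rhs + as.vector(crossprod(X, a))
    dtsum <- dtsum + iv$dt
  }
  as.vector(solve(xtx * dtsum, rhs))
}

## closed-form sigma^2 at fixed (alpha, gamma): normalized weighted RSS
sigma2_closed_form <- function(sm, X, alpha, gamma) {
  trend <- as.vector(X %*% gamma)
  rss <- 0
  for (pd in sm$pds) for (iv in pd$intervals) {
    r <- as.vector(lag_operator(iv$w, alpha) %*% iv$dz) - iv$dt * trend
    rss <- rss + sum(r^2) / iv$dt
  }
  rss / (sm$n * sm$n_intervals)
}

#' Closed-form M-step update for the trend coefficients
#'
#' The exact maximizer of the averaged complete-data log-likelihood in
#' `gamma` at fixed `alpha`: a weighted least-squares solve pooling every
#' inter-event interval of every imputed path, with responses
#' `(I - alpha W) dz`.
#'
#' @param paths list of [coevol_path()] objects (imputed or simulated),
#'   all starting from the same `(y0, z0)`.
#' @param y0,z0 shared initial states.
#' @param X covariate matrix.
#' @param alpha influence strength at which to profile.
#' @return numeric vector of length `ncol(X)`.
#' @export
mstep_gamma <- function(paths, y0, z0, X, alpha) {
  sm <- summarize_paths(paths, y0, z0, X,
                        statistic_spec("outdegree"))  # spec unused here
  gamma_closed_form(sm, X, alpha)
}

#' Closed-form M-step update for the noise variance
#'
#' The exact maximizer of the averaged complete-data log-likelihood in
#' `sigma^2` at fixed `(alpha, gamma)`: the residual sum of squares of
#' `(I - alpha W) dz - dt X gamma`, weighted by `1/dt`, divided by
#' `n` times the total number of intervals.
#'
#' @inheritParams mstep_gamma
#' @param gamma trend coefficients (typically [mstep_gamma()]'s output).
#' @return nonnegative scalar estimate of `sigma^2`.
#' @export
mstep_sigma2 <- function(paths, y0, z0, X, alpha, gamma) {
  sm <- summarize_paths(paths, y0, z0, X, statistic_spec("outdegree"))
  s2 <- sigma2_closed_form(sm, X, alpha, gamma)
  if (s2 == 0)
    warning("all residuals zero; sigma^2 estimate degenerate at 0")
  s2
}

#' Profiled Monte Carlo EM objective
#'
#' The Monte-Carlo average of the complete-data log-likelihood over the
#' imputed paths, with `lambda`, `gamma` and `sigma^2` replaced by their
#' closed-form maximizers, leaving a function of `(theta, alpha)` only.
#' This is the objective the M-step maximizes numerically.
#'
#' @inheritParams mstep_gamma
#' @param theta network effect coefficients.
#' @param spec a [statistic_spec()].
#' @return scalar objective value.
#' @export
profile_h <- function(theta, alpha, paths, y0, z0, X, spec) {
  sm <- summarize_paths(paths, y0, z0, X, spec)
  make_profile_fn(sm, X, spec$q)(c(theta, alpha))
}

## fast closure over a fixed summary; caches the alpha-only block so that
## finite-difference moves in theta reuse it. par = c(theta, alpha).
make_profile_fn <- function(sm, X, q) {
  t_total <- sum(vapply(sm$pds[[1]]$intervals, `[[`, numeric(1), "dt"))
  kbar <- mean(sm$kvec)
  lam <- max(kbar, 1e-12) / t_total
  lam_part <- -lam * t_total + kbar * log(lam) - kbar * log(sm$n)
  cache <- new.env(parent = emptyenv())
  cache$alpha <- NA_real_
  function(par) {
    theta <- par[seq_len(q)]
    alpha <- par[q + 1L]
    net <- 0
    for (pd in sm$pds) {
      for (e in pd$events) {
        lw <- as.vector(e$s %*% theta)
        net <- net + lw[e$sel] - logsumexp(lw)
      }
    }
    if (!identical(alpha, cache$alpha)) {
      gam <- gamma_closed_form(sm, X, alpha)
      s2 <- max(sigma2_closed_form(sm, X, alpha, gam), 1e-12)
      trend <- as.vector(X %*% gam)
      ld <- 0
      dtlog <- 0
      for (pd in sm$pds) for (iv in pd$intervals) {
        m <- lag_operator(iv$w, alpha)
        ld <- ld + as.numeric(determinant(m, logarithm = TRUE)$modulus)
        dtlog <- dtlog + log(iv$dt)
      }
      nK <- sm$n * sm$n_intervals
      cache$alpha <- alpha
      cache$gamma <- gam
      cache$sigma2 <- s2
      ## quadratic term at the profiled sigma^2 collapses to nK/2
      cache$beh <- ld - nK / 2 * (log(2 * pi * s2) + 1) - sm$n / 2 * dtlog
    }
    lam_part + (net + cache$beh) / sm$R
  }
}
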