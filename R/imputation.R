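## Imputation of the latent event history between two panel waves.
##
## A whole-path independence proposal: the event count is drawn from a
## parity-restricted Poisson (the toggle count must reach the d disagreeing
## dyads and match their parity), times are ordered-uniform, behavior
## increments come from a bridge normal pinned to the observed endpoint,
## and edges are drawn with model weights under an "important list"
## bookkeeping that guarantees the network endpoint is hit exactly. A
## Metropolis-Hastings accept/reject step corrects the proposal to the
## exact conditional distribution.
##
## Proposal bookkeeping for the acceptance ratio: the event-count pmf
## (parity-restricted Poisson) times the ordered-uniform times density is
## e^{-lambda T} lambda^k / C with C the parity normalizer, so its only
## k-dependent part is k log(lambda); it is carried as log_k and exactly
## cancels the lambda factor of the complete-data likelihood in the ratio.
## Omitting it would bias the sampler toward large k by lambda^2 per
## surplus event pair.

#' Parity-restricted event-count proposal
#'
#' Draws `k` from the Poisson(`lambda * t_total`) distribution restricted
#' to the feasible support `{d, d + 2, d + 4, ...}` and renormalized (the
#' series is truncated when the remaining tail mass is below `1e-12`).
#'
#' @param lambda event rate.
#' @param t_total horizon.
#' @param d number of disagreeing dyads between the two observed networks.
#' @return integer event count with `k >= d` and `k - d` even.
#' @export
sample_event_count_conditional <- function(lambda, t_total, d) {
  pm <- parity_poisson_pmf(lambda, t_total, d)
  pm$k[sample.int(length(pm$k), 1L, prob = pm$p)]
}

## support and renormalized pmf of the parity-restricted Poisson
parity_poisson_pmf <- function(lambda, t_total, d, tol = 1e-12) {
  stopifnot(d >= 0, t_total > 0)
  mu <- lambda * t_total
  ks <- integer(0)
  ps <- numeric(0)
  k <- d
  repeat {
    p <- dpois(k, mu)
    ks <- c(ks, k)
    ps <- c(ps, p)
    ## Poisson tail beyond k is < p * mu/(k+1) / (1 - mu/(k+2)) once k > mu
    if (k > mu && p < tol * max(sum(ps), .Machine$double.xmin)) break
    if (k > mu + 50 * sqrt(mu + 1) + d + 100) break
    k <- k + 2L
  }
  if (sum(ps) == 0) {  # extreme tail: fall back to the minimum count
    ks <- d
    ps <- 1
  }
  list(k = ks, p = ps / sum(ps))
}

## dyad disagreement matrix between two networks
disagreement_matrix <- function(y, yT) (y != yT) * 1L

#' Propose a complete latent path consistent with both observed endpoints
#'
#' Builds one whole-path proposal: `k` from
#' [sample_event_count_conditional()], ordered-uniform times, bridge-normal
#' behavior increments with mean `dt/(T - t_{u-1}) * (zT - z^{u-1})` and
#' covariance `(T - t_u) dt / (T - t_{u-1}) * sigma^2 (M M')^{-1}` (with
#' `M = I - alpha W^{u-1}`; future influence matrices are frozen at the
#' current one, the accept/reject step corrects for it), and edge draws
#' with exponential change-statistic weights: over all ordered dyads while
#' surplus event pairs remain (`a > 0`), restricted to the important list
#' once `a = 0`. The final toggle closes the last disagreeing dyad and the
#' final increment is forced to land exactly on `zT`.
#'
#' @param obs a [coevol_obs()].
#' @param params a [coevol_params()].
#' @param spec a [statistic_spec()].
#' @param X covariate matrix.
#' @return list of class `"proposal_record"` with `path` (a
#'   [coevol_path()]), `log_q` (summed increment proposal log-densities),
#'   `log_r` (summed edge proposal log-probabilities) and `log_k`
#'   (`k log(lambda)`, the k-dependent part of the event-count and times
#'   proposal density; see the acceptance-ratio note above).
#' @export
propose_hidden_path <- function(obs, params, spec, X) {
  n <- obs$n
  t_total <- obs$t_total
  dis <- disagreement_matrix(obs$y0, obs$yT)
  d <- sum(dis)
  k <- sample_event_count_conditional(params$lambda, t_total, d)
  a <- (k - d) %/% 2L
  times <- sample_event_times(k, t_total)
  bounds <- c(0, times, t_total)
  y <- obs$y0
  z <- obs$z0
  toggles <- matrix(0L, k, 2L)
  increments <- matrix(0, k + 1L, n)
  log_q <- 0
  log_r <- 0
  for (u in seq_len(k)) {
    ## bridge increment over (t_{u-1}, t_u)
    dt <- bounds[u + 1L] - bounds[u]
    span <- t_total - bounds[u]
    m <- lag_operator(influence_matrix(y), params$alpha)
    cvar <- (t_total - bounds[u + 1L]) * dt / span * params$sigma^2
    mu <- dt / span * (obs$zT - z)
    eps <- rnorm(n)
    dz <- mu + sqrt(cvar) * as.vector(solve(m, eps))
    log_q <- log_q +
      as.numeric(determinant(m, logarithm = TRUE)$modulus) -
      n / 2 * log(2 * pi * cvar) - sum(eps^2) / 2
    increments[u, ] <- dz
    z <- z + dz
    ## edge toggle at t_u
    if (u < k) {
      lw <- (2 * y - 1) * weighted_delta(spec, params$theta, y, z, X)
      diag(lw) <- -Inf
      if (a > 0L) {
        lse <- logsumexp(lw[is.finite(lw)])
        p <- exp(lw - lse)
        idx <- sample.int(n * n, 1L, prob = as.vector(p))
        log_r <- log_r + lw[idx] - lse
      } else {
        inlist <- which(dis == 1L)
        lwl <- lw[inlist]
        lse <- logsumexp(lwl)
        idx <- inlist[sample.int(length(inlist), 1L,
                                 prob = exp(lwl - lse))]
        log_r <- log_r + lw[idx] - lse
      }
      i <- (idx - 1L) %% n + 1L
      j <- (idx - 1L) %/% n + 1L
      if (dis[i, j] == 1L) {
        dis[i, j] <- 0L
      } else {
        dis[i, j] <- 1L
        a <- a - 1L
        if (a < 0L) stop("internal: surplus counter went negative")
      }
    } else {
      ## last toggle is forced to the single remaining disagreeing dyad
      idx <- which(dis == 1L)
      if (length(idx) != 1L)
        stop("internal: important list not reduced to one dyad")
      i <- (idx - 1L) %% n + 1L
      j <- (idx - 1L) %/% n + 1L
      dis[i, j] <- 0L
    }
    toggles[u, ] <- c(i, j)
    y <- toggle_edge(y, i, j)
  }
  if (sum(dis) != 0L)
    stop("internal: unresolved dyads after final toggle")
  increments[k + 1L, ] <- obs$zT - z
  structure(list(path = coevol_path(times, toggles, increments, t_total),
                 log_q = log_q, log_r = log_r,
                 log_k = k * log(params$lambda), log_lik = NULL),
            class = "proposal_record")
}

record_loglik <- function(rec, obs, params, spec, X) {
  if (is.null(rec$log_lik))
    rec$log_lik <- complete_log_likelihood(rec$path, obs$y0, obs$z0, X,
                                           params, spec)
  rec
}

#' One Metropolis-Hastings step of the path sampler
#'
#' Proposes a fresh full path (independence sampler) and accepts it with
#' probability `min(1, [L(prop) g(cur)] / [L(cur) g(prop)])` computed in
#' log space, where `L` is the complete-data likelihood and `g` the full
#' proposal density (increment densities `q`, edge probabilities `r`, and
#' the k-dependent part of the event-count/times proposal).
#'
#' @param current a `"proposal_record"` for the same observation.
#' @inheritParams propose_hidden_path
#' @return the retained `"proposal_record"`, with an `accepted` flag.
#' @export
mh_step <- function(current, obs, params, spec, X) {
  current <- record_loglik(current, obs, params, spec, X)
  prop <- record_loglik(propose_hidden_path(obs, params, spec, X),
                        obs, params, spec, X)
  log_ratio <- (prop$log_lik - prop$log_k - prop$log_q - prop$log_r) -
    (current$log_lik - current$log_k - current$log_q - current$log_r)
  if (is.finite(log_ratio) && log(runif(1)) < log_ratio) {
    prop$accepted <- TRUE
    prop
  } else {
    current$accepted <- FALSE
    current
  }
}

#' Impute latent event histories by MCMC
#'
#' Runs the whole-path Metropolis-Hastings sampler and returns `R`
#' (approximately stationary) draws of the complete event history,
#' conditional on both panel waves.
#'
#' @inheritParams propose_hidden_path
#' @param R number of retained draws.
#' @param burn_in steps discarded before retention.
#' @param thin keep every `thin`-th step after burn-in.
#' @return list of class `"coevol_imputation"`: `paths` (list of `R`
#'   [coevol_path()]s), `acceptance` (acceptance rate over all steps),
#'   `k` (retained event counts), and `last` (the final record, usable to
#'   continue the chain).
#' @export
run_imputation <- function(obs, params, spec, X, R = 50, burn_in = 100,
                           thin = 1) {
  stopifnot(R >= 1, burn_in >= 0, thin >= 1)
  cur <- record_loglik(propose_hidden_path(obs, params, spec, X),
                       obs, params, spec, X)
  paths <- vector("list", R)
  kvec <- numeric(R)
  acc <- 0L
  total <- burn_in + R * thin
  kept <- 0L
  for (s in seq_len(total)) {
    cur <- mh_step(cur, obs, params, spec, X)
    if (isTRUE(cur$accepted)) acc <- acc + 1L
    if (s > burn_in && (s - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      paths[[kept]] <- cur$path
      kvec[kept] <- cur$path$k
    }
  }
  structure(list(paths = paths, acceptance = acc / total, k = kvec,
                 last = cur),
            class = "coevol_imputation")
}

#' @export
print.coevol_imputation <- function(x, ...) {
  cat("<coevol_imputation> ", length(x$paths), " retained paths, ",
      "mean k = ", format(mean(x$k)),
      ", acceptance = ", format(round(x$acceptance, 3)), "\n", sep = "")
  invisible(x)
}
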