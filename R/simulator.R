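## Forward simulation of the joint network/behavior process.

#' Draw the number of network change events
#'
#' @param lambda event rate per unit time.
#' @param t_total horizon.
#' @return Poisson(`lambda * t_total`) draw.
#' @export
sample_event_count <- function(lambda, t_total) {
  stopifnot(lambda >= 0, t_total > 0)
  rpois(1L, lambda * t_total)
}

#' Draw the event times given their count
#'
#' Conditional on `k` events in `(0, t_total)`, the times are the order
#' statistics of `k` independent Uniform(0, t_total) draws (joint density
#' `k! / t_total^k` on the ordered simplex).
#'
#' @param k nonnegative event count.
#' @param t_total horizon.
#' @return increasing numeric vector of length `k`.
#' @export
sample_event_times <- function(k, t_total) {
  stopifnot(k >= 0, t_total > 0)
  sort(runif(k, 0, t_total))
}

#' Simulate the joint process forward over one observation period
#'
#' Draws the event count and times, then advances the state event by event:
#' on each inter-event interval the behavior increment is drawn using the
#' influence matrix of the pre-event network; at the event an actor is
#' chosen uniformly and one of their edges is toggled with
#' [edge_change_distribution()] weights evaluated at the pre-event network
#' and the post-increment behavior; a final increment covers
#' `(t_k, t_total)`.
#'
#' @param y0 initial adjacency matrix.
#' @param z0 initial behavior vector.
#' @param X covariate matrix.
#' @param params a [coevol_params()].
#' @param spec a [statistic_spec()] with `spec$q == length(params$theta)`.
#' @param t_total horizon.
#' @return list with `path` (a [coevol_path()]), `y0`, `z0`, and the final
#'   states `yT`, `zT`.
#' @examples
#' set.seed(1)
#' fix <- make_fixture(n = 10, density = 0.3, behavior_mean = 22.9,
#'                     behavior_sd = 2, bounds = c(14, 46))
#' spec <- statistic_spec("outdegree", "reciprocity")
#' pars <- coevol_params(1, c(-1, 0.5), 0.001, 0.1, 0.1)
#' sim <- simulate_coevolution(fix$y, fix$z, fix$X, pars, spec, t_total = 5)
#' sim$path$k
#' @export
simulate_coevolution <- function(y0, z0, X, params, spec, t_total) {
  validate_network(y0)
  stopifnot(length(params$theta) == spec$q)
  n <- nrow(y0)
  k <- sample_event_count(params$lambda, t_total)
  times <- sample_event_times(k, t_total)
  bounds <- c(0, times, t_total)
  y <- y0
  z <- as.numeric(z0)
  toggles <- matrix(0L, k, 2L)
  increments <- matrix(0, k + 1L, n)
  for (u in seq_len(k)) {
    dt <- bounds[u + 1L] - bounds[u]
    dz <- draw_increment(influence_matrix(y), X, params, dt)
    increments[u, ] <- dz
    z <- z + dz
    i <- sample.int(n, 1L)
    dist <- edge_change_distribution(spec, params, y, z, X, i)
    j <- dist$alters[sample.int(n - 1L, 1L, prob = dist$probs)]
    toggles[u, ] <- c(i, j)
    y <- toggle_edge(y, i, j)
  }
  dt <- t_total - bounds[k + 1L]
  dz <- draw_increment(influence_matrix(y), X, params, dt)
  increments[k + 1L, ] <- dz
  z <- z + dz
  list(path = coevol_path(times, toggles, increments, t_total),
       y0 = y0, z0 = as.numeric(z0), yT = y, zT = z)
}

#' Generate a synthetic two-wave starting state
#'
#' Builds the simulation-study starting conditions: a directed
#' Erdos-Renyi graph (each off-diagonal entry an independent
#' Bernoulli(`density`) draw), a behavior vector drawn from a normal
#' distribution truncated to `bounds` (BMI-like values), and a single
#' constant covariate column.
#'
#' @param n number of actors.
#' @param density tie probability in (0, 1).
#' @param behavior_mean,behavior_sd mean and sd of the (untruncated)
#'   behavior distribution.
#' @param bounds length-2 vector, truncation limits for the behavior draw.
#' @return list with adjacency `y`, behavior `z`, and covariates `X`
#'   (an `n x 1` constant column).
#' @export
make_fixture <- function(n, density = 0.3, behavior_mean = 22.9,
                         behavior_sd = 4.4, bounds = c(14, 46)) {
  stopifnot(density >= 0, density < 1, bounds[1] < bounds[2])
  y <- matrix(rbinom(n * n, 1L, density), n, n)
  diag(y) <- 0L
  lo <- pnorm(bounds[1], behavior_mean, behavior_sd)
  hi <- pnorm(bounds[2], behavior_mean, behavior_sd)
  z <- qnorm(runif(n, lo, hi), behavior_mean, behavior_sd)
  list(y = y, z = z, X = matrix(1, n, 1))
}

#' Statistic specification and parameters of the bundled simulation study
#'
#' Convenience constructors for the desk-scale simulation design used
#' throughout the package's examples and tests: 30 actors, initial tie
#' density 0.3, BMI-like behavior with mean 22.9, a 60-day horizon, event
#' rate 1/day, trend 0.001/day, influence 0.1, noise scale 0.1, and effects
#' outdegree, reciprocity, transitive triplets and centered BMI similarity
#' (range 32, centering constant 0.8619) with coefficients
#' (-3.42, 2.33, 0.50, 0.39).
#'
#' @return `bmi_study_spec()`: a [statistic_spec()];
#'   `bmi_study_params()`: a [coevol_params()].
#' @export
bmi_study_spec <- function() {
  statistic_spec("outdegree", "reciprocity", "transitive_triplets",
                 effect("similarity", range = 32, mean_sim = 0.8619))
}

#' @rdname bmi_study_spec
#' @export
bmi_study_params <- function() {
  coevol_params(lambda = 1, theta = c(-3.42, 2.33, 0.50, 0.39),
                gamma = 0.001, alpha = 0.1, sigma = 0.1)
}
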