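## Reference calculator for the discrete-choice actor-based (SAOM)
## comparison model: forward behavior/network change probabilities and the
## waiting-time arithmetic. No estimation -- coefficients are inputs.

#' Actor-based behavior objective
#'
#' The behavior objective for actor `i` evaluated at a candidate value
#' `z_i'`:
#' `g_i = linear_coef (z_i' - center) + quad_coef (z_i' - center)^2 +
#'  similarity_coef * mean_j over friends of (1 - |z_i' - z_j|/range - mean_sim)`,
#' the similarity term entering only when the actor names at least one
#' friend. Behavior moves are unit steps on an integer grid bounded by
#' `bounds`; moves that would leave the bounds are infeasible.
#'
#' @param linear_coef,quad_coef,center linear/quadratic shape coefficients
#'   and their centering constant (behavior units).
#' @param similarity_coef coefficient of the average-similarity term.
#' @param range,mean_sim similarity divisor and centering constant.
#' @param bounds integer length-2 vector `(z_min, z_max)`, `z_min < z_max`.
#' @return An object of class `"absm_behavior_model"`.
#' @export
absm_behavior_model <- function(linear_coef, quad_coef, center,
                                similarity_coef = 0, range = 1, mean_sim = 0,
                                bounds) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2], range > 0)
  structure(list(linear_coef = linear_coef, quad_coef = quad_coef,
                 center = center, similarity_coef = similarity_coef,
                 range = range, mean_sim = mean_sim,
                 bounds = as.numeric(bounds)),
            class = "absm_behavior_model")
}

absm_objective <- function(model, y, z, i, zi_new) {
  g <- model$linear_coef * (zi_new - model$center) +
    model$quad_coef * (zi_new - model$center)^2
  deg <- sum(y[i, ]) - y[i, i]
  if (model$similarity_coef != 0 && deg > 0) {
    sims <- 1 - abs(zi_new - z) / model$range - model$mean_sim
    sims[i] <- 0
    g <- g + model$similarity_coef * sum(y[i, ] * sims) / deg
  }
  g
}

#' Behavior change probabilities under the actor-based model
#'
#' Probability that actor `i`, given the opportunity, moves its behavior
#' down one unit, stays, or moves up one unit: a softmax of the behavior
#' objective over the feasible candidates. Moves that would leave the
#' model's bounds get probability exactly 0 and the remaining mass is
#' renormalized (they are excluded from the normalizing sum, not assigned a
#' vanishing weight).
#'
#' @param model an [absm_behavior_model()].
#' @param y adjacency matrix (`NULL` for a friendless actor).
#' @param z behavior vector (or a scalar, the actor's own value, when
#'   `y` is `NULL`).
#' @param i actor index (ignored when `y` is `NULL`).
#' @return named numeric vector `c(down, same, up)` summing to 1.
#' @examples
#' # quadratic objective in vertex form 0.0144 (z - 17.5)^2, bounds [14, 46]
#' m <- absm_behavior_model(linear_coef = 0, quad_coef = 0.0144,
#'                          center = 17.5, bounds = c(14, 46))
#' round(behavior_change_probabilities(m, NULL, 30), 3)
#' @export
behavior_change_probabilities <- function(model, y, z, i = 1L) {
  if (is.null(y)) {
    y <- matrix(0, 1, 1)
    z <- z[1]
    i <- 1L
  }
  zi <- z[i]
  if (zi < model$bounds[1] || zi > model$bounds[2])
    stop("behavior value ", zi, " outside bounds [",
         model$bounds[1], ", ", model$bounds[2], "]", call. = FALSE)
  steps <- c(-1, 0, 1)
  feasible <- zi + steps >= model$bounds[1] & zi + steps <= model$bounds[2]
  g <- vapply(steps, function(s) {
    znew <- z
    znew[i] <- zi + s
    absm_objective(model, y, znew, i, zi + s)
  }, numeric(1))
  w <- ifelse(feasible, exp(g - max(g[feasible])), 0)
  p <- w / sum(w)
  names(p) <- c("down", "same", "up")
  p
}

#' Network change probabilities under the actor-based model
#'
#' When actor `i` gets a network change opportunity there are `n` candidate
#' outcomes: toggle one of the `n - 1` edges in row `i`, or leave the
#' network unchanged (the candidate `j = i`). Each candidate network `y'`
#' gets probability proportional to `exp(f_i(y', z))`, with
#' `f_i = sum_k beta_k u_ik` built from a [statistic_spec()].
#'
#' @param spec a [statistic_spec()].
#' @param beta coefficient vector, one entry per effect.
#' @param y adjacency matrix.
#' @param z behavior vector.
#' @param X covariate matrix.
#' @param i actor index.
#' @return numeric vector of length `n` summing to 1; entry `j` is the
#'   probability of moving to `c(y, i, j)` (entry `i` = stay put).
#' @export
network_change_probabilities_absm <- function(spec, beta, y, z, X, i) {
  n <- nrow(y)
  f <- vapply(seq_len(n), function(j) {
    ycand <- if (j == i) y else toggle_edge(y, i, j)
    sum(beta * evaluate_statistics(spec, ycand, z, X, i))
  }, numeric(1))
  w <- exp(f - max(f))
  w / sum(w)
}

#' Per-actor opportunity rates for the actor-based model
#'
#' @param rate_network,rate_behavior per-actor opportunity rates (scalars
#'   are recycled to `n_actors`).
#' @param n_actors number of actors.
#' @return An object of class `"absm_rates"` with the total rate
#'   `sum_i (rate_network_i + rate_behavior_i)`.
#' @export
absm_rates <- function(rate_network, rate_behavior, n_actors) {
  rn <- rep_len(rate_network, n_actors)
  rb <- rep_len(rate_behavior, n_actors)
  stopifnot(all(rn >= 0), all(rb >= 0))
  structure(list(rate_network = rn, rate_behavior = rb,
                 n_actors = n_actors, total = sum(rn) + sum(rb)),
            class = "absm_rates")
}

#' Mean waiting time between change opportunities
#'
#' The waiting time between opportunities is exponential with the total
#' rate, so its mean is `1 / total`. `convert` rescales the result to a
#' different time unit (e.g. `365 * 24` turns a per-year rate into a
#' waiting time in hours).
#'
#' @param rates an [absm_rates()].
#' @param convert multiplicative unit conversion applied to `1 / total`.
#' @return positive scalar.
#' @examples
#' r <- absm_rates(12.29, 4.17, n_actors = 624)
#' mean_waiting_time(r, convert = 365 * 24)  # hours
#' @export
mean_waiting_time <- function(rates, convert = 1) {
  if (rates$total <= 0)
    stop("total opportunity rate must be positive", call. = FALSE)
  convert / rates$total
}
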