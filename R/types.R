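#' Model parameters for the network-behavior co-evolution process
#'
#' Bundles the five parameter blocks of the joint model: the Poisson event
#' rate `lambda` (network change events per unit time), the vector `theta` of
#' coefficients on the network change statistics, the covariate trend
#' coefficients `gamma` (one per column of the covariate matrix), the peer
#' influence strength `alpha` (the spatial-lag coefficient on friends' mean
#' behavior change), and the diffusion scale `sigma` (standard deviation of
#' the behavior noise per unit time^1/2).
#'
#' `alpha` is restricted to (-1, 1): with a row-stochastic influence matrix
#' the spectral radius is at most 1, so `|alpha| < 1` guarantees that
#' `I - alpha * W` is invertible for every network the process can visit.
#'
#' @param lambda positive event rate.
#' @param theta numeric vector of network effect coefficients; its length
#'   must match the number of effects in the [statistic_spec()] used with it.
#' @param gamma numeric vector of covariate trend coefficients.
#' @param alpha influence strength, `abs(alpha) < 1`.
#' @param sigma positive noise scale.
#' @return An object of class `"coevol_params"`.
#' @examples
#' coevol_params(lambda = 1, theta = c(-3.42, 2.33), gamma = 0.001,
#'               alpha = 0.1, sigma = 0.1)
#' @export
coevol_params <- function(lambda, theta, gamma, alpha, sigma) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0,
            is.numeric(theta), is.numeric(gamma),
            is.numeric(alpha), length(alpha) == 1L, abs(alpha) < 1,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  structure(list(lambda = as.numeric(lambda), theta = as.numeric(theta),
                 gamma = as.numeric(gamma), alpha = as.numeric(alpha),
                 sigma = as.numeric(sigma)),
            class = "coevol_params")
}

#' @export
print.coevol_params <- function(x, ...) {
  cat("<coevol_params>\n")
  cat("  lambda:", format(x$lambda), "\n")
  cat("  theta: ", paste(format(x$theta), collapse = ", "), "\n")
  cat("  gamma: ", paste(format(x$gamma), collapse = ", "), "\n")
  cat("  alpha: ", format(x$alpha), "\n")
  cat("  sigma: ", format(x$sigma), "\n")
  invisible(x)
}

#' Validate a directed binary adjacency matrix
#'
#' The network state is a plain `n x n` 0/1 matrix with a zero diagonal
#' (no self-nominations); entry `(i, j) = 1` means actor `i` names `j`
#' a friend. Called at user-facing boundaries; internal code assumes a
#' valid matrix.
#'
#' @param y matrix to check.
#' @param n optional expected number of actors.
#' @return `y`, invisibly, after validation.
#' @export
validate_network <- function(y, n = NULL) {
  if (!is.matrix(y) || nrow(y) != ncol(y))
    stop("network must be a square matrix", call. = FALSE)
  if (!is.null(n) && nrow(y) != n)
    stop("network has ", nrow(y), " actors, expected ", n, call. = FALSE)
  if (any(y != 0 & y != 1))
    stop("network entries must be 0 or 1", call. = FALSE)
  if (any(diag(y) != 0))
    stop("network must have a zero diagonal (no self-loops)", call. = FALSE)
  invisible(y)
}

#' Two-wave panel observation
#'
#' The observed data: the network and behavior vector at the first wave
#' (time 0) and at the second wave (time `t_total`). Everything between the
#' waves -- the number of events, their times, which edge toggled at each,
#' and the behavior increments -- is latent.
#'
#' @param y0,yT adjacency matrices at the two waves (same dimension).
#' @param z0,zT behavior vectors at the two waves.
#' @param t_total positive inter-wave duration (same time unit as `lambda`).
#' @return An object of class `"coevol_obs"` with an element `d`, the number
#'   of dyads on which the two networks disagree (the size of the important
#'   list; every latent history must contain at least `d` events, with the
#'   event count matching `d` in parity).
#' @export
coevol_obs <- function(y0, z0, yT, zT, t_total) {
  validate_network(y0); validate_network(yT, n = nrow(y0))
  n <- nrow(y0)
  stopifnot(length(z0) == n, length(zT) == n,
            all(is.finite(z0)), all(is.finite(zT)),
            is.numeric(t_total), length(t_total) == 1L, t_total > 0)
  structure(list(y0 = y0, z0 = as.numeric(z0), yT = yT, zT = as.numeric(zT),
                 t_total = as.numeric(t_total), n = n,
                 d = sum(y0 != yT)),
            class = "coevol_obs")
}

#' @export
print.coevol_obs <- function(x, ...) {
  cat("<coevol_obs> ", x$n, " actors, horizon ", format(x$t_total),
      ", ", x$d, " disagreeing dyads\n", sep = "")
  invisible(x)
}

#' Complete-data event path
#'
#' The complete data over one observation period: the event count `k`, the
#' strictly increasing event times in `(0, t_total)`, the toggled dyad at
#' each event (a `k x 2` matrix of 1-based actor indices), and the behavior
#' increment on each of the `k + 1` inter-event intervals (a
#' `(k + 1) x n` matrix; the last row covers `(t_k, t_total)`).
#'
#' @param times numeric vector of event times.
#' @param toggles integer `k x 2` matrix, columns `i` (ego) and `j` (alter).
#' @param increments numeric `(k + 1) x n` matrix of behavior increments.
#' @param t_total observation horizon.
#' @return An object of class `"coevol_path"`.
#' @export
coevol_path <- function(times, toggles, increments, t_total) {
  k <- length(times)
  toggles <- matrix(as.integer(toggles), ncol = 2L)
  if (nrow(toggles) != k)
    stop("need one toggle per event time", call. = FALSE)
  if (k > 0) {
    if (any(diff(times) <= 0) || times[1] <= 0 || times[k] >= t_total)
      stop("event times must be strictly increasing inside (0, t_total)",
           call. = FALSE)
    if (any(toggles[, 1] == toggles[, 2]))
      stop("a toggle must join two distinct actors", call. = FALSE)
  }
  if (nrow(increments) != k + 1L)
    stop("need k + 1 behavior increments", call. = FALSE)
  structure(list(k = k, times = as.numeric(times), toggles = toggles,
                 increments = increments, t_total = as.numeric(t_total)),
            class = "coevol_path")
}

#' @export
print.coevol_path <- function(x, ...) {
  cat("<coevol_path> ", x$k, " events over (0, ", format(x$t_total), ")\n",
      sep = "")
  invisible(x)
}

#' Replay a complete path from initial states
#'
#' Applies the recorded increments and toggles of a path to `(y0, z0)` and
#' returns the implied terminal states. Used both to advance the simulator's
#' bookkeeping and as a self-consistency oracle: a valid path replayed from
#' its own initial states must land exactly on its recorded endpoints.
#'
#' @param path a [coevol_path()].
#' @param y0 initial adjacency matrix.
#' @param z0 initial behavior vector.
#' @return list with terminal `y`, terminal `z`, and `states`, the list of
#'   per-interval pre-increment networks (length `k + 1`, first element `y0`).
#' @export
replay_path <- function(path, y0, z0) {
  y <- y0
  z <- as.numeric(z0)
  states <- vector("list", path$k + 1L)
  for (u in seq_len(path$k)) {
    states[[u]] <- y
    z <- z + path$increments[u, ]
    y <- toggle_edge(y, path$toggles[u, 1], path$toggles[u, 2])
  }
  states[[path$k + 1L]] <- y
  z <- z + path$increments[path$k + 1L, ]
  list(y = y, z = z, states = states)
}
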