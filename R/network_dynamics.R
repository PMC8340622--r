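## Single-edge change mechanics at a network event.
##
## At an event, an actor i is drawn uniformly and exactly one of the n - 1
## edges in row i is toggled. The probability of toggling (i, j) is
## proportional to exp{(2 y_ij - 1) theta' delta_ij(y, z)}: the sign factor
## makes present and absent ties enter with opposite sign. The uniform 1/n
## actor factor is a separate draw and is not part of this distribution.

#' Flip one directed edge
#'
#' @param y adjacency matrix.
#' @param i,j distinct actor indices; entry `(i, j)` is flipped.
#' @return The network with edge `(i, j)` toggled.
#' @export
toggle_edge <- function(y, i, j) {
  if (i == j) stop("toggle_edge: i and j must differ", call. = FALSE)
  y[i, j] <- (if (is.integer(y)) 1L else 1) - y[i, j]
  y
}

#' Edge-change distribution for one actor
#'
#' Given that actor `i` makes the next network change, returns the
#' probability of toggling each edge `(i, j')`, `j' != i`, proportional to
#' `exp{(2 y_ij' - 1) theta' delta_ij'(y, z)}`. Log-weights are shifted by
#' their maximum before exponentiation, so large coefficients cannot
#' overflow.
#'
#' With `sign = "reversed"` the sign factor is negated, so ties whose
#' presence contributes positively to the ego's statistics become the least
#' likely to be dismantled; the default keeps the model's printed
#' convention, which is also the one the path sampler uses.
#'
#' @param spec a [statistic_spec()].
#' @param params a [coevol_params()] (only `theta` is used).
#' @param y adjacency matrix.
#' @param z behavior vector (the value immediately before the toggle).
#' @param X covariate matrix.
#' @param i ego index.
#' @param sign `"as_printed"` (default) or `"reversed"`.
#' @return An object of class `"edge_change_distribution"`: list with
#'   `actor`, `alters` (the indices `j' != i`), `probs` (summing to 1) and
#'   `log_weights` (the unnormalized `(2 y_ij' - 1) theta' delta_ij'`).
#' @export
edge_change_distribution <- function(spec, params, y, z, X, i,
                                     sign = c("as_printed", "reversed")) {
  sign <- match.arg(sign)
  n <- nrow(y)
  stopifnot(n >= 2, i >= 1, i <= n)
  wd <- weighted_delta(spec, params$theta, y, z, X)
  lw <- (2 * y[i, ] - 1) * wd[i, ]
  if (sign == "reversed") lw <- -lw
  lw <- lw[-i]
  w <- exp(lw - max(lw))
  structure(list(actor = i, alters = seq_len(n)[-i],
                 probs = w / sum(w), log_weights = lw),
            class = "edge_change_distribution")
}

#' @export
print.edge_change_distribution <- function(x, ...) {
  cat("<edge_change_distribution> actor ", x$actor, ", ",
      length(x$alters), " alters\n", sep = "")
  invisible(x)
}

## log-probability matrix over all ordered dyads for one event, including
## the uniform 1/n actor factor: entry (i, j) is the exact log-probability
## that the event toggles (i, j). Row-wise log-sum-exp normalization.
event_logprob_matrix <- function(spec, theta, y, z, X) {
  n <- nrow(y)
  lw <- (2 * y - 1) * weighted_delta(spec, theta, y, z, X)
  diag(lw) <- -Inf
  m <- apply(lw, 1, max)
  lse <- m + log(rowSums(exp(lw - m)))
  lw - lse - log(n)
}
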