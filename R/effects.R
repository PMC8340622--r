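## Network/behavior statistics and their change statistics.
##
## Each effect is defined from the ego's perspective: u_i(y, z) is a scalar
## statistic of actor i's out-neighbourhood, and the change statistic
## delta_ij = u_i(y with edge (i,j) forced on) - u_i(y with it forced off)
## is, by construction, independent of the current value of y_ij.
## Built-in effects provide a closed-form n x n matrix of change statistics
## (delta for every ordered dyad at once); this is the hot path of both the
## simulator and the path sampler.

.effect_registry <- new.env(parent = emptyenv())

register_effect <- function(name, constructor) {
  assign(name, constructor, envir = .effect_registry)
  invisible(name)
}

#' Create a network effect by name
#'
#' Effects are registered by name so that the coefficient vector `theta`,
#' the declaration order of a [statistic_spec()], and any configuration file
#' stay aligned. Built-in effects:
#'
#' * `"outdegree"`: number of friends named, `sum_j y_ij`.
#' * `"reciprocity"`: mutual ties, `sum_j y_ij y_ji`.
#' * `"transitive_triplets"`: ordered transitive triples
#'   `sum_j y_ij sum_h y_ih y_hj`.
#' * `"same_attribute"`: ties to actors sharing a categorical covariate,
#'   `sum_j y_ij I(x_i = x_j)`; requires `column`, the covariate column index.
#' * `"similarity"`: centered behavior similarity
#'   `sum_j y_ij (1 - |z_i - z_j| / range - mean_sim)`; requires `range`
#'   (the behavior range used as divisor) and `mean_sim` (the centering
#'   constant, e.g. an observed mean similarity score). Both are supplied by
#'   the user, never computed silently.
#'
#' @param name effect name (see above).
#' @param ... effect parameters (`column`, or `range` and `mean_sim`).
#' @return An object of class `"coevol_effect"`.
#' @examples
#' effect("outdegree")
#' effect("similarity", range = 32, mean_sim = 0.8619)
#' @export
effect <- function(name, ...) {
  if (!exists(name, envir = .effect_registry, inherits = FALSE))
    stop("unknown effect '", name, "'; available: ",
         paste(sort(ls(.effect_registry)), collapse = ", "), call. = FALSE)
  eff <- get(name, envir = .effect_registry)(...)
  eff$name <- name
  class(eff) <- "coevol_effect"
  eff
}

#' @export
print.coevol_effect <- function(x, ...) {
  cat("<coevol_effect>", x$name, "\n")
  invisible(x)
}

register_effect("outdegree", function() {
  list(eval = function(y, z, X, i) sum(y[i, ]),
       dmat = function(y, z, X) {
         n <- nrow(y)
         matrix(1, n, n)
       })
})

register_effect("reciprocity", function() {
  list(eval = function(y, z, X, i) sum(y[i, ] * y[, i]),
       dmat = function(y, z, X) t(y))
})

register_effect("transitive_triplets", function() {
  list(eval = function(y, z, X, i) {
         v <- y[i, ]
         sum(v * as.vector(crossprod(y, v)))
       },
       ## toggling (i,j) changes u_i by the i->h->j two-paths plus the
       ## triples where (i,j) serves as the i->h leg: sum_j' y_ij' y_jj'
       dmat = function(y, z, X) y %*% y + tcrossprod(y))
})

register_effect("same_attribute", function(column) {
  stopifnot(is.numeric(column), length(column) == 1L)
  list(column = column,
       eval = function(y, z, X, i) {
         x <- X[, column]
         sum(y[i, ] * (x == x[i]))
       },
       dmat = function(y, z, X) {
         x <- X[, column]
         outer(x, x, "==") * 1
       })
})

register_effect("similarity", function(range, mean_sim) {
  stopifnot(is.numeric(range), range > 0, is.numeric(mean_sim))
  list(range = range, mean_sim = mean_sim,
       eval = function(y, z, X, i)
         sum(y[i, ] * (1 - abs(z[i] - z) / range - mean_sim)),
       dmat = function(y, z, X)
         1 - abs(outer(z, z, "-")) / range - mean_sim)
})

#' Declare the vector of network change statistics
#'
#' Collects effects (in declaration order) into the statistic vector
#' `u(y, z)` whose change statistics, weighted by `theta`, drive the edge
#' choice at each network change event.
#'
#' @param ... [effect()] objects, or bare character names for effects
#'   without parameters.
#' @return An object of class `"statistic_spec"` with elements `effects`,
#'   `names` and `q` (the number of effects, which must equal
#'   `length(theta)`).
#' @examples
#' statistic_spec("outdegree", "reciprocity",
#'                effect("similarity", range = 32, mean_sim = 0.8619))
#' @export
statistic_spec <- function(...) {
  effs <- lapply(list(...), function(e) {
    if (is.character(e)) effect(e) else e
  })
  ok <- vapply(effs, inherits, logical(1), what = "coevol_effect")
  if (length(effs) == 0L || !all(ok))
    stop("statistic_spec() takes one or more effect() objects or names",
         call. = FALSE)
  structure(list(effects = effs,
                 names = vapply(effs, `[[`, character(1), "name"),
                 q = length(effs)),
            class = "statistic_spec")
}

#' @export
print.statistic_spec <- function(x, ...) {
  cat("<statistic_spec> ", x$q, " effects: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate the statistic vector from one actor's perspective
#'
#' @param spec a [statistic_spec()].
#' @param y adjacency matrix.
#' @param z behavior vector.
#' @param X covariate matrix (rows = actors).
#' @param i ego index.
#' @return numeric vector of length `spec$q`, one entry per effect in
#'   declaration order.
#' @export
evaluate_statistics <- function(spec, y, z, X, i) {
  stopifnot(inherits(spec, "statistic_spec"))
  n <- nrow(y)
  if (!(is.numeric(i) && length(i) == 1L && i >= 1 && i <= n))
    stop("actor index i out of range", call. = FALSE)
  diag(y) <- 0  # self-loops are never read
  vapply(spec$effects, function(e) e$eval(y, z, X, i), numeric(1))
}

#' Change statistics for one dyad
#'
#' Returns `u_i(y` with edge `(i,j)` on`) - u_i(y` with it off`)`, one entry
#' per effect. Independent of the current value of `y[i, j]`.
#'
#' @inheritParams evaluate_statistics
#' @param j alter index, `j != i`.
#' @return numeric vector of length `spec$q`.
#' @export
change_statistic <- function(spec, y, z, X, i, j) {
  if (i == j) stop("change_statistic: i and j must differ", call. = FALSE)
  vapply(delta_matrices(spec, y, z, X), function(d) d[i, j], numeric(1))
}

## n x n matrices of change statistics for every effect (list of length q);
## diagonals are meaningless and must never be read.
delta_matrices <- function(spec, y, z, X) {
  diag(y) <- 0  # self-loops are never read
  lapply(spec$effects, function(e) e$dmat(y, z, X))
}

## theta' delta for every ordered dyad: n x n matrix (diagonal garbage).
weighted_delta <- function(spec, theta, y, z, X) {
  dm <- delta_matrices(spec, y, z, X)
  out <- matrix(0, nrow(y), ncol(y))
  for (q in seq_along(dm)) out <- out + theta[q] * dm[[q]]
  out
}
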