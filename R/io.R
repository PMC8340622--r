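## Readers and writers: TSV edge lists for networks, CSV for actor
## attributes, versioned JSON for complete paths. Actor ids are 1-based
## in all files, matching the in-memory convention.

#' Read a directed network from a TSV edge list
#'
#' Expects a header row with columns `source` and `target` (1-based actor
#' ids). Rejects out-of-range ids, self-loops and duplicate edges with the
#' offending file line number.
#'
#' @param file path to the TSV file.
#' @param n number of actors (fixes the adjacency dimension; isolated
#'   actors need not appear in the file).
#' @return `n x n` adjacency matrix.
#' @export
read_network <- function(file, n) {
  df <- utils::read.delim(file, header = TRUE)
  if (!all(c("source", "target") %in% names(df)))
    stop("edge list must have columns 'source' and 'target'", call. = FALSE)
  y <- matrix(0L, n, n)
  for (r in seq_len(nrow(df))) {
    i <- df$source[r]
    j <- df$target[r]
    line <- r + 1L  # header is line 1
    if (!is.numeric(i) || !is.numeric(j) || i != round(i) || j != round(j) ||
        i < 1 || i > n || j < 1 || j > n)
      stop("line ", line, ": actor id out of range 1..", n, call. = FALSE)
    if (i == j)
      stop("line ", line, ": self-loop (", i, ", ", j, ") not allowed",
           call. = FALSE)
    if (y[i, j] == 1L)
      stop("line ", line, ": duplicate edge (", i, ", ", j, ")",
           call. = FALSE)
    y[i, j] <- 1L
  }
  y
}

#' Write a directed network as a TSV edge list
#'
#' @param y adjacency matrix.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_network <- function(y, file) {
  validate_network(y)
  idx <- which(y == 1, arr.ind = TRUE)
  df <- data.frame(source = idx[, 1], target = idx[, 2])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read actor attributes from a CSV file
#'
#' One row per actor, in actor-id order. The column named `behavior_col`
#' becomes the behavior vector; all remaining numeric columns become the
#' covariate matrix (a single constant column when there are none).
#'
#' @param file path to the CSV file.
#' @param behavior_col name of the behavior column.
#' @return list with `z` (behavior vector), `X` (covariate matrix) and
#'   `data` (the full table as a tibble).
#' @export
read_attributes <- function(file, behavior_col = "behavior") {
  df <- utils::read.csv(file, header = TRUE)
  if (!behavior_col %in% names(df))
    stop("no column named '", behavior_col, "' in ", file, call. = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric column(s): ",
         paste(names(df)[!num], collapse = ", "), call. = FALSE)
  z <- df[[behavior_col]]
  rest <- df[setdiff(names(df), behavior_col)]
  X <- if (ncol(rest) > 0) as.matrix(rest) else
    matrix(1, nrow(df), 1, dimnames = list(NULL, "const"))
  list(z = z, X = X, data = tibble::as_tibble(df))
}

#' Write actor attributes to a CSV file
#'
#' @param z behavior vector.
#' @param X optional covariate matrix (constant-only columns are written
#'   too).
#' @param file output path.
#' @param behavior_col column name for the behavior.
#' @return `file`, invisibly.
#' @export
write_attributes <- function(z, X = NULL, file, behavior_col = "behavior") {
  df <- data.frame(z)
  names(df) <- behavior_col
  if (!is.null(X)) {
    Xd <- as.data.frame(X)
    if (is.null(colnames(X)))
      names(Xd) <- paste0("x", seq_len(ncol(X)))
    df <- cbind(df, Xd)
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

path_schema_version <- 1L

#' Write a complete event path to JSON
#'
#' The schema carries an explicit `version` field and serializes all
#' numbers at full precision, so write/read round-trips are bit-exact.
#'
#' @param path a [coevol_path()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_path <- function(path, file) {
  obj <- list(version = path_schema_version,
              t_total = path$t_total,
              k = path$k,
              times = path$times,
              toggles = path$toggles,
              increments = path$increments)
  ## 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(file)
}

#' Read a complete event path from JSON
#'
#' @param file path to a JSON file produced by [write_path()].
#' @return a [coevol_path()].
#' @export
read_path <- function(file) {
  obj <- tryCatch(jsonlite::read_json(file, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse ", file, ": ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(obj$version) || obj$version != path_schema_version)
    stop("unsupported path schema version: ",
         if (is.null(obj$version)) "missing" else obj$version,
         " (expected ", path_schema_version, ")", call. = FALSE)
  k <- obj$k
  inc <- obj$increments
  n <- if (is.matrix(inc)) ncol(inc) else length(unlist(inc))
  tg <- obj$toggles
  if (!is.matrix(tg)) tg <- matrix(as.integer(unlist(tg)), nrow = k, ncol = 2)
  if (!is.matrix(inc))
    inc <- matrix(as.numeric(unlist(inc)), nrow = k + 1L, ncol = n,
                  byrow = TRUE)
  coevol_path(times = as.numeric(unlist(obj$times)),
              toggles = tg,
              increments = inc,
              t_total = obj$t_total)
}
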