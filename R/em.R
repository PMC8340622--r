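## Monte Carlo EM: alternate path imputation at the current parameters
## (E-step) with closed-form updates for lambda, gamma, sigma^2 and a
## box-constrained quasi-Newton maximization of the profiled objective
## over (theta, alpha) (M-step).

params_to_vec <- function(p, effect_names = NULL) {
  th <- p$theta
  names(th) <- if (!is.null(effect_names) && length(effect_names) == length(th))
    paste0("theta_", effect_names) else paste0("theta", seq_along(th))
  gm <- p$gamma
  names(gm) <- paste0("gamma", seq_along(gm))
  c(lambda = p$lambda, th, gm, alpha = p$alpha, sigma = p$sigma)
}

default_init <- function(obs, X, q) {
  t_total <- obs$t_total
  lam0 <- max(obs$d, 1) / t_total
  dz <- obs$zT - obs$z0
  gam0 <- as.vector(solve(crossprod(X) * t_total, crossprod(X, dz)))
  resid <- dz - t_total * as.vector(X %*% gam0)
  sig0 <- sqrt(max(sum(resid^2) / (obs$n * t_total), 1e-4))
  coevol_params(lambda = lam0, theta = rep(0, q), gamma = gam0,
                alpha = 0, sigma = sig0)
}

#' Fit the co-evolution model to a two-wave panel by Monte Carlo EM
#'
#' Each iteration imputes `R` latent event histories by the
#' Metropolis-Hastings path sampler at the current parameters, then
#' updates: `lambda` as the mean imputed event count divided by the
#' horizon; `(theta, alpha)` by maximizing the profiled Monte Carlo
#' objective ([profile_h()]) with `alpha` box-constrained to
#' `(-0.99, 0.99)`; and `gamma`, `sigma` by their closed forms at the new
#' `alpha`. Iteration stops when the largest relative parameter change
#' falls below `tol` or after `max_iter` iterations (non-convergence gives
#' a warning and a `converged = FALSE` flag, never an error).
#'
#' By default every E-step reuses one fixed random seed (common random
#' numbers), which removes Monte Carlo jitter from the EM trajectory and
#' makes the stopping rule meaningful at moderate `R`; set
#' `common_seed = FALSE` for independent draws per iteration.
#'
#' @param obs a [coevol_obs()].
#' @param X covariate matrix.
#' @param spec a [statistic_spec()].
#' @param init optional [coevol_params()] starting values; by default a
#'   crude moment-based start (`lambda = d / t_total`, `theta = 0`,
#'   `alpha = 0`, least-squares `gamma`, residual `sigma`).
#' @param R imputations per E-step.
#' @param burn_in,thin MCMC settings passed to [run_imputation()].
#' @param max_iter,tol EM stopping rule.
#' @param common_seed reuse one seed across E-steps (see above).
#' @param verbose print per-iteration progress.
#' @return An object of class `"coevol_fit"`: `estimates` (a
#'   [coevol_params()]), `trajectory` (matrix, one row per iteration
#'   including the start), `diagnostics` (acceptance rates, `R`,
#'   iterations, convergence flag, SE method), and the inputs needed to
#'   resume or bootstrap (`obs`, `X`, `spec`).
#' @seealso [standard_errors()], [tidy.coevol_fit()], [glance.coevol_fit()]
#' @export
coevol_fit <- function(obs, X, spec, init = NULL, R = 50, burn_in = 100,
                       thin = 1, max_iter = 50, tol = 1e-3,
                       common_seed = TRUE, verbose = FALSE) {
  stopifnot(inherits(obs, "coevol_obs"), R >= 1)
  q <- spec$q
  cur <- if (is.null(init)) default_init(obs, X, q) else init
  stopifnot(length(cur$theta) == q, length(cur$gamma) == ncol(X))
  traj <- matrix(NA_real_, max_iter + 1L,
                 length(params_to_vec(cur, spec$names)))
  colnames(traj) <- names(params_to_vec(cur, spec$names))
  traj[1L, ] <- params_to_vec(cur)
  acc <- numeric(max_iter)
  hval <- numeric(max_iter)
  seed <- if (common_seed) sample.int(.Machine$integer.max, 1L) else NA
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (common_seed) set.seed(seed)
    imp <- run_imputation(obs, cur, spec, X, R = R, burn_in = burn_in,
                          thin = thin)
    acc[it] <- imp$acceptance
    lam <- max(lambda_mle(mean(imp$k), obs$t_total), 1e-8)
    sm <- summarize_paths(imp$paths, obs$y0, obs$z0, X, spec)
    fn <- make_profile_fn(sm, X, q)
    opt <- optim(c(cur$theta, cur$alpha), fn, method = "L-BFGS-B",
                 lower = c(rep(-Inf, q), -0.99),
                 upper = c(rep(Inf, q), 0.99),
                 control = list(fnscale = -1, factr = 1e9))
    theta <- opt$par[seq_len(q)]
    alpha <- opt$par[q + 1L]
    hval[it] <- opt$value
    gam <- gamma_closed_form(sm, X, alpha)
    sig <- sqrt(max(sigma2_closed_form(sm, X, alpha, gam), 1e-10))
    new <- coevol_params(lam, theta, gam, alpha, sig)
    old_v <- params_to_vec(cur)
    new_v <- params_to_vec(new)
    rel <- max(abs(new_v - old_v) / pmax(abs(old_v), 0.1))
    traj[it + 1L, ] <- new_v
    cur <- new
    if (verbose)
      message(sprintf("iter %d: h = %.3f, acc = %.2f, max rel change = %.4f",
                      it, hval[it], acc[it], rel))
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EM did not reach tol = ", tol, " within ", max_iter,
            " iterations; returning last iterate")
  structure(list(estimates = cur,
                 trajectory = traj[seq_len(it + 1L), , drop = FALSE],
                 diagnostics = list(acceptance = acc[seq_len(it)],
                                    h = hval[seq_len(it)],
                                    R = R, burn_in = burn_in, thin = thin,
                                    iterations = it, converged = converged,
                                    se_method = "parametric bootstrap"),
                 obs = obs, X = X, spec = spec),
            class = "coevol_fit")
}

#' @export
print.coevol_fit <- function(x, ...) {
  cat("<coevol_fit> ", x$diagnostics$iterations, " EM iterations (",
      if (x$diagnostics$converged) "converged" else "not converged",
      "), R = ", x$diagnostics$R, "\n", sep = "")
  est <- params_to_vec(x$estimates, x$spec$names)
  if (!is.null(x$std_errors)) {
    print(cbind(estimate = round(est, 4), se = round(x$std_errors, 4)))
  } else {
    print(round(est, 4))
  }
  invisible(x)
}

#' Parametric-bootstrap standard errors for a fitted model
#'
#' Simulates `B` two-wave datasets forward from the fitted parameters
#' (starting at the observed first wave), refits each with reduced EM
#' settings starting from the fitted values, and reports the
#' coordinate-wise standard deviations of the bootstrap estimates.
#'
#' @param fit a [coevol_fit()] result.
#' @param B number of bootstrap replicates (at least 2).
#' @param R,burn_in,max_iter reduced EM settings for the refits.
#' @param verbose print progress.
#' @return `fit`, with a `std_errors` vector and the bootstrap estimate
#'   matrix attached (`boot_estimates`).
#' @export
standard_errors <- function(fit, B = 20, R = 10, burn_in = 50,
                            max_iter = 5, verbose = FALSE) {
  if (B < 2) stop("need at least 2 bootstrap replicates", call. = FALSE)
  obs <- fit$obs
  est <- fit$estimates
  boot <- matrix(NA_real_, B, length(params_to_vec(est)))
  colnames(boot) <- names(params_to_vec(est, fit$spec$names))
  for (b in seq_len(B)) {
    sim <- simulate_coevolution(obs$y0, obs$z0, fit$X, est, fit$spec,
                                obs$t_total)
    bobs <- coevol_obs(sim$y0, sim$z0, sim$yT, sim$zT, obs$t_total)
    bfit <- suppressWarnings(
      coevol_fit(bobs, fit$X, fit$spec, init = est, R = R,
                 burn_in = burn_in, max_iter = max_iter, tol = 1e-3))
    boot[b, ] <- params_to_vec(bfit$estimates)
    if (verbose) message("bootstrap replicate ", b, " done")
  }
  fit$std_errors <- apply(boot, 2, sd)
  fit$boot_estimates <- boot
  fit
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameter estimates of a fitted co-evolution model
#'
#' @param x a [coevol_fit()] result.
#' @param ... unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and
#'   `std.error` when [standard_errors()] has been run.
#' @export
tidy.coevol_fit <- function(x, ...) {
  est <- params_to_vec(x$estimates, x$spec$names)
  out <- tibble::tibble(term = names(est), estimate = unname(est))
  if (!is.null(x$std_errors)) out$std.error <- unname(x$std_errors)
  out
}

#' One-row summary of a fitted co-evolution model
#'
#' @param x a [coevol_fit()] result.
#' @param ... unused.
#' @return A tibble with the iteration count, convergence flag, final
#'   profiled objective, mean MH acceptance rate and E-step size.
#' @export
glance.coevol_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(iterations = d$iterations, converged = d$converged,
                 objective = if (d$iterations > 0) d$h[d$iterations] else NA_real_,
                 mean_acceptance = mean(d$acceptance),
                 R = d$R)
}

#' Plot the EM parameter trajectory
#'
#' One panel per parameter, value against EM iteration.
#'
#' @param object a [coevol_fit()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coevol_fit <- function(object, ...) {
  tr <- object$trajectory
  df <- data.frame(iteration = rep(seq_len(nrow(tr)) - 1L, ncol(tr)),
                   term = rep(colnames(tr), each = nrow(tr)),
                   value = as.vector(tr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "EM iteration", y = "parameter value")
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' @export
plot.coevol_fit <- function(x, ...) print(autoplot.coevol_fit(x, ...))
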