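test_that("complete-data log-likelihood equals the per-step product", {
  set.seed(40)
  spec <- full_spec()
  pars <- coevol_params(2, c(-1, 0.8, 0.3, 0.2, 0.5), 0.01, 0.15, 0.25)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    fix <- make_fixture(n, density = 0.4)
    X <- cbind(const = rep(1, n), group = sample(1:2, n, replace = TRUE))
    pars_rep <- coevol_params(2, pars$theta, c(0.01, -0.02), 0.15, 0.25)
    sim <- simulate_coevolution(fix$y, fix$z, X, pars_rep, spec, 2)
    path <- sim$path
    # independent oracle: accumulate per-event edge-choice log-probabilities
    # (uniform actor factor included) and per-interval increment densities
    y <- sim$y0
    z <- sim$z0
    bounds <- c(0, path$times, path$t_total)
    oracle <- -pars_rep$lambda * path$t_total + path$k * log(pars_rep$lambda)
    for (u in seq_len(path$k + 1)) {
      dt <- bounds[u + 1] - bounds[u]
      dz <- path$increments[u, ]
      oracle <- oracle +
        increment_log_density(dz, influence_matrix(y), X, pars_rep, dt)
      z <- z + dz
      if (u <= path$k) {
        i <- path$toggles[u, 1]; j <- path$toggles[u, 2]
        ecd <- edge_change_distribution(spec, pars_rep, y, z, X, i)
        oracle <- oracle + log(ecd$probs[which(ecd$alters == j)]) - log(n)
        y <- toggle_edge(y, i, j)
      }
    }
    ll <- complete_log_likelihood(path, sim$y0, sim$z0, X, pars_rep, spec)
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("eventless path reduces to -lambda*T plus one increment density", {
  set.seed(41)
  n <- 5
  fix <- make_fixture(n)
  pars <- coevol_params(0.5, c(0, 0), 0.01, 0.1, 0.2)
  spec <- statistic_spec("outdegree", "reciprocity")
  path <- coevol_path(numeric(0), matrix(0L, 0, 2),
                      matrix(rnorm(n, 0, 0.5), 1, n), t_total = 3)
  ll <- complete_log_likelihood(path, fix$y, fix$z, fix$X, pars, spec)
  expect_equal(ll, -0.5 * 3 +
                 increment_log_density(path$increments[1, ],
                                       influence_matrix(fix$y),
                                       fix$X, pars, 3),
               tolerance = 1e-12)
})

test_that("log-likelihood is stationary in lambda at k / T", {
  set.seed(42)
  fix <- make_fixture(6)
  spec <- statistic_spec("outdegree", "reciprocity")
  pars <- coevol_params(2, c(-0.5, 0.3), 0, 0.1, 0.2)
  sim <- simulate_coevolution(fix$y, fix$z, fix$X, pars, spec, 4)
  k <- sim$path$k
  skip_if(k == 0)
  lam_hat <- k / 4
  ll_at <- function(l) complete_log_likelihood(
    sim$path, sim$y0, sim$z0, fix$X,
    coevol_params(l, pars$theta, pars$gamma, pars$alpha, pars$sigma), spec)
  expect_gt(ll_at(lam_hat), ll_at(lam_hat * 1.05))
  expect_gt(ll_at(lam_hat), ll_at(lam_hat * 0.95))
  expect_equal(lambda_mle(60, 60), 1)
  expect_equal(lambda_mle(65, 60), 65 / 60)
  expect_warning(lambda_mle(0, 10), "degenerate")
})

test_that("closed-form gamma matches a weighted least-squares oracle", {
  set.seed(43)
  n <- 6
  fix <- make_fixture(n)
  X <- cbind(1, rnorm(n))
  spec <- statistic_spec("outdegree", "reciprocity")
  pars <- coevol_params(2, c(-0.5, 0.3), c(0.05, -0.02), 0.2, 0.3)
  paths <- replicate(3, simulate_coevolution(fix$y, fix$z, X, pars,
                                             spec, 2)$path,
                     simplify = FALSE)
  alpha <- 0.2
  gam <- mstep_gamma(paths, fix$y, fix$z, X, alpha)
  # oracle: stack (I - alpha W) dz / sqrt(dt) on sqrt(dt) X and run lm
  yy <- NULL; xx <- NULL
  for (p in paths) {
    y <- fix$y
    z <- fix$z
    bounds <- c(0, p$times, p$t_total)
    for (u in seq_len(p$k + 1)) {
      dt <- bounds[u + 1] - bounds[u]
      m <- diag(n) - alpha * influence_matrix(y)
      yy <- c(yy, as.vector(m %*% p$increments[u, ]) / sqrt(dt))
      xx <- rbind(xx, sqrt(dt) * X)
      if (u <= p$k) y <- toggle_edge(y, p$toggles[u, 1], p$toggles[u, 2])
    }
  }
  oracle <- unname(coef(lm(yy ~ xx - 1)))
  expect_equal(gam, oracle, tolerance = 1e-8)
  # R identical paths give the same estimate as R = 1
  expect_equal(mstep_gamma(rep(paths[1], 4), fix$y, fix$z, X, alpha),
               mstep_gamma(paths[1], fix$y, fix$z, X, alpha),
               tolerance = 1e-12)
})

test_that("gamma collapses to mean drift for alpha = 0, constant X", {
  set.seed(44)
  n <- 5
  fix <- make_fixture(n)
  spec <- statistic_spec("outdegree", "reciprocity")
  pars <- coevol_params(1, c(0, 0), 0.05, 0, 0.2)
  p <- simulate_coevolution(fix$y, fix$z, fix$X, pars, spec, 2)$path
  expect_equal(mstep_gamma(list(p), fix$y, fix$z, fix$X, 0),
               mean(colSums(p$increments)) / 2, tolerance = 1e-10)
})

test_that("closed forms are the exact argmax of the averaged likelihood", {
  set.seed(45)
  n <- 5
  fix <- make_fixture(n)
  spec <- statistic_spec("outdegree", "reciprocity")
  pars <- coevol_params(2, c(-0.5, 0.3), 0.02, 0.15, 0.3)
  paths <- replicate(2, simulate_coevolution(fix$y, fix$z, fix$X, pars,
                                             spec, 2)$path,
                     simplify = FALSE)
  alpha <- 0.15
  gam <- mstep_gamma(paths, fix$y, fix$z, fix$X, alpha)
  s2 <- mstep_sigma2(paths, fix$y, fix$z, fix$X, alpha, gam)
  avg_ll <- function(g, s) mean(vapply(paths, function(p)
    complete_log_likelihood(p, fix$y, fix$z, fix$X,
                            coevol_params(2, pars$theta, g, alpha, s), spec),
    numeric(1)))
  base <- avg_ll(gam, sqrt(s2))
  for (eps in c(-1e-3, 1e-3)) {
    expect_lte(avg_ll(gam + eps, sqrt(s2)), base + 1e-9)
    expect_lte(avg_ll(gam, sqrt(s2) + eps), base + 1e-9)
  }
  # one-interval special case: sigma2 = ||dz||^2 / (n dt) at alpha = gamma = 0
  p0 <- coevol_path(numeric(0), matrix(0L, 0, 2),
                    matrix(rnorm(n), 1, n), t_total = 2)
  expect_equal(mstep_sigma2(list(p0), fix$y, fix$z, fix$X, 0, 0),
               sum(p0$increments^2) / (n * 2), tolerance = 1e-12)
})

test_that("profiled objective matches the plugged-in log-likelihood at R = 1", {
  set.seed(46)
  n <- 5
  fix <- make_fixture(n)
  spec <- statistic_spec("outdegree", "reciprocity")
  pars <- coevol_params(2, c(-0.5, 0.3), 0.02, 0.15, 0.3)
  p <- simulate_coevolution(fix$y, fix$z, fix$X, pars, spec, 2)$path
  skip_if(p$k == 0)
  theta <- c(-0.4, 0.2); alpha <- 0.1
  gam <- mstep_gamma(list(p), fix$y, fix$z, fix$X, alpha)
  s2 <- mstep_sigma2(list(p), fix$y, fix$z, fix$X, alpha, gam)
  lam <- p$k / 2
  h <- profile_h(theta, alpha, list(p), fix$y, fix$z, fix$X, spec)
  ll <- complete_log_likelihood(p, fix$y, fix$z, fix$X,
                                coevol_params(lam, theta, gam, alpha,
                                              sqrt(s2)), spec)
  expect_equal(h, ll, tolerance = 1e-8)
})

test_that("profiled objective is invariant to a constant behavior shift", {
  set.seed(47)
  n <- 5
  fix <- make_fixture(n)
  spec <- statistic_spec("outdegree",
                         effect("similarity", range = 32, mean_sim = 0.5))
  pars <- coevol_params(2, c(-0.5, 0.3), 0.02, 0.15, 0.3)
  p <- simulate_coevolution(fix$y, fix$z, fix$X, pars, spec, 2)$path
  h1 <- profile_h(c(-0.4, 0.2), 0.1, list(p), fix$y, fix$z, fix$X, spec)
  h2 <- profile_h(c(-0.4, 0.2), 0.1, list(p), fix$y, fix$z + 5, fix$X, spec)
  expect_equal(h1, h2, tolerance = 1e-9)
})
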