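test_that("conditional event-count proposal respects parity and support", {
  set.seed(50)
  for (d in c(0, 3)) {
    ks <- replicate(2000, sample_event_count_conditional(1, 4, d))
    expect_true(all(ks >= d))
    expect_true(all((ks - d) %% 2 == 0))
  }
  # lambda*T -> 0 with d = 0 concentrates on k = 0
  expect_true(all(replicate(50,
    sample_event_count_conditional(1e-9, 1, 0)) == 0))
})

test_that("conditional count pmf matches direct renormalized summation", {
  set.seed(51)
  d <- 2; lambda <- 1.3; t_total <- 3
  ks <- replicate(40000, sample_event_count_conditional(lambda, t_total, d))
  # brute-force normalization oracle
  support <- seq(d, 60, by = 2)
  pk <- dpois(support, lambda * t_total)
  pk <- pk / sum(pk)
  emp <- vapply(support, function(k) mean(ks == k), numeric(1))
  expect_true(all(abs(emp - pk) < 4 * sqrt(pk * (1 - pk) / 40000) + 1e-4))
})

test_that("proposed paths hit both observed endpoints exactly", {
  set.seed(52)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    fix <- make_fixture(n, density = 0.4)
    spec <- statistic_spec("outdegree", "reciprocity")
    pars <- coevol_params(2, c(-0.8, 0.5), 0.01, 0.1, 0.3)
    sim <- simulate_coevolution(fix$y, fix$z, fix$X, pars, spec, 2)
    obs <- coevol_obs(sim$y0, sim$z0, sim$yT, sim$zT, 2)
    rec <- propose_hidden_path(obs, pars, spec, fix$X)
    rp <- replay_path(rec$path, obs$y0, obs$z0)
    expect_identical(rp$y, obs$yT)
    expect_equal(rp$z, obs$zT, tolerance = 1e-12)
    expect_equal(colSums(rec$path$increments), obs$zT - obs$z0,
                 tolerance = 1e-12)
    expect_gte(rec$path$k, obs$d)
    expect_equal((rec$path$k - obs$d) %% 2, 0)
    expect_true(is.finite(rec$log_q) && is.finite(rec$log_r))
  }
})

test_that("identical endpoints with a tiny rate give the empty path", {
  set.seed(53)
  n <- 5
  fix <- make_fixture(n)
  spec <- statistic_spec("outdegree", "reciprocity")
  pars <- coevol_params(1e-9, c(0, 0), 0, 0, 0.3)
  obs <- coevol_obs(fix$y, fix$z, fix$y, fix$z + 0.1, 2)
  rec <- propose_hidden_path(obs, pars, spec, fix$X)
  expect_equal(rec$path$k, 0)
  expect_equal(rec$log_r, 0)
  expect_equal(rec$path$increments[1, ], obs$zT - obs$z0)
})

test_that("the Metropolis-Hastings step is reproducible and well-formed", {
  set.seed(54)
  n <- 5
  fix <- make_fixture(n)
  spec <- statistic_spec("outdegree", "reciprocity")
  pars <- coevol_params(1.5, c(-0.8, 0.5), 0.01, 0.1, 0.3)
  sim <- simulate_coevolution(fix$y, fix$z, fix$X, pars, spec, 2)
  obs <- coevol_obs(sim$y0, sim$z0, sim$yT, sim$zT, 2)
  start <- propose_hidden_path(obs, pars, spec, fix$X)
  set.seed(99)
  a <- mh_step(start, obs, pars, spec, fix$X)
  set.seed(99)
  b <- mh_step(start, obs, pars, spec, fix$X)
  expect_identical(a$path, b$path)
  expect_identical(a$accepted, b$accepted)
})

test_that("every retained draw is a valid endpoint-exact path", {
  set.seed(55)
  n <- 6
  fix <- make_fixture(n, density = 0.4)
  spec <- statistic_spec("outdegree", "reciprocity")
  pars <- coevol_params(2, c(-0.8, 0.5), 0.01, 0.1, 0.3)
  sim <- simulate_coevolution(fix$y, fix$z, fix$X, pars, spec, 2)
  obs <- coevol_obs(sim$y0, sim$z0, sim$yT, sim$zT, 2)
  imp <- run_imputation(obs, pars, spec, fix$X, R = 30, burn_in = 20)
  expect_length(imp$paths, 30)
  for (p in imp$paths) {
    rp <- replay_path(p, obs$y0, obs$z0)
    expect_identical(rp$y, obs$yT)
    expect_equal(rp$z, obs$zT, tolerance = 1e-12)
    expect_gte(p$k, obs$d)
    expect_equal((p$k - obs$d) %% 2, 0)
  }
  expect_gte(imp$acceptance, 0)
  # R = 1 with no burn-in returns the state after a single MH decision
  one <- run_imputation(obs, pars, spec, fix$X, R = 1, burn_in = 0)
  expect_length(one$paths, 1)
})

test_that("sampler matches the enumerated conditional on a tiny instance", {
  # light version of the exactness check (the full-scale one lives in the
  # acceptance suite): d = 1, moderate chain
  set.seed(56)
  y0 <- enum_decode3(9)
  yT <- toggle_edge(y0, 1, 2)
  z0 <- c(20, 22, 24)
  zT <- z0 + c(0.3, -0.2, 0.4)
  obs <- coevol_obs(y0, z0, yT, zT, 2)
  pars <- coevol_params(1.5, c(-0.8, 0.6), 0, 0, 0.5)
  spec <- statistic_spec("outdegree", "reciprocity")
  X <- matrix(1, 3, 1)
  imp <- run_imputation(obs, pars, spec, X, R = 4000, burn_in = 200)
  pk <- enum_k_pmf3(y0, yT, 1.5, 2, -0.8, 0.6)
  emp <- vapply(0:30, function(k) mean(imp$k == k), numeric(1))
  expect_lt(0.5 * sum(abs(emp - pk)), 0.05)  # total variation distance
})
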