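# shared fixture builders (all generated in code, seeded by each test)

random_network <- function(n, density = 0.4) {
  y <- matrix(rbinom(n * n, 1L, density), n, n)
  diag(y) <- 0L
  y
}

# a small spec exercising every built-in effect
full_spec <- function(range = 10, mean_sim = 0.5) {
  statistic_spec("outdegree", "reciprocity", "transitive_triplets",
                 effect("same_attribute", column = 2),
                 effect("similarity", range = range, mean_sim = mean_sim))
}

# covariates: constant column + a categorical-ish column for same_attribute
random_covariates <- function(n) {
  cbind(const = rep(1, n), group = sample(1:2, n, replace = TRUE))
}

random_behavior <- function(n, mean = 22.9, sd = 2) rnorm(n, mean, sd)

# brute-force per-actor statistics, written independently of the registry
brute_stats <- function(y, z, X, i, range = 10, mean_sim = 0.5) {
  n <- nrow(y)
  outd <- sum(y[i, ])
  recip <- 0
  trans <- 0
  for (j in seq_len(n)) {
    if (j == i) next
    recip <- recip + y[i, j] * y[j, i]
    for (h in seq_len(n)) {
      if (h == i || h == j) next
      trans <- trans + y[i, j] * y[i, h] * y[h, j]
    }
  }
  same <- 0
  sim <- 0
  for (j in seq_len(n)) {
    if (j == i) next
    same <- same + y[i, j] * (X[i, 2] == X[j, 2])
    sim <- sim + y[i, j] * (1 - abs(z[i] - z[j]) / range - mean_sim)
  }
  unname(c(outd, recip, trans, same, sim))
}

# the paper-scale simulation design used in the acceptance tests
study_setup <- function() {
  fix <- make_fixture(n = 30, density = 0.3, behavior_mean = 22.9,
                      behavior_sd = 4.4, bounds = c(14, 46))
  list(fix = fix, spec = bmi_study_spec(), params = bmi_study_params(),
       t_total = 60)
}
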