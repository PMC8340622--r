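# Exact conditional distribution of the event count on a 3-actor instance,
# by enumeration over the 2^6 network states. Valid when alpha = 0 and
# gamma = 0 with purely structural effects (outdegree, reciprocity): the
# behavior factor then integrates to the same constant for every event
# count and toggle sequence, times integrate out, and
#   P(k | endpoints) ~ Poisson(k; lambda*T) * (Q^k)[y0 -> yT]
# with Q the one-event transition matrix. Built scalar-by-scalar,
# independently of the package's samplers.

enum_dyads3 <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))

enum_encode3 <- function(y) {
  bits <- vapply(seq_len(6), function(r) y[enum_dyads3[r, 1],
                                           enum_dyads3[r, 2]], numeric(1))
  sum(bits * 2^(0:5)) + 1
}

enum_decode3 <- function(s) {
  bits <- as.integer(intToBits(s - 1))[1:6]
  y <- matrix(0L, 3, 3)
  for (r in 1:6) y[enum_dyads3[r, 1], enum_dyads3[r, 2]] <- bits[r]
  y
}

enum_transition3 <- function(theta_out, theta_rec) {
  Q <- matrix(0, 64, 64)
  for (s in 1:64) {
    y <- enum_decode3(s)
    for (i in 1:3) {
      w <- numeric(0)
      js <- setdiff(1:3, i)
      for (j in js)
        w <- c(w, exp((2 * y[i, j] - 1) *
                        (theta_out + theta_rec * y[j, i])))
      p <- w / sum(w)
      for (a in seq_along(js)) {
        y2 <- y
        y2[i, js[a]] <- 1 - y2[i, js[a]]
        Q[s, enum_encode3(y2)] <- Q[s, enum_encode3(y2)] + p[a] / 3
      }
    }
  }
  Q
}

# exact pmf of k on its feasible support, truncated where Poisson mass dies
enum_k_pmf3 <- function(y0, yT, lambda, t_total, theta_out, theta_rec,
                        kmax = 30) {
  Q <- enum_transition3(theta_out, theta_rec)
  s0 <- enum_encode3(y0)
  sT <- enum_encode3(yT)
  pk <- numeric(kmax + 1)
  Pk <- diag(64)
  for (k in 0:kmax) {
    pk[k + 1] <- dpois(k, lambda * t_total) * Pk[s0, sT]
    Pk <- Pk %*% Q
  }
  pk / sum(pk)
}
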