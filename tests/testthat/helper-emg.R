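# Shared fixtures and independent oracles. Everything here is deliberately
# written with different primitives than the package code it checks.

# db2 scaling filter, hardcoded independently from standard tables.
DB2_REC_LO <- c(0.4829629131445341, 0.8365163037378079,
                0.2241438680420134, -0.1294095225512604)

# Dense analysis matrix of one circular (periodization) DWT level: rows are
# the even-shifted decomposition filters. Independent matrix-based oracle
# for the convolution-decimation code.
periodic_dwt_matrix <- function(n, rec_lo = DB2_REC_LO) {
  l <- length(rec_lo)
  dec_lo <- rev(rec_lo)
  dec_hi <- rev(rev(rec_lo) * (-1)^(seq_along(rec_lo) - 1))
  o <- n %/% 2
  a_lo <- matrix(0, o, n)
  a_hi <- matrix(0, o, n)
  for (i in seq_len(o)) {
    for (k in seq_len(l)) {
      col <- (2 * (i - 1) + k - 1) %% n + 1
      a_lo[i, col] <- a_lo[i, col] + dec_lo[k]
      a_hi[i, col] <- a_hi[i, col] + dec_hi[k]
    }
  }
  list(lo = a_lo, hi = a_hi)
}

# Euclidean projection onto {0 <= a <= C, sum(a * t) = 0} (t in {-1, +1})
# by bisection on the hyperplane multiplier.
project_dual_feasible <- function(a, t, c_penalty) {
  f <- function(lam) sum(t * pmin(pmax(a - lam * t, 0), c_penalty))
  lo <- -(max(abs(a)) + c_penalty + 1)
  hi <- -lo
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  pmin(pmax(a - ((lo + hi) / 2) * t, 0), c_penalty)
}

# Projected-gradient solver for the SVM dual on small problems:
# maximize sum(a) - 0.5 a' Q a  s.t.  0 <= a <= C, sum(a * t) = 0,
# with Q = (t t') * K. Independent oracle for the SMO trainer.
qp_oracle <- function(kmat, t, c_penalty, iters = 200000) {
  n <- length(t)
  q <- outer(t, t) * kmat
  obj <- function(a) sum(a) - 0.5 * as.numeric(t(a) %*% q %*% a)
  step <- 1 / max(sum(abs(q)), 1)
  a <- project_dual_feasible(rep(min(c_penalty / 2, 1e-3), n), t, c_penalty)
  last <- obj(a)
  for (i in seq_len(iters)) {
    a <- project_dual_feasible(a + step * (1 - as.numeric(q %*% a)), t,
                               c_penalty)
    if (i %% 1000 == 0) {
      cur <- obj(a)
      if (cur - last < 1e-12) break
      last <- cur
    }
  }
  list(alpha = a, objective = obj(a))
}

# Well-separated Gaussian blobs in d dimensions for classifier sanity checks.
make_blobs <- function(n_per_class, classes, d = 6, sep = 6, sd = 1,
                       seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(length(classes) * d, sd = sep), length(classes), d)
  x <- do.call(rbind, lapply(seq_along(classes), function(i) {
    matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d) +
      matrix(centers[i, ], n_per_class, d, byrow = TRUE)
  }))
  list(x = x, y = rep(classes, each = n_per_class))
}

# Small labeled synthetic dataset for pipeline tests: short trials so the
# suite stays fast.
tiny_dataset <- function(motions = c(1, 2, 5, 6), trials = 2, seed = 50,
                         snr_db = 15) {
  generate_dataset(motions, trials, base_seed = seed, snr_db = snr_db,
                   ramp_s = 0.3, hold_s = 0.8, rest_s = 0.3)
}
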