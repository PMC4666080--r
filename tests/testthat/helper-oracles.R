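# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / generic linear algebra so they never share code
# with the package's implementation paths.

# exhaustive enumeration of the five helix connectivity rules for an
# isolated duplex in local indexing (piece A = 0..n_bp-1, partner of local
# k is n_bp + k), mapped to 1-based strand indices (A = 1..n_bp, B
# antiparallel = n_bp+1..2*n_bp)
oracle_duplex_pairs <- function(n_bp) {
  to_strand <- function(l) ifelse(l < n_bp, l + 1L, 2L * n_bp - (l - n_bp))
  prs <- list()
  add <- function(i, j) {
    if (i >= 0 && j >= 0 && i < 2 * n_bp && j < 2 * n_bp && i != j) {
      s <- sort(c(to_strand(i), to_strand(j)))
      prs[[length(prs) + 1L]] <<- s
    }
  }
  for (k in 0:(n_bp - 1)) {
    for (d in 1:3) {
      if (k + d <= n_bp - 1) add(k, k + d)                 # piece A neighbors
      if (k + d <= n_bp - 1) add(n_bp + k, n_bp + k + d)   # piece B neighbors
    }
    add(k, k + n_bp)                                       # base pair
    add(k, k + n_bp + 1L)                                  # counterpart +1
    if (k + n_bp - 1L >= n_bp) add(k, k + n_bp - 1L)       # counterpart -1
  }
  unique(prs)
}

# numerical gradient of the total energy by central differences
oracle_num_gradient <- function(conf, ff, h = 1e-5) {
  G <- matrix(0, nrow(conf), 3)
  for (i in seq_len(nrow(conf))) {
    for (k in 1:3) {
      cp <- conf; cp[i, k] <- cp[i, k] + h
      cm <- conf; cm[i, k] <- cm[i, k] - h
      G[i, k] <- (total_forces(cp, ff)$energy -
                  total_forces(cm, ff)$energy) / (2 * h)
    }
  }
  G
}

# rigid-body bead-model hydrodynamics re-derived with base-R linear algebra
# at an arbitrary origin (Angstrom in, CGS out)
oracle_rigid_dt <- function(conf_A, origin_A = colMeans(conf_A),
                            sigma = 3.15, eta = 0.01, temp = 293) {
  kT <- 1.380649e-16 * temp
  X <- (conf_A - matrix(origin_A, nrow(conf_A), 3, byrow = TRUE)) * 1e-8
  sig <- sigma * 1e-8
  N <- nrow(X)
  mob0 <- 1 / (6 * pi * eta * sig)
  B <- matrix(0, 3 * N, 3 * N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) {
        blk <- mob0 * diag(3)
      } else {
        d <- X[i, ] - X[j, ]
        r <- sqrt(sum(d^2))
        rh <- d / r
        blk <- if (r >= 2 * sig) {
          sr <- sig / r
          mob0 * 0.75 * sr * ((1 + 2 / 3 * sr^2) * diag(3) +
                                (1 - 2 * sr^2) * outer(rh, rh))
        } else {
          mob0 * ((1 - 9 * r / (32 * sig)) * diag(3) +
                    3 * r / (32 * sig) * outer(rh, rh))
        }
      }
      B[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- blk
    }
  }
  Z <- solve(B)
  skew <- function(r) matrix(c(0, r[3], -r[2],
                               -r[3], 0, r[1],
                               r[2], -r[1], 0), 3, 3)
  Xtt <- matrix(0, 3, 3); Xrt <- matrix(0, 3, 3); Xrr <- matrix(0, 3, 3)
  for (i in seq_len(N)) {
    Ai <- skew(X[i, ])
    for (j in seq_len(N)) {
      Zij <- Z[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
      Aj <- skew(X[j, ])
      Xtt <- Xtt + Zij
      Xrt <- Xrt + Ai %*% Zij
      Xrr <- Xrr - Ai %*% Zij %*% Aj
    }
  }
  Xrr <- Xrr + N * 8 * pi * eta * sig^3 * diag(3)
  R6 <- rbind(cbind(Xtt, t(Xrt)), cbind(Xrt, Xrr))
  R6 <- (R6 + t(R6)) / 2
  D6 <- kT * solve(R6)
  list(D_t = sum(diag(D6[1:3, 1:3])) / 3,
       D_rr = D6[4:6, 4:6])
}

# Boltzmann CDF of a single 3-D Hooke spring length, by quadrature of
# p(l) ~ l^2 exp(-H (l - le)^2 / 2)
oracle_spring_cdf <- function(le, H, lmax = le + 8 / sqrt(H), n = 20000) {
  l <- seq(1e-6, lmax, length.out = n)
  p <- l^2 * exp(-0.5 * H * (l - le)^2)
  cdf <- cumsum(p)
  cdf <- cdf / cdf[n]
  stats::approxfun(l, cdf, yleft = 0, yright = 1)
}

# tiny deterministic pseudo-random conformation helper
random_cloud <- function(n, spread = 20, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = spread), n, 3)
}
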