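p <- model_parameters()

free_bead_ff <- function() {
  net <- structure(list(springs = data.frame(
    i = integer(), j = integer(), kind = character(), l_e = numeric(),
    H = numeric()), n_beads = 1L), class = "spring_network")
  forcefield(net, p)
}

two_bead_ff <- function(l_e = p$l_e1) {
  net <- build_spring_network(secondary_structure(2, NULL), p)
  net$springs$l_e <- l_e
  forcefield(net, p)
}

test_that("the stability criterion rejects oversized time steps", {
  expect_error(bd_config(n_steps = 10, dt = 1), "unstable")
  cfg <- bd_config(n_steps = 10, dt = 0.1)
  expect_s3_class(cfg, "bd_config")
})

test_that("free single-bead displacements have variance 2 D0 dt", {
  ff <- free_bead_ff()
  tr <- run_bd(matrix(0, 1, 3), ff,
               bd_config(n_steps = 1e5, snapshot_every = 1, seed = 10))
  steps <- apply(tr$coords[1, , ], 1, diff) # per-coordinate increments
  v <- mean(apply(steps, 2, stats::var))
  expect_equal(v, 2 * p$D0 * 0.1, tolerance = 0.02)
})

test_that("MSD of a free bead recovers Stokes-Einstein diffusion", {
  ff <- free_bead_ff()
  tr <- run_bd(matrix(0, 1, 3), ff,
               bd_config(n_steps = 1e6, snapshot_every = 10, seed = 11))
  est <- msd_diffusion(tr, fit_min_ps = 10, fit_max_frac = 0.01)
  expect_equal(est$D_t, p$D0_cgs, tolerance = 0.03)
  expect_false(est$sublinear)
})

test_that("zeroed noise moves a stretched spring downhill only", {
  ff <- two_bead_ff()
  conf <- rbind(c(0, 0, 0), c(1.5 * p$l_e1, 0, 0))
  out <- bd_step(conf, ff, noise_scale = 0)
  expect_gt(out[1, 1], 0)
  expect_lt(out[2, 1], 1.5 * p$l_e1)
  expect_equal(out[, 2:3], conf[, 2:3])
})

test_that("trajectories are reproducible for a fixed seed", {
  ss <- parse_dot_bracket("((((....))))")
  net <- assign_equilibrium_lengths(build_spring_network(ss, p),
                                    ideal_conformation(ss, p), p)
  ff <- forcefield(net, p)
  x0 <- assemble_initial_conformation(ss, p, seed = 2)
  t1 <- run_bd(x0, ff, bd_config(n_steps = 2000, snapshot_every = 100,
                                 seed = 12))
  t2 <- run_bd(x0, ff, bd_config(n_steps = 2000, snapshot_every = 100,
                                 seed = 12))
  expect_identical(t1$coords, t2$coords)
  t3 <- run_bd(x0, ff, bd_config(n_steps = 2000, snapshot_every = 100,
                                 seed = 13))
  expect_false(identical(t1$coords, t3$coords))
})

test_that("zero production steps yield only the initial conformation", {
  ff <- two_bead_ff()
  conf <- rbind(c(0, 0, 0), c(p$l_e1, 0, 0))
  tr <- run_bd(conf, ff, bd_config(n_steps = 0))
  expect_equal(dim(tr$coords), c(2, 3, 1))
  expect_equal(tr$coords[, , 1], conf)
})

test_that("overstretched springs abort the run with a diagnostic", {
  ff <- two_bead_ff()
  conf <- rbind(c(0, 0, 0), c(4 * p$l_e1, 0, 0))
  expect_error(run_bd(conf, ff, bd_config(n_steps = 100, seed = 1)),
               "instability")
})

test_that("BD-noHI samples the Boltzmann spring-length distribution", {
  # single spring: p(l) ~ l^2 exp(-H (l - le)^2 / 2); KS vs quadrature
  ff <- two_bead_ff()
  thin <- 50 # ~17 spring relaxation times between samples
  tr <- run_bd(rbind(c(0, 0, 0), c(p$l_e1, 0, 0)), ff,
               bd_config(n_steps = 1e5 * thin, snapshot_every = thin,
                         equilibration_steps = 5000, seed = 14))
  l <- sqrt(apply((tr$coords[1, , ] - tr$coords[2, , ])^2, 2, sum))
  cdf <- oracle_spring_cdf(p$l_e1, p$H)
  ks <- max(abs(seq_along(l) / length(l) - cdf(sort(l))))
  expect_lt(ks, 0.02)
  # second moment against quadrature
  lq <- seq(1e-3, p$l_e1 + 8 / sqrt(p$H), length.out = 20000)
  w <- lq^2 * exp(-0.5 * p$H * (lq - p$l_e1)^2)
  expect_equal(mean(l^2), sum(lq^2 * w) / sum(w), tolerance = 0.03)
})

test_that("RPY mobility has Stokes diagonal, Oseen far field, SPD always", {
  m1 <- rpy_mobility(matrix(0, 1, 3), p)
  expect_equal(m1, diag(3) * p$D0_cgs, tolerance = 1e-12)

  r <- 1000 * p$sigma
  m2 <- rpy_mobility(rbind(c(0, 0, 0), c(r, 0, 0)), p)
  oseen <- p$kBT / (8 * pi * p$eta_s * r * 1e-8) *
    (diag(3) + outer(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(m2[1:3, 4:6], oseen, tolerance = 1e-3)

  for (seed in 1:3) {
    x <- random_cloud(20, spread = 8, seed = seed) # includes overlaps
    M <- rpy_mobility(x, p)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("HI and free-draining runs agree on equilibrium averages", {
  ss <- parse_dot_bracket("(((....)))")
  net <- assign_equilibrium_lengths(build_spring_network(ss, p),
                                    ideal_conformation(ss, p), p)
  ff <- forcefield(net, p)
  x0 <- assemble_initial_conformation(ss, p, seed = 5)
  nofd <- run_bd(x0, ff, bd_config(n_steps = 3e5, snapshot_every = 500,
                                   equilibration_steps = 2e4, seed = 20))
  hi <- run_bd(x0, ff, bd_config(n_steps = 6e4, snapshot_every = 100,
                                 equilibration_steps = 4e3, hi = TRUE,
                                 seed = 21))
  b1 <- block_stats(nofd$rg^2)
  b2 <- block_stats(hi$rg^2)
  expect_lt(abs(b1$mean - b2$mean),
            2.5 * sqrt(b1$sd^2 / 5 + b2$sd^2 / 5) + 0.02 * b1$mean)
})

test_that("HI displacements carry the RPY cross-correlation", {
  # repeated single steps from a frozen two-bead configuration: the
  # y-displacement covariance between beads must equal 2 D12_yy dt
  net <- structure(list(springs = data.frame(
    i = integer(), j = integer(), kind = character(), l_e = numeric(),
    H = numeric()), n_beads = 2L), class = "spring_network")
  ff2 <- forcefield(net, p)
  ff2$conn[] <- 1L # disable the LJ pair: pure diffusion
  x0 <- rbind(c(0, 0, 0), c(2.5 * p$sigma, 0, 0))
  n_rep <- 2000
  d1 <- numeric(n_rep); d2 <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    out <- bd_step(x0, ff2, hi = TRUE, seed = 5000 + k)
    d1[k] <- out[1, 2]; d2[k] <- out[2, 2]
  }
  D <- rpy_mobility(x0, p) * 1e4 # A^2/ps
  expect_equal(stats::cov(d1, d2), 2 * D[2, 5] * 0.1,
               tolerance = 0.25)
  expect_equal(stats::var(d1), 2 * p$D0 * 0.1, tolerance = 0.15)
})

test_that("network spring-length fluctuations are ~5 percent of l_e", {
  # in the duplex network each bead is held by several springs, so the
  # per-spring length fluctuation drops below the isolated-spring value
  # sqrt(kBT/H) = 7.1 percent of l_e
  ss <- secondary_structure(22, data.frame(a_start = 1, a_end = 11,
                                           b_start = 12, b_end = 22))
  net <- assign_equilibrium_lengths(build_spring_network(ss, p),
                                    ideal_conformation(ss, p), p)
  ff <- forcefield(net, p)
  tr <- run_bd(ideal_conformation(ss, p), ff,
               bd_config(n_steps = 3e5, snapshot_every = 2000,
                         equilibration_steps = 2e4, seed = 33))
  bb <- net$springs$kind == "backbone"
  l <- vapply(seq_len(dim(tr$coords)[3]), function(s) {
    X <- tr$coords[, , s]
    d <- X[net$springs$i[bb], ] - X[net$springs$j[bb], ]
    sqrt(rowSums(d^2))
  }, numeric(sum(bb)))
  rel <- stats::sd(as.numeric(l)) / mean(as.numeric(l))
  expect_gt(rel, 0.04)
  expect_lt(rel, 0.065)
})
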