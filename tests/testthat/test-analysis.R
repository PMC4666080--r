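test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(0, 5, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(6.3, 0, 0))), 3.15)
  # collinear beads at spacing a: Rg = a sqrt((N^2 - 1) / 12)
  a <- 6.3; N <- 12
  rod <- cbind((0:(N - 1)) * a, 0, 0)
  expect_equal(radius_of_gyration(rod), a * sqrt((N^2 - 1) / 12),
               tolerance = 1e-12)
  expect_equal(a * sqrt((N^2 - 1) / 12), 21.748, tolerance = 1e-3)
})

test_that("Rg is invariant under rigid motions", {
  x <- random_cloud(20, seed = 30)
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  expect_equal(radius_of_gyration(x %*% t(R) +
                                    matrix(c(3, 4, 5), 20, 3, byrow = TRUE)),
               radius_of_gyration(x), tolerance = 1e-12)
})

test_that("block statistics split series into contiguous fifths", {
  b <- block_stats(1:10, 5)
  expect_equal(b$block_means, c(1.5, 3.5, 5.5, 7.5, 9.5))
  expect_equal(b$mean, 5.5)
  expect_equal(block_stats(rep(3.3, 25))$sd, 0)
  # permutation within blocks leaves the result unchanged
  x <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  expect_equal(block_stats(x, 5)$block_means, c(1.5, 3.5, 5.5, 7.5, 9.5))
  expect_error(block_stats(1:3, 5), "shorter than")
})

test_that("Svedberg coefficient follows s = Dt M (1 - v rho) / RT", {
  s <- svedberg(6.2e-7, 40000, 0.53, 1, 293)
  expect_equal(s, 4.785, tolerance = 1e-3)
  expect_equal(round(s), 5)
  expect_warning(s0 <- svedberg(6.2e-7, 40000, 1, 1, 293), "floats")
  expect_equal(s0, 0)
  expect_equal(svedberg(2 * 6.2e-7, 40000, 0.53, 1, 293), 2 * s,
               tolerance = 1e-12)
})

synthetic_arms <- function() {
  arm_definition(arm1 = 1:4, arm2 = 5:8, hinge1 = 1, tip1 = 4,
                 hinge2 = 5, tip2 = 8)
}

test_that("inter-arm angle reads principal-axis geometry", {
  arms <- synthetic_arms()
  spacing <- 6.3
  # two collinear stems pointing oppositely from a shared hinge
  conf <- rbind(cbind(-(0:3) * spacing, 0, 0), cbind((0:3) * spacing, 0.01, 0))
  expect_equal(inter_arm_angle(conf, arms), 180, tolerance = 0.1)
  # perpendicular stems
  conf2 <- rbind(cbind((0:3) * spacing, 0, 0), cbind(0.01, (0:3) * spacing, 0))
  expect_equal(inter_arm_angle(conf2, arms), 90, tolerance = 0.1)
  # rotation invariance
  th <- 1.3
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  expect_equal(inter_arm_angle(conf2 %*% t(R), arms),
               inter_arm_angle(conf2, arms), tolerance = 1e-9)
  # degenerate stem
  conf3 <- conf2; conf3[1:4, ] <- 0
  expect_error(inter_arm_angle(conf3, arms), "degenerate")
})

test_that("angle histograms are normalized frequency tables", {
  arms <- synthetic_arms()
  conf <- rbind(cbind((0:3) * 6.3, 0, 0), cbind(0.01, (0:3) * 6.3, 0))
  coords <- array(rep(conf, 120), c(8, 3, 120))
  traj <- structure(list(coords = coords, times = 1:120,
                         energy = rep(0, 120), rg = rep(NA_real_, 120),
                         final = conf, config = bd_config(n_steps = 120)),
                    class = "rnabd_traj")
  h <- angle_histogram(traj, arms)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-12)
  expect_equal(sum(h$count > 0), 1) # delta-distributed: single occupied bin
  occupied <- h[h$count > 0, ]
  expect_true(occupied$bin_lo <= 90 && occupied$bin_hi >= 90)
  expect_equal(nrow(h), 18)
})

test_that("MSD fitting recovers a known diffusion coefficient", {
  D <- 5e-7 # cm^2/s
  dt_snap <- 10 # ps
  S <- 1e4
  set.seed(41)
  com <- apply(matrix(rnorm(3 * S, sd = sqrt(2 * D * 1e4 * dt_snap)), S, 3),
               2, cumsum)
  traj <- structure(list(coords = array(t(com), c(1, 3, S)),
                         times = (1:S) * dt_snap,
                         energy = rep(0, S), rg = rep(0, S),
                         final = matrix(com[S, ], 1),
                         config = bd_config(n_steps = S)),
                    class = "rnabd_traj")
  est <- msd_diffusion(traj, fit_min_ps = 20, fit_max_frac = 0.01)
  expect_equal(est$D_t, D, tolerance = 0.05)
  # static trajectory
  traj0 <- traj
  traj0$coords[] <- 1
  expect_equal(msd_diffusion(traj0)$D_t, 0)
})

test_that("angle statistics are invariant to snapshot order reversal", {
  arms <- synthetic_arms()
  set.seed(51)
  coords <- array(rnorm(8 * 3 * 40, sd = 5), c(8, 3, 40))
  traj <- structure(list(coords = coords, times = 1:40,
                         energy = rep(0, 40), rg = rep(NA_real_, 40),
                         final = coords[, , 40],
                         config = bd_config(n_steps = 40)),
                    class = "rnabd_traj")
  rev_traj <- traj
  rev_traj$coords <- coords[, , 40:1]
  expect_equal(sort(angle_trace(traj, arms)),
               sort(angle_trace(rev_traj, arms)))
  expect_equal(mean(angle_trace(traj, arms)),
               mean(angle_trace(rev_traj, arms)))
})
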