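p <- model_parameters()

test_that("a single bead recovers the Stokes closed forms exactly", {
  h <- rigid_body_hydro(matrix(0, 1, 3), p)
  D_t_stokes <- p$kBT / (6 * pi * p$eta_s * p$sigma * 1e-8)
  D_r_stokes <- p$kBT / (8 * pi * p$eta_s * (p$sigma * 1e-8)^3)
  expect_equal(h$D_t, D_t_stokes, tolerance = 1e-12)
  expect_equal(h$D_r, D_r_stokes, tolerance = 1e-12)
  expect_equal(h$tau_h, 1 / (6 * D_r_stokes) * 1e9, tolerance = 1e-12)
  expect_equal(h$R_g, 0)
})

test_that("rigid-body treatment matches a generic linear-algebra oracle", {
  # two touching beads
  x2 <- rbind(c(0, 0, 0), c(2 * p$sigma, 0, 0))
  h2 <- rigid_body_hydro(x2, p)
  o2 <- oracle_rigid_dt(x2, origin_A = h2$origin)
  expect_equal(h2$D_t, o2$D_t, tolerance = 1e-10)
  expect_equal(h2$D_rr, o2$D_rr, tolerance = 1e-9)
  # irregular cloud, including overlapping beads
  x <- random_cloud(9, spread = 5, seed = 4)
  h <- rigid_body_hydro(x, p)
  o <- oracle_rigid_dt(x, origin_A = h$origin)
  expect_equal(h$D_t, o$D_t, tolerance = 1e-10)
})

test_that("the reported origin is the center of diffusion (minimal D_t)", {
  x <- random_cloud(14, spread = 12, seed = 8)
  h <- rigid_body_hydro(x, p)
  set.seed(15)
  for (k in 1:10) {
    other <- oracle_rigid_dt(x, origin_A = h$origin + rnorm(3, sd = 8))
    expect_gte(other$D_t, h$D_t)
  }
})

test_that("D_rr is origin independent and D_t/tau_h rotation invariant", {
  x <- random_cloud(10, spread = 10, seed = 21)
  h0 <- rigid_body_hydro(x, p)
  h1 <- rigid_body_hydro(x + matrix(c(100, -50, 30), 10, 3, byrow = TRUE), p)
  expect_equal(h0$D_rr, h1$D_rr, tolerance = 1e-9)
  expect_equal(h0$tau_h, h1$tau_h, tolerance = 1e-9)
  expect_equal(h0$D_t, h1$D_t, tolerance = 1e-9)

  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  h2 <- rigid_body_hydro(x %*% t(R), p)
  expect_equal(h2$D_t, h0$D_t, tolerance = 1e-9)
  expect_equal(sort(eigen(h2$D_rr, symmetric = TRUE)$values),
               sort(eigen(h0$D_rr, symmetric = TRUE)$values),
               tolerance = 1e-9)
  expect_equal(h2$tau_h, h0$tau_h, tolerance = 1e-9)
})

test_that("Kirkwood approximation tracks the full treatment on tRNA", {
  # Kirkwood preaverages the Oseen coupling and ignores translation-
  # rotation coupling; measured against the center-of-diffusion D_t it
  # overestimates by ~5 % on the open fixture build and up to ~9 % on
  # compact equilibrium snapshots
  fx <- load_fixture("trna_phe")
  x <- ideal_conformation(fx$ss, p)
  full <- rigid_body_hydro(x, p)$D_t
  kirk <- kirkwood_dt(x, p)
  expect_gt(kirk, full) # preaveraging overestimates mobility
  expect_lt(abs(kirk - full) / full, 0.10)
  ref <- ideal_conformation(fx$ss, p)
  net <- assign_equilibrium_lengths(build_spring_network(fx$ss, p), ref, p)
  ff <- forcefield(net, p)
  xr <- run_bd(assemble_initial_conformation(fx$ss, p, seed = 1), ff,
               bd_config(n_steps = 0, equilibration_steps = 3e5,
                         seed = 9))$final
  fullr <- rigid_body_hydro(xr, p)$D_t
  expect_lt(abs(kirkwood_dt(xr, p) - fullr) / fullr, 0.10)
})

test_that("coincident beads are reported as singular", {
  x <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(rigid_body_hydro(x, p), "coincident")
})

test_that("ensemble properties over identical conformations collapse", {
  x <- random_cloud(8, spread = 6, seed = 2)
  coords <- array(rep(x, 30), c(8, 3, 30))
  traj <- structure(list(coords = coords, times = 1:30,
                         energy = rep(0, 30), rg = rep(NA_real_, 30),
                         final = x,
                         config = bd_config(n_steps = 30)),
                    class = "rnabd_traj")
  pr <- ensemble_properties(traj, p)
  single <- rigid_body_hydro(x, p)
  expect_equal(pr$D_t, single$D_t, tolerance = 1e-12)
  expect_equal(pr$tau_h, single$tau_h, tolerance = 1e-12)
  expect_equal(pr$R_g, single$R_g, tolerance = 1e-12)
  expect_equal(pr$D_t_sd, 0)
  expect_equal(pr$tau_h_sd, 0)
})

test_that("insufficient sampling is refused", {
  x <- random_cloud(5, spread = 6, seed = 3)
  coords <- array(rep(x, 12), c(5, 3, 12))
  traj <- structure(list(coords = coords, times = 1:12,
                         energy = rep(0, 12), rg = rep(NA_real_, 12),
                         final = x, config = bd_config(n_steps = 12)),
                    class = "rnabd_traj")
  expect_error(ensemble_properties(traj, p), "insufficient sampling")
})
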