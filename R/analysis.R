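#' Radius of gyration of a conformation
#'
#' Root-mean-square bead distance from the center of mass (equal-mass
#' beads): `sqrt(sum |r_i - r_cm|^2 / N)`.
#'
#' @param conf N x 3 coordinate matrix (Angstrom).
#' @return Rg in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(6.3, 0, 0))) # 3.15
#' @export
radius_of_gyration <- function(conf) {
  stopifnot(is.matrix(conf), ncol(conf) == 3, nrow(conf) >= 1)
  rg_of(conf)
}

#' Translational diffusion coefficient from center-of-mass MSD
#'
#' Einstein relation `<d^2> = 6 D_t dt`: computes the center-of-mass mean
#' squared displacement over a set of lag times and fits `<d^2>` against
#' `6 * lag` through the origin, weighting each lag by its number of
#' independent displacement pairs. Physically meaningful for trajectories
#' run with hydrodynamic interaction; on a free-draining trajectory it
#' recovers the free-draining mobility, not the solution value.
#'
#' @param traj an `rnabd_traj`.
#' @param fit_min_ps shortest lag included in the fit (ps); the default
#'   1000 ps (1 ns) skips short-time intramolecular transients.
#' @param fit_max_frac longest lag as a fraction of the trajectory length.
#' @param n_lags number of (approximately evenly spaced) lags evaluated.
#' @return List with `D_t` (cm^2/s), `msd` data frame (`lag_ps`, `msd_A2`,
#'   `n_pairs`), `r_squared` of the fit, and `sublinear` flag (TRUE when
#'   `r_squared < 0.9`, with a warning).
#' @export
msd_diffusion <- function(traj, fit_min_ps = 1000, fit_max_frac = 0.1,
                          n_lags = 40) {
  stopifnot(inherits(traj, "rnabd_traj"))
  S <- dim(traj$coords)[3]
  if (S < 10) stop("too few snapshots for an MSD fit")
  com <- t(apply(traj$coords, 3, colMeans))
  dt_snap <- diff(traj$times[1:2])
  max_lag <- max(2L, floor(S * fit_max_frac))
  min_lag <- max(1L, ceiling(fit_min_ps / dt_snap))
  if (min_lag >= max_lag) min_lag <- max(1L, max_lag %/% 4L)
  lags <- unique(round(seq(min_lag, max_lag, length.out = n_lags)))
  msd <- vapply(lags, function(L) {
    d <- com[(1 + L):S, , drop = FALSE] - com[1:(S - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  npairs <- S - lags
  if (all(msd == 0)) {
    return(list(D_t = 0,
                msd = data.frame(lag_ps = lags * dt_snap, msd_A2 = msd,
                                 n_pairs = npairs),
                r_squared = 1, sublinear = FALSE))
  }
  x <- 6 * lags * dt_snap # ps
  w <- npairs / lags^2 # ~ inverse variance of each MSD estimate
  slope <- sum(w * msd * x) / sum(w * x^2) # through-origin weighted fit
  ss_res <- sum(w * (msd - slope * x)^2)
  ss_tot <- sum(w * (msd - stats::weighted.mean(msd, w))^2)
  r2 <- 1 - ss_res / ss_tot
  sublinear <- is.finite(r2) && r2 < 0.9
  if (sublinear)
    warning("center-of-mass MSD is sublinear over the fit window (R^2 = ",
            format(r2, digits = 3), ")")
  list(D_t = slope * 1e-4, # A^2/ps -> cm^2/s
       msd = data.frame(lag_ps = lags * dt_snap, msd_A2 = msd,
                        n_pairs = npairs),
       r_squared = r2, sublinear = sublinear)
}

#' Define the two arms for inter-arm angle analysis
#'
#' Each arm is the ordered bead-index list of one stem (both strands of the
#' duplex), with separate hinge-proximal and tip bead sets fixing the axis
#' orientation.
#'
#' @param arm1,arm2 integer vectors of bead indices (>= 3 each, disjoint).
#' @param hinge1,tip1,hinge2,tip2 bead indices of the hinge-proximal and
#'   tip ends of each arm (subsets of the arm).
#' @return An `arm_definition` object.
#' @export
arm_definition <- function(arm1, arm2, hinge1, tip1, hinge2, tip2) {
  stopifnot(length(arm1) >= 3, length(arm2) >= 3,
            !any(arm1 %in% arm2),
            all(hinge1 %in% arm1), all(tip1 %in% arm1),
            all(hinge2 %in% arm2), all(tip2 %in% arm2))
  structure(list(arm1 = arm1, arm2 = arm2, hinge1 = hinge1, tip1 = tip1,
                 hinge2 = hinge2, tip2 = tip2), class = "arm_definition")
}

arm_axis <- function(conf, beads, hinge, tip) {
  X <- conf[beads, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 1)
  if (sv$d[1] < 1e-8)
    stop("degenerate stem: zero-variance bead coordinates")
  v <- sv$v[, 1]
  ref <- colMeans(conf[tip, , drop = FALSE]) -
    colMeans(conf[hinge, , drop = FALSE])
  if (sum(v * ref) < 0) v <- -v
  v
}

#' Inter-arm angle of one conformation
#'
#' Each arm vector is the principal axis (largest-variance direction) of
#' its stem's bead coordinates, oriented hinge to tip; the angle is the
#' arccos of the unit-vector dot product, in `[0, 180]` degrees. The
#' principal-axis estimator is robust to spring-length fluctuation, unlike
#' an endpoint difference.
#'
#' @param conf N x 3 coordinate matrix.
#' @param arms an [arm_definition()].
#' @return Angle in degrees.
#' @export
inter_arm_angle <- function(conf, arms) {
  stopifnot(inherits(arms, "arm_definition"))
  v1 <- arm_axis(conf, arms$arm1, arms$hinge1, arms$tip1)
  v2 <- arm_axis(conf, arms$arm2, arms$hinge2, arms$tip2)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Inter-arm angle trace and histogram over a trajectory
#'
#' @param traj an `rnabd_traj`.
#' @param arms an [arm_definition()].
#' @param bin_width histogram bin width (degrees; bins span `[0, 180]`).
#' @return `angle_trace()` returns a numeric vector of angles (degrees) per
#'   snapshot; `angle_histogram()` returns a data frame with `bin_lo`,
#'   `bin_hi`, `count`, `frequency` (frequencies sum to 1).
#' @export
angle_trace <- function(traj, arms) {
  vapply(seq_len(dim(traj$coords)[3]),
         function(s) inter_arm_angle(traj$coords[, , s], arms), numeric(1))
}

#' @rdname angle_trace
#' @export
angle_histogram <- function(traj, arms, bin_width = 10) {
  theta <- angle_trace(traj, arms)
  breaks <- seq(0, 180, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  counts <- table(cut(theta, breaks, include.lowest = TRUE, right = FALSE))
  # fold theta == 180 into the last bin
  counts[length(counts)] <- counts[length(counts)] + sum(theta == 180)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = as.integer(counts),
             frequency = as.numeric(counts) / length(theta))
}

#' Svedberg sedimentation coefficient
#'
#' `s = D_t M (1 - v_bar rho) / (R T)`, reported in Svedberg units
#' (1 S = 1e-13 s). A buoyant-density product `v_bar * rho >= 1` yields a
#' non-positive value with a flotation warning.
#'
#' @param D_t translational diffusion coefficient (cm^2/s).
#' @param M molar mass (Da = g/mol).
#' @param v_bar partial specific volume (cm^3/g).
#' @param rho solvent density (g/cm^3).
#' @param temperature absolute temperature (K).
#' @return Sedimentation coefficient in S.
#' @examples
#' svedberg(6.2e-7, 40000, 0.53, 1, 293) # ~4.8 S
#' @export
svedberg <- function(D_t, M, v_bar, rho, temperature = 293) {
  stopifnot(D_t > 0, M > 0, v_bar > 0, rho > 0, temperature > 0)
  buoy <- 1 - v_bar * rho
  if (buoy <= 0)
    warning("v_bar * rho >= 1: the particle floats (non-positive s)")
  D_t * M * buoy / (.Rgas * temperature) * 1e13
}

#' Block-average statistics of a series
#'
#' Splits a per-snapshot series into `n_blocks` contiguous, near-equal
#' blocks; reports the mean of the block means and their standard
#' deviation.
#'
#' @param values numeric series (length >= `n_blocks`).
#' @param n_blocks number of blocks (default 5).
#' @return List with `mean`, `sd`, and `block_means`.
#' @examples
#' block_stats(1:10)$mean # 5.5
#' @export
block_stats <- function(values, n_blocks = 5) {
  n <- length(values)
  if (n < n_blocks)
    stop("series length ", n, " is shorter than n_blocks = ", n_blocks)
  id <- ceiling(seq_along(values) / (n / n_blocks))
  id[id > n_blocks] <- n_blocks
  bm <- as.numeric(tapply(values, id, mean))
  list(mean = mean(bm), sd = stats::sd(bm), block_means = bm)
}
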