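// Core numerics: pairwise forces, Ermak-McCammon propagation (free-draining
// and RPY hydrodynamic interaction), rigid-body bead-model hydrodynamics,
// and a capped-step energy minimizer used by the conformation builder.
//
// Internal units on the simulation side: Angstrom, picosecond, kBT == 1.
// The rigid-body routine works in CGS (cm, s, erg) because its outputs are
// reported in cm^2/s and s^-1.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forces and energy for the bead-spring + excluded-volume model.
// springs: S x 4 matrix, columns (i, j, l_e, H) with 0-based i < j.
// conn: N x N 0/1 matrix, 1 where a spring joins the pair (LJ excluded).
// Returns total energy; fills F (N x 3) and the component energies.
// maxRatio reports max(l / l_e) over springs (instability monitor).
static double eval_forces(const arma::mat &X, const arma::mat &springs,
                          const arma::umat &conn, double eps, double sigLJ,
                          double cutoff2, arma::mat &F, double &eSpring,
                          double &eLJ, double &maxRatio) {
  const arma::uword N = X.n_rows;
  F.zeros(N, 3);
  eSpring = 0.0;
  eLJ = 0.0;
  maxRatio = 0.0;
  const double sig2 = sigLJ * sigLJ;

  // column-major raw views: coordinate k of bead i is x[k * N + i]
  const double *x = X.memptr();
  double *f = F.memptr();
  const double *xx = x, *xy = x + N, *xz = x + 2 * N;
  double *fx = f, *fy = f + N, *fz = f + 2 * N;
  const arma::uword *cn = conn.memptr(); // N x N, column-major

  const arma::uword S = springs.n_rows;
  const double *si = springs.memptr();
  const double *sj = si + S, *sle = si + 2 * S, *sH = si + 3 * S;
  for (arma::uword s = 0; s < S; ++s) {
    const arma::uword i = (arma::uword)si[s];
    const arma::uword j = (arma::uword)sj[s];
    const double le = sle[s], H = sH[s];
    const double dx = xx[i] - xx[j];
    const double dy = xy[i] - xy[j];
    const double dz = xz[i] - xz[j];
    const double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (l < 1e-10)
      stop("coincident beads on spring (%d, %d)", (int)i + 1, (int)j + 1);
    const double ratio = l / le;
    if (ratio > maxRatio) maxRatio = ratio;
    const double dl = l - le;
    eSpring += 0.5 * H * dl * dl;
    const double fmag = -H * dl / l; // along (xi - xj), applied to i
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }

  for (arma::uword i = 0; i + 1 < N; ++i) {
    const double xi = xx[i], yi = xy[i], zi = xz[i];
    double fxi = 0, fyi = 0, fzi = 0;
    const arma::uword *ci = cn + i * N; // column i of the symmetric mask
    for (arma::uword j = i + 1; j < N; ++j) {
      if (ci[j]) continue;
      const double dx = xi - xx[j];
      const double dy = yi - xy[j];
      const double dz = zi - xz[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12)
        stop("coincident beads on nonbonded pair (%d, %d)", (int)i + 1,
             (int)j + 1);
      if (cutoff2 > 0.0 && r2 > cutoff2) continue;
      const double inv_r2 = 1.0 / r2;
      const double s2 = sig2 * inv_r2;
      const double s6 = s2 * s2 * s2;
      const double s12 = s6 * s6;
      eLJ += 4.0 * eps * (s12 - s6);
      const double fscal = 24.0 * eps * (2.0 * s12 - s6) * inv_r2;
      fxi += fscal * dx; fyi += fscal * dy; fzi += fscal * dz;
      fx[j] -= fscal * dx; fy[j] -= fscal * dy; fz[j] -= fscal * dz;
    }
    fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
  }
  return eSpring + eLJ;
}

// [[Rcpp::export]]
List cpp_forces(const arma::mat &X, const arma::mat &springs,
                const arma::umat &conn, double eps, double sigLJ,
                double cutoff) {
  arma::mat F;
  double eS, eL, mr;
  double e = eval_forces(X, springs, conn, eps, sigLJ,
                         cutoff > 0 ? cutoff * cutoff : -1.0, F, eS, eL, mr);
  return List::create(_["forces"] = F, _["energy"] = e,
                      _["energy_spring"] = eS, _["energy_lj"] = eL,
                      _["max_extension_ratio"] = mr);
}

// RPY diffusion supermatrix, prefactor D0 = kT/(6 pi eta sigma) in the
// caller's units; coordinates and sigma share one length unit.
static void rpy_fill(const arma::mat &X, double sigma, double D0,
                     arma::mat &D) {
  const arma::uword N = X.n_rows;
  D.zeros(3 * N, 3 * N);
  for (arma::uword i = 0; i < N; ++i)
    D.submat(3 * i, 3 * i, 3 * i + 2, 3 * i + 2) = D0 * arma::eye(3, 3);
  for (arma::uword i = 0; i + 1 < N; ++i) {
    for (arma::uword j = i + 1; j < N; ++j) {
      arma::rowvec d = X.row(i) - X.row(j);
      const double r = arma::norm(d);
      if (r < 1e-10)
        stop("coincident beads (%d, %d) in mobility matrix", (int)i + 1,
             (int)j + 1);
      arma::vec rh = d.t() / r;
      double c1, c2;
      if (r >= 2.0 * sigma) {
        const double sr = sigma / r;
        c1 = D0 * 0.75 * sr * (1.0 + (2.0 / 3.0) * sr * sr);
        c2 = D0 * 0.75 * sr * (1.0 - 2.0 * sr * sr);
      } else { // overlap regularization
        c1 = D0 * (1.0 - 9.0 * r / (32.0 * sigma));
        c2 = D0 * (3.0 * r / (32.0 * sigma));
      }
      arma::mat blk = c1 * arma::eye(3, 3) + c2 * (rh * rh.t());
      D.submat(3 * i, 3 * j, 3 * i + 2, 3 * j + 2) = blk;
      D.submat(3 * j, 3 * i, 3 * j + 2, 3 * i + 2) = blk;
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_rpy_matrix(const arma::mat &X, double sigma, double D0) {
  arma::mat D;
  rpy_fill(X, sigma, D0, D);
  return D;
}

// Ermak-McCammon propagation. Positions in Angstrom, dt in ps, forces in
// kBT/Angstrom, D0 in Angstrom^2/ps. With hi=false the mobility is diagonal
// (free draining); with hi=true the RPY supermatrix is rebuilt every step and
// its Cholesky factor every choleskyEvery steps. Gaussian displacements use
// R's RNG so runs are reproducible through set.seed().
// [[Rcpp::export]]
List cpp_bd_run(const arma::mat &X0, const arma::mat &springs,
                const arma::umat &conn, double eps, double sigLJ,
                double cutoff, double dt, int nsteps, int snapEvery, bool hi,
                double sigma, double D0, int choleskyEvery, double noiseScale,
                double maxBondRatio) {
  const arma::uword N = X0.n_rows;
  arma::mat X = X0;
  arma::mat F;
  double eS, eL, mr;
  const double cutoff2 = cutoff > 0 ? cutoff * cutoff : -1.0;

  if (snapEvery < 1) snapEvery = 1;
  const int nsnap = nsteps / snapEvery;
  arma::cube snaps(N, 3, std::max(nsnap, 0));
  arma::vec snapE(std::max(nsnap, 0));
  arma::vec snapRg(std::max(nsnap, 0));

  arma::mat D, L;
  arma::vec xi(3 * N), dr(3 * N), f(3 * N);
  const double fdStep = D0 * dt;
  const double fdNoise = std::sqrt(2.0 * D0 * dt) * noiseScale;
  const double hiNoise = std::sqrt(2.0 * dt) * noiseScale;

  int isnap = 0;
  for (int step = 0; step < nsteps; ++step) {
    double e = eval_forces(X, springs, conn, eps, sigLJ, cutoff2, F, eS, eL, mr);
    if (!std::isfinite(e))
      stop("non-finite energy at step %d", step + 1);
    if (springs.n_rows > 0 && mr > maxBondRatio)
      stop("instability: spring extension ratio %.2f exceeds %.2f at step %d "
           "(reduce dt)", mr, maxBondRatio, step + 1);

    if (!hi) {
      double *xp = X.memptr();
      const double *fp = F.memptr();
      for (arma::uword t = 0; t < 3 * N; ++t)
        xp[t] += fdStep * fp[t] + fdNoise * norm_rand();
    } else {
      rpy_fill(X, sigma, D0, D);
      if (step % choleskyEvery == 0) {
        if (!arma::chol(L, D, "lower"))
          stop("Cholesky factorization of the RPY matrix failed at step %d",
               step + 1);
      }
      for (arma::uword i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k) {
          f(3 * i + k) = F(i, k);
          xi(3 * i + k) = norm_rand();
        }
      dr = dt * (D * f) + hiNoise * (L * xi);
      for (arma::uword i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k) X(i, k) += dr(3 * i + k);
    }

    if ((step + 1) % snapEvery == 0 && isnap < nsnap) {
      snaps.slice(isnap) = X;
      snapE(isnap) = e;
      arma::rowvec cm = arma::mean(X, 0);
      double s2 = 0.0;
      for (arma::uword i = 0; i < N; ++i) {
        arma::rowvec d = X.row(i) - cm;
        s2 += arma::dot(d, d);
      }
      snapRg(isnap) = std::sqrt(s2 / N);
      ++isnap;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["snapshots"] = snaps, _["final"] = X,
                      _["energy"] = snapE, _["rg"] = snapRg,
                      _["n_snapshots"] = isnap);
}

// Rigid-body bead-model hydrodynamics of one conformation, CGS units.
// X in cm, sigma in cm, eta in poise, kT in erg. Builds the RPY mobility
// supermatrix, inverts it to the friction supermatrix, assembles the 6x6
// resistance at the bead centroid (adding each bead's own rotational
// friction 8 pi eta sigma^3), locates the center of diffusion, and reports
// the diffusion matrix there.
static void resistance_at(const arma::mat &Xc, const arma::mat &Z,
                          double bead_rot, arma::mat &R6) {
  const arma::uword N = Xc.n_rows;
  arma::mat Xtt(3, 3, arma::fill::zeros), Xrt(3, 3, arma::fill::zeros),
      Xrr(3, 3, arma::fill::zeros);
  auto skew = [](const arma::rowvec &r) {
    arma::mat A(3, 3, arma::fill::zeros);
    A(0, 1) = -r(2); A(0, 2) = r(1);
    A(1, 0) = r(2);  A(1, 2) = -r(0);
    A(2, 0) = -r(1); A(2, 1) = r(0);
    return A;
  };
  for (arma::uword i = 0; i < N; ++i) {
    arma::mat Ai = skew(Xc.row(i));
    for (arma::uword j = 0; j < N; ++j) {
      const arma::mat Zij = Z.submat(3 * i, 3 * j, 3 * i + 2, 3 * j + 2);
      arma::mat Aj = skew(Xc.row(j));
      Xtt += Zij;
      Xrt += Ai * Zij;
      Xrr -= Ai * Zij * Aj;
    }
  }
  Xrr += bead_rot * (double)N * arma::eye(3, 3);
  R6.zeros(6, 6);
  R6.submat(0, 0, 2, 2) = Xtt;
  R6.submat(3, 0, 5, 2) = Xrt;
  R6.submat(0, 3, 2, 5) = Xrt.t();
  R6.submat(3, 3, 5, 5) = Xrr;
  R6 = 0.5 * (R6 + R6.t());
}

// [[Rcpp::export]]
List cpp_rigid_hydro(const arma::mat &X, double sigma, double eta, double kT) {
  const arma::uword N = X.n_rows;
  const double mob0 = 1.0 / (6.0 * M_PI * eta * sigma); // mobility prefactor
  arma::mat B;
  rpy_fill(X, sigma, mob0, B); // mobility supermatrix (no kT)
  arma::mat Z;
  if (!arma::inv_sympd(Z, B))
    stop("singular mobility supermatrix (coincident beads?)");

  const double bead_rot = 8.0 * M_PI * eta * std::pow(sigma, 3);
  arma::rowvec O = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - O;
  arma::mat R6;
  resistance_at(Xc, Z, bead_rot, R6);
  arma::mat D6 = kT * arma::inv(R6);

  // center of diffusion from the coupling and rotational blocks
  arma::mat Drr = D6.submat(3, 3, 5, 5);
  arma::mat Dtr = D6.submat(0, 3, 2, 5); // translation-rotation coupling
  arma::mat M(3, 3);
  M(0, 0) = Drr(1, 1) + Drr(2, 2); M(0, 1) = -Drr(0, 1); M(0, 2) = -Drr(0, 2);
  M(1, 0) = -Drr(0, 1); M(1, 1) = Drr(0, 0) + Drr(2, 2); M(1, 2) = -Drr(1, 2);
  M(2, 0) = -Drr(0, 2); M(2, 1) = -Drr(1, 2); M(2, 2) = Drr(0, 0) + Drr(1, 1);
  // minimizer of trace(Dtt) over origin shifts t:
  // trace(Dtt(t)) = trace(Dtt) + 2 v.t + t' M t  =>  t = -M^{-1} v
  arma::vec v(3);
  v(0) = Dtr(1, 2) - Dtr(2, 1);
  v(1) = Dtr(2, 0) - Dtr(0, 2);
  v(2) = Dtr(0, 1) - Dtr(1, 0);
  arma::vec rCD = -arma::solve(M, v);

  arma::mat XcD = Xc.each_row() - rCD.t();
  resistance_at(XcD, Z, bead_rot, R6);
  arma::mat D6cd = kT * arma::inv(R6);

  const double Dt = arma::trace(D6cd.submat(0, 0, 2, 2)) / 3.0;
  arma::mat DrrCD = D6cd.submat(3, 3, 5, 5);
  const double Dr = arma::trace(DrrCD) / 3.0;

  arma::rowvec originAbs = O + rCD.t();
  return List::create(_["D_t"] = Dt, _["D_rr"] = DrrCD, _["D_r"] = Dr,
                      _["D6"] = D6cd, _["origin"] = originAbs);
}

// Capped-step steepest-descent relaxation used by the conformation builder.
// [[Rcpp::export]]
arma::mat cpp_minimize(const arma::mat &X0, const arma::mat &springs,
                       const arma::umat &conn, double eps, double sigLJ,
                       int nsteps, double step0, double maxDisp) {
  arma::mat X = X0, F, Xtry;
  double eS, eL, mr;
  double step = step0;
  double e = eval_forces(X, springs, conn, eps, sigLJ, -1.0, F, eS, eL, mr);
  for (int it = 0; it < nsteps; ++it) {
    arma::mat dX = step * F;
    // cap per-bead displacement
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      double nrm = arma::norm(dX.row(i));
      if (nrm > maxDisp) dX.row(i) *= maxDisp / nrm;
    }
    Xtry = X + dX;
    double eTry = eval_forces(Xtry, springs, conn, eps, sigLJ, -1.0, F, eS,
                              eL, mr);
    if (eTry <= e) {
      X = Xtry;
      e = eTry;
      step = std::min(step * 1.2, 10.0 * step0);
    } else {
      step *= 0.5;
      // recompute forces at the kept position
      e = eval_forces(X, springs, conn, eps, sigLJ, -1.0, F, eS, eL, mr);
      if (step < 1e-8) break;
    }
  }
  return X;
}
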