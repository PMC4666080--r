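---
title: "Coarse-grained RNA Brownian dynamics: model, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained RNA Brownian dynamics: model, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnabd)
```

## The model

`rnabd` represents an RNA molecule by one bead per nucleotide, all beads
sharing the hydrodynamic radius $\sigma = 3.15$ &Aring;. The secondary
structure partitions the strand into ungapped double helices and unpaired
runs (hairpin loops, internal loops, and the hinge joining the stems). Two
intramolecular interactions act on the beads:

**Elastic network.** Hooke springs, $V = \tfrac12 H (l - l_e)^2$, with one
force constant for every spring, $H = 200\,k_BT/l_{e,1}^2$, where
$l_{e,1} = 2\sigma = 6.30$ &Aring; is the touching-bead strand spacing.
Within every double-helical region, bead $i$ is connected to

* its first neighbors along its helix piece ($i \pm 1$) — connectivity,
* its second neighbors ($i \pm 2$) — bending,
* its third neighbors ($i \pm 3$) — torsion,
* its base-pair partner, and
* the partner's first neighbors — these last two maintain the duplex.

Beads in loops and hinges carry only first-neighbor springs. Neighbor
rules are truncated at helix boundaries (a bending or torsion spring never
reaches into a loop); first-neighbor springs always cross boundaries so
the strand stays connected. Equilibrium lengths are measured on an ideal
A-form reference build (below); boundary-crossing first-neighbor springs
are pinned to $l_{e,1}$ exactly so loops and helix junctions share one
bond length.

The harmonic exponent deserves one remark: the spring potential is
implemented as $\tfrac12 H (l-l_e)^2$, the only form consistent with a
Hooke spring and with a force constant carrying units of energy over
length squared.

**Excluded volume.** All bead pairs not joined by any spring interact
through the full 12-6 Lennard-Jones potential with
$\varepsilon_{LJ} = 0.1\,k_BT$ and $\sigma_{LJ} = 0.8\,l_{e,1} = 5.04$
&Aring;, i.e. including the (shallow) attractive tail. No cutoff is
applied by default — at $N \le$ a few hundred beads the $O(N^2)$ pair sum
is cheap; an optional cutoff is available for speed and, set at the
potential minimum, reproduces the purely repulsive (WCA) variant exactly
in the dynamics.

**A-form geometry.** Helices are built as ideal right-handed A-form
duplexes: helix radius 10 &Aring;, rise 2.8 &Aring;, 11 bp per turn, the
complementary strand offset azimuthally by the phase angle
$\phi = 200°$, paired beads sharing the same height on the axis. With one
bead per nucleotide these four numbers fully determine bead placement;
the base inclination (16.1°) and groove widths carried in
`model_parameters()` are descriptive A-form metadata and do not enter the
builder. Consecutive beads along an ideal strand come out 6.29 &Aring;
apart — within 0.2 % of $l_{e,1}$, which is the internal consistency the
parameter set implies.

## Initial conformations (the synthetic-structure builder)

`ideal_conformation()` produces a deterministic, rigid reference: every
loop (hinge, internal, hairpin) is laid out as a circle sized so that its
beads and the anchor pairs of its helices sit at their natural chord
distances ($l_{e,1}$ between strand neighbors, 19.70 &Aring; across a
base pair), with child helices pointing radially outward and laid out
recursively in 3-D from their actual inner base-pair positions. This is
the classic radial RNA drawing generalized to 3-D; it guarantees that
strand-adjacent anchors — including direct helix–helix junctions — end up
adjacent. Terminal tails extend outward at $l_{e,1}$ spacing.

`assemble_initial_conformation()` adds a small seeded Gaussian jitter
(0.1 &Aring;) to unpaired beads, breaking the exact planarity of the
layout, and then runs a capped-step steepest-descent relaxation under the
model force field to remove residual clashes. The result is
deterministic for a given seed; the inter-helix arrangement is arbitrary
by design, because all reported properties are equilibrium trajectory
averages and only the topology must be exact. What this builder emulates
is the *connectivity* of real RNA secondary structure; it makes no claim
about tertiary contacts (see Limitations).

## Brownian dynamics

Positions evolve by the Ermak–McCammon scheme,
$\Delta r = (\Delta t/k_BT)\,\mathbf{D}F + R$, with $E[R] = 0$ and
$\mathrm{Cov}[R] = 2\mathbf{D}\Delta t$:

* **Free draining** (`hi = FALSE`): $\mathbf{D} = D_0 I$ with
  $D_0 = k_BT/(6\pi\eta_s\sigma)$; independent Gaussian displacements.
* **Hydrodynamic interaction** (`hi = TRUE`): $\mathbf{D}$ is the
  Rotne–Prager–Yamakawa supermatrix (with the overlap regularization, so
  it is positive definite for any configuration); correlated
  displacements are drawn through its Cholesky factor. The RPY divergence
  is zero, so no drift correction is needed.

Internal units are &Aring;, ps, and $k_BT$; conversion to CGS happens only
at the property-reporting boundary. The default time step is
$\Delta t = 0.1$ ps, giving a stiffness number
$H\,\Delta t\,D_0/k_BT \approx 0.034$; `bd_config()` enforces the bound
0.05. At this step the sampled single-spring length distribution matches
Boltzmann quadrature to a Kolmogorov–Smirnov distance well under 0.02
(tested), and the backbone spring-length fluctuation in a duplex network
comes out at 5 % of $l_e$ — below the isolated-spring value
$\sqrt{k_BT/H} = 7.1\%$, as the multiple springs per bead predict.

The Cholesky factor is refreshed every step by default
(`cholesky_every = 1`); thinning it is available for speed and only
affects the correlated noise, not the drift.

Free-draining BD samples the equilibrium ensemble correctly (HI changes
dynamics, not statics — tested on small systems by comparing HI and
free-draining $R_g$), which is what makes the "smart Monte Carlo" route
below legitimate.

## Solution-property estimators

**Rigid-body treatment.** Each snapshot is treated as instantaneously
rigid: the $3N \times 3N$ RPY mobility supermatrix is inverted to the
friction supermatrix; the $6\times6$ resistance matrix is assembled at
the bead centroid, each bead adding its own rotational friction
$8\pi\eta_s\sigma^3$ (this term makes the single-bead limit exactly
Stokes for both translation and rotation, a closed form the test suite
checks to $10^{-12}$); the resistance is inverted and the diffusion
matrix translated to the center of diffusion, the origin that minimizes
the translational trace. Reported per snapshot: $D_t$ (trace/3 of the
translational block), the rotational tensor $D_{rr}$ (origin
independent), $D_r$ (mean of its eigenvalues), and
$\tau_h = 1/(6 D_r)$, the harmonic mean of the five rotational relaxation
times of an arbitrary rigid body.

**Ensemble averages.** `ensemble_properties()` averages $D_t$ and $D_r$
over the snapshots ($\tau_h = 1/(6\langle D_r\rangle)$) and reports
$R_g = \langle R_g^2\rangle^{1/2}$; uncertainties are standard deviations
over five contiguous trajectory blocks.

**Einstein route.** On an HI trajectory, `msd_diffusion()` fits the
center-of-mass mean squared displacement to $\langle d^2\rangle =
6 D_t \Delta t$ through the origin, weighting each lag by
`pairs / lag^2` (an inverse-variance proxy). The default window runs from
1 ns (skipping intramolecular transients) to 10 % of the trajectory
length; a fit with $R^2 < 0.9$ is flagged sublinear. This is the
reference route for dynamics; the rigid-body ensemble is the inexpensive
default.

**Kirkwood cross-check.** `kirkwood_dt()` implements the classical
double-sum approximation
$D_t \approx \frac{k_BT}{6\pi\eta\sigma N}\bigl(1 + \frac{\sigma}{N}
\sum_{i \ne j} r_{ij}^{-1}\bigr)$. On the tRNA fixture conformations it
sits about 5–6 % above the full treatment (Kirkwood preaverages and
ignores translation–rotation coupling, and is evaluated here against the
center-of-diffusion value, which is the minimum over origins); the
deviation grows to ~9 % on compact equilibrium snapshots. It is used as
a sanity cross-check, not as an estimator.

**Inter-arm angle.** Each arm vector is the principal axis of its stem's
beads (both strands), oriented hinge→tip by the sign of the projection
onto the hinge-to-tip centroid difference; the angle is the arccos of the
unit dot product. The principal axis was chosen over an endpoint
difference because it is robust to spring-length fluctuation.
Histograms use 10° bins over [0°, 180°].

**Svedberg estimate.** $s = D_t M (1-\bar v\rho)/(RT)$, reported in
Svedberg units; for the 5S rRNA inputs ($M = 40\,000$ Da,
$\bar v = 0.53$ cm³/g, $\rho = 1$ g/cm³, $D_t = 6.2\times10^{-7}$ cm²/s)
it evaluates to 4.8 S.

## Protocol and problem sizes

`run_pipeline()` sizes runs in units of the molecule's rotational
relaxation time: $\tau_h$ is first estimated from the relaxed initial
build (for equilibration, default 10 estimated relaxation times), then
re-estimated from a short pilot ensemble of ~25 snapshots after
equilibration (for production, default 20 estimated relaxation times,
~600 snapshots). The pilot-ensemble estimate replaces a single-snapshot
one, whose scatter is far too large to size a run. For the shipped
76-nt tRNA these defaults mean roughly $7\times10^6$ steps
(~0.7 µs of model time) and run in a few minutes on one CPU; the 120-nt
5S rRNA is run at reduced length (about 4 + 6 relaxation times) to stay
desk-scale. Master seed `s` deterministically derives the build,
equilibration, pilot, and production seeds (`s`..`s+4`).

## Fixtures

* `trna_phe`: 76-nt cloverleaf (acceptor 7 bp, D 4 bp, anticodon 5 bp,
  T 5 bp), three hairpin loops, central hinge, 3' tail, with an
  `arm_definition()` for the acceptor/anticodon angle.
* `5s_rrna`: 120-nt, five helices. The consensus structure of E. coli
  5S rRNA contains bulged helices that an ungapped-duplex model cannot
  represent, so the shipped table is a synthetic idealized encoding
  (labelled as such in the file) that absorbs bulges while preserving
  the five-helix, four-loop, one-hinge organization and the paired
  fraction (86/120 nt). Results for this fixture therefore carry an
  extra topology uncertainty on top of statistical error.

## Numerical choices and degenerate inputs

* Time step 0.1 ps (stability bound 0.05 on $H \Delta t/\zeta$,
  enforced); runs abort with a diagnostic if any spring stretches past
  $3 l_e$.
* Loop circles are sized by solving $\sum_k 2\asin(c_k/2R) = 2\pi$ for
  the chord list $c_k$ (uniroot, bracketed); if the chords cannot close a
  circle the smallest legal radius is used and the relaxation step
  absorbs the residual.
* The minimizer caps per-bead displacement at 0.25 &Aring; per iteration
  and backtracks on energy increase; it is deterministic.
* Pseudoknots (crossing pairs) are rejected at parse time; bulges split
  helices into separate ungapped duplexes.
* Degenerate arm stems (zero variance) and coincident beads raise
  errors rather than producing silent nonsense.

## Measured behavior and limitations

The tests and the acceptance script, not this document, are the source of
all numbers; the qualitative picture they paint is worth stating.

* The integrator and thermostat are validated at machine or statistical
  precision (Stokes closed forms, Boltzmann sampling, displacement
  covariances, force–gradient consistency).
* The equilibrium ensembles of this Hamiltonian are compact: the
  fully flexible hinge crumples entropically, and the excluded-volume
  beads ($\sigma_{LJ} = 5.04$ &Aring;) are much thinner than the ~20
  &Aring; steric diameter of a real A-form duplex, so stems approach each
  other more closely than real RNA stems can. Predicted sizes and
  rotational times for multi-branch molecules are therefore on the
  compact/fast side of reported solution values, while stem-orientation
  observables (the inter-arm angle) are insensitive to this and agree
  well. A thicker effective excluded volume or explicit tertiary
  restraints would counteract the compaction; both are deliberately out
  of scope because the model is defined by the parameter set above.
* Electrostatics, ionic strength, sequence dependence, and non-canonical
  pair geometry are not modeled.
* The rigid-body treatment estimates rotational relaxation of a flexible
  molecule only through the ensemble average of instantaneous rigid-body
  tensors; it is exact for conformational properties ($R_g$) and an
  acceptable estimate for $D_t$ and $\tau_h$.
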