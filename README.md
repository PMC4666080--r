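# rnabd

Brownian dynamics of coarse-grained RNA bead-spring models, with
solution-property prediction.

## The problem

Dilute-solution observables — the radius of gyration $R_g$, the
translational diffusion coefficient $D_t$, rotational relaxation times,
sedimentation coefficients — report on the overall three-dimensional
structure and flexibility of an RNA in solution, and connect directly to
dynamic light scattering, ultracentrifugation, and relaxation
experiments. Computing them for a *flexible* molecule needs a model that
keeps the secondary structure rigid where it is rigid (the double
helices) and free where it is free (loops and hinges), and a dynamical
scheme that knows about solvent friction.

`rnabd` implements such a scheme for structural biophysicists working on
tRNA-sized to small-rRNA-sized molecules:

* **Model** — one bead per nucleotide ($\sigma = 3.15$ Å), double helices
  as ideal A-form duplexes held by a minimalist elastic network of Hooke
  springs ($V = \frac12 H (l-l_e)^2$, $H = 200 k_BT/l_{e,1}^2$, five
  connectivity rules per helix bead, first-neighbor springs only in
  loops), and a 12-6 Lennard-Jones excluded volume
  ($\varepsilon_{LJ} = 0.1 k_BT$, $\sigma_{LJ} = 0.8\, l_{e,1}$) between
  non-connected beads.
* **Dynamics** — the Ermak–McCammon Brownian dynamics algorithm, either
  free-draining or with hydrodynamic interaction through the
  Rotne–Prager–Yamakawa tensor and Cholesky-correlated displacements
  (compiled inner loops; ~20 µs/step for 76 beads).
* **Properties** — the rigid-body bead-model treatment per snapshot
  (invert the 3N×3N RPY supermatrix, assemble the 6×6 resistance, read
  $D_t$ and the rotational tensor at the center of diffusion;
  $\tau_h = 1/(6\langle D_r\rangle)$), the Einstein relation
  $\langle d^2\rangle = 6 D_t \Delta t$ on HI trajectories, inter-arm
  angle statistics, five-block uncertainties, and the Svedberg relation
  $s = D_t M (1-\bar v \rho)/RT$.

Topologies come from dot-bracket strings or helix tables; yeast tRNA-Phe
(76 nt cloverleaf) and E. coli 5S rRNA (120 nt, synthetic ungapped
encoding) ship as fixtures.

## Worked example

```r
library(rnabd)

fx  <- load_fixture("trna_phe")      # 76-nt cloverleaf + arm definition
rep <- run_pipeline(fx, seed = 1)    # build, equilibrate, BD, rigid-body
print(rep)
```

This builds the elastic network (174 springs for the cloverleaf),
equilibrates for 10 estimated rotational relaxation times, runs a
free-draining production trajectory of 20 estimated relaxation times
(~0.3 µs of model time, a few minutes on one CPU), applies the
rigid-body hydrodynamic treatment to 600 snapshots, and prints:

```
rnabd pipeline report
  topology: 76 beads, 174 springs (hash 362df23c)
  property                        value   block SD
  D_t (1e-7 cm^2/s)                9.54       0.26
  tau_h (ns)                       16.0        1.2
  R_g (A)                          21.6        1.0
  inter-arm angle (deg)            92.0       12.6
```

Reading: the model tRNA diffuses at $9.5\times10^{-7}$ cm²/s, tumbles
with a harmonic rotational relaxation time of ~16 ns, has an rms radius
of gyration of ~22 Å, and holds its acceptor and anticodon stems at
~85–92° on average (seed-to-seed) — close to the crystallographic
inter-arm angle of ~90°.
Uncertainties are standard deviations over five contiguous trajectory
blocks. The angle trace and 10°-bin histogram are in `rep$theta`;
`svedberg()` turns a $D_t$ into a sedimentation coefficient (the shipped
5S inputs give 4.8 S ≈ 5 S).

Note that this fully flexible, thin-bead model equilibrates on the
compact side: its hinge crumples entropically, so predicted sizes and
rotational times sit below (and $D_t$ above) solution measurements of
real tRNA, while stem-orientation observables agree well. The methods
vignette (`vignettes/rnabd-methods.Rmd`) details the model, estimators,
and this limitation.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/rnabd.R run --topology trna_phe --seed 1 --out out/
Rscript inst/cli/rnabd.R fixtures list
```

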