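---
title: "Constructing and estimating absolute binding free energies with abfekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and estimating absolute binding free energies with abfekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abfekit)
```

## The problem

The standard (absolute) binding free energy of a protein–ligand complex,
$\Delta G^\circ_{bind}$, links directly to the dissociation constant,
$K_d = e^{\Delta G^\circ_{bind}/RT}$ at the 1 M standard concentration.
Computing it from simulation requires a reversible path between the bound
and the dissociated state. abfekit implements the construction and the
statistical analysis of the restraint-based alchemical route:

$$-\Delta G^\circ_{bind} = \Delta G_{p,att} + \Delta G_{l,conf,att} +
\Delta G_{l,TR,att} + \Delta G_{trans} + \Delta G_{l,conf,rel} +
\Delta G_{l,TR,rel} + \Delta G_{p,rel}$$

The protein and ligand are held by two kinds of harmonic restraint:
*translational/rotational* (TR) restraints that pin each molecule to three
lab-frame dummy particles (N1, N2, N3), and *conformational* restraints on
internal coordinates. Every restraint is harmonic with the convention
$u(x) = k\,(x - x_0)^2$ — no 1/2 factor — with $k$ in kcal/mol/Å² for
distances and kcal/mol/rad² for angles and torsions. The transfer term
$\Delta G_{trans}$ is obtained either by double decoupling (DD; bound and
bulk legs simulated separately, $\Delta G_{trans} = (\Delta G_{elec,bound}
+ \Delta G_{LJ,bound}) - (\Delta G_{elec,unbound} + \Delta
G_{LJ,unbound})$) or by simultaneous decoupling–recoupling (SDR; both legs
in one box, so the electrostatic and LJ components arrive already as
bound-minus-bulk differences and the system's net charge never changes).
The attach–pull–release (APR) physical path is deliberately exposed only
as an erroring stub.

abfekit does not run molecular dynamics. Sampling enters through a
per-window sample interface (TSV tables of restraint coordinates, reduced
potentials, or $\partial U/\partial\lambda$ values produced by any MD
engine's post-processing) and, for testing and demonstration, through a
synthetic Boltzmann sampler with closed-form reference free energies.

## The restraint frame

Anchor atoms define the frame: P1–P3 on the protein (user-chosen
selectors such as `:15@CA`) and L1–L3 on the ligand (chosen
automatically). After the complex is aligned to a reference protein
(global Needleman–Wunsch sequence alignment of the Cα residues followed
by Kabsch superposition of the matched pairs), L1 is the ligand heavy
atom inside a "strike zone" — a square of side `2*l1_range` centred at
$(x_{P1}+l1_x,\, y_{P1}+l1_y)$ — whose $|z - z_{P1}|$ is smallest, subject
to `l1_z` $\le |z - z_{P1}| \le$ `l1_zm`. If no such atom exists the pose
is declared unstable and no free energy is computed for it; the same test
applied after equilibration is the pose-retention filter.

N1 is placed 5.0 Å from L1 along z, on the P1 side; the system is rotated
about z so P1, L1 and N1 share one x value; N2 takes P1's x,y at N1's z;
and N3 sits $|N1{-}N2|$ above N2. This makes the N2–N1–L1 and N1–N2–P1
angles exactly 90°, which keeps the orientational torsions T1 and T4 away
from gimbal lock. L2 then minimises $|\angle(N1,L1,L2) - 90^\circ|$ with
$|L1L2|$ inside `[min_adis, max_adis]`, and L3 does the same with
$\angle(L1,L2,L3)$.

```{r anchors}
fx <- make_synthetic_complex(seed = 1)
an <- build_anchor_set(fx$complex, fx$reference, fx$P1, fx$P2, fx$P3,
                       fx$zone, fx$lig_resname)
an
```

The ligand TR restraints are D1 = N1–L1, A1 = N2–N1–L1, A2 = N1–L1–L2,
T1 = N3–N2–N1–L1, T2 = N2–N1–L1–L2, T3 = N1–L1–L2–L3 (`lig_distance_force`
for D1, `lig_angle_force` for the rest); the protein TR restraints are the
analogous D2/A3/A4/T4/T5/T6 through P1–P3. One subtlety worth recording:
the exact-90° constructions are the angles N2–N1–L1 (which *is* A1) and
N1–N2–P1 (apex N2) — the protein restraint A3 = N2–N1–P1 has its apex at
N1 and its reference value is simply measured from the structure, like
every other reference value.

Conformational restraints comprise the three anchor–anchor distances on
each molecule, optional backbone $\phi/\psi$ restraints over a residue
range ($\omega$ is never restrained), and — to make the ligand essentially
rigid — one dihedral restraint per heavy-atom *central bond* of the ligand
graph: a bond both of whose atoms have a further heavy neighbour, ring
bonds included. These torsions can be decoded from an AMBER prmtop
dihedral section (`read_prmtop_dihedrals()`, with impropers excluded and
1–4 exclusion markers retained) or enumerated directly from a MOL/SDF
V2000 connection table. The
per-bond quadruple is the lexicographically smallest heavy $(a,b,c,d)$,
replacing an arbitrary choice with a reproducible one. On the packaged
BRD4 test ligand 89J this yields 14 dihedral restraints:

```{r dihedrals}
g <- ligand_89j()
nrow(enumerate_central_bonds(g))
```

## Estimators

**Window schedule.** Restraints are attached over windows scaled by
`attach_rest(i)/100` applied to the full spring constant. The reduced
potential of window $i$ on pooled sample $n$ is $\beta \sum_r k_{ir}
(x_{nr} - x_{0,r})^2$ with dihedral differences wrapped to
$(-180^\circ, 180^\circ]$.

**MBAR.** Per-window free energies solve the standard self-consistent
multistate Bennett acceptance ratio equations. The solver iterates
self-consistently with log-sum-exp stabilisation, switching to Newton
steps on the convex MBAR objective after a few sweeps (falling back to
the self-consistent update whenever a Newton step is ill-conditioned),
and declares convergence when no free energy moves by more than
$10^{-8}\,kT$; the gauge is $G_1 = 0$. Oracles used in the tests are
independent of this code path: closed-form Gaussian partition functions,
two-sided exponential (Zwanzig) averaging, and direct numerical
quadrature.

**TI-GQ.** Thermodynamic integration evaluates $\sum_i w_i \langle
\partial U/\partial\lambda\rangle_i$ on Gauss–Legendre nodes mapped to
$[0,1]$ (12 nodes by default; user `lambdas`/`weights` override).

**Semi-analytic TR release.** Releasing the ligand TR restraints into the
standard-state volume ($C^\circ$ = 1 M = 1/1661 Å$^{-3}$) is computed, not
simulated:

$$\Delta G_{l,TR,rel} = kT\ln\frac{C^\circ}{8\pi^2}
 + kT\ln\!\big[I_r I_\theta I_\phi\big] + kT\ln\!\big[I_\Theta I_\Phi I_\Psi\big]$$

where the six one-dimensional Boltzmann integrals carry the $r^2\sin\theta
\sin\Theta$ Jacobian and are evaluated by adaptive quadrature to a relative
tolerance of $10^{-8}$, with the radial integral truncated where the
integrand falls below $10^{-16}$ of its peak. A force constant $\le 0$ is
an error (the integral diverges). In the stiff-spring limit the result
approaches the Gaussian closed form $kT \ln[(C^\circ/8\pi^2)\, r_0^2
\sin\theta_0 \sin\Theta_0\, \pi^3 (kT)^3 / \sqrt{k_d k_a^5}]$, which the
tests verify to below 0.01 kcal/mol at $k \ge 100$.

```{r release}
analytic_tr_release(tr_release_spec(k_d = 5, k_a = 250))
```

**Uncertainties.** Each window's trajectory is split into `blocks`
contiguous blocks (sizes differing by at most one, remainder to the last
blocks) and the free energy recomputed per block; the reported spread is
$\sigma = \sqrt{\tfrac1{N_b}\sum_n (x_n - \bar x)^2}$ with $\bar x$ the
*full-trajectory* estimate — deliberately not the block mean, and thus a
conservative convergence diagnostic rather than a textbook standard
deviation. Component uncertainties combine in quadrature.

**Cycle assembly and poses.** `assemble_dd()` / `assemble_sdr()` apply the
cycle sum literally over the letter-coded components (a, l, t, e, v, w, f,
b, c, r; SDR excludes f and w and rejects them if supplied). Multiple
docked poses combine by Boltzmann weighting, $\Delta G^\circ_{bind} =
-RT\ln\sum_i e^{-\Delta G^\circ_i/RT}$ over the stable poses; unstable
poses are excluded rather than penalised, matching the choice to run no
calculation for them. The combination is therefore bounded by the best
pose and by best $-\ RT\ln N_{pose}$, both asserted in the tests.

## The synthetic data generator

`make_synthetic_complex()` emulates the *geometry* of a binding site: a
rigid 30-residue helical Cα/N/C scaffold, a 12-heavy-atom ligand placed
inside the default strike zone about 6 Å below P1, and a reference copy
related by a random rigid transform so the alignment step does real work.
It does not emulate chemistry, flexibility, solvent or force-field
energetics — passing its tests demonstrates the correctness of the
geometric construction and the estimators, not of any force field.

`harmonic_system_spec()`/`sample_harmonic_window()` draw i.i.d. samples
from the exact Gaussian Boltzmann density of a restrained 1-D coordinate
(variance $kT/2(k_{sys}+k_{win})$ under the no-1/2 convention), and
`toy_alchemical_spec()` defines $U(x;\lambda) = (1-\lambda) k_A (x-a)^2 +
\lambda k_B (x-b)^2$, harmonic at every $\lambda$ with an exactly
integrable partition function. Because sampling is exact, any estimator
error is the estimator's own. Real MD data differ in two ways these
fixtures cannot capture: samples are time-correlated (here the block
spread absorbs what autocorrelation analysis would; no statistical
inefficiency subsampling is attempted), and real potentials produce
heavier-tailed work distributions than Gaussians.

In the end-to-end synthetic pipeline (`run_pose_pipeline()`), each
restrained coordinate fluctuates in an intrinsic well centred on its
reference value with spring equal to the full restraint spring
(`k_sys_frac = 1`) — a realistic regime in which each window overlaps its
neighbours well — and each decoupling component is a fixed toy
transformation. The exact attach free energy of this model,
$\sum_r \tfrac{kT}2 \ln(1 + k_r/k_{sys,r})$, anchors the tests.

## Numerical and design choices

* Constants: $R$ = 1.98720425864083 × 10⁻³ kcal/(mol K); default
  temperature 298.15 K; standard-state volume 1661 Å³.
* MBAR is implemented in its standard self-consistent form, the
  established statistically optimal multistate estimator.
* Needleman–Wunsch scores default to match +1 / mismatch −1 / gap −2 with
  tie-breaks diagonal → up → left, replacing a structural-alignment
  program whose matching rules are not published; for same-family
  proteins, sequence alignment plus Cα Kabsch is adequate and fully
  deterministic.
* Strike-zone boundaries are inclusive; ties in anchor selection break on
  the lowest atom serial; the canonical rotation takes the
  smaller-magnitude angle (positive on a tie); N3 is offset along +z.
  Each choice is arbitrary in the source procedure and fixed here for
  reproducibility.
* Only heavy atoms are anchor candidates, consistent with the heavy-atom
  dihedral policy.
* Angle and dihedral spring constants are interpreted per rad²
  throughout; reference values are stored in degrees.
* The z-padding solver inverts the linear water-count model
  $N(b_z) = \rho\,[A\,(z_{ext} + 2 b_z) - V_{excl}]$ by damped Newton
  iteration (relaxation 0.5) with a bisection fallback; water densities
  per model (0.0329 molecules/Å³ for TIP3P-like packing by default) are
  configurable inputs, since the effective packing density depends on
  the solvation tool and water model in use.
* The reference DD protocol budget (16-window attach/release legs at
  6–12 ns per window, 12-window decoupling legs, 80 ns of
  equilibration; 1.24 μs in total) ships as a data fixture rather than
  hard-coded truth.

## Problem sizes used in the tests

The test suite runs entirely on synthetic data at desk scale: harmonic
attach legs use up to 5 × 10⁴ samples per window (two windows) for the
estimator-recovery study over 100 seeded replicates, and the TI-vs-MBAR
consistency check uses 10⁴ samples per window with 12 quadrature nodes
against 23 MBAR windows — mirroring the window counts of the reference
protocol while keeping the whole suite inside a few minutes of CPU time.
These sizes are statements about the fixtures, not about what real
systems need; the reference MD protocol above is three orders of
magnitude larger.

## Known limitations

* Reading is limited to PDB, MOL/SDF V2000 and prmtop dihedral sections;
  no mmCIF, no protonation or hydrogen placement.
* Soft-core potential forms, force-field parameterisation and actual
  solvation/ion placement are out of scope: the package consumes
  per-window outputs an MD engine produces.
* No autocorrelation-based subsampling or bootstrapped covariances; the
  block spread is the only uncertainty model.
* Automorphism search for symmetry-aware RMSD is exhaustive and limited
  to fragments of ≤ 12 atoms.
* The multi-pose combination assumes pose free energies are estimated at
  a common temperature and standard state; no docking-score weighting.
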