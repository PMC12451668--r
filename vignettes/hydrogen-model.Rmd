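---
title: "A minimal semiempirical model of hydrogen clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal semiempirical model of hydrogen clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Semiempirical quantum mechanics (SQM) replaces expensive *ab initio*
integrals with parameterized matrix elements fit to reference data.
`sqmkit` implements the two structural ingredients such models are built
from and exercises them end to end on hydrogen clusters:

1. **Two-center matrix elements** in the Slater–Koster form: any matrix
   element of a rotationally invariant one-body kernel between atomic
   orbitals $p = (\mathbf r, \tau, l, m)$ and $q = (\mathbf r', \tau', l', m')$
   decomposes as
   $$K_{p,q} = \sum_{M=-L}^{L} R^{l}_{m,M}(\mathbf u)\,
     K^{\tau\tau'}_{|M|}(|\mathbf r - \mathbf r'|)\,
     R^{l'}_{m',M}(\mathbf u), \qquad L = \min(l, l'),$$
   with $\mathbf u$ the unit bond vector, $R^l$ the rotation matrices of
   real spherical harmonics, and $K_m^{\tau\tau'}(r)$ radial channels —
   the model parameters.  The transposition symmetry
   $K^{\tau\tau'}_m = (-1)^{l+l'} K^{\tau'\tau}_m$ reduces the
   independent set to $0 \le m \le l \le l'$.
2. **Factored four-center Coulomb integrals** through an atom-local
   auxiliary basis: $V_{pq,rs} \approx \sum_{\mu\nu} X^\mu_{p,q}
   V_{\mu\nu} X^\nu_{r,s}$, where $V_{\mu\nu}$ is the auxiliary Coulomb
   metric and the fit tensors $X$ conserve electronic charge exactly,
   $\sum_\mu X^\mu_{p,q} Q_\mu = S_{p,q}$.  For two-center pairs the
   charge-conserving solution is
   $$X^\mu_{p,q} = \sum_\nu \Lambda_{\mu\nu}\,(Q_\nu\, w_{p,q} + W^\nu_{p,q}),
   \qquad w_{p,q} = \frac{S_{p,q} - \sum_{\mu\nu} Q_\mu \Lambda_{\mu\nu}
   W^\nu_{p,q}}{\sum_{\mu\nu} Q_\mu \Lambda_{\mu\nu} Q_\nu},$$
   with $\Lambda$ the inverse of the pair's metric block and $W$ built
   from the one-center projection tensor $Z$ (or supplied directly as
   oracle Coulomb projections, which makes the expression the exact
   constrained Coulomb-metric fit).  With orthogonal orbitals and
   $Z = 0$ every cross-atom fit coefficient vanishes and the model
   reduces to the NDDO (neglect of diatomic differential overlap)
   approximation — `nddo_limit_check()` verifies this identity exactly.

Atomic units (hartree, bohr) are used everywhere.

## The hydrogen-cluster model

The shipped example is the smallest interesting SQM model: one s-type
primary *and* auxiliary function per hydrogen atom.  It has two
one-center parameters — the orbital energy $\varepsilon$, held at the
exact isolated-atom value $-0.5$ hartree and never fit, and the Coulomb
self-energy $U$ — and five two-center parameters at each interatomic
distance: overlap $S$, one-body Hamiltonian $H$, and electron–electron
($V_{ee}$), electron–proton ($V_{eH}$) and proton–proton ($V_{HH}$)
Coulomb interactions.

`model_integrals()` maps these to an integral set: $S$ off-diagonal in
the overlap matrix; $H$ off-diagonal and $\varepsilon - \sum_{j \ne i}
V_{eH}(r_{ij})$ on the diagonal of the one-body matrix (a positive
$V_{eH}$ is an attraction; off-diagonal electron–proton terms are
absorbed into $H$, a pure convention that moves no model flexibility);
the Coulomb tensor through the density fit with $V_{\mu\mu} = U$,
$V_{\mu\nu} = V_{ee}(r_{\mu\nu})$ and $Z = 0$; and nuclear repulsion
$\sum_{i<j} V_{HH}(r_{ij})$.  With the primary function as its own
auxiliary the identity fit returns $(ii|ii) = U$ and $(ii|jj) = V_{ee}$
exactly, and bridge integrals become
$(ij|kk) = \tfrac12 S_{ij}(V_{ik} + V_{jk})$.

Electron correlation is treated exactly: `cluster_spectrum()` runs full
configuration interaction (FCI) in every $(N, S_z \ge 0)$ block after
Löwdin orthogonalization, so remaining errors are purely Hamiltonian
model errors.

### Cluster geometries and second neighbors

The reference systems are the hydrogen dimer and the symmetric trimer at
a common nearest-neighbor spacing $r$.  The trimer is **linear** by
default: with the $(N, S_z \ge 0)$ block convention this yields exactly
10 ground-state targets (4 dimer + 6 trimer sectors) and 23
stationary-state targets (6 + 17), the task sizes the fitting protocol
is built around.  An equilateral variant is supported
(`hcluster("equilateral_trimer", r)`); its point-group degeneracies
merge levels and give smaller counts, which is how the two conventions
are told apart.

The linear trimer has a second-neighbor pair at $2r$.  Scalar
parameters apply at the nearest-neighbor distance only; beyond it the
local channels ($S$, $H$) are truncated to zero while Coulomb channels
follow their parameter-free monopole tails $1/(2r)$.  This keeps every
distance's fit self-contained.  A structural consequence worth knowing:
with zero second-neighbor overlap the trimer overlap matrix
$\bigl[\begin{smallmatrix}1&S&0\\S&1&S\\0&S&1\end{smallmatrix}\bigr]$
is positive definite only for $|S| < 1/\sqrt 2 \approx 0.707$, whereas
the physical 1s overlap at 1.4 bohr is $\approx 0.753$.  The fit is
therefore barred from the natural overlap at short distances, which is
one reason the minimal model's short-range errors are large (see
Limitations).

## Reference data: the internal FCI oracle

`reference_spectrum()` generates all reference energies internally from
a brute-force s-Gaussian integral engine: closed-form overlap, kinetic,
nuclear-attraction and two-electron integrals over an even-tempered
basis of 10 primitives per atom (exponents $0.02 \cdot 2.5^k$).  This
basis puts the isolated-atom ground state within $3\cdot10^{-5}$
hartree of the exact $-0.5$; it is a deliberately reduced-scale,
fully-internal substitute for benchmark-quality quantum-chemistry
reference data (no p or higher polarization functions, so absolute
correlation energies are underconverged, especially near 1 bohr).  Any
external engine can replace it through a function with the same
signature and return schema.

Per $(N, S_z \ge 0)$ block the $k$ lowest total energies are retained,
where $k$ is the dimension of the block's single-occupancy
configuration space in the minimal atomic basis (at most one electron
per atom) — the states a minimal-basis model can meaningfully target.
The model side applies the same lowest-$k$ selection to its own
minimal-basis FCI (a configurable alternative restricts the model CI
space to single occupancy instead; the default keeps model and
reference treatment symmetric).

## Numerical choices

* **FCI solver.** Blocks up to dimension 1500 are diagonalized densely
  (LAPACK).  Larger blocks (the trimer reference has a 13050-dimensional
  $(N{=}3, S_z{=}\tfrac12)$ block) are assembled as sparse matrices by
  the Slater–Condon rules in compiled code and solved by a Davidson
  iteration with diagonal preconditioning.  Before that, the integral
  set is rotated to the eigenbasis of the one-electron Hamiltonian —
  the FCI spectrum is invariant, but the determinant Hamiltonian
  becomes diagonally dominant, which the preconditioner needs.  The
  Davidson start vectors are unit vectors on the lowest-diagonal
  determinants with a small deterministic perturbation (a fixed linear
  congruential sequence, no global RNG use) so that symmetry-orthogonal
  starts cannot lock out target states.  Residual tolerance:
  $10^{-8}$.
* **Spin labels.** $\langle S^2 \rangle$ is evaluated per eigenvector
  with the operator identity $S^2 = S_z(S_z + 1) + S_- S_+$ in the
  determinant basis; states are labeled by the nearest $S(S+1)$ ladder
  value (tolerance $10^{-6}$).  Energies within $10^{-9}$ hartree of
  one another inside a block count as one level
  (`distinct_levels()`); model/reference pairing in fits uses
  $10^{-6}$.
* **Rotation blocks.** The $l = 1$ block comes from the Cartesian
  rotation taking $z$ to the bond direction (Rodrigues formula); the
  anti-parallel case $\mathbf u \approx (0, 0, -1)$ is resolved by a
  fixed auxiliary rotation of $\pi$ about the x axis.  Higher $l$
  follows the stable Ivanic–Ruedenberg-type recursion.  The real
  harmonics are ordered $m = -l..l$ (for p: $y, z, x$); this phase
  convention is self-consistent and validated against a sphere-sampling
  re-expansion oracle, but cross-reading externally published
  Slater–Koster tables may require a sign map.
* **Radial channels.** Cubic splines on a uniform grid (start 0.5 bohr,
  spacing 0.1 bohr, cutoff 10 bohr) or analytic callables.  Beyond the
  cutoff, declared tails apply exactly (zero, or monopole $qq'/r$);
  grid channels must meet their tail value at the cutoff (checked to
  $10^{-8}$), avoiding energy discontinuities in distance scans.
* **Constrained fits.** Charge conservation is imposed through KKT
  systems with explicit equality constraints — never penalty weights —
  so the sum rule holds to machine precision; rank-deficient systems
  fall back to the smallest-norm solution via the pseudoinverse (reported).

## The fitting protocol

`fit_hmodel()` minimizes the RMS deviation between model and reference
energies over one of two task target sets: task 1, the ground-state
energy of each distinct charge/spin sector (10 targets); task 2, all
distinct stationary states of the single-occupancy blocks (23 targets).
States are paired by (system, electron count, spin key, ascending
index); weights are uniform unless supplied.

The protocol (`run_protocol()`) has two stages: a joint 6-parameter fit
($U$ plus the five two-center values) at $r = 1.4$ bohr, near the dimer
equilibrium bond length, after which $U$ is frozen; then independent
5-parameter fits at every other grid distance.  Each fit runs 20
multistarts (seed 12345 by default): a bounded Nelder–Mead simplex
followed by Levenberg–Marquardt refinement with a numerical Jacobian
and box bounds ($|S| \le 0.99$, non-negative Coulomb parameters).  The
first start is computed from brute-force integrals of the isolated
atom's 1s orbital (`init_from_oracle()`) — a good initial guess
matters because the least-squares landscape has local minima — and the
remaining starts are seeded perturbations of it.  Starts that land in
the overlap-positivity-violating region are pulled back toward
$S = 0$ before optimization, and the penalty outside the feasible
region is graded in $|S|$ so the simplex can find its way back.
Everything is deterministic given (seed, configuration);
`recovery_test()` demonstrates exact recovery (better than $10^{-8}$
in every parameter) on zero-noise self-generated references.

## What the synthetic generator does and does not emulate

The internal oracle reproduces the *structure* of benchmark reference
data — sector-resolved, spin-labeled, single-occupancy-selected total
energies of real Coulombic hydrogen clusters — at reduced basis
quality.  Passing tests therefore demonstrate correctness of the
machinery (integrals, FCI, selection, fitting) and the qualitative
behavior of the minimal model, not quantitative agreement with
basis-set-converged reference energies: an s-only reference basis
lacks angular correlation, and the missing polarization grows toward
short distances.  The acceptance checks are designed around quantities
robust to this (task combinatorics, parameter counts, exact algebraic
identities, and a lower bound on the short-distance RMS error).

## Problem sizes

Unit tests run the reference pipeline on reduced bases (3–8 functions
per atom) and the fitting tests on model-generated references, keeping
the default suite in the minutes range; the full-size protocol (10
functions per atom, 20 multistarts) runs in the acceptance script and
in one dedicated acceptance test.

## Known limitations

* The minimal model cannot reach chemical accuracy (0.0016 hartree) at
  short separations; with this package's conventions the short-range
  RMS is further inflated by the $|S| < 1/\sqrt 2$ positivity bound the
  truncated linear trimer imposes, and by the s-only reference basis.
  The acceptance script computes the actual value.
* d and higher shells are not shipped in parameter sets (the rotation
  machinery is $l$-generic; tests cover s and p).  Periodic boundary
  conditions and Ewald-type electrostatics are out of scope.
* The Coulomb-kernel oracle covers s functions only; p support exists
  for the overlap/kinetic equivalence tests.
* `projection_Z()` implements the s-only single-auxiliary fit; the
  hydrogen example uses $Z = 0$ throughout (its printed parameter list
  has no $Z$ entries), so richer $Z$ fitting (tertiary bases, multipole
  constraints beyond the charge) is left out.
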