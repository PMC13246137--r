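---
title: "Multicomponent NEO-HF: models, solvers, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicomponent NEO-HF: models, solvers, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscf)
```

## The model

`neoscf` solves the nuclear-electronic orbital Hartree-Fock (NEO-HF) problem:
a molecule is partitioned into $N_e$ electrons, $N_p$ quantum protons, and
$N_c$ classical point-charge nuclei. Electrons and quantum protons each get
molecular orbitals expanded in Gaussian basis sets; the two subsystems couple
through their mutual Coulomb attraction. The Hamiltonian contains the usual
electronic terms, a proton kinetic term scaled by $1/m_p$
($m_p = 1836.15267343$ electron masses), proton-proton and
electron-proton Coulomb terms, proton-classical-nucleus repulsion, and the
classical-classical repulsion constant. A quantum proton carries *no*
classical point charge anywhere: its charge acts only through its density.
Electrons are treated restricted closed-shell; open-shell electrons are out
of scope.

Two nuclear wavefunction forms are supported:

* **SD** (Slater determinant): all quantum protons share one antisymmetrized
  wavefunction and one Fock operator,
  $f^p = h^p + \sum_{j'} (J^p_{j'} - K^p_{j'}) - 2\sum_i^{N_e/2} J^e_i$.
  Because the $j'$ sum is unrestricted, each proton feels its own
  self-Coulomb and self-exchange; the two cancel exactly in the energy but
  not in the operator.
* **HP** (Hartree product): protons are distinguishable, each with its own
  Fock operator
  $f^p_{i'} = h^p + \sum_{j' \ne i'} J^p_{j'} - 2\sum_i J^e_i$, no
  proton-proton exchange and no self terms. **HP\*** adds the per-proton
  self-Coulomb and self-exchange back onto the HP operator; the stationary
  energy is unchanged (the occupied-virtual block of $J[D_{i'}]-K[D_{i'}]$
  with respect to orbital $i'$ vanishes identically), but the optimization
  landscape reverts to SD-like behavior. HP\* exists precisely to isolate
  the self-terms as the cause of slow SD convergence, and the package's
  tests reproduce that behavior.

Energy bookkeeping follows the representation: SD counts
$\tfrac12\mathrm{Tr}[D^p_\mathrm{tot}(J-K)[D^p_\mathrm{tot}]]$ (self terms
cancel pairwise), while HP/HP\* count proton-proton Coulomb once over
ordered pairs and carry no exchange term. The two totals differ only by the
inter-proton exchange, which for localized protons is 8-15 orders of
magnitude below the electronic exchange — far below any SCF convergence
threshold, which is why both representations report the same energy.

## Basis sets and layouts

Gaussian shells are contracted *Cartesian* functions with $l \le 2$ (1, 3, 6
components), sufficient for minimal/split-valence electronic sets and s/p/d
protonic sets at the scale this package targets, and the simplest correct
choice for the McMurchie-Davidson recursions. Geometry input is Angstrom;
everything internal is bohr/Hartree with the conversion constant
(0.52917721092 Angstrom/bohr) fixed in one place.

The protonic default is an even-tempered generator
($\alpha_k = \alpha_0\beta^k$; defaults $\alpha_0 = 4.0\,\mathrm{bohr}^{-2}$,
$\beta = 2.5$, 4 s shells and 3 p shells per proton). These defaults were
chosen once so that a proton bound to a first-row atom has compact, flexible
orbitals: exponents from 4 to 62.5 bracket the ~10-25 bohr$^{-2}$ width of
typical protonic ground states. Externally supplied protonic basis files in
the documented JSON/YAML dialect are accepted wherever the generator is
used.

Under SD all protonic functions form one shared block. Under HP each proton
is by default restricted to the shells centered on it (each distinguishable
nucleus has its own set); `shared_hp_layout = TRUE` instead gives every
proton the full shared set so HP-vs-SD energy comparisons can be made in an
identical variational space. Whether a Hartree-product code should allow
protonic functions on other protons' centers is genuinely open; both
behaviors are provided rather than guessing one.

## Integrals

All one- and two-body integrals are evaluated by McMurchie-Davidson Hermite
expansion in compiled code: overlap, kinetic (with the particle mass
folded in), point-charge Coulomb with the sign chosen by particle kind, and
the generic two-cloud repulsion tensor $(\mu\nu|\lambda\sigma)$ whose
$1/r_{12}$ kernel is particle-agnostic (the same routine produces the ee,
pp, and ep tensors; interaction signs live in the Fock builders). The Boys
function switches from a series-plus-downward-recursion branch to an
erf-based asymptotic branch at $x = 35$; protonic exponents routinely put
Coulomb integrals deep into the asymptotic regime, so that branch is tested
explicitly up to $x = 200$. Shell-quartet screening uses the Schwarz bound
at $10^{-14}$. Tensors are held in memory, pre-reshaped for J- and
K-contractions — at the package's intended scale (up to ~200 basis
functions) this costs at most a few hundred MB and keeps every Fock build a
single matrix-vector product.

Every integral class is validated in the test suite against independent
adaptive quadrature: nested 1D rules over the Gaussian transform
$1/r = (2/\sqrt{\pi})\int_0^\infty e^{-u^2 r^2}\,du$, recentered on the
Gaussian product so narrow kernels stay resolved.

## Guesses

*Core*: diagonalize the one-particle core Hamiltonian. The nuclear variant
is block-diagonalized by proton center — inter-center blocks of $h^p$ are
zeroed and each center's block is solved separately — so several protons
cannot collapse onto one center; the raw full diagonalization remains
available behind a flag for pathological-guess experiments.

*SAD*: a spherically averaged, fractional-occupation atomic SCF per distinct
element (cached per element and basis) assembles a block-diagonal electronic
density, globally rescaled to $N_e$. The nuclear SAD guess solves each
proton in the frozen SAD electronic field, restricted to its own center's
shells. The literature does not pin down the exact nuclear-SAD construction;
this frozen-field one-proton solve is the package's definition, chosen
because it is deterministic, cheap, and plays the role of the "good" guess.
Inter-proton Coulomb is deliberately omitted from the frozen field. An
optional seeded random orthogonal perturbation of any guess supports
robustness sweeps.

## Solvers

All solvers update the electronic and nuclear orbitals **simultaneously**
each iteration; a stepwise mode (alternating full electronic and nuclear
convergence, each stage with its own subsystem-local DIIS) is kept as the
baseline it historically was. Convergence requires the energy change *and
both* subsystem error norms (orthonormalized Fock-density commutators,
$S^{-1/2}(FDS - SDF)S^{-1/2}$) below threshold — 1e-8 Hartree and 1e-8 by
default. No level shifting or damping is applied by default; both exist
behind flags.

* **DIIS**: one shared coefficient vector extrapolates both subsystems'
  Fock matrices, from the combined Gram matrix
  $\langle e_k^e|e_l^e\rangle + \langle e_k^p|e_l^p\rangle$ (subspace cap
  15). The Gram block is rescaled to $O(1)$ before the augmented Lagrange
  solve — its raw entries shrink quadratically with the error norm and
  would otherwise trip the ill-conditioning guard (condition $>10^{12}$
  drops the oldest entries; a fully degenerate subspace resets).
* **GDM-style quasi-Newton**: preconditioned limited-memory BFGS (20 pairs)
  over the stacked orbital-rotation parameters, Armijo backtracking
  (parameter 1e-4) with a 0.5-radius trust cap after two rejections, and a
  curvature guard that keeps the implicit Hessian positive definite. The
  preconditioner is the orbital-energy-difference diagonal floored at 0.05
  Hartree. Stored curvature pairs are reused unchanged in the current
  orbital frame — a transport approximation, adequate for the small
  accepted steps; full geodesic transport is documented upstream of this
  package's scope, which is why the docs say "GDM-style".
* **TRAH**: the lowest eigenpair of the $\alpha$-scaled augmented Hessian
  $\begin{pmatrix}0 & \alpha g^T\\ \alpha g & H\end{pmatrix}$ yields the
  level-shifted step $(H-\mu I)s = -g$ with $s = \tilde{x}(\alpha)/\alpha$.
  The eigenpair comes from a Davidson iteration over exact coupled
  Hessian-vector products (assembled from Fock-like contractions of
  first-order rotated densities; the ep blocks couple the subsystems), with
  an orbital-energy-difference diagonal preconditioner refreshed every
  outer iteration. If the $\alpha = 1$ step is interior it is taken
  (approaching the Newton step as the gradient shrinks); otherwise
  $\log\alpha$ is bisected (clamped to $[-6, 6]$) until
  $\|s\| \in [0.8\Delta, \Delta]$. Raising $\alpha$ deepens the shift and
  monotonically shortens the step, so the bisection stays on the strongly
  coupled side where Davidson is well conditioned, and consecutive probes
  are warm-started. Trust radius: init 0.4, shrink by 0.7 when the
  actual/predicted ratio is below 0.25, grow by 1.2 (cap 1.0) above 0.75,
  reject-and-halve if the energy rises by more than 1e-12. These schedule
  constants are this package's choices. TRAH supports the SD representation
  only; the HP off-diagonal Hessian coupling blocks are out of scope.
* **Hybrid DIIS-GDM**: DIIS until the combined error norm stalls, defined
  here as less than 1% relative decrease over 5 iterations (the stall rule
  is this package's choice), then GDM continues from the current state.

Proton occupations are aufbau, with a maximum-overlap reassignment *only*
when the aufbau set would localize two SD protons onto the same center.
Unconditional overlap tracking was rejected: it can lock a proton onto an
excited orbital of its own Fock operator and converge to a spurious
stationary state.

The keystone consistency check ties everything together: the analytic
orbital gradient ($g_{ai} = 2\,\mathrm{occ}\,F^{MO}_{ai}$ per subsystem) and
the Hessian-vector products are verified against central finite differences
of the energy and gradient, which guarantees the electronic and nuclear
Fock matrices derive from one energy expression.

## Fixtures and what the tests show

Built-in fixtures (`h2`, `water`, `h3o+`, `acetylene`, `water_dimer`,
`h5o2+`, `h9o4+`) use standard experimental-style internal coordinates
hard-coded in source, all hydrogens quantum, minimal electronic basis,
even-tempered protonic basis. They emulate the *structure* of benchmark
NEO systems — multiple coupled quantum protons on realistic geometries — at
desk scale. They do not emulate large electronic basis sets, optimized
protonic sets, correlation, open shells, or geometry relaxation, so passing
tests demonstrate the representation/solver properties (energy equivalence,
self-term-driven convergence differences, solver agreement) rather than
quantitative energies of real systems.

On this suite the package reproduces, at reduced scale, the qualitative
findings its design targets: SD and HP converge to identical energies;
HP needs roughly 2-4x fewer DIIS iterations; HP\* restores SD-like
iteration counts; TRAH converges in the fewest outer iterations; and with
deliberately poor core,core guesses the SD representation strands on
higher-energy solutions or fails on some fixtures while HP converges to the
lowest energy on all of them. The numbers behind these statements are
computed by the test suite and the acceptance script, not stored.

## Numerical choices and degenerate inputs

* Generalized eigenproblems go through symmetric orthogonalization;
  overlap eigenvalues below 1e-8 trigger a linear-dependence warning and
  non-positive ones an error.
* Orbital rotations exponentiate skew-symmetric generators by
  eigendecomposition; orthonormality is restored by symmetric
  re-orthogonalization when drift exceeds 1e-10.
* Problem sizes in tests and the acceptance script are chosen so a full run
  completes in minutes on one core: minimal electronic basis, 4s3p protonic
  sets, fixtures up to the Zundel cation (65 nuclear basis functions). The
  Eigen cation fixture (`h9o4+`) is provided for users but exercised only
  structurally in tests, since its pp tensor alone is ~1.5 GB.
* Zero quantum protons degrade gracefully to conventional RHF (used by the
  clamped-proton oracle tests); a proton with an empty basis block is a
  validation error.

## Known limitations

No NEO-DFT functionals (the `dft_hooks()` interface ships empty), no
electron-proton correlation, no open-shell electrons, no effective core
potentials, no density fitting or Cholesky decomposition, no analytic
geometry gradients, and no TRAH for the Hartree-product representation.
Cartesian $d$ is the highest angular momentum. Fixture geometries are fixed;
the package optimizes orbitals, not structures.
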