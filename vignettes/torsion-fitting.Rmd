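---
title: "Fitting torsional potentials by exact least squares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting torsional potentials by exact least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionfit)
```

## The model

A force-field torsional potential for a dihedral angle $\phi$ is the
truncated cosine series

$$V(\phi) = \sum_{j=1}^{m} k_j\,\bigl(1 + \cos j\phi\bigr), \qquad m \in \{3,4\},$$

with zero phase offsets. A molecule contains many dihedral *instances*
but a force field assigns coefficients per dihedral *type* — the
equivalence class of the four atom types spanning the bond. In dimethyl
phosphoric acid (DMPH), the running example, 15 instances collapse into 6
types with multiplicities $(2,2,2,6,1,2)$, so a 4-term fit has
$6 \times 4 = 24$ free coefficients.

The fitting evidence is a set of relaxed dihedral scans: for each
dihedral, one conformer per grid angle, each conformer characterised by
the values of *all* dihedrals (constraining one drags the others along)
and a target torsional energy
$E_{\mathrm{tors}} = E_{\mathrm{ref}} - E_{\mathrm{zero\text{-}tors}}$,
the reference energy minus the MM energy with all torsional coefficients
zeroed. Computing $E_{\mathrm{zero\text{-}tors}}$ (an MM single point) and
the reference energies (QM scans) is upstream of this package; the
package consumes the resulting table.

Writing $A_{ikj} = 1 + \cos(j\,\Phi_{ik})$ for instance $i$ in conformer
$k$, and summing same-type instances into one design column per
(type, term) pair, the objective

$$F(K) = \sum_k \Bigl(\textstyle\sum_{g,j} B_{k,(g,j)}\,k_g^j - E_{k,\mathrm{tors}}\Bigr)^2$$

is a convex quadratic in the coefficient vector $K$. Its stationarity
conditions form the linear *normal equations* $WK = C$ with
$W = B^\top B$ and $C = B^\top y$, and the solution is the **global
minimizer** — found exactly, with no initialisation, step sizes or
cooling schedules. This is the package's core
(`build_design_system()` + `solve_global()`).

Because reference and MM energies have unrelated zeros, the target
carries an arbitrary additive constant. By default an all-ones design
column absorbs it; the fitted constant is reported as `offset` and is
deliberately never exported as a force-field parameter (no standard field
exists for it, and constants exert no forces). Disabling it
(`include_offset = FALSE`) makes the fit absorb the constant into the
coefficients, which distorts them — keep it on unless the target is known
to be zero-aligned.

## The bounded ("local") variant

Unconstrained optima occasionally contain large coefficients, and
torsional coefficients beyond roughly $\pm 20$ kJ/mol are known to
destabilise MD integration (the package warns when a global fit crosses
that magnitude). `solve_bounded()` minimizes the same $F(K)$ subject to
$-T \le k_g^j \le T$ (default $T = 20$ kJ/mol; the offset stays free).
The problem is a convex box-constrained quadratic program; it is solved
by cyclic coordinate descent, where each update is the exact
one-dimensional minimizer clipped to the box — guaranteed to converge to
the unique constrained optimum for a convex quadratic. The solver
warm-starts from the clipped global solution and returns the global
solution untouched when no bound is active. Convergence is declared when
the largest per-sweep coordinate change falls below $10^{-12}$ (relative
to the coefficient scale), tight enough that the test suite checks
agreement with an independent constrained optimizer (`optim`'s L-BFGS-B)
to $10^{-6}$ relative objective.

By construction `objective(global) <= objective(local, T)` for any $T$,
and the bounded objective is non-increasing in $T$.

## The Monte Carlo baseline

`mc_fit()` implements the stochastic fitter the exact method is compared
against: Metropolis acceptance with probability $1$ for
$\mathrm{d}F \le 0$ and $e^{-\mathrm{d}F/T}$ otherwise, a temperature
factor that prevents premature trapping. The proposal perturbs one
uniformly chosen coefficient by a centred Gaussian
(`proposal_sigma`, default 2 kJ/mol), and the temperature cools
geometrically from `T_start` (default 100, in objective units
kJ²/mol²) to `T_end` (default 0.01) — choices made once, as reasonable
annealing practice, since no canonical schedule exists for this problem.
The best visited point is returned and runs are bit-reproducible under a
fixed seed.

Two facts make the comparison fair and deterministic in outcome: any MC
run's objective is bounded below by the exact optimum, and an MC run
*confined to the same box* as a bounded fit is bounded below by the
bounded optimum. The method-ranking checks therefore run MC with
`bounds = T`, turning the ordering
$F_{\mathrm{global}} \le F_{\mathrm{local}} \le F_{\mathrm{MC}}$ into a
theorem of convex optimization rather than a stochastic accident. In
practice the gap is large: on a noisy DMPH-like dataset a 50,000-step MC
run typically lands an order of magnitude above the exact optimum (see
`scripts/acceptance.R` output), while the exact solution costs one small
linear solve.

## Fourier ↔ Ryckaert-Bellemans conversion

MD engines often use the Ryckaert-Bellemans polynomial
$V(\phi) = \sum_{n=0}^{5} C_n \cos^n\psi$ with $\psi = \phi - 180^\circ$.
Substituting $\cos\phi = -\cos\psi$ and expanding $\cos j\phi$ by the
Chebyshev identities gives the exact linear map

$$C_0 = k_1 + k_3 + 2k_4,\quad C_1 = -k_1 + 3k_3,\quad C_2 = 2k_2 - 8k_4,$$
$$C_3 = -4k_3,\quad C_4 = 8k_4,\quad C_5 = 0,$$

which `fourier_to_rb()` implements (3-term sets are zero-padded). Unlike
some conversion tables, the constant term is preserved exactly, so the
identity `rb_energy(fourier_to_rb(p)) == fourier_energy(p)` holds at
every angle to machine precision — the test suite verifies it below
$10^{-10}$ kJ/mol on a half-degree grid for a thousand random coefficient
sets. The map restricted to $(k_1,\dots,k_4) \to (C_1,\dots,C_4)$ is
triangular and invertible; `rb_to_fourier()` inverts it when $C_5 = 0$,
moving any leftover constant into the offset.

```{r conversion}
p <- fourier_params(matrix(c(1, 0, 0, 0), 1, 4))
fourier_to_rb(p)$C     # 1 + cos(phi) = 1 - cos(psi)
```

## Evaluating a fit

`profile_rmsd()` scores a reconstructed energy profile against its
reference. Profiles are min-aligned by default — each shifted so its
minimum is zero — because absolute energy zeros are physically
meaningless here; only the relative profile shape matters for
conformational behaviour. (Mean-alignment would be an equally defensible
convention; min-alignment was chosen because torsional barriers are
conventionally quoted relative to the profile minimum.)
`scan_report()` groups conformers by scanned dihedral, computes one RMSD
per scan, and averages *unweighted* across scans, treating each
dihedral's profile as equally important regardless of its energy range.

## The synthetic-scan generator

`generate_dataset()` produces datasets with the structure of a real scan
campaign and a known ground truth, so solver accuracy, parameter
recovery and the method ranking are all checkable without quantum
chemistry:

- **Grid.** Half-open $[-180^\circ, 180^\circ)$ at a 10° step — 36
  conformers per scanned dihedral, 540 for DMPH. (A closed grid would
  have 37 points with $\pm 180^\circ$ duplicated; the half-open
  convention keeps 36 distinct conformations, and `scan_dataset()` folds
  $+180^\circ$ onto $-180^\circ$ on input.)
- **Coupling.** The default `"smooth"` mode sets each off-scan dihedral
  to a fixed per-instance baseline plus a 25° sinusoid of the scan angle
  (deterministic, seed-independent), imitating a relaxed scan in which
  all dihedrals move together — the very feature that forces simultaneous
  fitting. `"random"` draws off-scan angles uniformly; `"fixed"` holds
  them constant, which makes the coefficients of never-scanned types
  unidentifiable — the generator checks the design rank and warns.
- **Noise.** Gaussian noise of chosen standard deviation on the target
  energies; 0.5 kJ/mol is used throughout the tests as a realistic scale
  for combined QM/MM inconsistencies.
- **Ground truth.** `example_params()` provides a fixed DMPH-like set
  with $|k| \le 6$ kJ/mol, typical of OPLS-style torsions.

What the generator does *not* emulate: systematic (non-Gaussian) errors
from the zero-torsion MM model, anharmonic couplings beyond smooth
sinusoids, geometry relaxation failures, and Boltzmann weighting of
conformers. Passing recovery tests on synthetic data therefore
demonstrates the correctness of the estimator, not the adequacy of any
particular force field for a real molecule.

```{r roundtrip}
truth <- example_params()
ds <- generate_dataset(dmph_typing(), truth, seed = 1)
fit <- torsion_fit(ds)
max(abs(coef(fit) - truth$k))    # exact recovery on noiseless data
```

## Numerical choices and degenerate inputs

- Normal equations are solved by Cholesky factorisation of $W$; if $W$
  is singular (rank-deficient design) the minimum-norm least-squares
  solution is returned via the SVD pseudo-inverse with
  `diagnostics$singular = TRUE` rather than failing — the fitted
  energies are still optimal, only the coefficient split is non-unique.
- An all-zero design matrix raises a degenerate-system error; an empty
  dataset cannot be constructed.
- Underdetermined systems (fewer conformers than parameters) warn.
- Angles are validated into $[-180, 180)$ at dataset construction, and
  the stored scan angle must match the scanned dihedral's entry to
  $10^{-6}$ degrees.
- Coefficient CSVs and scan CSVs are written with 17 significant digits,
  so write/read round trips are exact; `.itp` export is fixed-width with
  6 decimals and no timestamps, hence byte-identical across runs.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` work at the natural size of the
DMPH problem (540 conformers × 24 parameters), with 50 random small
systems for the solver/oracle comparisons, 20 noise realisations for the
recovery statistics, 1,000 random coefficient sets for the conversion
identity, and 50,000-step Monte Carlo runs for the method ranking. The
whole suite completes in well under a minute on one core.

## Limitations

The method inherits the quality of its inputs: the target energies
presuppose correct non-torsional parameters (charges, van der Waals) in
the zero-torsion model, and a fit can only be as good as that
decomposition. Improper dihedrals, CMAP-style cross terms, phase-shifted
cosine bases and Boltzmann-weighted objectives are out of scope, as is
computing the zero-torsion energies or QM references themselves.
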