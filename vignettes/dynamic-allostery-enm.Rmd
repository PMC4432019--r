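---
title: "Elastic network models of entropy-driven allostery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic network models of entropy-driven allostery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## The model

allonet implements a Tirion-style elastic network treatment of dynamic
(entropy-driven) allostery in multimeric proteins, with the cAMP-binding CAP
homodimer as the guiding example. The protein is coarse-grained to one bead
per residue at the C-alpha position; every bead pair closer than a cutoff
(default 8 Angstrom, closed interval) is joined by a Hookean spring with a
single uniform constant `k`. The potential is

$$E = \tfrac12 \sum_{(i,j)} k \,\bigl(|r_i - r_j| - d^0_{ij}\bigr)^2,$$

whose mass-weighted second-derivative (Hessian) matrix at the crystal
geometry yields normal modes: eigenvalues $\lambda_m$ (frequencies
$\omega_m = \sqrt{\lambda_m}$, arbitrary units) and orthonormal eigenvectors.
A connected, non-collinear network has exactly six zero-frequency rigid-body
modes; every additional connected component contributes six more, and a
surplus of zero modes is therefore the diagnostic for an improperly
connected model.

Ligand binding is modelled as a purely elastic perturbation: the bound
nucleotide either adds beads (its heavy-atom centroid, or every heavy atom)
wired into the network with the same cutoff and spring constant, or — as a
third option — adds no beads and instead stiffens the springs among the
pocket residues. Three states are built from one structure: apo (no
ligand), holo1 (one ligand) and holo2 (both ligands).

## Allosteric free energy and K2/K1

In the classical (high-temperature) harmonic limit the vibrational entropy
difference between two states reduces to frequency ratios,
$\Delta S_i / k_B = -\ln(\omega_i'/\omega_i)$ per mode, with modes paired by
ascending rank after removing zero modes. All $\hbar\omega/k_BT$ prefactors
cancel, which is what makes the arbitrary stiffness units of the network
harmless. The allosteric free energy of the second binding event relative
to the first is then pure bookkeeping over the three spectra,

$$\frac{\Delta\Delta G}{k_B T}
  = \sum_i \ln \omega_i^{holo2} + \sum_i \ln \omega_i^{apo}
  - 2 \sum_i \ln \omega_i^{holo1},
\qquad K_2/K_1 = e^{\Delta\Delta G / k_B T},$$

so that $K_2/K_1 > 1$ means negative cooperativity (the second dissociation
constant is larger, i.e. the second binding is weaker). Because the
expression is a difference of log-products, multiplying every spring by a
common factor cancels exactly at any fixed mode count; the package asserts
this invariance to ~1e-12 rather than treating it as an empirical result.

`convergence_curve()` evaluates $K_2/K_1(m)$ for every truncation $m$ and
reports the smallest $m$ whose following `window` values (default 20) stay
within `rel_tol` (default 1e-3) of $K_2/K_1(m)$, together with the
full-truncation value. Two caveats are deliberate and documented here:

* With ligand models that add beads, the three states have different mode
  counts; the curve runs over the shared count (the apo spectrum), and the
  balanced "full spectrum" bookkeeping
  ($N_{apo} + N_{holo2} = 2N_{holo1}$) is available separately through
  `allosteric_free_energy(..., m = "full")`.
* The windowed plateau criterion can latch onto an early flat stretch of
  the curve. On structures whose soft modes respond immediately to binding
  the criterion behaves as intended; on structures whose allosteric signal
  lives in higher-frequency modes the converged value can sit at the early
  plateau while the full-truncation value differs. Both numbers are always
  reported, and scans default to the fixed full-truncation policy, which is
  deterministic and exactly scale-invariant.

## Diagnostics

* **B-factors.** The per-bead mobility $\sum_m |v_m(i)|^2/\lambda_m$ (the
  trace of the Hessian pseudoinverse diagonal block) is compared to
  crystallographic B-factors by squared Pearson correlation, since the
  model profile is defined only up to an affine transformation.
* **Cumulative motion.** $\sum_{i\le m} \lambda_i^{-1} / \sum \lambda_i^{-1}$
  measures how much of the total thermal motion the softest $m$ modes carry.
* **Eigenvector overlap.** $|v_a \cdot v_b|$ between states, computed on the
  shared protein coordinates with each subvector renormalized (ligand beads
  differ between states), skipping rigid modes.
* **Cross-correlations.** The normalized residue-residue covariance map
  built from the same mode sums, in $[-1, 1]$ with unit diagonal.

## The allosteric control map

`control_map()` rescales the springs incident to one residue's bead by a
factor $k_R/k$ — in all three states, and in both chains of the homodimer,
because a point mutation is present everywhere — then recomputes
$K_2/K_1$. The default grid has 22 multiplicative steps spanning
$2^{-2}$ to $2^{2}$ in even log steps, with the step nearest 1 snapped to
exactly 1 so the wild-type column is part of every map. The range is a
package choice: it covers symmetric strengthening and weakening of a
side-chain environment by up to four-fold, and it is prominently
configurable (`default_factor_grid(n_steps, log2_range)`).
`classify_sites()` calls a residue a control site when some factor moves
$K_2/K_1$ by at least 5% relative to wild type (again a package default,
exposed as `threshold`), and flags rows that cross $K_2/K_1 = 1$ as sign
switches between negative and positive cooperativity.

Scan cells are independent and deterministic; a residue subset scan is
bit-identical to the matching rows of a larger scan. Each cell costs one
dense eigendecomposition per state (~0.7 s at 3N ≈ 1270 on one CPU), so a
full 210-residue, 22-factor map is an overnight batch job while targeted
scans of candidate sites run in minutes; the bundled tests and the
acceptance script scan three residues.

## What the synthetic generator emulates — and what it cannot

No structure download is assumed anywhere: all tests and the acceptance
script run on fixtures built in code. Two kinds matter.

`dimer_toy()` is the minimal scalar model of coupled-monomer allostery: one
internal coordinate per monomer (stiffness `k`), interface coupling
`k_coupling`, and binding as multiplication of the bound monomer's
stiffness by `alpha`. Its cooperativity has the closed form
$\sqrt{\det K_{00}\det K_{11}}/\det K_{10}$, which makes it the exact oracle
for the thermodynamic bookkeeping (for `k = 1, k_coupling = 1, alpha = 2`:
$K_2/K_1 = \sqrt{24}/5 \approx 0.9798$; with `k_coupling = 0` exactly 1,
since uncoupled monomers cannot be cooperative).

`synthetic_cap_structure()` is a synthetic stand-in for a CAP-like crystal
structure, generated deterministically from a seed. It encodes the
architecture the real protein is described by — two identical 210-residue
chains related by a C2 axis, a 138-residue ligand-binding domain whose
residues 112–136 form a long ideal helix at the dimer interface, a
C-terminal DNA-binding domain, and one 22-heavy-atom cAMP per monomer
placed between the domain body and the interface helix — while everything
else is a compact self-avoiding walk at 3.8 Angstrom C-alpha spacing with
globular packing (sphere radii follow $R_g \approx 2.2\,N^{0.38}$, the
empirical scaling for folded domains). Its B-factor column is generated
from an inverse contact-density heuristic with mild lognormal noise.

What this surrogate cannot provide is the real protein's elastic
anisotropy: the specific beta-barrel topology, the packing inhomogeneity
between domains, chain breaks and flexible termini of a real crystal
structure, and genuinely measured B-factors. Consequently, tests that pass
on the surrogate demonstrate the correctness and invariances of the
machinery (oracle agreement, zero-mode accounting, scale invariance,
closed-form cooperativity, map identities) — they do not demonstrate that a
random compact fold reproduces the published CAP numbers, and on the
surrogate the cooperativity signal is indeed much weaker and
differently distributed across the spectrum than for the real protein.
Running the same pipeline on an actual liganded homodimer structure file
is a one-line change (`run_config(structure = "path/to/file.pdb")`).

## Numerical choices

* Zero modes are classified relative to the largest eigenvalue
  (`zero_tol = 1e-8`); eigenvalues below $-$`zero_tol`$\cdot\lambda_{max}$
  raise an error, since the Tirion Hessian is positive semidefinite by
  construction.
* The spectrum is computed by full dense symmetric eigendecomposition
  (LAPACK via `eigen(symmetric = TRUE)`): whole-spectrum quantities (free
  energies, cumulative motion, correlation maps) need all modes, and
  3N ≈ 1270 takes well under a second.
* The cutoff comparison is closed (distance ≤ cutoff), so boundary pairs
  are included; whether the boundary is open or closed is not recoverable
  from published tables and is absorbed by their tolerances.
* Alternate locations resolve to the highest-occupancy conformer with
  alphabetical tie-breaks; only the first model of multi-model files is
  read. Residues without a C-alpha are skipped with a warning.
* Sparse, tree-like networks (an undercrosslinked random cloud, or a
  collinear chain of three or more beads) legitimately carry more than six
  zero modes — transverse displacements see no central-force restoring
  term. `validate_modes()` accounts for the two-bead (five zero modes) and
  disconnected (six per component) cases and reports any surplus as
  improper connectivity.
* A mass-weighting column is kept in the API (default: unit masses
  everywhere, including ligand beads); cooperativity ratios are insensitive
  to a common mass scale, and per-state mass differences cancel in the
  frequency-ratio bookkeeping only when the same masses are used in all
  three states, which the state builder guarantees.
* Which monomer binds first is not observable; `build_state_networks()`
  takes the ligand of the first chain in file order and exposes
  `holo1_group` to flip or average the choice. On exactly symmetric
  structures the two choices agree to machine precision.

## Known limitations

Only the entropic, harmonic contribution to allostery is modelled: no
enthalpy, no quantum statistics, no absolute binding free energies, no
anharmonic or time-domain dynamics. Side-chain substitutions are
represented solely as spring-constant scalings — contact rearrangements
(a rotamer creating a genuinely new interaction) can be expressed only as
user-supplied extra spring pairs. Sequence-dependent or distance-weighted
spring constants are deliberately out of scope, as is any DNA-binding
function of the protein.
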