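# allonet

Elastic network models (ENMs) of **entropy-driven allostery** in multimeric
proteins.

Many allosteric proteins transmit the effect of ligand binding without any
appreciable conformational change: binding retunes the protein's thermal
fluctuations, and the resulting vibrational-entropy differences alone can
make the second binding event weaker (negative cooperativity) or stronger
(positive cooperativity) than the first. The catabolite activator protein
(CAP) of *E. coli* — a homodimeric transcription factor with one cAMP site
per monomer — is the classic experimental exemplar, and the system this
package is organized around.

`allonet` is for structural bioinformaticians and biophysicists who want to

* build Tirion C-alpha spring networks for the apo, singly-liganded
  (holo1) and doubly-liganded (holo2) states of a homodimer,
* compute normal modes and per-mode vibrational entropy changes,
* obtain the allosteric free energy and cooperativity ratio,
* diagnose the model (B-factor fits, cumulative motion, eigenvector
  overlaps, residue cross-correlation maps), and
* scan per-residue spring perturbations into a global **allosteric control
  map** that predicts mutations which enhance, suppress, or sign-switch
  cooperativity.

## The core quantity

Beads (protein C-alphas plus optional ligand beads) within a cutoff
(default 8 Å) are joined by uniform Hookean springs. Diagonalizing the
mass-weighted Hessian of each state gives mode frequencies
ω<sub>m</sub> = √λ<sub>m</sub>. In the classical harmonic limit the
entropic allosteric free energy of the second binding event is

```
ΔΔG / k_BT = Σ ln ω_i(holo2) + Σ ln ω_i(apo) − 2 Σ ln ω_i(holo1)
K2/K1      = exp(ΔΔG / k_BT)
```

summed over the first *m* vibrational modes of each state by rank.
K2/K1 > 1 means negative cooperativity. The ratio is exactly invariant
under uniform spring rescaling at fixed *m*, and is reported both at a
convergence-selected mode count and at the full shared spectrum.

## Worked example

```r
library(allonet)

## exact scalar toy: two monomers coupled across an interface
toy <- dimer_toy(k = 1, k_coupling = 1, alpha = 2)
print(toy)
#> dimer_toy: k=1 k_coupling=1 alpha=2  K2/K1 = 0.979796
```

The toy's closed form is √(det K00 · det K11)/det K10 = √24/5 ≈ 0.9798:
weak *positive* cooperativity, and exactly 1 if `k_coupling = 0` —
uncoupled monomers cannot be cooperative.

```r
## full pipeline on the synthetic homodimer (or any PDB file via read_pdb)
st     <- synthetic_cap_structure(seed = 1)
states <- build_state_networks(st, cutoff = 8, base_spring = 1)
res    <- allostery(states)
print(res)
#> allostery_result: K2/K1 = 0.999999 (converged at m = 1), ddG/kBT = -6.69392e-07
#>   full-spectrum (m = 1254): K2/K1 = 1.0396

cumulative_motion(res$modes$apo, 25)   # share of motion in the 25 softest modes
#> 0.905
```

On this surrogate the full-spectrum ratio is 1.04 — mild negative
cooperativity carried by higher-frequency modes, so the windowed
convergence criterion settles on the early flat part of the curve (both
values are always reported). A real liganded structure, with its much more
anisotropic elastic architecture, concentrates the signal in the soft
modes.

```r
## which residues control allostery?
cm <- control_map(states, factors = c(0.5, 1, 2), residues = c(132, 140))
round(cm$values, 4)
#>        0.5      1      2
#> 132 1.0396 1.0396 1.1188
#> 140 1.0396 1.0396 1.0290
```

Stiffening the springs at residue 132 — in the interface helix — raises
K2/K1 by ~8% (stronger negative cooperativity); residue 140 barely moves
it. The factor-1 column always equals the wild type. `classify_sites()`
turns a full map into enhancer/suppressor/neutral lists and
`mutation_preset()` gives a one-site verdict.

A shell front end covers the same workflows:

```sh
Rscript exec/allonet allostery --structure synthetic --out runs/wt
Rscript exec/allonet sweep --cutoffs 8,8.5,9 --out runs/sweep
Rscript exec/allonet scan --residues 132,140,160 --out runs/scan
```

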