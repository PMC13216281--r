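---
title: "Chemical bonding from maximally entangled atomic orbitals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical bonding from maximally entangled atomic orbitals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`meaobond` quantifies chemical bonds as entanglement between atom-localized
orbitals.  In second quantization every spatial orbital carries a
four-dimensional Fock space spanned by $|0\rangle, |\!\uparrow\rangle,
|\!\downarrow\rangle, |\!\uparrow\downarrow\rangle$.  For two symmetrically
orthogonalized atomic orbitals sharing an electron pair, the doubly occupied
bonding orbital becomes

$$|\Psi_{\mathrm{bond}}\rangle = \tfrac12\big(|0,\uparrow\downarrow\rangle
 + |\uparrow,\downarrow\rangle - |\downarrow,\uparrow\rangle
 + |\uparrow\downarrow,0\rangle\big),$$

a maximally entangled state of the two orbital Fock spaces with entanglement
entropy $\log 4$.  Electron sharing and spin pairing -- the textbook
ingredients of a covalent bond -- appear as the number and spin coherences of
this state.  The package turns this observation into an automated analysis:

1. **Partition** the one-particle Hilbert space into atomic subspaces
   spanned by orthonormal localized orbitals (intrinsic atomic orbitals,
   IAOs, against a shipped minimal reference basis; or a Loewdin fallback).
2. **Rotate within atoms** to find the maximally entangled atomic orbitals
   (MEAOs): the basis maximizing
   $$F(\mathcal B) = \sum_{i<j}\big|\Gamma^{i\uparrow,i\downarrow}_{j\uparrow,j\downarrow}\big|^2
     + \big|\Gamma^{i\uparrow,j\downarrow}_{j\uparrow,i\downarrow}\big|^2,$$
   the summed squared bond coherences of the two-particle reduced density
   matrix over inter-center pairs.  $F$ is a computationally cheap proxy for
   the total inter-center two-orbital entanglement; it equals $1/8$ for the
   ideal bond state.  For a closed-shell determinant the proxy reduces to
   $2\sum_{i<j}(\gamma_{ij}/2)^4$ with $\gamma$ the spin-free 1RDM.
3. **Cluster** MEAOs into bonds: orbitals are connected when their mutual
   information $I_{ij} = S(\rho_i)+S(\rho_j)-S(\rho_{ij})$ exceeds
   $\eta\,I_{\max}$ with $I_{\max}=2\log 4$ and $\eta = 0.10$; connected
   components of two vertices are two-center bonds, larger components
   multicenter bonds.
4. **Score** each bond from a correlated wavefunction: two-center bonds by
   the pair mutual information and the relative entropy of entanglement
   $E(\rho_{ij}) = \min_{\sigma\ \mathrm{separable}}
   \mathrm{Tr}[\rho_{ij}(\log\rho_{ij}-\log\sigma)]$; multicenter clusters by
   the genuine multipartite entanglement
   $\mathrm{GME}(|\Psi\rangle)=\min_A S(\rho_A)$ over cluster bipartitions,
   evaluated on a complete-active-space (CAS) wavefunction whose active
   orbitals are exactly the cluster MEAOs.

All entropies are natural logarithms; every reported quantity is normalized
($I/2\log4$, $E/\log4$, GME$/\log4$), which makes the outputs
base-independent.

## The built-in electronic-structure engine

The pipeline needs a mean field, localized orbitals, and CAS-CI solutions.
To keep the package self-contained it ships a minimal engine: McMurchie--
Davidson Gaussian integrals (s, p, d shells, spherical harmonics),
restricted Hartree--Fock with DIIS, and a determinant CAS-CI solver
(generator-decomposed sigma vectors, Davidson iteration, dense
diagonalization for small spaces).  The SCF energies were validated against
an independent quantum-chemistry program to $10^{-8}$ hartree during
development.  Three basis-set tables are shipped as plain text (cc-pVDZ,
6-311++G(d,p), and the MINAO minimal reference used by the IAO
construction).

Two consequences of this design are worth knowing:

* **The mean field is Hartree--Fock.**  Reference analyses of
  ring systems used a hybrid-functional mean field for the correlation
  diagram.  For the cluster-CAS GME values this distinction is nearly
  irrelevant (the ethyl-cation value changes by $<10^{-3}$), with one
  exception: benzene, where the HF pipeline gives GME $\approx 0.970$ for
  both the optimized and the experimental geometry (the hybrid-functional
  value for the optimized geometry is 0.967).  Both are inside the
  package's acceptance band.
* **Geometries are inputs.**  Structures whose published provenance is a
  geometry optimization (ethyl cation, benzene, cyclohexane at
  B3LYP/6-311++G(d,p); the lithium trimer cation at CCSD) are shipped as
  plain-text XYZ files, generated once at the stated level of theory with
  an external engine and recorded as such in their comment lines.
  Experimental geometries come from the standard reference tables and are
  quoted in the files.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `eta` | 0.10 | correlation-graph threshold, fraction of $I_{\max} = 2\log 4$ |
| `restarts` | 4 | MEAO optimizer starts (identity + 3 seeded random block rotations) |
| `gtol` | 1e-8 | gradient max-norm convergence of the MEAO ascent |
| `beta` | 1e3 Ha$^{-1}$ | inverse temperature of thermal ensembles |
| `nroots` | 4 | eigenstates entering a thermal ensemble |
| REE `tol` | 1e-6 | Frank--Wolfe duality-gap certificate (nats) |
| `max_full_dim` | 4e4 | determinant cap for treating the whole minimal-IAO space as one CAS |

The MEAO optimizer is a safeguarded Newton--Raphson ascent on the
antisymmetric generator of partition-preserving rotations: diagonal Hessian
entries by central differences (refreshed every five iterations), a
Levenberg-style shift whenever an entry has the wrong sign, and a
backtracking line search that guarantees monotone ascent.  Ties between
restarts (within $10^{-10}$) resolve to the lowest restart index, and the
iteration trace is retained for reproducibility; a fixed seed gives a
bitwise-identical trace.

## The separable set of the pair-entanglement solver

The relative entropy of entanglement is computed by away-step Frank--Wolfe
over mixtures of pure product states, with the linear subproblem (the best
product state against the gradient) solved by alternating
smallest-eigenvector iterations.  The Frank--Wolfe gap certifies the result
as an upper bound tight to the requested tolerance.

A subtle convention matters here.  For a *real* molecular wavefunction one
can restrict the product factors to real vectors; the mathematically
unrestricted separable set also contains complex product states (the
closest separable states of Bell-diagonal two-qubit states, for example,
require complex factors).  The published reference values for molecular
pairs are reproduced by the *real-factor* restriction (e.g. the N$_2$
$\sigma$ pair: real 0.950, complex 0.939), so `factors = "real"` is the
reporting default, while `factors = "complex"` is available and is what the
Bell-diagonal closed-form oracle test uses.  A third option,
`superselect = TRUE`, restricts the separable set by local particle-number
and $S_z$ superselection; each local sector of one orbital is
one-dimensional, so that set collapses to diagonal states and the minimum
has the closed form $S(\mathrm{diag}\,\rho) - S(\rho)$.  It bounds the
unrestricted value from above and is reported alongside when requested.

## GME evaluation and the mps-cuts approximation

For clusters of up to 8 orbitals the bipartition minimum is exhaustive
($2^{K-1}-1$ cuts, each a reduced-density eigenvalue problem evaluated
directly from the CAS CI vector with all fermionic reordering parities).
The `mps-cuts` mode restricts the minimization to single-orbital entropies,
two-orbital entropies and contiguous chain cuts -- the approximation a
matrix-product-state code would use.  On every cluster of $\le 6$ orbitals
exercised by the test suite the two modes agree to $10^{-10}$; the
exhaustive value can never exceed the approximate one, and the suite
asserts both facts.

## Multicenter actives spaces

A cluster's CAS is built by restricting the spin-free 1RDM to the
non-cluster MEAOs and diagonalizing: natural occupations $>1$ become closed
orbitals, $<1$ virtual orbitals.  Occupations more than 0.2 away from 0 or
2 trigger a warning (the construction assumes the non-active space is
nearly idle), and an occupation within $10^{-6}$ of exactly 1 is an error
since no classification rule exists.  Electron count is conserved by
construction: $2 n_{\mathrm{closed}} + n_{\mathrm{active}} = N$.

**Negative controls.**  Saturated rings have no multicenter cluster at
$\eta = 0.10$; the reported "highest six-orbital GME" is evaluated by
`best_k_orbital_gme()`: enumerate unions of three two-center ring-bond
clusters whose atom-sharing graph is connected, solve each union's CAS(6,6)
and keep the maximal exhaustive GME.  Disconnected unions are nearly
biseparable (their GME is bounded by the weak inter-pair correlation, an
order of magnitude smaller), which is why connectivity is required; the
connected rule reproduces the published cyclohexane control value
($\approx 0.014$ here vs 0.015) while the disjoint choice gives 0.002.

## What the fixtures establish -- and what they do not

The analytic module (`bond_state()`, `ghz_state()`, `w_state()`,
`ionicity_family()`) exercises every entanglement routine without any
electronic-structure run, with closed-form expected values.  The synthetic
ionicity family is an interpolation between the covalent bond state and an
ionic product state used only for monotonicity testing; it is *not* a
reproduction of any published ionicity model.  Green tests on these
fixtures establish the correctness of the entropy, REE and GME machinery;
they do not establish chemical accuracy, which is probed separately by the
acceptance tests on real molecules (CH$_4$, N$_2$, LiH, He$_2$, the ethyl
cation, Li$_3^+$, benzene, cyclohexane) at their stated geometries and
bases.

Known limitations: no DFT and no unrestricted mean field; CAS-CI is
determinant-based and practical to roughly $10^5$ determinants (larger
correlated treatments would need a matrix-product-state solver, which is
out of scope); elements H--Ar and basis sets shipped as text (cc-pVDZ,
6-311++G(d,p), MINAO); the thermal-ensemble machinery is exercised on
small fixtures only -- the stretched-LiH entanglement-peak curve requires
an augmented basis and excited-state solver settings beyond the built-in
engine's practical range; transition-metal systems (mixed basis families)
are not supported.

## Numerical conventions

* Fock basis per orbital ordered $|0\rangle,|\!\uparrow\rangle,
  |\!\downarrow\rangle,|\!\uparrow\downarrow\rangle$; modes ordered
  site-ascending with up before down; with these conventions the bond
  state's $|\downarrow,\uparrow\rangle$ amplitude is $-1/2$.
* Density-matrix eigenvalues below $10^{-14}$ are treated as exact zeros in
  entropies; an eigenvalue below $-10^{-8}$ raises an error.
* Two-orbital RDMs of particle-number/$S_z$-conserving states are
  block-diagonal; off-block magnitudes are asserted $<10^{-10}$.
* SCF converges the DIIS error and energy change to $10^{-9}$; orbital
  signs are fixed (largest-magnitude coefficient positive) for
  reproducible coherence signs.
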