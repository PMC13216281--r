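# meaobond

Quantitative chemical-bonding analysis from quantum information theory, in
R.

Chemical bonds are usually described either by molecular-orbital ideas
(delocalized, hard to map onto "this bond between these two atoms") or by
Lewis structures (intuitive, but not an observable).  `meaobond` takes a
third route: it treats each atom's orbitals as quantum subsystems and asks
how entangled they are.  An ideal two-electron covalent bond between two
orthogonalized atomic orbitals is a *maximally entangled* state of the two
orbital Fock spaces (entanglement `log 4`), so bond detection and bond
strength become entanglement detection and entanglement measures:

* **MEAOs** (maximally entangled atomic orbitals): atom-local orbital
  rotations that maximize the summed squared bond coherences
  `F = sum_{i<j} |G_iijj|^2 + |G_ijji|^2` of the two-particle reduced
  density matrix over inter-atom pairs (`F = 1/8` for the perfect bond).
* **Bond detection**: orbital pairs with mutual information
  `I_ij = S(rho_i) + S(rho_j) - S(rho_ij)` above 10% of `I_max = 2 log 4`
  form the edges of a correlation graph; connected components are bonds
  (two-center) or multicenter bonding groups.
* **Bond strength**: for pairs, the relative entropy of entanglement
  `E(rho_ij) = min over separable sigma of Tr[rho (log rho - log sigma)]`;
  for multicenter clusters and aromatic rings, genuine multipartite
  entanglement `GME = min over bipartitions A of S(rho_A)`, computed from a
  complete-active-space wavefunction on the cluster orbitals.

Everything runs from an XYZ geometry and a basis-set name: the package
contains its own Gaussian-integral engine, restricted Hartree-Fock,
intrinsic-atomic-orbital localization and determinant CAS-CI solver, plus
the entanglement machinery (away-step Frank-Wolfe for the relative
entropy, exhaustive or chain-cut bipartition search for GME).  It is aimed
at method developers and computational chemists who want reproducible,
quantitative bond orders and aromaticity indices with no external
quantum-chemistry dependency.

## Worked example

The lithium trimer cation, a textbook three-center two-electron bond.  The
shipped geometry is an equilateral triangle optimized at
CCSD/6-311++G(d,p):

```r
library(meaobond)
geom <- system.file("extdata/geometries/li3_cation_ccsd.xyz",
                    package = "meaobond")
cfg <- run_config(geom, basis = "6-311++g(d,p)", charge = 1,
                  correlation = "cluster", seed = 1)
rep <- run_bonding_analysis(cfg)
print(rep)
#> MEAO bonding analysis (6-311++g(d,p), iao-minimal)
#> multicenter clusters (normalized GME):
#>   cluster {2+4+6} CAS(3, 2): GME = 0.909
```

The three valence MEAOs (one 2s-like orbital per lithium) form a single
three-orbital cluster; its CAS(3 orbitals, 2 electrons) ground state has a
normalized genuine multipartite entanglement of 0.909 -- a strong
three-center bond (the ideal value is 1; a saturated ring like cyclohexane
scores about 0.01).  For a two-center example:

```r
rep <- run_bonding_analysis(run_config(
  system.file("extdata/geometries/lih.xyz", package = "meaobond"),
  basis = "cc-pvdz", correlation = "full-minimal"))
print(rep)
#> MEAO bonding analysis (cc-pvdz, iao-minimal)
#> two-center bonds (normalized I, E):
#>   orbitals 2-3 (atoms 1-2): I = 0.767  E = 0.767
```

The partially ionic Li-H bond shows correspondingly reduced correlation
and entanglement (a pure covalent bond like H2 approaches 1, the van der
Waals dimer He2 gives exactly 0).

## Command line

```sh
inst/cli/meao-bond run    --geometry mol.xyz --basis cc-pvdz --charge 0 --seed 1
inst/cli/meao-bond graph  --geometry mol.xyz --out graph.graphml
inst/cli/meao-bond cubes  --geometry mol.xyz --orbitals 1,2,3 --out cubes/
inst/cli/meao-bond report --geometry mol.xyz --out report.json
```

## Scope notes

The built-in mean field is restricted Hartree-Fock (no DFT); shipped basis
sets are cc-pVDZ, 6-311++G(d,p) and the MINAO reference for the IAO
construction; CAS-CI is practical to ~1e5 determinants.  See the methods
vignette (`vignettes/meao-bonding.Rmd`) for the model, conventions,
algorithmic choices and limitations.
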