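# znoligomer

Analysis of zinc-induced oligomerization of the amyloid-beta metal-binding
domain (residues 1-16) and its disease-linked variants, centred on the Taiwan
mutant D7H.

The unmodified metal-binding domain (`DAEFRHDSGYEVHHQK`) binds one Zn(2+) and
stays monomeric. Modified domains — the D7H mutant, the isoaspartate-7
isoform — gain extra zinc-coordination sites, so that a shared zinc ion can
bridge two peptides through paired residues (e.g. `E11/H14:ZN:E11/H14`), and
chains of such bridges grow oligomers and aggregation seeds. This package
implements the computational chain used to establish that mechanism, with
seeded synthetic generators standing in for the instruments:

* **ITC binding isotherms** — forward simulation and non-linear fitting of
  one- and two-independent-sites models. For site class *i* with
  stoichiometry `N_i`, association constant `Ka_i` and enthalpy `dH_i`, the
  free ligand `L` solves `X_t = L + M_t * sum_i N_i * Ka_i L / (1 + Ka_i L)`
  and per-injection heats follow the perfusion-cell displacement convention.
  `itc_fit()` returns a classed model object with `print`, `summary`, `coef`,
  `predict`, `plot`, `residuals`, `simulate` and `vcov` methods; site-count
  selection uses AICc.
* **Tandem-MS chelator localization** — theoretical b/y/c/z and internal
  fragments with zinc adducts (each bound Zn shifts the neutral mass by
  Zn - 2H = 61.91349 Da), ppm-tolerance spectrum annotation, and a
  fragment-intersection algorithm (`infer_chelators()`) that ranks
  chelation-capable residues from minimal zinc-carrying spans and
  cleavage-suppressed regions.
* **Trajectory contact census** — residue-pair contact counting over
  multi-model PDB trajectories (minimum side-chain heavy-atom distance
  < 4.5 A by default) and steric-exclusion logic (`feasible_interfaces()`)
  selecting the feasible zinc-mediated interfaces.
* **Oligomer assembly graphs** — subunits with variant-specific interface
  sites, zinc bridges with valence and compatibility rules, named topologies
  (dimer, tetramers, octamer, dodecamer, heterotrimers) and
  polymerization-seed counting.
* **Synthetic data generators** — `synth_itc()`, `synth_spectra()`,
  `synth_trajectory()` produce every input class with recorded ground truth
  and byte-identical regeneration under a fixed seed.

## Worked example

```r
library(znoligomer)
report <- run_pipeline(demo_config(seed = 1, n_frames = 200))
print(report)
```

```
== zinc-oligomerization pipeline report ==

[itc] selected 2 site class(es)
         N      Ka    dH
high 0.335 2140000 -8.19
low  1.030   24200 -9.96

[ms] chelator candidates: 3, 6, 7, 11, 13, 14 

[contacts] census:
    pair frames_in_contact frames_total
1  E3/H6                 9          200
2 H7/H13                 5          200
3 E3/H13                 0          200
feasible interfaces: E11/H14:ZN:E11/H14, E3/H6:ZN:E3/H6, H7/H13:ZN:H7/H13 

[assemble]
  dimer_EVHH            2 subunits,  1 Zn, 2 seed(s)
  heterotrimer_D7H      3 subunits,  2 Zn, 0 seed(s)
  heterotrimer_isoD7    3 subunits,  2 Zn, 0 seed(s)
  dodecamer            12 subunits, 11 Zn, 3 seed(s)
```

Reading the report: the titration of the D7H domain resolves **two** zinc
site classes — a sub-stoichiometric high-affinity site (N ≈ 0.35, the shared
intermolecular `11-EVHH-14` site; N < 1 signals oligomerization) and a
low-affinity site with N ≈ 1. The MS stage recovers the six chelating
residues E3, H6, H7, E11, H13, H14. The contact census keeps the two
low-affinity interfaces whose residue pairs actually meet in the trajectory
and discards the partition built on the never-contacting E3/H13 pair. The
assembly stage reports zinc counts (one per bridge) and polymerization
seeds — free docking loci for a fresh zinc-bridged dimer — including the
three seeds of the dodecamer lattice.

The methods vignette (`vignettes/zinc-oligomerization.Rmd`) documents the
models, the algorithmic choices and their limitations.

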