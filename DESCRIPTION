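Package: znoligomer
Title: Zinc-Induced Oligomerization Analysis for the Amyloid-Beta Metal-Binding Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the zinc-dependent oligomerization of the amyloid-beta
    metal-binding domain (residues 1-16) and its familial variants, in particular the
    Taiwan (D7H) mutant. Provides forward simulation and non-linear fitting of one- and
    two-independent-sites isothermal titration calorimetry (ITC) binding isotherms;
    theoretical peptide fragmentation with zinc adducts, tandem-MS spectrum annotation and
    a fragment-intersection algorithm that localizes zinc-chelating residues; residue-pair
    contact censuses over multi-model PDB trajectories with steric-exclusion logic for
    selecting feasible zinc-mediated interfaces; a combinatorial model of zinc-bridged
    oligomer assembly (dimers, tetramers, octamers, dodecamers and heterotrimers) with
    polymerization-seed counting; and seeded synthetic-data generators for every input
    class so that the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
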