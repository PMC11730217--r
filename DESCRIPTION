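Package: iodosite
Title: Geometry and Thermodynamics of Directional Thyroxine Synthesis in
    Engineered Protein Precursors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale modelling of thyroxine (T4) formation at an
    engineered single hormonogenic site. Builds precursor models by grafting
    an extended hexapeptide tail bearing an acceptor tyrosine onto a scaffold
    via internal-coordinate (NeRF) chain construction, edits tyrosines to
    mono- or 3,5-di-iodotyrosine, samples conformational ensembles of the
    flexible tail and donor side chain with a torsion-space Metropolis Monte
    Carlo sampler under an implicit-solvent energy, and computes reaction
    propensity statistics (interatomic distance distributions, pi-pi
    stacking classification, carboxylate-to-hydroxyl proximity). A
    thermodynamic layer estimates iodotyrosine pKa values by a
    phenol-referenced cycle, pH-dependent deprotonation fractions, and
    free-energy bookkeeping for sequential versus concerted iodotyrosine
    coupling pathways with variant ranking. Also scans protein sequences and
    alignments for the conserved acidic-residue/tyrosine acceptor motif.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    tools
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'iodosite-package.R'
    'geometry.R'
    'AllClasses.R'
    'io-pdb.R'
    'io-fasta.R'
    'residues.R'
    'builder.R'
    'fixtures.R'
    'sampler.R'
    'stats.R'
    'conservation.R'
    'thermo.R'
    'pipeline.R'
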