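---
title: "Modelling directional thyroxine synthesis at an engineered hormonogenic site"
author: "iodosite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling directional thyroxine synthesis at an engineered hormonogenic site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iodosite)
```

## The problem

Thyroxine (T4) is synthesised on a protein precursor: two tyrosines of a
hormonogenic site are enzymatically iodinated to 3,5-di-iodotyrosine (DIT),
and the hydroxyl oxygen (O&zeta;) of the *acceptor* DIT couples to the
C&beta; of the *donor* DIT, leaving T4 at the acceptor position and a
dehydroalanine at the donor.  In thyroglobulin the acceptor tyrosine of the
resolved sites is consistently preceded by an acidic residue (glutamate at
the early site, aspartate at the late sites), and that acidic residue is
what makes hormone synthesis *directional*: it assists early deprotonation
of the acceptor iodophenol, the step that licenses the radical coupling.

`iodosite` models this mechanism at desk scale on a minimal single-site
precursor: a small scaffold carrying one solvent-exposed donor tyrosine
(numbered 341) and a flexible C-terminal hexapeptide tail
S~371~-G-S-X-Y-S~376~ whose position 374 (X = E, D, K or S) precedes the
acceptor tyrosine Y375.  The package covers:

1. model construction (tail grafting, variant mutation, iodination
   editing),
2. conformational sampling of the flexible degrees of freedom,
3. reaction-propensity geometry statistics,
4. acceptor-motif and conservation scanning of sequences, and
5. a thermodynamic layer (iodotyrosine pKa, pH-dependent deprotonation,
   coupling-pathway free-energy bookkeeping, variant ranking).

## Model construction

Tails are built in internal coordinates with the natural-extension
reference frame (NeRF): each atom is placed from three reference atoms by
bond length, bond angle and dihedral.  Backbone torsions of the built tail
default to the extended configuration &Phi; = &minus;120&deg;,
&Psi; = 120&deg; (&omega; trans); measuring the torsions on the built model
recovers the configured values to numerical precision, which the test suite
asserts to 10^-6^ degrees.  Bond lengths and angles are ideal values
(N&ndash;C&alpha; 1.458 &Aring;, C&alpha;&ndash;C 1.525 &Aring;,
C&ndash;N 1.329 &Aring;).  Hydrogens are omitted except the tyrosine ring
H&epsilon;1/H&epsilon;2, which anchor iodination.

Iodination replaces H&epsilon;1/H&epsilon;2 by iodines I1/I2 placed along
the C&epsilon;&ndash;H unit vectors at 2.10 &Aring;, the standard
aryl&ndash;iodine bond length (configurable via `buildConfig()`); the
residue is renamed TYD (di-iodo) or IYR (mono-iodo).  The iodine atom
naming and the C&ndash;I length are package choices; neither is dictated by
a community convention for these non-standard residues.  The edit is
strictly local: all other atoms are bit-identical.

Side chains for built or mutated residues start from the most common
rotamer and fall back through a short &chi;1 list on steric clash
(heavy-atom overlap below 2.0 &Aring;).  The four variant models share
bit-identical backbones and differ only in the residue-374 side chain.

### The synthetic scaffold

The default scaffold (`makeScaffold()`) is an idealized 25-residue
&alpha;-helix (&Phi; = &minus;57&deg;, &Psi; = &minus;47&deg;) whose
C-terminal residue is the donor tyrosine, renumbered 341, followed by a
three-glycine extended linker.  The geometry is chosen so that the grafted
tail's acceptor can physically reach the donor ring when the tail folds
back (the tail base sits about 13 &Aring; from the donor C&beta;), while
the fully extended build keeps the pair more than 24 &Aring; apart &mdash;
the same qualitative arrangement as a structured donor in an exposed helix
next to a flexible C-terminal acceptor region.  A user-supplied scaffold
(e.g. a maltose-binding-protein structure) is accepted by
`appendExtendedTail()` but never required; no download is needed to build
or test the package.

## The conformational sampler

The molecular-dynamics stage of the original analysis (explicit water,
particle-mesh Ewald, 100-ns trajectories) is out of scope at desk scale.
Its statistical role &mdash; producing distributions over the same
flexible degrees of freedom &mdash; is filled by a torsion-space
Metropolis Monte Carlo sampler:

* **Degrees of freedom.** &phi;/&psi; and side-chain &chi; of tail
  residues 371&ndash;376 plus &chi;1/&chi;2 of donor 341; the scaffold is
  frozen.  (The original simulations froze nothing, but their scaffold is
  a stable fold; this is a documented divergence.)
* **Moves.** One torsion per step, perturbed uniformly within a class
  width (25&deg; backbone, 60&deg; side chain).  With probability 0.2 the
  move is a full-range jump (&plusmn;180&deg;), and with probability 0.05
  every mobile torsion is re-randomized at once ("regrow").  All three
  move types are symmetric, so Metropolis acceptance
  exp(&minus;&Delta;E/kT) preserves the Boltzmann distribution; the
  jump/regrow mixture lets the chain hop between the entropically dominant
  extended basin and the compact contact basin within short runs.
* **Energy.** Pairwise Lennard-Jones (element-based parameters) plus
  Coulomb with distance-dependent dielectric &epsilon;(r) = 4r over all
  pairs at bond-graph separation &ge; 3, with smeared partial charges on
  the polar groups that matter for the proximity statistics (carboxylates,
  the lysine ammonium, the tyrosine hydroxyl, small iodine charges).  An
  attractive Gaussian well between the donor and acceptor ring centroids
  (depth 4 kcal/mol, centre 3.6 &Aring;, width 3 &Aring;) stands in for
  the aromatic-contact preference at the potential-of-mean-force level;
  its centre is the observed &pi;-contact distance.  Overlapping atoms
  return infinite energy rather than raising an error.
* **Conditions.** `Y_distal` (no iodines) and `DIT_distal` (both
  tyrosines TYD) start from the built extended conformation;
  `DIT_proximal` starts from the most probable proximal frame of a prior
  non-iodinated ensemble (modal bin of the O&zeta;&ndash;C&beta;
  distribution, lowest energy within the bin &mdash; the "most stable
  proximal conformation" is not defined operationally in the source
  analysis, so this modal-then-lowest-energy rule is the package's
  explicit choice), then iodinated.
* **Bookkeeping.** Temperature 300 K; frames recorded every 10 steps
  after a 10 % burn-in; three replica seeds by default.  A fixed seed
  reproduces an ensemble bit-exactly, and each stored frame energy equals
  the full potential recomputed on that frame.

The sampler's parameters were calibrated once so that, pooled over three
replicas of 2 &times; 10^4^ steps, every variant's
O&zeta;(375)&ndash;C&beta;(341) distribution is broad (interdecile range
well above 3 &Aring;) while still visiting the sub-6-&Aring; contact
region.  The tests assert exactly this qualitative regime; nothing in the
package claims numerical agreement with molecular-dynamics distributions.
What passing tests show is that the pipeline's statistics behave correctly
on ensembles with the right gross features &mdash; not that the stand-in
energy model reproduces real conformational thermodynamics.

## Geometry statistics

Distance series (C&beta;&ndash;C&beta;, O&zeta;&ndash;C&beta;, and the
carboxylate-carbon&ndash;O&zeta; proximity for the acidic variants:
C&delta; of glutamate, C&gamma; of aspartate) are histogrammed on
0.25-&Aring; bins (edges aligned to multiples of the width; mode = centre
of the maximum bin, leftmost on ties).  &pi;-stacking is classified from
ring centroids and best-fit-plane normals: contact within 5.0 &Aring; and
interplanar angle &lt; 30&deg; is *parallel*, &gt; 60&deg; is
*perpendicular* (T-shaped), anything else *none*.  The 3.6-&Aring;
&pi;-contact reference is observed; the 5.0-&Aring; contact cutoff and the
30&deg;/60&deg; bands are package choices, stated here because no
classification thresholds are given in the source analysis.  The
`reactiveFraction()` statistic is the fraction of frames within a cutoff
(default 6 &Aring; in the pipeline report).

## Sequence analysis

`scanAcceptorMotifs()` reports every tyrosine preceded by E or D, with
1-based indices honouring a `firstIndex` offset, so the engineered tail
numbered from 371 yields its single hit at 375 and the site-A flank NIFEY
numbered from 20 yields the acceptor at 24 (preproprotein numbering: a
19-residue signal peptide precedes it).  `columnConservation()` uses modal
frequency as the per-column score &mdash; the simplest statistic
consistent with a consensus display; an entropy-based score would be a
straightforward extension but is deliberately not the default.  Ties are
broken alphabetically and flagged, and a tied or non-acidic predecessor
column classifies a site as `mixed`.  The synthetic alignment generator
plants [E/D]Y column pairs at stated conservation into a uniform random
background (15 sequences &times; 2700 columns by default, mirroring a
vertebrate thyroglobulin alignment); real thyroglobulin background
composition, domain architecture and phylogenetic correlation are *not*
emulated, so conservation scores away from planted columns carry no
biological meaning.

## The thermodynamic layer

The pKa of an iodinated tyrosine phenol is referenced to phenol
(pKa 10.0) through the deprotonation free-energy shift &Delta;&Delta;G:

pKa = pKa~ref~ + &Delta;&Delta;G / (ln 10 &middot; R &middot; T)

with R = 1.98720425864083 &times; 10^-3^ kcal/(mol K) kept at full
precision so the worked examples are bit-stable, and T = 298.15 K (no
temperature is stated for the published estimates; standard state is
assumed and the parameter is configurable).  Shifts of &minus;2.10 and
&minus;4.64 kcal/mol give pKa 8.46 (MIT) and 6.60 (DIT).  The
Henderson&ndash;Hasselbalch fraction 1/(1+10^(pKa&minus;pH)^) then
quantifies the pH window: DIT is mostly deprotonated at pH 7.4 (fraction
0.86) and mostly protonated below pH 6, matching the known pH dependence
of the coupling reaction.

Quantum-chemical energies are *data* to this package, never computed:
species enter as a TSV table (species, energy, charge, spin) and pathways
as a signed-stoichiometry ledger.  `reactionDeltaG()` evaluates
products-minus-reactants per stage (multi-stage = sequential pathway, the
first stage forming the protonated-C&alpha; intermediate) with
charge-balance checking and Hess-additive arithmetic.  The packaged
synthetic tables encode only the qualitative orderings that the source
analysis states: the radical sequential step lies below the anionic one,
the concerted route is exergonic for all four variants, and the concerted
free energies rank the variants E &lt; D &lt; K &lt; S.  The magnitudes in
those tables are invented placeholders tagged `synthetic`; they are not
density-functional results.

## The pipeline and its report

`runPipeline()` executes build &rarr; sample (variants &times; conditions
&times; replicas) &rarr; statistics &rarr; thermodynamics and returns a
JSON-serializable report: per-cell distance-distribution summaries,
stacking-label counts, reactive fractions, carboxylate proximity (marked
`not-applicable` for K/S), per-replica diagnostics (frames, acceptance,
mean energy), a thermodynamic section, and provenance (seeds, config hash,
package version).  Replicas are pooled by concatenating frames; per-replica
summaries are retained.  Any failing cell is recorded with its error
message and the run continues.  `validateRunReport()` checks the report
against the packaged schema.  The package exposes this orchestration as R
functions; the functions, scripts and this vignette are the interface.

```{r, eval = FALSE}
report <- runPipeline(runConfig(
  variants = "E",
  conditions = c("Y_distal", "DIT_distal", "DIT_proximal"),
  sampler = samplerConfig(nSteps = 20000),
  replicaSeeds = c(101, 102, 103)))
writeRunReport(report, "run_report.json")
```

## Numerical choices and degenerate inputs

* Angles live in (&minus;180&deg;, 180&deg;]; a collinear atom triple
  makes a dihedral undefined and raises an error rather than returning
  NaN.
* Histogram bins are aligned to multiples of the bin width; the mode is
  the leftmost maximal bin.
* Coincident atoms in a distance series violate a validity invariant and
  are reported as such.
* Rings must be planar within an RMS residual of 0.2 &Aring; before
  stacking classification.
* An empty ensemble, an empty distance series, a gapped sequence passed to
  the motif scanner, and a ragged alignment all raise early, descriptive
  errors.

## Problem sizes

The shipped tests sample 2 &times; 10^4^ Monte Carlo steps per replica
(three replicas pooled) for the ensemble-level properties, 10^4^ recorded
frames for the uniform-marginal and reach properties, and 500-step runs
for smoke-level checks; these sizes were chosen as the smallest at which
the qualitative ensemble features stabilize.

## Known limitations

* The sampler is a stand-in: its implicit-solvent energy and mean-force
  ring attraction reproduce a qualitative regime, not molecular-dynamics
  observables.  No free energies are extracted from it.
* The scaffold is frozen; backbone relaxation of the donor helix is
  absent.
* Polar hydrogens are not modelled, so hydrogen-bond directionality is
  invisible to the energy.
* The conservation score is a modal frequency; it saturates for deep
  alignments and ignores residue similarity.
* Species energies are user-supplied; the package performs bookkeeping,
  never electronic-structure computation.
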