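---
title: "Integrative coarse-grained assembly from cross-link and contact restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative coarse-grained assembly from cross-link and contact restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlassemble)
```

## The problem

During *Bacillus subtilis* sporulation the intramembrane metalloprotease
SpoIVFB cleaves Pro-sigmaK; the membrane proteins BofA and SpoIVFA hold the
protease inactive until the right developmental signal. No experimental
structure of the inhibition complex exists. What does exist is sparse,
heterogeneous distance information: engineered-cysteine disulfide
cross-links between residue pairs of the partners (including pairs that
demonstrably do *not* cross-link), and residue-residue contacts predicted
from co-evolutionary couplings in paired alignments of interacting
proteins. `xlassemble` turns such data into coarse-grained structural
models: one bead per residue at the C-alpha position, assembled by
restrained stochastic optimization, with every step of the pipeline (from
alignment pairing to ensemble selection) reproducible and testable against
synthetic data with planted ground truth.

## The model and its energy

A model is a set of chains with one 3-D coordinate per residue
(`ca_model`). The score of a model under a restraint set is a weighted sum
of non-negative class energies; zero means every weighted restraint is
satisfied.

* **Cross-links** and **predicted contacts** are flat-bottom harmonic upper
  bounds on the C-alpha distance between two sites: zero inside the bound
  `u`, `(d - u)^2` beyond it. Because chemically equivalent copies of an
  oligomer cannot be distinguished experimentally, both sides of a pair
  restraint carry an equivalence set of chain copies and the energy acts on
  the **minimum distance over all copy combinations** (here: over the four
  protease subunits). Cross-links that were *not* observed (negative
  polarity) contribute no energy; they enter violation diagnostics and the
  contact curation step only, because non-cross-linking is weak evidence of
  distance, strong evidence only against predicted proximity.
* **Rigid groups** (helices, domains) restrain internal pairwise distances
  to reference values, so groups keep their shape but move freely as
  bodies.
* **Anchors** tether residues to reference coordinates with `k = 0.1`
  score-units/A^2 by default, the force constant used to keep refined
  models near the assembled C-alpha model.
* A **membrane slab** penalizes membrane-annotated residues outside
  `|z| <= 15` A (half-width configurable).
* **Chain bonds** (springs at 3.8 A between consecutively numbered
  residues) and **soft-core sterics** (quadratic penalty below 4.0 A
  between non-bonded beads) maintain chain integrity and excluded volume;
  the values are standard C-alpha-trace geometry.

The class weights default to 25 for cross-links, 0.25 for inter-protein
contacts and 0.1 for intra-protein contacts -- the relative weighting used
for the published inhibition-complex models -- with unit weights on the
structural classes. Score units are dimensionless; the literature's numeric
constants (25 / 0.25 / 0.1, k = 0.1, the 10-unit violation cutoff) are kept
verbatim even though the underlying energy functions are this package's
own, simpler forms rather than Rosetta's.

Everything is 1-based author residue numbering, keyed by `(chain, resno)`.

## Optimization protocol

`minimize()` is plain gradient descent with Armijo backtracking on the
total score (the flat-bottom terms are C1, so the score is everywhere
differentiable); the default 100 steps per call mirrors the protocol's
minimization length. `anneal()` alternates cycles of Metropolis
Monte-Carlo sampling -- rigid-body moves of whole chains plus single-bead
jitter -- with minimization, over a falling temperature ladder (default 5
cycles at kT = 5, 3, 2, 1, 0.5 score-units, 500 proposals per cycle).
Monte-Carlo sampling at temperature stands in for the short
elevated-temperature dynamics of the original protocol: the contract is
stochastic exploration followed by minimization, and true C-alpha dynamics
would require a force field the data do not determine. At every cycle
boundary the engine keeps the best post-minimization state seen so far
(a greedy restart), which makes the cycle-boundary score trace
non-increasing by construction.

`run_stage_plan()` executes the staged assembly: chains are introduced one
stage at a time (monomer, dimer, tetramer, substrate, truncation of the
substrate proregion, then each inhibitor), each newly added chain placed
with a random orientation 10 A outside the bounding sphere of the current
complex -- an unbiased, seeded choice. Only restraints whose residues are
all present are active in a stage, with ambiguous sides restricted to the
copies present so far. Removing residues (the proregion truncation) deletes
them together with every restraint touching them.

`build_ensemble()` repeats the plan `n_models = 8` times with consecutive
seeds and selects the model with the fewest cross-link violations. The
protocol specifies only that first key; ties are broken by lowest total
score, then lowest index, a deterministic completion. `place_zinc()` then
adds one catalytic zinc pseudo-atom per protease subunit at the centroid of
the three ligand C-alphas (residues 43, 47 and 137), with a 2 A clash
check; a geometric placement, not an energy minimization.

All randomness flows through a single seeded stream per run, so identical
configuration and seeds give byte-identical serialized results
(`serialize_assembly()` writes canonical JSON at fixed precision).

## Alignment tools and contact curation

`build_hybrid_msa()` pastes two alignments of interacting proteins row by
row, pairing sequences by an organism tag parsed from the FASTA header
after the first `|` (collisions keep the first occurrence, with a
warning); rows without a partner are dropped and logged. The reference row
receives a 20-glycine linker between the two sequences -- the insertion
used to keep a contact predictor from hallucinating couplings across the
pasted junction -- while homolog rows get gaps there to stay aligned.
`mask_linker()` then discards any prediction touching the linker columns
and re-indexes the rest to per-protein positions.

`curate_contacts()` applies, in the order the original protocol describes:
(1) keep predictions with probability **strictly** greater than 0.15;
(2) given a model, drop predictions whose per-contact restraint score
exceeds 10 score-units -- the per-contact score is the class weight times
the flat-bottom energy on the ambiguous minimum distance, i.e. exactly the
term the total score would add, substituting for the Rosetta-internal
score the published cutoff referred to; (3) apply a manual exclusion list
(contacts incompatible with cross-linking data). Upper bounds default to
10 A C-alpha-C-alpha for contacts and 12 A for disulfide-competent
cross-link pairs; neither value is stated by the protocol, both are
conventional for the respective data type, and both are configuration
fields.

`call_conservation()` implements the 70% identity rule: a column is
conserved when the modal non-gap residue appears in at least 70% of the
sequences. Whether gaps belong in the denominator is not specified in the
original rule; the strict reading (denominator = all rows) is implemented.
The threshold comparison is `>=` ("at least 70%") while contact curation
uses `>` ("higher than 0.15"), mirroring the respective wording. Ties
between equally frequent residues resolve to the alphabetically first,
for determinism.

## Quantification

`cleavage_ratio()` (`product / (substrate + product)`) and
`complex_fraction()` (`complex / (monomer + dimer + complex)`) are the
band-intensity formulas of the cleavage and cross-linking immunoblot
assays. `fit_trend()` fits an ordinary least-squares straight line to the
pooled replicate points of a ratio time course; the source figures draw
straight trend lines, and no other functional form is implied, so linear
is the implemented (and flagged) reading. `compare_ratios()` wraps the
two-tailed t-test used for condition comparisons.

## The synthetic benchmark

`make_reference_complex()` builds ideal alpha-helical C-alpha traces
(1.5 A rise, 100 degrees per residue, 2.3 A radius, hence ~3.8 A between
consecutive residues) packed on a 10 A hexagonal lattice of helix axes
with antiparallel alternation -- clash-free by construction. Helices of a
chain are separate rigid segments with a numbering gap, as across a chain
break. The default spec *is* the benchmark condition used everywhere: 2
chains x 3 helices x 15 residues (~90 residues), membrane half-width 15 A,
12 planted true-positive cross-links with no false positives, and a
contact map with true-positive rate 0.8 and false-positive rate 0.05.

`simulate_crosslinks()` draws true positives uniformly from inter-chain
pairs within the bound, true negatives and decoys from pairs beyond
`bound + margin` (margin 8 A keeps the classes unambiguous), and keeps
ground-truth labels for the oracles. `simulate_contact_map()` draws true
contacts' probabilities from Beta(5, 2) scaled to (0.15, 1] and false
ones from Beta(2, 5) scaled to (0, 0.3] -- overlapping but separable
around the 0.15 threshold, so curation tests are informative.
`simulate_msa()` plants the modal residue of each column in
`floor(target x n_rows)` rows; the floor (rather than nearest-integer
rounding) guarantees that a column conserved at the 70% call is exactly a
column whose target reached 0.70, including at the boundary (target 0.69
with 20 rows gives 13/20 = 0.65, not 14/20 = 0.70). `scramble()` applies
seeded rigid per-chain transforms (rotation plus translation up to the
magnitude) without touching internal geometry.

What the generator does *not* emulate: real loop flexibility (helices are
ideal and rigid), non-helical secondary structure, the distance geometry
of disulfide chemistry beyond a C-alpha bound, correlated errors in
contact prediction, and alignment gaps or phylogenetic structure beyond
per-column identity control. Passing the recovery benchmark therefore
shows that the optimizer and restraint machinery can reassemble a complex
whose restraint network is as informative as the planted one -- not that
any particular experimental network determines a unique structure.

## Numerical choices and limitations

* Minimizer: gradient descent with backtracking, not L-BFGS -- simple,
  dependency-light, and sufficient at these sizes; the `1e-6` gradient
  norm tolerance and maximum initial step of ~1 A per coordinate are
  conservative.
* The gradient of a minimum-over-pairs term flows through the argmin pair
  only (the function is piecewise smooth; descent is unaffected).
* The compiled score/gradient (Rcpp) and the plain-R dispatch are two
  independent routes over the same semantics; the test suite holds them to
  1e-9 relative agreement, and a brute-force re-derivation in the tests
  checks both.
* Benchmark problem sizes (a ~90-residue recovery complex, ensembles of 8
  over 10 seeds, 500-record contact maps, 20-row alignments) are the
  package's standard desk-scale conditions; the staged 7-stage plan is
  exercised on toy helix geometry.
* PDB output carries 3-decimal coordinate precision; round-trips are exact
  to that precision. Insertion codes, mmCIF and multi-model files are out
  of scope.
* The assembly engine models C-alpha geometry only: no side chains, no
  all-atom refinement, no explicit membrane. Zinc placement is geometric.
  Conclusions at side-chain resolution (e.g. which rotamer contacts which)
  are outside what these models can support.
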