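---
title: "Scaffold architecture analysis with scaffscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold architecture analysis with scaffscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Medicinal chemists compare compound collections by their *scaffolds* — the
ring-containing cores left after stripping substituents — because rings fix a
molecule's shape and are the unit of "scaffold hopping" in lead optimization.
A collection dominated by a few heavily reused cores offers less chemical
novelty than one whose molecules spread over many cores, and two collections
can share cores even when no individual molecule is shared. `scaffscape`
implements a complete scaffold-architecture workflow: decomposition of every
molecule into standard scaffold representations, a hierarchical Scaffold Tree,
frequency-based diversity statistics, fingerprint-based cross-library
similarity, and cluster/treemap visualization of scaffold space.

## Scaffold representations

For a molecule with at least one ring the package computes (see
`decompose()`):

* **Murcko framework** — the union of all ring systems and the linkers that
  connect them; equivalently, the molecule after iteratively pruning terminal
  side-chain atoms. Atoms attached to a ring or linker atom by a double or
  triple bond (carbonyl oxygens being the common case) are *retained*: the
  Scaffold Tree convention keeps functionalized ring systems intact, so a
  lactone keeps its carbonyl while an acetyl side chain is pruned whole.
* **Graph framework** — the Murcko framework with every atom relabeled carbon
  and every bond set to single: a pure topology signature.
* **Rings** — the individual rings of a smallest set of smallest rings
  (SSSR); the count always equals the circuit rank
  (bonds − atoms + components), which is basis-independent.
* **Ring assemblies** — contiguous ring systems: connected components after
  deleting every bond that sits in no ring, plus retained exocyclic
  double-bond atoms.
* **Bridge assemblies** — the ring assemblies in which some pair of SSSR
  rings shares two or more bonds. Norbornane qualifies; naphthalene (one
  shared bond) and spiro systems (one shared atom) do not.
* **Linkers** — acyclic atoms on a direct path between two ring systems. A
  direct ring–ring bond (biphenyl) has no atoms on the path and therefore
  emits no linker fragment. Linker fragments carry their retained exocyclic
  atoms, so an amide linker keeps its oxygen.
* **Side chains** — every remaining acyclic substituent, reported with its
  attachment point marked by a dummy atom (`*C` is a methyl on some core) and
  counted once per occurrence.

Scaffold identity is the stereo-stripped canonical SMILES of the fragment;
molecule identity (used by `deduplicate()`) keeps stereochemistry. The
asymmetry is deliberate: cis/trans isomers are different molecules, but
scaffold counting across libraries must not fragment on stereo labels that
are annotated inconsistently between sources.

## The Scaffold Tree

`build_chain()` reduces a Murcko framework one peripheral ring at a time
until a single ring remains. Level 0 is that final ring; Level k holds k+1
rings; the top level (n−1 for an n-ring framework) is the framework itself.
"Ring" always means one circuit-rank unit, so fused and bridged systems
descend one basis ring per step, and a ring whose removal would disconnect
the scaffold is never peripheral.

The original Scaffold Tree publication resolves removal order with a long
prioritization cascade; published analyses typically delegate to one of
several tool implementations whose cascades differ in detail. This package
fixes a deterministic five-rule cascade, chosen to honour the published
intent (remove the least scaffold-like ring, retain the most functionalized
system) while being short enough to verify exhaustively:

1. remove three-membered heterorings first;
2. prefer the removal that deletes the fewest acyclic linker bonds;
3. remove the ring with the fewest heteroatoms;
4. remove the larger ring;
5. break remaining ties by the lexicographically smallest canonical SMILES
   of the resulting parent scaffold.

Rule 3 is what keeps the pyridine of quinoline and the pyrrole of indole as
Level 0. The test suite contains an oracle that enumerates *every* peripheral
removal order on multi-ring fixtures and applies the cascade independently;
the implementation must reproduce it exactly. Chains are computed after
re-canonicalizing the framework, so the result does not depend on how the
input molecule was written. A different published cascade could shift
Level-1/Level-2 counts slightly; this is an acknowledged degree of freedom of
the method, not of this implementation.

Each molecule contributes exactly one chain (a path, not the tree of all
alternatives), matching how level censuses are reported: the Level-k total
counts molecules possessing a Level-k scaffold and is therefore non-increasing
in k.

## Diversity statistics

`count_frequencies()` tallies occurrences per distinct scaffold;
`csf_curve()` sorts counts descending (ties broken by the scaffold string so
curves are reproducible) and accumulates them as the percentage of the
library covered by the top-N scaffolds. The denominator is always the full
prepared library, not only the molecules bearing the representation: this
keeps "percentage of molecules with a Level-2 scaffold" and "coverage of the
top-N Level-2 scaffolds" on the same scale, with the latter capping at the
former. A redundant library shows a steep curve; a diverse one approaches
the diagonal that an all-singleton library would produce.

## Fingerprints and cross-library overlap

`circular_fingerprint()` is an ECFP-style circular fingerprint: each atom
starts from an invariant tuple (element, heavy-atom degree, formal charge,
implicit hydrogen count, ring membership) and is iteratively re-hashed with
its sorted (bond order, neighbour hash) pairs out to radius 3 (diameter 6).
Features are kept as sparse (radius, hash) pairs with presence semantics —
no folding to a fixed width — so "similarity exactly 1" in an overlap table
means identical feature sets rather than a collision artefact. Different
toolkits' circular fingerprints differ in their atom invariants, so absolute
overlap counts are implementation-sensitive; the structural properties
(monotone columns, the cutoff-0 row equalling the unique scaffold count) are
what the package asserts and tests.

`cross_library_overlap()` computes, for each scaffold of library A, the
maximum Tanimoto similarity to any scaffold of library B, and tabulates
counts at a descending cutoff grid. The cutoff-1 row uses identity
semantics; the cutoff-0 row is |A| by definition and equals the library's
unique scaffold count — the structural identity that ties an overlap table's
bottom row to the fragment census.

## Clustering and treemaps

`cluster_scaffolds()` performs maxmin (sphere-exclusion style) selection:
the number of centers is fixed at ⌈N / target⌉ with a default target average
cluster size of 50 scaffolds; the first center is drawn uniformly under the
seed, each subsequent center maximizes the minimum 1 − Tanimoto distance to
all chosen centers (ties by scaffold string), and every scaffold joins its
nearest center (ties toward the lower cluster index). The procedure is
seed-dependent only through the first center; re-running with the same seed
reproduces the model bit-exactly, and a different seed changes assignments
but never the center count. Clustering sees each unique scaffold once;
frequencies enter only the display. Whether "average cluster size" should
count scaffolds or parent compounds is ambiguous in published descriptions;
this package counts scaffolds (configurable via `target_avg_size`).

`layout_treemap()` renders the model as nested squarified rectangles:
cluster regions sized by summed member frequency, scaffold rectangles by own
frequency. Rectangles rather than circle packs because a rectangle layout
tiles exactly: with continuous coordinates the area shares equal the
frequency shares to floating-point precision, which the tests check
arithmetically on the exported JSON.

## The synthetic library generator

Published scaffold-architecture studies rest on proprietary databases, so
`generate_library()` provides libraries with *planted, fully known* scaffold
structure. Molecules are assembled as linear chains of ring units from a
curated pool (~44 units spanning simple aromatics and aliphatics, fused
bicyclics, bridged cages and spiro systems), joined by linker fragments or
direct bonds, and decorated with acyclic side chains at framework atoms with
free valence. Because assembly is linear and side chains attach by single
bonds to substitutable positions, the planted assembly *is* the molecule's
Murcko framework — the generator verifies this by construction for every
scaffold it emits — and recovery by the pipeline is exact, not approximate.

Defaults emulate a drug-like screening collection: Zipf-distributed scaffold
frequencies (exponent 1.2 — a few heavily populated cores plus a long tail),
one to six rings per scaffold with proportions chosen so that roughly 93% of
molecules have at least two rings and 70% at least three (the shape seen in
published level censuses of drug-like libraries), and a Poisson(1.2) number
of side chains per molecule. A "diverse" configuration (many scaffolds,
uniform frequencies) and a "redundant" one (few scaffolds, Zipf) reproduce
the qualitative contrasts the method is designed to expose: unique-framework
counts, CSF steepness and cluster counts all separate the two.

The manifest records each molecule's planted scaffold and the implied
Scaffold Tree chain (computed once per unique scaffold structure at
generation time). `manifest_census()` aggregates the manifest independently
of the pipeline, so planted-recovery tests compare two different routes to
the same counts: manifest bookkeeping versus parse → standardize → prune →
census on the emitted SMILES.

What the generator does *not* emulate: tautomerism, stereochemistry, charge
states, synthesizability, and the idiosyncratic chemistry of real databases.
Passing the planted-recovery tests therefore demonstrates that the pipeline
machinery is exact on well-formed organic molecules, not that any particular
real library would show a particular diversity profile.

## Library preparation

`read_library()` accepts SMILES (one record per line, optional id) and SDF
V2000. Standardization keeps the largest covalently connected fragment,
drops records without carbon, clears isotope labels and recanonicalizes —
a deliberately minimal, documented protocol; tautomer canonicalization and
charge-state enumeration are out of scope. The molecular-weight cutoff is a
strict `mw < 600` Da (a record at exactly 600.0 is excluded).
`match_mw_distribution()` aligns MW distributions by largest-remainder
integer quotas over fixed-width bins (default 25 Da over (0, 600), i.e. 24
bins; the sources this workflow follows state no bin width) with per-bin
uniform sampling, quota shortfalls redistributed to the nearest bins with
capacity, and the achieved Kolmogorov–Smirnov distance reported.

## Numerical and engineering choices

* **Chemistry I/O** is delegated to ChemmineR/ChemmineOB (OpenBabel):
  SMILES/SDF parsing and canonical SMILES generation. Aromatic systems are
  held kekulized internally; fragments whose inherited kekulé pattern is
  broken by ring removal are exported with aromatic bond flags plus explicit
  bracket hydrogens so OpenBabel re-kekulizes them (this is why removing one
  anthracene ring yields naphthalene, not a cyclohexadiene pattern).
  OpenBabel may print "Failed to kekulize" warnings for intermediate
  fragments; these are expected and handled by a kekulé-order fallback.
* **SSSR** is a Horton-style minimum cycle basis per ring system: candidate
  cycles from shortest paths, sorted by size with deterministic tie-breaks,
  reduced greedily over GF(2). An exhaustive cycle-enumeration oracle checks
  it on every fixture molecule. SSSR is not unique for some cages; all
  counting statistics use the basis *size* (circuit rank), which is.
* **Individual rings** cut from a fused kekulized aromatic keep their parent
  bond orders, so one naphthalene ring canonicalizes to a cyclohexadiene-like
  SMILES rather than benzene. Extraction is deterministic, so counting is
  stable; lone aromatic rings that form complete systems re-aromatize.
* **Molecular weight** is computed from standard atomic masses plus an
  implicit-hydrogen valence model (C4, N3, O2, S2, halogens 1; charge raises
  N and lowers O), cross-checked against OpenBabel in the tests.
* **Determinism**: every sampling function takes an explicit seed and uses
  an isolated RNG scope; identical seeds give bit-identical libraries,
  models and report files.

## Problem sizes

The bundled validation exercises the pipeline at the scale a desk analysis
needs: decomposition oracles on ~70 hand-built molecules, chain invariants
and planted-frequency recovery on 5,000-molecule synthetic libraries (50
Zipf scaffolds, and 2,000 uniform scaffolds for the diversity contrast),
overlap tables at 200 × 200 scaffolds, clustering at N = 120 with a
brute-force oracle at N = 30. The acceptance script runs the end-to-end
pipeline on two 1,500-molecule libraries. All sizes are package choices made
to keep a full validation run on a laptop pleasant; every stage scales to
libraries of tens of thousands of molecules in minutes.

## Known limitations

* Ring perception is SSSR-based; alternative schemes (relevant mostly to
  macrocycles and complex cages) are out of scope.
* The removal cascade is one fixed, documented choice among the published
  variants; absolute Level-k counts can differ between tools.
* Fingerprint hash collisions are possible in principle; with sparse
  unfolded features they are negligible at library scale, and the "=1" rows
  of overlap tables compare feature sets, not structures.
* SDF stereo wedges are not perceived; stereo identity is preserved only
  through SMILES input.
* The generator's linear assembly never produces branched ring-system
  topologies (a ring system bonded to three or more others), which real
  libraries do contain; the decomposition and tree code handle them, but
  planted ground truth does not cover them.
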