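---
title: "Automated extraction of reaction templates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated extraction of reaction templates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(templater)
```

## The problem

Kinetic model generators and retro-synthesis tools both consume *reaction
templates*: a generalized blueprint that states which substructures the
reactants must contain and a *recipe* of graph edits (bond formations and
scissions, bond-order changes, radical/charge/stereo changes) that turns
matched reactants into products. Writing templates by hand is tedious and
incomplete; `templater` mines them automatically from three kinds of
reaction sources: structured identifier lists (SMILES/InChI per reaction),
directories of MDL RXN (V2000) files, and CHEMKIN-format mechanisms whose
species declarations carry an identifier comment.

The pipeline has four stages: database interpretation (readers plus a
balance filter), atom–atom mapping (AAM), extraction of the reactive center
and its changes, and formalization into SMARTS patterns with recipe and
constraints. A template application engine closes the loop: every extracted
template is replayed on its own reactants and must regenerate the recorded
products.

## Molecular model

Molecules are attributed graphs: atoms carry element, formal charge,
unpaired-electron count and an optional stereo descriptor; bonds carry an
integer (Kekulé) order, an aromaticity flag and an optional E/Z tag.

Three representation choices matter downstream:

* **All hydrogens are explicit.** Hydrogen-abstraction and hydrogen-shift
  templates act on hydrogens, so hydrogens must be mappable atoms. The
  SMILES/InChI readers add them on import.
* **Aromatic systems are Kekulé-localized** for change detection (mapping
  needs a localized electron picture); atoms are re-marked aromatic only
  when SMARTS is emitted.
* **Atom indices are 1-based throughout.** R and every graph tool it ships
  with (igraph) are 1-based; RXN files are 1-based too, so no index
  translation exists anywhere in the package.

Canonical identity (`canonical_key()`) is an InChI-style layered string
built from a BLISS canonical labeling with bond orders encoded as colored
edge-subdivision vertices. No InChI library exists in this R stack, so the
identifier is *InChI-like*, not a standard InChI; what the pipeline needs
from it is exactly the paper-level contract: equal keys iff isomorphic
(respecting element, charge, unpaired electrons, bond orders), with an
explicit unpaired-electron layer so a radical never collides with its
closed-shell parent — the known failure mode of fingerprint identifiers. A
coarse fingerprint key (formula + degree histogram) remains as fallback when
canonicalization fails.

The InChI *reader* supports single-component standard InChIs with
formula/c/h layers. An InChI stores no bond orders; they are reconstructed
by a small backtracking solver that distributes valence deficits over the
heavy-atom skeleton, maximizing saturation, so closed-shell inputs come back
closed-shell and leftover deficits become unpaired electrons. Mobile-H
groups and charge layers are rejected with a clear error (use SMILES for
those species).

## Atom–atom mapping

The mapper is a plug-in: any function from a reaction record to a (possibly
partial) atom map can be used, and pre-mapped RXN input bypasses computation
entirely. The built-in baseline mapper is exact on the molecule sizes this
package targets:

1. Branch-and-bound over element-preserving heavy-atom bijections. The
   bound uses per-pair "definitely changed" costs (radical/charge mismatch
   or different neighborhood element/order profile), which prunes identical
   and near-identical mappings immediately.
2. Hydrogens are completed optimally per heavy assignment: each heavy pair
   keeps `min(#H, #H')` of its own hydrogens, and the few leftovers (the
   migrating or free hydrogens) are assigned by exhaustive permutation.

The objective is lexicographic: first minimize the number of atoms whose
bonding changed, then the number of changed bonds. The secondary criterion
is what picks, e.g., the Diels–Alder mapping with two bond formations and
four order changes over an equally atom-cheap but bond-noisier alternative.
Ties beyond that break deterministically by canonical atom rank, so reruns
are byte-identical.

**Resonance.** For records containing delocalizable radicals, every
localized structure (allylic radical shifts, capped at 16 per molecule and
64 combinations per reaction) is tried on both sides and the combination
with the fewest reactive atoms wins. This is what maps a butenyl-radical
recombination through its two *primary* radicals rather than the secondary
localizations an identifier reader returns.

**Symmetric gap completion.** When a plug-in mapper leaves exactly two atoms
of one element unmapped on each side and the two atoms on at least one side
(reactants checked first) sit in identical chemical environments, the pair
assignment retaining the most mapped (neighbor, bond) relations is added and
the status becomes `heuristically_completed`. Environment identity uses the
subgraph-radius criterion: same eccentricity and isomorphic rooted shells at
every radius (`i = 1..r` within one molecule, `i = 0..r` across molecules).
All other gap patterns — nothing mapped, extra lone atoms, no symmetry —
are left untouched; those records are not analyzed further.

**Known limitation (inherited, deliberate).** A hydrogen shift between two
species of the same canonical identity (1-butyl → 1-butyl via a 1–4 shift)
is indistinguishable from the identity reaction for *any* computed mapping;
only pre-mapped input preserves such templates. Likewise two shifts of
different span between the same species pair are linked as reverse
templates. Both behaviors are documented consequences of the species-level
reverse definition and are preserved, not patched.

## Reactive center and recipe

With a complete accepted map, every mapped atom pair is compared: neighbor
sets (by element *and* mapped index), bond orders, unpaired electrons,
charge, stereo. Stereo comparisons require descriptors on both sides — an
atom gaining or losing an *undefined* descriptor is not a change, since
identifiers routinely omit stereo and spurious changes would flood the
template table.

The reactive center is the set of changed atoms. For intramolecular
reactions it may be disconnected, so per molecule the package runs BFS
shortest paths between all reactive-atom pairs, builds the complete weighted
graph, takes a minimum spanning tree (Kruskal, edges pre-sorted by weight
then canonical endpoint ranks) and realizes each chosen edge by the
lexicographically smallest shortest path. Path atoms join the center labeled
`connector`. Consistent tie-breaking matters because template equality
compares center graphs verbatim. With the (default-on) hetero option, every
non-C/non-H atom bonded to a reactive atom joins as `hetero_expansion`,
making templates more specific; switching it off collapses hetero-adjacent
variants of a family into one template. Connector and hetero atoms are
emitted as typed atoms with full annotations (the wildcard alternative is
noted as future work).

A mapping in which some radical-bearing reactant has no radical atom in the
center is construed incorrect (`mechanism acceptable` check) — radicals
react via the radical. The one systematic exception is hydroperoxyl
elimination (ROO• → olefin + HOO•), which computed mappings consistently
render through a four-membered cyclic transition state, in either of two
guises: hydrogen taken from the peroxy-bearing carbon, or the two oxygens
swapped so the radical appears unchanged. Both are detected via the implied
transition-state ring size and remapped to the five-membered ring: the
carbon-bearing oxygen maps to the product radical oxygen and the hydrogens
are re-completed, which forces the leaving hydrogen onto the β carbon.

## Templates

A template stores per-reactant center fragments (atoms annotated with
element, charge, unpaired electrons, neighbor count X and valence v measured
in the source molecule, role label) plus the recipe in a fixed action order
(breaks, order changes, forms, then electron/charge/stereo changes).

*Equality* is label-preserving isomorphism of centers with item-for-item
identical recipes, implemented as string equality of a canonical
serialization: atoms colored by all annotations and their atom-level
actions, real bonds colored by order and bond-level actions, bond formations
added as virtual colored edges. Deduplication is therefore hash-like and
order-independent; stereo-only actions are excluded from the signature so
stereo-only reactions collapse to status `identical` (their stereo items are
preserved internally).

*Reversibility* is deliberately species-level, two-part: some source
reaction of one template has products equal (by canonical keys) to the
reactants of a source reaction of the other and vice versa, and both
templates must regenerate their own products when applied. Self-inverse
templates (symmetric hydrogen transfers) link to themselves and are not
counted as "reverse", which is why reverse counts sit slightly below half
of the table.

*SMARTS.* Center patterns start from the fragment connectivity and add `X`
(neighbor count) and `v` (valence) to every atom, explicit bond symbols, and
re-identified aromatic atoms; hydrogen is written `#1` (bracket `H` is a
count primitive in SMARTS). Per-atom patterns permute the writing order so
the described atom comes first. Matching inside the package is structural
(colored subgraph isomorphism with an induced-embedding filter) and the
emitted strings are cross-validated against RDKit in the test suite.

*Constraints.* One global constraint caps molecule size at the largest
molecule of the analyzed corpus (heavy atoms); each reactant gets a
single-electron cap equal to its source reactant's radical count. The
kinetics block is an empty group-additivity placeholder for the user to
fill — kinetics extraction is out of scope.

*Classification* is rule-based on recipe shape and molecularity: hydrogen
abstraction (sub-labeled by the abstracting element) vs intramolecular
hydrogen shift, beta scission vs radical addition (bond scission/formation
coupled to a π-order change with radical migration), recombination,
hydroperoxyl elimination, Diels–Alder cycloaddition (two σ formations, four
π-order changes, closed shell), closed-shell substitution, `identical`,
`other`.

## Synthetic corpus: what it emulates, what it does not

`generate_synthetic_corpus()` draws balanced, fully mapped, ground-truth
labeled records from eight family generators: hydrogen abstraction (random
C1–C4 substrates, optionally decorated with OH/Cl at probability 0.25, the
value chosen once as a realistic hetero incidence for a small pyrolysis-style
network; abstractors H•/CH3•/OH•/C2H5•), 1–k hydrogen shifts (C3–C5
1-alkyl radicals), beta scissions and radical additions (each the reverse
family of the other), radical recombinations, hydrolysis-type substitutions
(R–Cl + H2O), Diels–Alder cycloadditions (optionally methylated diene and
dienophile), and hydroperoxyl eliminations (with an option to emit the
wrong four-ring mapping, exercising the corrector). Defaults are uniform
family proportions, seed 42.

The generator emulates the *reaction structure* of small-radical pyrolysis
and simple organic chemistry: correct stoichiometry, radical bookkeeping,
known mappings, known families. It does not emulate thermochemical realism,
rate-weighted family frequencies, aromatics ring chemistry, charged species,
or mapping noise — so a green round-trip result establishes that extraction,
formalization and application are mutually consistent and family-faithful on
clean inputs, not that the mapper would survive a noisy external database
unscathed. Test reactions (25 variants per base reaction by default) replace
non-center hydrogens with substituent fragments (methyl, ethyl, vinyl,
hydroxyl, chloride) symmetrically on both sides through the map; hetero
fragments are never attached adjacent to the center so the hetero-expanded
template stays invariant too.

## Numerical and degenerate-input choices

* Resonance caps: 16 structures/molecule, 64 combinations/reaction; on
  overflow the input localization is used and logged.
* The brute-force leftover-hydrogen search is capped at 5 atoms; beyond
  that hydrogens are assigned first-fit (they are all changed in that
  regime).
* Balance checking includes net charge, not just element multisets.
* CHEMKIN reversible lines (`=`/`<=>`) import as forward-only records; a
  chemically present reverse line is its own record, which is exactly what
  feeds the reverse-template detector. DUPLICATE lines each count once.
* Identifier-list delimiters: `" >> "` between sides, spaced `" + "` or `.`
  between species (spaced, so bracket charges like `[NH4+]` survive).
* Molecules with undefined atoms (generic "R" groups) are rejected by the
  readers and logged.
* Empty corpora flow through every stage and produce empty, well-formed
  outputs.

## Known limitations

Beyond the inherited mapping limitations above: no 3D/conformer handling,
no tautomers, no charged-resonance enumeration (neutral radical
delocalization only), V2000 RXN only, no kinetics or group-additivity
regression, and the classifier's sub-labels cover the families the
generators produce — exotic recipes fall into `other` rather than being
mislabeled.
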