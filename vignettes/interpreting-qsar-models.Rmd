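---
title: "Interpreting binary QSAR classifiers with feature networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting binary QSAR classifiers with feature networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragnet)
```

## The model and its assumptions

fragnet explains the prediction of an arbitrary binary classifier by
observing how the model behaves on sub-features of the query molecule. The
method rests on two domain assumptions appropriate for reactivity-driven
endpoints such as Ames mutagenicity:

1. activity of a compound can be attributed to the presence of a structural
   feature; and
2. inactivity arises either from the absence of any activating feature or
   from the deactivation of every activating feature by its molecular
   context.

Nothing about the classifier is assumed beyond determinism and a
feature-vector interface (`predict_fv`), and the interpretation never alters
the prediction: the network root is the full query and keeps the plain model
output. What the method *cannot* see is also fixed by these assumptions:
models built on global properties (logP, molecular weight) are not
interrogable, because sub-features must map to atoms and bonds.

Two enumeration routes produce the sub-features:

* **Feature-vector route.** Subsets of the set bits of a structural-key
  fingerprint. For `n` set bits there are `2^n - 1` non-empty combinations;
  the all-zero combination is never instantiated as a node because it has no
  structural meaning. Enumeration is exhaustive up to `prune_level` bits per
  combination (default 4), and the full combination is always appended so
  the query itself is a node whatever the pruning. Disconnected bit
  combinations are possible here by design.
* **Structure route (default).** Connected fragments from a reduced graph
  (below). Fragments are connected by construction, rings are never broken,
  and the fingerprint of a fragment is computed on the fragment itself, so
  hashed fingerprints become usable: the fragment, not the bit, carries the
  atom mapping.

## Reduced-graph fragmentation

The molecule is condensed into structural units with precedence
**ring > functional group > linker**:

1. every SSSR ring is one unit (fused rings are separate units connected
   through their shared atoms);
2. functional groups are matched from the unit-flagged patterns of the key
   library on atoms not already claimed by rings, longest pattern first,
   ties by lowest atom id;
3. every remaining atom is a single-atom linker unit.

Every connected subset of units (up to `max_depth`, unlimited by default and
guarded by a 25-unit cap) expands back to a molecular fragment: the union of
unit atoms plus all internal bonds, with attachment points closed by
implicit hydrogens and aromatic flags retained so ring fragments stay valid
standalone molecules. For 1-nitronaphthalene (units: two fused rings and the
nitro group, a path in the reduced graph) this yields six fragments
including the query; a path of *m* units yields `m(m+1)/2` fragments, which
the test suite verifies against an exhaustive connected-subset oracle.

The granularity of units bounds the resolution of any explanation: no cause
smaller than one unit can ever be reported, and a model that truly keys on
"nitro attached to any aromatic carbon" will be reported as "nitro plus this
particular ring".

## The six assessment types

After every node is predicted, nodes are classified bottom-up (ascending
payload size) by rules that read raw predictions of parents/ascendants and
assessments of already-visited descendants:

* inactive node: `DEACTIVATING` if some child is predicted active, else
  `IGNORE`;
* active node, in precedence order: `DEACTIVATED` (an inactive parent
  exists), `ACTIVITY_IDENTIFIED` (an ACTIVATING descendant exists),
  `NEGATED` (all parents active but an inactive ascendant exists),
  `ACTIVATING` (otherwise — the lowest non-deactivated active feature).

The precedence between `ACTIVITY_IDENTIFIED` and `NEGATED` is a genuinely
open corner of the rule set: the rule set as stated does not resolve a
node that has both an ACTIVATING descendant and an inactive ascendant.
fragnet places `ACTIVITY_IDENTIFIED` first so that a node sitting above an
established activation is never relabelled as negated; the package treats
this as its own design choice and documents it here. A single bottom-up pass
suffices because ACTIVATING decisions depend only on already-visited
descendants and on raw predictions above; the test suite nevertheless
verifies equivalence against an independent fixpoint evaluation of the rules
on ~1000 random networks.

Two structural consequences follow from the rules and are asserted as
invariants: a network contains an ACTIVATING node iff the root is predicted
active, and an ACTIVATING node never has an ACTIVATING descendant.

Confidence values are carried through and exported but never participate in
classification.

## Summary, highlights and condensation

The summary maps assessments back to query atoms and bonds: one highlight
per ACTIVATING node and one (deactivated, deactivating) pair per
DEACTIVATING-parent/DEACTIVATED-child edge. For the deactivating side the
highlight is reduced to the *added context* (parent atoms minus child
atoms): in the worked ortho-acid example the deactivated aromatic amine is
highlighted as amine + ring and the deactivating context as the carboxylic
acid alone, which matches how a chemist reads a localised deactivation.

Symmetric or nested contexts can produce chains — a feature deactivated,
re-established higher up, then deactivated again. `condense_deactivations()`
(opt-in, not applied by default) keeps only the pair whose deactivation
occurred in the largest context: a pair is dropped when another pair's
deactivated node is an ascendant of its deactivating node.

## Fingerprints and the subset property

Two schemes are provided:

* **Structural keys** (default): ~40 shipped patterns in a restricted SMARTS
  dialect, each bit traceable to match witnesses (atom/bond sets). The
  dialect is deliberately **monotone** — element, aromaticity, charge, bond
  order and connectivity only; no H-count, degree or negation primitives.
  Monotonicity makes the fragment-subset property (`fp(fragment) ⊆
  fp(parent)`) a theorem rather than an empirical accident: any match inside
  an induced subgraph is a match inside the parent. This is why the shipped
  "secondary/tertiary aromatic amine" keys are expressed through attached
  carbon substituents rather than H-counts, and why the amine patterns
  constrain the nitrogen to be uncharged (`[N+0]`) so they cannot fire on
  nitro nitrogens.
* **Hashed paths**: simple heavy-atom paths up to `max_depth = 6` bonds,
  labelled with element/aromaticity/charge and bond order, canonicalised by
  lexicographic direction, hashed onto `n_bits = 1024` positions (a power of
  two). Bits are not individually traceable; the scheme exists for the
  structure route, where the fragment supplies the mapping. Every fragment
  path is a parent path, so the subset property holds here too.

## Chemistry kernel: scope and numerical choices

No R cheminformatics toolkit is available in the supported environment, so
the package implements the minimum it needs; RDKit (via the system python)
is used in the test suite only, as an independent oracle for heavy-atom,
aromatic-atom and ring counts.

* **SMILES/MOL dialect**: organic subset, bracket atoms with charges and
  explicit H counts, branches, ring closures including `%nn`, dot-separated
  components, V2000 MOL blocks. Stereochemistry tokens are parsed and
  stripped (interpretation operates on constitution only); isotopes and atom
  maps are dropped.
* **Aromaticity**: perceived over SSSR rings of size 5–6 with an electron
  count — an atom contributes one electron via a multiple bond to a ring
  atom, two as a heteroatom lone pair, and a ring is aromatic at a count of
  six. Exocyclic double bonds contribute nothing, so quinones stay
  non-aromatic. This is narrower than a full Hückel treatment (no fused
  macro-ring perception, no charged-ring aromaticity) and is documented as a
  known limitation; it is exact for the chemotypes the package generates and
  tests.
* **SSSR**: shortest cycle through every bond, then a smallest-first basis
  under GF(2) independence, sized `|E| - |V| + components`.
* **Canonical SMILES**: Morgan-style iterative refinement of an invariant
  (element, aromaticity, charge, degree, H count) with deterministic
  tie-splitting, then a DFS emit that always follows the lowest canonical
  rank. Ranks are compared through zero-padded strings so ordering is
  numeric. This is not RDKit-canonical; it is deterministic and
  order-invariant for the molecule classes in scope, which is all fragment
  keys and dictionaries require. Pathological highly-symmetric graphs that
  defeat Morgan refinement are out of scope.
* **Exact counting**: binomial coefficients are computed by the
  multiplicative rule and are exact up to `2^53`; beyond that the functions
  raise an error rather than return rounded doubles (no bignum dependency).
  The enumeration caps (20 bits, 25 units) keep all realistic uses far below
  the bound.

## Applicability domain and mining

The fragment dictionary stores, per canonical fragment key, the number of
*training structures* containing it (a fragment occurring twice in one
molecule counts once — structure-level support; the alternative
per-occurrence reading is noted as an open point and rejected for
determinism of the in-domain rule). Keys below `min_occurrence = 4` are
dropped. A query is in domain iff, after removing the atoms and bonds of
every dictionary-covered query fragment, nothing remains; otherwise the
uncovered atoms are returned as a highlight. Raising the threshold is
provably monotone (fewer keys ⇒ less coverage), and both monotonicity and
training-set self-coverage are asserted in the acceptance suite.

Mining interprets every structure of a labelled dataset and tallies, per
canonical fragment key: occurrence, number of structures where the key was
assessed ACTIVATING, experimental signal (fraction of supporting structures
labelled active) and model accuracy (fraction of supporting structures whose
*final* prediction matched the label — node-level accuracy was the other
candidate reading; final-prediction accuracy is adopted because it is the
quantity a model user experiences). Both thresholds are strict (`> 5` by
default). Feature identity is the canonical fragment SMILES, so substitution
variants stay distinct.

## What the synthetic generators emulate — and what they do not

`make_toy_library(n, seed)` assembles molecules from a scaffold + substituent
grammar (benzene, ortho/para-disubstituted benzene, naphthalene,
cyclohexane, butane × nitro, amine, epoxide, aziridine, acid, alkyl, halide,
ether substituents), with weights chosen once so that a 40-structure library
carries roughly a dozen nitro-containing molecules and a mid-range class
balance (30–70% actives). Labels come from the built-in rule oracle — nitro,
epoxide, aziridine and aromatic amine activate; an ortho carboxylic acid
deactivates the aromatic amine — so label logic and planted ground truth
coincide by construction, and the ground-truth alert atoms equal the minimal
active fragment under the default unit rules. The first ten structures are
fixed exemplars covering every motif class. Molecules stay ≤ 30 heavy atoms
and ≤ 8 units, keeping exhaustive enumeration trivially fast.

This stated world makes planted-alert recovery a *sharp* test of the
pipeline plumbing (a single mis-mapped atom id fails it), but it cannot
establish anything about real Ames data: real training sets have correlated
features, noisy labels, and alerts whose context-dependence no small rule
set captures. A green recovery test means the machinery is faithful to the
rules, not that the rules are good toxicology. Similarly,
`make_random_network` fuzzes the assessment rules over random subset
lattices with random predictions — coverage of rule combinations, not of
chemistry. The eleven-node demonstration network is a reconstruction
satisfying every stated constraint; its exact edge list is not
printed anywhere and the package labels it accordingly.

## Known limitations

* Aromaticity and canonicalisation cover common organic chemotypes, not the
  full aromatic zoo (azulenes, charged rings, macrocycles).
* The restricted SMARTS dialect cannot express H-counts, degrees or
  negations; key libraries needing them must be rewritten in monotone form
  (as done for the amine keys).
* The feature-vector route inherits fingerprint ambiguity: a bit witnessed
  by several substructures highlights their union.
* `combinations_count` is exact only below `2^53`.
* Mining on cross-validation folds is exposed as a plain loop over fits by
  the user; the package deliberately mines a single fit by default to stay
  desk-fast.
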