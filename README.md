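# fragnet

Model-agnostic interpretation of binary (Q)SAR classifiers through feature
networks, with an Ames-mutagenicity flavour.

## The problem

Strongly predictive models for binary toxicity endpoints (random forests,
SVMs on structural fingerprints) are black boxes: they output
active/inactive with no indication of *which part of the molecule* drove the
call. For endpoints governed by reactive substructures — mutagenicity being
the canonical case — an expert reviewing a prediction wants structural-alert
style evidence: *these atoms and bonds activate; that context deactivates.*

fragnet supplements any binary classifier, without retraining or conversion
to rules, by interrogating the model's behaviour on sub-features of the
query:

1. **Enumerate sub-features.** Either subsets of set fingerprint bits
   (feature-vector route), or connected molecular fragments obtained by
   condensing the molecule to a **reduced graph** of structural units (SSSR
   rings, functional groups, linker atoms) and expanding every connected
   unit subset back to atoms and bonds (structure route). Rings are never
   broken, so every fragment is a valid standalone molecule and its
   fingerprint sets a **subset** of the parent's bits.
2. **Organise into a feature network.** A DAG ordered by strict subset
   inclusion of payloads (bit sets or atom-id sets); the full query is the
   root. For `n` set bits the exhaustive route enumerates
   `sum_{k=1..n} C(n,k) = 2^n - 1` combinations, so pruning by maximum
   cardinality is supported.
3. **Predict every node** with the unchanged black-box model.
4. **Assess every node** into exactly one of six types, bottom-up:

   | type | rule |
   |---|---|
   | `DEACTIVATING` | inactive node with an active child |
   | `IGNORE` | inactive node, no active child |
   | `DEACTIVATED` | active node with an inactive parent |
   | `ACTIVITY_IDENTIFIED` | active node above an ACTIVATING descendant |
   | `NEGATED` | active, all parents active, some ascendant inactive |
   | `ACTIVATING` | the lowest active, non-deactivated feature on its path |

5. **Summarise** as atom/bond highlights on the query: activations (one per
   ACTIVATING node) and (deactivated, deactivating) pairs per
   DEACTIVATING→DEACTIVATED edge. A final prediction is active iff at least
   one ACTIVATING node exists; chained deactivations can optionally be
   condensed to their largest context.

Also included: a fragment-dictionary **applicability domain** (a query is in
domain iff every atom and bond is covered by training-set fragments
occurring ≥ 4 times), **ACTIVATING-feature mining** across datasets with
occurrence / experimental-signal / accuracy statistics, and BAC / SEN /
SPEC / COV metrics.

Because no R cheminformatics toolkit is assumed, the package carries a small
chemistry kernel: SMILES and V2000 MOL parsing, aromaticity and SSSR ring
perception, canonical SMILES, and subgraph matching over a restricted,
deliberately monotone SMARTS dialect (no H-count/degree primitives), which
is what makes the fragment fingerprint-subset property exact.

## Worked example

2-amino-6-nitrobenzoic acid with the built-in rule oracle (nitro, epoxide,
aziridine and aromatic amine are alerts; an ortho carboxylic acid
deactivates the aromatic amine):

```r
library(fragnet)
oracle <- default_rule_oracle()
query  <- parse_structure("Nc1cccc([N+](=O)[O-])c1C(=O)O")
res    <- interpret(query, oracle)
res$network
#> <FeatureNetwork: 11 nodes, root=10, predicted, assessed>
res$summary
#> <InterpretationSummary: active; 1 activation(s), 1 deactivation pair(s)>
#>   ACTIVATING atoms {6,7,8} bonds {6,7}
#>   DEACTIVATED atoms {0,1,2,3,4,5,9} by atoms {10,11,12} (nodes 4-8)
```

Read: the prediction is **active**; the cause is the nitro group (atoms
6–8). Independently, the aromatic amine (atoms 0–5, 9) would have been an
activation, but the model switched to inactive once the ortho carboxylic
acid (atoms 10–12) entered the context — a localised deactivation that does
not change the overall call.

Fragmentation of 1-nitronaphthalene (three units: two fused rings + nitro)
gives the expected six fragments, the query among them:

```r
frags <- enumerate_fragments(build_reduced_graph(parse_structure("O=[N+]([O-])c1cccc2ccccc12")))
length(frags)
#> [1] 6
vapply(frags, `[[`, "", "key")
#> [1] "[NH+]([O-])=O"  "c1ccccc1"  "c1ccccc1"
#> [4] "c1ccc(cc1)[N+]([O-])=O"  "c1ccc2ccccc2c1"  "c1ccc2c(cccc2c1)[N+]([O-])=O"
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fragnet", package = "fragnet"))')
Rscript "$CLI" fixtures export --n 40 --seed 1 --out toy.tsv
Rscript "$CLI" interpret --model oracle --input toy.smi --out summaries.json
Rscript "$CLI" fragment --input toy.smi --out fragments.tsv
Rscript "$CLI" domain build --input training.smi --threshold 4 --out dict.tsv
```

Subcommands: `interpret`, `fragment`, `enumerate-bits`, `domain build`,
`domain check`, `mine`, `train-toy`, `fixtures export`.

## Layout

- `R/` — chemistry kernel (`smiles.R`, `perception.R`, `canonical.R`,
  `match.R`), fingerprints and key library, fragmentation, enumeration,
  network, assessment, applicability domain, mining, fixtures, CLI.
- `inst/extdata/default_keys.tsv` — the shipped ~40-key library.
- `vignettes/interpreting-qsar-models.Rmd` — methods notes: model,
  assumptions, parameter choices, known limitations.
- `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (fixpoint rule evaluation, exhaustive subset enumeration,
  brute-force superset relations, RDKit-via-python parse checks).
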