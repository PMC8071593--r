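---
title: "Merging CLD ensembles and classifying their feedback loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging CLD ensembles and classifying their feedback loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldmapr)
```

## The model

A causal loop diagram (CLD) is modelled as a simple signed digraph
$G = (V, E)$ with $E \subseteq V \times V$, no self-loops, at most one
link per ordered pair, and a polarity
$\sigma : E \to \{+1, -1\}$. A link $A \xrightarrow{+} B$ asserts that,
all else equal, an increase in $A$ drives an increase in $B$; a negative
link inverts the direction of influence. A feedback loop is a simple
directed cycle $c = (v_1, \dots, v_k, v_1)$, $k \ge 2$, and its polarity
is $\prod_i \sigma(v_i, v_{i+1})$: $+1$ makes the loop *reinforcing*
(perturbations travelling around it are amplified), $-1$ makes it
*balancing* (the loop counteracts change). These parity semantics are
exact for the monotone, qualitative reading of a CLD; they say nothing
about rates, delays or dominance, which require a quantitative
simulation model and are out of scope here.

Every variable and link carries *provenance*: the set of group-map
identifiers it originates from. Provenance is unioned at every merge
step, so each master-map element can be audited back to the workshop
maps that asserted it.

Variable identity across free-text maps is anchored by a *slug*:
lowercase ASCII fold, non-alphanumeric runs collapsed to single
underscores ("Stress-Eating" → `stress_eating`). Slugs make the exact
tier of duplicate detection reproducible and human-checkable. Themes —
the nine colour classes used on such maps (emotional, online, physical
activity, food/drink, economic/commercial, knowledge, home life, body
weight, unclassified) — are assigned by a longest-substring keyword
lexicon. Hand colour-coding is a broad judgment call; the shipped
lexicon is its editable, deterministic surrogate. The longest-match rule
is monotone in a useful sense: adding a *shorter* keyword can never
change a label already matched by a longer one.

## The merging protocol

One fold of feeder map $F$ into base map $B$ proceeds:

1. **Pruning.** Variables with in-degree 0 or out-degree 0 carry no
   feedback and are removed. The default iterates to a fixpoint: a
   single pass can strand new endpoints (pruning the sink of a chain
   exposes its predecessor), and the evident purpose of the step is to
   isolate loop-relevant structure. `single_pass` is available where the
   literal one-sweep behaviour is wanted. Fixpoint pruning is sound
   (post-condition: all degrees ≥ 1), monotone, and idempotent — all
   property-tested.
2. **Base selection.** Among the pruned maps, the one with most
   variables; ties broken by most links, then smallest map id. The
   tie-breaks are arbitrary but fixed, because the fold result can
   depend on which map is the base.
3. **Judging variables.** Each feeder variable receives exactly one
   decision, in fixed order: a manual decision file (label → park or
   discard) first — nothing is parked or discarded automatically,
   because "does not fit anywhere" is researcher judgment with no
   reproducible rule — then exact slug match, then an explicit synonym
   table, then (only if a threshold is set) normalized edit similarity.
   Fuzzy matching defaults to *off*: duplicate judgment in group model
   building is semantic, and a silent fuzzy merge is a false join you
   cannot audit. Anything unmatched is *added*, keeping the algorithm
   conservative: the merged map may be larger than a hand-merged one,
   but nothing asserted by participants is lost silently.
4. **Carrying links.** Feeder links are mapped through the decisions.
   Links touching parked/discarded variables are skipped (counted);
   links whose endpoints collapse onto one base variable are dropped as
   self-loops (counted); a link already on the base with the same sign
   unions provenance; with the opposite sign it becomes a *polarity
   conflict*, resolved by majority of contributing source maps (the
   provenance-set sizes), ties keeping the base sign. Every conflict is
   recorded in the fold's report with its votes and resolution. The
   merged map is then re-validated and each retained feeder link is
   verified present.

Countries fold their group maps in sorted-map-id order; the identical
protocol then folds the country maps into the master. Fold order can
matter in principle, so it is fixed and documented rather than left to
input order. With fixed inputs the whole pipeline is seed-free
deterministic — two runs produce byte-identical CSV artifacts, which the
acceptance suite checks with raw file comparison.

## Loop enumeration

Simple cycles are enumerated by depth-first search rooted at each node
in C-locale lexicographic order, with the search restricted to nodes
sorting after the root. Each cycle is therefore discovered exactly once,
already in canonical rotation (starting at its smallest id), making loop
identity independent of traversal order; results are sorted by (length,
node sequence). Cycle counts grow exponentially with density, so the
search is doubly bounded: `max_length` (default 12 — longer loops are
rarely interpretable on qualitative maps) and `max_cycles` (default
10,000). Truncation is never silent: it raises a warning and sets a
`truncated` attribute on the result. The enumerator is cross-checked in
the test suite against an independent brute-force oracle (all
rotation-canonical permutations of all vertex subsets) on hundreds of
random digraphs, and the parity classifier against the sign-product
oracle exhaustively up to length 12.

Loop *ranking* (descending theme breadth, then ascending length, then
node sequence) is a documented deterministic ordering for reports. Which
loops "stand out" on a real map is a narrative judgment; the ranking
makes reports stable, it does not claim salience.

## The synthetic study generator

`synthetic_study_config()` encodes the study conditions the package is
designed around, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_countries` × `groups_per_country` | 5 × 4 | the multi-country school-group design |
| `vars_per_group` | 15–40 | typical size range of one workshop map |
| `shared_vocabulary_size` | 60 labels | spans all nine themes with a few variants each |
| `shared_fraction` | 0.6 | group findings are largely congruent across countries |
| `edge_density` | 1.8 links/variable | sparse, as hand-drawn maps are |
| `p_negative` | 0.2 | the published narrative loops carry 4 negative links in 19 |
| `planted_loops_per_group` | 1, length 3–6 | recoverable ground truth |
| `shared_planted_loops` | TRUE | the planted loop is common to all maps, mirroring the congruence the merge is meant to surface |

Per-group RNG streams are derived from the master seed and the group's
identity (a string hash, kept under $2^{31}$), so any group map can be
regenerated independently of generation order. Planted loops live on
shared-vocabulary nodes; with `shared_planted_loops` their node choice
and signs are keyed only on the master seed and loop index, which is
exactly the "same loop in every map" condition under which recovery
through the full merge is tested (10/10 seeded runs in the acceptance
suite, at the default 5 × 4 design with `shared_fraction = 1`).

What the generator emulates is graph structure, theme mix and label
overlap — not the content realism of participant discussion, the
correlation structure of real causal claims, or facilitation effects.
A passing recovery test shows the merge machinery preserves structure
that is genuinely shared; it cannot show that real workshop maps share
such structure. Label noise (`label_noise = TRUE`, off by default)
jitters case, punctuation and plurals on shared labels to exercise
normalization and fuzzy matching; with it on, ground-truth node ids may
differ from on-map ids by a plural, which is the intended difficulty.

## Numerical and degenerate-input choices

* Polarity cells in CSVs accept `+`, `-`, `+1`, `-1`, `1` and the
  Unicode minus — hand-edited files contain all of these. Unparseable
  cells fail with the row number.
* Edit similarity is $1 - d/\max(|a|,|b|)$ on normalized labels with
  Levenshtein distance $d$; ties in fuzzy matching resolve to the
  smallest base id. The worked threshold example: "advertisment" vs
  "advertisement" has $d = 1$ over 13 characters, similarity ≈ 0.92.
* Empty maps are legal everywhere: pruning an acyclic map to fixpoint
  yields an empty CLD, merging empties yields an empty master, and loop
  enumeration of an empty map returns an empty list.
* A country with one group degenerates to its pruned map; merging a map
  with itself is the identity up to provenance (both are tested).
* All string ordering uses radix (C-locale) sorting so artifacts do not
  depend on the session locale.

## Fixtures

The three packaged fixtures encode the classic single-loop narratives.
Signs follow monotone orientation of each variable: in the mental-health
loop, `self_esteem` is oriented "more is better", so body-image pressure
*lowers* it (−) and it in turn *lowers* stress (−); the two negatives
cancel and the loop is reinforcing, i.e. self-perpetuating, as each
narrative describes. The classification is invariant to any consistent
re-orientation of variables (re-orienting one variable flips both its
incident links). Fixture files are pinned by checksum; they are data,
not code, and never change.

## Problem sizes

The test suite and acceptance script run on deliberately moderate sizes
chosen to exercise every code path: oracle equivalence on 200 random
digraphs of ≤ 8 nodes plus exhaustive parity checks to length 12;
merge-invariant properties on dozens of random and synthetic ensembles;
planted-loop recovery on ten full 5 × 4 studies; loop reports on masters
of roughly 170–200 variables with enumeration capped (and flagged) at
the defaults. These sizes are the package's own validation design;
larger ensembles only lengthen the same computations.

## Known limitations

* Merging is order-dependent in principle; fixing fold order makes it
  reproducible, not order-free. A different base map can yield a
  differently-labelled (though structurally similar) master.
* The duplicate tier is lexical (slug/synonym/edit distance). Semantic
  matching — "screen time" vs "device use" — needs a curated synonym
  table; no embedding-based matching is attempted.
* Parity classification is qualitative; no loop dominance, gain, or
  time behaviour is computed.
* Theme assignment is only as good as the lexicon; unmatched labels are
  reported as `unclassified` rather than guessed.
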