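---
title: "Contact-constrained probabilistic context-free grammars for protein motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-constrained probabilistic context-free grammars for protein motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactpcfg)
```

## The model

A probabilistic context-free grammar assigns each rewriting rule a
probability; the grammar is *proper* when the probabilities of all rules
sharing a left-hand side sum to one, so that a top-down derivation is a
well-defined stochastic process. The probability of a parse tree is the
product of its rule probabilities, and the probability of a sequence is the
sum over all of its parse trees (the *inside* probability).

This package works with grammars in **Chomsky Form with Contacts (CFC)**.
Non-terminals split into *lexical* ones (`V_T`, rewritten only into single
amino acids) and *structural* ones (`V_N`). Three rule shapes are allowed:

* lexical: `v_t -> a`, one terminal;
* branching: `v_k -> y z` with `y, z` any non-terminals (Chomsky Normal
  Form when these are the only structural rules);
* contact: `v_k -> v_t v_l v_u` with lexical flanks around a structural
  core.

A contact rule is the grammatical counterpart of a residue–residue
contact: the two terminals it generates are spatial neighbours. Because
every terminal hangs under its lexical parent, the leaf-to-leaf path
between those two terminals always has exactly 4 edges, and 4 is the
minimum leaf distance any CFC tree can realise. Consistency of a tree `u`
with a (partial) contact map `m` is therefore defined as
`d_u(i, j) <= delta` for every contact pair, with `delta = 4` the natural
choice: at that threshold, consistency means "every contact pair is
generated by a contact rule". We use the non-strict inequality: contact
rules place pairs at distance exactly 4, so a strict `< 4` would make
consistency unsatisfiable — the non-strict form is the only reading under
which the constrained parser and the descriptive metrics at `delta = 4`
are coherent.

Only *CF-compatible* maps can be enforced by a single context-free tree:
no two pairs may cross or share an endpoint (nesting is fine). Crossing
contacts are real in proteins; `extract_cf_compatible_subset()` selects a
maximum-cardinality non-crossing subset by interval dynamic programming
(the same recurrence used for non-crossing base pairing in RNA folding),
which automates what would otherwise be a manual choice of training pairs.
Pairs at sequence separation 2 are flagged at construction: the inner
non-terminal of a contact rule yields at least two terminals, so such
pairs have constrained probability 0; separation 1 is rejected outright.

## Constrained parsing

`inside()`, `skeleton_mass()` and `viterbi()` share one bottom-up CKY
chart over spans. Contact constraints enter through a side table: the
lexical probabilities of in-contact positions are removed from the base
chart row and reserved for contact rules completing *exactly* that pair,
with both flanks drawn from the same table (base row or side table, never
mixed). A tree that fails to route a contact pair through a contact rule
then simply contributes zero. The complexity stays O(n³ · |R|) because the
number of non-crossing pairs is O(n).

The contrastive denominator `prob(U_n^m | G)` — the probability mass of
all map-consistent tree *shapes* over any sequence of length n — falls out
of the same chart: for a proper grammar the total emission mass of each
lexical non-terminal is 1, so running the constrained parser with every
lexical probability set to 1 sums the structural derivation probabilities
exactly once per shape. This makes the quantity independent of the lexical
probabilities, which the tests assert directly.

Numerics: the inside chart is stored in linear space with one logarithmic
scale factor per span length. Cells of equal span share a scale and a
span-j cell only ever combines spans k and j−k, so scales compose
additively and the inner loop stays free of `exp`/`log` calls; a 120-residue
sequence whose probability is far below the smallest double still yields a
finite log probability. Viterbi uses plain log space (max–product needs no
summation) with a deterministic tie-break — branching rules before contact
rules, then rule-table order, then leftmost split — so identical inputs
yield identical trees across platforms. The chart kernels are implemented
in C++ (Rcpp): a training run evaluates the objective on the order of 10⁵
times, which is out of reach for an R-level chart.

Correctness is anchored by an enumeration oracle in the test suite: all
CFC tree shapes up to 6 leaves are enumerated explicitly (58 shapes at
n = 6), each shape's labeling mass is a direct product–sum over the shape,
consistency is decided by igraph shortest paths, and the chart results are
required to match to 1e−9 relative error over dozens of random proper
grammars. The same harness pins the two analytic constants: contact-rule
pairs sit at leaf distance exactly 4, and the minimum leaf distance in CNF
trees over pairs with sequence separation ≥ 3 is exactly 5 (which is why
CNF grammars score zero recall at `delta = 4`).

## Training objectives and the genetic algorithm

Three objectives are implemented, each as a mean per training item so that
values are comparable across sample sizes:

* `objective_ml` — mean log probability of the map-consistent tree sets;
  with empty maps this reduces exactly to the ordinary sequence
  log-likelihood.
* `objective_ce_m` — mean log probability of the consistent trees of each
  sequence minus the log skeleton mass of the shared map. Requires one map
  and a common length; always ≤ 0.
* `objective_ce_x` — mean log ratio between each sequence's consistent
  trees and all its trees; ≤ 0, exactly 0 when all maps are empty.

Optimisation is a Pittsburgh-style genetic algorithm over the full vector
of rule weights of a fixed covering rule set. Decoding normalizes weights
per left-hand side, so every individual in every generation is a proper
grammar by construction; weight groups that mutate to all-zero fall back
to uniform. The starting grammar seeds one individual and elitism keeps
the best two, which makes the best objective non-decreasing and guarantees
the result is at least as good as the initial grammar. Negative data are
never used in training.

Defaults (population 100, 500 generations, tournament size 3, uniform
crossover 0.8, elitism 2, per-gene mutation 0.1) are deliberately plain;
every value is recorded in the returned configuration. One operator
deserves comment: mutation is **multiplicative log-normal**
(`w <- w * exp(N(0, 1))`) rather than additive Gaussian. Decoded rule
probabilities span several orders of magnitude (a 400-rule covering
grammar gives branching groups of 49 rules, most of which must become
small), and additive perturbations of fixed scale can neither produce nor
fine-tune small weights. On the recovery benchmark below the additive
operator stalls about 3 nats per item short of the generating grammar's
objective, while the multiplicative one matches it within 150
generations. `train_ga_multi()` runs several seeds and returns the
best-objective grammar, mirroring the usual practice of multi-restart
training with selection; per-run grammars can also be combined by
`ensemble_score()`.

## Scoring and evaluation

All reported scores are decimal log-odds against a unigram null model, so
a score of 3 means the sequence is exactly 1,000 times more probable under
the grammar than under the null. The default background table (Swiss-Prot
amino-acid frequencies) ships as a plain-text file and is fully
overridable. Discrimination is summarised by average precision over the
recall–precision curve, which is robust to the extreme class imbalance of
motif search; ties share one threshold step, so AP is invariant under
strictly monotone transformations of the scores.

Descriptive evaluation treats the most likely parse tree as a contact
predictor: pairs at leaf distance ≤ δ are predicted contacts. Recall at
δ = 4 against the (partial) training map measures how much of the imposed
constraint the grammar has internalised; precision at δ = 4 and AP over
all δ against a full reference map measure how faithful the tree is to the
structure. Predicted pairs are restricted to sequence separation ≥ 3 and
pairs at equal tree distance share a threshold step (per-unique-distance
stepping; the alternative optimistic/pessimistic orderings are not
meaningfully different for trees, whose distance values are few and
heavily tied). Local per-residue AP uses only the contacts of one residue,
highlighting which parts of a motif the tree explains. An empty reference
map yields `NA` metrics, never a fake 0.

The 8-fold cross-validation harness (`cv_split`) partitions a sample and
enumerates all 56 ordered validation/test part combinations with the
remaining six parts for training, reproducibly from a seed.

## The synthetic benchmark

`make_benchmark()` draws positives from a known CFC grammar by top-down
sampling (`sample_derivation`, depth-capped at 50 with an explicit
overflow signal; rejection sampling to a target length aborts after 10⁴
attempts per item with guidance). Each positive carries the contact map
its own derivation generated (`map_from_tree`), which is CF-compatible by
construction — the synthetic analogue of assigning one representative
structure's contacts to a family of fixed-length motif sequences.

The fixture generator `toy_hairpin_grammar()` models a beta-hairpin-like
motif: nested contact rules build the stem ladder between
hydrophobic-biased residues, a loop of loop-friendly residues closes it,
and optional bulges add length variation; with defaults the modal product
is an 8-residue hairpin, and `stem_extend = 0.65` shifts the ladder length
so that 16-residue motifs are common. The lexical profiles (favoured
residues get 9× weight) produce clear but not caricatural composition
bias, comparable to real hydrophobic cores.

Negatives are i.i.d. unigram draws of the same lengths. By default they
are drawn from the *positives' own empirical residue composition* (with
one pseudocount per residue) rather than from the global background. The
reason is what the benchmark is supposed to measure: with background
negatives, even an untrained uniform covering grammar separates the
classes almost entirely through the null-model term whenever the family's
composition deviates from background — the task then measures composition,
not grammar. Composition-matched negatives push the untrained baseline to
roughly the positive prevalence and leave structure (position and pairing
preferences) as the only usable signal. The global background remains
available through the `background` argument.

What passing the synthetic benchmark does and does not show: positives are
exactly grammar-generated, maps are complete and noise-free, and lengths
are filtered — real motif families have crossing contacts, alignment
errors, unobserved contacts and length variation, so performance numbers
here are upper bounds on clean-signal behaviour, not predictions for real
data.

## Problem sizes used in the automated checks

The recovery experiment trains the 400-rule covering grammar (3 lexical +
4 structural non-terminals, all contact-capable) on 24 positives of length
16 sampled from the extended hairpin generator, with constrained ML,
population 100, 300 generations and 3 seeds, then evaluates the
best-objective run: most likely parses of the sequences alone recover the
training contacts (recall ≥ 0.8 at δ = 4; observed ≈ 1.0) and AP against
96 composition-matched negatives exceeds the untrained baseline by well
over 0.2 (observed ≈ 0.83 vs ≈ 0.25). Oracle comparisons use 2-letter
alphabets and sequences up to length 6, where exhaustive shape enumeration
is exact and fast. These sizes were chosen so the full suite runs on a
single CPU in a few minutes while still exercising every code path at
realistic rule-set scale.

## Known limitations

* Only non-crossing, endpoint-disjoint contact subsets can be enforced;
  crossing dependencies would need tree decompositions or a relaxed
  consistency notion (only-if instead of iff), neither implemented here.
* The GA optimises rule probabilities over a fixed covering rule set; it
  neither induces rules nor scales comfortably beyond a few hundred rules
  (a ten-non-terminal mixed-capability inventory, 675 rules, is about the
  practical ceiling).
* The unigram null model ignores length and local composition effects;
  scores across very different lengths are not directly comparable.
* `sample_derivation` conditions on derivation depth ≤ max_depth; for
  grammars with heavy recursion the sampled distribution is truncated
  accordingly (the overflow signal makes this visible).
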