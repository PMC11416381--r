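---
title: "Evolving weighted regular-expression models of peptide function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving weighted regular-expression models of peptide function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepregex)
```

## The problem and the model

Short peptides (10–13 residues here) can act as contrast agents for
chemical exchange saturation transfer (CEST) MRI: their exchangeable
amide protons, saturated at an offset of 3.6 ppm, transfer signal loss
to water. The measured phenotype is the magnetization transfer ratio
asymmetry,

$$\mathrm{MTR_{asym}} = \frac{S(-3.6\,\mathrm{ppm}) - S(+3.6\,\mathrm{ppm})}{S_0},$$

in percent. Given a panel of peptides with measured phenotypes, the
package learns a *rule-list model*: an ordered set of rules, each a
regular expression over the 20-letter amino-acid alphabet with a real
weight. A peptide's **predicted score** is the sum of the weights of all
rules whose pattern matches somewhere in the sequence — match presence,
not match count, so the model is a weighted combination of binary
pattern indicators.

Rule patterns are *genotypes*: depth-bounded binary trees stored in heap
layout (node $i$ has children $2i+1$ and $2i+2$; unexpressed slots are
empty). Internal nodes are the regex operators — concatenation,
alternation, the `+` quantifier, a fixed repeat `{n}`, including and
excluding character classes, and grouping — and leaves hold one or more
residues. The depth bound of 6 keeps expressions short and cheap to
match. Trees are generated by ramped half-and-half: the `full` method
places operators on every level above the deepest, `grow` may close
branches early, and the population mixes both across depths 2–6.

## Weight training against the motif database

Weights are not free parameters. From the training panel a **motif
database** is built with sliding windows of 1–6 residues: each training
sequence is classed positive when its phenotype reaches the class
boundary $T$ (default 12.5, the phenotype of the poly-L-lysine gold
standard K12), each unique motif is assigned the class in which it
occurs more often (occurrence counting, overlapping windows, ties to the
negative class), and its value is the mean phenotype over its
occurrences in the winning class. Averaging over occurrences rather than
distinct sequences makes the construction invariant to record order.

A rule's trained weight is the signed sum over all training sequences
and all regex matches of (motif value × motif length): added when the
motif's value is at or above $T$, subtracted when below. Matches absent
from the database — never seen in training, or longer than the largest
window — contribute nothing. Rules are therefore anchored to the
evidence in the panel; a rule that can only reach high-value motifs has
a non-negative weight by construction.

## Fitness and the evolutionary loop

Model fitness is the Pearson correlation between predicted scores and
measured phenotypes. To control overfitting it is computed under k-fold
cross-validation (default $k = 6$): for each fold the motif database is
rebuilt from the other folds only — held-out phenotypes never leak into
weights — weights are retrained, and the fitness is the mean correlation
over the training folds, with the mean held-out correlation reported as
an overfitting monitor. A model with constant predictions (for example
all weights zero) is defined to have fitness 0 rather than an undefined
correlation.

The genetic-programming loop uses tournament selection (size 5),
one-point crossover on the rule lists (probability 0.9), and two
mutation tiers at rate 0.1: whole-list mutations (add, replace, delete a
rule, respecting the 1–30 rule bounds) and per-rule structural tree
mutations (replace a subtree, exchange a node within its arity class,
delete a subtree with sibling promotion, extend a leaf by 1–4 residues).
The best individual is copied unchanged into the next generation, and
truncation keeps the best S individuals, ties broken by parsimony (fewer
rules) and then insertion order. The fold assignment is drawn once per
run, so the elite's fitness is stable and the best-so-far fitness is
non-decreasing. After the run, the returned model's weights are
retrained once on the full training set.

A control mode (`mode = "random_weights"`) disables training entirely:
weights start uniform in $[-10, 10]$ and drift by random redraws at rate
0.1 per rule per generation, with plain training-set correlation as
fitness. It serves as the baseline against which the value of the
training step is judged.

## In-silico directed evolution

The best evolved model replaces the wet-lab screen in a
directed-evolution loop: a library of 1000 random 12-mers is
hill-climbed for a chosen number of cycles. Each cycle proposes one
random substitution per slot (the new residue always differs from the
old) and accepts it only when the predicted score strictly improves, so
per-slot scores are monotone and the library size never changes.
Finally, peptides whose summed per-residue hydropathy is zero or
negative are discarded as non-soluble, and the top 20 survivors by score
are reported.

The shipped hydropathy scale is the Wimley–White
water-to-membrane-interface free-energy scale with the charged values
for Asp, Glu, Lys and Arg. The neutral His value is used, consistent
with sample preparation near pH 7.3; no reported quantity depends on
that choice. Any 20-residue scale can be substituted via
`read_hydropathy_scale()`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `population_size` | 1000 | individuals kept per generation |
| `generations` | 300 | evolutionary iterations |
| `max_rules` | 30 | rule-list length cap |
| `crossover_prob` | 0.9 | chance a parent pair recombines |
| `mutation_prob` | 0.1 | per-individual and per-rule mutation rate |
| `tournament_k` | 5 | selection pressure |
| `max_depth` | 6 | regex-tree depth bound |
| `cv_folds` | 6 | folds of the fitness cross-validation |
| `threshold` | 12.5 | phenotype class boundary (K12's value) |
| `cycles` (DE) | 10/100/1000 | screening cycles; more cycles converge harder |

The defaults reproduce the published study configuration. The package's
own test and example runs use scaled-down sizes (populations of 20–100,
15–80 generations, synthetic panels of 50–200 peptides) chosen so the
whole suite runs on a laptop; the qualitative behavior — elitism
monotonicity, motif recovery, screening amplification — is unchanged.

## The synthetic-data generator

`simulate_peptides()` creates panels with known ground truth: sequences
drawn residue-wise from a composition distribution (by default enriched
in K, T, R and S and depleted in aromatics, mirroring measured CEST
panels), phenotype = baseline + Σ effect × overlapping-occurrence count
+ Gaussian noise, clamped to $[0, 25]$. The default effect profile
(`KK` +4, `SK` +3, `QS` +2, `EE` −3, baseline 6, noise SD 1) emulates
the qualitative structure of measured data: lysine-rich motifs raise
contrast, acidic motifs lower it, pairwise identity stays mostly below
10%.

What the generator does *not* emulate: the exchange physics behind the
phenotype (effects are exactly additive here), dataset-level selection
bias, and measurement error structure beyond i.i.d. noise. Passing
recovery tests therefore demonstrates that the pipeline can extract
planted additive motif structure — not that it will reach any particular
accuracy on real panels.

One property of the default profile deserves emphasis. With a
residue-wise i.i.d. composition the mean phenotype sits near 7.5, well
below the 12.5 class boundary, so nearly every motif is majority
negative-class and all trained weights come out non-positive — a
degenerate regime for the weighting scheme. Real screening panels are
not i.i.d.: they contain engineered lysine-rich candidates (the gold
standard itself is K12). The paired trained-versus-random comparison
therefore uses a mixture panel — 70% background composition plus 30%
`engineered_composition()` draws — which restores a meaningful class
split (~18% positive) and exercises the weighting mechanism the way a
real panel does. This also bounds what the control comparison can show
at desk scale: with ten paired replicates and moderate run sizes, the
trained mode wins most replicates and has the higher mean held-out
correlation, but a one-sided sign test at the 0.05 level requires 9/10
wins, which the effect size at this scale does not reliably deliver; the
published comparison used 50 replicates of population-1000 runs.

## Numerical and design choices

* **Pairwise identity** counts positional matches with no alignment,
  divided by the *longer* sequence length — the conservative choice when
  lengths differ (a 10-mer can never be 100% identical to a 13-mer).
* **Train/test split** draws `ceiling(fraction × n)` records, so an
  80% split of 158 peptides gives the conventional 127/31.
* **Class boundary**: a phenotype exactly equal to the threshold counts
  as positive, matching the `≥ T` branch of the weighting rule.
* **Character classes** over arbitrary subtrees are rendered by
  flattening: the class collects the distinct residues of all leaves
  beneath the bracket, and generation never places quantifiers inside a
  bracket subtree. The `group` operator is supported by the validator
  and renderer but not drawn during random generation — quantifier
  operands are parenthesized automatically, which is the only place
  grouping is needed.
* **Repeat counts** `{n}` are drawn uniformly from 2–9.
* **Crossover** excludes cut pairs that would recreate both parents or
  leave an offspring empty; two single-rule parents admit no such cut
  and pass through unchanged.
* **Pathological patterns**: matching uses the PCRE engine, whose
  internal backtracking budget turns a catastrophic pattern into a
  caught error; such a rule simply matches nothing (with a warning)
  instead of stalling a run. Subjects are at most 13 residues, which
  bounds backtracking in practice.
* **Regex engine semantics**: PCRE alternation is leftmost-first while
  POSIX engines are leftmost-longest, so the two can extract different
  (equally valid) substrings from the same alternation pattern. The test
  suite uses R's second engine (TRE) as an independent oracle for
  alternation-free patterns and compares match presence otherwise.
* **Degenerate correlations** (either vector constant) are defined as 0
  throughout, treating uninformative models as uncorrelated.

## Limitations

* Weights are exactly the signed motif-value sums (or random, in the
  control mode); there is no gradient or closed-form refitting, by
  design — the weights are the explanation.
* The one-point crossover recombines rule lists, not trees; building
  blocks below the rule level travel only through mutation.
* Fitness cross-validation folds are fixed per run; redrawing folds each
  generation would trade elitism monotonicity for lower fold-overfitting.
* The screening loop accepts only strict improvements, so multi-residue
  motifs can only be completed, not approached, under a single-motif
  model; real models provide partial-credit gradients through their many
  rules.
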