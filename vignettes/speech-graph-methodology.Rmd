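---
title: "Speech graph methodology: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech graph methodology: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechgraphs)
```

## The model

Speech graphs are network representations of transcribed discourse: nodes
are linguistic units, edges are relations between them, and graph-theoretic
summaries of the network quantify how much a speaker says, how tightly the
discourse hangs together, and how organized it is relative to chance. These
properties track language disorganization and impoverishment, the two axes
of speech disturbance most relevant to psychosis-spectrum conditions.

The package builds two graph types from the same annotated transcript:

* **Structural (sequential) graphs** connect each content lemma to the next
  one in spoken order, across utterance boundaries. Content words are nouns,
  proper nouns, pronouns, non-auxiliary verbs, adjectives, and adverbs;
  determiners, adpositions, conjunctions, particles, auxiliaries,
  interjections, and filled pauses are excluded. "The kid is grabbing the
  cookie jar" contributes the chain `kid → grab → cookie → jar`.
* **Semantic (action-predication) graphs** are built from semantic role
  labels within each utterance. Every verb frame contributes *predication*
  edges from the predicate lemma to each of its core arguments (PropBank
  A0, A1, A2), and *action* edges from the actor (A0) to each undergoer
  (A1, A2) present. The same sentence contributes `grab → kid`,
  `grab → cookie jar`, and `kid → cookie jar`, with the multiword argument
  "the cookie jar" kept as the single node `cookie jar`.

Both graphs are directed and simple: repeating a relation does not add a
parallel edge but increments the integer edge weight (first occurrence 1,
each repetition +1). Would-be self-loops — identical consecutive lemmas, or
a frame whose two endpoint labels coincide — are skipped; disfluent
repetitions would otherwise dominate, and the random-graph null model below
assumes simple digraphs.

## The nine features

For each graph we compute three domains of features:

| Domain | Features |
|---|---|
| Size | NN (nodes), NE (distinct edges), diameter, ASPL |
| Connectedness | AWD (average weighted degree), density, LSCC |
| Organization | LSCCZ, ASPLZ (z-scores against random graphs) |

Distances are unweighted directed hop counts; edge weights enter only AWD
(`2 × total weight / NN`). ASPL is the mean, and diameter the maximum, over
*ordered node pairs joined by a finite path*, excluding self-pairs. Speech
graphs are rarely strongly connected, so unreachable pairs must be handled
somehow; restricting to finite pairs keeps both measures defined, and the
identical convention is applied to the random baselines so the z-scores
compare like with like. A graph with no reachable pair reports 0 for both,
with a degeneracy flag. Density is `NE / (NN × (NN − 1))`, and LSCC is the
node count of the largest strongly connected component.

Organization is measured by comparison with chance: LSCCZ and ASPLZ are
z-scores of LSCC and ASPL relative to 1000 Erdős–Rényi random digraphs
matched on NN and NE. We use the G(n, m) variant (uniform over simple
digraphs with exactly the observed node and edge counts, no self-loops)
because the baseline matches both NN and NE. The spread is the population
(n-denominator) standard deviation — immaterial at 1000 replicates but fixed
for determinism. When the matched ensemble is degenerate (e.g., a complete
digraph, where only one graph exists and the sd is zero), the z-score is
reported as 0 with a flag rather than NaN, so window averages downstream
stay defined. Baselines are memoized per (NN, NE, replicates, seed):
moving windows repeat sizes heavily, and without the cache a desk-scale run
would spend nearly all its time re-simulating identical ensembles.

Seeding: each baseline's seed is derived deterministically from a seed base
and (NN, NE). The base defaults to the master seed but is its own
configuration field, because the null ensemble for a given size does not
depend on the data — repeated-cohort experiments can therefore share one
cache across cohorts.

## Static and dynamic measurement

Static features summarize the whole-response graph. Dynamic features control
for speech quantity: a fixed-length window slides through the sample, all
nine features are computed per window (z-scores against each window's own
(NN, NE) baseline), and the dynamic feature is the arithmetic mean across
windows. Structural windows cover 30 content tokens with step 1; semantic
windows cover 3 utterances with step 1, the closest equivalent given a mean
utterance length of roughly ten words. Both geometries are configurable.

Samples shorter than one window yield a single whole-sample window flagged
`short_sample` rather than being dropped — no exclusion rule is imposed, and
the flag lets an analysis exclude brief responses explicitly. Only
full-length windows are emitted otherwise, so an n-unit sample yields
`n − L + 1` windows at step 1.

Features are extracted separately for each response and averaged feature-wise
(unweighted) across each participant's responses within a task, giving a
participant × task table with exactly 36 columns: 9 metrics × {static,
dynamic} × {structural `SEQ`, semantic `AP`}, named like `D_AP_LSCCZ`.

## Statistical battery

Group comparisons use the Mann–Whitney U test with the rank-biserial
correlation (RBC) as effect size: `RBC = 2·U1/(n1·n2) − 1`, positive when
the first group is stochastically larger. The first group defaults to PS−
(participants without psychosis-spectrum disorder), so impoverishment
effects appear as positive RBC on size features. The p-value uses the exact
U distribution when `n1·n2 ≤ 400` and no ties are present, otherwise a
tie-corrected normal approximation with continuity correction.

Dimensional associations use Spearman's rank correlation (Pearson on
mid-ranks) with the t approximation for p-values. Multiplicity is handled by
Bonferroni correction; family sizes default to features × tasks for group
comparisons and surviving features × clinical measures × tasks for
correlations, and both are explicit configuration because different analysis
layouts imply different arithmetic.

Redundancy among the 36 features is pruned by stepwise variance-inflation-
factor elimination: compute `VIF_i = 1/(1 − R²_i)` for each feature
regressed on the rest, remove the largest while it is ≥ 5, repeat. Ties at
the maximum are broken by fixed column order, and constant columns (which
have no defined VIF) are excluded up front with a warning. The layered
protocol applies this per task: first within each (graph type, mode, domain)
block, then pooling survivors per graph type, then pooling across graph
types — mirroring the domain → type → task integration levels of the
original analysis. We split stage-1 blocks per task because the published
survivor tables are reported per task.

## The synthetic-data generator

No public transcript corpus accompanies the method, so the package ships a
seeded generator that emulates the *shape* of the data: two-group cohorts
(default 81 PS+ / 124 PS−), three picture-description and two open-ended
narrative responses per participant, utterances of about ten tokens built
from verb clauses with determiners and auxiliaries, occasional filled
pauses, per-clause SRL frames with configurable A0/A1/A2 presence
(0.9/0.8/0.15), occasional two-noun compound arguments, and a
Zipf-distributed content lexicon (200 nouns, 50 verbs, exponent 1.0).
Picture responses average 11 utterances and narratives 16, reproducing the
reported ~110 and ~162 words per response. Surface forms equal lemmas:
graph construction consumes lemmas only, so simulating morphology would be
untested dead weight.

Group effects act through a per-participant severity latent (cases
N(1, 0.25), controls N(0, 0.25), clamped to [0, 1.5] when applied):
*vocabulary shrinkage* scales the effective lexicon (default case multiplier
0.7 — chosen as a realistic impoverishment of the active vocabulary) and
*repetition inflation* multiplies the perseveration rate (default 1.75).
Clinical scores (BPRS, SANS, TLC) are linear-Gaussian in the same latent,
with intercepts and slopes set so group means approximate the published
cohort description; linearity makes rank-correlation recovery predictable.

What the generator does *not* emulate: real syntax and discourse coherence,
coreference, word-sense ambiguity, SRL errors, or annotation noise. Passing
parameter-recovery tests on these cohorts therefore demonstrates that the
pipeline is a faithful estimator of graph-level structure it models — not
that the features will behave identically on clinical recordings.

## Validation experiments and problem sizes

The test suite validates each stage against independent oracles: brute-force
all-pairs BFS and mutual-reachability SCC for the seven basic metrics (200
random digraphs of up to 8 nodes), exhaustive enumeration of all 220
four-node/three-edge digraphs for the baseline moments, explicit pair
counting for U and RBC, and a normal-equations solve for VIF.

Two calibration experiments run the whole pipeline end to end. The
*recovery* experiment generates 100 cohorts of 40+40 participants, one
picture response each at the realistic response length (11 utterances), with
a strong constructed impoverishment effect (vocabulary multiplier 0.5,
repetition inflation 1.75), and asks whether the PS−-vs-PS+ comparison on
dynamic structural NN detects the effect with the constructed sign at
p < 0.05. An a-priori power sweep put per-cohort power near 99.5% under
these conditions, so a ≥ 95% detection rate is the expected outcome; at the
package's default effect (0.7) the per-cohort effect size is comparable to
published clinical values (RBC ≈ 0.3) and 40+40 cohorts would be
underpowered, which is why the recovery experiment fixes the stronger
constructed effect explicitly. The *null* experiment zeroes both effect
knobs and checks the rejection rate lands in the central binomial band
around the nominal 5% (between 1% and 11% over 100 cohorts). These
experiment sizes — one response per participant, 40+40, 100 cohorts, and
z-scores disabled (`replicates = 0`) where only size features are examined —
were chosen once as the package's desk-scale validation conditions.

## Degenerate inputs and numerical conventions

* Empty graphs (a response whose content filter removes everything, or
  utterances with no frames) produce all-zero features with flags, never
  errors, and are counted in row metadata.
* An argument span emptied by the content filter falls back to the
  lemmatized full span, so every tagged argument yields a node.
* Unknown POS tags warn and exclude by default (configurable to error).
* Exact collinearity in VIF is reported as `Inf` (removed first); `1 − R²`
  below 1e-12 is treated as exact.
* Spearman correlations of zero-variance vectors report rho 0 with an
  `undefined` flag and are never marked significant.
* All randomness flows from explicit seeds; repeated runs are bit-identical.

## Known limitations

* Argument-node identity is exact string equality of lemmatized labels:
  coreferent mentions with different wording remain distinct nodes.
* The SRL backend is pluggable but not bundled; the package consumes
  pre-annotated transcripts and ships only the adapter contract.
* Utterance segmentation is taken as given in the input.
* The finite-pairs ASPL/diameter convention is one of several defensible
  choices for disconnected digraphs; it is declared, applied identically to
  observed and random graphs, and isolated behind the metrics configuration.
* Adjunct arguments (AM-TMP, AM-LOC, ...) and higher-numbered core arguments
  are deliberately unused.
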