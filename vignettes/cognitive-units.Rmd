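---
title: "Learning cognitive units and predicting eye fixations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning cognitive units and predicting eye fixations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogseg)
```

This vignette is the package's account of its models: what is assumed,
which knobs matter, and where design choices were genuinely open.

## Reading units and the linking hypothesis

The package starts from the view that the units of reading are not fixed
at the word level: the mental lexicon plausibly stores subword pieces,
words, and frequent multiword sequences alike, and first-pass eye
fixations land near the centers of whichever units the reader is
currently using. Under that linking hypothesis a segmentation of a text
into units makes a concrete, falsifiable prediction: each unit receives
exactly one first-pass fixation, located at the center of its character
span and credited to the word containing that center. A word covered by
the tail of a larger unit is predicted to be skipped; a long word split
into two units is predicted to be fixated twice.

The rule is deliberately bare. Perceptual-span asymmetry, refixation
correction after bad landings, and predictability effects all influence
real fixation locations, but modelling them would smuggle eye-movement
knowledge into what is meant to be a segmentation-only prediction, so
they are intentionally left out. The only concession to perception is the
optional maximum unit length, swept by `length_sweep()`: if real units
are bounded by the perceptual span, prediction quality should peak near
that bound.

Two center cases need a convention the linking idea itself does not fix.
A unit of even effective length has its center on a boundary between two
characters; a multiword unit can have its center on an internal space.
When the two characters flanking the center belong to one word, that word
takes the fixation (this covers the canonical "i have" example, centered
between *h* and *a*, predicting a skip of "i"). Otherwise the fixation
goes to the word contributing more characters to the unit, and an exact
tie goes to the right-hand word — a forward-bias tie-break consistent
with the rightward direction of reading. Tie cases are rare (they require
a perfectly balanced unit) but the choice is visible in tests, so it is
stated here as a package convention rather than a claim about readers.

## Text model

All models operate on normalised text: lowercase, diacritics stripped by
canonical decomposition, punctuation turned into hard sequence dividers,
and every word token ending in one space. Spaces are boundary markers,
not symbols: no unit starts with a space, units that end at a word
boundary own the following space in both span and form ("do " is a
different unit type from the prefix "do" in "down"), and concatenating
the token forms of any segmentation reproduces the rendered sequence
character for character. That exactness is checked on every segmentation
the package produces and is what makes the fixation-count conservation
property (sum of predicted counts = number of tokens) hold without
exceptions.

Apostrophes adjacent to a letter are kept, so possessives, contractions,
and clitics like Dutch "'t" survive; free-standing apostrophes divide.
Hyphens divide like other punctuation, which splits hyphenated source
tokens into several model words; `build_hyphen_map()` plus
`align_reference_words()` sum model-word counts back onto the single
reference words that word-level eye-tracking exports use.

## The Less-is-Better learner

The learner maintains an ordered lexicon of unit types. Rank — not any
stored count — encodes the model's confidence that a type is a real
cognitive unit. Segmentation is greedy with one look ahead:

* **Larger-first selection.** At each position the longest lexicon entry
  matching the upcoming characters is the default choice; unknown symbols
  come out as singleton tokens.
* **Counterfactual evaluation.** When at least two entries match, the
  longest candidate is tested against the second longest by greedily
  segmenting the following input with each and counting tokens. The
  comparison stops at the first end offset the two paths share: beyond
  resynchronisation both continuations are identical, so the bounded
  horizon loses nothing and keeps the cost linear. Strictly more tokens
  for the longest candidate marks it *Bad* and the runner-up is taken;
  ties favour the longest candidate, which is marked *Good*. No nested
  counterfactuals run inside the lookahead.

After each epoch's batch is segmented, three updates run in order:

* **Memorizing.** Every adjacent token pair within a sequence is sampled
  with probability `p_memorize` (default 0.1); sampled concatenations are
  appended at the lowest rank, as are all novel symbols. Sampling plays
  the role of frequency tracking: frequent pairs are sampled more often,
  at a fraction of the bookkeeping.
* **Re-ranking.** A *Good* type at rank *r* moves to rank
  `ceiling(r * promote_factor)` (default 0.5) and its probation is
  cancelled; a *Bad* type moves to `ceiling(r * demote_factor)` (default
  2), clamped to the lexicon. Multiplicative moves keep the front of the
  lexicon — where established units live — stable while letting tail
  entries move quickly.
* **Forgetting.** Entries in the tail `probation_zone` (default the last
  20%) age by one epoch; entries that reach `probation_period` (default
  3) epochs without a *Good* verdict are removed. Single-symbol types are
  exempt so the alphabet always remains segmentable.

Training samples a `batch_size = 200` sequence batch per epoch, with
replacement for ordinary corpora; on corpora too large to revisit, batches
are taken sequentially and training ends with the material. The stopping
signal for the ordinary mode is the batch's Shannon code length under its
own empirical token frequencies ("encoding bits",
`-sum log2(f(token)/N)`): training stops after `stop_patience = 3` epochs
without a new minimum. Batches are random, so the bits trajectory is
noisy; the patience rule reads "no longer decreases" as "no new minimum
for several epochs", which tolerates that noise without a smoothing
constant. A `max_epochs` cap (default 200) guards runaway configurations.
Several knobs — the exact memorization probability, the probation zone
and period, the re-rank factors — are free hyperparameters of this
implementation; they are surfaced in `lib_config()` with the defaults
above rather than buried.

Whether evaluation runs at every selection and whether re-ranking applies
immediately or per epoch were open design points: the package evaluates
at every selection with at least two candidates and applies verdicts
batched per epoch, which makes an epoch a pure function of the lexicon
state plus the batch and keeps runs reproducible. One consequence of the
epoch-batched update is that types memorized in an epoch first become
usable in the next one. A single seeded RNG stream drives batch and pair
sampling, so a run is fully determined by its configuration.

## The CBL comparator

The Chunk-Based Learner operates on words, not characters. Initially
every word is a chunk; on each adjacent pair the backward transitional
probability `count(left, right) / count(right)` is compared to the
running mean of all such probabilities evaluated so far, and a pair
strictly above the mean merges into a new chunk that immediately replaces
the pair in further processing — so chunks of chunks arise naturally.
The very first evaluation has no average to beat and never merges, a
conservative cold start in keeping with the model's no-hyperparameters
spirit. The running average includes every evaluation event, repeated
pairs included. Training is a single incremental pass (configurable);
test-time segmentation freezes the inventory and scans left to right
with greedy longest match over whole words — the scanning order at test
time is a package decision, as the learner itself only defines the
training pass. CBL never produces subword tokens, so its predictions can
never put more than one fixation on a word except through hyphen splits
handled at alignment.

## Baselines and the metric

*Word-by-Word* predicts one fixation per word. *Only-Length* shuffles the
observed counts within groups of words with the same number of letters,
keeping each group's count multiset identical; since the shuffle is
stochastic, `only_length_score()` reports the mean weighted F1 over 100
shuffles by default (one shuffle reproduces the single-shot protocol).

Scoring treats each distinct observed fixation count as a label and
weights each label's binary F1 by its number of true instances. Labels
come from the observed side only: a count value that is predicted but
never observed has weight zero by construction and affects the score only
through the false positives it inflicts on observed labels; this also
means the zero-division case of binary F1 cannot arise for a weighted
label, and the isolated `binary_f1(0, 0, 0)` is defined as 0. Scores are
percentages reported to two decimals.

Mean observed unit length is inferred from counts alone: if every
fixation sits at the center of one unit and units tile the sequence, a
sequence's mean unit length is its rendered length divided by its total
fixation count. The corpus aggregate weights sequences by their fixation
counts (equivalently, total length over total fixations); an unweighted
per-sequence mean is available as a secondary estimator, and
zero-fixation sequences are excluded. Any within-sequence boundary
placement yields the same per-sequence ratio, so this operationalisation
is as far as counts alone can carry the inference.

## What the synthetic generator does and does not emulate

`make_inventory()` builds a chunk inventory of random word forms over a
small alphabet (12 letters by default, so subword structure is learnable
from modest corpora), multiword chunks composed of those words, and short
subword pieces that concatenate with following chunks into longer written
words, emulating productive morphology. Token frequencies are Zipfian
(`s = 1`) with the multiword chunks placed in the upper half of the
ranks: the multiword units worth positing are precisely the
high-frequency collocations, and the recovery analyses target them.
Corpora are sampled chunk by chunk (3–8 chunks per sequence, 2,000
sequences by default), the generating boundaries are recorded as the true
segmentation, and "observed" fixation tables are produced from the true
segmentation by the same center rule, optionally perturbed by ±1 with a
floor at zero — a pure testing device with no claim about reading noise.

What passing on this world shows: the learner can recover a chunk
inventory from distributional evidence alone, the linking rule and the
metric close exactly (true segmentation scores 100.00 on noiseless
counts), and every conservation property holds at scale. What it does not
show: natural-language performance. The generator has no syntax, no
sequence-level dependencies between chunks, no ambiguity between
competing parses of the same characters beyond what random collisions
produce, and its noise is symmetric and independent — all unlike real
reading data. Occasionally a subword chunk precedes a multiword chunk, so
a "multiword" token can start mid-written-word; this is harmless for the
linking rule but slightly harder than natural morphology. Scores on
synthetic worlds are therefore comparable across models within the world,
not across to published corpus results.

## Problem sizes and runtime choices

The test suite exercises the oracle equivalences on 500 random
lexicon/string instances, the metric oracle on 1,000 random confusion
triples, conservation on a 1,000-sequence world, and full parameter
recovery on the default 2,000-sequence world (about ten seconds of
training); `scripts/acceptance.R` reruns the full pipeline on the default
world in about a minute. These sizes were chosen so the whole suite stays
interactive while the recovery analysis still runs at the generator's
default study conditions.

## Known limitations

* The learner's hyperparameter defaults are declared, not fitted; no
  sensitivity analysis ships with the package.
* Counterfactual evaluation compares only the top two candidates; a
  third-longest entry that would beat both is never considered, by
  design.
* The exact minimal-token segmentation (dynamic programming) is not what
  the model computes — greediness plus one counterfactual is the
  cognitive claim — so token counts are not guaranteed minimal.
* Only first-pass fixation counts are modelled; regressions, re-reading,
  and fixation durations are out of scope.
* Non-alphabetic scripts (e.g. Chinese) and any tokenisation beyond
  space/punctuation handling are out of scope.
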