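---
title: "Extracting time-event-description triples from Chinese clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting time-event-description triples from Chinese clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The extraction problem

A History-of-Present-Illness narrative records what happened to one patient
as a sequence of period-delimited statements, each a chain of short
comma-separated clauses: a temporal phrase, one or more medical terms,
possibly a negation, possibly a free-text description ("3天前咳嗽，色黄。").
The target structure is the set of (time, event, description) triples: the
time is a surface temporal expression (not a normalized date), the event is
a dictionary term the patient actually experienced, and the description is
an optional clause elaborating the event — a sputum colour, a spirometry
reading.

General-purpose Chinese segmenters degrade badly on this register, so the
whole framework is character-based and dictionary-driven.  That choice
recurs everywhere below: "words" in context windows, look-backs and
features are *characters*, including punctuation.

## Lexica and their enrichment

Six categorized lexica (disease, symptom, drug, body part, procedure,
clinical test) are held in a `lexicon_set` with one provenance tag per
(term, category) pair; a term may belong to several categories, and the
first recorded provenance wins, so core terms are never silently relabelled
by later enrichment.

The bootstrap enriches the disease and drug lexica only: their local
contexts are discriminative ("诊断为…", "给予…"), whereas the other
categories mostly occur before an uninformative colon.  Each iteration
harvests the up-to-3×3 grid of literal character contexts around every
tagged occurrence of the target category (nine patterns per occurrence with
full context; truncated and deduplicated at document boundaries), then
scores each pattern:

* `PS` — unique extracted fillers already in the lexicon ("correct" means
  present as of the *previous* iteration, core plus earlier accretions);
* `PP` — `PS` divided by all unique extracted fillers, undefined when the
  pattern extracts nothing.

All three thresholds are strict (`PS > PST`, `PP > PPT`, `TF > TFT`),
matching their verbal definitions — with `TFT = 1` a term must be extracted
by *more than one* accepted pattern.  The package defaults are the
grid-searched optima `PST = 7, PPT = 0.7` (disease) and `PST = 6,
PPT = 0.85` (drug); `grid_search_thresholds()` re-runs the search over
PST 3–10 × PPT 0.30–0.90 (step 0.05), breaking F1 ties toward the more
conservative pair (higher PPT, then higher PST).

Slot fillers are matched shortest-first per anchor with a default length
cap of 10 characters and a clause-punctuation bar.  The source procedure
leaves the slot unbounded; unbounded greedy matching would swallow whole
clauses, and shortest-match is the only deterministic choice that
reproduces the worked context examples.  Pattern harvesting draws on every
tagged occurrence of the slot category, not only core-lexicon occurrences;
provenance tags make the stricter policy recoverable post hoc.

## Compound terms

Two Chinese writing conventions produce terms no static dictionary holds.

*Enumerations*: in `B1、B2 D` (body parts sharing a trailing term) and
`B D1、D2` the compounds `B1D` / `BD2` are implied but not written.  The
package accepts the directly adjacent pair outright (when its concatenation
is not already a dictionary term) and gates every distributed pair by the
corpus adjacency probability `P(D follows | B)` — adjacent co-occurrence
count over total `B` occurrences — against a threshold (default 0.01).
The conditional-on-B denominator is a package choice; the source text
names only "the probability of a B term followed by a D term".  Drugs are
excluded from the D side: compound drug names do not take body-part
prefixes.  Distributed compounds are inherently non-contiguous; their
`surface` is the concatenation of the components while their offsets cover
the enumeration region, and a `contiguous` flag separates the two cases.

*Directional/extensional prefixes*: 左/右/双/上/下/侧/内/外/全 extend known
terms (左侧输尿管结石).  A three-character look-back absorbs the longest
suffix of the window decomposable into configured prefix strings; the
vocabulary is an editable seed list, not a closed class.  Expansion is
idempotent whenever the directional run is at most the look-back width,
which holds for the documented examples and for generated corpora; longer
runs would extend again on a second pass.

## Tagging and event filtering

`tag_terms()` implements the published longest-match procedure exactly:
candidate lengths from longest to shortest, start positions left to right,
and a Boolean "tagged" array consulted only at a candidate's *first and
last* character.  This boundary-only check is reproduced as printed — it
permits a shorter term nested strictly inside the untouched middle of a
longer, failed region, and the test-suite oracle encodes the same rule
independently.  Substrings found in several dictionaries emit one span per
category; nothing in the procedure justifies a priority order.

Mentions are then filtered: a symptom, procedure or clinical-test span is a
non-event when a negation (无, 拒绝, 否认, 未见) or future marker (拟,
建议) precedes it inside the same clause (between ，、。；： boundaries) —
the narrowest faithful reading of "prefixed with".  Diseases and drugs are
always events; body-part spans never are on their own (they exist to feed
assembly).

## Temporal expressions and scoping

Two regular-expression forms over editable vocabularies cover durations
(`(Pre-AW)? Numbers (Unit)? TemporalUnit (Post-AW)? Preposition`, e.g.
约3个月前) and day references (`Day (Period)? ((Pre-AW)? Point
(Post-AW)?)?`, e.g. 昨天下午3点左右), plus six idioms (昨夜, 昨晚, 今夜,
今晚, 今早, 今晨).  Numbers match Arabic, full-width and Chinese numerals;
no calendar normalization is attempted — events link to temporal *surface*
terms.  Overlapping matches resolve longest-first at each position.

Scoping follows three rules over the statements of a document: a single
time covers its whole statement (including events written before it);
with several times each covers from its own start to the next time's start,
and the prefix before the first time inherits the carried-forward time
(falling back to the first time at document start — the source leaves this
case unstated); a time-less statement inherits the last time seen, and
events before any time in the document get an unspecified time.  Duration
expressions that actually denote periods rather than anchors remain
ambiguous here, as in the source method.

## Description linking

Within a statement, the maximal character runs covered by no span and no
temporal term, stripped of punctuation, are candidate descriptions;
candidates overlapping a non-event span or containing administrative stop
words (入院, 出院, 住院, 就诊, 治疗) are discarded.  Every remaining
(event, candidate) pair *within one statement* is featurized — statement
scope matches the temporal scoping unit and bounds the pair count — with
eight feature groups: 3 characters of context each side of the event and of
the candidate (sentinel-padded at boundaries), a digit flag, the NGD of the
two surfaces, counts of terms / candidates / commas strictly between, and
the event's category.

The NGD is computed from a pluggable frequency provider.  The default
backend counts document frequencies over the working corpus (`M` =
documents, `f(x)` = documents containing `x`, `f(x,y)` = documents
containing both); a cached-count backend serves precomputed (e.g. search
engine) counts offline.  Degenerate cases — any zero frequency, or a term
present in every document — map to a configurable cap (default 10) so
feature vectors stay finite; the log base cancels and natural logs are
used.  `ngd(x, x)` is 0 whenever `f(x) > 0`.

Pairs are classified by a linear-kernel SVM with balanced class weights —
the model family is given, kernel and weighting are package choices —
with one-hot encoding over the training vocabulary (unseen values fall
into an out-of-vocabulary bucket) and standardized numeric features.
Probability calibration is disabled, which makes fits deterministic under a
seed.  All pairs classified true are accepted: one description may serve
several events and vice versa.  Time is attached afterwards from temporal
scoping; the feature set contains no time fields.  The reference baseline
links every event to the nearest candidate that starts at or after it.

## The synthetic corpus

No clinical corpus ships with the package; a seeded generator stands in for
one.  It emulates the *structure* of the narratives: 2–4 statements per
document drawn from templates — time-anchored symptom onsets with optional
description clauses, drug/disease mentions inside shared bootstrap contexts
(给予…抗感染, 予…口服, 诊断为…), clinical-test statements with digit-bearing
readings, negated and future mentions, and two-event statements whose
single description belongs to a *randomly chosen* one of the two events, so
that position alone cannot decide a link and co-occurrence (hence NGD)
must.  Pseudo-terms are built from disjoint per-category character
inventories with realistic suffixes (symptoms end in 痛/肿/…, drugs in
素/林/…), keeping terms disjoint from template glue, temporal vocabulary
and directional prefixes; as a consequence tagging generated text with the
full lexica reproduces the gold spans exactly, which the suite asserts.
Each planted unknown disease/drug is guaranteed at least two distinct
contexts, so it is recoverable at `TFT = 1`.  Description vocabularies are
unique per term — two dedicated strings each — making corpus co-occurrence
maximally informative.

What the generator does *not* emulate bounds what green tests show:
real paragraph-level discourse, abbreviation variants, OCR noise, segmentation
ambiguity inside terms, descriptions shared across many events, and
period-vs-anchor temporal ambiguity are all absent.  Passing tests
demonstrate algorithmic correctness under the stated structural
assumptions, not clinical-grade accuracy on hospital text.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 1,000 random strings (length
≤ 30, 20-character alphabet, 50-term lexicon) for the tagger–oracle
equivalence; a 500-document corpus with 20 planted drugs for bootstrap
recovery at `PST = 3, PPT = 0.5, TFT = 1`; five repetitions of a
~1,000-statement corpus with a 75/25 document split for the linker
benchmark (the source protocol trains on 300 of 400 labelled records and
tests on 100; the seeded 75/25 split is the synthetic analogue); and a
500-document corpus for end-to-end evaluation.  Exact span matching
requires identical offsets and category; inexact requires any character
overlap within the same category; triple matching additionally requires
equal time surfaces and identical description intervals (an
overlap-tolerant description variant is deliberately not the default, since
partial description credit is undefined in the source).  Greedy one-to-one
matching pairs predictions with gold without replacement.

Known limitations: the boundary-only blocking of the tagger is faithful but
can nest shorter terms inside failed longer regions; adjacency statistics
need a corpus large enough that one context family occurs more than a
handful of times (at very small scales no pattern clears `PS > 3`, and the
bootstrap correctly adds nothing); the event filter is rule-based and
clause-local, so long-range negation escapes it; and temporal expressions
are linked as surfaces, never normalized to a timeline.
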