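---
title: "Methods: taxon search, climatic niches and semantic expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxon search, climatic niches and semantic expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioexplore)
```

This vignette documents the models and procedures behind `bioexplore`, the
choices made where the design was genuinely open, and what the synthetic
data used in the tests does and does not establish about real data.

## Taxonomic backbone and search

The backbone is a simplified GBIF-style export: each record has an opaque
id, a scientific name, one of the seven major ranks (kingdom, phylum, class,
order, family, genus, species) and a parent id. Intermediate ranks are
rejected at load time: the seven-step rank ladder is what the rank colour
scale (red for species through blue for kingdom) and the "6 shared ancestors
+ k leaves" tree arithmetic are defined over, and admitting subfamilies or
tribes would make both rank-dependent behaviours ambiguous. The loader
enforces the structural invariants (parents present, parent rank strictly
higher, chains ending at a kingdom), so everything downstream can assume a
well-formed forest.

**Matching rule.** `suggest()` uses case-insensitive substring matching
against the full scientific name and against each vernacular name. A single
substring rule reproduces both observed behaviours of interactive taxon
search bars: prefix queries ("hymenopt") match higher taxa and their names,
and infix queries ("nikolay") match specific epithets, because an epithet is
itself a substring of the full binomial. Fuzzy or typo-tolerant matching is
deliberately out of scope.

**Ordering.** Real search backends rank by relevance signals that are not
recoverable offline, so ordering here is a deterministic stand-in:
scientific-name matches before vernacular-only matches, then earliest match
position, then alphabetical scientific name. Every tie is broken, which is
what makes the suggestion list byte-stable for testing.

**Tree semantics.** The session tree is exactly the union of the lineages of
the queried taxa. Merging is idempotent and order-independent (set union),
and a lineage asserting a different parent for a known node is refused as a
mixed-backbone error rather than silently rewiring the tree. Exports are
deterministic (children sorted alphabetically): DOT for rendering, JSON for
lossless round-tripping, Newick for phylogenetic tooling. Newick requires a
single kingdom root; a two-kingdom forest has no Newick representation, and
the error says so instead of inventing a pseudo-root.

## Climatic-niche summary

The climate engine follows four steps: load 9 monthly variables × 12 months
as rasters; bin occurrence points into hexagonal zones; overlay zones on
rasters; and summarise. The summary, per variable, is the **spatial mean
over the occupied cells for each month**, the **annual mean** of those
twelve monthly means, and their **min and max** as the displayed range.

Open choices, resolved as follows:

* *Range semantics.* "Min/max over the monthly distributions" could mean the
  twelve monthly spatial means or every raw cell × month value. The default
  is the monthly means, because the range accompanies a monthly-averaged
  metric and should be commensurate with it; `range_over = "cells"` gives
  the other reading.
* *Elevation* has no seasonal cycle but travels through the same monthly
  pipeline: a single elevation grid is accepted and replicated across the
  twelve months, keeping every code path uniform.
* *Weighting.* Cells are unweighted by occurrence counts: the quantity of
  interest is the climate across the taxon's range, not across its sampling
  density. Counts are retained on zones for future weighted variants. A cell
  covered by two zones is counted once (union semantics), which also makes
  the summary invariant under zone duplication.
* *Nodata.* Cells equal to the layer's sentinel are excluded before
  averaging. A variable with no valid cell in any month is reported
  *missing*, never as zero — zero is a legal climate value.
* *Geometry.* Coordinates are plate carrée lon/lat throughout; polygons that
  straddle the antimeridian are rejected with an explicit error rather than
  being averaged across the wrong hemisphere. Point-in-polygon inclusion is
  cell-centre based, with boundary centres counted as inside.

Hexagonal binning uses a flat-topped axial grid anchored at the origin with
a user-set circumradius; a point belongs to the hexagon with the nearest
centre (cube rounding), so the zones partition the plane and point counts
are conserved. Rasters are read from ESRI ASCII grids, a plain-text format
that keeps fixtures human-readable and the reader dependency-free.

## Semantic expansion

Entities come in four categories — taxon, biological process, habitat,
measurement — supplied as one label list per category. Labels are lowered
and underscore-joined into tokens (`Vespa soror` → `vespa_soror`), and the
corpus is *phrased*: greedy longest-leftmost replacement of entity word
sequences by their tokens, so multi-word entities become single embedding
tokens. Greedy leftmost with longest-at-position is the simplest
deterministic resolution of overlapping mentions and matches how standard
phrase tools behave on non-overlapping text.

Embeddings are trained with skip-gram and negative sampling: 5 negative
samples from the 0.75-power unigram distribution, dynamic context window
(uniform 1..window), linear learning-rate decay from 0.025, and a dedicated
xorshift generator so that a given seed yields bitwise-identical vectors on
every run and platform. Determinism is non-negotiable here: the
compatibility scores below are only testable if the model is. Defaults
(dimension 32, window 5, 5 epochs, `min_count` 1) are sized for the small
corpora this package trains on; production-scale literature corpora would
use larger dimensions and a `min_count` above 1.

**Compatibility score.** For a query word, the model's entries containing
that word (whole underscore-segment containment by default, so "vespa"
matches `vespa_mandarina` but not `vespavirus`; substring mode behind a
flag) are collected — N of them. An entity's score is 100 × the minimum
cosine similarity between its vector and those N entries' vectors. The
minimum, not the mean, expresses "compatible with *all* entries containing
the query". Two boundary decisions: scores are raw cosines × 100, so they
live in [−100, 100] — no floor or rescaling is applied because 100 is
defined as perfect similarity and negative cosines are informative; and when
the entity's own token is among the entries it is excluded from the minimum
(unless it is the only entry), otherwise every entity would trivially score
100 against a query equal to its own token.

**Multi-anchor queries** combine per-anchor scores by taking the minimum
over anchors. This extends the min-based single-anchor definition and gives
the monotonicity a "constrained by both" semantics requires: adding an
anchor can never raise a score. `expand_entities()` ranks the requested
categories' entities by combined score, descending, ties alphabetical,
capped at `top_k` (default 20). N is uncapped.

## Synthetic data: what it emulates, and what it does not

The generators produce the study conditions for every test:

* **Backbones**: pseudo-Latin names built from syllable templates (checked
  against the packaged worked-example names and query strings so they can
  serve as distractors), all genera sharing kingdom–order and each genus its
  own family. That topology makes the bifurcation arithmetic exact: k
  congeners plus one distant species bifurcate exactly once, at the order.
* **Rasters**: per-variable monthly base values (a temperate seasonal cycle
  by default) plus a zero-mean west–east gradient, so every layer's spatial
  mean is analytically known and recorded in a manifest; optional nodata
  holes exercise the missing-data paths.
* **Corpora**: every sentence embeds exactly two entity mentions at most
  three words apart (inside the default window), drawn from the same planted
  group with probability `within_group_rate` (default 0.8), padded to eight
  filler words from a 50-word lexicon. Two mentions per sentence — not a
  variable count — keeps the planted co-occurrence signal analysable;
  a 0.8 within-group rate gives the clear topical clustering that a
  literature corpus sorted by subject exhibits, while leaving enough
  cross-group mixing that recovery is not trivial. Entity categories cycle
  within each group with a per-group offset, so all four categories are
  populated and groups span categories; partner-recovery checks therefore
  rank across all categories, since a 5-entity group has no guaranteed
  same-category partner.

Passing tests on these fixtures establish the *mechanics* — conservation,
invariances, exact agreement with brute-force oracles, recovery of planted
structure — not performance on real data. Real backbones carry intermediate
ranks and synonymy that this package deliberately rejects; real occurrence
data have spatial sampling biases the unweighted mean inherits; and real
literature corpora have polysemy, morphology and frequency skew that a
5,000-sentence planted corpus does not emulate. Scores printed by any
production system trained on a proprietary corpus are not reproducible here
and are not targets of the test suite.

## Numerical and scale choices

Test problem sizes are chosen to keep the full suite comfortably
desk-scale: grids of a few hundred to a few thousand cells, corpora of
300–10,000 sentences, 20-seed replications for the stochastic recovery
check, 50-seed replications for the exact-oracle checks. Brute-force oracles
agree with the implementation to 1e−9 relative (climate, where sums of
hundreds of doubles accumulate rounding) and 1e−12 absolute (cosines, a
handful of operations). Constant-raster summaries are exact because a mean
of identical representable values is exact. Degenerate inputs fail loudly:
empty queries, empty point sets, all-nodata windows, out-of-vocabulary
anchors and multi-kingdom Newick requests all raise targeted errors rather
than returning silent defaults.
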