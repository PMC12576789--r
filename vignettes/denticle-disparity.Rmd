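---
title: "Coding denticle morphology and measuring disparity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding denticle morphology and measuring disparity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denticode)
```

## The problem

Dermal denticles — the microscopic placoid scales that cover shark and ray
skin — are abundant microfossils and a rich source of ecological and
evolutionary signal, but they are almost always recovered disarticulated,
often broken, and imaged with heterogeneous techniques. Comparing them
across studies requires a shared, discrete morphological vocabulary and a
dissimilarity measure that tolerates missing information instead of being
distorted by it. `denticode` implements such a system: a versioned
character schema, validated coding sheets, a weighted missing-data-aware
disparity, morphotype identification, and NMDS ordination of the resulting
morphospace.

## The character schema

Version `denticles_v0.5` defines 46 discrete characters in 15 groups:
overall crown shape (A), anterior/posterior margins (B, C), symmetry (D),
cusps (E), ridge system and ridge counts (F–H), central and non-central
ridges (I, J), the central ridge system shape (K), ridge size (L),
depressions and dimples (M), secondary surface textures (N), and the
subcutaneous base (O). Each trait carries:

* an ordered set of integer **states** with verbal labels;
* a **weight** in {0.5, 1, 2}. The first character describing a feature
  carries weight 1 (the two most diagnostic characters, overall crown shape
  A1 and ridge system F1, carry 2), and nested characters that merely
  elaborate a feature carry 0.5, so the absence of, say, ridges is not
  counted a dozen times over;
* a symmetric **state-distance matrix** over the non-zero states.

State **0** is a sentinel with two readings that are treated identically in
analysis: the character is broken/unobservable, or it is inapplicable
because a controlling character lacks the feature (no cusps, hence no cusp
shape). Zero states are excluded from every pairwise comparison and a
distance involving 0 is a distinct "not comparable" value (`NA`), never a
numeric 0, so missingness can never masquerade as similarity.

**Nesting rules** make the controller/dependent relationships explicit:
for example a smooth crown (`F1 = 1`) pins every ridge descriptor, and
`E1 = 1` (no cusps) pins `E2`–`E4`. Three implications beyond the obvious
ones follow directly from the printed state definitions and are encoded as
rules too: non-spade crowns pin the spade subtype (`A2 = 0`), a crown with
no central ridge pins the central-ridge descriptors (`I1 = 1` ⇒
`I2 = I3 = 0`), and non-dimple depressions pin the dimple shape
(`M2 ∈ {1, 2}` ⇒ `M4 = 0`). The validator enforces range, nesting, and the
lower-score-first convention for the B2/C2 margin textures on denticles
without directionality.

### From verbal descriptions to numbers

The per-trait disparity descriptions are verbal orderings ("more similar",
"equally different", "very different from all other"). We map that
vocabulary onto integers 0–4 (`descriptor_scale()`) and build each matrix
with `build_matrix_from_descriptors()`; ordinal traits specified as
one-step chains are completed by min-plus shortest path, which expands a
chain to |i − j| unit steps and keeps every filled entry consistent with
the triangle inequality inside the trait. Two properties are worth
stating plainly:

* Only the *orderings* are guaranteed. Any strictly monotone mapping
  preserves them, and `load_schema()` accepts external JSON/YAML schema
  files, so an alternative numeric convention (for example a canonical set
  of matrices curated elsewhere) can be dropped in without code changes.
  `matrix_ordering_checks()` evaluates 58 transcribed orderings against
  whatever schema is loaded.
* The shortest-path completion caps long ordinal chains that pass through a
  flat "very different" row: with eleven cusp-count states, one cusp vs
  ten-or-more is capped at 6 rather than 9. We prefer this to an
  unbounded chain because it keeps a single trait from dominating the
  normalized disparity, at the cost of flattening the extremes of ordinal
  traits with many states.

The bundled `denticles_v0.5.json` is generated once from the curated
descriptor tables and frozen; a unit test asserts the file and the
generator stay identical. Historical versions v0.1/v0.2/v0.4 load as
flagged stubs (structure only), and `bump_version()` implements the
versioning convention: +0.1 for added states, +1 for added characters.
One open point we resolved: ridge length state `L1 = 1` ("no ridges") is an
ordinary codable state (it is 1, not 0), so it *does* participate in
distances; its row is "very different" from the ridge-length classes.

## The disparity measure

For codes $a, b$ let $S = \{t : a_t \neq 0 \wedge b_t \neq 0\}$ — the
shared codable traits ("Venn overlap"). Raw disparity is

$$ \mathrm{raw}(a,b) = \sum_{t \in S} w_t \, d_t(a_t, b_t), $$

and the default normalized disparity divides by the maximum attainable
weighted distance over the *same* shared set,

$$ D(a,b) = \frac{\sum_{t \in S} w_t\, d_t(a_t,b_t)}
                 {\sum_{t \in S} w_t\, \max d_t} \in [0, 1]. $$

The pair-specific denominator is the point of the design: a heavily broken
fossil compared over 12 traits and a pristine specimen pair compared over
46 live on the same scale. When $S$ is empty (or can attain no distance),
the pair is **undefined** (`NA`) — reported, never imputed; downstream
ordination refuses undefined pairs and `prune_undefined()` removes the
fewest specimens needed. A raw (unnormalized) mode is kept for
diagnostics, `trait_contributions()` decomposes any pair by trait, and
`character_jackknife()` re-runs the analysis with characters or whole
groups removed (dropping a trait renormalizes over the reduced maximum, so
dropping an agreed trait changes normalized values only through the
denominator; dropping group O from crown-only fossil data changes nothing
at all).

Whether normalization should be per-pair or global is not decidable from
first principles; both modes exist and per-pair is the default for the
reason above.

## Morphotypes

A morphotype is a unique combination of character states. At
`merge_tolerance = 0`, `assign_morphotypes()` groups by exact state-vector
equality (zeros equal only zeros) — a true equivalence relation. At
tolerance 1–2 it merges near-duplicates by single linkage on the number of
differing comparable traits, reflecting the working definition of a
morphotype as codes that are identical or differ in only one or two
specific traits. Trait *counts*, not weighted disparity, drive the
merging, because that is how near-duplication is defined; a
weighted-disparity threshold is available as an option. Canonical codes
are the lexicographically smallest member vectors, which also makes the
partition deterministic. `match_to_catalog()` ranks catalog entries by
disparity to a query code — a broken denticle finds its better-preserved
representative — with undefined matches ranked last and flagged. Gross
types (the 18 visually defined groupings, from "Arrowheads, Airplanes,
Diamonds, and Triangles" to "Other Meandering") are carried as metadata
labels only; they are defined independently of the disparity calculation,
so the package deliberately implements no classifier for them.

## Morphospace

`nmds()` ordinates a disparity matrix by non-metric multidimensional
scaling, minimizing Kruskal stress-1 with monotone regression on ranks and
primary (weak) tie handling — ties are abundant in categorical data, and
weak ties let tied disparities spread apart without stress penalty. The
optimizer is `vegan::monoMDS`, driven with a principal-coordinates start
plus `n_restarts` random starts under a caller-supplied seed; the best
configuration is returned with its stress and a non-increasing restart
trace. Defaults: `k = 3` (the dimensionality used for published denticle
morphospaces), 20 restarts, 300 iterations, stress tolerance `1e-6`.
`overlay_grouping()` summarizes per-state centroids and spreads and a
between/within ratio, which quantifies the observation that the ridge
system (F1) is a strong indicator of morphological similarity while
overall crown shape (A1) is less diagnostic.

## The synthetic generator

No external data ship with the package; everything is exercised with
generated codes. `generate_code()` samples controllers first and
conditions dependents (uniform over non-zero states — the literature
offers no state frequencies, and we do not pretend to taxon-specific
realism). `make_cluster_dataset()` draws centroids that are pairwise
distinct in at least 5 traits, then emits each morphotype as its canonical
exemplar plus members mutated per trait with probability `mutation_rate`.
Two design decisions deserve emphasis:

* **Members stay within the near-duplicate bound.** Mutation proposals are
  per-trait Bernoulli, but at most two (randomly chosen) proposals are
  applied per member, because a specimen deviating in three or more traits
  is, by the definition of a morphotype, a different morphotype — truth
  labels must stay consistent with the concept they label. Nested
  dependents implied by a mutated controller follow it and are not counted
  as separate deviations.
* **Mutation re-repair.** After mutating a controller, dependents pinned
  by the rules are reset and dependents freed by the change are resampled
  to valid non-zero states; members always validate.

`degrade_code()` simulates taphonomic loss by zeroing each zero-capable
trait with probability `breakage_fraction` and re-firing the zero rules;
fossil mode (`base_loss`) zeroes the whole O group, since bases are rarely
preserved. Degradation never changes a surviving state, so a code and its
degraded copy have disparity 0 wherever defined.

The default study conditions used in the acceptance checks — 5 morphotypes
× 10 specimens, mutation 0.05, 40% breakage applied to half the specimens
— produce datasets whose clusters are recoverable (adjusted Rand index
≥ 0.9 at tolerance 2) and whose 3-D NMDS stress is well under 0.15. What
passing these checks shows is that the *machinery* behaves as designed
under realistic missingness; it does not show that real denticle
assemblages are this cleanly clustered, that state frequencies are
uniform, or that real morphotypes are equidistant — none of which the
generator attempts to emulate.

## Numerical choices and limitations

* Distances involving state 0 are `NA` throughout; no numeric sentinel.
* Undefined pairs propagate as `NA` and block ordination loudly.
* Single-linkage merging uses `hclust`/`cutree` at integer thresholds;
  pairs sharing no codable trait are assigned an unreachable distance so
  they never merge directly.
* NMDS stress is restart-dependent to ~10⁻³; invariance checks in the
  test suite use tolerances of that order, and reproducibility is exact
  for a fixed seed.
* Problem sizes in the tests (tens of specimens, 200 randomized engine
  checks) were chosen to exercise every code path while keeping the whole
  suite under half a minute.
* The shipped matrices are one faithful monotone realization of the verbal
  descriptions, not canonical numbers; analyses that depend on exact
  distances rather than orderings should load an explicitly curated
  schema file.

## A worked example

```{r example}
sch <- load_schema("denticles_v0.5")
sch

cfg <- generator_config(seed = 42, n_morphotypes = 5,
                        specimens_per_type = 10, mutation_rate = 0.05)
ds <- make_cluster_dataset(sch, cfg)
dm <- disparity_matrix(ds$codes, sch)
dm

mt <- assign_morphotypes(ds$codes, sch, merge_tolerance = 2)
mt

ord <- nmds(dm, k = 3, seed = 1, n_restarts = 10)
ord
overlay_grouping(ord, ds$codes, "F1", sch)$ratio
```
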