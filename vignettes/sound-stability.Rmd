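---
title: "Estimating sound-group stability and its link to vocal iconicity"
author: "soundstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sound-group stability and its link to vocal iconicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundstab)
```

## The problem

Sound change is usually assumed to be blind to meaning, yet a measurable
share of basic vocabulary keeps resemblance-based form–meaning mappings
(vocal iconicity) across language families. One mechanism that could let
iconic mappings survive is differential *stability*: if the sound groups
that carry iconic associations are also the groups that resist phonetic
replacement, iconic words decay more slowly than arbitrary ones. Testing
that idea needs three ingredients:

1. **SSt** — a per-sound-group stability rate estimated from aligned
   homologous (cognate) word forms across related languages;
2. **Ico** — a per-(concept, group) iconicity coding from a
   cross-linguistic sample, expressed as odds ratios with a
   region-of-practical-equivalence (ROPE) decision rule;
3. **L1** — a small matrix classifying phonetic features as acquired
   *earlier* or *later* in first-language acquisition.

`soundstab` implements all three, joins them into one combined table, and
fits consonant/vowel-stratified regressions of iconic value on stability.
Because the real corpora are external, the package ships a
lexical-evolution simulator with exact ground truth, and every stage is
validated by parameter recovery on simulated data.

## Sound groups and segments

IPA strings are tokenized greedily against a shipped inventory
(`segmentInventory()`); combining diacritics and length marks attach to
the preceding base, tie-bar affricates are single stop-class segments, and
a voiceless ring overrides voicing. Each segment maps to one articulatory
bundle: consonants carry place (five-way: labial, alveolar, palatal,
velar, glottal — dental/retroflex merge with alveolar, uvular with velar),
manner (nasal, stop, continuant, vibrant, lateral — fricatives and
approximants are continuants, trills and taps vibrants), and voicing;
vowels carry height, backness and rounding. Diphthongs are two vowel
segments.

The default registry (`defaultRegistry()`) holds 54 groups: 32 consonant
groups (voicing ×2, manner ×5, manner-by-voicing ×10, place ×5,
place-by-voicing ×10) and 22 vowel groups (height ×3, backness ×3,
rounding ×2, height-by-backness ×9, backness-by-rounding ×4, plus low
front rounded). Five groups — voiced glottals, voiceless nasals, voiceless
laterals, voiceless vibrants, low front rounded vowels — are flagged
`sparseExcluded()` and always reported with `NA` stability, matching
their exclusion from the source analysis for data sparsity. The
enumeration is a reconstruction constrained to total 54 (so that 344
concepts × 54 groups give the published 18 576 combined rows) and to
contain every group named in the source; it is overridable via a TSV with
the same schema.

## Information weighting

Lexical databases store dictionary forms, so recurrent inflection-like
endings would otherwise dominate alignments. Each language gets a trigram
model over its segmented forms, fitted forward (two start pads) and
backward (two end pads). A position's weight is

    min(1, mean(forward surprisal, backward surprisal) / log2(V + 1))

with add-0.5 smoothing over `V + 1` outcomes (`V` = language inventory
size). A segment that is predictable from either direction — as shared
endings are from the word end — gets a low weight; unseen contexts hit the
uniform cap and get weight 1. This is a deliberately simple, fully
specified substitute for gappy multi-context information-content
estimators; the property the pipeline needs (suffix positions weigh less
than stem positions for every simulated suffix lexicon) is asserted in the
test suite rather than assumed.

## Alignment, correspondences, homologue sets

Word pairs are aligned globally (Needleman–Wunsch, linear gap penalty −1,
compiled in C++ for the ~10^5–10^6 pairs a run needs). Traceback ties
break deterministically: match/mismatch, then a gap on the left, then on
the right. The test suite checks optimality against a brute-force
enumeration oracle on small inputs.

Correspondence scores start from feature-based values (identical +2, same
place and manner +1, same major class 0, cross-major −2) and are
re-estimated iteratively: align all cross-language same-concept pairs,
keep the best 70% by length-normalized score, and recompute every score as
the PMI `log2(p(a,b)/(p(a)p(b)))` of aligned non-gap pairs with add-0.1
smoothing, clipped to ±3. Three iterations are the default; on fixture
data the table reaches an exact fixed point well before ten.

Homologue sets are formed per concept by average-linkage clustering of the
distance `1 − score(f,g)/mean(score(f,f), score(g,g))` (clipped to [0, 1])
cut at 0.45. At 50-concept scale the PMI table is sparse — segment pairs
never seen co-aligned sit at the −3 clip — so the distance is harsh on
strongly diverged subfamilies; the bundled recovery check therefore runs
the clusterer at within-family divergence (uniform intensity 0.3, branch
length 0.15: distant pairs still share roughly two thirds of their
segments, between the worked example's closely related pair at 0.79 and a
cross-family 0.25). B-cubed F against the simulator's true sets is
asserted ≥ 0.85 there.

## The SSt statistic

For every unordered language pair, all cross-language form pairs inside
each homologue set are aligned. The pair's stability `s` is the
information-weighted share of aligned both-segment cells with identical
tokens ("identical" means the full token, diacritics included); its
complement `1 − s` is the pair's replacement rate. Two biases motivate the
weighting scheme:

* closely related languages would otherwise flood the counts, so every
  instance is weighted by the pair's replacement rate (a pair at
  `s = 0.791` counts each instance at 20.9% of a full sound pair, and an
  identical pair contributes nothing);
* recurrent morphology would otherwise be over-counted, so every instance
  is also weighted by its information content.

Each aligned cell is then tallied once per side into four outcomes for
every group containing that side's segment: *stable* (identical token),
*shift in group*, *shift out of group*, *loss or gain* (gap). SSt is the
weighted share of the first two. The decomposition is conservative (the
four proportions sum to one) and scale-free (rescaling all info weights
changes nothing), and both properties are asserted exactly in the tests.
If no pair has any replacement the weighting annihilates every count and
all groups are `NA` — the documented degenerate case.

Stability is treated as symmetric per unordered pair; gap cells are
excluded from `s` (the "aligned segment pairs" of the worked tallies read
most naturally as both-segment cells) but enter the group tallies as
loss/gain.

## Iconicity coding

Occurrence is presence/absence per (language, concept) slot — any synonym
containing the group makes the slot positive. For each (concept, group)
cell with `k` positive of `n` attesting languages against a baseline of
`K` positive of `N` slots over all concepts, the posterior is a flat-prior
Beta-Binomial contrast: `p ~ Beta(k+1, n−k+1)`, `q ~ Beta(K+1, N−K+1)`,
OR draws `odds(p)/odds(q)`, summarised by the median and the equal-tailed
95% interval. The *iconic value* is the centre of that interval. The
classification follows the ROPE rule: *strong* needs a centre of at least
1.25 with the whole interval above the ROPE (default `(1/1.25, 1.25)`,
symmetric on the log scale and aligned with the 25% threshold); *weak*
needs the centre over 1.25, a log-OR interval excluding zero
(`ci_low > 1`) and a median above the ROPE. Rows with `k = 0` are never
noteworthy: with flat priors and `n ≪ N` an absent group gets a huge OR
purely from the prior, and a group that never occurs in a concept cannot
be overrepresented there. Rows with iconic value below 1
(underrepresentations, largely mirror images of overrepresentations) are
removed after classification; the pre-filter row count is kept as
metadata.

## Combined table and regressions

The combined table is the full cross product of the iconicity table's
concepts with the registry (so 344 concepts × 54 groups = 18 576 rows),
joined with per-group SSt (`NA` for sparse-excluded or unobserved groups)
and the five per-axis L1 codings. A group is coded on an axis exactly when
its defining conjunction entails a value coded in the acquisition matrix —
so `voiced stop` is *earlier* on the manner axis and *later* on the
voicing axis, and a single-label query for such a group returns `none`.

Regressions are ordinary least squares of `log(iconic value)` on SSt over
rows with iconic value ≥ 1 and defined SSt, for all data, consonants
only, and vowels only. The response is logged because iconic values are
ratio-scaled odds-ratio centres; a flag allows the raw response. The
simple-regression identity `R² = F/(F + df2)` and the stratum bookkeeping
`n(all) = n(consonants) + n(vowels)` are asserted for every fit.

## The simulator and its ground truth

`simulateWordlist()` evolves one proto-word per concept (CV-alternating,
length uniform on `word_length`) down a balanced binary tree. Along each
edge of length `t` every segment is replaced with probability
`1 − exp(−λ_class · t)`, where λ is set per manner class for consonants
and per height class for vowels; a replacement is a within-class
substitution (α), an out-of-class substitution (β, staying in the major
class with probability 0.9), or a deletion (δ), and insertions are
Poisson. Replacement is segment-wise independent with exponential waiting
times — deliberately no conditioned sound laws, mirroring the estimator's
own assumption. Suffix mode appends a per-language ending drawn from a
small shared inventory *after* evolution, creating genuinely
low-information recurrent material; borrowing copies a donor leaf's form.
Everything is reproducible from one seed.

Ground truth comes in two forms:

* `truth$retention` — per-segment identity retention
  `exp(−λ_g · path)` averaged over leaf pairs, the right oracle for
  position-level identity (checked against Monte-Carlo replicates);
* `trueGroupStability()` — the exact probability that the partner of an
  in-group instance is again in-group, computed from the simulator's
  per-edge transition matrix over the inventory plus an absorbing
  deletion state, with the same replacement-rate weighting the estimator
  uses. This, not identity retention, is the quantity SSt estimates:
  broad groups legitimately sit above their identity retention because
  within-group shifts count as stable. The recovery experiment (20
  languages, 300 concepts, intensities spanning 0.2–2.0, fixed seed)
  asserts Spearman ≥ 0.9 between estimated SSt and this oracle. The SSt
  run uses the simulator's true homologue sets with PMI-learned scores:
  cognate-detection quality is evaluated separately (B-cubed), and mixing
  the two error sources would make the recovery unidentifiable.

### Presets

* **null** — 100 languages, 50 concepts, uniform intensity 1. Calibrates
  the noteworthiness classifier, so it must realise the *null*: branch
  length 2.5 (leaves effectively independent, emulating a
  one-language-per-family sample), fixed word length 5 (otherwise
  longer-word concepts are genuinely enriched for every group), and no
  indels (deletions are heritable through shared branches and correlate
  lengths within a concept). Each of these three choices removes a source
  of *true* enrichment that would otherwise masquerade as classifier
  error; the strong-flag rate is asserted ≤ 2% of pre-filter rows.
* **graded** — 32 languages, 100 concepts, suffixing on, intensities
  ordered nasal < stop < lateral < continuant < vibrant < vowels, the
  coarse stability ordering in which labials, nasals and laterals are most
  stable and sonorous vowels least.
* **coupled** — the graded intensities plus 24 iconic seeds (boost 0.85)
  placed in low-intensity consonant groups and in high vowels, coupling
  iconicity to stability. The end-to-end assertions: ≥ 80% of seeded
  pairs flagged noteworthy, and positive regression slopes with
  p < 0.001 in all three strata.
* **recovery** — the parameter-recovery experiment above.

## Numerical choices

* Info model: add-0.5 smoothing over `V + 1` outcomes; weight capped at
  the uniform surprisal; gap cells take the non-gap side's weight.
* PMI: add-0.1 smoothing, clip ±3, symmetric counting; keep-fraction
  ties resolved by stable order, deterministic given input order.
* Traceback tie-break: diagonal, left-gap, right-gap; candidate values
  are recomputed from identical operands so exact floating-point equality
  reproduces the fill.
* Clustering distance clipped to [0, 1]; non-positive self-scores map to
  distance 1.
* A deletion that would empty a form is skipped; a simulated form can
  never be empty.
* Monte-Carlo posteriors use per-row seeds `seed + i`, making single
  cells and full tables reproducible independently.
* Degenerate inputs: all-identical wordlists yield all-`NA` SSt; a
  widened ROPE classifies nothing as noteworthy; `k = 0` rows are never
  noteworthy.

## Problem sizes and runtime

The bundled experiments are sized for a laptop-class single core: the
recovery preset (20 × 300), the coupled preset (48 × 80), the null
preset (100 × 50, no alignment needed) and the clustering fixture
(10 × 50) together run the full suite in a few minutes, with 4000
Monte-Carlo draws per posterior cell (20 000 where a tighter tolerance is
asserted). These sizes are the package's own validation conditions, not
limits of the method.

## What passing the synthetic tests does and does not show

The simulator emulates tree-structured divergence, class-dependent
replacement rates, recurrent morphology, borrowing and seeded
iconicity — the features the estimators are designed around. It does not
emulate conditioned sound laws, metathesis, semantic shift, dialect
chains, morphological reanalysis, or realistic phoneme frequency
distributions. Recovery on simulated data therefore validates the
statistical machinery (weighting, decomposition, calibration), not the
historical-linguistic adequacy of automated homologue judgements on real
corpora — the source analysis itself treats those as high but evenly
distributed noise. The published regression statistics depend on the
NorthEuraLex corpus, its published homologue judgements and the published
iconicity values, none of which ship here; reproducing them is explicitly
out of scope.
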