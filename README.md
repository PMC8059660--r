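# soundstab

Sound-group stability and vocal iconicity in lexical evolution.

Sound change is assumed to be blind to meaning, yet basic vocabulary keeps
a measurable amount of vocal iconicity (resemblance-based form–meaning
mapping) across language families. One candidate explanation is
differential stability: iconic associations survive where the sounds that
carry them resist phonetic replacement. `soundstab` implements the full
analysis pipeline behind that question:

* **IPA segmentation and articulatory classification** — greedy
  longest-match tokenization, diacritic handling, a 54-group registry of
  articulatory sound groups over five feature classes, and an
  earlier/later first-language-acquisition (L1) matrix.
* **Information-weighted alignment** — per-language forward/backward
  trigram surprisal models that down-weight recurrent inflection-like
  endings; Needleman–Wunsch global alignment (C++ core) with iteratively
  learned PMI sound-correspondence scores; average-linkage homologue
  (cognate) clustering.
* **SSt, the sound-stability statistic** — for each group, the weighted
  share of aligned instances that stay identical or within the group,
  with every instance weighted by *information content × the language
  pair's replacement rate* (a pair with stability *s* = 0.791 counts each
  instance at 1 − *s* = 20.9% of a full sound pair), and the four-way
  outcome decomposition stable / shift in group / shift out of group /
  loss or gain.
* **Iconicity coding** — per (concept, group) presence/absence odds
  ratios with a Monte-Carlo Beta-Binomial posterior, the centre of the
  95% interval as the iconic value, a ROPE decision rule for
  strong/weak noteworthiness, and the ≥ 1 filter.
* **Combined table and stratified regression** — the concept × group
  cross product joined with SSt and L1 codings, and OLS of log iconic
  value on SSt for all data / consonants / vowels.
* **A lexical-evolution simulator** — homologous forms diverging along a
  balanced binary tree with per-class replacement intensities, shared
  suffixes, borrowing, seeded iconicity, and exact ground truth
  (including the closed-form per-group stability the estimator targets),
  so every stage is testable without external corpora.

## Worked example

Simulate a 12-language family in which nasals, stops and laterals evolve
slowly and vowels quickly, then run the full pipeline:

```r
library(soundstab)

cfg <- simConfig(n_leaves = 12L, concept_count = 60L, branch_length = 0.2,
                 intensities = c(nasal = 0.3, stop = 0.35, lateral = 0.45,
                                 continuant = 0.7, vibrant = 0.9,
                                 high = 0.9, mid = 1.3, low = 1.7),
                 suffix_mode = TRUE, seed = 14L)
sim <- simulateWordlist(cfg)
wl  <- sim$wordlist
wl
#> Wordlist: 720 forms, 12 languages, 60 concepts
#>   L01 C001 ʔ u t͡ʃ m i
#>   L01 C002 v u ŋ ɑ ʀ m i
#>   L01 C003 ʔ ɐ t m i

pmi <- estimatePMI(wl, initialScores(wl), iterations = 3)
hom <- clusterHomologues(wl, pmi, threshold = 0.45)
sst <- computeSST(wl, hom, pmi)
head(sst$pairs, 3)
#>   language_a language_b         s n_word_pairs n_segment_pairs n_identical
#> 1        L01        L02 0.8638422           54             387         341
#> 2        L01        L03 0.7603682           53             386         305
#> 3        L01        L04 0.6123425            3              23          13
```

Sister languages L01/L02 share 86% of aligned segments, so their
instances are down-weighted to 14% of a full pair. The per-group
stability summary reproduces the expected ordering — laterals, stops and
glottals near the top, low and mid vowels at the bottom:

```r
summ <- summarizeStability(sst$sst)
head(summ[, c("group", "stable", "shift_in", "stability_rate")], 5)
#>            group    stable   shift_in stability_rate
#> 1        lateral 0.7652414 0.15197660      0.9172180
#> 2 voiced lateral 0.7652414 0.15197660      0.9172180
#> 3           stop 0.7464337 0.07569992      0.8221336
#> 4         voiced 0.6366053 0.17225770      0.8088630
#> 5        glottal 0.8070211 0.00000000      0.8070211
tail(subset(summ, !excluded)[, c("group", "stable", "shift_in", "stability_rate")], 3)
#>                group    stable   shift_in stability_rate
#> 47    low back vowel 0.3194299 0.03578346      0.3552134
#> 48    mid back vowel 0.2628770 0.02588414      0.2887612
#> 49 low central vowel 0.2503258 0.00000000      0.2503258
```

Iconicity coding and the stratified regression of log iconic value on
stability:

```r
ico  <- buildIconicityTable(wl, n_draws = 4000, seed = 1, filter = FALSE)
comb <- combineTables(ico, sst$sst)
fitRegression(comb, "consonants")
#>       subset   n  f_stat df1 df2            p         r2    slope intercept
#> 1 consonants 985 90.9298   1 983 1.128357e-20 0.08467016 5.466166  -1.58255
```

Here 985 consonant rows survive the iconic-value ≥ 1 filter and defined
SSt; the positive slope says that, in this simulated family, groups with
higher stability carry systematically higher iconic values — on real data
the same machinery quantifies how far stability explains where iconicity
survives.

See the vignette (`vignettes/sound-stability.Rmd`) for the model,
its assumptions, every tunable parameter, the simulator presets, and the
parameter-recovery design.

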