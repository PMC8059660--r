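# Shared fixtures and independent oracles for the test suite.

# Brute-force global alignment score by plain recursion over all
# alignments; independent of the dynamic-programming implementation.
brute_align_score <- function(a, b, S, gap) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) best <- max(best, rec(i - 1L, j - 1L) + S[a[i], b[j]])
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    best
  }
  rec(length(a), length(b))
}

# tiny two-language wordlist with a perfect k:k correspondence and k
# occurring in roughly one word in two (so its PMI hits the +3 clip)
toy_kk_wordlist <- function() {
  stems <- c("kala", "muna", "kivi", "pesa", "mota", "lumi", "pasi", "veri",
             "kuu", "nimi", "kieli", "suoni", "moti", "meri", "sumi", "tami",
             "sola", "puna", "pura", "vene")
  rows <- data.frame(
    language_id = rep(c("A", "B"), each = length(stems)),
    concept_id = rep(sprintf("c%02d", seq_along(stems)), 2L),
    form = c(stems, stems),  # language B identical: k always corresponds to k
    stringsAsFactors = FALSE)
  # perturb B's vowels deterministically so the wordlist is not degenerate
  rows$form[rows$language_id == "B"] <-
    chartr("aeiou", "eioua", rows$form[rows$language_id == "B"])
  asWordlist(rows)
}

# one Alignment built by hand (weights chosen freely)
hand_alignment <- function(left, right, weights, score = 0,
                           la = "X", lb = "Y") {
  new("Alignment", left = left, right = right, weights = weights,
      score = score, left_language = la, right_language = lb)
}

.finish_sst_for_test <- function(acc, reg) soundstab:::.finish_sst(acc, reg)

# memoised heavy pipeline runs shared across acceptance tests
.acc_cache <- new.env(parent = emptyenv())

acc_coupled <- function() {
  if (is.null(.acc_cache$coupled)) {
    cfg <- defaultPresets()$coupled
    sim <- simulateWordlist(cfg)
    pmi <- estimatePMI(sim$wordlist, initialScores(sim$wordlist),
                       iterations = 3L)
    sst <- computeSST(sim$wordlist, sim$truth$homologues, pmi)
    ico <- buildIconicityTable(sim$wordlist, n_draws = 4000L, seed = 6L,
                               filter = FALSE)
    .acc_cache$coupled <- list(sim = sim, sst = sst, ico = ico,
                               comb = combineTables(ico, sst$sst))
  }
  .acc_cache$coupled
}

acc_recovery <- function() {
  if (is.null(.acc_cache$recovery)) {
    cfg <- defaultPresets()$recovery
    sim <- simulateWordlist(cfg)
    pmi <- estimatePMI(sim$wordlist, initialScores(sim$wordlist),
                       iterations = 3L)
    sst <- computeSST(sim$wordlist, sim$truth$homologues, pmi)
    .acc_cache$recovery <- list(sim = sim, sst = sst,
                                oracle = trueGroupStability(cfg))
  }
  .acc_cache$recovery
}

# the committed moderate-rate clustering fixture (within-family divergence)
acc_moderate <- function() {
  if (is.null(.acc_cache$moderate)) {
    cfg <- simConfig(n_leaves = 10L, concept_count = 50L,
                     branch_length = 0.15,
                     intensities = c(nasal = 0.3, stop = 0.3,
                                     continuant = 0.3, vibrant = 0.3,
                                     lateral = 0.3, high = 0.3, mid = 0.3,
                                     low = 0.3),
                     seed = 101L)
    sim <- simulateWordlist(cfg)
    pmi <- estimatePMI(sim$wordlist, initialScores(sim$wordlist),
                       iterations = 3L)
    .acc_cache$moderate <- list(sim = sim, pmi = pmi)
  }
  .acc_cache$moderate
}
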