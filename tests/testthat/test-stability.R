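test_that("pair stability is the weighted identity proportion", {
  a1 <- hand_alignment(c("p", "a"), c("p", "e"), c(1, 1))
  a2 <- hand_alignment("t", "t", 0.5)
  # weights (1, 1, 0.5), identity (yes, no, yes) -> 1.5 / 2.5
  ps <- pairStability(list(a1, a2), "X", "Y")
  expect_equal(ps@s, 0.6)
  expect_equal(ps@n_word_pairs, 2L)
  expect_equal(ps@n_segment_pairs, 3L)
  expect_equal(ps@n_identical, 2L)
  # all identical -> 1; none identical -> 0
  expect_equal(pairStability(list(a2), "X", "Y")@s, 1)
  a3 <- hand_alignment(c("p", "a"), c("k", "e"), c(1, 0.3))
  expect_equal(pairStability(list(a3), "X", "Y")@s, 0)
  # gap-only alignments are undefined
  a4 <- hand_alignment(c("p", NA), c(NA, "e"), c(1, 1))
  expect_error(pairStability(list(a4), "X", "Y"), "undefined pair")
})

test_that("replacement rate is the complement of stability", {
  expect_equal(replacementRate(0.791), 0.209)
  expect_equal(replacementRate(1), 0)
  expect_equal(replacementRate(0.254), 0.746)
  ps <- new("PairStability", language_a = "fin", language_b = "krl",
            s = 0.791, n_word_pairs = 779L, n_segment_pairs = 5513L,
            n_identical = 3968L)
  expect_equal(replacementRate(ps), 0.209)
})

test_that("outcome accumulation follows the four-way rules", {
  reg <- defaultRegistry()
  p_groups <- c("voiceless", "stop", "labial", "voiceless stop",
                "voiceless labial")
  # identical pair: + weight x rate to stable, once per side
  acc <- accumulateOutcomes(hand_alignment("p", "p", 1), rate = 0.5, reg)
  expect_equal(acc$w_stable[acc$group %in% p_groups], rep(1, 5))
  expect_equal(sum(acc$w_stable), 5)
  expect_equal(sum(acc$w_shift_in) + sum(acc$w_shift_out) +
                 sum(acc$w_indel), 0)
  # p vs b: "stop" gets shift_in from both sides; "voiceless" shift_out
  acc2 <- accumulateOutcomes(hand_alignment("p", "b", 1), rate = 1, reg)
  expect_equal(acc2$w_shift_in[acc2$group == "stop"], 2)
  expect_equal(acc2$w_shift_out[acc2$group == "voiceless"], 1)
  expect_equal(acc2$w_shift_out[acc2$group == "voiced"], 1)
  expect_equal(acc2$w_shift_in[acc2$group == "labial"], 2)
  # p vs gap: p's groups get indel; the gap side contributes nothing
  acc3 <- accumulateOutcomes(hand_alignment(c("p"), NA_character_, 1),
                             rate = 1, reg)
  expect_equal(acc3$w_indel[acc3$group %in% p_groups], rep(1, 5))
  expect_equal(sum(acc3$w_indel), 5)
})

# two-language wordlist whose SSt is computed by hand: info weights are
# forced to 1 by querying models trained on disjoint material
hand_sst <- function() {
  wl <- asWordlist(data.frame(
    language_id = rep(c("X", "Y"), each = 3L),
    concept_id = rep(c("c1", "c2", "c3"), 2L),
    form = c("pa", "tu", "ki", "pe", "tu", "ke"),
    stringsAsFactors = FALSE))
  dummy <- asWordlist(data.frame(language_id = c("X", "Y"),
                                 concept_id = "d", form = "ɔɔ",
                                 stringsAsFactors = FALSE))
  info <- list(X = fitInfoModel(dummy, "X"), Y = fitInfoModel(dummy, "Y"))
  computeSST(wl, trueHomologues(wl), initialScores(wl), info = info)
}

test_that("SSt matches the hand-computed micro-example to 1e-12", {
  res <- hand_sst()
  expect_equal(res$pairs$s, 2 / 3, tolerance = 1e-12)
  expect_equal(res$pairs$n_word_pairs, 3L)
  expect_equal(res$pairs$n_segment_pairs, 6L)
  expect_equal(res$pairs$n_identical, 4L)
  sst <- res$sst
  g <- function(x, col) sst[[col]][sst$group == x]
  expect_equal(g("voiceless stop", "w_stable"), 2, tolerance = 1e-12)
  expect_equal(g("voiceless stop", "sst"), 1, tolerance = 1e-12)
  expect_equal(g("high vowel", "total"), 1, tolerance = 1e-12)
  expect_equal(g("high vowel", "sst"), 2 / 3, tolerance = 1e-12)
  expect_equal(g("low vowel", "total"), 1 / 3, tolerance = 1e-12)
  expect_equal(g("low vowel", "sst"), 0, tolerance = 1e-12)
  expect_equal(g("mid vowel", "sst"), 0, tolerance = 1e-12)
  expect_equal(g("front vowel", "total"), 4 / 3, tolerance = 1e-12)
  expect_equal(g("front vowel", "sst"), 1, tolerance = 1e-12)
  # unobserved groups have zero totals and NA sst
  expect_true(is.na(g("vibrant", "sst")))
})

test_that("proportions are conserved and sst bounded on simulated data", {
  mod <- acc_moderate()
  res <- computeSST(mod$sim$wordlist, mod$sim$truth$homologues, mod$pmi)
  sst <- res$sst
  obs <- sst$total > 0
  sums <- sst$p_stable + sst$p_shift_in + sst$p_shift_out + sst$p_indel
  expect_true(all(abs(sums[obs] - 1) < 1e-9))
  ok <- !is.na(sst$sst)
  expect_true(all(sst$sst[ok] >= 0 & sst$sst[ok] <= 1))
  expect_true(all(is.na(sst$sst[sst$group %in%
                                  sparseExcluded(defaultRegistry())])))
})

test_that("rescaling all info weights leaves s and sst unchanged", {
  reg <- defaultRegistry()
  left <- c("p", "a", "k")
  right <- c("p", "e", NA)
  w <- c(0.9, 0.4, 0.6)
  for (c_scale in c(0.5, 0.1)) {
    a1 <- hand_alignment(left, right, w)
    a2 <- hand_alignment(left, right, w * c_scale)
    expect_equal(pairStability(list(a1), "X", "Y")@s,
                 pairStability(list(a2), "X", "Y")@s)
    f1 <- .finish_sst_for_test(accumulateOutcomes(a1, 0.3, reg), reg)
    f2 <- .finish_sst_for_test(accumulateOutcomes(a2, 0.3, reg), reg)
    expect_equal(f1$sst, f2$sst)
  }
})

test_that("a pair with no change contributes nothing; all-identical data is NA", {
  cfg <- simConfig(n_leaves = 4L, concept_count = 10L,
                   intensities = c(nasal = 0, stop = 0, continuant = 0,
                                   vibrant = 0, lateral = 0, high = 0,
                                   mid = 0, low = 0),
                   insertion_rate = 0, seed = 2L)
  sim <- simulateWordlist(cfg)
  res <- computeSST(sim$wordlist, sim$truth$homologues,
                    initialScores(sim$wordlist))
  expect_true(all(res$pairs$s == 1))
  expect_true(all(is.na(res$sst$sst)))
  expect_true(all(res$sst$total == 0))
})
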