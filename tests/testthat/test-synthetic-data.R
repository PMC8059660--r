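test_that("with zero intensities every leaf equals its proto-word", {
  cfg <- simConfig(n_leaves = 6L, concept_count = 15L,
                   intensities = setNames(rep(0, 8L),
                                          c("nasal", "stop", "continuant",
                                            "vibrant", "lateral", "high",
                                            "mid", "low")),
                   insertion_rate = 0, seed = 5L)
  sim <- simulateWordlist(cfg)
  f <- forms(sim$wordlist)
  for (cc in unique(f$concept_id))
    expect_equal(length(unique(f$form[f$concept_id == cc])), 1L)
  expect_true(all(sim$truth$retention$retention == 1, na.rm = TRUE))
})

test_that("simulation is reproducible from its seed", {
  cfg <- simConfig(n_leaves = 8L, concept_count = 20L, suffix_mode = TRUE,
                   borrowing_rate = 0.05, seed = 99L)
  a <- simulateWordlist(cfg)
  b <- simulateWordlist(cfg)
  expect_identical(forms(a$wordlist), forms(b$wordlist))
  expect_identical(a$truth$retention, b$truth$retention)
})

test_that("expected retention has its closed form", {
  expect_equal(expectedRetention(0, 3), 1)
  expect_equal(expectedRetention(log(2), 1), 0.5)
  expect_equal(expectedRetention(2, 0.5), exp(-1))
})

test_that("empirical stop identity matches expected retention", {
  # two leaves one branch from the root; only stops evolve, all replacement
  # is within-class (so stop slots stay stops and are identifiable), no
  # indels: a slot is identical iff neither lineage replaced it, or both
  # replaced it and coincidentally drew the same of the 10 alternatives
  lam <- c(nasal = 0, stop = 0.5, continuant = 0, vibrant = 0, lateral = 0,
           high = 0, mid = 0, low = 0)
  same <- 0L
  total <- 0L
  for (r in seq_len(150L)) {
    cfg <- simConfig(n_leaves = 2L, concept_count = 10L, branch_length = 1,
                     word_length = c(8L, 8L), intensities = lam,
                     replacement_kernel = c(alpha = 1, beta = 0, delta = 0),
                     insertion_rate = 0, seed = 1000L + r)
    f <- forms(simulateWordlist(cfg)$wordlist)
    a <- f$segments[f$language_id == "L01"]
    b <- f$segments[f$language_id == "L02"]
    for (i in seq_along(a)) {
      st <- which(classifySegment(a[[i]])$manner == "stop")
      same <- same + sum(a[[i]][st] == b[[i]][st])
      total <- total + length(st)
    }
  }
  p <- same / total
  ret <- expectedRetention(0.5, 2)           # exp(-lambda * (t1 + t2))
  exp_p <- ret + (1 - expectedRetention(0.5, 1))^2 / 10
  se <- sqrt(exp_p * (1 - exp_p) / total)
  expect_lt(abs(p - exp_p), 3 * se)
  expect_lt(abs(p - ret), 3 * se + 0.016)    # coincidence allowance
})

test_that("path matrix and addresses describe a balanced tree", {
  P <- soundstab:::.path_matrix(soundstab:::.balanced_tree(8L), 0.5)
  expect_equal(dim(P), c(8L, 8L))
  expect_equal(P, t(P))
  expect_equal(P[1L, 2L], 1)          # siblings: 2 edges x 0.5
  expect_equal(P[1L, 8L], 3)          # across the root: 6 edges x 0.5
  expect_true(all(diag(P) == 0))
})

test_that("presets encode the documented study conditions", {
  pr <- defaultPresets()
  expect_equal(nrow(pr$null@iconic_seeds), 0L)
  expect_gt(min(pr$graded@intensities[c("high", "mid", "low")]),
            pr$graded@intensities[["nasal"]])
  expect_equal(pr$recovery@n_leaves, 20L)
  expect_equal(pr$recovery@concept_count, 300L)
  expect_equal(range(pr$recovery@intensities), c(0.2, 2.0))
  expect_equal(pr$recovery@seed, 20200190L)
  # coupled seeds sit in low-intensity groups: every seeded consonant group
  # entails nasal/stop/lateral manners or places; vowel seeds are high
  seeds <- pr$coupled@iconic_seeds
  expect_gt(nrow(seeds), 0L)
  expect_true(all(seeds$boost > 0.5))
})

test_that("closed-form group stability is bounded and ordered by intensity", {
  cfg <- defaultPresets()$recovery
  ts <- trueGroupStability(cfg)
  ok <- !is.na(ts$true_sst)
  expect_true(all(ts$true_sst[ok] >= 0 & ts$true_sst[ok] <= 1))
  v <- function(g) ts$true_sst[ts$group == g]
  expect_gt(v("nasal"), v("continuant"))
  expect_gt(v("continuant"), v("low vowel"))
  expect_gt(v("high vowel"), v("low vowel"))
})

test_that("borrowing copies forms verbatim from a donor leaf", {
  cfg <- simConfig(n_leaves = 6L, concept_count = 30L,
                   borrowing_rate = 0.2, seed = 31L,
                   intensities = setNames(rep(2, 8L),
                                          c("nasal", "stop", "continuant",
                                            "vibrant", "lateral", "high",
                                            "mid", "low")))
  sim <- simulateWordlist(cfg)
  f <- forms(sim$wordlist)
  dup <- 0L
  for (cc in unique(f$concept_id)) {
    forms_c <- f$form[f$concept_id == cc]
    dup <- dup + (length(forms_c) - length(unique(forms_c)))
  }
  expect_gt(dup, 0L)  # at high divergence, repeats come from borrowing
})
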