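test_that("occurrence counts match a hand tally on a toy wordlist", {
  wl <- asWordlist(data.frame(
    language_id = c("A", "B", "C", "A", "B", "C"),
    concept_id = rep(c("eye", "sun"), each = 3L),
    form = c("ma", "mi", "ka", "ku", "pa", "mu"),
    stringsAsFactors = FALSE))
  oc <- occurrenceCounts(wl)
  row <- function(cc, g) oc[oc$concept_id == cc & oc$group == g, ]
  r <- row("eye", "nasal")  # m in ma, mi; not in ka
  expect_equal(r$k, 2L)
  expect_equal(r$n, 3L)
  expect_equal(r$K, 3L)  # ma, mi, mu
  expect_equal(r$N, 6L)
  r2 <- row("sun", "voiceless stop")  # k in ku; p in pa
  expect_equal(r2$k, 2L)
  r3 <- row("eye", "vibrant")
  expect_equal(r3$k, 0L)
  expect_equal(r3$K, 0L)
  # a group present everywhere: vowels are in every form
  r4 <- row("eye", "unrounded vowel")  # a, i, a
  expect_equal(r4$k, 3L)
  # synonyms count once per language-concept slot
  wl2 <- asWordlist(data.frame(
    language_id = c("A", "A", "B", "A", "B"),
    concept_id = c("eye", "eye", "eye", "sun", "sun"),
    form = c("ma", "mi", "ka", "tu", "ti"),
    stringsAsFactors = FALSE))
  oc2 <- occurrenceCounts(wl2)
  r5 <- oc2[oc2$concept_id == "eye" & oc2$group == "nasal", ]
  expect_equal(r5$k, 1L)
  expect_equal(r5$n, 2L)
  expect_equal(r5$N, 4L)
})

test_that("a balanced odds ratio centres near 1", {
  post <- orPosterior(5000, 10000, 5000, 10000, n_draws = 20000L, seed = 9L)
  expect_lt(abs(log(post$median)), 0.05)
  expect_true(post$ci_low <= post$median && post$median <= post$ci_high)
  expect_equal(post$center, (post$ci_low + post$ci_high) / 2)
})

test_that("clear overrepresentation lifts the whole interval", {
  post <- orPosterior(50, 50, 100, 10000, n_draws = 20000L, seed = 9L)
  expect_gt(post$ci_low, 1.25)
})

test_that("posteriors are reproducible and stable in the draw count", {
  a <- orPosterior(12, 40, 300, 2000, n_draws = 20000L, seed = 33L)
  b <- orPosterior(12, 40, 300, 2000, n_draws = 20000L, seed = 33L)
  expect_identical(a, b)
  d <- orPosterior(12, 40, 300, 2000, n_draws = 40000L, seed = 34L)
  expect_lt(abs(d$median - a$median) / a$median, 0.01)
})

test_that("posterior median is monotone in k", {
  med <- vapply(c(5, 10, 20, 30, 38), function(k)
    orPosterior(k, 40, 300, 2000, n_draws = 4000L, seed = 2L)$median,
    numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("noteworthiness follows the ROPE decision rule", {
  expect_equal(classifyNoteworthy(1.5, 1.30, 1.80, 1.55,
                                  rope = c(0.8, 1.25)), "strong")
  expect_equal(classifyNoteworthy(1.28, 1.05, 1.60, 1.325,
                                  rope = c(0.8, 1.25)), "weak")
  expect_equal(classifyNoteworthy(1.3, 1.02, 1.2, 1.11,
                                  rope = c(0.8, 1.25)), "none")
  # widening the ROPE to everything degenerates the classification
  expect_true(all(classifyNoteworthy(c(3, 10), c(2, 8), c(5, 12), c(3.5, 10),
                                     rope = c(1e-9, 1e9)) == "none"))
  expect_error(classifyNoteworthy(1, 1, 1, 1, rope = c(1.5, 2)),
               "configuration error")
})

test_that("the iconicity table is filtered with pre-filter metadata", {
  wl <- simulateWordlist(simConfig(n_leaves = 20L, concept_count = 10L,
                                   seed = 4L))$wordlist
  ico <- buildIconicityTable(wl, n_draws = 1000L, seed = 3L)
  expect_equal(attr(ico, "n_prefilter"), 10L * 54L)
  expect_true(all(ico$center >= 1))
  full <- buildIconicityTable(wl, n_draws = 1000L, seed = 3L, filter = FALSE)
  expect_equal(nrow(full), 540L)
  expect_true(all(full$noteworthy[full$k == 0L] == "none"))
})

test_that("a seeded overrepresentation is flagged strong", {
  # concept "hi" contains a nasal in 30/40 languages; baseline ~ 8/40
  set.seed(8)
  langs <- sprintf("L%02d", 1:40)
  mk <- function(has) ifelse(has, "ma", "ka")
  df <- rbind(
    data.frame(language_id = langs, concept_id = "hi",
               form = mk(seq_along(langs) <= 30), stringsAsFactors = FALSE),
    data.frame(language_id = langs, concept_id = "x1",
               form = mk(seq_along(langs) <= 8), stringsAsFactors = FALSE),
    data.frame(language_id = langs, concept_id = "x2",
               form = c(mk(seq_along(langs) <= 8)[-1], "mi"),
               stringsAsFactors = FALSE),
    data.frame(language_id = langs, concept_id = "x3",
               form = mk(c(rep(FALSE, 32), rep(TRUE, 8))),
               stringsAsFactors = FALSE))
  wl <- asWordlist(df)
  ico <- buildIconicityTable(wl, n_draws = 2000L, seed = 12L, filter = FALSE)
  expect_equal(ico$noteworthy[ico$concept_id == "hi" &
                                ico$group == "nasal"], "strong")
})
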