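stub_sst <- function() {
  reg <- defaultRegistry()
  data.frame(group = groupNames(reg),
             sst = seq(0.2, 0.9, length.out = 54L),
             stringsAsFactors = FALSE)
}

stub_ico <- function(concepts) {
  data.frame(concept_id = concepts, group = "stop",
             center = 1.5, noteworthy = "none", stringsAsFactors = FALSE)
}

test_that("the combined table is the concept x group cross product", {
  comb <- combineTables(stub_ico(c("eye", "sun")), stub_sst())
  expect_equal(nrow(comb), 108L)
  expect_equal(sort(unique(comb$group)), sort(groupNames(defaultRegistry())))
  expect_error(
    combineTables(data.frame(concept_id = "eye", group = "nope",
                             center = 1, noteworthy = "none"),
                  stub_sst()),
    "join error.*nope")
})

test_that("sparse-excluded groups carry NA sst through the join", {
  mod <- acc_moderate()
  res <- computeSST(mod$sim$wordlist, mod$sim$truth$homologues, mod$pmi)
  ico <- buildIconicityTable(mod$sim$wordlist, n_draws = 1000L, seed = 2L,
                             filter = FALSE)
  comb <- combineTables(ico, res$sst)
  expect_true(all(is.na(comb$sst[comb$group == "voiceless nasal"])))
  expect_equal(nrow(comb), 50L * 54L)
  # L1 columns contain earlier/later/none and nothing else
  expect_true(all(comb$l1_manner %in% c("earlier", "later", "none")))
})

test_that("a noiseless linear relation is recovered exactly", {
  rows <- data.frame(concept_id = "c", group = letters[1:20],
                     ico = exp(2 * seq(0.1, 0.9, length.out = 20L)),
                     sst = seq(0.1, 0.9, length.out = 20L),
                     major = "consonant", stringsAsFactors = FALSE)
  # lm warns that the fit is essentially perfect, which is the point here
  fit <- suppressWarnings(fitRegression(rows, "all"))
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$df1, 1)
  expect_equal(fit$df2, fit$n - 2)
})

test_that("OLS summaries match closed-form formulas on a 10-row table", {
  x <- c(0.12, 0.25, 0.31, 0.40, 0.47, 0.55, 0.63, 0.71, 0.84, 0.92)
  ic <- c(1.9, 1.1, 2.4, 1.7, 3.0, 2.1, 3.9, 2.8, 4.4, 3.6)
  rows <- data.frame(concept_id = "c", group = letters[1:10], ico = ic,
                     sst = x, major = "vowel", stringsAsFactors = FALSE)
  fit <- fitRegression(rows, "all")
  y <- log(ic)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  alpha <- mean(y) - beta * mean(x)
  yhat <- alpha + beta * x
  sse <- sum((y - yhat)^2)
  sst_tot <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst_tot
  fstat <- (sst_tot - sse) / (sse / 8)
  expect_equal(fit$slope, beta, tolerance = 1e-9)
  expect_equal(fit$intercept, alpha, tolerance = 1e-9)
  expect_equal(fit$r2, r2, tolerance = 1e-9)
  expect_equal(fit$f_stat, fstat, tolerance = 1e-9)
  expect_equal(fit$p, pf(fstat, 1, 8, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(fit$r2, fit$f_stat / (fit$f_stat + fit$df2), tolerance = 1e-9)
})

test_that("too few usable rows is an error", {
  rows <- data.frame(concept_id = "c", group = c("a", "b"), ico = c(2, 3),
                     sst = c(0.5, NA), major = "vowel",
                     stringsAsFactors = FALSE)
  expect_error(fitRegression(rows, "all"), "insufficient")
})

test_that("under a flat null the slope test is calibrated", {
  set.seed(77)
  rej <- 0L
  for (r in seq_len(200L)) {
    rows <- data.frame(concept_id = "c", group = as.character(seq_len(500L)),
                       ico = exp(rnorm(500L)), sst = runif(500L),
                       major = "consonant", stringsAsFactors = FALSE)
    rows <- rows[rows$ico >= 1, ]
    fit <- fitRegression(rows, "all")
    if (fit$p < 0.001) rej <- rej + 1L
  }
  expect_lte(rej / 200, 0.01)
})

test_that("stability summary sorts by rate with NA groups last", {
  sst <- data.frame(group = c("g1", "g2", "g3"),
                    p_stable = c(0.2, 0.8, NA), p_shift_in = c(0.2, 0.1, NA),
                    p_shift_out = c(0.3, 0.05, NA), p_indel = c(0.3, 0.05, NA),
                    sst = c(0.4, 0.9, NA), stringsAsFactors = FALSE)
  out <- summarizeStability(sst)
  expect_equal(out$group, c("g2", "g1", "g3"))
  expect_true(out$excluded[3L])
  rowsum <- out$stable + out$shift_in + out$shift_out + out$indel
  expect_true(all(abs(rowsum[1:2] - 1) < 1e-9))
})

test_that("L1 separation partitions rows and reports group means", {
  comb <- combineTables(stub_ico(c("eye", "sun")), stub_sst())
  sep <- l1Separation(comb, "manner")
  reg <- defaultRegistry()
  coding <- l1Coding(reg, "manner")
  expect_equal(nrow(sep$earlier), 2L * sum(coding == "earlier"))
  expect_equal(nrow(sep$later), 2L * sum(coding == "later"))
  expect_true(all(grepl("stop", sep$earlier$group)))
  expect_true(all(grepl("continuant", sep$later$group)))
  # an axis where all rows are none yields empty halves and NA means
  vowels_only <- comb[comb$major == "vowel", ]
  sep2 <- l1Separation(vowels_only, "manner")
  expect_equal(nrow(sep2$earlier), 0L)
  expect_true(is.na(sep2$summary$mean_sst[1L]))
})
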